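# qPCR phantom: per-sample CT tables drawn around group means with
# technical noise in cycles.

#' Expression table of CT values
#'
#' @param data data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param housekeeping housekeeping gene name (must be measured for every
#'   sample).
#' @return An `expression_table`.
#' @export
expression_table <- function(data, housekeeping = "Actb") {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(data)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(data$ct))) stop("CT values must be finite")
  hk <- tapply(data$gene == housekeeping, data$sample, any)
  if (!all(hk))
    stop("housekeeping gene ", housekeeping, " missing for some samples")
  structure(data, class = c("expression_table", "data.frame"),
            housekeeping = housekeeping)
}

#' Generate a CT table around group means
#'
#' Per-sample CT = group mean + Gaussian(0, `noise_sd`) cycles.
#'
#' @param group_means data.frame with columns `gene`, `group`, `mean_ct`
#'   (e.g. [qpcr_group_means()]).
#' @param noise_sd technical noise in cycles (0 gives the means exactly).
#' @param n_per_group samples per group.
#' @param seed integer RNG seed.
#' @param housekeeping housekeeping gene (must appear in `group_means`).
#' @return An [expression_table()].
#' @export
generate_ct_table <- function(group_means, noise_sd = 0.2, n_per_group = 6,
                              seed = 1, housekeeping = "Actb") {
  if (!housekeeping %in% group_means$gene)
    stop("housekeeping gene ", housekeeping, " absent from group_means")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  groups <- unique(group_means$group)
  genes <- unique(group_means$gene)
  with_seed(seed, {
    rows <- list()
    for (g in groups) {
      for (i in seq_len(n_per_group)) {
        sid <- sprintf("%s_%02d", g, i)
        for (gene in genes) {
          mu <- group_means$mean_ct[group_means$group == g &
                                      group_means$gene == gene]
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sid, group = g, gene = gene,
            ct = mu + rnorm(1, 0, noise_sd))
        }
      }
    }
    expression_table(do.call(rbind, rows), housekeeping = housekeeping)
  })
}
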