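# Molecular and histological quantification: housekeeping selection,
# delta-delta-CT fold changes, total-protein normalization, positive-pixel
# scoring, Sirius Red collagen fraction, and the group statistics used
# throughout (normality/equal-variance checks, t-test, one-way ANOVA with
# Tukey HSD).

#' Select the most stably expressed housekeeping gene
#'
#' Returns the candidate with the smallest CT standard deviation across
#' all samples; ties break alphabetically (with a message).
#'
#' @param table an [expression_table()].
#' @param candidates candidate gene names (>= 1 present).
#' @return The selected gene name.
#' @export
select_housekeeping <- function(table, candidates) {
  present <- intersect(candidates, unique(table$gene))
  if (!length(present)) stop("no candidate housekeeping gene present")
  sds <- vapply(present, function(g) sd(table$ct[table$gene == g]),
                numeric(1))
  best <- sort(present[sds == min(sds)])
  if (length(best) > 1)
    message("housekeeping tie broken alphabetically: ", best[1])
  best[1]
}

#' Delta-delta-CT relative fold change
#'
#' Per sample, dCT = CT(target) - CT(housekeeping); ddCT is the mean dCT
#' of the comparison group minus the mean dCT of the reference group, and
#' the fold change is `2^-ddCT`. Per-sample relative values
#' `2^-(dCT - mean dCT(reference))` are returned for SEM reporting.
#'
#' @param table an [expression_table()].
#' @param target target gene.
#' @param reference_group,comparison_group group labels (both non-empty).
#' @param housekeeping housekeeping gene; defaults to the table's
#'   attribute.
#' @return List with `fold`, `ddct`, `per_sample` (sample, group,
#'   relative value), and group `sem` of the relative values.
#' @export
ddct_fold_change <- function(table, target, reference_group,
                             comparison_group, housekeeping = NULL) {
  housekeeping <- housekeeping %||% attr(table, "housekeeping")
  if (!target %in% table$gene) stop("target gene absent: ", target)
  if (!housekeeping %in% table$gene)
    stop("housekeeping gene absent: ", housekeeping)
  dct_of <- function(grp) {
    tg <- table[table$gene == target & table$group == grp, ]
    hk <- table[table$gene == housekeeping & table$group == grp, ]
    if (!nrow(tg) || !nrow(hk)) stop("empty group: ", grp)
    m <- merge(tg[, c("sample", "ct")], hk[, c("sample", "ct")],
               by = "sample", suffixes = c("_t", "_h"))
    data.frame(sample = m$sample, group = grp, dct = m$ct_t - m$ct_h)
  }
  ref <- dct_of(reference_group)
  cmp <- dct_of(comparison_group)
  ddct <- mean(cmp$dct) - mean(ref$dct)
  both <- rbind(ref, cmp)
  both$relative <- 2^(-(both$dct - mean(ref$dct)))
  sems <- tapply(both$relative, both$group, sem)
  list(fold = 2^(-ddct), ddct = ddct, per_sample = both,
       sem = sems, target = target, housekeeping = housekeeping)
}

#' Fold-change table across genes with display scaling
#'
#' Computes the ddCT fold change of each target against the reference
#' group, plus per-sample relative expression rescaled so that the lowest
#' expressed gene/group mean equals 1 (the display convention used
#' alongside ddCT reporting).
#'
#' @param table an [expression_table()].
#' @param targets target gene names.
#' @param reference_group reference group label.
#' @return data.frame: gene, group, mean relative expression (reference
#'   scaling and lowest-gene display scaling), SEM, and the fold vs the
#'   reference group.
#' @export
fold_change_table <- function(table, targets, reference_group) {
  groups <- unique(table$group)
  rows <- list()
  for (g in targets) {
    for (grp in groups) {
      r <- ddct_fold_change(table, g, reference_group, grp)
      rel <- r$per_sample[r$per_sample$group == grp, "relative"]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, group = grp, fold = r$fold,
        mean_relative = mean(rel), sem = sem(rel))
    }
  }
  out <- do.call(rbind, rows)
  lowest <- min(out$mean_relative)
  out$display_relative <- out$mean_relative / lowest
  out
}

#' Normalize analyte abundance to total protein
#'
#' @param analyte analyte concentrations (e.g. pg/ml) per sample.
#' @param total_protein total protein (e.g. mg/ml) per sample (> 0).
#' @param group optional group labels for mean +/- SEM summaries.
#' @return Normalized values, or (with `group`) a list with `values` and a
#'   per-group `summary` data.frame.
#' @export
normalize_to_total_protein <- function(analyte, total_protein, group = NULL) {
  if (any(total_protein <= 0)) stop("total protein must be positive")
  if (length(analyte) != length(total_protein))
    stop("analyte and total_protein lengths differ")
  v <- analyte / total_protein
  if (is.null(group)) return(v)
  s <- data.frame(group = unique(group))
  s$n <- vapply(s$group, function(g) sum(group == g), numeric(1))
  s$mean <- vapply(s$group, function(g) mean(v[group == g]), numeric(1))
  s$sem <- vapply(s$group, function(g) sem(v[group == g]), numeric(1))
  list(values = v, summary = s)
}

# RGB (x, y, 3 array) -> list of hue (degrees), saturation, value matrices
rgb_to_hsv_planes <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  i <- d > 0 & mx == r
  h[i] <- 60 * (((g - b) / d)[i] %% 6)
  i <- d > 0 & mx == g & !(mx == r)
  h[i] <- 60 * (((b - r) / d + 2))[i]
  i <- d > 0 & mx == b & !(mx == r) & !(mx == g)
  h[i] <- 60 * (((r - g) / d + 4))[i]
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

in_hue_window <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' Positive-pixel immunostaining score
#'
#' Classifies stained pixels by a hue window and intensity bands
#' (negative / weak / medium / strong, darker = stronger staining) and
#' returns the summed strong-class staining intensity divided by the
#' masked tissue area in square micrometers.
#'
#' @param image RGB array (x, y, 3) in \[0, 1\].
#' @param tissue_mask logical matrix of tissue pixels (non-empty).
#' @param pixel_size_um pixel edge length, um.
#' @param hue_window `c(lo, hi)` degrees of the stain hue (wrapping
#'   allowed), default brown (DAB).
#' @param bands intensity cut-points `c(strong, medium, weak)`: pixel
#'   value below `bands[1]` is strong, etc.
#' @param min_saturation minimum saturation for a stained pixel.
#' @return A `stain_score`: list with `score`
#'   (intensity sum / tissue area), `strong_intensity_sum`,
#'   `tissue_area_um2` and the per-band pixel counts.
#' @export
positive_pixel_score <- function(image, tissue_mask, pixel_size_um = 0.5,
                                 hue_window = c(10, 70),
                                 bands = c(0.45, 0.65, 0.82),
                                 min_saturation = 0.15) {
  if (!any(tissue_mask)) stop("tissue mask is empty")
  hsv <- rgb_to_hsv_planes(image)
  stained <- in_hue_window(hsv$h, hue_window[1], hue_window[2]) &
    hsv$s >= min_saturation & tissue_mask
  inten <- 1 - hsv$v  # staining intensity: darker pixel = more stain
  strong <- stained & hsv$v < bands[1]
  medium <- stained & !strong & hsv$v < bands[2]
  weak <- stained & !strong & !medium & hsv$v < bands[3]
  area <- sum(tissue_mask) * pixel_size_um^2
  structure(
    list(score = sum(inten[strong]) / area,
         strong_intensity_sum = sum(inten[strong]),
         tissue_area_um2 = area,
         n_pixels = c(strong = sum(strong), medium = sum(medium),
                      weak = sum(weak))),
    class = "stain_score")
}

#' Collagen area fraction with blood-vessel exclusion
#'
#' Sirius-Red-class pixels (hue near red, saturated) as a percentage of
#' non-vessel tissue pixels; tissue is any sufficiently saturated pixel,
#' and everything inside the vessel mask is excluded from both numerator
#' and denominator.
#'
#' @param image RGB array (x, y, 3) in \[0, 1\].
#' @param vessel_mask logical matrix of vessel regions to exclude (same
#'   shape as the image planes).
#' @param red_hue `c(lo, hi)` degrees (wrapping) of the collagen hue.
#' @param min_saturation minimum saturation of a tissue pixel.
#' @return Collagen fraction in percent.
#' @export
collagen_fraction <- function(image, vessel_mask = NULL,
                              red_hue = c(330, 25), min_saturation = 0.15) {
  if (is.null(vessel_mask))
    vessel_mask <- matrix(FALSE, dim(image)[1], dim(image)[2])
  if (!all(dim(vessel_mask) == dim(image)[1:2]))
    stop("vessel mask shape must match the image")
  hsv <- rgb_to_hsv_planes(image)
  tissue <- hsv$s >= min_saturation & !vessel_mask
  if (!any(tissue)) stop("no tissue pixels outside the vessel mask")
  red <- in_hue_window(hsv$h, red_hue[1], red_hue[2]) & tissue
  100 * sum(red) / sum(tissue)
}

#' Group comparison with the study's statistical conventions
#'
#' Checks normality (Shapiro-Wilk per group) and equal variance
#' (Brown-Forsythe) at the 0.05 rejection level, then compares groups:
#' two-sided Student's t-test for two groups, one-way ANOVA with Tukey's
#' multiple comparisons for more. Reports group means with SEM and flags
#' significance at P < 0.05.
#'
#' @param values numeric measurements.
#' @param group group label per value (>= 2 groups, >= 2 values each).
#' @param design `"auto"` (by number of groups), `"two_group"` or
#'   `"multi_group"`.
#' @return A `group_comparison`: list with `summary` (group, n, mean,
#'   sem), `assumptions` (normality and equal-variance P-values),
#'   `test`, `p_value`, and `pairwise` (Tukey-adjusted, for the
#'   multi-group design).
#' @export
group_compare <- function(values, group,
                          design = c("auto", "two_group", "multi_group")) {
  design <- match.arg(design)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  ns <- table(group)
  if (any(ns < 2)) stop("singleton group: every group needs >= 2 values")
  if (design == "auto")
    design <- if (nlevels(group) == 2) "two_group" else "multi_group"

  summary_df <- data.frame(
    group = levels(group),
    n = as.integer(ns),
    mean = as.numeric(tapply(values, group, mean)),
    sem = as.numeric(tapply(values, group, sem)))

  normality <- vapply(levels(group), function(g) {
    x <- values[group == g]
    if (length(x) < 3 || sd(x) == 0) return(NA_real_)
    shapiro.test(x)$p.value
  }, numeric(1))
  equal_var <- tryCatch(
    car::leveneTest(values ~ group, center = median)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  assumptions <- list(
    normality_p = normality,
    normality_rejected = any(normality < 0.05, na.rm = TRUE),
    equal_variance_p = equal_var,
    equal_variance_rejected = isTRUE(equal_var < 0.05))

  if (design == "two_group") {
    if (nlevels(group) != 2) stop("two_group design needs exactly 2 groups")
    tt <- t.test(values ~ group, var.equal = TRUE)
    out <- list(summary = summary_df, assumptions = assumptions,
                test = "Student t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, significant = tt$p.value < 0.05,
                pairwise = NULL)
  } else {
    fit <- aov(values ~ group)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL)
    out <- list(summary = summary_df, assumptions = assumptions,
                test = "one-way ANOVA + Tukey HSD",
                statistic = an[1, "F value"],
                p_value = an[1, "Pr(>F)"],
                significant = an[1, "Pr(>F)"] < 0.05,
                pairwise = pw)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, P = %.4g%s\n", x$test, x$statistic,
              x$p_value, if (x$significant) " *" else ""))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}
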