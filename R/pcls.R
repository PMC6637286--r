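# PCLS artery analysis: lumen segmentation by grayscale threshold and pixel
# summation, concentration-response construction as percent reduction of
# initial artery area, and four-parameter logistic fitting for pEC50 and
# maximum contraction.

#' Segment the artery lumen and return its area in pixels
#'
#' Pixels on the dark side of the threshold are candidate lumen; the area
#' is the pixel count of the connected component containing `seed_point`
#' (or the largest dark component when no seed is given). The default
#' threshold is Otsu within the region of interest.
#'
#' @param image 2D grayscale matrix.
#' @param threshold `"auto"` (Otsu) or a fixed intensity.
#' @param seed_point optional `(x, y)` inside the lumen.
#' @param roi optional `c(x, y, w, h)` region of interest for the
#'   auto-threshold.
#' @return Lumen area in pixels (0 with a warning when nothing lies below
#'   the threshold).
#' @export
segment_lumen <- function(image, threshold = "auto", seed_point = NULL,
                          roi = NULL) {
  if (!is.matrix(image) || !length(image)) stop("image must be a matrix")
  sub <- if (!is.null(roi))
    image[roi[1]:(roi[1] + roi[3] - 1), roi[2]:(roi[2] + roi[4] - 1)]
  else image
  thr <- if (identical(threshold, "auto")) otsu_threshold(sub)
         else as.numeric(threshold)
  dark <- image < thr
  if (!any(dark)) {
    warning("no pixels below threshold; lumen area is zero")
    return(0L)
  }
  lab <- label_components(dark)
  if (!is.null(seed_point)) {
    l <- lab[seed_point[1], seed_point[2]]
    if (l == 0) {
      warning("seed point is not inside a dark component; lumen area is zero")
      return(0L)
    }
    return(sum(lab == l))
  }
  max(tabulate(lab[lab > 0]))
}

#' Lumen area trace
#'
#' @param times acquisition times, seconds.
#' @param areas lumen areas, pixels.
#' @param pixel_size optional um per pixel.
#' @return A `lumen_trace` object.
#' @export
lumen_trace <- function(times, areas, pixel_size = NULL) {
  stopifnot(length(times) == length(areas), all(areas >= 0))
  structure(list(times = times, areas = areas, pixel_size = pixel_size),
            class = "lumen_trace")
}

#' Measure the lumen on every frame of a time-lapse
#'
#' @param tl a `pcls_timelapse` (or list with `frames` and `times`).
#' @param ... passed to [segment_lumen()].
#' @return A [lumen_trace()].
#' @export
measure_timelapse <- function(tl, ...) {
  nt <- dim(tl$frames)[3]
  areas <- vapply(seq_len(nt),
                  function(t) as.numeric(segment_lumen(tl$frames[, , t], ...)),
                  numeric(1))
  lumen_trace(tl$times, areas)
}

#' Build a concentration-response curve from a lumen trace
#'
#' The response at each concentration is the percent reduction of the
#' initial artery area, `100 * (1 - plateau / initial)`, where the plateau
#' is the mean area over the final `plateau_frac` of the step window and
#' the initial area is the plateau of the zero-concentration (baseline)
#' step (or `initial_area` when supplied).
#'
#' @param trace a [lumen_trace()].
#' @param steps data.frame with `concentration`, `start`, `end` (seconds);
#'   windows must not overlap.
#' @param plateau_frac final fraction of each window averaged.
#' @param initial_area optional explicit baseline area.
#' @return A `concentration_response`: data.frame of `concentration` and
#'   `response` (percent reduction), with the baseline as attribute.
#' @export
build_concentration_response <- function(trace, steps, plateau_frac = 0.2,
                                         initial_area = NULL) {
  stopifnot(inherits(trace, "lumen_trace"))
  steps <- steps[order(steps$start), , drop = FALSE]
  if (nrow(steps) > 1 &&
      any(steps$start[-1] < steps$end[-nrow(steps)] - 1e-9))
    stop("step windows overlap")
  plateau <- vapply(seq_len(nrow(steps)), function(i) {
    w <- which(trace$times >= steps$start[i] & trace$times < steps$end[i])
    if (!length(w)) return(NA_real_)
    n <- length(w)
    keep <- w[max(1, ceiling((1 - plateau_frac) * n) + 1):n]
    mean(trace$areas[keep])
  }, numeric(1))
  if (is.null(initial_area)) {
    base <- which(steps$concentration == 0)
    if (!length(base))
      stop("no baseline (zero-concentration) step; supply initial_area")
    initial_area <- plateau[base[1]]
  }
  if (!isTRUE(initial_area > 0)) stop("initial area must be positive")
  drug <- steps$concentration > 0
  out <- data.frame(concentration = steps$concentration[drug],
                    response = 100 * (1 - plateau[drug] / initial_area))
  structure(out, class = c("concentration_response", "data.frame"),
            initial_area = initial_area, plateau = plateau)
}

#' Fit a four-parameter logistic concentration-response model
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((logec50 - log10(c)) * hill))`
#' with the response expressed as percent reduction of initial area and
#' the Hill slope constrained positive. Because the response is defined
#' relative to its own baseline, the zero-drug asymptote is 0 by
#' construction; `fix_bottom = TRUE` (default) therefore anchors
#' `bottom = 0`, which removes the instability of extrapolating a free
#' lower asymptote from drug-only data. Returns pEC50 (`-logec50`), the
#' fitted maximum (top plateau) and standard errors.
#'
#' @param cr a [build_concentration_response()] result, or a data.frame
#'   with `concentration` (molar, > 0) and `response` columns; at least 4
#'   distinct concentrations are required.
#' @param fix_bottom anchor the zero-drug asymptote at 0.
#' @param hill_bounds allowed Hill-slope range. Single-receptor
#'   vasoconstrictor responses have slopes near 1; the default `[0.5, 5]`
#'   excludes degenerate shallow fits whose extrapolated top plateau is
#'   unstable on 6-point designs. Widen for atypical pharmacology.
#' @return A `fourpl_fit`: list with `params` (estimates on the
#'   reduction scale), `pec50`, `ec50`, `max_reduction`, `se` (named
#'   standard errors), `fitted`, `residuals` and the underlying `nls`
#'   object.
#' @export
fit_four_pl <- function(cr, fix_bottom = TRUE, hill_bounds = c(0.5, 5)) {
  df <- as.data.frame(cr)[, c("concentration", "response")]
  df <- df[df$concentration > 0 & is.finite(df$response), , drop = FALSE]
  if (length(unique(df$concentration)) < 4)
    stop("need at least 4 distinct concentrations")
  if (diff(range(df$response)) < 1e-8)
    warning("degenerate (flat) concentration-response data")
  df$logc <- log10(df$concentration)
  fit <- tryCatch({
    if (fix_bottom) {
      minpack.lm::nlsLM(
        response ~ top / (1 + 10^((logec50 - logc) * hill)),
        data = df,
        start = list(top = max(df$response), logec50 = median(df$logc),
                     hill = 1),
        lower = c(top = -Inf, logec50 = min(df$logc) - 3,
                  hill = hill_bounds[1]),
        upper = c(top = Inf, logec50 = max(df$logc) + 3,
                  hill = hill_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) /
          (1 + 10^((logec50 - logc) * hill)),
        data = df,
        start = list(bottom = min(df$response), top = max(df$response),
                     logec50 = median(df$logc), hill = 1),
        lower = c(bottom = -Inf, top = -Inf,
                  logec50 = min(df$logc) - 3, hill = hill_bounds[1]),
        upper = c(bottom = Inf, top = Inf,
                  logec50 = max(df$logc) + 3, hill = hill_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) stop("4PL fit did not converge: ",
                              conditionMessage(e)))
  cf <- stats::coef(fit)
  if (fix_bottom) cf <- c(bottom = 0, cf)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(stats::coef(fit))))
  structure(
    list(params = as.list(cf), pec50 = unname(-cf["logec50"]),
         ec50 = unname(10^cf["logec50"]),
         max_reduction = unname(cf["top"]),
         se = se, fitted = stats::fitted(fit),
         residuals = stats::resid(fit), fit = fit),
    class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: pEC50 = %.3f (EC50 = %.3g M), max reduction = %.1f%%, hill = %.2f\n",
    x$pec50, x$ec50, x$max_reduction, x$params$hill))
  invisible(x)
}
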