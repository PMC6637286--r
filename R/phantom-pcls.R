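# PCLS phantom: a dark artery lumen (ellipse) in brighter tissue, shrinking
# with agonist concentration according to a four-parameter logistic law.

#' Generate a synthetic PCLS artery time-lapse
#'
#' Each frame shows a dark elliptical lumen in brighter tissue. The lumen
#' area at each concentration step follows the four-parameter logistic law
#' on the percent-initial-area scale, times `(1 + Gaussian noise)` drawn
#' once per step; a baseline (zero-drug) step precedes the first
#' concentration. Ground-truth areas are recorded per frame.
#'
#' @param params a [fourpl_params()] (percent-initial-area scale).
#' @param concentrations strictly ascending molar concentrations.
#' @param frames_per_step frames recorded at each step (>= 1).
#' @param noise_sd multiplicative area noise per step (fraction, >= 0).
#' @param initial_area_px baseline lumen area in pixels.
#' @param shape frame dimensions in pixels.
#' @param seed integer RNG seed.
#' @param frame_interval_s seconds between frames (0.5 Hz acquisition).
#' @param lumen_intensity,tissue_intensity gray levels of lumen and tissue.
#' @param image_noise_sd additive pixel noise.
#' @return A `pcls_timelapse`: frames `[x, y, t]`, per-frame `times`,
#'   `concentration` and ground-truth `area_px`, plus the step table.
#' @export
generate_pcls_timelapse <- function(params, concentrations,
                                    frames_per_step = 10, noise_sd = 0.05,
                                    initial_area_px = 1200,
                                    shape = c(128, 128), seed = 1,
                                    frame_interval_s = 2,
                                    lumen_intensity = 0.15,
                                    tissue_intensity = 0.7,
                                    image_noise_sd = 0.01) {
  stopifnot(inherits(params, "fourpl_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (frames_per_step < 1) stop("frames_per_step must be >= 1")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly ascending")

  conc_steps <- c(0, concentrations)  # baseline first
  with_seed(seed, {
    pct <- fourpl_area(params, conc_steps)          # percent initial area
    mult <- 1 + c(0, rnorm(length(concentrations), 0, noise_sd))
    # baseline defines "initial": keep it noise-free
    area_step <- initial_area_px * (pct / params$bottom) * mult
    nt <- length(conc_steps) * frames_per_step
    frames <- array(0, c(shape, nt))
    area_frame <- numeric(nt)
    conc_frame <- numeric(nt)
    ctr <- shape / 2
    axis_ratio <- 1.4
    t <- 0L
    for (s in seq_along(conc_steps)) {
      A <- max(area_step[s], 1)
      a <- sqrt(A * axis_ratio / pi)
      b <- a / axis_ratio
      xs <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
      ys <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
      lumen <- ((xs - ctr[1]) / a)^2 + ((ys - ctr[2]) / b)^2 <= 1
      img <- matrix(tissue_intensity, shape[1], shape[2])
      img[lumen] <- lumen_intensity
      for (k in seq_len(frames_per_step)) {
        t <- t + 1L
        f <- img
        if (image_noise_sd > 0)
          f <- f + matrix(rnorm(prod(shape), 0, image_noise_sd),
                          shape[1], shape[2])
        frames[, , t] <- f
        area_frame[t] <- sum(lumen)
        conc_frame[t] <- conc_steps[s]
      }
    }
    steps <- data.frame(
      concentration = conc_steps,
      start = (seq_along(conc_steps) - 1) * frames_per_step * frame_interval_s,
      end = seq_along(conc_steps) * frames_per_step * frame_interval_s)
    structure(
      list(frames = frames, times = (seq_len(nt) - 1) * frame_interval_s,
           concentration = conc_frame, area_px = area_frame,
           steps = steps, params = params,
           target_area = area_step),
      class = "pcls_timelapse")
  })
}

#' @export
print.pcls_timelapse <- function(x, ...) {
  cat(sprintf("pcls_timelapse: %d frames %d x %d, %d concentration steps\n",
              dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
              nrow(x$steps)))
  invisible(x)
}

#' Sample concentration-response data directly from a 4PL profile
#'
#' Draws one replicate concentration-response dataset without going
#' through image rendering: the response (percent reduction of initial
#' area) follows the logistic law with multiplicative area noise per
#' concentration, matching what [build_concentration_response()] recovers
#' from a rendered time-lapse.
#'
#' @param params a [fourpl_params()] (percent-initial-area scale).
#' @param concentrations molar concentrations (ascending).
#' @param noise_sd multiplicative area noise (fraction).
#' @param seed integer RNG seed.
#' @return A `concentration_response` data.frame.
#' @export
sample_concentration_response <- function(params, concentrations,
                                          noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(params, "fourpl_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    pa <- fourpl_area(params, concentrations) / params$bottom  # area fraction
    area <- pa * (1 + rnorm(length(concentrations), 0, noise_sd))
    out <- data.frame(concentration = concentrations,
                      response = 100 * (1 - area))
    structure(out, class = c("concentration_response", "data.frame"),
              initial_area = 1)
  })
}
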