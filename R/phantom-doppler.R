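# Doppler phantom: deterministic single-peaked pulmonary-artery ejection
# velocity envelopes with configurable time-to-peak and ejection time.

#' Generate a synthetic Doppler velocity trace
#'
#' Builds a piecewise-smooth single-peaked ejection envelope: zero outside
#' `[0, rvet]`, peak exactly at `tpv`, sampled over one heart period at
#' `sample_rate`. The default `"triangle"` envelope is piecewise linear,
#' which makes the downstream TPV/RVET ratio exactly invariant to the
#' relative threshold used for ejection-window detection; `"cosine"` gives
#' a smooth raised-cosine rise and fall. The generator is deterministic.
#'
#' @param profile a [doppler_profile()] (fields `tpv`, `rvet`,
#'   `peak_velocity`, `sample_rate`, `heart_period`; ms and Hz).
#' @param shape envelope shape.
#' @return A `velocity_trace`: data.frame with `time_ms` and `velocity`,
#'   carrying the profile as attribute.
#' @export
generate_doppler_trace <- function(profile, shape = c("triangle", "cosine")) {
  shape <- match.arg(shape)
  tpv <- profile$tpv; rvet <- profile$rvet
  if (!(0 < tpv && tpv < rvet && rvet < profile$heart_period))
    stop("profile must satisfy 0 < tpv < rvet < heart_period")
  dt <- 1000 / profile$sample_rate  # ms per sample
  if (tpv / dt < 10)
    stop("sample_rate too low: fewer than 10 samples before the peak")
  t <- seq(0, profile$heart_period, by = dt)
  v <- numeric(length(t))
  up <- t >= 0 & t <= tpv
  dn <- t > tpv & t <= rvet
  if (shape == "triangle") {
    v[up] <- t[up] / tpv
    v[dn] <- (rvet - t[dn]) / (rvet - tpv)
  } else {
    v[up] <- 0.5 * (1 - cos(pi * t[up] / tpv))
    v[dn] <- 0.5 * (1 + cos(pi * (t[dn] - tpv) / (rvet - tpv)))
  }
  out <- data.frame(time_ms = t, velocity = profile$peak_velocity * v)
  structure(out, class = c("velocity_trace", "data.frame"),
            profile = profile)
}
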