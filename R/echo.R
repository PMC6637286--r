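# Echocardiographic indices: TPV/RVET from a pulmonary-artery Doppler
# envelope (inversely related to pulmonary vascular resistance) and
# left-ventricular fractional shortening from M-mode diameters.

#' Compute the TPV/RVET ratio from a Doppler velocity trace
#'
#' The ejection window is either supplied or detected as the first and
#' last crossings of `threshold_frac` of peak velocity (crossing times
#' linearly interpolated between samples). TPV is the time from window
#' start to the velocity maximum; RVET is the window duration; the ratio
#' lies in (0, 1).
#'
#' @param trace a `velocity_trace` or data.frame with `time_ms` and
#'   `velocity`.
#' @param window optional `c(start, end)` in ms; detected when omitted.
#' @param threshold_frac fraction of peak velocity defining the ejection
#'   window.
#' @return List with `ratio`, `tpv_ms`, `rvet_ms`, `window`.
#' @export
compute_tpv_rvet <- function(trace, window = NULL, threshold_frac = 0.05) {
  t <- trace$time_ms
  v <- trace$velocity
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (diff(range(v)) == 0) stop("flat trace: no unique velocity peak")
  vmax <- max(v)
  ipk <- which(v == vmax)
  if (length(ipk) > 1) {
    warning("multiple equal velocity maxima; using the first")
    ipk <- ipk[1]
  }
  t_peak <- t[ipk]
  if (is.null(window)) {
    thr <- threshold_frac * vmax
    above <- v >= thr
    i0 <- which(above)[1]
    i1 <- tail(which(above), 1)
    t0 <- if (i0 > 1)
      t[i0 - 1] + (thr - v[i0 - 1]) / (v[i0] - v[i0 - 1]) * (t[i0] - t[i0 - 1])
    else t[i0]
    t1 <- if (i1 < length(t))
      t[i1] + (v[i1] - thr) / (v[i1] - v[i1 + 1]) * (t[i1 + 1] - t[i1])
    else t[i1]
    window <- c(t0, t1)
  }
  if (!(window[2] > window[1])) stop("degenerate ejection window")
  if (!(t_peak > window[1] && t_peak < window[2]))
    stop("velocity peak lies outside the ejection window")
  tpv <- t_peak - window[1]
  rvet <- window[2] - window[1]
  list(ratio = tpv / rvet, tpv_ms = tpv, rvet_ms = rvet, window = window)
}

#' Left-ventricular fractional shortening
#'
#' The standard M-mode index `100 * (LVIDd - LVIDs) / LVIDd` from internal
#' diameters at end-diastole and end-systole.
#'
#' @param lvidd end-diastolic internal diameter, mm (> 0).
#' @param lvids end-systolic internal diameter, mm (must not exceed
#'   `lvidd`).
#' @return Fractional shortening, percent.
#' @export
fractional_shortening <- function(lvidd, lvids) {
  if (any(lvidd <= 0)) stop("LVIDd must be positive")
  if (any(lvids > lvidd))
    stop("LVIDs exceeds LVIDd: implausible measurement")
  100 * (lvidd - lvids) / lvidd
}
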