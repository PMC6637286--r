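# Bundled condition profiles: editable YAML/CSV configs under inst/extdata
# encoding the relative group differences the phantoms are calibrated to.
# The qPCR group-mean table is synthetic, back-computed from published fold
# changes (no raw CT values exist); see the file header comments.

pv_extdata <- function(name) {
  p <- system.file("extdata", name, package = "pulmovasc", mustWork = FALSE)
  if (!nzchar(p)) stop("bundled profile file not found: ", name)
  p
}

#' Bundled vessel-diameter condition profile
#'
#' Loads one of the shipped micro-CT condition profiles (`air_vehicle`,
#' `hyperoxia_vehicle`, `hyperoxia_il1ra`). A profile holds ascending
#' diameter bin edges (um), the expected vessel count per bin for one lung
#' lobe volume, and (for non-reference groups) the per-bin depletion factor
#' relative to the reference; expected counts of depleted groups are the
#' reference counts times the factor.
#'
#' @param name condition label.
#' @param file optional path to an alternative profile YAML.
#' @return An object of class `condition_profile` with fields `name`,
#'   `bin_edges`, `expected_counts`, `depletion`.
#' @export
condition_profile <- function(name = c("air_vehicle", "hyperoxia_vehicle",
                                       "hyperoxia_il1ra"),
                              file = NULL) {
  name <- match.arg(name)
  cfg <- yaml::read_yaml(file %||% pv_extdata("microct_profiles.yaml"))
  edges <- as.numeric(cfg$bin_edges)
  nb <- length(edges) - 1L
  ref <- cfg$conditions[[cfg$reference]]
  if (is.null(ref$expected_counts))
    stop("reference condition must carry expected_counts")
  ref_counts <- as.numeric(ref$expected_counts)
  cond <- cfg$conditions[[name]]
  if (is.null(cond)) stop("no such condition in profile file: ", name)
  depl <- if (is.null(cond$depletion)) rep(1, nb) else as.numeric(cond$depletion)
  counts <- if (is.null(cond$expected_counts)) ref_counts * depl
            else as.numeric(cond$expected_counts)
  out <- structure(
    list(name = name, bin_edges = edges, expected_counts = counts,
         depletion = depl),
    class = "condition_profile")
  validate_condition_profile(out)
  out
}

validate_condition_profile <- function(p) {
  if (any(diff(p$bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (length(p$expected_counts) != length(p$bin_edges) - 1L)
    stop("expected_counts must have one entry per bin")
  if (any(p$expected_counts < 0)) stop("expected_counts must be nonnegative")
  if (any(p$depletion < 0)) stop("depletion factors must be nonnegative")
  invisible(p)
}

#' @export
print.condition_profile <- function(x, ...) {
  cat("condition_profile:", x$name, "\n")
  nb <- length(x$bin_edges) - 1L
  print(data.frame(bin = sprintf("[%g,%g)", x$bin_edges[-(nb + 1L)],
                                 x$bin_edges[-1]),
                   expected = x$expected_counts, depletion = x$depletion))
  invisible(x)
}

#' Bundled Doppler timing profile
#'
#' Pulmonary-artery ejection timing (ms) for one experimental group; the
#' tpv/rvet ratios reproduce the reported group TPV/RVET means (0.32 air
#' vehicle, 0.27 hyperoxia vehicle, 0.31 hyperoxia IL-1Ra).
#'
#' @param name group label.
#' @param file optional alternative YAML.
#' @return A list with `tpv`, `rvet`, `peak_velocity`, `sample_rate`,
#'   `heart_period`, of class `doppler_profile`.
#' @export
doppler_profile <- function(name = c("air_vehicle", "hyperoxia_vehicle",
                                     "hyperoxia_il1ra"),
                            file = NULL) {
  name <- match.arg(name)
  cfg <- yaml::read_yaml(file %||% pv_extdata("doppler_profiles.yaml"))
  p <- cfg$profiles[[name]]
  if (is.null(p)) stop("no such Doppler profile: ", name)
  p$name <- name
  if (!(0 < p$tpv && p$tpv < p$rvet && p$rvet < p$heart_period))
    stop("Doppler profile must satisfy 0 < tpv < rvet < heart_period")
  structure(p, class = "doppler_profile")
}

#' Bundled agonist concentration-response profile
#'
#' Four-parameter logistic parameters on the percent-initial-artery-area
#' scale for the two vasoconstrictors used on precision-cut lung slices,
#' plus the tested concentration grid (molar).
#'
#' @param name `"et1"` or `"u46619"`.
#' @param file optional alternative YAML.
#' @return A list of class `fourpl_params` with `bottom`, `top`, `logec50`,
#'   `hill`, `concentrations`.
#' @export
agonist_profile <- function(name = c("et1", "u46619"), file = NULL) {
  name <- match.arg(name)
  cfg <- yaml::read_yaml(file %||% pv_extdata("pcls_agonists.yaml"))
  p <- cfg$profiles[[name]]
  if (is.null(p)) stop("no such agonist profile: ", name)
  p$name <- name
  p$concentrations <- as.numeric(p$concentrations)
  fourpl_params(p$bottom, p$top, p$logec50, p$hill,
                concentrations = p$concentrations, name = name)
}

#' Four-parameter logistic parameter set
#'
#' Parameters of the logistic concentration-response law on the
#' percent-initial-area scale: `bottom` is the area at zero drug, `top` the
#' area at saturating drug (`bottom >= top` for a constrictor), `logec50`
#' the log10 molar concentration of half-maximal effect and `hill > 0` the
#' slope factor.
#'
#' @param bottom,top percent initial area at zero / saturating drug.
#' @param logec50 log10 molar EC50.
#' @param hill slope factor (> 0).
#' @param concentrations optional molar concentration grid.
#' @param name optional label.
#' @return An object of class `fourpl_params`.
#' @export
fourpl_params <- function(bottom, top, logec50, hill,
                          concentrations = NULL, name = NULL) {
  if (hill <= 0) stop("hill slope must be > 0")
  if (bottom < top)
    stop("bottom must be >= top for a constrictor (area decreases)")
  structure(list(bottom = bottom, top = top, logec50 = logec50, hill = hill,
                 concentrations = concentrations, name = name),
            class = "fourpl_params")
}

#' Evaluate the four-parameter logistic law (percent initial area)
#'
#' @param params a [fourpl_params()].
#' @param conc molar concentrations (0 allowed: returns `bottom`).
#' @return Percent initial area at each concentration.
#' @export
fourpl_area <- function(params, conc) {
  out <- rep(params$bottom, length(conc))
  pos <- conc > 0
  out[pos] <- params$bottom + (params$top - params$bottom) /
    (1 + 10^((params$logec50 - log10(conc[pos])) * params$hill))
  out
}

#' Bundled angiography branching profile
#'
#' Tree layout parameters and per-generation pruning fractions for the
#' cine-angiography phantom; hyperoxia pruning encodes the reported
#' generation-2 (-18%) and generation-3 (-21%) vessel losses.
#'
#' @param name group label.
#' @param file optional alternative YAML.
#' @return A list with `n_trees`, `children`, `depth`, `prune_g2`,
#'   `prune_g3`.
#' @export
angio_profile <- function(name = c("air_vehicle", "hyperoxia_vehicle",
                                   "hyperoxia_il1ra"),
                          file = NULL) {
  name <- match.arg(name)
  cfg <- yaml::read_yaml(file %||% pv_extdata("angio_profiles.yaml"))
  p <- cfg$profiles[[name]]
  if (is.null(p)) stop("no such angiography profile: ", name)
  out <- c(cfg$defaults, p)
  out$name <- name
  if (out$prune_g2 >= 1 / out$children || out$prune_g3 >= 1 / out$children)
    stop("pruning fractions must be < 1/children (one child per junction)")
  out
}

#' Bundled histology (collagen) profile
#'
#' @param name group label.
#' @param file optional alternative YAML.
#' @return A list with `collagen_fraction`, `vessel_fraction`, `cv`.
#' @export
histology_profile <- function(name = c("air_vehicle", "hyperoxia_vehicle",
                                       "hyperoxia_il1ra"),
                              file = NULL) {
  name <- match.arg(name)
  cfg <- yaml::read_yaml(file %||% pv_extdata("histology_profiles.yaml"))
  p <- cfg$profiles[[name]]
  if (is.null(p)) stop("no such histology profile: ", name)
  list(name = name, collagen_fraction = p$collagen_fraction,
       vessel_fraction = cfg$vessel_fraction, cv = cfg$cv)
}

#' Synthetic qPCR group-mean CT table
#'
#' Group-mean cycle-threshold values for the cardiac genes assayed at day
#' 28 (Lgals3, Ccl2, Nppb, with Actb as housekeeping). The table is
#' synthetic: it was back-computed from the published fold changes, since
#' raw CT values are not available.
#'
#' @param file optional alternative CSV (columns gene, group, mean_ct).
#' @return A data.frame with columns `gene`, `group`, `mean_ct`.
#' @export
qpcr_group_means <- function(file = NULL) {
  read.csv(file %||% pv_extdata("qpcr_group_means_synthetic.csv"),
           stringsAsFactors = FALSE)
}
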