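# Micro-CT branching analysis: per-plane difference-of-Gaussian edge
# detection, large-vessel filling, filament tracing (large vessels in the
# filled channel, small vessels in the original intensity volume),
# distance-transform/partial-volume diameter estimation, diameter binning
# and air-group normalization.

#' Detect large-vessel edges by sequential difference-of-Gaussian filtering
#'
#' Applies two successive difference-of-Gaussian band-pass filters of
#' increasing scale to every plane of the stack, then thresholds, binarizes
#' and despeckles each plane. The scales are interpreted as Gaussian sigmas
#' in pixels with the classic 1.6 inner/outer ratio. Per-plane thresholds
#' default to Otsu, guarded by a robust noise floor (median + 4 MAD of the
#' plane response) so that planes without vessel content yield empty masks.
#'
#' @param volume a [volume3d()].
#' @param r1,r2 filter scales in pixels (`r2 > r1 > 0`).
#' @param ratio inner/outer sigma ratio of each band-pass.
#' @param threshold `"otsu"` or a fixed numeric response threshold.
#' @param despeckle apply a 3x3 majority (median) filter per plane.
#' @return A [binary_volume()] edge mask.
#' @export
detect_large_vessel_edges <- function(volume, r1 = 2, r2 = 5, ratio = 1.6,
                                      threshold = "otsu", despeckle = TRUE) {
  stopifnot(inherits(volume, "volume3d"))
  if (!(r2 > r1 && r1 > 0)) stop("need r2 > r1 > 0")
  v <- volume$voxels
  dims <- dim(v)
  if (dims[3] < 1) stop("per-plane processing needs at least one plane")

  d2 <- dog_bandpass(v, r1, r2, ratio)

  mask <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    p <- d2[, , z]
    thr <- if (identical(threshold, "otsu")) otsu_threshold(p)
           else as.numeric(threshold)
    floor_z <- median(p) + 4 * mad(p)
    mask[, , z] <- p > max(thr, floor_z)
  }
  if (despeckle) mask <- majority3x3(mask)
  binary_volume(mask, volume$voxel_size)
}

# Two sequential per-plane difference-of-Gaussian band-pass filters at
# scales r1 then r2 (each DoG = blur(sigma) - blur(ratio * sigma)).
dog_bandpass <- function(v, r1, r2, ratio = 1.6) {
  dims <- dim(v)
  plane_blur <- function(a, sigma) {
    k <- gauss_kernel(sigma)
    cpp_sepconv3d(a, dims, k, k, 1)
  }
  d1 <- plane_blur(v, r1) - plane_blur(v, ratio * r1)
  plane_blur(d1, r2) - plane_blur(d1, ratio * r2)
}

# 3x3 per-plane majority filter (the binary median): keep a pixel when at
# least 5 of the 9 pixels in its neighborhood are set.
majority3x3 <- function(mask) {
  dims <- dim(mask)
  cnt <- cpp_sepconv3d(mask * 1, dims, c(1, 1, 1), c(1, 1, 1), 1)
  array(cnt >= 5, dims)
}

#' Fill large vessels from their edge mask
#'
#' Reproduces the filling chain: despeckle, skeletonize each plane, remove
#' short skeleton fragments, detect skeleton tips, close gaps by connecting
#' each tip to its nearest tip within `max_gap` pixels with a straight
#' line, and fill all fully-enclosed areas. The filled regions are combined
#' with the despeckled input, so an already-solid mask passes through
#' unchanged (idempotence on filled input).
#'
#' @param edges a [binary_volume()] edge mask (from
#'   [detect_large_vessel_edges()] or compatible).
#' @param max_gap largest tip-to-tip gap to close, voxels (> 0).
#' @param min_fragment minimum skeleton fragment size to keep, voxels.
#' @return A [binary_volume()] with solid large vessels.
#' @export
fill_large_vessels <- function(edges, max_gap = 5, min_fragment = 5) {
  stopifnot(inherits(edges, "binary_volume"))
  if (max_gap <= 0) stop("max_gap must be > 0")
  m <- edges$mask
  dims <- dim(m)
  closed <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    p <- m[, , z]
    # despeckle: drop specks smaller than 3 px (keeps solid input intact)
    p <- remove_small_components(p, 3)
    if (!any(p)) { closed[, , z] <- p; m[, , z] <- p; next }
    sk <- skeletonize(p)
    sk <- remove_small_components(sk, min_fragment)
    cl <- close_tip_gaps(sk, max_gap)
    closed[, , z] <- cl
    m[, , z] <- p
  }
  filled <- EBImage::fillHull(closed * 1) > 0
  binary_volume(m | array(filled, dims), edges$voxel_size)
}

# Connect each skeleton tip to its nearest other tip within max_gap by a
# straight pixel line (2D).
close_tip_gaps <- function(sk, max_gap) {
  if (!any(sk)) return(sk)
  cnt <- blur_count2d(sk)
  tips <- which(sk & cnt == 1, arr.ind = TRUE)
  if (nrow(tips) < 2) return(sk)
  out <- sk
  for (i in seq_len(nrow(tips))) {
    d <- sqrt((tips[, 1] - tips[i, 1])^2 + (tips[, 2] - tips[i, 2])^2)
    d[i] <- Inf
    j <- which.min(d)
    if (d[j] > max_gap) next
    n <- max(2, ceiling(d[j]) + 1)
    xs <- round(seq(tips[i, 1], tips[j, 1], length.out = n))
    ys <- round(seq(tips[i, 2], tips[j, 2], length.out = n))
    out[cbind(xs, ys)] <- TRUE
  }
  out
}

# number of set 8-neighbors of each pixel of a 2D mask
blur_count2d <- function(m) {
  a <- array(m * 1, c(dim(m), 1L))
  cnt <- cpp_sepconv3d(a, dim(a), c(1, 1, 1), c(1, 1, 1), 1)[, , 1]
  cnt - m
}

# Tube amplitude reference: median intensity of voxels lying clearly in
# the interior of bright structures (>= 1.5 voxels from the half-maximum
# boundary), where partial volume cannot reduce the value. Falls back to
# the robust maximum when no structure is thick enough to have an
# interior (then the reference is itself partial-volume limited).
estimate_amplitude <- function(original, filled_mask = NULL) {
  vmax <- as.numeric(quantile(original, 1 - 1e-5))
  bright <- original >= 0.5 * vmax
  if (any(bright)) {
    interior <- distance_transform(bright) >= 1.5
    if (sum(interior) >= 5) return(median(original[interior]))
  }
  vmax
}

#' Trace the filament network (large "dendrites", small "spines")
#'
#' The large-vessel channel is the filled mask gated by a smoothed
#' intensity surface (removing filling artifacts that extend beyond the
#' true vessel surface). Small vessels are detected in the original
#' intensity volume: lightly smoothed in 3D and thresholded; the region
#' within `surface_margin` voxels of the gated large-vessel surface is
#' masked out of the reported small-vessel mask. The union of the two
#' channels is thinned once, so a vessel caught partly by each cannot be
#' counted twice, and every skeleton path between tips/branch points
#' becomes one segment, classed `large` or `small` by where the majority
#' of its centerline lies.
#'
#' @param filled a [binary_volume()] from [fill_large_vessels()].
#' @param original the original [volume3d()] (same shape and voxel size).
#' @param small_vessel_threshold `"auto"` (5% of the estimated tube
#'   amplitude) or an absolute intensity.
#' @param surface_margin exclusion margin around the filled surface,
#'   voxels.
#' @param smooth_sigma 3D Gaussian sigma for small-vessel detection,
#'   voxels.
#' @param min_fragment minimum skeleton fragment length to keep, voxels.
#' @param min_component minimum small-vessel component size, voxels.
#' @param prune_tips remove tip-ending skeleton spurs shorter than this
#'   many voxels (junction artifacts of thinning).
#' @param min_junction_seg drop junction-to-junction stubs shorter than
#'   this Euclidean length (voxels); junction clusters occasionally split
#'   into nearby sub-clusters connected by such stubs.
#' @return A `filament_network`: segments with polylines, class labels and
#'   junction topology; masks and intensity context are carried along for
#'   [estimate_diameters()].
#' @export
trace_filaments <- function(filled, original,
                            small_vessel_threshold = "auto",
                            surface_margin = 2, smooth_sigma = 0.8,
                            min_fragment = 5, min_component = 8,
                            prune_tips = 8, min_junction_seg = 4) {
  stopifnot(inherits(filled, "binary_volume"), inherits(original, "volume3d"))
  if (!all(dim(filled$mask) == dim(original$voxels)))
    stop("filled mask and original volume must share shape")

  v <- original$voxels
  if (diff(range(v)) == 0 && !any(filled$mask)) {
    # nothing to trace: constant volume and empty mask
    return(structure(
      list(segments = list(), voxel_size = original$voxel_size,
           filled = filled$mask, small_mask = array(FALSE, dim(v)),
           original = v, smoothed = v, amplitude = max(v, 1e-9)),
      class = "filament_network"))
  }
  amp <- estimate_amplitude(v)
  smoothed <- blur3d(v, smooth_sigma)
  # smoothed-surface gating: the DoG response extends well beyond thin
  # vessels, so the filled channel is restricted to voxels that are also
  # bright, removing filling artifacts around the true surface
  core_large <- filled$mask & (smoothed >= 0.25 * amp)
  core_large <- remove_small_components(core_large, min_component)
  thr <- if (identical(small_vessel_threshold, "auto"))
    max(0.05 * amp, median(v) + 6 * mad(v) / sqrt((2 * ceiling(3 * smooth_sigma) + 1)^1.5))
  else as.numeric(small_vessel_threshold)
  small_raw <- smoothed >= thr
  small_mask <- small_raw & !dilate_mask(core_large, surface_margin)
  small_mask <- remove_small_components(small_mask, min_component)

  # one skeleton over the union of the two channels, so a vessel caught
  # partly by each cannot be counted twice; segments are classed by where
  # the majority of their path lies
  union_mask <- remove_small_components(core_large | small_raw,
                                        min_component)
  segs <- list()
  if (any(union_mask)) {
    sk <- skeletonize(union_mask)
    res <- skeleton_segments(sk, min_fragment = min_fragment,
                             prune_tips = prune_tips)
    for (s in res$segments) {
      if (all(!is.na(s$junc)) &&
          polyline_length(s$path) < min_junction_seg) next
      in_large <- core_large[cbind(s$path[, 1], s$path[, 2], s$path[, 3])]
      s$class <- if (mean(in_large) >= 0.5) "large" else "small"
      segs[[length(segs) + 1L]] <- s
    }
  }
  structure(
    list(segments = segs, voxel_size = original$voxel_size,
         filled = core_large, small_mask = small_mask,
         original = v, smoothed = smoothed, amplitude = amp),
    class = "filament_network")
}

#' @export
print.filament_network <- function(x, ...) {
  cls <- vapply(x$segments, function(s) s$class %||% "?", character(1))
  cat(sprintf("filament_network: %d segments (%d large, %d small)\n",
              length(x$segments), sum(cls == "large"), sum(cls == "small")))
  invisible(x)
}

#' @export
as.data.frame.filament_network <- function(x, ...) {
  if (!length(x$segments))
    return(data.frame(segment = integer(0), class = character(0),
                      n_points = integer(0), length_vox = numeric(0),
                      diameter_um = numeric(0), flagged = logical(0)))
  do.call(rbind, lapply(seq_along(x$segments), function(i) {
    s <- x$segments[[i]]
    data.frame(segment = i, class = s$class %||% NA_character_,
               n_points = nrow(s$path),
               length_vox = polyline_length(s$path),
               diameter_um = s$diameter_um %||% NA_real_,
               flagged = isTRUE(s$flagged))
  }))
}

#' Estimate per-segment vessel diameters
#'
#' Per-point radii come from the Euclidean distance transform of the
#' measurement mask near the centerline voxels (the maximum EDT value in
#' the 3x3x3 neighborhood of each path voxel, minus 0.5: the distance from
#' the voxel center to the boundary midplane, robust to the skeleton
#' sitting slightly off-center); the segment diameter is twice the median
#' per-point radius times the voxel size, the median resisting junction
#' inflation. The measurement mask is the half-maximum intensity mask
#' where available (boundary at the true surface for resolved vessels),
#' falling back to the union of the filled and small-vessel masks.
#' Segments thinner than `refine_below_vox` voxels are re-estimated from
#' integrated partial-volume intensity: voxels near the centerline are
#' partitioned into per-point slabs, each slab's background-subtracted
#' intensity sum divided by the local step length gives a cross-section
#' area, and the median slab area over the trimmed path yields the
#' diameter. This recovers sub-voxel calibres that the distance transform
#' quantizes away. Binary input volumes skip the refinement. Segments
#' lying outside all masks are flagged and excluded with a warning.
#'
#' @param network a `filament_network` from [trace_filaments()].
#' @param filled optional [binary_volume()] override of the filled mask.
#' @param original_mask optional [binary_volume()]: the intensity-derived
#'   (half-maximum) mask; computed from the carried volume when omitted.
#' @param refine_below_vox apply intensity refinement below this estimated
#'   diameter (voxels); the default `Inf` refines every segment of a
#'   grayscale volume, since the slab estimator is unbiased at all
#'   calibres while the distance transform quantizes at the voxel scale.
#' @param integration_radius minimum radius (voxels) of the tube
#'   neighborhood used for intensity integration (widened automatically
#'   for thicker segments).
#' @return The network with `diameter_um`, `method` and `flagged` set on
#'   every segment.
#' @export
estimate_diameters <- function(network, filled = NULL, original_mask = NULL,
                               refine_below_vox = Inf,
                               integration_radius = 2.5) {
  stopifnot(inherits(network, "filament_network"))
  if (!length(network$segments)) return(network)
  vs <- network$voxel_size
  fm <- if (is.null(filled)) network$filled else filled$mask
  v <- network$original
  amp <- network$amplitude
  vals <- unique(as.vector(v))
  is_binary <- length(vals) <= 2

  hm <- if (is.null(original_mask)) {
    if (is_binary) v >= 0.5 * amp else network$smoothed >= 0.5 * amp
  } else original_mask$mask
  union_mask <- fm | network$small_mask | hm
  edt_half <- distance_transform(hm)
  edt_union <- distance_transform(union_mask)
  dims <- dim(v)

  # per path voxel: max EDT within the 3x3x3 neighborhood (the skeleton
  # may sit off the exact tube center)
  neigh_max <- function(edt, pts) {
    out <- rep(0, nrow(pts))
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      nb <- cbind(pts[, 1] + dx, pts[, 2] + dy, pts[, 3] + dz)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (any(ok)) out[ok] <- pmax(out[ok], edt[nb[ok, , drop = FALSE]])
    }
    out
  }

  refine <- logical(length(network$segments))
  for (i in seq_along(network$segments)) {
    s <- network$segments[[i]]
    pts <- cbind(s$path[, 1], s$path[, 2], s$path[, 3])
    rh0 <- edt_half[pts]
    ru0 <- edt_union[pts]
    if (all(rh0 == 0) && all(ru0 == 0)) {
      s$flagged <- TRUE
      s$diameter_um <- NA_real_
      s$method <- "excluded"
      network$segments[[i]] <- s
      next
    }
    rh <- neigh_max(edt_half, pts)
    ru <- neigh_max(edt_union, pts)
    r <- ifelse(rh > 0, rh, ru)
    r <- r[r > 0]
    d_vox <- 2 * (median(r) - 0.5)
    s$diameter_um <- max(d_vox, 0.1) * vs
    s$method <- "edt"
    s$flagged <- FALSE
    s$edt_radius_vox <- max(median(ru0[ru0 > 0]), 0.5)
    network$segments[[i]] <- s
    if (!is_binary && d_vox < refine_below_vox) refine[i] <- TRUE
  }
  if (any(vapply(network$segments, function(s) isTRUE(s$flagged), logical(1))))
    warning("segments lying outside all masks were flagged and excluded")

  if (any(refine)) {
    bg <- median(v[!dilate_mask(union_mask, 2)])
    claims <- intensity_claims(network, which(refine), integration_radius)
    for (i in which(refine)) {
      s <- network$segments[[i]]
      vox <- claims[claims$seg == i, , drop = FALSE]
      if (nrow(vox) < 4) next
      p <- s$path
      np <- nrow(p)
      if (np < 5) next
      # local step length per path point, from 4-step chords so the
      # zigzag of the digital path does not inflate the length
      k_lo <- pmax(1, seq_len(np) - 2)
      k_hi <- pmin(np, seq_len(np) + 2)
      half <- sqrt(rowSums((p[k_hi, , drop = FALSE] -
                              p[k_lo, , drop = FALSE])^2)) / (k_hi - k_lo)
      slab <- tapply(v[vox$lin] - bg, factor(vox$k, levels = seq_len(np)),
                     sum)
      slab[is.na(slab)] <- 0
      area <- as.numeric(slab) / half / amp
      # trim slabs near free tips (cap spill-over) and junction ends
      r0 <- s$edt_radius_vox %||% 0.5
      trim <- ceiling(r0 + 2)
      keep <- rep(TRUE, np)
      n_keep <- max(3, np - 2 * trim)
      if (np > 2 * trim + 3) keep[c(seq_len(trim), (np - trim + 1):np)] <- FALSE
      a_med <- median(area[keep & area > 0])
      if (!is.finite(a_med) || a_med <= 0) next
      s$diameter_um <- 2 * sqrt(a_med / pi) * vs
      s$method <- "intensity"
      network$segments[[i]] <- s
    }
  }
  network
}

# Voxel ownership for intensity integration: every voxel within reach of a
# refined segment's polyline, assigned to the segment with the smallest
# distance scaled by its rough radius (so junction voxels go to the
# thicker parent), and within the segment to its nearest path point
# (slab partition).
intensity_claims <- function(network, idx, w_min) {
  dims <- dim(network$original)
  rows <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    s <- network$segments[[i]]
    p <- s$path
    r0 <- s$edt_radius_vox %||% 0.5
    w <- max(w_min, 1.8 * r0 + 1.5)
    lo <- pmax(1, floor(apply(p, 2, min)) - ceiling(w) - 1)
    hi <- pmin(dims, ceiling(apply(p, 2, max)) + ceiling(w) + 1)
    grid <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                  z = lo[3]:hi[3]))
    dmin <- rep(Inf, nrow(grid))
    kmin <- rep(1L, nrow(grid))
    for (k in seq_len(nrow(p))) {
      d <- (grid[, 1] - p[k, 1])^2 + (grid[, 2] - p[k, 2])^2 +
        (grid[, 3] - p[k, 3])^2
      upd <- d < dmin
      dmin[upd] <- d[upd]
      kmin[upd] <- k
    }
    dmin <- sqrt(dmin)
    keep <- dmin <= w
    if (!any(keep)) next
    lin <- grid[keep, 1] + dims[1] * (grid[keep, 2] - 1) +
      dims[1] * dims[2] * (grid[keep, 3] - 1)
    rows[[q]] <- data.frame(lin = lin, seg = i, k = kmin[keep],
                            score = dmin[keep] / r0)
  }
  all <- do.call(rbind, rows)
  if (is.null(all))
    return(data.frame(lin = integer(0), seg = integer(0), k = integer(0)))
  all <- all[order(all$score), ]
  all[!duplicated(all$lin), c("lin", "seg", "k")]
}

#' Bin vessels by diameter
#'
#' Counts network segments into half-open diameter bins
#' \eqn{[lo, hi)}{[lo, hi)}. Vessels thinner than the first edge (4 um by
#' default) are discarded as below the resolution limit; vessels at or
#' above the last edge are tracked separately as overflow. Percent of total
#' is relative to all binned vessels of the specimen (lobe).
#'
#' @param network a `filament_network` with diameters estimated.
#' @param bin_edges ascending bin edges in micrometers (first edge 4).
#' @param specimen_id,group labels carried into downstream normalization.
#' @return A `diameter_histogram`: data.frame with `bin_lo_um`,
#'   `bin_hi_um`, `count`, `percent`, plus attributes `total`,
#'   `discarded`, `overflow`, `specimen_id`, `group`,
#'   `undefined_percent`.
#' @export
bin_vessels <- function(network, bin_edges = c(4, 5, 6, 7, 10, 15, 20, 30),
                        specimen_id = NA_character_, group = NA_character_) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be ascending")
  df <- as.data.frame(network)
  d <- df$diameter_um[!df$flagged & !is.na(df$diameter_um)]
  nb <- length(bin_edges) - 1L
  discarded <- sum(d < bin_edges[1])
  overflow <- sum(d >= bin_edges[nb + 1L])
  inrange <- d[d >= bin_edges[1] & d < bin_edges[nb + 1L]]
  counts <- tabulate(findInterval(inrange, bin_edges), nbins = nb)
  total <- sum(counts)
  percent <- if (total > 0) 100 * counts / total else rep(NA_real_, nb)
  out <- data.frame(bin_lo_um = bin_edges[-(nb + 1L)],
                    bin_hi_um = bin_edges[-1],
                    count = counts, percent = percent)
  structure(out, class = c("diameter_histogram", "data.frame"),
            total = total, discarded = discarded, overflow = overflow,
            specimen_id = specimen_id, group = group,
            undefined_percent = total == 0)
}

#' Normalize diameter histograms to a reference group
#'
#' Applies the air-group normalization: each specimen's per-bin percent of
#' total is scaled by its total vessel count divided by the mean total of
#' the reference group, so group differences in overall vessel number are
#' retained in the per-bin values.
#'
#' @param histograms list of [bin_vessels()] results carrying `group`
#'   attributes.
#' @param reference_group reference group label (must have >= 1 specimen
#'   and nonzero mean total).
#' @return The list with a `normalized` column added to each histogram.
#' @export
normalize_to_reference <- function(histograms, reference_group) {
  groups <- vapply(histograms, function(h) attr(h, "group"), character(1))
  if (!any(groups == reference_group))
    stop("reference group not present: ", reference_group)
  totals <- vapply(histograms, function(h) attr(h, "total"), numeric(1))
  ref_mean <- mean(totals[groups == reference_group])
  if (ref_mean == 0) stop("reference group mean total vessel count is zero")
  lapply(histograms, function(h) {
    f <- attr(h, "total") / ref_mean
    h$normalized <- h$percent * f
    attr(h, "norm_factor") <- f
    h
  })
}

#' Group mean and SEM of normalized histograms
#'
#' @param histograms list of normalized [bin_vessels()] results.
#' @return data.frame: group, bin, mean and SEM of the normalized values.
#' @export
histogram_group_summary <- function(histograms) {
  groups <- vapply(histograms, function(h) attr(h, "group"), character(1))
  out <- list()
  for (g in unique(groups)) {
    hs <- histograms[groups == g]
    m <- sapply(hs, function(h) h$normalized)
    out[[g]] <- data.frame(
      group = g,
      bin_lo_um = hs[[1]]$bin_lo_um, bin_hi_um = hs[[1]]$bin_hi_um,
      mean = rowMeans(m, na.rm = TRUE),
      sem = apply(m, 1, sem))
  }
  do.call(rbind, out)
}

#' Run the full micro-CT pipeline on one volume
#'
#' Edge detection, filling, tracing, diameter estimation and binning with
#' the package defaults (overridable through `...`, passed to the
#' individual steps by name).
#'
#' @param volume a [volume3d()].
#' @param specimen_id,group labels for the histogram.
#' @param bin_edges diameter bin edges, um.
#' @param r1,r2 DoG scales for [detect_large_vessel_edges()].
#' @param max_gap,min_fragment gap closing / fragment pruning, voxels.
#' @return A list with `network` (diameters estimated) and `histogram`.
#' @export
microct_pipeline <- function(volume, specimen_id = NA_character_,
                             group = NA_character_,
                             bin_edges = c(4, 5, 6, 7, 10, 15, 20, 30),
                             r1 = 2, r2 = 5, max_gap = 5, min_fragment = 5) {
  edges <- detect_large_vessel_edges(volume, r1 = r1, r2 = r2)
  filled <- fill_large_vessels(edges, max_gap = max_gap,
                               min_fragment = min_fragment)
  net <- trace_filaments(filled, volume, min_fragment = min_fragment)
  net <- estimate_diameters(net)
  hist <- bin_vessels(net, bin_edges = bin_edges,
                      specimen_id = specimen_id, group = group)
  list(network = net, histogram = hist)
}
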