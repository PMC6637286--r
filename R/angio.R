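# Digital subtraction angiography analysis: pre-injection frame
# subtraction, median filtering, and per-generation vessel counting
# (manual color-dot tallies or automated branch-depth counting).

#' Subtract the pre-injection frame from post-injection frames
#'
#' The frame acquired just before contrast injection is subtracted from
#' every later frame; negative differences are clipped to zero (opacity
#' only increases with contrast). Static background structures cancel
#' exactly.
#'
#' @param seq an `angiogram_sequence` (or a list with `frames` and
#'   `pre_injection_index`).
#' @return An `enhanced_frames` object: difference frames `[x, y, t]`, the
#'   index map to original frames, and `peak_index` (the difference frame
#'   of maximal total opacity).
#' @export
subtract_background <- function(seq) {
  fr <- seq$frames
  pre <- seq$pre_injection_index
  nt <- dim(fr)[3]
  if (is.null(pre) || pre < 1 || pre >= nt)
    stop("pre_injection_index out of range")
  ref <- fr[, , pre]
  post <- (pre + 1L):nt
  enh <- array(0, c(dim(fr)[1:2], length(post)))
  for (k in seq_along(post)) enh[, , k] <- pmax(fr[, , post[k]] - ref, 0)
  totals <- apply(enh, 3, sum)
  structure(list(frames = enh, source_frames = post,
                 peak_index = which.max(totals),
                 pixel_size = seq$pixel_size),
            class = "enhanced_frames")
}

#' Median filter angiogram frames
#'
#' Per-frame median filtering over a disk neighborhood (2-pixel radius by
#' default), the clean-up applied to subtraction angiograms.
#'
#' @param frames an `enhanced_frames` object, a 2D matrix or a 3D array.
#' @param radius disk radius in pixels (>= 1).
#' @return Same type as the input, filtered.
#' @export
median_filter_frames <- function(frames, radius = 2) {
  if (radius < 1) stop("radius must be >= 1")
  if (inherits(frames, "enhanced_frames")) {
    frames$frames <- median_filter_frames(frames$frames, radius)
    return(frames)
  }
  if (is.matrix(frames)) return(cpp_median2d(frames, as.integer(radius), TRUE))
  out <- frames
  for (t in seq_len(dim(frames)[3]))
    out[, , t] <- cpp_median2d(frames[, , t], as.integer(radius), TRUE)
  out
}

#' Count vessels per branching generation
#'
#' Manual mode tallies color-coded marks `(x, y, generation)` per
#' generation 1-3, reproducing the dot-counting workflow. Automated mode
#' thresholds the peak subtraction frame (Otsu by default), skeletonizes
#' it, builds the branch graph, takes the widest segment of each connected
#' component as the inflow root, and assigns each segment the topological
#' depth from the root (root = 1), counting segments per generation up to
#' `max_generation`.
#'
#' @param enhanced a single 2D frame (typically the peak frame of
#'   [subtract_background()], after [median_filter_frames()]), or an
#'   `enhanced_frames` object from which the peak frame is taken.
#' @param marks optional data.frame with columns `x`, `y`, `generation`
#'   (manual mode).
#' @param threshold `"otsu"` or a fixed intensity.
#' @param min_branch_len spur-pruning length for skeleton artifacts,
#'   pixels.
#' @param merge_junctions contract junction clusters linked by segments
#'   shorter than this many pixels (thinning splits wide branch points
#'   into nearby sub-junctions; should exceed the widest vessel).
#' @param max_generation deepest generation counted.
#' @return A `generation_counts` object: integer counts named by
#'   generation, with a `mode` attribute.
#' @export
count_generations <- function(enhanced, marks = NULL, threshold = "otsu",
                              min_branch_len = 6, merge_junctions = 8,
                              max_generation = 3) {
  if (!is.null(marks)) {
    if (!all(marks$generation %in% seq_len(max_generation)))
      stop("marks must carry generations in 1..", max_generation)
    counts <- tabulate(marks$generation, nbins = max_generation)
    return(structure(setNames(as.integer(counts), seq_len(max_generation)),
                     mode = "manual_marks", class = "generation_counts"))
  }
  frame <- if (inherits(enhanced, "enhanced_frames"))
    enhanced$frames[, , enhanced$peak_index] else enhanced
  thr <- if (identical(threshold, "otsu")) otsu_threshold(frame)
         else as.numeric(threshold)
  mask <- frame > thr
  zero <- structure(setNames(integer(max_generation), seq_len(max_generation)),
                    mode = "automated", class = "generation_counts")
  if (!any(mask) || diff(range(frame)) == 0) {
    warning("no foreground above threshold; returning zero counts")
    return(zero)
  }
  sk <- skeletonize(mask)
  res <- skeleton_segments(sk, min_fragment = 4, prune_tips = min_branch_len,
                           merge_len = merge_junctions)
  segs <- res$segments
  if (!length(segs)) {
    warning("no skeleton segments found; returning zero counts")
    return(zero)
  }
  # mean half-width along each segment, for root (inflow trunk) selection
  edt <- distance_transform(mask)
  width <- vapply(segs, function(s) {
    mean(edt[cbind(s$path[, 1], s$path[, 2])])
  }, numeric(1))

  # per connected component: root at its widest segment, then
  # breadth-first depth across shared junctions
  depth <- rep(NA_integer_, length(segs))
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    root <- todo[which.max(width[todo])]
    d <- segment_depths(segs, root)
    newly <- !is.na(d) & is.na(depth)
    depth[newly] <- d[newly]
    if (is.na(depth[root])) depth[root] <- 1L
  }
  counts <- tabulate(depth[depth <= max_generation], nbins = max_generation)
  structure(setNames(as.integer(counts), seq_len(max_generation)),
            mode = "automated", class = "generation_counts")
}

#' @export
print.generation_counts <- function(x, ...) {
  cat(sprintf("generation_counts (%s): %s\n", attr(x, "mode"),
              paste(sprintf("g%s=%d", names(x), x), collapse = ", ")))
  invisible(x)
}
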