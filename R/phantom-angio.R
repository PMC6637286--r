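# Cine-angiography phantom: contrast-arrival frame sequences over a static
# background (low-frequency smoothed noise plus rib-like bars), with
# branching vessel trees of generations 1-3 and exact per-generation
# ground-truth counts.

#' Sample a branching vessel-tree layout for the angiography phantom
#'
#' Builds `n_trees` inflow trunks, each fanning into `children`
#' generation-2 vessels which fan into `children` generation-3 vessels.
#' Pruning (vascular rarefaction) removes at most one child per junction
#' with the probability that yields the profile's expected per-generation
#' loss, so every surviving junction keeps degree >= 3 and automated
#' segment counting stays exact. Geometry is jittered and re-sampled until
#' no two unrelated segments come closer than `gap` pixels.
#'
#' @param profile an [angio_profile()].
#' @param shape frame dimensions in pixels.
#' @param seed integer RNG seed.
#' @param widths vessel widths per generation, pixels.
#' @param lengths mean segment lengths per generation, pixels.
#' @param gap minimum clearance between unrelated segments, pixels.
#' @return data.frame of segments (`x0, y0, x1, y1, width, generation,
#'   tree`) with a `counts` attribute (vessels per generation).
#' @export
sample_angiogram_tree <- function(profile, shape = c(512, 512), seed = 1,
                                  widths = c(7, 5, 3),
                                  lengths = c(110, 50, 26), gap = 4) {
  stopifnot(profile$depth == 3, profile$children >= 2)
  nch <- profile$children
  p2 <- profile$prune_g2
  p3 <- profile$prune_g3
  # per-junction single-child removal probabilities giving the expected
  # generation losses
  rho2 <- nch * p2
  extra3 <- if (p2 < 1) max(0, 1 - (1 - p3) / (1 - p2)) else 0
  rho3 <- nch * extra3

  with_seed(seed, {
    for (try in 1:60) {
      segs <- list()
      add <- function(p0, p1, w, gen, tr, junc) {
        segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, w = w,
                                           gen = gen, tree = tr, junc = junc)
      }
      xs <- seq(shape[1] / (2 * profile$n_trees), shape[1],
                by = shape[1] / profile$n_trees)
      jid <- 0L
      for (t in seq_len(profile$n_trees)) {
        a0 <- (90 + runif(1, -8, 8)) * pi / 180  # mostly downward
        d0 <- c(cos(a0), sin(a0))
        p0 <- c(xs[t] + runif(1, -10, 10), 30)
        L1 <- lengths[1] * runif(1, 0.9, 1.1)
        p1 <- p0 + L1 * d0
        jid <- jid + 1L
        j1 <- jid
        add(p0, p1, widths[1], 1L, t, c(NA_integer_, j1))
        drop2 <- if (runif(1) < rho2) sample.int(nch, 1) else 0L
        base2 <- atan2(d0[2], d0[1])
        fan <- seq(-30, 30, length.out = nch)
        for (c2 in seq_len(nch)) {
          if (c2 == drop2) next
          a2 <- base2 + (fan[c2] + runif(1, -5, 5)) * pi / 180
          d2 <- c(cos(a2), sin(a2))
          L2 <- lengths[2] * runif(1, 0.9, 1.1)
          q1 <- p1 + L2 * d2
          jid <- jid + 1L
          j2 <- jid
          add(p1, q1, widths[2], 2L, t, c(j1, j2))
          drop3 <- if (runif(1) < rho3) sample.int(nch, 1) else 0L
          for (c3 in seq_len(nch)) {
            if (c3 == drop3) next
            a3 <- a2 + (fan[c3] + runif(1, -5, 5)) * pi / 180
            d3 <- c(cos(a3), sin(a3))
            L3 <- lengths[3] * runif(1, 0.9, 1.1)
            add(q1, q1 + L3 * d3, widths[3], 3L, t, c(j2, NA_integer_))
          }
        }
      }
      if (tree_layout_ok(segs, shape, gap)) {
        df <- do.call(rbind, lapply(segs, function(s) {
          data.frame(x0 = s$p0[1], y0 = s$p0[2], x1 = s$p1[1], y1 = s$p1[2],
                     width = s$w, generation = s$gen, tree = s$tree)
        }))
        attr(df, "counts") <- tabulate(df$generation, nbins = 3)
        return(df)
      }
    }
    stop("could not sample a non-overlapping tree layout; widen the frame")
  })
}

# all segments in bounds and unrelated pairs separated
tree_layout_ok <- function(segs, shape, gap) {
  for (s in segs) {
    if (any(c(s$p0, s$p1) < s$w / 2 + 2) ||
        any(c(s$p0[1], s$p1[1]) > shape[1] - s$w / 2 - 2) ||
        any(c(s$p0[2], s$p1[2]) > shape[2] - s$w / 2 - 2)) return(FALSE)
  }
  n <- length(segs)
  if (n < 2) return(TRUE)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    si <- segs[[i]]; sj <- segs[[j]]
    shared <- length(intersect(na.omit(si$junc), na.omit(sj$junc))) > 0
    if (shared) next
    d <- seg_seg_dist(c(si$p0, 0), c(si$p1, 0), c(sj$p0, 0), c(sj$p1, 0))
    if (d < (si$w + sj$w) / 2 + gap) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic cine-angiogram sequence
#'
#' Frames before contrast arrival contain only the static background
#' (smoothed low-frequency noise plus high-contrast bars standing in for
#' ribs); later frames add vessel opacity ramping along a saturating
#' contrast-arrival curve. The background is identical in every frame, so
#' subtracting the pre-injection frame isolates the vessels exactly.
#' Optional salt noise is recorded in a registry for filter validation.
#'
#' @param tree segment layout from [sample_angiogram_tree()] (or a
#'   compatible data.frame with columns `x0, y0, x1, y1, width,
#'   generation`).
#' @param n_frames total frames (> `pre_injection_frames`).
#' @param pre_injection_frames frames acquired before contrast arrival
#'   (>= 1).
#' @param pixel_size pixel pitch, um.
#' @param shape frame dimensions.
#' @param seed integer RNG seed.
#' @param background render the static background (FALSE gives pure vessel
#'   frames).
#' @param vessel_contrast peak vessel opacity.
#' @param arrival_tau contrast-arrival time constant, frames.
#' @param salt_rate fraction of pixels per post-injection frame replaced by
#'   salt noise.
#' @param frame_interval ms between frames.
#' @return An `angiogram_sequence`: frames array `[x, y, t]`,
#'   `pre_injection_index`, pixel/frame metadata, ground-truth generation
#'   `counts`, the vessel opacity map, and the salt-noise registry.
#' @export
generate_angiogram_sequence <- function(tree, n_frames = 40,
                                        pre_injection_frames = 8,
                                        pixel_size = 9.9,
                                        shape = c(512, 512), seed = 1,
                                        background = TRUE,
                                        vessel_contrast = 0.5,
                                        arrival_tau = 5,
                                        salt_rate = 0,
                                        frame_interval = 30) {
  if (is.null(tree) || !nrow(tree) || !any(tree$generation >= 1))
    stop("tree layout with at least one generation required")
  if (!(n_frames > pre_injection_frames && pre_injection_frames >= 1))
    stop("need n_frames > pre_injection_frames >= 1")
  counts <- attr(tree, "counts") %||% tabulate(tree$generation, nbins = 3)

  with_seed(seed, {
    dims3 <- c(as.integer(shape), 1L)
    vmap <- array(0, dims3)
    for (i in seq_len(nrow(tree))) {
      vmap <- cpp_render_capsule(vmap, dims3,
                                 c(tree$x0[i], tree$y0[i], 1),
                                 c(tree$x1[i], tree$y1[i], 1),
                                 tree$width[i] / 2, 1, 4L)
    }
    vmap <- vmap[, , 1]
    bg <- if (background) {
      lowfreq <- blur2d(matrix(runif(prod(shape)), shape[1], shape[2]), 12)
      lowfreq <- 0.25 + 0.5 * (lowfreq - min(lowfreq)) /
        max(1e-12, diff(range(lowfreq)))
      ribs <- matrix(0, shape[1], shape[2])
      if (shape[2] >= 112) {
        for (yc in seq(60, shape[2] - 40, by = 90))
          ribs[, yc:min(yc + 11, shape[2])] <- 0.2
      }
      lowfreq + ribs
    } else matrix(0, shape[1], shape[2])

    arrival <- ifelse(seq_len(n_frames) <= pre_injection_frames, 0,
                      1 - exp(-(seq_len(n_frames) - pre_injection_frames) /
                                arrival_tau))
    frames <- array(0, c(shape, n_frames))
    registry <- list()
    for (t in seq_len(n_frames)) {
      f <- bg + arrival[t] * vessel_contrast * vmap
      if (salt_rate > 0 && t > pre_injection_frames) {
        ns <- round(salt_rate * prod(shape))
        pix <- sample.int(prod(shape), ns)
        f[pix] <- 1
        registry[[length(registry) + 1L]] <-
          data.frame(frame = t, pixel = pix)
      }
      frames[, , t] <- f
    }
    structure(
      list(frames = frames, pixel_size = pixel_size,
           frame_interval = frame_interval,
           pre_injection_index = pre_injection_frames,
           counts = counts, vessel_map = vmap, tree = tree,
           salt_registry = if (length(registry)) do.call(rbind, registry)
                           else NULL,
           arrival = arrival),
      class = "angiogram_sequence")
  })
}

#' @export
print.angiogram_sequence <- function(x, ...) {
  cat(sprintf(
    "angiogram_sequence: %d frames %d x %d, %.1f um/px, pre-injection 1..%d\n",
    dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
    x$pixel_size, x$pre_injection_index))
  cat("ground-truth generation counts:", paste(x$counts, collapse = ", "),
      "\n")
  invisible(x)
}
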