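# Voxel primitives: distance transform against a brute-force oracle,
# thinning of tubes to centerlines, component labeling.

test_that("distance transform matches brute force on a random small mask", {
  set.seed(42)
  dims <- c(9, 8, 7)
  mask <- array(runif(prod(dims)) < 0.6, dims)
  got <- pulmovasc:::distance_transform(mask)
  coords <- which(mask, arr.ind = TRUE)
  bgc <- which(!mask, arr.ind = TRUE)
  for (k in sample(nrow(coords), min(25, nrow(coords)))) {
    p <- coords[k, ]
    d_in <- if (nrow(bgc)) min(sqrt(colSums((t(bgc) - p)^2))) else Inf
    # voxels outside the grid count as background
    d_out <- min(p, dims - p + 1)
    expect_equal(got[p[1], p[2], p[3]], min(d_in, d_out), tolerance = 1e-9)
  }
  expect_true(all(got[!mask] == 0))
})

test_that("thinning reduces a straight tube to its centerline", {
  mask <- capsule_mask(c(40, 15, 15), c(6, 8, 8), c(34, 8, 8), 2.1)
  sk <- skeletonize(mask)
  idx <- which(sk, arr.ind = TRUE)
  # one-voxel-wide path on the tube axis
  expect_true(all(idx[, 2] == 8) && all(idx[, 3] == 8))
  expect_gte(nrow(idx), 25)
  # thinning is idempotent
  expect_identical(skeletonize(sk), sk)
})

test_that("component labeling separates disjoint structures", {
  m <- array(FALSE, c(20, 20, 3))
  m[2:5, 2:5, 2] <- TRUE
  m[12:15, 12:15, 2] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab == 1), 16)
})

test_that("skeleton segments recover a Y-bifurcation topology", {
  dims <- c(48, 48, 15)
  m <- capsule_mask(dims, c(6, 24, 8), c(24, 24, 8), 2) |
    capsule_mask(dims, c(24, 24, 8), c(40, 12, 8), 2) |
    capsule_mask(dims, c(24, 24, 8), c(40, 36, 8), 2)
  sk <- skeletonize(m)
  res <- pulmovasc:::skeleton_segments(sk, min_fragment = 4, prune_tips = 5)
  expect_equal(length(res$segments), 3L)
  juncs <- unique(na.omit(unlist(lapply(res$segments, `[[`, "junc"))))
  expect_equal(length(juncs), 1L)
})
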