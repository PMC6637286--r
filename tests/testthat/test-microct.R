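# Micro-CT chain: DoG against a dense-convolution oracle, filling against
# a flood-fill oracle, tracing and diameter estimation on phantoms,
# binning rules and reference normalization.

test_that("empty volume yields an empty edge mask", {
  v <- volume3d(array(0, c(24, 24, 4)))
  e <- detect_large_vessel_edges(v)
  expect_false(any(e$mask))
})

test_that("sequential DoG response matches the dense convolution oracle", {
  n <- 21
  impulse <- matrix(0, n, n)
  impulse[11, 11] <- 1
  vol <- array(impulse, c(n, n, 1))
  got <- pulmovasc:::dog_bandpass(vol, 1.2, 2.0, 1.6)[, , 1]
  want <- dense_dog(dense_dog(impulse, 1.2), 2.0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("edge detection marks the wall band of a cylinder, not its fill", {
  # noise-free tube along z, radius 20 px: per-plane response concentrates
  # in an annulus near the wall; the deep interior stays dark (the
  # detector finds the edge, not the fill)
  n <- 96
  xs <- matrix(rep(seq_len(n), n), n)
  ys <- t(xs)
  d <- sqrt((xs - 48)^2 + (ys - 48)^2)
  plane <- ifelse(d <= 20, 1, 0)
  vol <- volume3d(array(rep(plane, 6), c(n, n, 6)))
  e <- detect_large_vessel_edges(vol)
  m <- e$mask[, , 3]
  expect_gt(sum(m), 50)                      # a wall band was detected
  expect_gt(mean(abs(d - 20)[m] <= 8), 0.9)  # concentrated at the wall
  expect_lt(mean(m[d <= 8]), 0.05)           # deep interior stays empty
})

test_that("filling equals the border flood-fill complement on contours", {
  ring <- annulus_mask()
  bv <- binary_volume(array(ring, c(dim(ring), 1L)))
  filled <- fill_large_vessels(bv)
  expect_equal(filled$mask[, , 1], flood_fill_oracle(ring))
  # idempotence: an already-solid disk passes through unchanged
  disk <- annulus_mask(r_in = 0)
  bv2 <- binary_volume(array(disk, c(dim(disk), 1L)))
  expect_equal(fill_large_vessels(bv2)$mask[, , 1], disk)
})

test_that("gap closing is controlled by max_gap", {
  ring <- annulus_mask()
  ring[16:17, 1:10] <- FALSE   # 2-px cut through the ring wall
  bv <- binary_volume(array(ring, c(dim(ring), 1L)))
  open_count <- sum(ring)
  # tip pairing must bridge the cut (skeleton endpoints retract a little,
  # so the tip-to-tip distance slightly exceeds the nominal 2-px gap);
  # after bridging, the interior fills to the closed-ring oracle
  closed <- fill_large_vessels(bv, max_gap = 5)
  unclosed <- fill_large_vessels(bv, max_gap = 1)
  oracle <- flood_fill_oracle(annulus_mask())
  expect_gt(sum(closed$mask), sum(oracle) * 0.9)
  expect_lt(sum(unclosed$mask), open_count + 10)
  expect_error(fill_large_vessels(bv, max_gap = 0), "max_gap")
})

test_that("tracing empty masks returns an empty network", {
  dims <- c(16, 16, 4)
  net <- trace_filaments(binary_volume(array(FALSE, dims)),
                         volume3d(array(0, dims)))
  expect_equal(length(net$segments), 0L)
  h <- bin_vessels(net)
  expect_true(all(h$count == 0))
  expect_true(attr(h, "undefined_percent"))
})

test_that("a thin tube phantom traces to one segment of the right length", {
  prof <- tiny_profile(c(7, 9), 1)
  ph <- generate_vascular_volume(prof, shape = c(56, 56, 56), seed = 4,
                                 noise_sd = 0, count_mode = "fixed",
                                 tree = FALSE)
  res <- microct_pipeline(ph$volume)
  df <- as.data.frame(res$network)
  df <- df[!df$flagged, ]
  expect_equal(nrow(df), 1L)
  expect_lt(abs(df$length_vox - ph$truth$segments$length_vox), 3)
})

test_that("diameters recover ground truth within a voxel across calibres", {
  for (d_true in c(8, 14, 24)) {
    prof <- tiny_profile(c(d_true - 0.2, d_true + 0.2), 1)
    ph <- generate_vascular_volume(prof, shape = c(56, 56, 56), seed = 6,
                                   noise_sd = 0, count_mode = "fixed",
                                   tree = FALSE)
    res <- microct_pipeline(ph$volume)
    df <- as.data.frame(res$network)
    df <- df[!df$flagged, ]
    expect_equal(nrow(df), 1L)
    expect_lt(abs(df$diameter_um - ph$truth$segments$diameter_um), 6)
  }
})

test_that("a one-voxel-wide binary line measures one voxel in diameter", {
  dims <- c(32, 16, 16)
  mask <- array(FALSE, dims)
  mask[6:26, 8, 8] <- TRUE
  net <- trace_filaments(binary_volume(mask), volume3d(mask * 1,
                                                       voxel_size = 6))
  net <- estimate_diameters(net)
  df <- as.data.frame(net)
  expect_equal(nrow(df), 1L)
  expect_equal(df$diameter_um, 6, tolerance = 1e-6)
})

test_that("binning applies the 4-um cutoff and half-open bins", {
  fake_net <- structure(list(segments = list(), voxel_size = 6),
                        class = "filament_network")
  df <- data.frame(segment = 1:3, class = "small", n_points = 10,
                   length_vox = 10, diameter_um = c(3.5, 4.2, 5.5),
                   flagged = FALSE)
  # route through the same binning code via a minimal as.data.frame stub
  h <- with(list(), {
    net <- fake_net
    net$segments <- lapply(seq_len(3), function(i) {
      list(path = cbind(1:2, 1, 1), class = "small",
           diameter_um = df$diameter_um[i], flagged = FALSE)
    })
    bin_vessels(net, bin_edges = c(4, 5, 6, 7))
  })
  expect_equal(h$count, c(1, 1, 0))
  expect_equal(attr(h, "discarded"), 1)
  expect_equal(sum(h$percent), 100)
})

test_that("percent of total sums to 100 and counts are conserved", {
  prof <- tiny_profile(c(4, 6, 10, 16), c(4, 3, 2))
  ph <- generate_vascular_volume(prof, shape = c(72, 72, 72), seed = 2,
                                 tree = FALSE)
  res <- microct_pipeline(ph$volume, bin_edges = c(4, 6, 10, 16))
  h <- res$histogram
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  df <- as.data.frame(res$network)
  n_ok <- sum(!df$flagged & !is.na(df$diameter_um))
  expect_equal(sum(h$count) + attr(h, "discarded") + attr(h, "overflow"),
               n_ok)
})

test_that("adding a vessel never decreases any bin count", {
  prof1 <- tiny_profile(c(10, 14, 20), c(2, 1))
  ph1 <- generate_vascular_volume(prof1, shape = c(64, 64, 64), seed = 8,
                                  noise_sd = 0, count_mode = "fixed",
                                  tree = FALSE)
  h1 <- microct_pipeline(ph1$volume, bin_edges = c(10, 14, 20))$histogram
  # same layout plus one more vessel: rebuild with an extra segment by
  # rendering the extra tube into the same volume
  v2 <- ph1$volume$voxels
  v2 <- pulmovasc:::cpp_render_capsule(v2, dim(v2), c(10, 50, 10),
                                       c(30, 55, 12), 1.0, 1, 6L)
  h2 <- microct_pipeline(volume3d(v2, 6),
                         bin_edges = c(10, 14, 20))$histogram
  expect_true(all(h2$count >= h1$count))
})

test_that("reference normalization follows the air-group convention", {
  mk <- function(counts, group, id) {
    net <- structure(list(segments = lapply(counts, function(d)
      list(path = cbind(1:2, 1, 1), class = "small", diameter_um = d,
           flagged = FALSE)), voxel_size = 6), class = "filament_network")
    bin_vessels(net, bin_edges = c(4, 6, 8), specimen_id = id,
                group = group)
  }
  # reference: two specimens, totals 4 and 2 (mean 3)
  h1 <- mk(c(4.5, 4.5, 6.5, 7.5), "ref", "r1")
  h2 <- mk(c(4.5, 6.5), "ref", "r2")
  # group B: total 3 = exactly the reference mean
  h3 <- mk(c(4.5, 4.5, 7.5), "B", "b1")
  out <- normalize_to_reference(list(h1, h2, h3), "ref")
  expect_equal(attr(out[[3]], "norm_factor"), 1)
  expect_equal(out[[3]]$normalized, out[[3]]$percent)
  # halved totals scale normalized values by 0.5
  h4 <- mk(c(4.5), "C", "c1")  # total 1
  h5 <- mk(c(6.5, 7.5), "C", "c2")  # total 2 -> mean 1.5 = 0.5 * ref mean
  out2 <- normalize_to_reference(list(h1, h2, h4, h5), "ref")
  expect_equal(attr(out2[[3]], "norm_factor"), 1 / 3)
  # reference normalized against itself: mean factor 1
  fac <- sapply(out[1:2], attr, "norm_factor")
  expect_equal(mean(fac), 1)
  expect_error(normalize_to_reference(list(h1), "missing"), "reference")
})
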