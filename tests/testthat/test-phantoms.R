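# Generator contracts: determinism, ground-truth completeness, calibration
# of realized counts against profile expectations, and argument validation.

test_that("vascular phantom is deterministic and complete", {
  prof <- tiny_profile(c(10, 14, 20), c(2, 2))
  a <- generate_vascular_volume(prof, shape = c(48, 48, 48), seed = 9,
                                tree = FALSE)
  b <- generate_vascular_volume(prof, shape = c(48, 48, 48), seed = 9,
                                tree = FALSE)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$segments, b$truth$segments)
  # different seed, different volume
  c <- generate_vascular_volume(prof, shape = c(48, 48, 48), seed = 10,
                                tree = FALSE)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
  # every emplaced segment appears in the truth, realized counts match
  expect_equal(sum(a$truth$counts), nrow(a$truth$segments))
  expect_equal(as.integer(table(factor(a$truth$segments$bin, levels = 1:2))),
               a$truth$counts)
})

test_that("single-tube deterministic phantom places exactly one segment", {
  prof <- tiny_profile(c(10, 12), 1)
  ph <- generate_vascular_volume(prof, shape = c(40, 40, 40), seed = 1,
                                 noise_sd = 0, count_mode = "fixed",
                                 tree = FALSE)
  expect_equal(nrow(ph$truth$segments), 1L)
  expect_gt(max(ph$volume$voxels), 0.9)
  d <- ph$truth$segments$diameter_um[1]
  expect_true(d >= 10 && d < 12)
})

test_that("realized per-bin counts are calibrated to expectations", {
  # over >= 20 seeds the mean realized count per bin stays within 3
  # standard errors of the Poisson expectation
  prof <- tiny_profile(c(4, 5, 6), c(6, 4))
  counts <- sapply(1:20, function(s) {
    generate_vascular_volume(prof, shape = c(64, 64, 64), seed = s,
                             noise_sd = 0, tree = FALSE)$truth$counts
  })
  for (b in 1:2) {
    se3 <- 3 * sqrt(prof$expected_counts[b] / 20)
    expect_lt(abs(mean(counts[b, ]) - prof$expected_counts[b]), se3)
  }
})

test_that("depletion factors carry through to expected counts", {
  air <- condition_profile("air_vehicle")
  hyp <- condition_profile("hyperoxia_vehicle")
  expect_equal(hyp$expected_counts[1] / air$expected_counts[1], 0.16)
  expect_equal(hyp$expected_counts[2] / air$expected_counts[2], 0.17)
  expect_equal(hyp$expected_counts[3] / air$expected_counts[3], 0.24)
  # realized counts across 20 seeds reflect the depletion within Poisson
  # error (compare against the configured expectation, 3 SE band)
  h1 <- sapply(1:20, function(s) {
    generate_vascular_volume(hyp, shape = c(96, 96, 96), seed = s,
                             noise_sd = 0, tree = FALSE)$truth$counts[1]
  })
  se3 <- 3 * sqrt(hyp$expected_counts[1] / 20)
  expect_lt(abs(mean(h1) - hyp$expected_counts[1]), se3)
})

test_that("impossible placements fail with the offending bin named", {
  prof <- tiny_profile(c(100, 120), 3)
  expect_error(
    generate_vascular_volume(prof, shape = c(24, 24, 24), seed = 1),
    "shape too small.*\\[100,120\\)")
})

test_that("angiogram phantom isolates vessels by frame subtraction", {
  tree <- data.frame(x0 = 40, y0 = 10, x1 = 40, y1 = 60, width = 5,
                     generation = 1)
  sq <- generate_angiogram_sequence(tree, n_frames = 12,
                                    pre_injection_frames = 4,
                                    shape = c(80, 80), seed = 1,
                                    background = FALSE, arrival_tau = 0.5)
  enh <- subtract_background(sq)
  peak <- enh$frames[, , enh$peak_index]
  # with no background, the difference equals the (ramped) vessel image
  ramp <- sq$arrival[enh$source_frames[enh$peak_index]]
  expect_equal(peak, 0.5 * ramp * sq$vessel_map, tolerance = 1e-12)
  # bookkeeping of configured counts
  expect_equal(sq$counts, c(1, 0, 0))
  expect_error(generate_angiogram_sequence(tree[0, ], seed = 1),
               "at least one generation")
  expect_error(generate_angiogram_sequence(tree, n_frames = 3,
                                           pre_injection_frames = 3),
               "n_frames")
})

test_that("pcls phantom obeys the logistic limits", {
  p <- fourpl_params(100, 60, -8, 1)
  expect_equal(fourpl_area(p, 0), 100)              # zero-drug limit
  expect_equal(fourpl_area(p, 1), 60, tolerance = 1e-6)  # saturation
  expect_equal(fourpl_area(p, 1e-8), 80)            # EC50 midpoint
  tl <- generate_pcls_timelapse(p, c(1e-9, 1e-8, 1e-7), noise_sd = 0,
                                frames_per_step = 3, seed = 2,
                                image_noise_sd = 0)
  # baseline frames carry the configured initial area (+- rasterization)
  expect_equal(tl$area_px[1] / 1200, 1, tolerance = 0.01)
  expect_error(generate_pcls_timelapse(p, c(1e-9, 1e-8), noise_sd = -1),
               "noise_sd")
  expect_error(generate_pcls_timelapse(p, c(1e-8, 1e-9)), "ascending")
})

test_that("doppler trace peaks at tpv and ends at rvet", {
  prof <- structure(list(tpv = 30, rvet = 100, peak_velocity = 500,
                         sample_rate = 1000, heart_period = 150),
                    class = "doppler_profile")
  tr <- generate_doppler_trace(prof)
  expect_equal(tr$time_ms[which.max(tr$velocity)], 30)
  nz <- tr$time_ms[tr$velocity > 0]
  expect_lte(max(nz), 100)
  expect_gt(max(nz), 98)
  # symmetric triangle: tpv = rvet/2 peaks mid-window
  prof$tpv <- 50
  tr2 <- generate_doppler_trace(prof)
  expect_equal(which.max(tr2$velocity), 51)  # t = 50 ms at 1 kHz
  # insufficient pre-peak sampling fails
  prof$sample_rate <- 100
  prof$tpv <- 30
  expect_error(generate_doppler_trace(prof), "sample_rate")
})

test_that("ct table generator reproduces group means at zero noise", {
  gm <- qpcr_group_means()
  tab <- generate_ct_table(gm, noise_sd = 0, n_per_group = 3, seed = 5)
  for (i in seq_len(nrow(gm))) {
    got <- tab$ct[tab$gene == gm$gene[i] & tab$group == gm$group[i]]
    expect_equal(got, rep(gm$mean_ct[i], 3))
  }
  expect_error(generate_ct_table(gm, housekeeping = "Gapdh"), "Gapdh")
})

test_that("histology phantom hits the requested collagen fraction", {
  ph <- generate_histology_image(0.25, 0, shape = c(128, 128), seed = 3)
  n_tissue <- sum(!ph$vessel_mask)
  expect_equal(sum(ph$collagen_mask), round(0.25 * n_tissue))
  ph0 <- generate_histology_image(0, 0.05, shape = c(64, 64), seed = 3)
  expect_equal(sum(ph0$collagen_mask), 0)
  expect_error(generate_histology_image(0.8, 0.5), "<= 1")
  expect_error(generate_histology_image(-0.1, 0), "fractions")
})
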