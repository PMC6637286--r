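# PCLS: lumen segmentation, concentration-response construction and
# four-parameter logistic fitting (exact recovery, potency ratio, bias).

test_that("lumen segmentation counts the dark ellipse within 1%", {
  p <- fourpl_params(100, 60, -8, 1)
  tl <- generate_pcls_timelapse(p, c(1e-9, 1e-8), frames_per_step = 2,
                                noise_sd = 0, initial_area_px = 500,
                                seed = 1, image_noise_sd = 0.01)
  a <- segment_lumen(tl$frames[, , 1])
  expect_lt(abs(a - tl$area_px[1]) / tl$area_px[1], 0.01)
})

test_that("uniform image warns and yields zero area", {
  expect_warning(a <- segment_lumen(matrix(0.5, 20, 20), threshold = 0.2),
                 "zero")
  expect_equal(a, 0L)
})

test_that("seeded segmentation counts only the seeded component", {
  img <- matrix(0.8, 40, 40)
  img[5:10, 5:10] <- 0.1    # 36 px
  img[25:34, 25:34] <- 0.1  # 100 px
  expect_equal(segment_lumen(img, threshold = 0.5, seed_point = c(6, 6)), 36)
  expect_equal(segment_lumen(img, threshold = 0.5, seed_point = c(30, 30)),
               100)
  expect_equal(segment_lumen(img, threshold = 0.5), 100)  # largest
})

test_that("constant areas give zero response; plateau arithmetic holds", {
  tr <- lumen_trace(times = 0:29, areas = rep(700, 30))
  steps <- data.frame(concentration = c(0, 1e-9, 1e-8),
                      start = c(0, 10, 20), end = c(10, 20, 30))
  cr <- build_concentration_response(tr, steps)
  expect_equal(cr$response, c(0, 0))
  # final plateau at 57% of initial -> response 43%
  tr2 <- lumen_trace(0:29, c(rep(1000, 10), rep(800, 10), rep(570, 10)))
  cr2 <- build_concentration_response(tr2, steps)
  expect_equal(cr2$response[2], 43)
  # overlapping windows are rejected
  bad <- data.frame(concentration = c(0, 1e-9), start = c(0, 5),
                    end = c(10, 20))
  expect_error(build_concentration_response(tr, bad), "overlap")
})

test_that("noise-free responses equal the logistic law exactly (round trip)", {
  ag <- agonist_profile("et1")
  tl <- generate_pcls_timelapse(ag, ag$concentrations, noise_sd = 0,
                                frames_per_step = 5, seed = 3,
                                image_noise_sd = 0)
  cr <- build_concentration_response(measure_timelapse(tl), tl$steps)
  want <- 100 * (1 - fourpl_area(ag, ag$concentrations) / ag$bottom)
  # rasterized ellipse areas quantize at the percent level
  expect_equal(cr$response, want, tolerance = 0.04)
})

test_that("noise-free 4PL data is recovered to machine precision", {
  ag <- agonist_profile("et1")
  cr <- sample_concentration_response(ag, ag$concentrations, 0, 1)
  fit <- fit_four_pl(cr)
  expect_equal(fit$pec50, -ag$logec50, tolerance = 1e-6)
  expect_equal(fit$max_reduction, ag$bottom - ag$top, tolerance = 1e-6)
  expect_equal(fit$params$hill, ag$hill, tolerance = 1e-6)
})

test_that("profiles one log unit apart fit a tenfold potency ratio", {
  e <- agonist_profile("et1")
  u <- agonist_profile("u46619")
  fe <- fit_four_pl(sample_concentration_response(e, e$concentrations, 0, 1))
  fu <- fit_four_pl(sample_concentration_response(u, u$concentrations, 0, 1))
  expect_equal(fu$ec50 / fe$ec50, 10, tolerance = 1e-4)
})

test_that("fitted curve is monotone and pEC50 bias stays under 0.1 logs", {
  ag <- agonist_profile("et1")
  pec <- sapply(1:40, function(s) {
    fit_four_pl(sample_concentration_response(ag, ag$concentrations,
                                              0.05, s))$pec50
  })
  expect_lt(abs(mean(pec) - (-ag$logec50)), 0.1)
  # monotonicity of the fitted curve in concentration (hill > 0)
  f <- fit_four_pl(sample_concentration_response(ag, ag$concentrations,
                                                 0.05, 11))
  cgrid <- 10^seq(-10, -6, length.out = 50)
  resp <- f$params$bottom + (f$params$top - f$params$bottom) /
    (1 + 10^((f$params$logec50 - log10(cgrid)) * f$params$hill))
  expect_true(all(diff(resp) >= -1e-9))
})

test_that("fitting rejects undersized designs and flags flat data", {
  cr <- data.frame(concentration = c(1e-9, 1e-8, 1e-7), response = 1:3)
  expect_error(fit_four_pl(cr), "4 distinct")
  flat <- data.frame(concentration = 10^seq(-9, -6, length.out = 5),
                     response = rep(20, 5))
  expect_warning(try(fit_four_pl(flat), silent = TRUE), "degenerate")
})

test_that("responses ignore uniform image intensity scaling", {
  p <- fourpl_params(100, 60, -8, 1)
  tl <- generate_pcls_timelapse(p, c(1e-9, 1e-8, 1e-7), frames_per_step = 4,
                                noise_sd = 0, seed = 9, image_noise_sd = 0)
  tl2 <- tl
  tl2$frames <- tl$frames * 0.5   # same threshold side under Otsu
  a1 <- measure_timelapse(tl)$areas
  a2 <- measure_timelapse(tl2)$areas
  expect_equal(a1, a2)
})
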