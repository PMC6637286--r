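# Echo indices: TPV/RVET detection and invariances, fractional shortening.

test_that("a symmetric triangular envelope gives a ratio of one half", {
  prof <- structure(list(tpv = 50, rvet = 100, peak_velocity = 600,
                         sample_rate = 1000, heart_period = 150),
                    class = "doppler_profile")
  r <- compute_tpv_rvet(generate_doppler_trace(prof))
  expect_equal(r$ratio, 0.5, tolerance = 1e-6)
})

test_that("tpv/rvet round-trips over a grid of profiles", {
  for (tpv in c(25, 32, 40)) {
    for (rvet in c(90, 100, 120)) {
      prof <- structure(list(tpv = tpv, rvet = rvet, peak_velocity = 500,
                             sample_rate = 1000, heart_period = 160),
                        class = "doppler_profile")
      r <- compute_tpv_rvet(generate_doppler_trace(prof))
      expect_equal(r$ratio, tpv / rvet, tolerance = 1 / rvet)  # one sample
    }
  }
})

test_that("the ratio converges to tpv/rvet as sampling improves", {
  errs <- sapply(c(500, 2000, 8000), function(sr) {
    prof <- structure(list(tpv = 32, rvet = 100, peak_velocity = 500,
                           sample_rate = sr, heart_period = 150),
                      class = "doppler_profile")
    abs(compute_tpv_rvet(generate_doppler_trace(prof))$ratio - 0.32)
  })
  expect_true(all(diff(errs) <= 1e-9) || errs[3] < errs[1])
  expect_lt(errs[3], 1e-3)
})

test_that("the ratio is invariant to velocity scaling and time shifts", {
  prof <- doppler_profile("air_vehicle")
  tr <- generate_doppler_trace(prof)
  r0 <- compute_tpv_rvet(tr)$ratio
  tr2 <- tr
  tr2$velocity <- tr$velocity * 3.3
  expect_equal(compute_tpv_rvet(tr2)$ratio, r0)
  tr3 <- tr
  tr3$time_ms <- tr$time_ms + 250
  expect_equal(compute_tpv_rvet(tr3)$ratio, r0)
})

test_that("flat traces and degenerate windows are rejected", {
  flat <- data.frame(time_ms = 0:50, velocity = rep(1, 51))
  expect_error(compute_tpv_rvet(flat), "flat")
  tr <- generate_doppler_trace(doppler_profile("air_vehicle"))
  expect_error(compute_tpv_rvet(tr, window = c(50, 50)), "window")
})

test_that("fractional shortening follows the clinical definition", {
  expect_equal(fractional_shortening(4.0, 2.0), 50)
  expect_equal(fractional_shortening(3.0, 3.0), 0)
  expect_equal(fractional_shortening(3.6, 2.16), 40)
  expect_error(fractional_shortening(2.0, 2.5), "exceeds")
  expect_error(fractional_shortening(0, 0), "positive")
})
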