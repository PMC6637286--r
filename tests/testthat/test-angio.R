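# Angiography: subtraction identities and linearity, median filtering of
# salt noise, manual tallies and automated generation counting.

test_that("subtraction cancels a static background exactly", {
  tree <- data.frame(x0 = 30, y0 = 10, x1 = 30, y1 = 50, width = 5,
                     generation = 1)
  sq <- generate_angiogram_sequence(tree, n_frames = 10,
                                    pre_injection_frames = 4,
                                    shape = c(64, 64), seed = 2,
                                    background = TRUE)
  enh <- subtract_background(sq)
  # pre-injection frames are identical, so an all-background difference
  # of two pre frames is zero
  expect_equal(sq$frames[, , 1], sq$frames[, , 4])
  # background is gone from every difference frame: off-vessel pixels 0
  off <- sq$vessel_map == 0
  for (k in seq_len(dim(enh$frames)[3]))
    expect_true(all(enh$frames[, , k][off] == 0))
  expect_error(subtract_background(list(frames = sq$frames,
                                        pre_injection_index = 99)),
               "out of range")
})

test_that("subtraction is linear in frame intensity before clipping", {
  tree <- data.frame(x0 = 30, y0 = 10, x1 = 30, y1 = 50, width = 5,
                     generation = 1)
  sq <- generate_angiogram_sequence(tree, n_frames = 8,
                                    pre_injection_frames = 3,
                                    shape = c(64, 64), seed = 3,
                                    background = FALSE)
  sq2 <- sq
  sq2$frames <- 2.5 * sq$frames
  e1 <- subtract_background(sq)
  e2 <- subtract_background(sq2)
  expect_equal(e2$frames, 2.5 * e1$frames, tolerance = 1e-12)
})

test_that("median filtering leaves constants and removes salt", {
  const <- matrix(0.4, 32, 32)
  expect_equal(median_filter_frames(const), const)
  salted <- const
  salted[16, 16] <- 1
  expect_equal(median_filter_frames(salted), const)
})

test_that("salt noise is suppressed by subtraction + median filtering", {
  tree <- sample_angiogram_tree(angio_profile("air_vehicle"),
                                shape = c(384, 384), seed = 5,
                                lengths = c(80, 40, 20))
  sq <- generate_angiogram_sequence(tree, shape = c(384, 384), seed = 5,
                                    salt_rate = 0.01)
  enh <- median_filter_frames(subtract_background(sq))
  reg <- sq$salt_registry
  k <- enh$peak_index
  src <- enh$source_frames[k]
  pix <- reg$pixel[reg$frame == src]
  # off-vessel salt pixels must be driven to (near) zero
  off <- pix[sq$vessel_map[pix] == 0]
  cleaned <- enh$frames[, , k][off]
  expect_gte(mean(cleaned < 0.05), 0.99)
})

test_that("manual mark tallies reproduce the color-dot counts", {
  marks <- data.frame(x = c(1, 2, 3), y = c(1, 1, 2),
                      generation = c(1, 1, 2))
  gc <- count_generations(NULL, marks = marks)
  expect_equal(as.integer(gc), c(2, 1, 0))
  expect_equal(attr(gc, "mode"), "manual_marks")
  expect_error(count_generations(NULL,
                                 marks = data.frame(x = 1, y = 1,
                                                    generation = 5)),
               "generations in 1")
})

test_that("automated counting matches ground truth on a binary-fan tree", {
  # user-specified layout: 2 trunks, each with 2 children, each with 2
  # grandchildren -> counts (2, 4, 8)
  seg <- function(x0, y0, ang_deg, len, w, gen) {
    a <- ang_deg * pi / 180
    data.frame(x0 = x0, y0 = y0, x1 = x0 + len * cos(a),
               y1 = y0 + len * sin(a), width = w, generation = gen)
  }
  rows <- list()
  for (tx in c(70, 186)) {
    t1 <- seg(tx, 16, 90, 70, 7, 1)
    rows <- c(rows, list(t1))
    for (a2 in c(55, 125)) {
      t2 <- seg(t1$x1, t1$y1, a2, 45, 5, 2)
      rows <- c(rows, list(t2))
      for (da in c(-30, 30))
        rows <- c(rows, list(seg(t2$x1, t2$y1, a2 + da, 25, 3, 3)))
    }
  }
  tree <- do.call(rbind, rows)
  sq <- generate_angiogram_sequence(tree, shape = c(256, 224), seed = 7)
  gc <- count_generations(median_filter_frames(subtract_background(sq)))
  expect_equal(as.integer(gc), c(2, 4, 8))
})

test_that("a single unbranched vessel counts (1, 0, 0)", {
  tree <- data.frame(x0 = 40, y0 = 10, x1 = 44, y1 = 70, width = 5,
                     generation = 1)
  sq <- generate_angiogram_sequence(tree, shape = c(80, 80), seed = 1)
  gc <- count_generations(median_filter_frames(subtract_background(sq)))
  expect_equal(as.integer(gc), c(1, 0, 0))
})

test_that("automated counts ignore uniform intensity scaling", {
  tree <- sample_angiogram_tree(angio_profile("air_vehicle"), seed = 3)
  sq <- generate_angiogram_sequence(tree, seed = 3)
  e <- median_filter_frames(subtract_background(sq))
  g1 <- count_generations(e)
  e$frames <- e$frames * 3.7
  g2 <- count_generations(e)
  expect_equal(as.integer(g1), as.integer(g2))
})

test_that("a frame with no foreground warns and returns zero counts", {
  expect_warning(gc <- count_generations(matrix(0.3, 32, 32)),
                 "no foreground")
  expect_equal(as.integer(gc), c(0, 0, 0))
})
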