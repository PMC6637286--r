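# Molecular quantification: housekeeping selection, ddCT identities,
# protein normalization, stain scoring, collagen fraction, group stats.

mk_table <- function(df, hk = "Actb") expression_table(df, housekeeping = hk)

test_that("housekeeping selection minimizes CT standard deviation", {
  df <- data.frame(
    sample = rep(c("s1", "s2", "s3", "s4"), each = 3),
    group = "g",
    gene = rep(c("Actb", "B2m", "T1"), 4),
    ct = c(18.0, 20.0, 25, 18.1, 20.5, 26, 17.9, 19.5, 24, 18.0, 21.0, 27))
  tab <- mk_table(df)
  expect_equal(select_housekeeping(tab, c("Actb", "B2m")), "Actb")
  # hand-computed sd check
  expect_equal(sd(df$ct[df$gene == "Actb"]), sd(c(18, 18.1, 17.9, 18)))
  expect_error(select_housekeeping(tab, "Gapdh"), "no candidate")
  # single present candidate wins by default
  expect_equal(select_housekeeping(tab, c("B2m", "Gapdh")), "B2m")
})

test_that("ddCT identities: unity fold, one-cycle doubling, shift invariance", {
  base <- expand.grid(sample = paste0("s", 1:6), gene = c("Actb", "T1"))
  base$group <- rep(c("a", "a", "a", "b", "b", "b"), 2)
  base$sample <- paste0(base$sample, "_", base$group)
  base$ct <- ifelse(base$gene == "Actb", 18, 26)
  tab <- mk_table(base)
  expect_equal(ddct_fold_change(tab, "T1", "a", "b")$fold, 1)
  # one cycle lower in the comparison group -> fold 2
  d2 <- base
  d2$ct[d2$gene == "T1" & d2$group == "b"] <- 25
  expect_equal(ddct_fold_change(mk_table(d2), "T1", "a", "b")$fold, 2)
  # adding a constant to every CT leaves folds unchanged
  d3 <- d2
  d3$ct <- d3$ct + 3.7
  expect_equal(ddct_fold_change(mk_table(d3), "T1", "a", "b")$fold, 2)
  # reference against itself is 1
  expect_equal(ddct_fold_change(mk_table(d2), "T1", "a", "a")$fold, 1)
})

test_that("the bundled group-mean fixture reproduces printed fold changes", {
  tab <- generate_ct_table(qpcr_group_means(), noise_sd = 0,
                           n_per_group = 4, seed = 1)
  hk <- select_housekeeping(tab, c("Actb", "Gapdh"))
  expect_equal(hk, "Actb")
  f <- ddct_fold_change(tab, "Lgals3", "air_vehicle", "hyperoxia_vehicle",
                        housekeeping = hk)
  expect_equal(f$fold, 2.9, tolerance = 1e-6)
  f2 <- ddct_fold_change(tab, "Ccl2", "air_vehicle", "hyperoxia_vehicle")
  expect_equal(f2$fold, 1.8, tolerance = 1e-6)
  # display scaling is relative to the lowest expressed gene mean
  ft <- fold_change_table(tab, c("Lgals3", "Ccl2", "Nppb"), "air_vehicle")
  expect_equal(min(ft$display_relative), 1)
})

test_that("total-protein normalization is a per-sample ratio", {
  expect_equal(normalize_to_total_protein(100, 2), 50)
  expect_equal(normalize_to_total_protein(200, 4),
               normalize_to_total_protein(100, 2))  # scale invariance
  r <- normalize_to_total_protein(c(10, 20, 28, 14), c(1, 2, 2, 1),
                                  group = c("a", "a", "b", "b"))
  expect_equal(r$summary$mean, c(10, 14))
  expect_error(normalize_to_total_protein(10, 0), "positive")
})

test_that("positive-pixel score equals the hand-computed strong-class sum", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 0.95; img[, , 2] <- 0.85; img[, , 3] <- 0.60  # pale tissue
  # 4 strongly stained brown pixels (dark, hue ~30 deg)
  for (px in list(c(2, 2), c(2, 3), c(5, 5), c(8, 8))) {
    img[px[1], px[2], ] <- c(0.40, 0.25, 0.10)
  }
  mask <- matrix(TRUE, 10, 10)
  s <- positive_pixel_score(img, mask, pixel_size_um = 2)
  expect_equal(unname(s$n_pixels["strong"]), 4)
  expect_equal(s$tissue_area_um2, 400)
  expect_equal(s$score, 4 * (1 - 0.40) / 400)
  # halving the tissue area doubles the score
  mask2 <- mask
  mask2[, 6:10] <- FALSE
  s2 <- positive_pixel_score(img, mask2, pixel_size_um = 2)
  expect_equal(unname(s2$n_pixels["strong"]), 3)
  expect_equal(s2$score, 3 * (1 - 0.40) / 200)
  expect_error(positive_pixel_score(img, mask & FALSE), "empty")
})

test_that("collagen fraction matches the generator mask with exclusion", {
  ph <- generate_histology_image(0.25, 0, shape = c(160, 160), seed = 7)
  got <- collagen_fraction(ph$image, ph$vessel_mask)
  expect_equal(got, 100 * ph$collagen_fraction, tolerance = 0.5)
  # red paint inside the vessel mask must not count
  ph2 <- generate_histology_image(0.10, 0.05, shape = c(160, 160), seed = 8)
  got2 <- collagen_fraction(ph2$image, ph2$vessel_mask)
  expect_equal(got2, 100 * ph2$collagen_fraction, tolerance = 0.5)
  # blank (all white) image: no tissue at all
  blank <- array(1, c(20, 20, 3))
  expect_error(collagen_fraction(blank, matrix(FALSE, 20, 20)), "tissue")
  # no red pixels -> 0%
  ph0 <- generate_histology_image(0, 0, shape = c(64, 64), seed = 1)
  expect_equal(collagen_fraction(ph0$image, ph0$vessel_mask), 0)
})

test_that("group comparison reproduces a hand-computed ANOVA", {
  vals <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  g <- group_compare(vals, grp)
  # hand ANOVA: SSB = 26, SSW = 6, F = (26/2)/(6/6) = 13
  expect_equal(g$statistic, 13, tolerance = 1e-9)
  expect_equal(g$test, "one-way ANOVA + Tukey HSD")
  expect_true(all(g$pairwise$p_adj >= 0 & g$pairwise$p_adj <= 1))
  expect_true(g$p_value >= 0 && g$p_value <= 1)
})

test_that("two identical groups give t = 0 and P = 1", {
  g <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
  expect_error(group_compare(c(1, 2), c("a", "b")), "singleton")
})

test_that("Tukey on two groups agrees with the squared-t relation", {
  set.seed(1)
  vals <- c(rnorm(6, 0), rnorm(6, 1))
  grp <- rep(c("a", "b"), each = 6)
  tt <- group_compare(vals, grp, design = "two_group")
  tk <- group_compare(vals, grp, design = "multi_group")
  # with two groups the ANOVA F equals t^2 and the P-values agree
  expect_equal(tk$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(tk$p_value, tt$p_value, tolerance = 1e-9)
  expect_equal(tk$pairwise$p_adj, tt$p_value, tolerance = 1e-6)
})
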