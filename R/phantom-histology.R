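# Histology phantom: two-class (collagen / myocardium) RGB sections with
# known area fractions and vessel regions recorded for exclusion.

#' Generate a synthetic Sirius-Red-style histology image
#'
#' Produces an RGB image in which red (collagen-class) pixels occupy
#' exactly `round(collagen_fraction * non-vessel tissue area)` pixels
#' (blob-shaped, trimmed/padded to the exact count), vessels are white
#' round regions recorded in a mask, and the rest is yellow myocardium.
#' About a third of each vessel region is also painted red so that
#' downstream vessel exclusion is exercised.
#'
#' @param collagen_fraction fraction of non-vessel tissue area stained red
#'   (in \[0, 1\]).
#' @param vessel_mask_fraction fraction of the image occupied by vessels
#'   (in \[0, 1\]; `collagen_fraction + vessel_mask_fraction <= 1`).
#' @param shape image dimensions in pixels.
#' @param seed integer RNG seed.
#' @param collagen_rgb,tissue_rgb,vessel_rgb class colors.
#' @return A `histology_phantom`: `image` (x, y, 3 array in \[0,1\]),
#'   `vessel_mask`, `collagen_mask`, and the realized `collagen_fraction`.
#' @export
generate_histology_image <- function(collagen_fraction,
                                     vessel_mask_fraction = 0.03,
                                     shape = c(256, 256), seed = 1,
                                     collagen_rgb = c(0.80, 0.15, 0.20),
                                     tissue_rgb = c(0.92, 0.82, 0.45),
                                     vessel_rgb = c(1, 1, 1)) {
  if (collagen_fraction < 0 || collagen_fraction > 1 ||
      vessel_mask_fraction < 0 || vessel_mask_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (collagen_fraction + vessel_mask_fraction > 1)
    stop("collagen_fraction + vessel_mask_fraction must be <= 1")

  with_seed(seed, {
    npx <- prod(shape)
    xs <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
    ys <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
    vessel <- matrix(FALSE, shape[1], shape[2])
    target_v <- round(vessel_mask_fraction * npx)
    while (sum(vessel) < target_v) {
      r <- runif(1, 5, 12)
      cx <- runif(1, r + 1, shape[1] - r)
      cy <- runif(1, r + 1, shape[2] - r)
      vessel <- vessel | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
    }
    tissue_px <- which(!vessel)
    n_red <- round(collagen_fraction * length(tissue_px))
    collagen <- matrix(FALSE, shape[1], shape[2])
    # grow blobs from random seeds until enough, then trim to exact count
    while (sum(collagen & !vessel) < n_red) {
      r <- runif(1, 2, 6)
      cx <- runif(1, r + 1, shape[1] - r)
      cy <- runif(1, r + 1, shape[2] - r)
      collagen <- collagen | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
    }
    excess <- sum(collagen & !vessel) - n_red
    if (excess > 0) {
      on <- which(collagen & !vessel)
      collagen[sample(on, excess)] <- FALSE
    }
    # stain part of the vessel regions red: must be excluded downstream
    vr <- which(vessel)
    if (length(vr)) collagen[sample(vr, ceiling(length(vr) / 3))] <- TRUE

    img <- array(0, c(shape, 3))
    for (ch in 1:3) {
      plane <- matrix(tissue_rgb[ch], shape[1], shape[2])
      plane[collagen] <- collagen_rgb[ch]
      plane[vessel & !collagen] <- vessel_rgb[ch]
      img[, , ch] <- plane
    }
    structure(
      list(image = img, vessel_mask = vessel,
           collagen_mask = collagen & !vessel,
           collagen_fraction = sum(collagen & !vessel) / sum(!vessel)),
      class = "histology_phantom")
  })
}
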