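# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures on disk.

# A condition profile with arbitrary bins/counts, for tiny phantoms.
tiny_profile <- function(bin_edges, expected_counts,
                         name = "test") {
  structure(list(name = name, bin_edges = bin_edges,
                 expected_counts = expected_counts,
                 depletion = rep(1, length(expected_counts))),
            class = "condition_profile")
}

# Binary capsule mask built directly from the renderer.
capsule_mask <- function(dims, p0, p1, radius) {
  v <- array(0, dims)
  v <- pulmovasc:::cpp_render_capsule(v, dims, p0, p1, radius, 1, 4L)
  v >= 0.5
}

# 2D annulus mask (ring) centered in an n x n plane.
annulus_mask <- function(n = 32, r_out = 10, r_in = 7) {
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), n), n)
  ys <- t(xs)
  d2 <- (xs - ctr)^2 + (ys - ctr)^2
  d2 <= r_out^2 & d2 >= r_in^2
}

# Independent border flood-fill complement oracle (4-connected, 2D):
# everything not reachable from the border through background is filled.
flood_fill_oracle <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  reach <- matrix(FALSE, n, m)
  queue <- which(!mask & (row(mask) %in% c(1, n) | col(mask) %in% c(1, m)))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    x <- (i - 1) %% n + 1; y <- (i - 1) %/% n + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      xx <- x + d[1]; yy <- y + d[2]
      if (xx < 1 || yy < 1 || xx > n || yy > m) next
      j <- xx + n * (yy - 1)
      if (!mask[j] && !reach[j]) {
        reach[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  mask | !reach
}

# Dense 2D convolution oracle with a separable Gaussian (zero padding),
# written independently of the package's C filters.
dense_gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  out1 <- matrix(0, n, m)
  for (y in seq_len(m)) {
    for (x in seq_len(n)) {
      acc <- 0
      for (t in seq_along(k)) {
        xx <- x + t - r - 1L
        if (xx >= 1 && xx <= n) acc <- acc + k[t] * img[xx, y]
      }
      out1[x, y] <- acc
    }
  }
  out2 <- matrix(0, n, m)
  for (y in seq_len(m)) {
    for (x in seq_len(n)) {
      acc <- 0
      for (t in seq_along(k)) {
        yy <- y + t - r - 1L
        if (yy >= 1 && yy <= m) acc <- acc + k[t] * out1[x, yy]
      }
      out2[x, y] <- acc
    }
  }
  out2
}

dense_dog <- function(img, sigma, ratio = 1.6) {
  dense_gauss_blur(img, sigma) - dense_gauss_blur(img, ratio * sigma)
}
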