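# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; all generators route their randomness through this so they are pure
# functions of (arguments, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Normalized Gaussian kernel sampled at integer offsets.
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 2D Gaussian blur of a matrix (zero padding), via the separable 3D kernel.
blur2d <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  a <- cpp_sepconv3d(array(m, c(dim(m), 1L)), c(dim(m), 1L), k, k, 1)
  a[, , 1]
}

# 3D Gaussian blur of a volume array.
blur3d <- function(a, sigma) {
  k <- gauss_kernel(sigma)
  cpp_sepconv3d(a, dim(a), k, k, k)
}

# Otsu threshold of a numeric vector/array (256-level histogram over range).
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  sb2 <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  mids[which.max(sb2)]
}

# Minimum distance between two 3D line segments p0-p1 and q0-q1.
seg_seg_dist <- function(p0, p1, q0, q1) {
  u <- p1 - p0
  v <- q1 - q0
  w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  sc <- sN <- sD <- D
  tc <- tN <- tD <- D
  if (D < 1e-12) {
    sN <- 0; sD <- 1; tN <- e; tD <- cc
  } else {
    sN <- b * e - cc * d
    tN <- a * e - b * d
    if (sN < 0) { sN <- 0; tN <- e; tD <- cc }
    else if (sN > sD) { sN <- sD; tN <- e + b; tD <- cc }
  }
  if (tN < 0) {
    tN <- 0
    if (-d < 0) sN <- 0 else if (-d > a) sN <- sD else { sN <- -d; sD <- a }
  } else if (tN > tD) {
    tN <- tD
    if ((-d + b) < 0) sN <- 0
    else if ((-d + b) > a) sN <- sD
    else { sN <- -d + b; sD <- a }
  }
  sc <- if (abs(sN) < 1e-12) 0 else sN / sD
  tc <- if (abs(tN) < 1e-12) 0 else tN / tD
  dP <- w + sc * u - tc * v
  sqrt(sum(dP * dP))
}

# Distance of points (n x 3 matrix) to segment a-b.
point_seg_dist <- function(pts, a, b) {
  v <- b - a
  L2 <- sum(v * v)
  if (L2 == 0) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  t <- pmin(1, pmax(0, (sweep(pts, 2, a) %*% v) / L2))
  proj <- cbind(a[1] + t * v[1], a[2] + t * v[2], a[3] + t * v[3])
  sqrt(rowSums((pts - proj)^2))
}

# Standard error of the mean.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# Euclidean length of a polyline given as an n x 3 (or n x 2) matrix.
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}
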