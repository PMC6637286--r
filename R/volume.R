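#' Grayscale image volume with physical voxel size
#'
#' Container for a reconstructed micro-CT volume: a 3D numeric array plus the
#' isotropic voxel edge length in micrometers (6.0 um for the synchrotron
#' lung scans this package targets).
#'
#' @param voxels 3D numeric array of intensities.
#' @param voxel_size voxel edge length in micrometers (> 0).
#' @param bit_depth optional source bit depth (8 or 32), kept as metadata.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size = 6.0, bit_depth = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1)) stop("volume grid must be non-empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)")
  structure(
    list(voxels = voxels, voxel_size = voxel_size, bit_depth = bit_depth),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "volume3d: %d x %d x %d voxels, %.2f um/voxel, intensity [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$voxel_size, min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary voxel mask with physical voxel size
#'
#' @param mask 3D logical array.
#' @param voxel_size voxel edge length in micrometers.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_size = 6.0) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, voxel_size = voxel_size),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_volume: %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Read a multi-page TIFF stack as a volume
#'
#' Accepts the 8-bit or 32-bit float grayscale stacks produced by CT
#' reconstruction; pages become the third array dimension.
#'
#' @param path path to a multi-page TIFF file.
#' @param voxel_size voxel edge length in micrometers.
#' @return A [volume3d()].
#' @export
read_volume_tiff <- function(path, voxel_size = 6.0) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  a <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  volume3d(a, voxel_size = voxel_size)
}

#' Write a volume (or binary mask) as a multi-page TIFF stack
#'
#' Intensities are clipped to \[0, 1\] as required by the TIFF writer.
#'
#' @param x a [volume3d()], [binary_volume()] or 3D array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path) {
  a <- if (inherits(x, "volume3d")) x$voxels
       else if (inherits(x, "binary_volume")) x$mask * 1
       else x
  a <- pmin(1, pmax(0, a))
  pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z])
  tiff::writeTIFF(pages, path)
  invisible(path)
}
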