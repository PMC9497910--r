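#' @useDynLib cytofcn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multi-resolution slide pyramid
#'
#' In-memory model of a pyramidal whole-slide image. Levels are indexed
#' `v = 1..N` from coarsest to finest; level `N` is the unique full-resolution
#' raster and has downsample factor 1. Pixel data are 8-bit RGB stored as
#' numeric arrays `(height, width, 3)` with values in `[0, 1]` on the
#' 256-level grid (`k/255`). Coordinates throughout the package are 0-based
#' `(i = column, j = row)` with the origin at the top-left pixel.
#'
#' @param levels list of RGB arrays `(height, width, 3)`, coarsest first; the
#'   last element must be the unique largest level.
#' @return An object of class `slide_pyramid` with fields `levels`,
#'   `level_count`, `dims` (matrix with columns `width`, `height`, one row per
#'   level) and `downsample` (factor relative to level `N`, per axis mean).
#' @examples
#' lvl <- array(runif(32 * 16 * 3), dim = c(16, 32, 3))
#' pyr <- slide_pyramid(list(lvl))
#' pyr$level_count
#' @export
slide_pyramid <- function(levels) {
  if (!is.list(levels) || length(levels) == 0L)
    stop("pyramid must contain at least one level")
  for (lv in levels) {
    if (!is.array(lv) || length(dim(lv)) != 3L || dim(lv)[3] != 3L)
      stop("unsupported format: every pyramid level must be an RGB array (height, width, 3)")
  }
  dims <- t(vapply(levels, function(lv) c(dim(lv)[2L], dim(lv)[1L]), numeric(2)))
  colnames(dims) <- c("width", "height")
  n <- nrow(dims)
  px <- dims[, 1L] * dims[, 2L]
  if (any(diff(px) < 0))
    stop("pyramid levels must be ordered coarsest first (non-decreasing size)")
  if (n > 1L && px[n] == px[n - 1L])
    stop("level N must be the unique largest level")
  ds <- (dims[n, 1L] / dims[, 1L] + dims[n, 2L] / dims[, 2L]) / 2
  structure(
    list(levels = levels, level_count = n, dims = dims, downsample = ds),
    class = "slide_pyramid"
  )
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("<slide_pyramid> %d level(s), full resolution %d x %d px\n",
              x$level_count, x$dims[x$level_count, 1L], x$dims[x$level_count, 2L]))
  for (v in seq_len(x$level_count))
    cat(sprintf("  v=%d: %6d x %5d  (downsample %.3g)\n",
                v, x$dims[v, 1L], x$dims[v, 2L], x$downsample[v]))
  invisible(x)
}

#' Read a pyramidal slide file
#'
#' Reads an SVS or pyramidal/multi-page TIFF into a [slide_pyramid]. Scanner
#' files conventionally store the full-resolution raster as the first page
#' (level 0); this adapter inverts that ordering so that internally `v = N` is
#' full resolution and `v = 1` the coarsest thumbnail. Non-RGB (single-band or
#' palette) images are rejected rather than converted: brightfield cytology
#' slides are RGB.
#'
#' @param path path to an SVS or (multi-page) TIFF file.
#' @return A [slide_pyramid].
#' @export
read_pyramid <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read slide file '%s': no such file", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = FALSE),
    error = function(e) stop(sprintf("cannot read slide file '%s': %s",
                                     path, conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  for (pg in pages) {
    d <- dim(pg)
    if (length(d) < 3L || d[3] < 3L)
      stop(sprintf("unsupported format in '%s': expected RGB pages, got %s channel(s)",
                   path, if (length(d) < 3L) 1L else d[3]))
  }
  pages <- lapply(pages, function(pg) {
    if (dim(pg)[3] > 3L) pg <- pg[, , 1:3, drop = FALSE]  # drop alpha
    pg
  })
  # scanner order: page 1 = full resolution; internal order: v=1 coarsest
  area <- vapply(pages, function(pg) prod(dim(pg)[1:2]), numeric(1))
  slide_pyramid(pages[order(area)])
}

#' Write a pyramid as a multi-page TIFF fixture
#'
#' Writes the pyramid in scanner page order (page 1 = level `N`, full
#' resolution) as an uncompressed 8-bit multi-page TIFF, so that
#' `read_pyramid(write_fixture(p))` is pixel-identical to `p`. Output is
#' byte-stable: writing the same pyramid twice yields identical files.
#'
#' @param pyramid a [slide_pyramid].
#' @param path output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(pyramid, path) {
  stopifnot(inherits(pyramid, "slide_pyramid"))
  for (v in seq_len(pyramid$level_count)) {
    d <- dim(pyramid$levels[[v]])
    if (d[1L] != pyramid$dims[v, 2L] || d[2L] != pyramid$dims[v, 1L])
      stop(sprintf("level %d raster is %dx%d but declared dims are %dx%d",
                   v, d[2L], d[1L], pyramid$dims[v, 1L], pyramid$dims[v, 2L]))
  }
  pages <- rev(pyramid$levels)
  # quantize to the 8-bit grid so the round trip is exact
  pages <- lapply(pages, function(pg) round(pg * 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
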