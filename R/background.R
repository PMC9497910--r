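#' Otsu threshold of a luminance raster
#'
#' Histogram thresholding that maximizes the between-class variance. The
#' raster (values in `[0, 1]`) is quantized onto `n_bins` levels, every cut
#' between two occupied parts of the histogram is scanned exhaustively, and
#' the cut with maximal between-class variance is returned as the midpoint
#' between its two adjacent bin centers (ties break toward the lowest cut, so
#' the result is deterministic). Pixels strictly below the returned value
#' belong to the lower (dark) class.
#'
#' @param gray numeric matrix of luminance values in `[0, 1]`.
#' @param n_bins number of histogram bins (default 256).
#' @return Threshold value in `(0, 1)`.
#' @examples
#' img <- matrix(c(rep(20, 50), rep(230, 50)) / 255, 10, 10)
#' otsu_threshold(img)
#' @export
otsu_threshold <- function(gray, n_bins = 256L) {
  if (length(gray) == 0L) stop("empty image")
  n_bins <- as.integer(n_bins)
  bins <- as.integer(round(gray * (n_bins - 1L)))          # 0 .. n_bins-1
  if (min(bins) == max(bins))
    stop("degenerate image: constant luminance, no threshold exists")
  counts <- as.numeric(tabulate(bins + 1L, nbins = n_bins))
  n <- length(bins)
  lev <- 0:(n_bins - 1L)
  # cumulative weight and mean for class 0 = bins <= t, t = 0..n_bins-2
  w0 <- cumsum(counts)[-n_bins]
  s0 <- cumsum(counts * lev)[-n_bins]
  w1 <- n - w0
  mu <- sum(counts * lev) / n
  valid <- w0 > 0L & w1 > 0L
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu * w0[valid] - s0[valid])^2 / (w0[valid] * w1[valid])
  t <- which.max(bcv) - 1L                                  # smallest maximizer
  (t + 0.5) / (n_bins - 1L)
}

#' Tissue mask of a coarse pyramid level
#'
#' Converts the level-`z` RGB raster to Rec.601 luminance
#' (`0.299 R + 0.587 G + 0.114 B`), computes the Otsu threshold, and marks as
#' tissue every pixel strictly darker than the threshold: stained cells are
#' dark material on a bright slide background. A constant (degenerate) raster
#' yields an all-background mask with a warning instead of an error.
#'
#' @param level_z_image RGB array `(height, width, 3)`, values in `[0, 1]`.
#' @param level pyramid level index the raster comes from (bookkeeping).
#' @return A `tissue_mask` object: fields `level`, `mask` (logical matrix,
#'   `TRUE` = tissue) and `threshold` (luminance cut, `NA` if degenerate).
#' @export
compute_tissue_mask <- function(level_z_image, level = NA_integer_) {
  d <- dim(level_z_image)
  if (length(d) != 3L || d[3L] != 3L) stop("expected an RGB array (height, width, 3)")
  lum <- 0.299 * level_z_image[, , 1L] +
         0.587 * level_z_image[, , 2L] +
         0.114 * level_z_image[, , 3L]
  thr <- tryCatch(otsu_threshold(lum), error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("degenerate (constant) level image: treating the slide as all background")
    mask <- matrix(FALSE, d[1L], d[2L])
  } else {
    # threshold on the quantized grid the histogram was built from, so pixels
    # landing exactly on a bin boundary fall on the side Otsu assigned them
    mask <- round(lum * 255) / 255 < thr
  }
  structure(list(level = level, mask = mask, threshold = thr),
            class = "tissue_mask")
}

# Summed-area table of a logical mask, with S[j+1, i+1] = sum over rows<=j, cols<=i.
sat_build <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  cs <- matrix(0, H, W)
  cs[] <- apply(mask, 2L, cumsum)            # cumulative down rows
  cs <- t(apply(cs, 1L, cumsum))             # then across columns (apply transposes)
  if (H == 1L) cs <- matrix(cs, 1L, W)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- cs
  S
}

# Bilinear evaluation of the summed-area table at fractional coordinates.
# Exact for piecewise-constant masks, so tissue fractions are independent of
# which coarse level the mask was computed on when the mask itself is ideal.
sat_at <- function(S, x, y) {
  W <- ncol(S) - 1L; H <- nrow(S) - 1L
  x <- pmin(pmax(x, 0), W); y <- pmin(pmax(y, 0), H)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0; fy <- y - y0
  i0 <- x0 + 1L; j0 <- y0 + 1L
  (1 - fx) * (1 - fy) * S[cbind(j0, i0)] +
    fx * (1 - fy) * S[cbind(j0, i0 + 1L)] +
    (1 - fx) * fy * S[cbind(j0 + 1L, i0)] +
    fx * fy * S[cbind(j0 + 1L, i0 + 1L)]
}

#' Keep/discard verdict per full-resolution tile
#'
#' Projects each level-`N` tile footprint onto the coarse tissue mask using
#' exact rational scaling of the tile corners (boundary mask pixels contribute
#' area-weighted fractions), measures the tissue fraction of the footprint,
#' and keeps the tile iff the fraction is at least `min_tissue_fraction`.
#' The default 0.70 implements the rule that patches containing less than 70%
#' tissue are discarded — exactly 70% is kept (inclusive threshold). Only kept
#' tiles are ever sent to the network.
#'
#' @param mask a [compute_tissue_mask] result at level `z`.
#' @param pyramid the [slide_pyramid] the mask was computed from.
#' @param grid a [compute_tile_grid] at level `N` (full resolution).
#' @param min_tissue_fraction minimum tissue fraction to keep a tile.
#' @return A `keep_set`: fields `grid`, `kept` (logical `zeta x gamma` matrix,
#'   rows = beta), `tissue_fraction` (same shape) and `min_tissue_fraction`.
#' @export
filter_tiles <- function(mask, pyramid, grid, min_tissue_fraction = 0.70) {
  stopifnot(inherits(mask, "tissue_mask"), inherits(pyramid, "slide_pyramid"),
            inherits(grid, "tile_grid"))
  N <- pyramid$level_count
  mz <- mask$mask
  z <- mask$level
  if (is.na(z)) {
    hit <- which(pyramid$dims[, 2L] == nrow(mz) & pyramid$dims[, 1L] == ncol(mz))
    if (length(hit) == 0L) stop("mask dims match no pyramid level")
    z <- hit[1L]
  }
  if (pyramid$dims[z, 2L] != nrow(mz) || pyramid$dims[z, 1L] != ncol(mz))
    stop(sprintf("declared level %d is %d x %d but mask raster is %d x %d",
                 z, pyramid$dims[z, 1L], pyramid$dims[z, 2L], ncol(mz), nrow(mz)))
  sx <- pyramid$dims[N, 1L] / pyramid$dims[z, 1L]
  sy <- pyramid$dims[N, 2L] / pyramid$dims[z, 2L]

  S <- sat_build(mz)
  frac <- matrix(0, grid$zeta, grid$gamma)
  for (b in 0:(grid$zeta - 1L)) {
    a <- 0:(grid$gamma - 1L)
    x0 <- a * grid$w / sx; x1 <- (a + 1L) * grid$w / sx
    y0 <- b * grid$psi / sy; y1 <- (b + 1L) * grid$psi / sy
    area <- (x1 - x0) * (y1 - y0)
    frac[b + 1L, ] <- (sat_at(S, x1, y1) - sat_at(S, x0, y1) -
                         sat_at(S, x1, y0) + sat_at(S, x0, y0)) / area
  }
  frac <- pmin(pmax(frac, 0), 1)
  structure(list(grid = grid, kept = frac >= min_tissue_fraction,
                 tissue_fraction = frac,
                 min_tissue_fraction = min_tissue_fraction),
            class = "keep_set")
}

#' @export
print.keep_set <- function(x, ...) {
  cat(sprintf("<keep_set> %d / %d tiles kept (tissue fraction >= %.2f)\n",
              sum(x$kept), length(x$kept), x$min_tissue_fraction))
  invisible(x)
}
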