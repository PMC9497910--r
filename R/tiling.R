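#' Tile grid for one pyramid level
#'
#' Builds the patch grid used by the hierarchical tile structure: a level of
#' width `W` and height `H` is cut into `gamma = floor(W / w)` columns and
#' `zeta = floor(H / psi)` rows of non-overlapping `w x psi` tiles. The border
#' remainder left by the floor division is discarded (it rarely contains
#' material of interest); each tile covers the half-open pixel range
#' `[alpha*w, (alpha+1)*w) x [beta*psi, (beta+1)*psi)`.
#'
#' @param level_dims `(width, height)` of the level in pixels.
#' @param tile_size `(w, psi)` tile width and height in pixels; default
#'   `c(512, 512)`, the unit tile used throughout.
#' @param level pyramid level index the grid lives on (bookkeeping only).
#' @return A `tile_grid` object with fields `w`, `psi`, `gamma` (columns),
#'   `zeta` (rows), `level`, `level_dims`.
#' @examples
#' compute_tile_grid(c(1024, 1024), c(512, 512))   # 2 x 2
#' @export
compute_tile_grid <- function(level_dims, tile_size = c(512L, 512L), level = NA_integer_) {
  w <- as.integer(tile_size[1L]); psi <- as.integer(tile_size[2L])
  if (w <= 0L || psi <= 0L) stop("tile size must be positive")
  W <- as.integer(level_dims[1L]); H <- as.integer(level_dims[2L])
  if (W < w || H < psi)
    stop(sprintf("grid error: level %dx%d is smaller than one %dx%d tile; pick a finer level",
                 W, H, w, psi))
  structure(
    list(w = w, psi = psi,
         gamma = W %/% w, zeta = H %/% psi,
         level = level, level_dims = c(width = W, height = H)),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d x %d px (level %s)\n",
              x$gamma, x$zeta, x$w, x$psi, x$level))
  invisible(x)
}

#' Locate a pixel inside the tile grid
#'
#' Maps a 0-based pixel coordinate `(i, j)` (column, row) to its tile address:
#' tile column `alpha = floor(i / w)`, tile row `beta = floor(j / psi)`, and
#' in-tile offsets `x = i - alpha * w`, `y = j - beta * psi`. The
#' reconstruction identity `i = alpha * w + x`, `j = beta * psi + y` always
#' holds on the covered region.
#'
#' @param i,j 0-based pixel column and row.
#' @param grid a [compute_tile_grid] result.
#' @return A list with `alpha`, `beta`, `x`, `y`, `level`.
#' @examples
#' g <- compute_tile_grid(c(2048, 1024))
#' locate(1000, 600, g)   # alpha=1, beta=1, x=488, y=88
#' @export
locate <- function(i, j, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  i <- as.integer(i); j <- as.integer(j)
  if (i < 0L || j < 0L || i >= grid$gamma * grid$w || j >= grid$zeta * grid$psi)
    stop(sprintf("pixel (%d, %d) lies outside the covered region (discarded border)", i, j))
  alpha <- i %/% grid$w
  beta  <- j %/% grid$psi
  list(alpha = alpha, beta = beta,
       x = i - alpha * grid$w, y = j - beta * grid$psi,
       level = grid$level)
}

#' Select the pyramid level for background filtering
#'
#' Returns the smallest (coarsest) level index `z` whose raster holds at least
#' as many pixels as one unit tile and on which at least one full tile fits in
#' both axes — the level closest to, and no smaller than, the size of a unit
#' tile. Otsu background filtering runs on this level, so a gigapixel slide is
#' thresholded on a thumbnail-sized raster.
#'
#' @param pyramid a [slide_pyramid].
#' @param tile_size `(w, psi)`; default `c(512, 512)`.
#' @return The level index `z` (`1 <= z <= N`).
#' @export
select_filter_level <- function(pyramid, tile_size = c(512L, 512L)) {
  stopifnot(inherits(pyramid, "slide_pyramid"))
  w <- as.integer(tile_size[1L]); psi <- as.integer(tile_size[2L])
  for (v in seq_len(pyramid$level_count)) {
    W <- pyramid$dims[v, 1L]; H <- pyramid$dims[v, 2L]
    if (W * H >= w * psi && W %/% w >= 1L && H %/% psi >= 1L)
      return(v)
  }
  stop(sprintf("no pyramid level holds a full %d x %d tile (full resolution is %d x %d)",
               w, psi, pyramid$dims[pyramid$level_count, 1L],
               pyramid$dims[pyramid$level_count, 2L]))
}
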