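#' Per-tile class probabilities
#'
#' Runs the network on one full-resolution tile and returns the per-pixel
#' class probability map (softmax over background / nontarget / target).
#' Dropout is disabled, so inference is deterministic given the model.
#'
#' @param model a trained `fcn_model`.
#' @param tile RGB array `(w, psi, 3)` in `[0, 1]`; dims must equal the
#'   configured tile size.
#' @param tile_size expected `(w, psi)`; default `c(512, 512)`.
#' @return Array `(w, psi, n_classes)` of probabilities summing to 1 per pixel.
#' @export
predict_tile <- function(model, tile, tile_size = c(512L, 512L)) {
  stopifnot(inherits(model, "fcn_model"))
  d <- dim(tile)
  if (length(d) != 3L || d[3L] != 3L) stop("tile must be an RGB array")
  if (d[1L] != tile_size[2L] || d[2L] != tile_size[1L])
    stop(sprintf("tile is %d x %d but the configured tile size is %d x %d",
                 d[2L], d[1L], tile_size[1L], tile_size[2L]))
  fw <- nn_forward(model, tile, train = FALSE)
  softmax3(fw$logits)
}

#' Per-pixel argmax class map
#'
#' Collapses a class probability map to integer labels `{0..C}` by taking the
#' class of maximum probability per pixel; ties break toward the lowest class
#' index, so the map is deterministic.
#'
#' @param probs array `(h, w, n_classes)` of per-pixel probabilities.
#' @return Integer matrix `h x w` with values in `{0..C}`.
#' @export
class_map <- function(probs) {
  if (!all(is.finite(probs))) stop("non-finite probabilities")
  C <- dim(probs)[3L]
  lab <- matrix(0L, dim(probs)[1L], dim(probs)[2L])
  best <- probs[, , 1L]
  for (c in seq_len(C)[-1L]) {
    better <- probs[, , c] > best            # strict: ties keep the lower index
    lab[better] <- c - 1L
    best[better] <- probs[, , c][better]
  }
  lab
}

#' Tumor-only segmentation of a tile
#'
#' Retains the source RGB value of every pixel whose class-map label exceeds 1
#' (the target / tumor class) and nulls everything else. The null marker is
#' rendered as black in the RGB result; the binary `tumor_mask` companion
#' raster carries the authoritative verdict.
#'
#' @param tile RGB array `(h, w, 3)`.
#' @param m integer class-map matrix `h x w`.
#' @return list with `rgb` (segmented RGB array) and `tumor_mask`
#'   (logical matrix, `TRUE` where label > 1).
#' @export
segment_tile <- function(tile, m) {
  d <- dim(tile)
  if (d[1L] != nrow(m) || d[2L] != ncol(m))
    stop("tile and class map dims differ")
  keep <- m > 1L
  out <- array(0, dim = d)
  for (c in 1:3) out[, , c] <- tile[, , c] * keep
  list(rgb = out, tumor_mask = keep)
}

#' Segment a whole slide
#'
#' The full pipeline on one pyramid: select the coarse filtering level,
#' compute the Otsu tissue mask, discard tiles with less than the minimum
#' tissue fraction, run the network once per kept tile, and stitch the
#' per-tile class maps and tumor segmentations into slide-level rasters of
#' size `gamma * w  x  zeta * psi` (the border remainder discarded by the
#' tiling floor is absent from the output). Discarded tiles are labelled
#' background everywhere and contribute no tumor pixels; a slide with zero
#' kept tiles short-circuits with an all-background result and no model
#' calls.
#'
#' @param pyramid a [slide_pyramid] with at least one full tile at level `N`.
#' @param model a trained `fcn_model`.
#' @param tile_size `(w, psi)`; default `c(512, 512)`.
#' @param min_tissue_fraction background-filter threshold; default 0.70.
#' @param verbose log tile accounting to `message()`.
#' @return A `slide_result`: `class_map` (integer matrix), `tumor_mask`
#'   (logical matrix), `rgb` (segmented RGB array), `keep_set`, `grid`,
#'   `model_calls` (number of network invocations), `summary` (list with
#'   tile and tumor-pixel accounting).
#' @export
run_slide <- function(pyramid, model, tile_size = c(512L, 512L),
                      min_tissue_fraction = 0.70, verbose = FALSE) {
  stopifnot(inherits(pyramid, "slide_pyramid"), inherits(model, "fcn_model"))
  N <- pyramid$level_count
  grid <- compute_tile_grid(pyramid$dims[N, ], tile_size, level = N)
  z <- select_filter_level(pyramid, tile_size)
  mask <- compute_tissue_mask(pyramid$levels[[z]], level = z)
  keep <- filter_tiles(mask, pyramid, grid, min_tissue_fraction)

  H <- grid$zeta * grid$psi; W <- grid$gamma * grid$w
  cmap <- matrix(0L, H, W)
  tumor <- matrix(FALSE, H, W)
  rgb <- array(0, dim = c(H, W, 3L))
  full <- pyramid$levels[[N]]
  calls <- 0L
  if (any(keep$kept)) {
    for (b in 0:(grid$zeta - 1L)) {
      for (a in 0:(grid$gamma - 1L)) {
        if (!keep$kept[b + 1L, a + 1L]) next
        rows <- (b * grid$psi + 1L):((b + 1L) * grid$psi)
        cols <- (a * grid$w + 1L):((a + 1L) * grid$w)
        tile <- full[rows, cols, , drop = FALSE]
        probs <- predict_tile(model, tile, tile_size)
        calls <- calls + 1L
        m <- class_map(probs)
        seg <- segment_tile(tile, m)
        cmap[rows, cols] <- m
        tumor[rows, cols] <- seg$tumor_mask
        rgb[rows, cols, ] <- seg$rgb
      }
    }
  } else if (verbose) {
    message("no tiles passed the tissue filter; returning an all-background result")
  }
  if (verbose)
    message(sprintf("tiles: %d total, %d kept, %d network call(s), %d tumor pixel(s)",
                    length(keep$kept), sum(keep$kept), calls, sum(tumor)))
  structure(list(
    class_map = cmap, tumor_mask = tumor, rgb = rgb,
    keep_set = keep, grid = grid, filter_level = z, model_calls = calls,
    summary = list(tiles_total = length(keep$kept), tiles_kept = sum(keep$kept),
                   model_calls = calls, tumor_pixels = sum(tumor),
                   tumor_area_fraction = mean(tumor))),
    class = "slide_result")
}

#' @export
print.slide_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<slide_result> %d x %d px, %d/%d tiles kept, %d tumor pixels (%.2f%%)\n",
              ncol(x$class_map), nrow(x$class_map), s$tiles_kept, s$tiles_total,
              s$tumor_pixels, 100 * s$tumor_area_fraction))
  invisible(x)
}

#' Tumor overlay raster
#'
#' Draws the tumor mask at 50% alpha (red) over a downsampled view of the
#' stitched slide region — a presentation aid, not part of the method.
#'
#' @param result a [run_slide] result.
#' @param pyramid the slide's [slide_pyramid].
#' @param max_side maximum side of the overlay raster in pixels.
#' @return RGB array of the overlay.
#' @export
overlay_raster <- function(result, pyramid, max_side = 1024L) {
  N <- pyramid$level_count
  H <- nrow(result$class_map); W <- ncol(result$class_map)
  f <- max(1L, ceiling(max(H, W) / max_side))
  hi <- seq(1L, H, by = f); wi <- seq(1L, W, by = f)
  base <- pyramid$levels[[N]][hi, wi, , drop = FALSE]
  m <- result$tumor_mask[hi, wi]
  out <- base
  out[, , 1L] <- ifelse(m, 0.5 * base[, , 1L] + 0.5, base[, , 1L])
  out[, , 2L] <- ifelse(m, 0.5 * base[, , 2L], base[, , 2L])
  out[, , 3L] <- ifelse(m, 0.5 * base[, , 3L], base[, , 3L])
  out
}
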