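#' Specification of a synthetic fixture slide
#'
#' Parameters of the synthetic pyramidal-slide generator used to exercise the
#' whole pipeline without clinical data. A slide is a near-white background
#' (bright, like an unstained glass region) on which tile-aligned cell
#' clusters are rendered: benign clusters as mid-dark blue-violet discs,
#' malignant clusters as much darker magenta discs speckled with a higher
#' fraction of near-black nuclei. Classes are deliberately separable by
#' low-level appearance (overall darkness plus hue and dark-fraction) so a
#' small network can learn them quickly; no attempt is made to model real
#' cytomorphology.
#'
#' The tissue layout is tile-based: `n_benign` and `n_malignant` tile cells
#' of the full-resolution grid receive material (discs clipped to their tile,
#' so every tile is either empty or densely covered), the rest stay
#' background. With the default `clusters_per_tile = 40` discs of radius
#' 70-120 px a material tile ends up roughly 95% tissue, comfortably above
#' the 70% keep threshold, while empty tiles are discarded.
#'
#' @param width,height level-N slide dims in pixels (divisible by every
#'   downsample factor).
#' @param downsamples per-level downsample factors, coarsest first, last = 1.
#' @param tile_size `(w, psi)` of the layout grid.
#' @param n_benign,n_malignant number of benign / malignant material tiles.
#' @param clusters_per_tile discs rendered per material tile.
#' @param radius_range disc radius range in pixels.
#' @param placement `"random"` scatters disc centres in the tile;
#'   `"center"` puts every disc at the tile centre (single-disc geometry).
#' @param malignant_mix fraction of discs in a malignant tile that carry
#'   tumor cells (the rest are benign bystanders, as in a real aspirate where
#'   metastatic clusters sit amid lymphocytes).
#' @param malignant_scale radius multiplier of tumor discs relative to
#'   `radius_range`: metastatic clusters are larger, compact syncytial-like
#'   blobs, which also keeps them resolvable at the network's 32-pixel
#'   output stride.
#' @param background_mean,background_sd background luminance (near white).
#' @param benign_color,malignant_color base RGB of the two cluster types.
#'   Both are darker than the background (so Otsu separates tissue from
#'   glass); malignant material is markedly darker again, mimicking the
#'   hyperchromatic, high nucleus-to-cytoplasm appearance of tumor clusters.
#' @param dark_fraction fraction of malignant disc pixels darkened to mimic
#'   a high nucleus-to-cytoplasm ratio (benign clusters use a tenth of it).
#' @param seed RNG seed; a fixed seed gives byte-identical slides.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(width = 2048L, height = 1024L,
                         downsamples = c(4L, 2L, 1L),
                         tile_size = c(512L, 512L),
                         n_benign = 3L, n_malignant = 2L,
                         clusters_per_tile = 40L,
                         radius_range = c(70, 120),
                         placement = c("random", "center"),
                         malignant_mix = 0.3,
                         malignant_scale = 1.6,
                         background_mean = 0.94, background_sd = 0.015,
                         benign_color = c(0.36, 0.36, 0.62),
                         malignant_color = c(0.22, 0.08, 0.16),
                         dark_fraction = 0.35,
                         seed = 1L) {
  placement <- match.arg(placement)
  downsamples <- as.integer(downsamples)
  if (downsamples[length(downsamples)] != 1L) stop("finest level must have downsample 1")
  if (is.unsorted(rev(downsamples), strictly = TRUE)) stop("downsamples must decrease to 1")
  if (any(width %% downsamples != 0L) || any(height %% downsamples != 0L))
    stop("slide dims must be divisible by every downsample factor")
  if (width < tile_size[1L] || height < tile_size[2L])
    stop("slide must hold at least one tile")
  lum <- function(col) sum(c(0.299, 0.587, 0.114) * col)
  if (lum(benign_color) >= background_mean || lum(malignant_color) >= background_mean)
    stop("cluster colors must be darker than the background")
  structure(list(width = as.integer(width), height = as.integer(height),
                 downsamples = downsamples, tile_size = as.integer(tile_size),
                 n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
                 clusters_per_tile = as.integer(clusters_per_tile),
                 radius_range = radius_range, placement = placement,
                 malignant_mix = malignant_mix,
                 malignant_scale = malignant_scale,
                 background_mean = background_mean, background_sd = background_sd,
                 benign_color = benign_color, malignant_color = malignant_color,
                 dark_fraction = dark_fraction, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Area-average downsampling of a matrix by an integer factor (mass preserving).
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  H <- nrow(m); W <- ncol(m)
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = H %/% f)      # rows
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = W %/% f))     # cols
}

#' Generate one synthetic pyramidal slide with ground truth
#'
#' Renders the level-N raster described by the spec, derives the coarser
#' levels by exact area-average downsampling, and returns the pyramid
#' together with the aligned 3-class reference mask (0 background, 1 benign,
#' 2 malignant) and a per-tile truth table. Deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec].
#' @return list with `pyramid` ([slide_pyramid]), `mask` (integer matrix at
#'   level N), `truth` (data frame: `alpha`, `beta`, `class`,
#'   `tissue_fraction`, `dominant_class`) and `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  w <- spec$tile_size[1L]; psi <- spec$tile_size[2L]
  grid <- compute_tile_grid(c(W, H), spec$tile_size)
  n_cells <- grid$gamma * grid$zeta
  n_mat <- spec$n_benign + spec$n_malignant
  if (n_mat > n_cells)
    stop(sprintf("generation error: %d clusters cannot fit a %d x %d tile layout",
                 n_mat, grid$gamma, grid$zeta))

  img <- array(stats::rnorm(H * W * 3, spec$background_mean, spec$background_sd),
               dim = c(H, W, 3L))
  mask <- matrix(0L, H, W)

  cells <- sample.int(n_cells, n_mat)           # linear cell index, column-major
  classes <- rep(c(1L, 2L), c(spec$n_benign, spec$n_malignant))
  layout <- integer(n_cells)
  layout[cells] <- classes

  for (cell in which(layout > 0L)) {
    cls <- layout[cell]
    beta <- (cell - 1L) %% grid$zeta            # row of the cell
    alpha <- (cell - 1L) %/% grid$zeta          # column of the cell
    r0 <- beta * psi; c0 <- alpha * w           # 0-based tile origin (row, col)
    # malignant tiles hold tumor discs amid benign bystander discs; the
    # tumor discs are drawn last (on top), so metastatic clusters form
    # compact blobs rather than fragments overdrawn by bystander cells
    n_mal_discs <- if (cls == 2L)
      max(1L, round(spec$malignant_mix * spec$clusters_per_tile)) else 0L
    disc_classes <- c(rep(1L, spec$clusters_per_tile - n_mal_discs),
                      rep(2L, n_mal_discs))
    tile_lab <- matrix(0L, psi, w)
    for (d in seq_len(spec$clusters_per_tile)) {
      disc_cls <- disc_classes[d]
      rad <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
      if (disc_cls == 2L)
        rad <- rad * spec$malignant_scale
      if (spec$placement == "center") {
        cy <- psi / 2; cx <- w / 2
      } else {
        cy <- stats::runif(1, 0, psi); cx <- stats::runif(1, 0, w)
      }
      yy <- pmax(1L, ceiling(cy - rad)):pmin(psi, floor(cy + rad + 1))
      xx <- pmax(1L, ceiling(cx - rad)):pmin(w, floor(cx + rad + 1))
      dy2 <- (yy - 0.5 - cy)^2
      dx2 <- (xx - 0.5 - cx)^2
      inside <- outer(dy2, dx2, "+") <= rad^2
      sub <- tile_lab[yy, xx]
      sub[inside] <- disc_cls
      tile_lab[yy, xx] <- sub
    }
    for (disc_cls in 1:2) {
      idx <- which(tile_lab == disc_cls)
      if (length(idx) == 0L) next
      n_in <- length(idx)
      rows <- r0 + (idx - 1L) %% psi + 1L
      cols <- c0 + (idx - 1L) %/% psi + 1L
      col_base <- if (disc_cls == 1L) spec$benign_color else spec$malignant_color
      dark_frac <- if (disc_cls == 1L) spec$dark_fraction / 10 else spec$dark_fraction
      shade <- rep(1, n_in)
      dark <- stats::runif(n_in) < dark_frac
      shade[dark] <- 0.45                      # dark nuclei
      for (ch in 1:3) {
        val <- col_base[ch] * shade + stats::rnorm(n_in, 0, 0.03)
        img[cbind(rows, cols, ch)] <- val
      }
      mask[cbind(rows, cols)] <- disc_cls
    }
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 255) / 255                 # 8-bit grid: file round trips exactly

  levels <- lapply(rev(spec$downsamples), function(f) {
    if (f == 1L) return(img)
    lv <- array(0, dim = c(H %/% f, W %/% f, 3L))
    for (ch in 1:3) lv[, , ch] <- block_mean(img[, , ch], f)
    round(lv * 255) / 255
  })
  pyramid <- slide_pyramid(rev(levels))

  truth <- do.call(rbind, lapply(seq_len(n_cells), function(cell) {
    beta <- (cell - 1L) %% grid$zeta
    alpha <- (cell - 1L) %/% grid$zeta
    sub <- mask[(beta * psi + 1L):((beta + 1L) * psi),
                (alpha * w + 1L):((alpha + 1L) * w)]
    tf <- mean(sub > 0L)
    dom <- if (tf == 0) 0L else as.integer(names(which.max(table(sub[sub > 0L]))))
    data.frame(alpha = alpha, beta = beta, class = layout[cell],
               tissue_fraction = tf, dominant_class = dom)
  }))
  list(pyramid = pyramid, mask = mask, truth = truth, spec = spec)
}

#' Generate a reproducible dataset of synthetic slides
#'
#' Produces a mixture of tumor-bearing and tumor-free slides mirroring (at
#' reduced scale) a cohort with both malignant and benign aspirates. Exactly
#' `round(n_slides * class_balance)` slides carry malignant clusters; the
#' rest contain only benign material. Each slide uses a sub-seed derived
#' from `seed`, so the whole dataset is reproducible.
#'
#' @param n_slides number of slides.
#' @param class_balance fraction of tumor-bearing slides in `[0, 1]`.
#' @param template a [fixture_spec] providing geometry and appearance.
#' @param seed RNG seed.
#' @return list of slides (each a [generate_slide] result, plus a
#'   `malignant` flag); the per-slide spec records the sub-seed used.
#' @export
generate_dataset <- function(n_slides, class_balance = 0.4,
                             template = fixture_spec(), seed = 1L) {
  stopifnot(n_slides >= 1, class_balance >= 0, class_balance <= 1)
  n_mal <- round(n_slides * class_balance)
  set.seed(as.integer(seed))
  is_mal <- seq_len(n_slides) %in% sample.int(n_slides, n_mal)
  lapply(seq_len(n_slides), function(i) {
    sp <- template
    sp$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    if (!is_mal[i]) {
      sp$n_benign <- sp$n_benign + sp$n_malignant
      sp$n_malignant <- 0L
    }
    out <- generate_slide(sp)
    out$malignant <- is_mal[i]
    out$slide_id <- sprintf("slide%03d", i)
    out
  })
}

#' Extract labelled tiles from a synthetic slide
#'
#' Cuts the level-N raster and its reference mask into aligned tiles for
#' training or evaluation. `min_tissue` drops tiles whose true tissue
#' fraction is below the cutoff (set it to 0 to keep every tile).
#'
#' @param slide a [generate_slide] result.
#' @param tile_size `(w, psi)` of the cut; may differ from the layout grid.
#' @param min_tissue minimum true tissue fraction for a tile to be returned.
#' @return list of `list(image, labels, alpha, beta)` training samples.
#' @export
fixture_tiles <- function(slide, tile_size = c(512L, 512L), min_tissue = 0.5) {
  img <- slide$pyramid$levels[[slide$pyramid$level_count]]
  mask <- slide$mask
  grid <- compute_tile_grid(c(ncol(mask), nrow(mask)), tile_size)
  out <- list()
  for (b in 0:(grid$zeta - 1L)) {
    for (a in 0:(grid$gamma - 1L)) {
      rows <- (b * grid$psi + 1L):((b + 1L) * grid$psi)
      cols <- (a * grid$w + 1L):((a + 1L) * grid$w)
      sub <- mask[rows, cols]
      if (mean(sub > 0L) < min_tissue) next
      out[[length(out) + 1L]] <- list(image = img[rows, cols, , drop = FALSE],
                                      labels = sub, alpha = a, beta = b)
    }
  }
  out
}
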