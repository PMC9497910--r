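# brute-force reference: scan every histogram cut, maximise between-class
# variance on the quantized 256-level luminance
otsu_brute <- function(gray, n_bins = 256L) {
  bins <- as.integer(round(gray * (n_bins - 1L)))
  counts <- as.numeric(tabulate(bins + 1L, nbins = n_bins))
  n <- length(bins)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:(n_bins - 2L)) {
    w0 <- sum(counts[1:(t + 1L)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:(t + 1L)] * (0:t)) / w0
    mu1 <- sum(counts[(t + 2L):n_bins] * ((t + 1L):(n_bins - 1L))) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  (best_t + 0.5) / (n_bins - 1L)
}

test_that("Otsu separates a perfectly bimodal image", {
  img <- matrix(c(rep(20, 50), rep(230, 50)) / 255, 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 20 / 255)
  expect_lt(thr, 230 / 255)
  expect_true(all((img < thr) == (img == 20 / 255)))   # dark side = tissue
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  set.seed(401)
  g <- c(rnorm(3000, 60, 10), rnorm(3000, 220, 10))
  g <- matrix(pmin(pmax(g, 0), 255) / 255, 60, 100)
  expect_equal(otsu_threshold(g), otsu_brute(g))
  for (s in 1:5) {
    set.seed(500 + s)
    g <- matrix(runif(512)^sample(1:3, 1), 16, 32)
    expect_equal(otsu_threshold(g), otsu_brute(g))
  }
})

test_that("Otsu handles minimal and degenerate input", {
  expect_lt(otsu_threshold(matrix(c(0, 1), 1, 2)), 1)      # {0,255}: separates
  expect_gt(otsu_threshold(matrix(c(0, 1), 1, 2)), 0)
  expect_error(otsu_threshold(matrix(0.5, 4, 4)), "degenerate")
})

test_that("tissue mask marks dark material on bright background", {
  white <- rgb_array(32, 32, value = c(1, 1, 1))
  expect_warning(m <- compute_tissue_mask(white), "all background")
  expect_equal(sum(m$mask), 0)

  # dark disc of radius 40 on white: tissue count matches disc area within 1%
  h <- 128; w <- 128; r <- 40
  img <- rgb_array(h, w, value = c(0.95, 0.95, 0.95))
  dy <- outer((1:h) - 0.5 - h / 2, rep(1, w))
  dx <- outer(rep(1, h), (1:w) - 0.5 - w / 2)
  disc <- dy^2 + dx^2 <= r^2
  for (c in 1:3) img[, , c][disc] <- 0.3
  tm <- compute_tissue_mask(img)
  expect_lt(abs(sum(tm$mask) - pi * r^2) / (pi * r^2), 0.01)

  # inverting the image flips the mask complement (boundary bin aside)
  inv <- 1 - img
  tm_inv <- compute_tissue_mask(inv)
  agree <- mean(tm_inv$mask == !tm$mask)
  expect_gt(agree, 0.999)
})

test_that("the 70% tissue rule is inclusive and exact at level N", {
  # mask at full resolution: fraction equals the per-tile mean of the mask
  pyr <- tiny_pyramid(list(c(40, 20)))
  grid <- compute_tile_grid(c(40, 20), c(10, 10))
  mk <- matrix(FALSE, 20, 40)
  mk[1:7, 1:10] <- TRUE                      # tile (0,0): exactly 70%
  mk[1:5, 11:20] <- TRUE                     # tile (1,0): 50%
  tm <- structure(list(level = 1L, mask = mk, threshold = 0.5), class = "tissue_mask")
  ks <- filter_tiles(tm, pyr, grid, 0.70)
  expect_true(ks$kept[1, 1])                 # exactly 70% is kept
  expect_false(ks$kept[1, 2])
  # exact agreement with the brute-force per-tile pixel count
  for (b in 0:1) for (a in 0:3)
    expect_equal(ks$tissue_fraction[b + 1, a + 1],
                 mean(mk[(b * 10 + 1):(b * 10 + 10), (a * 10 + 1):(a * 10 + 10)]))
})

test_that("tissue fraction is independent of the mask level for ideal masks", {
  # left half tissue on a 4x2 grid of 512-tiles; mask given at 4x downsample
  W <- 2048; H <- 1024
  pyr <- structure(list(levels = vector("list", 2), level_count = 2L,
                        dims = cbind(width = c(W / 4, W), height = c(H / 4, H)),
                        downsample = c(4, 1)), class = "slide_pyramid")
  mk <- matrix(FALSE, H / 4, W / 4)
  mk[, 1:(W / 8)] <- TRUE
  tm <- structure(list(level = 1L, mask = mk, threshold = 0.5), class = "tissue_mask")
  grid <- compute_tile_grid(c(W, H), c(512, 512), level = 2L)
  ks <- filter_tiles(tm, pyr, grid, 0.70)
  expect_equal(sum(ks$kept), 4L)
  expect_equal(unname(ks$tissue_fraction[, 1:2]), matrix(1, 2, 2))
  expect_equal(unname(ks$tissue_fraction[, 3:4]), matrix(0, 2, 2))

  # kept count is monotone non-increasing in the threshold
  mk2 <- matrix(runif(H / 4 * W / 4) < 0.6, H / 4, W / 4)
  tm2 <- structure(list(level = 1L, mask = mk2, threshold = 0.5), class = "tissue_mask")
  kept_at <- vapply(c(0.2, 0.4, 0.6, 0.8),
                    function(th) sum(filter_tiles(tm2, pyr, grid, th)$kept), numeric(1))
  expect_true(all(diff(kept_at) <= 0))
})

test_that("an all-white slide keeps nothing", {
  lv <- rgb_array(512, 1024, value = c(1, 1, 1))
  pyr <- slide_pyramid(list(lv))
  grid <- compute_tile_grid(c(1024, 512), c(512, 512), level = 1L)
  suppressWarnings(tm <- compute_tissue_mask(pyr$levels[[1]], level = 1L))
  ks <- filter_tiles(tm, pyr, grid)
  expect_equal(sum(ks$kept), 0L)
})
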