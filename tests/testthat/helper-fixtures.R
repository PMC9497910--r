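# Shared fixtures: tiny pyramids, a narrow network spec and a cached
# synthetic dataset so the expensive generation runs once per suite.

rgb_array <- function(h, w, value = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(value)) {
    arr <- array(round(stats::runif(h * w * 3) * 255) / 255, dim = c(h, w, 3))
  } else {
    arr <- array(rep(value, each = h * w), dim = c(h, w, 3))
  }
  arr
}

# pyramid with given per-level (width, height) pairs, random content
tiny_pyramid <- function(dims_list, seed = 1) {
  set.seed(seed)
  slide_pyramid(lapply(dims_list, function(d) rgb_array(d[2], d[1], seed = NULL)))
}

# narrow-width instance of the architecture: same layer sequence and spatial
# geometry as the full-width default, minute-scale parameters
narrow_spec <- function() network_spec(c(8L, 16L, 24L, 24L, 24L), 48L)

# one small cached fixture dataset for the training / end-to-end tests
fixture_cache <- new.env()
cached_dataset <- function() {
  if (is.null(fixture_cache$ds))
    fixture_cache$ds <- generate_dataset(3, 1.0, fixture_spec(), seed = 11)
  fixture_cache$ds
}
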