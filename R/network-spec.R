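#' Specification of the single-stream FCN
#'
#' Describes the modified fully convolutional network layer by layer: a
#' five-block VGG-style backbone (blocks 1-2 hold two 3x3 stride-1
#' convolutions, blocks 3-5 three each, every convolution followed by ReLU,
#' every block closed by a 2x2 stride-2 max-pooling), then a 7x7 stride-1
#' convolution to `fc_channels` with dropout, a 1x1 convolution to
#' `fc_channels` with dropout, a 1x1 score convolution to `n_classes`
#' channels, a single 64x64 stride-32 transposed convolution back to
#' `n_classes` channels, a crop to the input extent, and a per-pixel softmax.
#'
#' The spatial arithmetic follows the original FCN reproduction conventions:
#' the first convolution is zero-padded by 100, the remaining 3x3
#' convolutions by 1, the 7x7 and 1x1 convolutions are unpadded, pooling uses
#' ceiling-mode output sizes `ceil(s/2)`, the transposed convolution maps a
#' side `s` to `(s - 1) * 32 + 64`, and the crop removes a fixed 19-pixel
#' offset before cutting the input-sized window. Under these conventions a
#' 512-pixel input traces to 710 after the first convolution, 355 / 178 / 89 /
#' 45 / 23 after the five poolings, 17 after the 7x7 convolution, and 576
#' after upsampling.
#'
#' Channel widths default to the full reference architecture
#' (64/128/256/512/512 backbone, 4096 head). Narrower widths produce the same
#' layer sequence and identical spatial geometry with a fraction of the
#' parameters, which is what the desk-scale training presets use.
#'
#' @param channels backbone block widths (5 integers).
#' @param fc_channels width of the two fully convolutional head layers.
#' @param n_classes number of classes `C + 1` (background / nontarget /
#'   target, default 3).
#' @param dropout dropout ratio of the two dropout layers (default 0.5).
#' @return A `network_spec` object whose `layers` data frame lists
#'   (name, type, kernel, stride, pad, channels) row by row.
#' @examples
#' spec <- network_spec()
#' shape_trace(spec, 512)
#' @export
network_spec <- function(channels = c(64L, 128L, 256L, 512L, 512L),
                         fc_channels = 4096L, n_classes = 3L, dropout = 0.5) {
  if (length(channels) != 5L || any(channels < 1L))
    stop("backbone needs five positive block widths")
  if (fc_channels < 1L || n_classes < 2L) stop("invalid head widths")
  if (dropout < 0 || dropout >= 1) stop("dropout ratio must be in [0, 1)")
  convs_per_block <- c(2L, 2L, 3L, 3L, 3L)
  rows <- list(list("input", "input", NA, NA, NA, 3L))
  for (blk in 1:5) {
    for (cv in seq_len(convs_per_block[blk])) {
      pad <- if (blk == 1L && cv == 1L) 100L else 1L
      rows[[length(rows) + 1L]] <-
        list(sprintf("conv%d_%d", blk, cv), "conv", 3L, 1L, pad, channels[blk])
    }
    rows[[length(rows) + 1L]] <- list(sprintf("pool%d", blk), "pool", 2L, 2L, 0L, channels[blk])
  }
  rows[[length(rows) + 1L]] <- list("conv6", "conv", 7L, 1L, 0L, fc_channels)
  rows[[length(rows) + 1L]] <- list("drop6", "dropout", NA, NA, NA, fc_channels)
  rows[[length(rows) + 1L]] <- list("conv7", "conv", 1L, 1L, 0L, fc_channels)
  rows[[length(rows) + 1L]] <- list("drop7", "dropout", NA, NA, NA, fc_channels)
  rows[[length(rows) + 1L]] <- list("conv8", "conv", 1L, 1L, 0L, n_classes)
  rows[[length(rows) + 1L]] <- list("deconv9", "deconv", 64L, 32L, 0L, n_classes)
  rows[[length(rows) + 1L]] <- list("crop", "crop", NA, NA, 19L, n_classes)
  rows[[length(rows) + 1L]] <- list("softmax", "softmax", NA, NA, NA, n_classes)
  layers <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], type = r[[2]], kernel = r[[3]],
               stride = r[[4]], pad = r[[5]], channels = r[[6]])))
  structure(list(layers = layers, channels = as.integer(channels),
                 fc_channels = as.integer(fc_channels),
                 n_classes = as.integer(n_classes), dropout = dropout),
            class = "network_spec")
}

#' Validate a network spec against the canonical layer sequence
#'
#' Rebuilds the canonical layer table from the spec's widths and compares row
#' for row: layer order, types, kernel sizes, strides and paddings must all
#' match. The first offending row is named in the error.
#'
#' @param spec a [network_spec] (possibly tampered with).
#' @return `spec`, invisibly, if valid.
#' @export
validate_network_spec <- function(spec) {
  if (!inherits(spec, "network_spec")) stop("not a network_spec")
  ref <- network_spec(spec$channels, spec$fc_channels, spec$n_classes, spec$dropout)
  a <- spec$layers; b <- ref$layers
  if (nrow(a) != nrow(b))
    stop(sprintf("spec has %d layer rows, expected %d", nrow(a), nrow(b)))
  for (r in seq_len(nrow(b))) {
    same <- all(mapply(function(x, y) identical(is.na(x), is.na(y)) &&
                         (is.na(x) || x == y), a[r, ], b[r, ]))
    if (!same)
      stop(sprintf("spec row %d ('%s') deviates from the reference architecture", r, b$name[r]))
  }
  invisible(spec)
}

#' Closed-form shape trace of the network
#'
#' Computes the spatial side length and channel count after every layer for a
#' square input, using the spec's padding/stride conventions, without
#' building or running the model. This is the shape oracle the live forward
#' pass is checked against, and it reproduces the canonical feature-map sizes
#' for a 512-pixel input (see [network_spec]).
#'
#' @param spec a [network_spec].
#' @param input_side input side length in pixels (>= 224, so the map survives
#'   five poolings and the 7x7 convolution).
#' @return data frame with columns `layer`, `side`, `channels`.
#' @examples
#' shape_trace(network_spec(), 512)
#' @export
shape_trace <- function(spec, input_side) {
  validate_network_spec(spec)
  s <- as.integer(input_side)
  if (s < 224L)
    stop(sprintf("trace error: input side %d is below the 224-pixel minimum %s",
                 s, "(the map must survive five poolings and the 7x7 convolution)"))
  out <- list()
  ch <- 3L
  for (r in seq_len(nrow(spec$layers))) {
    ly <- spec$layers[r, ]
    s_new <- switch(ly$type,
      input   = s,
      conv    = s + 2L * ly$pad - ly$kernel + 1L,
      pool    = (s + 1L) %/% 2L,                    # ceiling mode
      dropout = s,
      deconv  = (s - 1L) * ly$stride + ly$kernel,
      crop    = as.integer(input_side),
      softmax = s
    )
    if (ly$type == "crop" && s < ly$pad + input_side)
      stop(sprintf("trace error: '%s' cannot cut a %d-pixel window at offset %d from a %d-pixel map",
                   ly$name, input_side, ly$pad, s))
    if (s_new < 1L)
      stop(sprintf("trace error: layer '%s' collapses the feature map (side %d -> %d); input too small",
                   ly$name, s, s_new))
    s <- s_new
    ch <- ly$channels
    out[[r]] <- data.frame(layer = ly$name, side = s, channels = ch)
  }
  do.call(rbind, out)
}
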