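# Model construction, forward/backward orchestration and SGD training.
# Layer arithmetic lives in src/layers.cpp; this file owns parameter
# initialisation, the execution plan, the loss, and the training loop.

bilinear_kernel <- function(size) {
  factor <- (size + 1) %/% 2
  center <- if (size %% 2 == 1) factor - 1 else factor - 0.5
  v <- 1 - abs(seq_len(size) - 1 - center) / factor
  outer(v, v)
}

#' Build the FCN model from a spec
#'
#' Instantiates seeded parameters for every layer of the spec: backbone and
#' head convolutions use fan-in scaled Gaussian weights (He initialisation,
#' `sd = sqrt(2 / (k * k * c_in))`) with zero biases, the score convolution
#' is initialised to zero, and the transposed convolution starts as an exact
#' bilinear upsampling filter (the standard FCN recipe), so an untrained
#' model upsamples its score map by plain bilinear interpolation. Two builds
#' with the same seed are identical.
#'
#' @param spec a [network_spec]; validated before use.
#' @param seed integer RNG seed for the weight draw.
#' @return A `fcn_model` object (spec + parameter list).
#' @export
build_network <- function(spec, seed = 1L) {
  validate_network_spec(spec)
  set.seed(as.integer(seed))
  layers <- spec$layers
  params <- vector("list", nrow(layers))
  cin <- 3L
  score_row <- max(which(layers$type == "conv"))   # conv8, the score layer
  for (r in seq_len(nrow(layers))) {
    ly <- layers[r, ]
    if (ly$type == "conv") {
      k <- ly$kernel; cout <- ly$channels
      if (r == score_row) {
        W <- array(0, dim = c(k, k, cin, cout))
      } else {
        W <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                   dim = c(k, k, cin, cout))
      }
      params[[r]] <- list(W = W, b = numeric(cout))
      cin <- cout
    } else if (ly$type == "deconv") {
      k <- ly$kernel; cout <- ly$channels
      W <- array(0, dim = c(k, k, cin, cout))
      ker <- bilinear_kernel(k)
      for (c in seq_len(min(cin, cout))) W[, , c, c] <- ker
      params[[r]] <- list(W = W, b = numeric(cout))
      cin <- cout
    } else if (ly$type %in% c("pool", "dropout", "crop", "softmax", "input")) {
      cin <- ly$channels
      if (is.na(cin)) cin <- layers$channels[r]
    }
  }
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "fcn_model")
}

#' @export
print.fcn_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p)
    if (is.null(p)) 0 else length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<fcn_model> %d layers, %s parameters (seed %d)\n",
              nrow(x$spec$layers), format(n_par, big.mark = ","), x$seed))
  invisible(x)
}

# Forward pass. x: (h, w, 3) array in [0, 1]. Returns per-pixel class logits
# (cropped to the input extent) plus the caches backward needs. Dropout is
# sampled from the current RNG stream only when train = TRUE. With
# trace = TRUE the live activation geometry (side, channels) is recorded
# after every layer for comparison against the closed-form shape_trace().
nn_forward <- function(model, x, train = FALSE, trace = FALSE) {
  layers <- model$spec$layers
  input_side <- dim(x)[1L]
  if (dim(x)[1L] != dim(x)[2L]) stop("tiles must be square")
  caches <- vector("list", nrow(layers))
  a <- x
  for (r in seq_len(nrow(layers))) {
    ly <- layers[r, ]
    if (ly$type == "conv") {
      caches[[r]] <- list(x = a)
      a <- cpp_conv_fwd(a, model$params[[r]]$W, model$params[[r]]$b, ly$pad)
      if (ly$name != "conv8") {                    # ReLU after every conv but the score
        caches[[r]]$relu <- a > 0
        a[a < 0] <- 0
      }
    } else if (ly$type == "pool") {
      pf <- cpp_pool_fwd(a)
      caches[[r]] <- list(dims = dim(a), idx = pf$idx)
      a <- pf$y
    } else if (ly$type == "dropout") {
      if (train && model$spec$dropout > 0) {
        p <- model$spec$dropout
        mask <- array((stats::runif(length(a)) >= p) / (1 - p), dim = dim(a))
        caches[[r]] <- list(mask = mask)
        a <- a * mask
      }
    } else if (ly$type == "deconv") {
      caches[[r]] <- list(x = a)
      a <- cpp_deconv_fwd(a, model$params[[r]]$W, model$params[[r]]$b, ly$stride)
    } else if (ly$type == "crop") {
      off <- ly$pad
      caches[[r]] <- list(dims = dim(a), off = off, side = input_side)
      a <- a[(off + 1L):(off + input_side), (off + 1L):(off + input_side), , drop = FALSE]
    }
    # input / softmax rows: identity here (softmax lives in the loss / predict)
    if (trace)
      caches[[r]]$live <- data.frame(layer = ly$name, side = dim(a)[1L],
                                     channels = dim(a)[3L])
  }
  out <- list(logits = a, caches = caches)
  if (trace)
    out$trace <- do.call(rbind, lapply(caches, function(cc) cc$live))
  out
}

# Backward pass from d(loss)/d(logits); returns per-layer gradients.
nn_backward <- function(model, caches, dlogits) {
  layers <- model$spec$layers
  grads <- vector("list", nrow(layers))
  d <- dlogits
  for (r in rev(seq_len(nrow(layers)))) {
    ly <- layers[r, ]
    if (ly$type == "conv") {
      if (ly$name != "conv8") d <- d * caches[[r]]$relu
      g <- cpp_conv_bwd(caches[[r]]$x, model$params[[r]]$W, d, ly$pad)
      grads[[r]] <- list(dW = g$dw, db = g$db)
      d <- g$dx
    } else if (ly$type == "pool") {
      dm <- caches[[r]]$dims
      d <- cpp_pool_bwd(caches[[r]]$idx, dm[1L], dm[2L], d)
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[r]])) d <- d * caches[[r]]$mask
    } else if (ly$type == "deconv") {
      g <- cpp_deconv_bwd(caches[[r]]$x, model$params[[r]]$W, d, ly$stride)
      grads[[r]] <- list(dW = g$dw, db = g$db)
      d <- g$dx
    } else if (ly$type == "crop") {
      full <- array(0, dim = caches[[r]]$dims)
      off <- caches[[r]]$off; side <- caches[[r]]$side
      full[(off + 1L):(off + side), (off + 1L):(off + side), ] <- d
      d <- full
    }
  }
  grads
}

# Per-pixel softmax over the channel axis.
softmax3 <- function(logits) {
  m <- pmax(logits[, , 1L], logits[, , 2L])
  for (c in seq_len(dim(logits)[3L])[-(1:2)]) m <- pmax(m, logits[, , c])
  e <- exp(logits - as.vector(m))
  s <- e[, , 1L]
  for (c in seq_len(dim(logits)[3L])[-1L]) s <- s + e[, , c]
  e / as.vector(s)
}

# Categorical cross-entropy over pixels with labels in {0..C}; reduction
# "sum" (the reference configuration) or "mean" (desk-scale preset).
softmax_ce <- function(logits, labels, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  C <- dim(logits)[3L]
  if (any(labels < 0L) || any(labels > C - 1L))
    stop(sprintf("label raster contains classes outside {0..%d}", C - 1L))
  probs <- softmax3(logits)
  npix <- length(labels)
  pick <- cbind(as.vector(row(labels)), as.vector(col(labels)), as.vector(labels) + 1L)
  p_true <- pmax(probs[pick], 1e-12)
  loss <- -sum(log(p_true))
  onehot <- array(0, dim = dim(logits))
  onehot[pick] <- 1
  dlogits <- probs - onehot
  if (reduction == "mean") { loss <- loss / npix; dlogits <- dlogits / npix }
  list(loss = loss, probs = probs, dlogits = dlogits)
}

#' Training configuration
#'
#' Bundles the optimisation settings. The `"reference"` preset is the
#' full-scale configuration: plain stochastic gradient descent with learning rate
#' 1e-10, dropout 0.5, weight decay 0.0005, batch size 1 and cross-entropy
#' *summed* over pixels (that tiny rate is meaningful only with the summed
#' loss, whose gradients scale with the pixel count). The `"smoke"` preset
#' is the desk-scale configuration for minute-scale synthetic training on a
#' CPU: the same plain SGD and batch size, but with the loss mean-reduced,
#' learning rate 0.01 (stepped to 0.3x after 12 epochs), and dropout off —
#' with a randomly initialised (non-pretrained) backbone the class signal
#' reaching the score layer is small, and dropout noise at 0.5 would
#' dominate a desk-scale gradient budget (see the package vignette).
#'
#' @param preset `"reference"` or `"smoke"`.
#' @param epochs number of passes over the training tiles.
#' @param seed RNG seed for tile order and dropout.
#' @param learning_rate,weight_decay,batch_size,dropout,loss_reduction
#'   overrides of the preset values.
#' @param lr_step_factor,lr_step_after step learning-rate schedule: after
#'   `lr_step_after` epochs the rate is multiplied by `lr_step_factor`
#'   (factor 1 = constant rate, the reference configuration; the smoke preset
#'   steps to 0.3x after 12 epochs to damp late-training oscillations of
#'   the jointly trained backbone and readout).
#' @param freeze_upsampling keep the transposed convolution fixed at its
#'   bilinear initialisation during training (the standard single-stream FCN
#'   practice; the layer is an interpolator, not a feature extractor).
#' @return A `training_config` object.
#' @export
training_config <- function(preset = c("reference", "smoke"), epochs = 10L, seed = 1L,
                            learning_rate = NULL, weight_decay = 0.0005,
                            batch_size = 1L, dropout = NULL,
                            loss_reduction = NULL, lr_step_factor = NULL,
                            lr_step_after = 12L, freeze_upsampling = TRUE) {
  preset <- match.arg(preset)
  if (is.null(learning_rate))
    learning_rate <- if (preset == "reference") 1e-10 else 0.01
  if (is.null(loss_reduction))
    loss_reduction <- if (preset == "reference") "sum" else "mean"
  if (is.null(dropout))
    dropout <- if (preset == "reference") 0.5 else 0
  if (is.null(lr_step_factor))
    lr_step_factor <- if (preset == "reference") 1 else 0.3
  stopifnot(learning_rate >= 0, weight_decay >= 0, batch_size >= 1, epochs >= 0,
            lr_step_factor > 0, lr_step_factor <= 1, lr_step_after >= 1)
  structure(list(preset = preset, optimizer = "sgd",
                 learning_rate = learning_rate,
                 lr_step_factor = lr_step_factor,
                 lr_step_after = as.integer(lr_step_after),
                 dropout = dropout,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 loss_reduction = loss_reduction,
                 freeze_upsampling = isTRUE(freeze_upsampling),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' @export
print.training_config <- function(x, ...) {
  cat(sprintf(paste0("<training_config> preset=%s optimizer=%s lr=%g ",
                     "lr_step=%gx@%d dropout=%g weight_decay=%g batch_size=%d ",
                     "loss=%s epochs=%d seed=%d\n"),
              x$preset, x$optimizer, x$learning_rate, x$lr_step_factor,
              x$lr_step_after, x$dropout, x$weight_decay, x$batch_size,
              x$loss_reduction, x$epochs, x$seed))
  invisible(x)
}

#' Train the FCN with seeded SGD
#'
#' Runs plain stochastic gradient descent (batch size 1: one update per
#' tile) over the labelled tiles for `config$epochs` epochs. Tile order is
#' reshuffled each epoch and dropout masks are resampled, both from the RNG
#' stream seeded by `config$seed`, so training is exactly reproducible.
#' Weight decay is applied to convolution weights (not biases). The recorded
#' loss per epoch is the mean per-tile training loss observed during that
#' epoch's pass.
#'
#' @param model a [build_network] model.
#' @param tiles list of training samples, each a list with `image`
#'   (`(s, s, 3)` array in `[0, 1]`) and `labels` (`s x s` integer matrix
#'   with classes in `{0..C}`).
#' @param config a [training_config].
#' @return list with `model` (trained) and `losses` (numeric, one per epoch).
#' @export
train_network <- function(model, tiles, config) {
  stopifnot(inherits(model, "fcn_model"), inherits(config, "training_config"))
  if (length(tiles) < 1L) stop("need at least one labelled tile")
  for (t in tiles) {
    if (any(t$labels < 0L) || any(t$labels > model$spec$n_classes - 1L))
      stop(sprintf("label raster contains classes outside {0..%d}",
                   model$spec$n_classes - 1L))
  }
  if (config$epochs == 0L) return(list(model = model, losses = numeric(0)))
  set.seed(config$seed)
  losses <- numeric(config$epochs)
  wd <- config$weight_decay
  frozen <- if (isTRUE(config$freeze_upsampling))
    which(model$spec$layers$type == "deconv") else integer(0)
  model$spec$dropout <- config$dropout
  for (ep in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      if (ep > config$lr_step_after) config$lr_step_factor else 1
    ord <- sample.int(length(tiles))
    ep_loss <- 0
    for (ti in ord) {
      tile <- tiles[[ti]]
      fw <- nn_forward(model, tile$image, train = TRUE)
      ce <- softmax_ce(fw$logits, tile$labels, config$loss_reduction)
      if (!is.finite(ce$loss))
        stop(sprintf("divergence: non-finite loss at epoch %d", ep))
      ep_loss <- ep_loss + ce$loss
      if (lr > 0) {
        grads <- nn_backward(model, fw$caches, ce$dlogits)
        for (r in seq_along(model$params)) {
          if (is.null(model$params[[r]]) || r %in% frozen) next
          model$params[[r]]$W <- model$params[[r]]$W -
            lr * (grads[[r]]$dW + wd * model$params[[r]]$W)
          model$params[[r]]$b <- model$params[[r]]$b - lr * grads[[r]]$db
        }
      }
    }
    losses[ep] <- ep_loss / length(tiles)
  }
  list(model = model, losses = losses)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the architecture spec and
#' all parameters; loading validates the spec before returning the model.
#'
#' @param model a `fcn_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fcn_model"))
  saveRDS(list(spec = model$spec, params = model$params, seed = model$seed),
          path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path))
  ck <- readRDS(path)
  validate_network_spec(ck$spec)
  structure(list(spec = ck$spec, params = ck$params, seed = ck$seed),
            class = "fcn_model")
}
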