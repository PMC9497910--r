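test_that("the 512-input shape trace reproduces the canonical feature sizes", {
  st <- shape_trace(network_spec(), 512)
  side <- function(l) st$side[st$layer == l]
  chan <- function(l) st$channels[st$layer == l]
  expect_equal(side("conv1_1"), 710)
  expect_equal(side("conv1_2"), 710)
  expect_equal(side("pool1"), 355)
  expect_equal(side("pool2"), 178)
  expect_equal(side("pool3"), 89)
  expect_equal(side("pool4"), 45)
  expect_equal(side("pool5"), 23)
  expect_equal(side("conv6"), 17)
  expect_equal(side("conv7"), 17)
  expect_equal(side("conv8"), 17)
  expect_equal(side("deconv9"), 576)
  expect_equal(side("crop"), 512)
  expect_equal(side("softmax"), 512)
  expect_equal(vapply(c("conv1_1", "conv2_1", "conv3_1", "conv4_1", "conv5_1",
                        "conv6", "conv7", "conv8", "deconv9"), chan, numeric(1)),
               c(conv1_1 = 64, conv2_1 = 128, conv3_1 = 256, conv4_1 = 512,
                 conv5_1 = 512, conv6 = 4096, conv7 = 4096, conv8 = 3, deconv9 = 3))
})

test_that("the trace follows the layer recurrences for other input sizes", {
  # independent evaluation of the recurrences for a 256-pixel input
  s <- 256
  s <- s + 200 - 2                      # first conv, pad 100
  for (p in 1:5) s <- ceiling(s / 2)    # ceiling-mode poolings (3x3 pad-1 convs keep size)
  s6 <- s - 6                           # unpadded 7x7
  sd <- (s6 - 1) * 32 + 64              # stride-32 deconv
  st <- shape_trace(network_spec(), 256)
  expect_equal(st$side[st$layer == "conv6"], s6)
  expect_equal(st$side[st$layer == "deconv9"], sd)
  expect_equal(st$side[st$layer == "crop"], 256)
  expect_error(shape_trace(network_spec(), 64), "trace error")
})

test_that("spec validation catches tampered layer rows", {
  sp <- network_spec()
  expect_silent(validate_network_spec(sp))
  sp$layers$kernel[sp$layers$name == "conv6"] <- 5L
  expect_error(validate_network_spec(sp), "conv6")
  sp2 <- network_spec()
  sp2$layers$stride[sp2$layers$name == "deconv9"] <- 16L
  expect_error(validate_network_spec(sp2), "deconv9")
  # the full-width default spec itself builds and validates
  expect_s3_class(network_spec(), "network_spec")
})

test_that("a live forward pass matches the closed-form trace layer for layer", {
  sp <- narrow_spec()
  model <- build_network(sp, seed = 2)
  x <- rgb_array(256, 256, seed = 21)
  fw <- cytofcn:::nn_forward(model, x, trace = TRUE)
  st <- shape_trace(sp, 256)
  live <- fw$trace
  ref <- st[match(live$layer, st$layer), ]
  expect_equal(live$side, ref$side)
  expect_equal(live$channels, ref$channels)
})

test_that("softmax output is a probability field and builds are seeded", {
  sp <- narrow_spec()
  m1 <- build_network(sp, seed = 7)
  x <- rgb_array(224, 224, seed = 3)
  p1 <- predict_tile(m1, x, c(224, 224))
  expect_equal(dim(p1), c(224, 224, 3))
  sums <- p1[, , 1] + p1[, , 2] + p1[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_gte(min(p1), 0)
  expect_lte(max(p1), 1)
  m2 <- build_network(sp, seed = 7)
  expect_identical(p1, predict_tile(m2, x, c(224, 224)))
  m3 <- build_network(sp, seed = 8)
  expect_false(identical(m1$params, m3$params))   # different seed, different draw
})

test_that("bilinear-initialised deconv performs plain bilinear upsampling", {
  k <- 8L; stride <- 4L
  ker <- cytofcn:::bilinear_kernel(k)
  x <- array(0, dim = c(5, 5, 1))
  x[, , 1] <- outer(1:5, 1:5, function(a, b) a + 2 * b) / 10   # ramp
  y <- cytofcn:::cpp_deconv_fwd(x, array(ker, dim = c(k, k, 1, 1)), 0, stride)
  # interior output samples of an upsampled ramp stay on the ramp plane:
  # second differences along each axis vanish where the support is complete
  interior <- y[8:16, 8:16, 1]
  expect_lt(max(abs(diff(interior[, 5], differences = 2))), 1e-10)
  expect_lt(max(abs(diff(interior[5, ], differences = 2))), 1e-10)
  # partition of unity: a constant map upsamples to the same constant where
  # the kernel support is complete (overlapping bilinear windows sum to 1)
  ones <- array(1, dim = c(5, 5, 1))
  yo <- cytofcn:::cpp_deconv_fwd(ones, array(ker, dim = c(k, k, 1, 1)), 0, stride)
  expect_equal(unique(round(as.vector(yo[9:12, 9:12, 1]), 10)), 1)
})

test_that("training contracts hold: no-op epochs, zero lr, divergence guards", {
  sp <- narrow_spec()
  model <- build_network(sp, seed = 1)
  set.seed(31)
  mk_tile <- function(cls) list(image = rgb_array(224, 224, seed = NULL),
                                labels = matrix(cls, 224, 224))
  tiles <- list(mk_tile(0L), mk_tile(1L))

  # zero epochs: model unchanged, empty loss record
  out0 <- train_network(model, tiles, training_config("smoke", epochs = 0, seed = 1))
  expect_identical(out0$model$params, model$params)
  expect_length(out0$losses, 0)

  # zero learning rate: weights unchanged across epochs
  out_lr0 <- train_network(model, tiles,
                           training_config("smoke", epochs = 2, seed = 1,
                                           learning_rate = 0))
  expect_identical(out_lr0$model$params, model$params)

  # labels outside {0..C} are a data error
  bad <- list(list(image = rgb_array(224, 224, seed = 2),
                   labels = matrix(3L, 224, 224)))
  expect_error(train_network(model, bad, training_config("smoke", epochs = 1)),
               "outside \\{0..2\\}")
})

test_that("a single uniformly-labelled tile is overfit to its label", {
  sp <- narrow_spec()
  model <- build_network(sp, seed = 11)
  set.seed(41)
  tile <- list(image = rgb_array(224, 224, seed = NULL),
               labels = matrix(0L, 224, 224))
  fit <- train_network(model, list(tile),
                       training_config("smoke", epochs = 4, seed = 2))
  expect_lt(fit$losses[4], fit$losses[1])
  m <- class_map(predict_tile(fit$model, tile$image, c(224, 224)))
  expect_true(all(m == 0L))
})

test_that("reference and smoke presets carry the documented settings", {
  tp <- training_config("reference")
  expect_equal(tp$learning_rate, 1e-10)
  expect_equal(tp$dropout, 0.5)
  expect_equal(tp$weight_decay, 5e-4)
  expect_equal(tp$batch_size, 1L)
  expect_equal(tp$loss_reduction, "sum")
  expect_equal(tp$optimizer, "sgd")
  ts <- training_config("smoke")
  expect_equal(ts$loss_reduction, "mean")
})

test_that("checkpoints round-trip the model", {
  sp <- narrow_spec()
  model <- build_network(sp, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  x <- rgb_array(224, 224, seed = 5)
  expect_identical(predict_tile(back, x, c(224, 224)),
                   predict_tile(model, x, c(224, 224)))
  expect_error(load_checkpoint("no/such.rds"), "not found")
})
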