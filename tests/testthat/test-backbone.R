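ns <- asNamespace("attdunet")

test_that("dense layer is BN -> ReLU -> 3x3 conv with growth channels", {
  set.seed(20)
  p <- dense_layer_params(2L, 4L)
  x <- rand_fm(5, 5, 2, 1)
  y <- dense_layer(x, p, training = TRUE)
  expect_equal(dim(y), c(5, 5, 4, 1))

  # zero conv weights annihilate the output
  p$conv$w$v[] <- 0
  p$conv$b$v[] <- 0
  expect_true(all(dense_layer(x, p, training = TRUE) == 0))

  # eval mode with identity BN equals the direct convolution oracle
  p2 <- dense_layer_params(2L, 3L)
  p2$bn$state$v <- list(mean = rep(0, 2), var = rep(1 - 1e-5, 2))
  y2 <- dense_layer(x, p2, training = FALSE)
  ref <- conv2d_ref(pmax(x, 0), p2$conv$w$v, p2$conv$b$v)
  expect_lt(max(abs(y2 - ref)), 1e-6)
})

test_that("dense block concatenates all previous layers (unrolled oracle)", {
  set.seed(21)
  p <- dense_block_params(3L, 2L, 2L)
  x <- rand_fm(6, 6, 3, 2)
  y <- dense_block(x, p, training = FALSE)
  expect_equal(dim(y)[3], 3 + 2 * 2)

  # unroll by hand through the public dense_layer
  y1 <- dense_layer(x, p$layers[[1]], training = FALSE)
  in2 <- array(0, c(6, 6, 5, 2))
  in2[, , 1:3, ] <- x
  in2[, , 4:5, ] <- y1
  y2 <- dense_layer(in2, p$layers[[2]], training = FALSE)
  ref <- array(0, c(6, 6, 7, 2))
  ref[, , 1:5, ] <- in2
  ref[, , 6:7, ] <- y2
  expect_lt(max(abs(y - ref)), 1e-12)

  # empty block is the identity
  p0 <- dense_block_params(3L, 0L, 2L)
  expect_identical(dense_block(x, p0), x)

  # channel arithmetic: 16 + 4*12 = 64
  expect_equal(dense_block_params(16L, 4L, 12L)$c_out, 64L)
})

test_that("transition compresses channels and halves the grid", {
  set.seed(22)
  p <- transition_params(6L, 0.5)
  x <- rand_fm(8, 8, 6, 1)
  y <- transition_down(x, p)
  expect_equal(dim(y), c(4, 4, 3, 1))

  # stepwise oracle: 1x1 conv then 2x2 average pooling
  z <- conv2d_ref(x, p$conv$w$v, p$conv$b$v)
  ref <- array(0, c(4, 4, 3, 1))
  for (c in 1:3) for (i in 1:4) for (j in 1:4) {
    ref[i, j, c, 1] <- mean(z[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1])
  }
  expect_lt(max(abs(y - ref)), 1e-10)

  # odd spatial dims floor-halve
  expect_equal(dim(transition_down(rand_fm(7, 9, 6, 1), p))[1:2], c(3, 4))

  # constant image through near-identity projection stays constant
  p2 <- transition_params(1L, 1)
  p2$conv$w$v[] <- 1
  p2$conv$b$v[] <- 0
  yc <- transition_down(array(3, c(4, 4, 1, 1)), p2)
  expect_true(all(abs(yc - 3) < 1e-12))
})

test_that("decoder level has the contracted shapes and composes its stages", {
  set.seed(23)
  p <- decoder_level_params(10L, 6L, 8L, r = 2L)
  deep <- rand_fm(4, 4, 10, 2)
  skip <- rand_fm(8, 8, 6, 2)
  y <- decoder_level(deep, skip, p, training = FALSE)
  expect_equal(dim(y), c(8, 8, 8, 2))

  # manual composition through the public sub-operations
  up <- ns$.cpp_resize_bilinear_fw(deep, 8L, 8L)
  up <- ns$.cpp_conv2d_fw(up, p$up$w$v, p$up$b$v)
  gated <- attention_gate(skip, up, p$ag)$gated
  cat_ <- ns$.cpp_concat_ch(list(up, gated))
  cal <- channel_attention(cat_, p$ca)
  fused <- ns$.cpp_conv2d_fw(cal, p$fuse$w$v, p$fuse$b$v)
  st <- p$fuse_bn$state$v
  bn <- ns$.cpp_bn_fw(fused, as.vector(p$fuse_bn$gamma$v),
                      as.vector(p$fuse_bn$beta$v), st$mean, st$var,
                      FALSE, 1e-5)
  expect_lt(max(abs(y - pmax(bn$y, 0))), 1e-10)
})

test_that("channel bookkeeping matches executed shapes for random configs", {
  set.seed(24)
  for (i in 1:3) {
    cfg <- model_config(base_channels = sample(3:6, 1),
                        growth_rate = sample(2:4, 1),
                        block_layers = sample(1:2, 4, replace = TRUE),
                        compression = sample(c(0.5, 0.75, 1), 1),
                        reduction_r = sample(2:4, 1),
                        decoder_channels = sample(4:8, 4, replace = TRUE),
                        la_reduction = 4L, la_mid = 2L)
    ch <- model_channels(cfg)
    net <- adu_net(cfg)
    x <- rand_fm(32, 32, 1, 1)
    tape <- ns$ag_tape()
    h <- ns$fwd_conv(tape, net$stem, ns$ag_leaf(tape, x))
    expect_equal(dim(h$v)[3], cfg$base_channels)
    for (b in 1:4) {
      h <- ns$fwd_dense_block(tape, net$enc[[b]], h, TRUE)
      expect_equal(dim(h$v)[3], ch$skip[b])
      h <- ns$fwd_transition(tape, net$trans[[b]], h)
      expect_equal(dim(h$v)[3], ch$trans[b])
      expect_equal(dim(h$v)[1], 32 / 2^b)
    }
    h <- ns$fwd_dense_block(tape, net$bottleneck, h, TRUE)
    expect_equal(dim(h$v)[3], ch$bottleneck)
    logits <- net_forward(net, x, training = TRUE)
    expect_equal(dim(logits), c(32, 32, cfg$n_classes, 1))
  }
})

test_that("forward output resolution equals input resolution", {
  set.seed(25)
  net <- adu_net(tiny_config())
  expect_equal(dim(net_forward(net, rand_fm(64, 64, 1, 2))), c(64, 64, 2, 2))
  expect_equal(dim(net_forward(net, rand_fm(128, 128, 1, 1))),
               c(128, 128, 2, 1))
  expect_equal(dim(net_forward(net, rand_fm(32, 48, 1, 1))), c(32, 48, 2, 1))
  expect_error(net_forward(net, rand_fm(60, 60, 1, 1)), "divisible by 16")
})

test_that("every trainable parameter receives gradient (no dead branches)", {
  set.seed(26)
  net <- adu_net(tiny_config())
  x <- rand_fm(32, 32, 1, 2)
  y <- array(sample(0:1, 32 * 32 * 2, TRUE), c(32, 32, 2))
  tape <- ns$ag_tape()
  logits <- ns$fwd_adu_net(tape, net, ns$ag_leaf(tape, x), training = TRUE)
  loss <- ns$op_softmax_xent(tape, logits, y)
  params <- module_params(net)
  ns$zero_grads(params)
  ns$ag_backward(tape, loss)
  for (nm in names(params)) {
    expect_false(is.null(params[[nm]]$g), label = paste("no grad:", nm))
    expect_gt(max(abs(params[[nm]]$g)), 0, label = paste("zero grad:", nm))
  }
})

test_that("builds are deterministic under a fixed seed and size-agnostic", {
  cfg <- tiny_config()
  net1 <- initialize_weights(adu_net(cfg), seed = 99)
  net2 <- initialize_weights(adu_net(cfg), seed = 99)
  x <- rand_fm(32, 32, 1, 1)
  expect_identical(net_forward(net1, x), net_forward(net2, x))

  n_params <- function(net) {
    sum(vapply(module_params(net), function(p) length(p$v), 0))
  }
  # parameter count does not depend on input resolution (fully conv)
  invisible(net_forward(net1, rand_fm(64, 64, 1, 1)))
  expect_equal(n_params(net1), n_params(net2))
})

test_that("checkpoint round trip reproduces forward outputs bit for bit", {
  set.seed(27)
  net <- initialize_weights(adu_net(tiny_config()), seed = 5)
  # perturb running stats so buffers are exercised too
  invisible(net_forward(net, rand_fm(32, 32, 1, 2), training = TRUE))
  x <- rand_fm(32, 32, 1, 1)
  ref <- net_forward(net, x)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f, norm = c(mean = 0.5, std = 0.2),
                  history = data.frame(epoch = 1))
  ck <- load_checkpoint(f)
  expect_identical(net_forward(ck$net, x), ref)
  expect_equal(ck$norm, c(mean = 0.5, std = 0.2))
  unlink(f)

  bad <- tempfile(fileext = ".rds")
  saveRDS(list(oops = 1), bad)
  expect_error(load_checkpoint(bad), "malformed")
  unlink(bad)
})
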