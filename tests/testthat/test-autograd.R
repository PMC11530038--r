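# Gradient correctness of the autodiff primitives, checked against
# central finite differences on tiny tensors.

ag <- function(name) get(name, envir = asNamespace("attdunet"))

# scalar objective: weighted sum of the op output, differentiated wrt
# every input/parameter and compared to finite differences
check_grad <- function(build, envs, tol = 1e-6) {
  wts <- NULL
  run <- function() {
    tape <- ag("ag_tape")()
    out <- build(tape)
    if (is.null(wts)) wts <<- array(rnorm(length(out$v)),
                                    dim = dim(out$v) %||% length(out$v))
    sum(out$v * wts)
  }
  loss0 <- run()
  tape <- ag("ag_tape")()
  out <- build(tape)
  node <- ag("ag_node")(tape, sum(out$v * wts),
                        bw = function(g) ag("ag_acc")(out, array(g * wts,
                          dim = dim(out$v) %||% length(out$v))))
  for (p in envs) p$g <- NULL
  ag("ag_backward")(tape, node)
  for (nm in names(envs)) {
    p <- envs[[nm]]
    fd <- fd_grad(run, p)
    expect_lt(max(abs(as.vector(p$g) - as.vector(fd))), tol,
              label = paste("grad mismatch for", nm))
  }
  invisible(loss0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mkenv <- function(v) {
  e <- new.env(); e$v <- v; e$g <- NULL; e
}

test_that("conv2d forward matches the direct convolution oracle", {
  set.seed(1)
  for (k in c(1L, 3L)) {
    x <- rand_fm(5, 4, 2, 2)
    w <- array(rnorm(k * k * 2 * 3), c(k, k, 2, 3))
    b <- rnorm(3)
    tape <- ag("ag_tape")()
    y <- ag("op_conv2d")(tape, mkenv(x), mkenv(w), mkenv(b))$v
    expect_lt(max(abs(y - conv2d_ref(x, w, b))), 1e-10)
  }
})

test_that("conv2d gradients agree with finite differences", {
  set.seed(2)
  x <- mkenv(rand_fm(4, 4, 2, 1))
  w <- mkenv(array(rnorm(3 * 3 * 2 * 2, sd = 0.5), c(3, 3, 2, 2)))
  b <- mkenv(rnorm(2))
  check_grad(function(tape) ag("op_conv2d")(tape, x, w, b),
             list(x = x, w = w, b = b), tol = 1e-5)
})

test_that("batchnorm gradients agree with finite differences", {
  set.seed(3)
  x <- mkenv(rand_fm(3, 3, 2, 2))
  gamma <- mkenv(array(runif(2, 0.5, 1.5), 2))
  beta <- mkenv(array(rnorm(2), 2))
  state <- ag("new_buffer")(list(mean = rep(0, 2), var = rep(1, 2)))
  # training mode (batch statistics are part of the graph)
  check_grad(function(tape) {
    st <- ag("new_buffer")(list(mean = rep(0, 2), var = rep(1, 2)))
    ag("op_batchnorm")(tape, x, gamma, beta, st, TRUE)
  }, list(x = x, gamma = gamma, beta = beta), tol = 1e-4)
  # eval mode (frozen statistics)
  state$v <- list(mean = c(0.3, -0.2), var = c(1.5, 0.7))
  check_grad(function(tape) {
    ag("op_batchnorm")(tape, x, gamma, beta, state, FALSE)
  }, list(x = x, gamma = gamma, beta = beta), tol = 1e-5)
})

test_that("pooling, resize and broadcast multiply gradients check out", {
  set.seed(4)
  x <- mkenv(rand_fm(4, 4, 2, 2))
  check_grad(function(tape) ag("op_avgpool2")(tape, x), list(x = x))
  check_grad(function(tape) ag("op_resize_bilinear")(tape, x, 7, 6),
             list(x = x))
  check_grad(function(tape) ag("op_gap")(tape, x), list(x = x))

  s <- mkenv(matrix(runif(4), 2, 2))
  check_grad(function(tape) ag("op_mul_channel")(tape, x, s),
             list(x = x, s = s))
  a <- mkenv(rand_fm(4, 4, 1, 2))
  check_grad(function(tape) ag("op_mul_spatial")(tape, x, a),
             list(x = x, a = a))

  y <- mkenv(rand_fm(4, 4, 3, 2))
  check_grad(function(tape) ag("op_concat_ch")(tape, list(x, y)),
             list(x = x, y = y))
})

test_that("global max pool routes gradient to the argmax only", {
  set.seed(5)
  x <- mkenv(rand_fm(3, 3, 2, 1))
  tape <- ag("ag_tape")()
  out <- ag("op_gmp")(tape, x)
  expect_equal(out$v[1, 1], max(x$v[, , 1, 1]))
  g <- matrix(1, 2, 1)
  node <- ag("ag_node")(tape, sum(out$v),
                        bw = function(gr) ag("ag_acc")(out, g * gr))
  x$g <- NULL
  ag("ag_backward")(tape, node)
  expect_equal(sum(x$g != 0), 2)  # one pixel per channel
  expect_equal(sum(x$g), 2)
})

test_that("linear, relu and sigmoid gradients check out", {
  set.seed(6)
  W <- mkenv(matrix(rnorm(6), 2, 3))
  xm <- mkenv(matrix(rnorm(6), 3, 2))
  b <- mkenv(array(rnorm(2), 2))
  check_grad(function(tape) ag("op_linear")(tape, W, xm, b),
             list(W = W, x = xm, b = b))
  x <- mkenv(rand_fm(3, 3, 2, 1))
  check_grad(function(tape) ag("op_relu")(tape, x), list(x = x), tol = 1e-4)
  check_grad(function(tape) ag("op_sigmoid")(tape, x), list(x = x))
})

test_that("softmax cross-entropy value and gradient are correct", {
  set.seed(7)
  H <- 4; W <- 3; N <- 2
  logits <- rand_fm(H, W, 2, N)
  labels <- array(sample(0:1, H * W * N, TRUE), c(H, W, N))
  tape <- ag("ag_tape")()
  ln <- mkenv(logits)
  loss <- ag("op_softmax_xent")(tape, ln, labels)

  # per-pixel -log softmax loop oracle
  ref <- 0
  for (n in 1:N) for (i in 1:H) for (j in 1:W) {
    z <- logits[i, j, , n]
    p <- exp(z) / sum(exp(z))
    ref <- ref - log(p[labels[i, j, n] + 1])
  }
  ref <- ref / (H * W * N)
  expect_lt(abs(loss$v - ref), 1e-10)

  ln$g <- NULL
  ag("ag_backward")(tape, loss)
  fd <- fd_grad(function() {
    tape2 <- ag("ag_tape")()
    ag("op_softmax_xent")(tape2, ln, labels)$v
  }, ln)
  expect_lt(max(abs(as.vector(ln$g) - as.vector(fd))), 1e-6)

  # uniform logits cost exactly log 2
  tape3 <- ag("ag_tape")()
  u <- ag("op_softmax_xent")(tape3, mkenv(array(0, c(H, W, 2, N))), labels)
  expect_equal(u$v, log(2))
})

test_that("bilinear resize matches the scalar reference and is exact on identity", {
  set.seed(8)
  x <- rand_fm(5, 7, 2, 1)
  tape <- ag("ag_tape")()
  y <- ag("op_resize_bilinear")(tape, mkenv(x), 9, 4)$v
  expect_lt(max(abs(y - resize_bilinear_ref(x, 9, 4))), 1e-12)
  y2 <- ag("op_resize_bilinear")(tape, mkenv(x), 5, 7)$v
  expect_identical(y2, x)
})
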