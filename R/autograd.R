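# Reverse-mode automatic differentiation on a linear tape.
#
# A "node" is an environment with the fields
#   v  : value (rank-4 feature map, matrix, or scalar)
#   g  : gradient accumulator, NULL until backward() touches it
#   bw : closure propagating node$g into parent nodes' g
# Nodes are appended to a tape in creation order; backward() walks the
# tape in reverse, so every node's gradient is complete before its own
# bw fires.  Trainable parameters are plain (v, g) environments that
# live outside the tape — leaf consumers add into their $g directly.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_node <- function(tape, value, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- bw
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, value) ag_node(tape, value)

ag_acc <- function(nd, grad) {
  nd$g <- if (is.null(nd$g)) grad else nd$g + grad
  invisible(nd)
}

#' @keywords internal
ag_backward <- function(tape, loss, seed_grad = 1) {
  loss$g <- seed_grad
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$bw) && !is.null(nd$g)) nd$bw(nd$g)
  }
  invisible(NULL)
}

new_param <- function(dim) {
  p <- new.env(parent = emptyenv())
  p$v <- array(0, dim = dim)
  p$g <- NULL
  class(p) <- "ad_param"
  p
}

new_buffer <- function(value) {
  b <- new.env(parent = emptyenv())
  b$v <- value
  class(b) <- "ad_buffer"
  b
}

fm_dim <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# ---- broadcast helpers (layout H, W, C, N) --------------------------------

# (C, N) matrix of per-channel scalars -> full (H, W, C, N) array
expand_ch <- function(s, H, W) {
  array(rep(as.vector(s), each = H * W), dim = c(H, W, nrow(s), ncol(s)))
}

# per-channel-per-sample sums of a (H, W, C, N) array -> (C, N)
reduce_ch <- function(a) {
  d <- dim(a)
  matrix(colSums(matrix(a, d[1] * d[2])), d[3], d[4])
}

# ---- primitive ops --------------------------------------------------------

op_conv2d <- function(tape, x, w, b) {
  y <- .cpp_conv2d_fw(x$v, w$v, b$v)
  ag_node(tape, y, bw = function(g) {
    r <- .cpp_conv2d_bw(x$v, w$v, g)
    ag_acc(x, r$gx)
    ag_acc(w, r$gw)
    ag_acc(b, r$gb)
  })
}

op_relu <- function(tape, x) {
  if (is.null(dim(x$v)) || length(dim(x$v)) != 4L) {
    y <- pmax(x$v, 0)
    if (!is.null(dim(x$v))) dim(y) <- dim(x$v)
    return(ag_node(tape, y, bw = function(g) ag_acc(x, g * (x$v > 0))))
  }
  ag_node(tape, .cpp_relu_fw(x$v),
          bw = function(g) ag_acc(x, .cpp_relu_bw(x$v, g)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  if (!is.null(dim(x$v))) dim(y) <- dim(x$v)
  ag_node(tape, y, bw = function(g) ag_acc(x, g * y * (1 - y)))
}

op_add <- function(tape, a, b) {
  stopifnot(identical(dim(a$v), dim(b$v)))
  ag_node(tape, a$v + b$v, bw = function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

# x: (H, W, C, N); s: (C, N) per-channel coefficients
op_mul_channel <- function(tape, x, s) {
  ag_node(tape, .cpp_mul_channel(x$v, s$v), bw = function(g) {
    ag_acc(x, .cpp_mul_channel(g, s$v))
    ag_acc(s, .cpp_dot_channel(g, x$v))
  })
}

# x: (H, W, C, N); a: (H, W, 1, N) per-pixel coefficients
op_mul_spatial <- function(tape, x, a) {
  ag_node(tape, .cpp_mul_spatial(x$v, a$v), bw = function(g) {
    ag_acc(x, .cpp_mul_spatial(g, a$v))
    ag_acc(a, .cpp_dot_spatial(g, x$v))
  })
}

op_concat_ch <- function(tape, xs) {
  cc <- vapply(xs, function(x) fm_dim(x$v)[3], numeric(1))
  out <- .cpp_concat_ch(lapply(xs, function(x) x$v))
  ag_node(tape, out, bw = function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      ag_acc(xs[[i]], .cpp_slice_ch(g, at, as.integer(cc[i])))
      at <- at + as.integer(cc[i])
    }
  })
}

op_avgpool2 <- function(tape, x) {
  d <- fm_dim(x$v)
  ag_node(tape, .cpp_avgpool2_fw(x$v),
          bw = function(g) ag_acc(x, .cpp_avgpool2_bw(g, d[1], d[2])))
}

op_resize_bilinear <- function(tape, x, Ho, Wo) {
  d <- fm_dim(x$v)
  if (d[1] == Ho && d[2] == Wo) return(x)
  ag_node(tape, .cpp_resize_bilinear_fw(x$v, Ho, Wo),
          bw = function(g) ag_acc(x, .cpp_resize_bilinear_bw(g, d[1], d[2])))
}

# global average pooling -> (C, N)
op_gap <- function(tape, x) {
  d <- fm_dim(x$v)
  HW <- d[1] * d[2]
  v <- reduce_ch(x$v) / HW
  ag_node(tape, v, bw = function(g) {
    ag_acc(x, expand_ch(g, d[1], d[2]) / HW)
  })
}

# global max pooling -> (C, N); gradient routed to the argmax pixel
op_gmp <- function(tape, x) {
  d <- fm_dim(x$v)
  HW <- d[1] * d[2]
  r <- .cpp_gmp_fw(x$v)
  ag_node(tape, r$value, bw = function(g) {
    gx <- array(0, dim = d)
    for (n in seq_len(d[4])) {
      for (c in seq_len(d[3])) {
        flat <- r$idx[c, n] + 1L + (c - 1L) * HW + (n - 1L) * d[3] * HW
        gx[flat] <- gx[flat] + g[c, n]
      }
    }
    ag_acc(x, gx)
  })
}

# fully connected layer on (Cin, N) matrices: y = W x + b
op_linear <- function(tape, W, x, b) {
  v <- W$v %*% x$v + as.vector(b$v)
  ag_node(tape, v, bw = function(g) {
    ag_acc(W, g %*% t(x$v))
    ag_acc(x, t(W$v) %*% g)
    ag_acc(b, rowSums(g))
  })
}

# Batch normalization over (H, W, N) per channel.
# state: buffer env with $v = list(mean, var); standard running-average
# update with the given momentum, unbiased variance stored.
op_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- fm_dim(x$v)
  m <- d[1] * d[2] * d[4]
  r <- .cpp_bn_fw(x$v, as.vector(gamma$v), as.vector(beta$v),
                  state$v$mean, state$v$var, training, eps)
  if (training && m > 1) {
    state$v$mean <- (1 - momentum) * state$v$mean + momentum * r$mean
    state$v$var <- (1 - momentum) * state$v$var +
      momentum * r$var * m / (m - 1)
  }
  ag_node(tape, r$y, bw = function(g) {
    bk <- .cpp_bn_bw(r$xhat, g, as.vector(gamma$v), r$inv_std, training)
    ag_acc(x, bk$gx)
    ag_acc(gamma, bk$ggamma)
    ag_acc(beta, bk$gbeta)
  })
}

op_sum_all <- function(tape, x) {
  ag_node(tape, sum(x$v), bw = function(g) {
    ag_acc(x, array(g, dim = dim(x$v)))
  })
}

# Mean per-pixel softmax cross-entropy for two-class logits.
# logits: (H, W, K, N); labels: (H, W, N) integer classes in 0..K-1
op_softmax_xent <- function(tape, logits, labels) {
  d <- fm_dim(logits$v)
  K <- d[3]
  HW <- d[1] * d[2]
  lm <- matrix(aperm(logits$v, c(3, 1, 2, 4)), K)  # K x (HW*N)
  cmax <- lm[1, ]
  for (k in seq_len(K)[-1]) cmax <- pmax(cmax, lm[k, ])
  lm <- sweep(lm, 2, cmax)
  el <- exp(lm)
  p <- sweep(el, 2, colSums(el), "/")
  lab <- as.integer(labels) + 1L
  npix <- HW * d[4]
  picked <- p[cbind(lab, seq_len(npix))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ag_node(tape, loss, bw = function(g) {
    gm <- p
    gm[cbind(lab, seq_len(npix))] <- gm[cbind(lab, seq_len(npix))] - 1
    gm <- gm * (g / npix)
    gl <- aperm(array(gm, dim = c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
    ag_acc(logits, gl)
  })
}
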