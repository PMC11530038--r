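# Independent brute-force oracles and small utilities shared by the
# tests.  These deliberately avoid the package's vectorized/GEMM code
# paths: everything is scalar loops and base-R arithmetic.

rand_fm <- function(h, w, c, n, sd = 1) {
  array(rnorm(h * w * c * n, sd = sd), dim = c(h, w, c, n))
}

sigmoid_ref <- function(z) 1 / (1 + exp(-z))

# direct stride-1 same-padding convolution, scalar loops
conv2d_ref <- function(x, w, b) {
  d <- dim(x)
  kd <- dim(w)
  kh <- kd[1]; kw <- kd[2]; cin <- kd[3]; cout <- kd[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  y <- array(0, dim = c(d[1], d[2], cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- b[co]
      for (ci in seq_len(cin)) for (a in seq_len(kh)) for (bb in seq_len(kw)) {
        ii <- i + a - 1 - ph; jj <- j + bb - 1 - pw
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
          s <- s + x[ii, jj, ci, n] * w[a, bb, ci, co]
        }
      }
      y[i, j, co, n] <- s
    }
  }
  y
}

# attention gate evaluated pixel by pixel from the additive-attention
# formula: alpha = sigmoid(psi' relu(Wx'x + Wg'g + b_g) + b_psi)
attention_gate_ref <- function(x, g, p) {
  d <- dim(x)
  fint <- p$f_int
  alpha <- array(0, dim = c(d[1], d[2], 1, d[4]))
  gated <- array(0, dim = d)
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    xv <- x[i, j, , n]
    gv <- g[i, j, , n]
    s <- numeric(fint)
    for (f in seq_len(fint)) {
      s[f] <- sum(p$wx$v[1, 1, , f] * xv) + sum(p$wg$v[1, 1, , f] * gv) +
        p$bg$v[f]
    }
    z <- sum(p$psi$v[1, 1, , 1] * pmax(s, 0)) + p$bpsi$v[1]
    al <- sigmoid_ref(z)
    alpha[i, j, 1, n] <- al
    gated[i, j, , n] <- al * xv
  }
  list(gated = gated, alpha = alpha)
}

# channel attention by explicit per-channel pooling and matrix MLP
channel_attention_ref <- function(x, p) {
  d <- dim(x)
  y <- array(0, dim = d)
  for (n in seq_len(d[4])) {
    avg <- vapply(seq_len(d[3]), function(c) mean(x[, , c, n]), 0)
    mx <- vapply(seq_len(d[3]), function(c) max(x[, , c, n]), 0)
    mlp <- function(v) {
      h <- pmax(as.vector(p$fc1$W$v %*% v + as.vector(p$fc1$b$v)), 0)
      as.vector(p$fc2$W$v %*% h + as.vector(p$fc2$b$v))
    }
    beta <- sigmoid_ref(mlp(avg) + mlp(mx))
    for (c in seq_len(d[3])) {
      y[, , c, n] <- x[, , c, n] * beta[c] + x[, , c, n]
    }
  }
  y
}

# bilinear resize with half-pixel centers, scalar loops
resize_bilinear_ref <- function(x, ho, wo) {
  d <- dim(x)
  y <- array(0, dim = c(ho, wo, d[3], d[4]))
  src <- function(i, out, inn) {
    s <- (i - 0.5) * inn / out - 0.5
    s <- min(max(s, 0), inn - 1)
    lo <- min(floor(s), inn - 1)
    list(lo = lo + 1, hi = min(lo + 1, inn - 1) + 1, w = s - lo)
  }
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      a <- src(i, ho, d[1]); b <- src(j, wo, d[2])
      top <- (1 - b$w) * x[a$lo, b$lo, c, n] + b$w * x[a$lo, b$hi, c, n]
      bot <- (1 - b$w) * x[a$hi, b$lo, c, n] + b$w * x[a$hi, b$hi, c, n]
      y[i, j, c, n] <- (1 - a$w) * top + a$w * bot
    }
  }
  y
}

# scale attention composed step by step from the tested primitives
scale_attention_ref <- function(pyramid, hw, p) {
  comp <- lapply(1:4, function(k) {
    z <- resize_bilinear_ref(pyramid[[k]], hw, hw)
    conv2d_ref(z, p$compress[[k]]$w$v, p$compress[[k]]$b$v)
  })
  d <- dim(comp[[1]])
  FF <- array(0, dim = c(d[1], d[2], 16, d[4]))
  for (k in 1:4) FF[, , (4 * k - 3):(4 * k), ] <- comp[[k]]
  mlp <- function(v) {
    h <- pmax(as.vector(p$fc1$W$v %*% v + as.vector(p$fc1$b$v)), 0)
    as.vector(p$fc2$W$v %*% h + as.vector(p$fc2$b$v))
  }
  out <- array(0, dim = dim(FF))
  for (n in seq_len(d[4])) {
    avg <- vapply(1:16, function(c) mean(FF[, , c, n]), 0)
    mx <- vapply(1:16, function(c) max(FF[, , c, n]), 0)
    gamma <- sigmoid_ref(mlp(avg) + mlp(mx))        # length 4
    Fg <- FF[, , , n, drop = FALSE]
    for (c in 1:16) Fg[, , c, 1] <- Fg[, , c, 1] * gamma[ceiling(c / 4)]
    h1 <- pmax(conv2d_ref(Fg, p$sp1$w$v, p$sp1$b$v), 0)
    gsp <- sigmoid_ref(conv2d_ref(h1, p$sp2$w$v, p$sp2$b$v))
    for (c in 1:16) {
      out[, , c, n] <- FF[, , c, n] + Fg[, , c, 1] +
        Fg[, , c, 1] * gsp[, , 1, 1]
    }
  }
  out
}

# central finite-difference gradient of f wrt param env p
fd_grad <- function(f, p, h = 1e-5) {
  g <- array(0, dim = if (is.null(dim(p$v))) length(p$v) else dim(p$v))
  for (i in seq_along(p$v)) {
    old <- p$v[i]
    p$v[i] <- old + h; up <- f()
    p$v[i] <- old - h; dn <- f()
    p$v[i] <- old
    g[i] <- (up - dn) / (2 * h)
  }
  g
}

# 4-connected component count of a binary matrix (BFS flood fill)
n_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cnt <- 0L
  for (i0 in seq_len(nrow(m))) for (j0 in seq_len(ncol(m))) {
    if (m[i0, j0] == 1 && lab[i0, j0] == 0L) {
      cnt <- cnt + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- cnt
      while (length(queue) > 0) {
        q <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- q[1] + d[1]; jj <- q[2] + d[2]
          if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
              m[ii, jj] == 1 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cnt
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  cnt
}

# random confusion-count tuples for metric property tests
rand_counts <- function(n, max_count = 500L) {
  lapply(seq_len(n), function(i) {
    structure(list(tp = sample(0:max_count, 1), fp = sample(0:max_count, 1),
                   fn = sample(0:max_count, 1), tn = sample(0:max_count, 1)),
              class = "confusion_counts")
  })
}

tiny_config <- function(...) {
  model_config(base_channels = 4L, growth_rate = 3L,
               block_layers = c(1L, 1L, 1L, 1L), reduction_r = 2L,
               decoder_channels = c(8L, 6L, 5L, 4L), la_reduction = 2L,
               la_mid = 3L, ...)
}
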