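# The three attention mechanisms used by the network:
#  * additive attention gate (AG): per-pixel coefficient alpha in (0,1)
#    from a skip feature x and a gating feature g,
#    alpha = sigmoid(psi' relu(Wx'x + Wg'g + b_g) + b_psi), output alpha*x
#  * channel attention (CA): per-channel coefficient beta in [0,1]^C from
#    global average + max pooling through a shared 2-layer MLP,
#    output x*beta + x (residual)
#  * scale attention (LA): decoder pyramid resized to full resolution,
#    each level compressed to 4 channels, concatenated into a 16-channel
#    hybrid map F; a per-scale coefficient gamma (4 values) and a
#    per-pixel coefficient gamma* combine as F + F*gamma + F*gamma*gamma*

#' Feature map helpers
#'
#' Feature maps are dense rank-4 arrays with `dim = c(H, W, C, N)`
#' (height, width, channel, batch) — the spatial index runs fastest in
#' R's column-major storage, which keeps the BLAS-backed convolution
#' kernels copy-free.
#'
#' @param x a numeric array; a bare `H x W` matrix is promoted to
#'   `c(H, W, 1, 1)`.
#' @return the validated rank-4 array
#' @export
as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) {
    stop("a feature map must be a rank-4 array (H, W, C, N)")
  }
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  x
}

# ---- attention gate -------------------------------------------------------

#' Attention gate parameters
#'
#' @param c_x channels of the skip (encoder) feature
#' @param c_g channels of the gating (decoder/upsampled) feature
#' @param f_int intermediate channels; default `max(c_x %/% 2, 1)`
#' @return an `ad_module` holding the 1x1 projections `wx`, `wg` (with
#'   gate bias), and the scoring projection `psi` (with bias)
#' @export
attention_gate_params <- function(c_x, c_g, f_int = max(c_x %/% 2L, 1L)) {
  stopifnot(f_int >= 1L)
  m <- new_module("ag",
                  wx = new_param(c(1L, 1L, c_x, f_int)),
                  wg = new_param(c(1L, 1L, c_g, f_int)),
                  bg = new_param(f_int),
                  psi = new_param(c(1L, 1L, f_int, 1L)),
                  bpsi = new_param(1L),
                  c_x = c_x, c_g = c_g, f_int = f_int)
  init_module(m)
  m
}

fwd_attention_gate <- function(tape, m, x, g) {
  dx <- fm_dim(x$v)
  dg <- fm_dim(g$v)
  if (dx[4] != dg[4]) stop("attention_gate: batch sizes differ")
  g <- op_resize_bilinear(tape, g, dx[1], dx[2])
  zx <- op_conv2d(tape, x, m$wx, zero_bias(m$f_int))
  zg <- op_conv2d(tape, g, m$wg, m$bg)
  s <- op_relu(tape, op_add(tape, zx, zg))
  score <- op_conv2d(tape, s, m$psi, m$bpsi)
  alpha <- op_sigmoid(tape, score)
  gated <- op_mul_spatial(tape, x, alpha)
  list(gated = gated, alpha = alpha)
}

#' Additive attention gate
#'
#' Computes the gating coefficient
#' `alpha = sigmoid(psi' relu(Wx'x + Wg'g + b_g) + b_psi)` at the grid of
#' `x` (a coarser `g` is bilinearly resized first) and returns `alpha * x`.
#'
#' @param x skip feature map `(H, W, C_x, N)`
#' @param g gating feature map `(H', W', C_g, N)`
#' @param p parameters from [attention_gate_params()]
#' @return list with `gated` (same shape as `x`) and `alpha`
#'   (`(H, W, 1, N)`, values in (0,1))
#' @export
attention_gate <- function(x, g, p) {
  x <- as_feature_map(x)
  g <- as_feature_map(g)
  tape <- ag_tape()
  r <- fwd_attention_gate(tape, p, ag_leaf(tape, x), ag_leaf(tape, g))
  list(gated = r$gated$v, alpha = r$alpha$v)
}

# ---- channel attention ----------------------------------------------------

#' Channel attention parameters
#'
#' The two-layer perceptron (`C -> max(C/r, 1) -> C`) is shared between
#' the average-pool and max-pool paths.
#'
#' @param c number of channels
#' @param r reduction ratio (default 16, clipped so the bottleneck keeps
#'   at least one unit)
#' @export
channel_attention_params <- function(c, r = 16L) {
  h <- max(c %/% r, 1L)
  m <- new_module("ca",
                  fc1 = nn_linear(c, h),
                  fc2 = nn_linear(h, c),
                  c = c, r = r, hidden = h)
  init_module(m)
  m
}

# shared-MLP channel coefficient beta as a (C, N) node
fwd_ca_beta <- function(tape, m, x) {
  mlp <- function(v) {
    fwd_linear(tape, m$fc2, op_relu(tape, fwd_linear(tape, m$fc1, v)))
  }
  a <- mlp(op_gap(tape, x))
  b <- mlp(op_gmp(tape, x))
  op_sigmoid(tape, op_add(tape, a, b))
}

fwd_channel_attention <- function(tape, m, x) {
  d <- fm_dim(x$v)
  if (d[3] != m$c) {
    stop(sprintf("channel_attention: input has %d channels, params expect %d",
                 d[3], m$c))
  }
  beta <- fwd_ca_beta(tape, m, x)
  op_add(tape, op_mul_channel(tape, x, beta), x)
}

#' Channel attention with dual pooling and residual connection
#'
#' `beta = sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))` per channel, and
#' the output is `x * beta + x`.
#'
#' @param x feature map `(H, W, C, N)`
#' @param p parameters from [channel_attention_params()]
#' @return feature map of the same shape
#' @export
channel_attention <- function(x, p) {
  x <- as_feature_map(x)
  tape <- ag_tape()
  fwd_channel_attention(tape, p, ag_leaf(tape, x))$v
}

# ---- scale attention ------------------------------------------------------

#' Scale attention parameters
#'
#' @param in_channels integer vector: channels of the four decoder
#'   outputs, deepest scale first
#' @param r reduction ratio of the channel branch MLP over the 16-channel
#'   hybrid map (default 4)
#' @param mid hidden width of the spatial branch (3x3 conv -> ReLU ->
#'   1x1 conv -> sigmoid; default 8)
#' @export
scale_attention_params <- function(in_channels, r = 4L, mid = 8L) {
  if (length(in_channels) != 4L) stop("scale attention expects 4 pyramid levels")
  m <- new_module("la",
                  compress = lapply(in_channels, function(ci) nn_conv(ci, 4L, k = 1L)),
                  fc1 = nn_linear(16L, max(16L %/% r, 1L)),
                  fc2 = nn_linear(max(16L %/% r, 1L), 4L),
                  sp1 = nn_conv(16L, mid, k = 3L),
                  sp2 = nn_conv(mid, 1L, k = 1L),
                  in_channels = as.integer(in_channels), r = r, mid = mid)
  init_module(m)
  m
}

# expand a per-scale (4, N) coefficient to the 16 hybrid channels
op_expand_scale <- function(tape, s, per = 4L) {
  idx <- rep(seq_len(nrow(s$v)), each = per)
  ag_node(tape, s$v[idx, , drop = FALSE], bw = function(g) {
    gs <- rowsum(g, group = idx, reorder = TRUE)
    dimnames(gs) <- NULL
    ag_acc(s, gs)
  })
}

fwd_scale_attention <- function(tape, m, pyramid, target_hw) {
  if (length(pyramid) != 4L) stop("scale attention expects 4 pyramid levels")
  H <- target_hw[1]
  W <- if (length(target_hw) > 1L) target_hw[2] else target_hw[1]
  comp <- vector("list", 4L)
  for (i in 1:4) {
    z <- op_resize_bilinear(tape, pyramid[[i]], H, W)
    comp[[i]] <- fwd_conv(tape, m$compress[[i]], z)
  }
  FF <- op_concat_ch(tape, comp)

  mlp <- function(v) {
    fwd_linear(tape, m$fc2, op_relu(tape, fwd_linear(tape, m$fc1, v)))
  }
  gamma4 <- op_sigmoid(tape, op_add(tape, mlp(op_gap(tape, FF)),
                                    mlp(op_gmp(tape, FF))))
  gamma16 <- op_expand_scale(tape, gamma4)
  Fg <- op_mul_channel(tape, FF, gamma16)

  spat <- op_sigmoid(tape, fwd_conv(tape, m$sp2,
                                    op_relu(tape, fwd_conv(tape, m$sp1, Fg))))
  out <- op_add(tape, op_add(tape, FF, Fg), op_mul_spatial(tape, Fg, spat))
  list(out = out, F = FF, gamma = gamma4, gamma_sp = spat)
}

#' Scale attention over a four-level decoder pyramid
#'
#' Each level is bilinearly resized to `target_hw`, compressed to 4
#' channels by its own 1x1 convolution and concatenated into the
#' 16-channel hybrid map `F`.  A channel branch (dual pooling + shared
#' MLP) yields the per-scale coefficient `gamma` (4 values in \[0,1\]),
#' a spatial branch applied to `F * gamma` yields the per-pixel
#' coefficient `gamma*`, and the output is
#' `F + F*gamma + F*gamma*gamma*`.
#'
#' @param pyramid list of four feature maps, deepest scale first
#' @param target_hw target spatial size (scalar or `c(H, W)`)
#' @param p parameters from [scale_attention_params()]
#' @return 16-channel feature map at `target_hw`
#' @export
scale_attention <- function(pyramid, target_hw, p) {
  if (!is.list(pyramid) || length(pyramid) != 4L) {
    stop("scale attention expects a list of 4 pyramid levels")
  }
  pyramid <- lapply(pyramid, as_feature_map)
  tape <- ag_tape()
  nodes <- lapply(pyramid, function(a) ag_leaf(tape, a))
  fwd_scale_attention(tape, p, nodes, target_hw)$out$v
}
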