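# Densely connected encoder-decoder segmentation network.
#
# Encoder: stem conv, then four dense blocks (BN -> ReLU -> 3x3 conv
# layers, each consuming the concatenation of the block input and all
# previous layer outputs) separated by transitions (1x1 compression conv
# + 2x2 average pooling).  A fifth dense block forms the bottleneck.
# Decoder: four levels; each bilinearly upsamples the deep feature,
# gates the encoder skip with an attention gate, concatenates, applies
# channel attention and fuses with a 3x3 conv.  The four decoder outputs
# feed the scale attention module, and a final 1x1 conv produces
# two-class logits at input resolution.

#' Model configuration
#'
#' All architecture hyperparameters in one list.  The defaults keep a
#' CPU-trainable footprint; every field can be overridden.
#'
#' @param in_channels input image channels (1 = grayscale)
#' @param n_classes output classes (2 = background/lesion)
#' @param base_channels stem convolution width
#' @param growth_rate channels added by every dense layer
#' @param block_layers integer vector of length 4: dense layers per
#'   encoder block (the bottleneck block reuses the last entry)
#' @param compression transition compression factor in (0, 1]
#' @param reduction_r channel-attention reduction ratio
#' @param decoder_channels integer vector of length 4, deepest level
#'   first
#' @param la_reduction,la_mid scale-attention channel-branch reduction
#'   and spatial-branch hidden width
#' @return a `model_config` list
#' @export
model_config <- function(in_channels = 1L, n_classes = 2L,
                         base_channels = 32L, growth_rate = 16L,
                         block_layers = c(4L, 4L, 4L, 4L),
                         compression = 0.5, reduction_r = 16L,
                         decoder_channels = c(128L, 64L, 32L, 16L),
                         la_reduction = 4L, la_mid = 8L) {
  cfg <- list(in_channels = as.integer(in_channels),
              n_classes = as.integer(n_classes),
              base_channels = as.integer(base_channels),
              growth_rate = as.integer(growth_rate),
              block_layers = as.integer(block_layers),
              compression = compression,
              reduction_r = as.integer(reduction_r),
              decoder_channels = as.integer(decoder_channels),
              la_reduction = as.integer(la_reduction),
              la_mid = as.integer(la_mid))
  if (length(cfg$block_layers) != 4L) stop("block_layers must have length 4")
  if (length(cfg$decoder_channels) != 4L) {
    stop("decoder_channels must have length 4")
  }
  if (cfg$compression <= 0 || cfg$compression > 1) {
    stop("compression must lie in (0, 1]")
  }
  counts <- c(cfg$in_channels, cfg$n_classes, cfg$base_channels,
              cfg$growth_rate, cfg$block_layers, cfg$decoder_channels)
  if (any(counts < 1L)) stop("all channel/layer counts must be >= 1")
  class(cfg) <- "model_config"
  cfg
}

#' Desk-scale preset configuration
#'
#' A deliberately small variant of [model_config()] sized so that a full
#' train/evaluate cycle on 64x64 phantoms finishes in minutes on one CPU
#' core, for tests and demos.
#'
#' @param ... overrides passed to [model_config()]
#' @export
desk_config <- function(...) {
  model_config(base_channels = 8L, growth_rate = 6L,
               block_layers = c(2L, 2L, 2L, 2L),
               reduction_r = 4L,
               decoder_channels = c(24L, 16L, 12L, 8L), ...)
}

#' Channel bookkeeping for a configuration
#'
#' Computes the channel count at every junction of the network from the
#' configuration alone (no tensors executed); used to cross-check the
#' executed shapes.
#'
#' @param cfg a [model_config()]
#' @return list with `skip` (4 encoder block outputs, shallow first),
#'   `trans` (4 transition outputs), `bottleneck`, and `decoder` (4
#'   decoder outputs, deepest first)
#' @export
model_channels <- function(cfg) {
  skip <- integer(4)
  trans <- integer(4)
  c_now <- cfg$base_channels
  for (b in 1:4) {
    c_now <- c_now + cfg$block_layers[b] * cfg$growth_rate
    skip[b] <- c_now
    c_now <- as.integer(ceiling(cfg$compression * c_now))
    trans[b] <- c_now
  }
  bottleneck <- c_now + cfg$block_layers[4] * cfg$growth_rate
  list(skip = skip, trans = trans, bottleneck = bottleneck,
       decoder = cfg$decoder_channels)
}

# ---- dense connectivity ---------------------------------------------------

#' Dense layer parameters (BN -> ReLU -> 3x3 conv)
#'
#' @param c_in input channels
#' @param growth output channels added by the layer
#' @export
dense_layer_params <- function(c_in, growth) {
  m <- new_module("dense_layer",
                  bn = nn_bn(c_in),
                  conv = nn_conv(c_in, growth, k = 3L),
                  c_in = c_in, growth = growth)
  init_module(m)
  m
}

fwd_dense_layer <- function(tape, m, x, training) {
  fwd_conv(tape, m$conv, op_relu(tape, fwd_bn(tape, m$bn, x, training)))
}

#' Apply a dense layer to a feature map
#'
#' @param x feature map `(H, W, C, N)`
#' @param p parameters from [dense_layer_params()]
#' @param training use batch statistics (TRUE) or running averages
#' @return feature map with `growth` channels, same spatial size
#' @export
dense_layer <- function(x, p, training = TRUE) {
  x <- as_feature_map(x)
  if (dim(x)[3] != p$c_in) {
    stop(sprintf("dense_layer: input has %d channels, params expect %d",
                 dim(x)[3], p$c_in))
  }
  tape <- ag_tape()
  fwd_dense_layer(tape, p, ag_leaf(tape, x), training)$v
}

#' Dense block parameters
#'
#' Layer `l` consumes the concatenation of the block input and all
#' previous layer outputs, so its input width is
#' `c_in + (l - 1) * growth`.
#'
#' @param c_in block input channels
#' @param n_layers number of dense layers (0 = identity block)
#' @param growth growth rate
#' @export
dense_block_params <- function(c_in, n_layers, growth) {
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    layers[[l]] <- dense_layer_params(c_in + (l - 1L) * growth, growth)
  }
  new_module("dense_block", layers = layers,
             c_in = c_in, n_layers = n_layers, growth = growth,
             c_out = c_in + n_layers * growth)
}

fwd_dense_block <- function(tape, m, x, training) {
  acc <- x
  for (l in seq_len(m$n_layers)) {
    y <- fwd_dense_layer(tape, m$layers[[l]], acc, training)
    acc <- op_concat_ch(tape, list(acc, y))
  }
  acc
}

#' Apply a dense block
#'
#' @inheritParams dense_layer
#' @param p parameters from [dense_block_params()]
#' @export
dense_block <- function(x, p, training = TRUE) {
  x <- as_feature_map(x)
  tape <- ag_tape()
  fwd_dense_block(tape, p, ag_leaf(tape, x), training)$v
}

#' Transition parameters (1x1 compression conv + 2x2 average pooling)
#'
#' @param c_in input channels
#' @param compression factor in (0, 1]; output has
#'   `ceiling(compression * c_in)` channels.  Odd spatial dims are
#'   floor-halved by the pooling.
#' @export
transition_params <- function(c_in, compression = 0.5) {
  c_out <- as.integer(ceiling(compression * c_in))
  m <- new_module("transition",
                  conv = nn_conv(c_in, c_out, k = 1L),
                  c_in = c_in, c_out = c_out)
  init_module(m)
  m
}

fwd_transition <- function(tape, m, x) {
  op_avgpool2(tape, fwd_conv(tape, m$conv, x))
}

#' Apply a transition (downsampling) layer
#'
#' @inheritParams dense_layer
#' @param p parameters from [transition_params()]
#' @export
transition_down <- function(x, p) {
  x <- as_feature_map(x)
  tape <- ag_tape()
  fwd_transition(tape, p, ag_leaf(tape, x))$v
}

# ---- decoder --------------------------------------------------------------

#' Decoder level parameters
#'
#' One level: bilinear 2x upsampling of the deep feature + 3x3 conv,
#' attention-gating of the encoder skip (gated by the upsampled map),
#' concatenation, channel attention over the concatenation, and a 3x3
#' fusion conv (+ BN + ReLU) to `c_out` channels.
#'
#' @param c_deep channels of the deep (coarser) feature
#' @param c_skip channels of the encoder skip feature
#' @param c_out output channels of the level
#' @param r channel-attention reduction ratio
#' @export
decoder_level_params <- function(c_deep, c_skip, c_out, r = 16L) {
  m <- new_module("decoder_level",
                  up = nn_conv(c_deep, c_out, k = 3L),
                  ag = attention_gate_params(c_skip, c_out),
                  ca = channel_attention_params(c_out + c_skip, r = r),
                  fuse = nn_conv(c_out + c_skip, c_out, k = 3L),
                  fuse_bn = nn_bn(c_out),
                  c_deep = c_deep, c_skip = c_skip, c_out = c_out)
  init_module(m)
  m
}

fwd_decoder_level <- function(tape, m, deep, skip, training) {
  ds <- fm_dim(skip$v)
  up <- op_resize_bilinear(tape, deep, ds[1], ds[2])
  up <- fwd_conv(tape, m$up, up)
  gate <- fwd_attention_gate(tape, m$ag, skip, up)
  cat_ <- op_concat_ch(tape, list(up, gate$gated))
  cal <- fwd_channel_attention(tape, m$ca, cat_)
  out <- op_relu(tape, fwd_bn(tape, m$fuse_bn,
                              fwd_conv(tape, m$fuse, cal), training))
  out
}

#' Apply one decoder level
#'
#' @param deep deep feature map (half the skip's resolution)
#' @param skip encoder skip feature map
#' @param p parameters from [decoder_level_params()]
#' @param training batch-norm mode
#' @export
decoder_level <- function(deep, skip, p, training = TRUE) {
  deep <- as_feature_map(deep)
  skip <- as_feature_map(skip)
  tape <- ag_tape()
  fwd_decoder_level(tape, p, ag_leaf(tape, deep), ag_leaf(tape, skip),
                    training)$v
}

# ---- full network ---------------------------------------------------------

#' Build the segmentation network
#'
#' @param cfg a [model_config()] (or [desk_config()])
#' @return an object of class `adu_net`
#' @export
adu_net <- function(cfg = model_config()) {
  ch <- model_channels(cfg)
  enc_blocks <- vector("list", 4L)
  transitions <- vector("list", 4L)
  c_now <- cfg$base_channels
  for (b in 1:4) {
    enc_blocks[[b]] <- dense_block_params(c_now, cfg$block_layers[b],
                                          cfg$growth_rate)
    transitions[[b]] <- transition_params(ch$skip[b], cfg$compression)
    c_now <- ch$trans[b]
  }
  bottleneck <- dense_block_params(ch$trans[4], cfg$block_layers[4],
                                   cfg$growth_rate)
  dec <- cfg$decoder_channels
  deep_c <- c(ch$bottleneck, dec[1], dec[2], dec[3])
  skip_c <- rev(ch$skip)   # deepest skip first
  dec_levels <- vector("list", 4L)
  for (l in 1:4) {
    dec_levels[[l]] <- decoder_level_params(deep_c[l], skip_c[l], dec[l],
                                            r = cfg$reduction_r)
  }
  net <- new_module("adu_net",
                    stem = nn_conv(cfg$in_channels, cfg$base_channels, k = 3L),
                    enc = enc_blocks,
                    trans = transitions,
                    bottleneck = bottleneck,
                    dec = dec_levels,
                    la = scale_attention_params(dec, r = cfg$la_reduction,
                                                mid = cfg$la_mid),
                    head = nn_conv(16L, cfg$n_classes, k = 1L),
                    config = cfg)
  init_module(net)
  class(net) <- c("adu_net", class(net))
  net
}

fwd_adu_net <- function(tape, net, x, training) {
  d <- fm_dim(x$v)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop(sprintf(paste0("input spatial size %dx%d must be divisible by 16 ",
                        "(four 2x downsamplings)"), d[1], d[2]))
  }
  h <- fwd_conv(tape, net$stem, x)
  skips <- vector("list", 4L)
  for (b in 1:4) {
    h <- fwd_dense_block(tape, net$enc[[b]], h, training)
    skips[[b]] <- h
    h <- fwd_transition(tape, net$trans[[b]], h)
  }
  h <- fwd_dense_block(tape, net$bottleneck, h, training)
  pyramid <- vector("list", 4L)
  for (l in 1:4) {
    h <- fwd_decoder_level(tape, net$dec[[l]], h, skips[[5L - l]], training)
    pyramid[[l]] <- h
  }
  fused <- fwd_scale_attention(tape, net$la, pyramid, c(d[1], d[2]))$out
  fwd_conv(tape, net$head, fused)
}

#' Run the network forward
#'
#' @param net an [adu_net()]
#' @param x image batch `(H, W, in_channels, N)`; `H` and `W` must be
#'   divisible by 16
#' @param training batch-norm mode (TRUE: batch statistics + running
#'   average update; FALSE: frozen running averages)
#' @return logits `(H, W, n_classes, N)`
#' @export
net_forward <- function(net, x, training = FALSE) {
  x <- as_feature_map(x)
  tape <- ag_tape()
  fwd_adu_net(tape, net, ag_leaf(tape, x), training)$v
}

#' @export
print.adu_net <- function(x, ...) {
  np <- sum(vapply(module_params(x), function(p) length(p$v), numeric(1)))
  cfg <- x$config
  cat(sprintf(paste0("<adu_net> dense attention U-Net\n",
                     "  in=%d classes=%d base=%d growth=%d blocks=%s\n",
                     "  decoder=%s  parameters: %s\n"),
              cfg$in_channels, cfg$n_classes, cfg$base_channels,
              cfg$growth_rate, paste(cfg$block_layers, collapse = "/"),
              paste(cfg$decoder_channels, collapse = "/"),
              format(np, big.mark = ",")))
  invisible(x)
}
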