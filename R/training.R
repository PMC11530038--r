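# Training loop: Adam on mean per-pixel softmax cross-entropy, He-normal
# initialization, per-epoch evaluation on the held-out set, best model
# kept by validation Dice.  All randomness flows from one seed, so the
# full history is reproducible.

#' Training configuration
#'
#' @param batch_size minibatch size (default 8)
#' @param learning_rate Adam step size (default 1e-4)
#' @param epochs training epochs (default 200)
#' @param beta1 Adam first-moment decay ("momentum", default 0.9)
#' @param beta2,eps Adam second-moment decay and stabilizer
#' @param seed master RNG seed (init, shuffling, augmentation)
#' @param select_metric validation metric selecting the best epoch
#'   (one of dsc/jsc/ppv/sen/f1; default `"dsc"`)
#' @param augment apply random flips/rescale to training batches
#' @param p_flip,scale_prob,scale_range augmentation knobs, see
#'   [augment_pair()]
#' @param verbose print one log line per epoch
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 8L, learning_rate = 1e-4,
                         epochs = 200L, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 0L,
                         select_metric = "dsc", augment = TRUE,
                         p_flip = 0.5, scale_prob = 0.5,
                         scale_range = c(0.8, 1.25), verbose = TRUE) {
  stopifnot(batch_size >= 1L, learning_rate > 0, epochs >= 0L)
  if (!select_metric %in% c("dsc", "jsc", "ppv", "sen", "f1")) {
    stop("select_metric must be one of dsc/jsc/ppv/sen/f1")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed), select_metric = select_metric,
                 augment = isTRUE(augment), p_flip = p_flip,
                 scale_prob = scale_prob, scale_range = scale_range,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' The paper-style protocol (batch 8, learning rate 1e-4, Adam beta1 =
#' 0.9) shortened to 25 epochs for CPU-scale runs on phantoms.
#'
#' @param ... overrides passed to [train_config()]
#' @export
desk_train_config <- function(...) {
  train_config(epochs = 25L, ...)
}

#' Initialize network weights
#'
#' `"he_normal"`: convolution and linear weights drawn from
#' `normal(0, sqrt(2 / fan_in))`, biases zero, batch-norm scale 1 /
#' shift 0, running statistics reset; attention-gate projections use a
#' zero-mean normal with sd 0.02.
#'
#' @param net an [adu_net()] (modified in place — parameters are
#'   environments)
#' @param scheme only `"he_normal"` is implemented
#' @param seed optional RNG seed for determinism
#' @return the network, invisibly
#' @export
initialize_weights <- function(net, scheme = "he_normal", seed = NULL) {
  if (!identical(scheme, "he_normal")) {
    stop("unknown initialization scheme: ", scheme)
  }
  if (!is.null(seed)) set.seed(seed)
  init_module(net)
  invisible(net)
}

#' Mean per-pixel cross-entropy loss
#'
#' @param logits `(H, W, n_classes, N)` array (two channels)
#' @param mask binary mask `(H, W)` or `(H, W, N)` of class labels
#' @return scalar loss
#' @export
net_loss <- function(logits, mask) {
  logits <- as_feature_map(logits)
  d <- dim(logits)
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (!identical(as.integer(dim(mask)), as.integer(d[c(1, 2, 4)]))) {
    stop("mask dimensions do not match logits")
  }
  tape <- ag_tape()
  op_softmax_xent(tape, ag_leaf(tape, logits), mask)$v
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p$v))),
       v = lapply(params, function(p) array(0, dim = dim(p$v))),
       t = 0L)
}

adam_step <- function(params, st, lr, beta1, beta2, eps) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$g)) next
    g <- p$g
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

# ---- batching -------------------------------------------------------------

stack_batch <- function(pairs) {
  h <- nrow(pairs[[1]]$image)
  w <- ncol(pairs[[1]]$image)
  n <- length(pairs)
  x <- array(0, dim = c(h, w, 1L, n))
  y <- array(0L, dim = c(h, w, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- pairs[[i]]$image
    y[, , i] <- pairs[[i]]$mask
  }
  list(x = x, y = y)
}

# forward + loss in evaluation mode, in batches
eval_loss_and_masks <- function(net, pairs, norm, batch_size) {
  total <- 0
  masks <- vector("list", length(pairs))
  idx <- split(seq_along(pairs), ceiling(seq_along(pairs) / batch_size))
  for (b in idx) {
    bp <- lapply(pairs[b], normalize_pair, mean = norm[["mean"]],
                 std = norm[["std"]])
    bt <- stack_batch(bp)
    logits <- net_forward(net, bt$x, training = FALSE)
    total <- total + net_loss(logits, bt$y) * length(b)
    pm <- (logits[, , 2, , drop = FALSE] > logits[, , 1, , drop = FALSE]) * 1
    for (j in seq_along(b)) masks[[b[j]]] <- matrix(pm[, , 1, j], dim(pm)[1])
  }
  list(loss = total / length(pairs), masks = masks)
}

log_line <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

# ---- training loop --------------------------------------------------------

#' Train the network
#'
#' Runs Adam over minibatches of the training set; after every epoch the
#' validation set is scored with [evaluate_dataset()] and the parameters
#' achieving the best `select_metric` are kept.  Normalization
#' statistics are computed from the training split only and stored with
#' the model.
#'
#' @param net an [adu_net()]; weights are (re-)initialized with
#'   `cfg$seed` unless `init = FALSE`
#' @param train_set,val_set non-empty lists of image pairs
#' @param cfg a [train_config()]
#' @param init re-initialize weights before training (default TRUE)
#' @return list with `net` (best weights loaded), `history` (one row per
#'   epoch: epoch, train_loss, val_loss, dsc, jsc, ppv, sen, f1),
#'   `best_epoch`, and `norm` (training-set mean/std)
#' @export
train_model <- function(net, train_set, val_set, cfg = train_config(),
                        init = TRUE) {
  force(net)   # build before seeding: construction draws from the RNG
  if (length(train_set) == 0L || length(val_set) == 0L) {
    stop("train_set and val_set must be non-empty")
  }
  set.seed(cfg$seed)
  if (init) init_module(net)
  norm <- dataset_stats(train_set)
  if (!is.finite(norm[["std"]]) || norm[["std"]] <= 0) {
    norm[["std"]] <- 1
  }
  params <- module_params(net)
  st <- adam_state(params)
  hist_rows <- vector("list", cfg$epochs)
  best <- -Inf
  best_epoch <- 0L
  best_params <- NULL

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(length(train_set))
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      bp <- train_set[b]
      if (cfg$augment) {
        bp <- lapply(bp, augment_pair, p_flip = cfg$p_flip,
                     scale_prob = cfg$scale_prob,
                     scale_range = cfg$scale_range)
      }
      bp <- lapply(bp, normalize_pair, mean = norm[["mean"]],
                   std = norm[["std"]])
      bt <- stack_batch(bp)
      tape <- ag_tape()
      logits <- fwd_adu_net(tape, net, ag_leaf(tape, bt$x), training = TRUE)
      loss <- op_softmax_xent(tape, logits, bt$y)
      if (!is.finite(loss$v)) {
        stop(sprintf("non-finite training loss at epoch %d (loss=%g); %s",
                     epoch, loss$v,
                     "check learning rate / input scaling"))
      }
      zero_grads(params)
      ag_backward(tape, loss)
      st <- adam_step(params, st, cfg$learning_rate, cfg$beta1, cfg$beta2,
                      cfg$eps)
      ep_loss <- ep_loss + loss$v * length(b)
    }
    ep_loss <- ep_loss / length(train_set)

    ev <- eval_loss_and_masks(net, val_set, norm, cfg$batch_size)
    rep <- evaluate_dataset(Map(function(pm, p) list(pred = pm, gt = p$mask,
                                                     id = p$id),
                                ev$masks, val_set))
    mm <- rep$mean_of_each
    hist_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = ev$loss, dsc = mm[["dsc"]],
                                     jsc = mm[["jsc"]], ppv = mm[["ppv"]],
                                     sen = mm[["sen"]], f1 = mm[["f1"]])
    if (cfg$verbose) {
      log_line("epoch %3d/%d  train_loss %.4f  val_loss %.4f  dsc %.4f",
               epoch, cfg$epochs, ep_loss, ev$loss, mm[["dsc"]])
    }
    score <- mm[[cfg$select_metric]]
    if (score > best) {
      best <- score
      best_epoch <- epoch
      best_params <- lapply(params, function(p) p$v)
      best_buffers <- lapply(module_buffers(net), function(b) b$v)
    }
  }

  history <- if (cfg$epochs > 0L) do.call(rbind, hist_rows) else
    data.frame(epoch = integer(), train_loss = numeric(),
               val_loss = numeric(), dsc = numeric(), jsc = numeric(),
               ppv = numeric(), sen = numeric(), f1 = numeric())

  if (!is.null(best_params)) {
    for (nm in names(best_params)) params[[nm]]$v <- best_params[[nm]]
    bufs <- module_buffers(net)
    for (nm in names(best_buffers)) bufs[[nm]]$v <- best_buffers[[nm]]
  }
  list(net = net, history = history, best_epoch = best_epoch, norm = norm)
}

#' Predict binary masks
#'
#' Softmax over the two output channels, argmax per pixel; a tie goes to
#' the background class.
#'
#' @param object a trained [adu_net()]
#' @param images list of `H x W` matrices (or image pairs), `H` and `W`
#'   divisible by 16
#' @param norm optional `c(mean, std)` standardization (use the training
#'   statistics stored in the checkpoint)
#' @param batch_size forward batch size
#' @param ... unused
#' @return list of binary `H x W` masks
#' @export
predict.adu_net <- function(object, images, norm = NULL, batch_size = 8L,
                            ...) {
  imgs <- lapply(images, function(im) if (inherits(im, "image_pair"))
    im$image else im)
  if (!is.null(norm)) {
    imgs <- lapply(imgs, function(im) (im - norm[["mean"]]) / norm[["std"]])
  }
  masks <- vector("list", length(imgs))
  idx <- split(seq_along(imgs), ceiling(seq_along(imgs) / batch_size))
  for (b in idx) {
    h <- nrow(imgs[[b[1]]])
    w <- ncol(imgs[[b[1]]])
    x <- array(0, dim = c(h, w, 1L, length(b)))
    for (j in seq_along(b)) x[, , 1L, j] <- imgs[[b[j]]]
    logits <- net_forward(object, x, training = FALSE)
    pm <- (logits[, , 2, , drop = FALSE] > logits[, , 1, , drop = FALSE]) * 1
    for (j in seq_along(b)) masks[[b[j]]] <- matrix(pm[, , 1, j], h)
  }
  masks
}

# ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all parameter and buffer
#' values, normalization statistics and the training history; loading
#' rebuilds the network and restores the values, so a save/load round
#' trip reproduces forward outputs exactly.
#'
#' @param net an [adu_net()]
#' @param path checkpoint file (RDS)
#' @param norm,history,extra optional payloads stored alongside
#' @export
save_checkpoint <- function(net, path, norm = NULL, history = NULL,
                            extra = NULL) {
  ck <- list(format = "attdunet-checkpoint-1",
             config = unclass(net$config),
             params = lapply(module_params(net), function(p) p$v),
             buffers = lapply(module_buffers(net), function(b) b$v),
             norm = norm, history = history, extra = extra)
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: list with `net`, `norm`, `history`, `extra`
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(ck) || !identical(ck$format, "attdunet-checkpoint-1")) {
    stop("malformed checkpoint: ", path)
  }
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config), NULL)])
  net <- adu_net(cfg)
  params <- module_params(net)
  if (!setequal(names(params), names(ck$params))) {
    stop("malformed checkpoint: parameter set mismatch")
  }
  for (nm in names(ck$params)) params[[nm]]$v <- ck$params[[nm]]
  bufs <- module_buffers(net)
  for (nm in names(ck$buffers)) bufs[[nm]]$v <- ck$buffers[[nm]]
  list(net = net, norm = ck$norm, history = ck$history, extra = ck$extra)
}
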