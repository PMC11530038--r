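# Parameterized layers ("modules").  A module is a list with class
# "ad_module" holding ad_param / ad_buffer environments and possibly
# nested modules; module_params()/module_buffers() walk the structure
# recursively so optimizers and checkpoints see a flat named list.

new_module <- function(kind, ...) {
  m <- list(...)
  m$kind <- kind
  class(m) <- "ad_module"
  m
}

#' Collect trainable parameters of a module tree
#'
#' @param m an `ad_module`
#' @return named flat list of parameter environments (`$v` value, `$g`
#'   gradient), names joined with `.` along the nesting path.
#' @export
module_params <- function(m) {
  out <- list()
  walk <- function(x, prefix) {
    if (inherits(x, "ad_param")) {
      out[[prefix]] <<- x
    } else if (inherits(x, "ad_module") || (is.list(x) && !inherits(x, "ad_buffer"))) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        if (is.list(x[[i]]) || inherits(x[[i]], c("ad_param", "ad_buffer"))) {
          walk(x[[i]], paste(prefix, nm, sep = "."))
        }
      }
    }
  }
  walk(m, "root")
  out
}

#' @rdname module_params
#' @export
module_buffers <- function(m) {
  out <- list()
  walk <- function(x, prefix) {
    if (inherits(x, "ad_buffer")) {
      out[[prefix]] <<- x
    } else if (is.list(x) && !inherits(x, "ad_param")) {
      nms <- names(x)
      for (i in seq_along(x)) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        if (is.list(x[[i]]) || inherits(x[[i]], c("ad_param", "ad_buffer"))) {
          walk(x[[i]], paste(prefix, nm, sep = "."))
        }
      }
    }
  }
  walk(m, "root")
  out
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- elementary layers ----------------------------------------------------

nn_conv <- function(c_in, c_out, k = 3L) {
  new_module("conv",
             w = new_param(c(k, k, c_in, c_out)),
             b = new_param(c_out),
             c_in = c_in, c_out = c_out, k = k)
}

fwd_conv <- function(tape, m, x) op_conv2d(tape, x, m$w, m$b)

nn_bn <- function(c) {
  m <- new_module("bn",
                  gamma = new_param(c),
                  beta = new_param(c),
                  state = new_buffer(list(mean = rep(0, c), var = rep(1, c))),
                  c = c)
  m$gamma$v[] <- 1
  m
}

fwd_bn <- function(tape, m, x, training) {
  op_batchnorm(tape, x, m$gamma, m$beta, m$state, training)
}

nn_linear <- function(c_in, c_out) {
  new_module("linear",
             W = new_param(c(c_out, c_in)),
             b = new_param(c_out),
             c_in = c_in, c_out = c_out)
}

fwd_linear <- function(tape, m, x) op_linear(tape, m$W, x, m$b)

# ---- weight initialization ------------------------------------------------

# He-normal: sd = sqrt(2 / fan_in); attention-gate projections instead
# use a plain zero-mean normal with sd 0.02; biases zero, BN scale 1.
init_module <- function(m) {
  init_param <- function(p, nm, in_ag) {
    d <- dim(p$v)
    if (length(d) == 4L) {            # conv kernel (kh, kw, cin, cout)
      sd <- if (in_ag) 0.02 else sqrt(2 / (d[1] * d[2] * d[3]))
      p$v[] <- stats::rnorm(length(p$v), 0, sd)
    } else if (length(d) == 2L) {     # linear (cout, cin)
      sd <- if (in_ag) 0.02 else sqrt(2 / d[2])
      p$v[] <- stats::rnorm(length(p$v), 0, sd)
    } else {                          # bias / BN vector
      if (identical(nm, "gamma")) p$v[] <- 1 else p$v[] <- 0
    }
  }
  rec <- function(x, in_ag) {
    if (inherits(x, "ad_module")) in_ag <- in_ag || identical(x$kind, "ag")
    nms <- names(x)
    for (i in seq_along(x)) {
      el <- x[[i]]
      nm <- if (!is.null(nms)) nms[i] else ""
      if (inherits(el, "ad_param")) {
        init_param(el, nm, in_ag)
      } else if (inherits(el, "ad_buffer")) {
        if (is.list(el$v) && all(c("mean", "var") %in% names(el$v))) {
          el$v$mean[] <- 0
          el$v$var[] <- 1
        }
      } else if (is.list(el)) {
        rec(el, in_ag)
      }
    }
  }
  rec(m, FALSE)
  invisible(m)
}

# shared immutable zero-bias helper for bias-free convolutions; not an
# ad_param, so optimizers and checkpoints never see it
zero_bias <- function(c_out) {
  e <- new.env(parent = emptyenv())
  e$v <- rep(0, c_out)
  e$g <- NULL
  e
}
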