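# Pixel-overlap evaluation metrics for binary segmentation masks.
#
# Everything derives from the four confusion counts TP/FP/FN/TN.  When
# tp + fp + fn == 0 (predicted and true masks both empty) all metrics
# return 1 by convention: two raters that agree there is no lesion get a
# perfect score, and the 0/0 forms never arise.

#' Confusion counts between two binary masks
#'
#' @param pred predicted binary mask (matrix or array of 0/1)
#' @param gt ground-truth binary mask, same dimensions
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`
#' @examples
#' confusion_counts(matrix(c(1, 0, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop(sprintf("mask dimensions differ: %s vs %s",
                 paste(dim(pred), collapse = "x"),
                 paste(dim(gt), collapse = "x")))
  }
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("masks must contain only values 0 and 1")
  }
  p <- as.logical(pred)
  g <- as.logical(gt)
  out <- list(tp = sum(p & g), fp = sum(p & !g),
              fn = sum(!p & g), tn = sum(!p & !g))
  class(out) <- "confusion_counts"
  out
}

.empty_fg <- function(c) (c$tp + c$fp + c$fn) == 0

#' Segmentation metrics from confusion counts
#'
#' * `dice(c)`: 2TP / (2TP + FP + FN)
#' * `jaccard(c)`: TP / (TP + FP + FN)
#' * `ppv(c)`: TP / (TP + FP)
#' * `sensitivity(c)`: TP / (TP + FN)
#' * `f1(c)`: 2 PPV SEN / (PPV + SEN)
#'
#' All return 1 when both masks are empty; `ppv`/`sensitivity`/`f1`
#' return 0 when their denominator is zero but foreground exists
#' somewhere.
#'
#' @param c a [confusion_counts()] object (or any list with tp/fp/fn/tn)
#' @return a value in \[0, 1\]
#' @export
dice <- function(c) {
  if (.empty_fg(c)) return(1)
  2 * c$tp / (2 * c$tp + c$fp + c$fn)
}

#' @rdname dice
#' @export
jaccard <- function(c) {
  if (.empty_fg(c)) return(1)
  c$tp / (c$tp + c$fp + c$fn)
}

#' @rdname dice
#' @export
ppv <- function(c) {
  if (.empty_fg(c)) return(1)
  if (c$tp + c$fp == 0) return(0)
  c$tp / (c$tp + c$fp)
}

#' @rdname dice
#' @export
sensitivity <- function(c) {
  if (.empty_fg(c)) return(1)
  if (c$tp + c$fn == 0) return(0)
  c$tp / (c$tp + c$fn)
}

#' @rdname dice
#' @export
f1 <- function(c) {
  if (.empty_fg(c)) return(1)
  p <- ppv(c)
  s <- sensitivity(c)
  if (p + s == 0) return(0)
  2 * p * s / (p + s)
}

all_metrics <- function(c) {
  c(dsc = dice(c), jsc = jaccard(c), ppv = ppv(c),
    sen = sensitivity(c), f1 = f1(c))
}

#' Evaluate a set of prediction/ground-truth mask pairs
#'
#' Metrics are computed per image and then averaged arithmetically
#' (means of per-image values, not metrics of pooled counts).
#'
#' @param pairs non-empty list; each element a list/pair with the
#'   predicted mask first and the ground-truth mask second (named
#'   `pred`/`gt` or positional)
#' @return object of class `metric_report`: `per_image` (data.frame with
#'   columns image_id, dsc, jsc, ppv, sen, f1), `mean_of_each` (named
#'   numeric), `n_images`
#' @export
evaluate_dataset <- function(pairs) {
  if (!is.list(pairs) || length(pairs) == 0L) {
    stop("evaluate_dataset: need a non-empty list of (pred, gt) pairs")
  }
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    pred <- if (!is.null(pr$pred)) pr$pred else pr[[1]]
    gt <- if (!is.null(pr$gt)) pr$gt else pr[[2]]
    id <- if (!is.null(pr$id)) pr$id else sprintf("img%04d", i)
    m <- all_metrics(confusion_counts(pred, gt))
    data.frame(image_id = id, dsc = m["dsc"], jsc = m["jsc"], ppv = m["ppv"],
               sen = m["sen"], f1 = m["f1"], row.names = NULL)
  })
  per_image <- do.call(rbind, rows)
  out <- list(per_image = per_image,
              mean_of_each = colMeans(per_image[, -1]),
              n_images = nrow(per_image))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d image(s)\n", x$n_images))
  cat("  mean:", paste(sprintf("%s=%.4f", names(x$mean_of_each),
                               x$mean_of_each), collapse = "  "), "\n")
  invisible(x)
}

#' Write a metric report as CSV
#'
#' One row per image plus a final `mean` summary row.
#'
#' @param report a [evaluate_dataset()] result
#' @param path output CSV path
#' @export
write_metrics_csv <- function(report, path) {
  df <- report$per_image
  mean_row <- data.frame(image_id = "mean",
                         t(as.data.frame(report$mean_of_each)),
                         row.names = NULL)
  names(mean_row) <- names(df)
  utils::write.csv(rbind(df, mean_row), path, row.names = FALSE)
  invisible(path)
}
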