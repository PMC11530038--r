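# PNG folder datasets: images/<id>.png paired with masks/<id><suffix>.png.
# Images are loaded as [0,1] grayscale (luminance conversion for color
# input), masks binarized at 0.5.  All spatial transforms are applied to
# image and mask jointly so the pair stays pixel-aligned.

new_image_pair <- function(image, mask, id) {
  structure(list(image = image, mask = mask, id = id), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> id=%s  %dx%d  lesion area %.1f%%\n",
              x$id, nrow(x$image), ncol(x$image), 100 * mean(x$mask)))
  invisible(x)
}

read_gray_png <- function(path) {
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("unreadable PNG: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]   # gray + alpha
    }
  }
  img
}

#' Load paired image/mask PNG folders
#'
#' Every `<id>.png` under `image_dir` must have a matching
#' `<id><mask_suffix>.png` under `mask_dir`.  Color images are converted
#' to grayscale by luminance; masks are binarized at 0.5.  Pairs are
#' returned sorted by id so downstream splits are deterministic.
#'
#' @param image_dir directory of grayscale (or color) PNG images
#' @param mask_dir directory of binary PNG masks; default
#'   `file.path(dirname(image_dir), "masks")`
#' @param mask_suffix filename suffix distinguishing masks (default
#'   `"_mask"`)
#' @return list of image pairs (possibly empty)
#' @export
load_pairs <- function(image_dir,
                       mask_dir = file.path(dirname(image_dir), "masks"),
                       mask_suffix = "_mask") {
  files <- sort(list.files(image_dir, pattern = "\\.png$"))
  if (length(files) == 0L) return(list())
  ids <- sub("\\.png$", "", files)
  mask_files <- file.path(mask_dir, paste0(ids, mask_suffix, ".png"))
  missing <- ids[!file.exists(mask_files)]
  if (length(missing) > 0L) {
    stop("images without a matching mask: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)",
                                            length(missing) - 10L) else "")
  }
  pairs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    img <- read_gray_png(file.path(image_dir, files[i]))
    msk <- (read_gray_png(mask_files[i]) >= 0.5) * 1
    if (!identical(dim(img), dim(msk))) {
      stop(sprintf("image/mask size mismatch for id '%s'", ids[i]))
    }
    pairs[[i]] <- new_image_pair(img, msk, ids[i])
  }
  pairs
}

# nearest-neighbor index map with half-pixel centers
nn_index <- function(n_out, n_in) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L, 1L), n_in)
}

resize_nearest <- function(m, h, w) {
  m[nn_index(h, nrow(m)), nn_index(w, ncol(m)), drop = FALSE]
}

resize_bilinear_mat <- function(m, h, w) {
  a <- m
  dim(a) <- c(dim(m), 1L, 1L)
  out <- .cpp_resize_bilinear_fw(a, as.integer(h), as.integer(w))
  dim(out) <- c(h, w)
  out
}

#' Resize an image pair
#'
#' The image uses the requested interpolation (bilinear by default;
#' nearest-neighbor reproduces the convention of datasets delivered that
#' way); the mask always uses nearest-neighbor so it stays binary.
#'
#' @param p an image pair
#' @param size target side length, divisible by 16
#' @param image_interp `"bilinear"` or `"nearest"`
#' @return the resized pair
#' @export
resize_pair <- function(p, size, image_interp = c("bilinear", "nearest")) {
  image_interp <- match.arg(image_interp)
  size <- as.integer(size)
  if (size %% 16L != 0L) stop("target size must be divisible by 16")
  img <- if (image_interp == "bilinear") {
    resize_bilinear_mat(p$image, size, size)
  } else {
    resize_nearest(p$image, size, size)
  }
  new_image_pair(img, resize_nearest(p$mask, size, size), p$id)
}

#' Random flip / rescale augmentation
#'
#' Horizontal and vertical flips are each applied independently with
#' probability `p_flip`; with probability `scale_prob` the pair is
#' isotropically rescaled by a factor drawn uniformly from
#' `scale_range` and center-cropped / zero-padded back to its original
#' size.  Image and mask receive identical coordinate transforms.
#' Randomness comes from the current RNG state (seed with `set.seed()`
#' for reproducibility).
#'
#' @param p an image pair
#' @param p_flip per-axis flip probability in \[0, 1\]
#' @param scale_prob probability of applying the rescale
#' @param scale_range range of the isotropic scale factor
#' @return the augmented pair
#' @export
augment_pair <- function(p, p_flip = 0.5, scale_prob = 0.5,
                         scale_range = c(0.8, 1.25)) {
  if (p_flip < 0 || p_flip > 1) stop("p_flip must lie in [0, 1]")
  img <- p$image
  msk <- p$mask
  if (stats::runif(1) < p_flip) {       # horizontal (flip columns)
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (stats::runif(1) < p_flip) {       # vertical (flip rows)
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  if (scale_prob > 0 && stats::runif(1) < scale_prob) {
    s <- stats::runif(1, scale_range[1], scale_range[2])
    h <- nrow(img)
    w <- ncol(img)
    nh <- max(1L, round(h * s))
    nw <- max(1L, round(w * s))
    zi <- resize_bilinear_mat(img, nh, nw)
    zm <- resize_nearest(msk, nh, nw)
    crop_pad <- function(m, th, tw) {
      out <- matrix(0, th, tw)
      sh <- max(0L, (nrow(m) - th) %/% 2L)
      sw <- max(0L, (ncol(m) - tw) %/% 2L)
      dh <- max(0L, (th - nrow(m)) %/% 2L)
      dw <- max(0L, (tw - ncol(m)) %/% 2L)
      ch <- min(th, nrow(m))
      cw <- min(tw, ncol(m))
      out[dh + seq_len(ch), dw + seq_len(cw)] <-
        m[sh + seq_len(ch), sw + seq_len(cw)]
      out
    }
    img <- crop_pad(zi, h, w)
    msk <- crop_pad(zm, h, w)
  }
  new_image_pair(img, msk, p$id)
}

#' Standardize an image pair
#'
#' `image' = (image - mean) / std`; the mask is untouched.
#'
#' @param p an image pair
#' @param mean,std standardization constants (`std > 0`)
#' @export
normalize_pair <- function(p, mean, std) {
  if (std <= 0) stop("std must be > 0")
  new_image_pair((p$image - mean) / std, p$mask, p$id)
}

#' Pooled pixel mean and standard deviation of a dataset
#'
#' @param pairs list of image pairs
#' @return named numeric `c(mean, std)`
#' @export
dataset_stats <- function(pairs) {
  px <- unlist(lapply(pairs, function(p) as.vector(p$image)))
  c(mean = mean(px), std = stats::sd(px))
}

#' Shuffled train/test split
#'
#' @param pairs list of at least two image pairs
#' @param train_frac fraction of pairs in the training set
#' @param seed RNG seed for the shuffle
#' @return list with `train` and `test` (disjoint, exhaustive);
#'   `|train| = round(train_frac * n)`
#' @export
split_dataset <- function(pairs, train_frac = 0.8, seed = 0L) {
  n <- length(pairs)
  if (n < 2L) stop("need at least 2 pairs to split")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(train_frac * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = pairs[perm[seq_len(n_train)]],
       test = pairs[perm[(n_train + 1L):n]])
}

#' Write a split manifest CSV (columns id, subset)
#'
#' @param split a [split_dataset()] result
#' @param path output CSV path
#' @export
write_split_csv <- function(split, path) {
  df <- rbind(
    data.frame(id = vapply(split$train, `[[`, "", "id"), subset = "train"),
    data.frame(id = vapply(split$test, `[[`, "", "id"), subset = "test"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
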