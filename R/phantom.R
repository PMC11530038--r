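# Synthetic ultrasound-like phantoms: a speckled multiplicative-noise
# background containing a single darker lesion of variable size, shape
# and margin irregularity, plus the exact binary mask of the lesion.
#
# Lesion geometry is a star-convex region: an ellipse whose radius is
# modulated per angle by a smooth low-order Fourier perturbation, which
# guarantees a single connected component.  Speckle is the normalized
# squared magnitude of a Gaussian-smoothed complex Gaussian field
# (Rayleigh-like intensity, mean 1), averaged over a few independent
# "looks" as in spatial compounding; speckle_scale interpolates between
# a noise-free image (0) and the full multiplicative field (1).

#' Phantom generator specification
#'
#' @param size image side in pixels, divisible by 16
#' @param radius_range lesion base radius as a fraction of `size`,
#'   within (0, 0.45)
#' @param irregularity radial perturbation amplitude (>= 0; 0 gives an
#'   exact discretized ellipse)
#' @param lesion_contrast darkening factor of the lesion interior,
#'   in (0, 1)
#' @param speckle_scale amplitude of the multiplicative speckle
#'   (>= 0; 0 = noise-free, 1 = full compounded speckle field)
#' @param speckle_corr speckle grain correlation length in pixels (> 0)
#' @param blur_sigma final Gaussian blur in pixels (>= 0)
#' @param looks independent speckle fields averaged together (>= 1);
#'   more looks mean milder multiplicative noise
#' @param bg_level background gray level in (0, 1]
#' @param seed integer seed, or NULL to draw from the current RNG state
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(size = 64L, radius_range = c(0.12, 0.30),
                         irregularity = 0.3, lesion_contrast = 0.65,
                         speckle_scale = 0.8, speckle_corr = 1.5,
                         blur_sigma = 0.8, looks = 4L, bg_level = 0.75,
                         seed = NULL) {
  s <- list(size = as.integer(size), radius_range = radius_range,
            irregularity = irregularity, lesion_contrast = lesion_contrast,
            speckle_scale = speckle_scale, speckle_corr = speckle_corr,
            blur_sigma = blur_sigma, looks = as.integer(looks),
            bg_level = bg_level, seed = seed)
  validate_phantom_spec(s)
  class(s) <- "phantom_spec"
  s
}

validate_phantom_spec <- function(s) {
  if (s$size %% 16L != 0L || s$size < 16L) {
    stop("phantom size must be a positive multiple of 16")
  }
  if (length(s$radius_range) != 2L || any(s$radius_range <= 0) ||
      any(s$radius_range >= 0.45) || diff(s$radius_range) < 0) {
    stop("radius_range must be an increasing pair within (0, 0.45)")
  }
  if (s$irregularity < 0) stop("irregularity must be >= 0")
  if (s$lesion_contrast <= 0 || s$lesion_contrast >= 1) {
    stop("lesion_contrast must lie in (0, 1)")
  }
  if (s$speckle_scale < 0) stop("speckle_scale must be >= 0")
  if (s$speckle_corr <= 0) stop("speckle_corr must be > 0")
  if (s$blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (s$looks < 1L) stop("looks must be >= 1")
  if (s$bg_level <= 0 || s$bg_level > 1) stop("bg_level must lie in (0, 1]")
  invisible(s)
}

# Separable Gaussian blur with edge renormalization (banded row-
# stochastic smoothing matrix applied on both sides).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  smat <- function(n) {
    r <- ceiling(3 * sigma)
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K
  }
  Kh <- smat(nrow(m))
  Kw <- if (ncol(m) == nrow(m)) Kh else smat(ncol(m))
  Kh %*% m %*% t(Kw)
}

# mean-1 multi-look speckle intensity field, damped by `scale`
speckle_field <- function(h, w, scale, corr, looks) {
  if (scale <= 0) return(matrix(1, h, w))
  acc <- matrix(0, h, w)
  for (l in seq_len(looks)) {
    re <- gauss_blur(matrix(stats::rnorm(h * w), h, w), corr)
    im <- gauss_blur(matrix(stats::rnorm(h * w), h, w), corr)
    acc <- acc + re^2 + im^2
  }
  1 + scale * (acc / mean(acc) - 1)
}

#' Generate one synthetic phantom image with its lesion mask
#'
#' @param spec a [phantom_spec()]; if `spec$seed` is not NULL the RNG is
#'   seeded first, making the phantom a pure function of the spec
#' @return an image pair: list with `image` (H x W matrix in \[0, 1\]),
#'   `mask` (H x W binary matrix) and `id`; the drawn lesion geometry
#'   (center, semi-axes, orientation) is attached as attribute `"geom"`
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$size

  # lesion geometry: ellipse with smooth radial perturbation
  r_base <- stats::runif(1, spec$radius_range[1], spec$radius_range[2]) * n
  aspect <- exp(stats::runif(1, -0.4, 0.4))
  a <- r_base * aspect
  b <- r_base / aspect
  phi <- stats::runif(1, 0, pi)
  margin <- min(max(a, b) * (1 + spec$irregularity) + 2, n / 2)
  cx <- stats::runif(1, margin, n - margin)
  cy <- stats::runif(1, margin, n - margin)

  kmax <- 5L
  fc <- stats::rnorm(kmax) / seq_len(kmax)
  fs <- stats::rnorm(kmax) / seq_len(kmax)
  radial <- function(theta) {
    pert <- rep(0, length(theta))
    for (k in 2:kmax) {
      pert <- pert + fc[k] * cos(k * theta) + fs[k] * sin(k * theta)
    }
    te <- theta - phi
    re <- a * b / sqrt((b * cos(te))^2 + (a * sin(te))^2)
    re * pmax(1 + spec$irregularity * pert, 0.3)
  }

  gx <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)  # column index
  gy <- matrix(rep(seq_len(n) - 0.5, times = n), n, n) # row index
  dx <- gx - cx
  dy <- gy - cy
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  mask <- (rr <= radial(th)) * 1

  soft <- gauss_blur(mask, 1.0)
  base <- spec$bg_level * (1 - spec$lesion_contrast * soft)
  img <- base * speckle_field(n, n, spec$speckle_scale, spec$speckle_corr,
                              spec$looks)
  img <- gauss_blur(img, spec$blur_sigma)
  img <- pmin(pmax(img, 0), 1)

  out <- new_image_pair(img, mask, "phantom")
  attr(out, "geom") <- list(cx = cx, cy = cy, a = a, b = b, phi = phi,
                            r_base = r_base)
  out
}

#' Generate a list of phantom pairs in memory
#'
#' @param n number of phantoms (>= 1)
#' @param spec a [phantom_spec()]; `spec$seed` (if set) seeds the whole
#'   sequence, individual phantoms are then drawn from one RNG stream
#' @return list of image pairs with ids `phantom_0001`, ...
#' @export
generate_pairs <- function(n, spec) {
  if (n < 1L) stop("n must be >= 1")
  validate_phantom_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec_i <- spec
  spec_i$seed <- NULL
  lapply(seq_len(n), function(i) {
    p <- generate_phantom(spec_i)
    p$id <- sprintf("phantom_%04d", i)
    p
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` 8-bit grayscale PNG pairs in the folder-dataset layout
#' (`images/<id>.png`, `masks/<id>_mask.png`) plus a JSON manifest.
#'
#' @param n number of phantoms (>= 1)
#' @param spec a [phantom_spec()]; `spec$seed` seeds the whole dataset
#' @param out_dir output directory (created if missing)
#' @return invisibly, the manifest data.frame (id, file paths, lesion
#'   area fraction)
#' @export
generate_dataset <- function(n, spec, out_dir) {
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(msk_dir)) {
    stop("cannot create output directory: ", out_dir)
  }
  pairs <- generate_pairs(n, spec)
  rows <- lapply(pairs, function(p) {
    fi <- file.path(img_dir, paste0(p$id, ".png"))
    fm <- file.path(msk_dir, paste0(p$id, "_mask.png"))
    png::writePNG(p$image, fi)
    png::writePNG(p$mask, fm)
    data.frame(id = p$id, image = fi, mask = fm,
               area_fraction = mean(p$mask))
  })
  manifest <- do.call(rbind, rows)
  meta <- list(spec = unclass(spec), n = n, manifest = manifest)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
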