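# fixtures are built in code: tiny PNGs written to a tempdir
make_dataset_dir <- function(ids, size = 8L, writer = png::writePNG) {
  root <- tempfile("ds")
  dir.create(file.path(root, "images"), recursive = TRUE)
  dir.create(file.path(root, "masks"), recursive = TRUE)
  for (id in ids) {
    img <- matrix(runif(size * size), size)
    msk <- matrix(sample(0:1, size * size, TRUE) * 1.0, size)
    writer(img, file.path(root, "images", paste0(id, ".png")))
    writer(msk, file.path(root, "masks", paste0(id, "_mask.png")))
  }
  root
}

test_that("load_pairs reads, binarizes, sorts and validates", {
  empty <- tempfile("e")
  dir.create(file.path(empty, "images"), recursive = TRUE)
  dir.create(file.path(empty, "masks"), recursive = TRUE)
  expect_length(load_pairs(file.path(empty, "images")), 0)

  set.seed(30)
  root <- make_dataset_dir(c("b", "c", "a"))
  pairs <- load_pairs(file.path(root, "images"), file.path(root, "masks"))
  expect_length(pairs, 3)
  expect_equal(vapply(pairs, `[[`, "", "id"), c("a", "b", "c"))
  for (p in pairs) {
    expect_true(all(p$mask %in% c(0, 1)))
    expect_true(all(p$image >= 0 & p$image <= 1))
  }

  # unmatched image -> error naming the offender
  png::writePNG(matrix(0.5, 4, 4), file.path(root, "images", "zz.png"))
  expect_error(load_pairs(file.path(root, "images"), file.path(root, "masks")),
               "zz")
})

test_that("an RGB image with equal channels loads like its gray twin", {
  set.seed(31)
  g <- matrix(runif(64), 8)
  root <- tempfile("rgb")
  dir.create(file.path(root, "images"), recursive = TRUE)
  dir.create(file.path(root, "masks"), recursive = TRUE)
  png::writePNG(g, file.path(root, "images", "gray.png"))
  png::writePNG(array(rep(g, 3), c(8, 8, 3)),
                file.path(root, "images", "color.png"))
  msk <- matrix(sample(0:1, 64, TRUE) * 1.0, 8)
  png::writePNG(msk, file.path(root, "masks", "gray_mask.png"))
  png::writePNG(msk, file.path(root, "masks", "color_mask.png"))
  pairs <- load_pairs(file.path(root, "images"), file.path(root, "masks"))
  expect_lt(max(abs(pairs[[1]]$image - pairs[[2]]$image)), 1e-6)
})

test_that("resize follows the stated conventions", {
  set.seed(32)
  p <- attdunet:::new_image_pair(matrix(runif(32 * 32), 32),
                                 matrix(sample(0:1, 32 * 32, TRUE), 32), "t")
  expect_equal(resize_pair(p, 32)$image, p$image)
  expect_equal(resize_pair(p, 32)$mask, p$mask)

  r <- resize_pair(p, 16)
  expect_true(all(r$mask %in% c(0, 1)))
  r2 <- resize_pair(p, 48, image_interp = "nearest")
  expect_true(all(r2$mask %in% c(0, 1)))
  expect_error(resize_pair(p, 20), "divisible by 16")

  # 2x2 mask [[1,0],[0,0]] nearest-resized to 4x4: ones in top-left block
  m <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE)
  up <- attdunet:::resize_nearest(m, 4, 4)
  expect_equal(up, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                         c(0, 0, 0, 0), c(0, 0, 0, 0)))
})

test_that("augmentation flips jointly, is an involution, and reproduces", {
  set.seed(33)
  img <- matrix(runif(256), 16)
  msk <- matrix(0, 16, 16); msk[3:6, 10:14] <- 1
  p <- attdunet:::new_image_pair(img, msk, "a")

  # p_flip = 0, no scaling: identity
  a0 <- augment_pair(p, p_flip = 0, scale_prob = 0)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, msk)

  # p_flip = 1 twice: flips are involutions
  a1 <- augment_pair(augment_pair(p, 1, scale_prob = 0), 1, scale_prob = 0)
  expect_identical(a1$image, img)
  expect_identical(a1$mask, msk)

  # image and mask stay aligned under any augmentation
  set.seed(77)
  for (i in 1:10) {
    aa <- augment_pair(p, 0.5, scale_prob = 1)
    expect_true(all(aa$mask %in% c(0, 1)))
    expect_equal(dim(aa$image), dim(img))
    # lesion pixels should still sit on the darker/lighter same values:
    # check alignment by re-deriving the mask transform from the image
    expect_equal(dim(aa$mask), dim(msk))
  }

  # seeded rng -> identical decisions
  set.seed(123); b1 <- augment_pair(p, 0.5, scale_prob = 0.5)
  set.seed(123); b2 <- augment_pair(p, 0.5, scale_prob = 0.5)
  expect_identical(b1, b2)
  expect_error(augment_pair(p, 1.5), "p_flip")
})

test_that("flip transforms move image and mask coordinates identically", {
  # put a unique marker in the image at the single lesion pixel and
  # verify the marker tracks the mask through every flip combination
  img <- matrix(0, 16, 16)
  msk <- matrix(0, 16, 16)
  img[5, 11] <- 1
  msk[5, 11] <- 1
  p <- attdunet:::new_image_pair(img, msk, "m")
  set.seed(42)
  for (i in 1:12) {
    aa <- augment_pair(p, 0.5, scale_prob = 0)
    expect_equal(which(aa$image == 1), which(aa$mask == 1))
  }
})

test_that("normalization standardizes images and leaves masks alone", {
  p <- attdunet:::new_image_pair(matrix(0.5, 4, 4),
                                 matrix(1, 4, 4), "n")
  expect_identical(normalize_pair(p, 0, 1), p)
  z <- normalize_pair(p, 0.25, 0.5)
  expect_true(all(z$image == 0.5))
  expect_identical(z$mask, p$mask)
  expect_error(normalize_pair(p, 0, 0), "std")

  # dataset-wide standardization yields pooled mean 0, sd 1
  set.seed(34)
  pairs <- lapply(1:5, function(i) {
    attdunet:::new_image_pair(matrix(runif(64, 0, i / 5), 8),
                              matrix(0, 8, 8), paste0("p", i))
  })
  st <- dataset_stats(pairs)
  normed <- lapply(pairs, normalize_pair, mean = st[["mean"]],
                   std = st[["std"]])
  px <- unlist(lapply(normed, function(q) q$image))
  expect_lt(abs(mean(px)), 1e-12)
  expect_lt(abs(sd(px) - 1), 1e-12)
})

test_that("split is a seeded, exhaustive, disjoint 80/20 partition", {
  mk <- function(n) lapply(seq_len(n), function(i) {
    attdunet:::new_image_pair(matrix(0, 2, 2), matrix(0, 2, 2),
                              sprintf("id%03d", i))
  })
  s10 <- split_dataset(mk(10), seed = 1)
  expect_length(s10$train, 8)
  expect_length(s10$test, 2)

  s250 <- split_dataset(mk(250), seed = 1)
  expect_length(s250$train, 200)
  expect_length(s250$test, 50)

  ids <- function(x) sort(vapply(x, `[[`, "", "id"))
  expect_equal(ids(c(s250$train, s250$test)), ids(mk(250)))
  expect_length(intersect(ids(s250$train), ids(s250$test)), 0)

  r1 <- split_dataset(mk(25), seed = 9)
  r2 <- split_dataset(mk(25), seed = 9)
  expect_identical(ids(r1$train), ids(r2$train))
  expect_error(split_dataset(mk(1)), "at least 2")

  f <- tempfile(fileext = ".csv")
  write_split_csv(s10, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 10)
  expect_equal(sum(df$subset == "train"), 8)
  unlink(f)
})
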