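test_that("a directory-per-class tree loads with correct counts, labels and shapes", {
  skip_if_not_installed("png")
  root <- withr::local_tempdir()
  set.seed(1)
  for (cl in CELL_CLASSES) {
    dir.create(file.path(root, cl))
    for (i in 1:5)
      png::writePNG(array(runif(16 * 16 * 3), dim = c(16, 16, 3)),
                    file.path(root, cl, sprintf("%s_%d.png", cl, i)))
  }
  data <- suppressMessages(load_image_dataset(root, size = 24L))
  expect_length(data$images, 20L)
  expect_equal(as.numeric(table(data$labels)), rep(5, 4))
  expect_true(all(vapply(data$images,
                         function(im) identical(dim(im), c(24L, 24L, 3L)),
                         TRUE)))
})

test_that("grayscale sources are replicated to three channels", {
  skip_if_not_installed("png")
  root <- withr::local_tempdir()
  dir.create(file.path(root, "lymphocyte"))
  png::writePNG(matrix(runif(64), 8, 8),
                file.path(root, "lymphocyte", "gray.png"))
  data <- suppressMessages(load_image_dataset(
    root, class_subdirs = c(lymphocyte = "lymphocyte"), size = 16L))
  img <- data$images[[1]]
  expect_identical(dim(img), c(16L, 16L, 3L))
  expect_identical(img[, , 1], img[, , 2])
})

test_that("a 100x50 source resizes to the full square canvas, matching a loop oracle", {
  set.seed(2)
  src <- array(runif(100 * 50 * 3), dim = c(100, 50, 3))
  out <- resize_bilinear(src, 224, 224)
  expect_identical(dim(out), c(224L, 224L, 3L))
  # spot-check a coarse sub-grid against the independent double-loop oracle
  small <- resize_bilinear(src, 13, 17)
  expect_equal(small, resize_oracle(src, 13, 17), tolerance = 1e-10)
})

test_that("the stratified split follows the 80:20 protocol and partitions the set", {
  set.seed(3)
  imgs <- lapply(1:400, function(i) array(0.5, dim = c(4, 4, 3)))
  labs <- rep(CELL_CLASSES, each = 100)
  data <- split_train_test(labeled_image_set(imgs, labs), seed = 5)
  for (cl in CELL_CLASSES) {
    expect_identical(sum(data$split == "train" & data$labels == cl), 80L)
    expect_identical(sum(data$split == "test" & data$labels == cl), 20L)
  }
  expect_false(any(is.na(data$split)))
})

test_that("stratified proportions are correct across a class-size sweep", {
  for (n_c in c(5L, 10L, 33L, 100L)) {
    imgs <- lapply(seq_len(4 * n_c), function(i) array(0, dim = c(2, 2, 3)))
    data <- split_train_test(
      labeled_image_set(imgs, rep(CELL_CLASSES, each = n_c)), seed = 7)
    for (cl in CELL_CLASSES)
      expect_identical(sum(data$split == "train" & data$labels == cl),
                       as.integer(round(0.8 * n_c)))
  }
})

test_that("splits are seed-deterministic and vary across seeds with fixed counts", {
  imgs <- lapply(1:80, function(i) array(0, dim = c(2, 2, 3)))
  data <- labeled_image_set(imgs, rep(CELL_CLASSES, each = 20))
  a <- split_train_test(data, seed = 1)
  b <- split_train_test(data, seed = 1)
  c <- split_train_test(data, seed = 2)
  expect_identical(a$split, b$split)
  expect_false(identical(a$split, c$split))
  expect_identical(table(c$split), table(a$split))
  single <- labeled_image_set(list(array(0, c(2, 2, 3))), "monocyte")
  expect_error(split_train_test(single), "at least 2")
})

test_that("the generator produces balanced, deterministic, range-valid sets", {
  spec <- synthetic_cell_spec(canvas = 64L, seed = 99L)
  a <- generate_synthetic_cells(spec, n_per_class = 3L)
  expect_length(a$images, 12L)
  expect_equal(as.numeric(table(a$labels)), rep(3, 4))
  b <- generate_synthetic_cells(spec, n_per_class = 3L)
  expect_identical(a$images, b$images)
  for (im in a$images) {
    expect_gte(min(im), 0)
    expect_lte(max(im), 1)
  }
  # every image carries its cell's ground-truth bounding box
  expect_length(a$geometry, 12L)
  expect_true(all(vapply(a$geometry, function(b)
    b[["row_max"]] > b[["row_min"]] && b[["col_max"]] > b[["col_min"]],
    TRUE)))
})

test_that("per-class mean images are separated by a clear margin", {
  data <- synth_set_400()
  means <- lapply(CELL_CLASSES, function(cl) {
    idx <- which(data$labels == cl)
    Reduce(`+`, data$images[idx]) / length(idx)
  })
  for (i in 1:3) for (j in (i + 1):4) {
    l2 <- sqrt(sum((means[[i]] - means[[j]])^2))
    expect_gt(l2, 5)   # margin in summed-pixel L2 units on a 224x224x3 canvas
  }
})

test_that("hand-crafted morphology features separate the classes with a linear classifier", {
  skip_if_not_installed("EBImage")
  data <- synth_set_400()

  feat_one <- function(img) {
    lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    nuc <- lum < 0.45
    cell <- lum < 0.85
    n_comp <- max(EBImage::bwlabel(EBImage::Image(nuc * 1)))
    mid <- cell & lum >= 0.45 & lum <= 0.62   # granule-tone fraction
    c(n_comp = n_comp,
      ratio = sum(nuc) / max(1, sum(cell)),
      granule = sum(mid) / max(1, sum(cell)))
  }
  X <- t(vapply(data$images, feat_one, numeric(3)))
  y <- data$labels
  train <- data$split == "train"
  fit <- MASS::lda(X[train, ], grouping = y[train])
  pred <- predict(fit, X[!train, ])$class
  acc <- mean(pred == y[!train])
  expect_gt(acc, 0.8)
})

test_that("a written dataset tree round-trips through the loader", {
  skip_if_not_installed("png")
  out <- withr::local_tempdir()
  set <- generate_synthetic_cells(synthetic_cell_spec(canvas = 48L,
                                                      seed = 5L), 2L)
  manifest <- write_image_dataset(set, out)
  expect_identical(nrow(manifest), 8L)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  back <- suppressMessages(load_image_dataset(out, size = 48L))
  expect_length(back$images, 8L)
  # PNG quantizes to 8 bits; content must survive to that precision
  expect_equal(back$images[[1]], set$images[[1]], tolerance = 1 / 254)
})
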