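test_that("horizontal flip follows the index mapping and is an involution", {
  img <- array(1:6 / 10, dim = c(2, 3, 1))
  flipped <- flip_horizontal(img)
  ref <- img
  W <- 3
  for (i in 1:2) for (j in 1:3) ref[i, j, 1] <- img[i, W - j + 1, 1]
  expect_equal(flipped, ref)

  set.seed(1)
  any_img <- array(runif(8 * 10 * 3), dim = c(8, 10, 3))
  expect_identical(flip_horizontal(flip_horizontal(any_img)), any_img)
  const <- array(0.4, dim = c(5, 5, 3))
  expect_identical(flip_horizontal(const), const)
})

test_that("rotation has the identity at zero and preserves constants away from the fill", {
  set.seed(2)
  img <- array(runif(21 * 21 * 3), dim = c(21, 21, 3))
  expect_identical(rotate_image(img, 0), img)

  const <- array(0.6, dim = c(31, 31, 3))
  rot <- rotate_image(const, 10)
  expect_equal(rot[10:22, 10:22, ], const[10:22, 10:22, ], tolerance = 1e-6)
})

test_that("a clockwise 10-degree rotation moves an off-center pixel to its analytic position", {
  S <- 41; ctr <- 21; r <- 12
  img <- array(0, dim = c(S, S, 1))
  img[ctr, ctr + r, 1] <- 1                     # at visual angle 0 from center
  rot <- rotate_image(img, 10)
  pk <- which(rot[, , 1] == max(rot[, , 1]), arr.ind = TRUE)[1, ]
  th <- 10 * pi / 180
  # clockwise: lands r*cos(10) right of and r*sin(10) below the center
  expect_lt(abs(pk[1] - (ctr + r * sin(th))), 1)
  expect_lt(abs(pk[2] - (ctr + r * cos(th))), 1)
})

test_that("origin-anchored zoom obeys the floor index mapping; scale 1 is the identity", {
  img <- array(0, dim = c(4, 4, 1))
  img[1:2, 1:2, 1] <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  z <- zoom_image(img, 2, anchor = "origin")
  ref <- img
  for (m in 0:3) for (n in 0:3)
    ref[m + 1, n + 1, 1] <- img[floor(m / 2) + 1, floor(n / 2) + 1, 1]
  expect_equal(z, ref)
  # each top-left source pixel paints a 2x2 block
  expect_equal(z[1:2, 1:2, 1], matrix(0.1, 2, 2))
  expect_equal(z[3:4, 3:4, 1], matrix(0.4, 2, 2))

  set.seed(3)
  any_img <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
  expect_identical(zoom_image(any_img, 1), any_img)
  const <- array(0.25, dim = c(8, 8, 3))
  expect_equal(zoom_image(const, 2, anchor = "center"), const,
               tolerance = 1e-12)
  expect_equal(zoom_image(const, 2, anchor = "origin"), const)
})

test_that("contrast stretching is mean-anchored, clipped and the identity at factor 1", {
  two <- array(c(0.4, 0.6), dim = c(1, 2, 1))
  out <- random_contrast(two, factor = 2)
  expect_equal(as.numeric(out), c(0.3, 0.7))

  set.seed(4)
  img <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
  expect_equal(random_contrast(img, factor = 1), img)
  big <- random_contrast(img, factor = 10)
  expect_gte(min(big), 0)
  expect_lte(max(big), 1)
})

test_that("transform properties hold across many random images", {
  set.seed(5)
  for (k in 1:50) {
    img <- array(runif(9 * 9 * 3), dim = c(9, 9, 3))
    expect_identical(flip_horizontal(flip_horizontal(img)), img)
    expect_identical(rotate_image(img, 0), img)
    expect_identical(zoom_image(img, 1), img)
    out <- random_contrast(img, augmentation_spec(seed = k))
    expect_true(min(out) >= 0 && max(out) <= 1)
  }
})

test_that("balancing expands every class to the target and keeps all originals", {
  set.seed(6)
  sizes <- c(eosinophil = 3, lymphocyte = 80, monocyte = 35, neutrophil = 25)
  imgs <- list(); labs <- character()
  for (cl in names(sizes)) for (i in seq_len(sizes[[cl]])) {
    imgs[[length(imgs) + 1L]] <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
    labs <- c(labs, cl)
  }
  data <- labeled_image_set(imgs, labs)
  out <- balance_augment(data, 100L, augmentation_spec(seed = 9))
  expect_equal(as.numeric(table(out$labels)), rep(100, 4))
  # originals retained verbatim at the head of the set
  expect_identical(out$images[seq_along(imgs)], imgs)
  expect_true(all(out$provenance[seq_along(imgs)] == "original"))
  expect_true(all(out$provenance[-seq_along(imgs)] == "augmented"))
  expect_error(balance_augment(data, 50L, augmentation_spec(seed = 9)),
               "never discarded")
})

test_that("balancing is byte-identical under the same seed", {
  set.seed(7)
  imgs <- lapply(1:12, function(i) array(runif(8 * 8 * 3), dim = c(8, 8, 3)))
  labs <- rep(CELL_CLASSES, each = 3)
  data <- labeled_image_set(imgs, labs)
  a <- balance_augment(data, 8L, augmentation_spec(seed = 11))
  b <- balance_augment(data, 8L, augmentation_spec(seed = 11))
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
})

test_that("with flips only, the reachable images are exhausted before any duplicate", {
  set.seed(8)
  imgs <- lapply(1:3, function(i) array(runif(6 * 6 * 3), dim = c(6, 6, 3)))
  data <- labeled_image_set(imgs, rep("eosinophil", 3))
  spec <- augmentation_spec(flip = TRUE, rotation_deg = 0, zoom_scale = 1,
                            contrast_range = c(1, 1), seed = 3)
  out <- balance_augment(data, 6L, spec)
  sigs <- vapply(out$images, function(im) paste(signif(im, 12),
                                                collapse = ","), "")
  expect_identical(length(unique(sigs)), 6L)
  # the three synthesized images are exactly the three flips
  flip_sigs <- vapply(imgs, function(im)
    paste(signif(flip_horizontal(im), 12), collapse = ","), "")
  expect_setequal(sigs[4:6], flip_sigs)
})

test_that("augmentation never changes labels, split tags or the pixel range", {
  set.seed(9)
  imgs <- lapply(1:8, function(i) array(runif(8 * 8 * 3), dim = c(8, 8, 3)))
  labs <- rep(c("monocyte", "lymphocyte"), each = 4)
  data <- labeled_image_set(imgs, labs,
                            split = rep(c("train", "test"), 4))
  out <- balance_augment(data, 5L, augmentation_spec(seed = 13),
                         split = "train")
  new_idx <- which(out$provenance == "augmented")
  expect_true(all(out$split[new_idx] == "train"))
  expect_true(all(vapply(out$images[new_idx],
                         function(im) min(im) >= 0 && max(im) <= 1, TRUE)))
  # the test split is untouched
  expect_identical(sum(out$split == "test"), sum(data$split == "test"))
})
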