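test_that("z-scoring statistics reproduce a standard-normal training set", {
  set.seed(21)
  imgs <- replicate(20, matrix(rnorm(16, mean = 3, sd = 2), 4, 4),
                    simplify = FALSE)
  norm <- fit_normalizer(imgs)
  z <- lapply(imgs, function(x) apply_normalizer(norm, x))
  flat <- do.call(rbind, lapply(z, as.vector))
  expect_lt(max(abs(colMeans(flat))), 1e-10)
  expect_lt(max(abs(apply(flat, 2, sd) - 1)), 1e-10)
})

test_that("identical training images hit the std floor and map to zero", {
  imgs <- replicate(5, matrix(0.3, 4, 4), simplify = FALSE)
  norm <- fit_normalizer(imgs)
  expect_true(all(norm$sd == norm$eps))
  expect_equal(apply_normalizer(norm, imgs[[1]]), matrix(0, 4, 4))
})

test_that("fit_normalizer requires at least two images", {
  expect_error(fit_normalizer(list(matrix(1, 2, 2))), "at least 2")
})

test_that("test images are standardized with training statistics, not their own", {
  set.seed(22)
  train <- replicate(10, matrix(rnorm(9), 3, 3), simplify = FALSE)
  test_img <- matrix(rnorm(9, mean = 10), 3, 3)
  norm <- fit_normalizer(train)
  z <- apply_normalizer(norm, test_img)
  expect_equal(z, (test_img - norm$mean) / norm$sd)
  # statistics unchanged by what is applied
  norm2 <- fit_normalizer(train)
  expect_identical(norm$mean, norm2$mean)
})

test_that("KLT recovers planted two-dimensional structure", {
  set.seed(23)
  # images vary only along two orthogonal pixel directions
  d1 <- matrix(0, 4, 4); d1[1, 1] <- 1
  d2 <- matrix(0, 4, 4); d2[4, 4] <- 1
  imgs <- lapply(1:30, function(i) rnorm(1, sd = 3) * d1 + rnorm(1) * d2)
  klt <- fit_klt(imgs)
  expect_s3_class(klt, "lk_klt")
  # basis spans exactly the planted plane: each planted direction projects
  # onto the basis with unit norm
  span <- crossprod(klt$basis, cbind(as.vector(d1), as.vector(d2)))
  expect_equal(unname(sqrt(colSums(span^2))), c(1, 1), tolerance = 1e-8)
  # projection captures all the variance
  flat <- do.call(rbind, lapply(imgs, as.vector))
  total_var <- sum(apply(flat, 2, var))
  expect_equal(sum(klt$eigenvalues), total_var, tolerance = 1e-8)
})

test_that("KLT eigenvalues match an independent eigendecomposition", {
  set.seed(24)
  flat <- matrix(rnorm(40 * 25), 40, 25)
  imgs <- lapply(seq_len(40), function(i) matrix(flat[i, ], 5, 5))
  klt <- fit_klt(imgs)
  ev <- eigen(cov(flat), symmetric = TRUE)   # independent oracle
  expect_equal(klt$eigenvalues, ev$values[1:2], tolerance = 1e-8)
  # projected (unwhitened) training variance equals the eigenvalues
  proj <- sweep(flat, 2, colMeans(flat)) %*% klt$basis
  expect_equal(apply(proj, 2, var), klt$eigenvalues, tolerance = 1e-8)
  # orthonormality and descending order
  expect_equal(crossprod(klt$basis), diag(2), tolerance = 1e-10)
  expect_gte(klt$eigenvalues[1], klt$eigenvalues[2])
  # sign convention: largest-magnitude entry positive
  for (j in 1:2) {
    expect_gt(klt$basis[which.max(abs(klt$basis[, j])), j], 0)
  }
})

test_that("KLT rejects rank-0 input and too-small training sets", {
  imgs <- replicate(5, matrix(1, 3, 3), simplify = FALSE)
  expect_error(fit_klt(imgs), "identical")
  expect_error(fit_klt(imgs[1:2]), "at least 3")
})

test_that("features are 2-dimensional for every input size", {
  ds <- generate_dataset(easy_config())
  prep <- fit_preprocessor(ds)
  cfg <- synth_config(seed = 1)   # full 19..138 size range
  for (size in c(19, 33, 64, 138)) {
    eye <- generate_eye(1L, size, cfg, seed = size)
    for (ch in c("R", "G", "B")) {
      x <- preprocess_channel(eye, ch, prep)
      expect_length(x, 2)
      expect_true(all(is.finite(x)))
    }
  }
})

test_that("full preprocessing is invariant to an additive illumination offset", {
  cfg <- synth_config(n_positive = 8, n_negative = 12, size_max = 50,
                      illumination_offset_range = 0,
                      illumination_gradient_range = 0, noise_sd = 0.02,
                      seed = 31)
  ds <- generate_dataset(cfg)
  prep <- fit_preprocessor(ds)
  eye <- generate_eye(-1L, 30, cfg, seed = 99)
  twin <- eye
  twin$pixels <- eye$pixels * 0.8 + 0.1   # clip-free offset+scale headroom
  eye$pixels <- eye$pixels * 0.8          # same scale, offset differs by 0.1
  for (ch in c("R", "G", "B")) {
    f1 <- preprocess_channel(eye, ch, prep)
    f2 <- preprocess_channel(twin, ch, prep)
    expect_lt(max(abs(f1 - f2)), 1e-8)
  }
})

test_that("the fused pipeline equals its stepwise composition", {
  ds <- generate_dataset(easy_config())
  prep <- fit_preprocessor(ds)
  eye <- generate_eye(1L, 19, synth_config(seed = 1), seed = 4)
  for (ch in c("R", "G", "B")) {
    i <- match(ch, c("R", "G", "B"))
    x <- eye$pixels[, , i]
    step <- dct2(x)
    step <- discard_illumination(step)
    step <- idct2(step)
    step <- resample_to_fixed(step, 32)
    p <- prep$channels[[ch]]
    z <- (as.vector(step) - p$mean) / p$sd
    by_hand <- drop(crossprod(p$klt$basis, z - p$klt$center)) / p$klt$sdev
    expect_equal(preprocess_channel(eye, ch, prep), by_hand, tolerance = 1e-12)
  }
})

test_that("preprocess_channel demands a fitted preprocessor", {
  eye <- generate_eye(1L, 19, synth_config(), seed = 1)
  expect_error(preprocess_channel(eye, "G", list()), "lk_preprocessor")
})

test_that("preprocess_features emits one 2-D row per image and channel", {
  cfg <- easy_config(n_pos = 4, n_neg = 5)
  ds <- generate_dataset(cfg)
  prep <- fit_preprocessor(ds)
  ft <- preprocess_features(ds, prep)
  expect_equal(nrow(ft), 9 * 3)
  expect_setequal(unique(ft$channel), c("R", "G", "B"))
  expect_true(all(is.finite(ft$x1)) && all(is.finite(ft$x2)))
  # list path and matrix path agree
  one <- ft[ft$channel == "G" & ft$id == 1, ]
  direct <- preprocess_channel(ds$image[[1]], "G", prep)
  expect_equal(c(one$x1, one$x2), unname(direct), tolerance = 1e-10)
})
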