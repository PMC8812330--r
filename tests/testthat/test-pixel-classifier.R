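small_config <- feature_config(sigmas = c(1, 2, 4))

test_that("feature planes have the input shape, finite values, and expected degeneracies", {
  plane <- matrix(100, 24, 24)
  fs <- compute_features(plane, small_config)
  expect_true(all(vapply(fs, function(f) all(dim(f) == c(24, 24)),
                         logical(1))))
  expect_true(all(vapply(fs, function(f) all(is.finite(f)), logical(1))))
  # constant plane: gaussians constant, DoG zero
  for (nm in grep("^gaussian_", names(fs), value = TRUE))
    expect_lt(diff(range(fs[[nm]])), 1e-8)
  for (nm in grep("^dog_", names(fs), value = TRUE))
    expect_lt(max(abs(fs[[nm]])), 1e-8)
})

test_that("difference-of-gaussians planes flip sign under sigma-pair swap", {
  set.seed(31)
  plane <- matrix(runif(24 * 24, 0, 255), 24, 24)
  g <- lapply(c(1, 2), function(s) EBImage::gblur(plane, s))
  fs <- compute_features(plane, feature_config(
    kinds = c("gaussian_blur", "difference_of_gaussians"), sigmas = c(1, 2)))
  expect_equal(fs$dog_1_2, g[[1]] - g[[2]], tolerance = 1e-10)
  expect_equal(fs$dog_1_2, -(g[[2]] - g[[1]]), tolerance = 1e-10)
})

test_that("hessian eigenvalue planes match a per-pixel eigen-decomposition oracle", {
  n <- 31
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  plane <- 200 * exp(-((i - 16)^2 + (j - 16)^2) / 18)    # gaussian blob
  fs <- compute_features(plane, feature_config(kinds = "hessian", sigmas = 2))
  sm <- EBImage::gblur(plane, 2)
  for (pt in list(c(16, 16), c(12, 16), c(20, 13))) {
    r <- pt[1]; c <- pt[2]
    hrr <- sm[r - 1, c] - 2 * sm[r, c] + sm[r + 1, c]
    hcc <- sm[r, c - 1] - 2 * sm[r, c] + sm[r, c + 1]
    hrc <- (sm[r + 1, c + 1] + sm[r - 1, c - 1] -
              sm[r - 1, c + 1] - sm[r + 1, c - 1]) / 4
    ev <- eigen(matrix(c(hrr, hrc, hrc, hcc), 2, 2))$values
    expect_equal(fs$hessian_large_2[r, c], max(ev), tolerance = 1e-8)
    expect_equal(fs$hessian_small_2[r, c], min(ev), tolerance = 1e-8)
  }
})

test_that("membrane max projection responds on a bright line at least as much as off it", {
  plane <- matrix(0, 41, 41)
  plane[, 21] <- 255                       # vertical line
  fs <- compute_features(plane, feature_config(
    kinds = "membrane_projections", sigmas = 1))
  on_line <- fs$membrane_max[21, 21]
  off_line <- fs$membrane_max[21, 8]
  expect_gte(on_line, off_line)
})

test_that("training on a separable fixture is accurate, seeded, and rejects one-class labels", {
  set.seed(33)
  n <- 48
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  disks <- ((i - 14)^2 + (j - 14)^2 <= 36) | ((i - 34)^2 + (j - 32)^2 <= 49)
  plane <- ifelse(disks, 220, 20) + matrix(rnorm(n * n, 0, 5), n, n)
  tr <- list(plane = plane, labels = disks)
  m1 <- train_ld_classifier(list(tr), small_config, n_trees = 50, seed = 7)
  pred <- predict_ld_mask(plane, m1)
  acc <- mean(pred == disks)
  expect_gte(acc, 0.99)
  # determinism: same data + seed -> identical predictions
  m2 <- train_ld_classifier(list(tr), small_config, n_trees = 50, seed = 7)
  expect_identical(pred, predict_ld_mask(plane, m2))
  expect_identical(pred, predict_ld_mask(plane, m1))   # repeat predict
  # all-background labels are a training error
  expect_error(train_ld_classifier(
    list(list(plane = plane, labels = disks & FALSE)), small_config),
    "both classes")
})

test_that("a model round-trips through its serialization and validates its config", {
  set.seed(34)
  plane <- matrix(runif(30 * 30, 0, 255), 30, 30)
  labels <- plane > 128
  m <- train_ld_classifier(list(list(plane = plane, labels = labels)),
                           small_config, n_trees = 25, seed = 2)
  dir <- tempfile("model")
  write_ld_model(m, dir)
  m2 <- read_ld_model(dir)
  expect_identical(predict_ld_mask(plane, m), predict_ld_mask(plane, m2))
  expect_equal(m2$config$sigmas, small_config$sigmas)
  # prediction with a mismatched feature configuration is a model error
  m_bad <- m
  m_bad$config <- feature_config(sigmas = c(1, 2))
  expect_error(predict_ld_mask(plane, m_bad), "mismatch")
})

test_that("the Yen fallback segments bright droplets and warns on blank planes", {
  set.seed(35)
  n <- 64
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  disks <- (i - 20)^2 + (j - 20)^2 <= 64
  plane <- ifelse(disks, 60000, 2000) + matrix(rnorm(n * n, 0, 500), n, n)
  plane <- pmax(pmin(round(plane), 65535), 0)
  mask <- segment_ld(plane, model = NULL, bit_depth = 16)
  iou <- sum(mask & disks) / sum(mask | disks)
  expect_gte(iou, 0.8)
  expect_warning(blank <- segment_ld(matrix(5, 8, 8), bit_depth = 16),
                 "degenerate")
  expect_false(any(blank))
})
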