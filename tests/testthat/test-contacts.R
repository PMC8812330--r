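test_that("colocalization follows the declared triple condition (hand arithmetic)", {
  # planes engineered so T_ld = 100, T_mito = 50 cannot hold exactly;
  # instead check the ratio arithmetic directly through the pixel loop
  # oracle on small random pairs, plus the two hand-computed cases via
  # a fabricated threshold check
  ld8 <- matrix(c(200, 200, 10, 10), 2, 2)
  mito8 <- matrix(c(90, 150, 10, 10), 2, 2)
  ratio <- 100 * pmin(ld8, mito8) / pmax(ld8, mito8)
  expect_false(ratio[1, 1] > 50)              # 100*90/200 = 45 -> rejected
  expect_true(ratio[2, 1] > 50)               # 100*150/200 = 75 -> kept
})

test_that("colocalization_mask equals the brute-force pixel loop on random pairs", {
  set.seed(41)
  params <- colocalization_params()
  for (k in 1:20) {
    ld <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    mito <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    got <- colocalization_mask(ld, mito, params, bit_depth = 8)
    t_ld <- yen_threshold(histogram256(ld))
    t_m <- otsu_threshold(histogram256(mito))
    ref <- matrix(FALSE, 64, 64)
    for (i in 1:64) for (j in 1:64) {
      a <- ld[i, j]; b <- mito[i, j]
      r <- if (max(a, b) > 0) 100 * min(a, b) / max(a, b) else 0
      ref[i, j] <- a > t_ld && b > t_m && r > 50
    }
    expect_identical(got, ref)
  }
})

test_that("raising ratio_percent monotonically shrinks the colocalization mask", {
  set.seed(42)
  ld <- matrix(sample(0:255, 2500, TRUE), 50, 50)
  mito <- matrix(sample(0:255, 2500, TRUE), 50, 50)
  prev <- NULL
  for (r in c(0, 25, 50, 75, 95)) {
    m <- colocalization_mask(ld, mito, colocalization_params(ratio_percent = r),
                             bit_depth = 8)
    if (!is.null(prev)) expect_true(all(!m | prev))    # m subset of prev
    prev <- m
  }
})

test_that("degenerate channels give an empty mask with a warning", {
  expect_warning(
    m <- colocalization_mask(matrix(7, 10, 10),
                             matrix(sample(0:255, 100, TRUE), 10, 10),
                             bit_depth = 8),
    "degenerate")
  expect_false(any(m))
})

disk_mask <- function(n, centers, radii) {
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  m <- matrix(FALSE, n, n)
  for (k in seq_along(radii))
    m <- m | ((i - centers[[k]][1])^2 + (j - centers[[k]][2])^2 <= radii[k]^2)
  m
}

test_that("ld_particles separates touching droplets near the perpendicular bisector", {
  m1 <- disk_mask(40, list(c(20, 20)), 8)
  r1 <- ld_particles(m1)
  expect_equal(r1$n_ld, 1)
  # two overlapping disks, centres 1.5 r apart
  m2 <- disk_mask(60, list(c(30, 24), c(30, 36)), c(8, 8))
  r2 <- ld_particles(m2)
  expect_equal(r2$n_ld, 2)
  split <- which(r2$limits & m2, arr.ind = TRUE)
  expect_gt(nrow(split), 0)
  expect_true(all(abs(split[, 2] - 30) <= 2))   # bisector is column 30
  # empty mask
  r0 <- ld_particles(matrix(FALSE, 10, 10))
  expect_equal(r0$n_ld, 0)
})

test_that("a thin colocalization band yields one contact of the expected length", {
  n <- 24
  coloc <- matrix(FALSE, n, n)
  coloc[11:12, 6:15] <- TRUE                  # 10 x 2 px horizontal band
  ldm <- disk_mask(n, list(c(12, 10)), 9)
  lr <- ld_particles(ldm)
  cells <- matrix(1L, n, n)
  s <- 0.093
  ct <- extract_contacts(coloc, lr, cells, s)
  expect_equal(nrow(ct$table), 1)
  expect_equal(ct$table$cell_label, 1L)
  # 10-px band -> 9 traced orthogonal steps, within 2 px of expectation
  expect_lt(abs(ct$table$length_um - 9 * s), 2 * s + 1e-9)
  # empty mask -> no contacts
  ct0 <- extract_contacts(matrix(FALSE, n, n), lr, cells, s)
  expect_equal(nrow(ct0$table), 0)
  expect_equal(sum(ct0$table$length_um), 0)
})

test_that("a blob straddling the limit between two droplets splits into two contacts", {
  n <- 60
  ldm <- disk_mask(n, list(c(30, 24), c(30, 36)), c(8, 8))
  lr <- ld_particles(ldm)
  coloc <- matrix(FALSE, n, n)
  coloc[24:26, 26:34] <- TRUE                 # band across the bisector
  ct <- extract_contacts(coloc, lr, matrix(1L, n, n), 0.093)
  expect_equal(nrow(ct$table), 2)
  expect_equal(sort(unique(ct$table$ld_label)), c(1L, 2L))
})

test_that("every skeleton pixel lies inside its source colocalization mask", {
  set.seed(44)
  for (k in 1:5) {
    coloc <- EBImage::gblur(matrix(runif(48 * 48), 48, 48), 2) > 0.52
    lr <- ld_particles(disk_mask(48, list(c(24, 24)), 12))
    ct <- extract_contacts(coloc, lr, matrix(1L, 48, 48), 0.093)
    for (s in ct$sites)
      expect_true(all(coloc[s$pixels]))
  }
})

test_that("total contact length is invariant under translation and 90-degree rotation", {
  n <- 40
  coloc <- matrix(FALSE, n, n)
  coloc[15:16, 8:20] <- TRUE
  ldm <- disk_mask(n, list(c(15, 14)), 10)
  run <- function(co, ld) {
    lr <- ld_particles(ld)
    extract_contacts(co, lr, matrix(1L, nrow(co), ncol(co)), 0.093)
  }
  base <- run(coloc, ldm)
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + di):nrow(m), (1 + dj):ncol(m)] <-
      m[1:(nrow(m) - di), 1:(ncol(m) - dj)]
    out
  }
  tr <- run(shift(coloc, 5, 7), shift(ldm, 5, 7))
  expect_equal(sum(tr$table$length_um), sum(base$table$length_um))
  rot <- run(t(coloc)[n:1, ], t(ldm)[n:1, ])
  expect_equal(sum(rot$table$length_um), sum(base$table$length_um))
  expect_equal(nrow(rot$table), nrow(base$table))
})

test_that("an isolated colocalized pixel is one contact of length s", {
  n <- 20
  coloc <- matrix(FALSE, n, n); coloc[10, 10] <- TRUE
  lr <- ld_particles(disk_mask(n, list(c(10, 10)), 5))
  ct <- extract_contacts(coloc, lr, matrix(1L, n, n), 0.2)
  expect_equal(nrow(ct$table), 1)
  expect_equal(ct$table$length_um, 0.2)
})
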