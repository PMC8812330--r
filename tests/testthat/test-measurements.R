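test_that("square and disk morphometry match hand geometry", {
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L                       # 10 x 10 px square
  m <- region_morphometry(lab, 1)
  expect_equal(m$area_um2, 100)
  expect_gte(m$perimeter_um, 36); expect_lte(m$perimeter_um, 40)
  expect_equal(m$perimeter_um, 36)            # golden: boundary chain rule
  # digitized disk radius 20 px: area within 2% of pi r^2
  n <- 51
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  dl <- matrix(0L, n, n); dl[(i - 26)^2 + (j - 26)^2 <= 400] <- 1L
  md <- region_morphometry(dl, 0.5)
  expect_equal(md$area_um2, pi * 400 * 0.25, tolerance = 0.02)
  # golden perimeter of this digitization, declared chain rule
  expect_equal(md$perimeter_um, 65.9411, tolerance = 1e-3)
  # empty label map
  expect_equal(nrow(region_morphometry(matrix(0L, 5, 5), 1)), 0)
  # single pixel: 4 s by convention
  sp <- matrix(0L, 4, 4); sp[2, 2] <- 1L
  expect_equal(region_morphometry(sp, 0.5)$perimeter_um, 2)
})

make_partition <- function(cells, border = NULL) {
  n <- max(cells)
  if (is.null(border)) border <- rep(FALSE, n)
  structure(list(cells = cells, n_cells = n, border_cell = border),
            class = "cell_partition")
}

empty_contacts <- function() {
  structure(list(sites = list(),
                 table = data.frame(contact = integer(0),
                                    cell_label = integer(0),
                                    ld_label = integer(0),
                                    length_um = numeric(0),
                                    n_pixels = integer(0))),
            class = "contact_set")
}

test_that("a cell with no droplets carries the NaN sentinel and zero contact fields", {
  cells <- matrix(1L, 20, 20)
  rec <- assemble_records(make_partition(cells), matrix(0L, 20, 20),
                          matrix(FALSE, 20, 20), empty_contacts(),
                          "img", 0.1)
  expect_equal(rec$n_ld, 0)
  expect_true(is.nan(rec$ld_mean_area_um2))
  expect_true(is.nan(rec$ld_mean_perimeter_um))
  expect_equal(rec$n_contacts, 0)
  expect_equal(rec$contact_total_length_um, 0)
  expect_true(is.nan(rec$contact_efficiency))   # no LD perimeter
})

test_that("three equal droplets give mean area of one disk and zero SD", {
  n <- 60
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  lds <- matrix(0L, n, n)
  centers <- list(c(15, 15), c(15, 45), c(45, 30))
  for (k in 1:3) lds[(i - centers[[k]][1])^2 + (j - centers[[k]][2])^2 <= 36] <- k
  cells <- matrix(1L, n, n)
  rec <- assemble_records(make_partition(cells), lds, matrix(FALSE, n, n),
                          empty_contacts(), "img", 0.1)
  one_area <- sum(lds == 1) * 0.01
  expect_equal(rec$n_ld, 3)
  expect_equal(rec$ld_mean_area_um2, one_area)
  expect_equal(rec$ld_area_sd_um2, 0)
  expect_equal(rec$ld_total_area_um2, 3 * one_area)
})

test_that("contacts are credited only to their assigned cell", {
  n <- 40
  cells <- matrix(0L, n, n)
  cells[, 1:19] <- 1L; cells[, 21:40] <- 2L
  lds <- matrix(0L, n, n); lds[8:12, 5:9] <- 1L
  site <- structure(list(pixels = cbind(10, 5:9), length_um = 0.4,
                         ld_label = 1L, cell_label = 1L),
                    class = "contact_site")
  ct <- structure(list(sites = list(site),
                       table = data.frame(contact = 1L, cell_label = 1L,
                                          ld_label = 1L, length_um = 0.4,
                                          n_pixels = 5L)),
                  class = "contact_set")
  rec <- assemble_records(make_partition(cells), lds, matrix(FALSE, n, n),
                          ct, "img", 0.1)
  expect_equal(rec$n_contacts, c(1, 0))
  expect_equal(rec$contact_total_length_um, c(0.4, 0))
  expect_equal(rec$contact_mean_length_um[1], 0.4)
  # exact conservation of assigned lengths
  expect_equal(sum(rec$contact_total_length_um), sum(ct$table$length_um))
})

test_that("mitochondria are counted as 4-connected components within each cell", {
  n <- 30
  cells <- matrix(1L, n, n)
  mito <- matrix(FALSE, n, n)
  mito[5:8, 5:8] <- TRUE
  mito[20, 20:26] <- TRUE
  mito[10, 15] <- TRUE
  rec <- assemble_records(make_partition(cells), matrix(0L, n, n), mito,
                          empty_contacts(), "img", 0.1)
  expect_equal(rec$n_mito, 3)
  expect_equal(rec$mito_total_area_um2, sum(mito) * 0.01)
})

test_that("per-cell LD areas never exceed the global droplet area (conservation)", {
  set.seed(51)
  n <- 64
  cells <- matrix(0L, n, n)
  cells[5:30, 5:30] <- 1L; cells[35:60, 30:60] <- 2L
  lds <- matrix(0L, n, n)
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  lds[(i - 12)^2 + (j - 12)^2 <= 16] <- 1L
  lds[(i - 45)^2 + (j - 45)^2 <= 25] <- 2L
  lds[(i - 32)^2 + (j - 62)^2 <= 9] <- 3L     # partially outside both cells
  rec <- suppressMessages(
    assemble_records(make_partition(cells), lds, matrix(FALSE, n, n),
                     empty_contacts(), "img", 0.1))
  expect_lte(sum(rec$ld_total_area_um2), sum(lds > 0) * 0.01 + 1e-9)
  expect_true(all(rec$ld_total_area_um2 >= 0))
  # all values finite or NaN sentinel, never negative
  nums <- unlist(rec[vapply(rec, is.numeric, logical(1))])
  expect_true(all(is.finite(nums) | is.nan(nums)))
  expect_true(all(nums[is.finite(nums)] >= 0))
})
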