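#' Nucleus mask
#'
#' Otsu threshold of the nucleus plane with holes filled. A degenerate
#' (single-bin) histogram yields an empty mask with a warning.
#'
#' @param nucleus_plane 2D intensity matrix.
#' @param bit_depth native bit depth.
#' @return Logical nucleus mask.
#' @export
nucleus_mask <- function(nucleus_plane, bit_depth = 16) {
  p8 <- to_8bit(nucleus_plane, bit_depth)
  h <- histogram256(p8)
  if (sum(h$counts > 0) < 2) {
    warning("degenerate nucleus histogram; empty nucleus mask")
    return(matrix(FALSE, nrow(nucleus_plane), ncol(nucleus_plane)))
  }
  m <- p8 > otsu_threshold(h)
  EBImage::fillHull(m * 1L) > 0
}

#' Composite seeding landscape for cell individualization
#'
#' Adds the intensity-compensated cytoplasmic channels to a binary
#' nucleus mask at full scale: `ld8 * f_ld + mito8 * f_mito + 255 *
#' nucleus`, clipped to the 8-bit working range. This is the landscape on
#' which maxima are sought to seed one region per cell.
#'
#' @param stack a [channel_stack].
#' @param compensation named factors in `(0, 1]`, e.g.
#'   `c(ld = 0.2, mito = 0.2)`.
#' @param nmask optional precomputed nucleus mask.
#' @return Numeric matrix in `[0, 255]`.
#' @export
composite_image <- function(stack, compensation = c(ld = 0.2, mito = 0.2),
                            nmask = NULL) {
  if (any(compensation <= 0) || any(compensation > 1))
    stop("compensation factors must be in (0, 1]")
  ld8 <- to_8bit(stack$planes$ld, stack$bit_depth)
  mito8 <- to_8bit(stack$planes$mito, stack$bit_depth)
  if (is.null(nmask)) nmask <- nucleus_mask(stack$planes$nucleus, stack$bit_depth)
  comp <- ld8 * compensation[["ld"]] + mito8 * compensation[["mito"]] +
    255 * nmask
  pmin(comp, 255)
}

#' Individualize cells without a membrane marker
#'
#' Pipeline: (1) [composite_image()] is partitioned by
#' [segmented_particles()] (one region per nucleus-seeded maximum);
#' (2) the flattened stack is median-filtered (radius 2) and
#' Huang-thresholded into a whole-cell foreground mask; (3) the per-pixel
#' minimum of the foreground and the limits-complement splits touching
#' cells along the ridge lines; (4) 4-connected particle analysis keeps
#' components of at least `min_cell_area_um2` that overlap the nucleus
#' mask, relabelled 1..n in raster order. Cells touching the image border
#' are kept and flagged.
#'
#' @param stack a [channel_stack].
#' @param prominence maxima prominence on the 8-bit composite
#'   (default 100).
#' @param compensation cytoplasmic channel factors (default 0.2, 0.2).
#' @param min_cell_area_um2 minimum retained cell area.
#' @return Object of class `cell_partition`: list with `cells` (integer
#'   label matrix), `n_cells`, `nucleus_mask`, `border_cell` (logical per
#'   label), `compensation`, `limits`.
#' @export
individualize_cells <- function(stack, prominence = 100,
                                compensation = c(ld = 0.2, mito = 0.2),
                                min_cell_area_um2 = 50) {
  nmask <- nucleus_mask(stack$planes$nucleus, stack$bit_depth)
  comp <- composite_image(stack, compensation, nmask = nmask)
  sp <- segmented_particles(comp, prominence)
  flat <- median_filter(flatten_to_8bit(stack), 2)
  h <- histogram256(round_half_up(flat))
  empty <- function() {
    warning("no cells found")
    structure(list(cells = matrix(0L, nrow(comp), ncol(comp)), n_cells = 0L,
                   nucleus_mask = nmask, border_cell = logical(0),
                   compensation = compensation, limits = sp$limits),
              class = "cell_partition")
  }
  if (sum(h$counts > 0) < 2) return(empty())
  fg <- flat > huang_threshold(h)
  split <- fg & !sp$limits            # minimum of 255/0 mask and limits image
  cc <- label_components(split, 4)
  if (max(cc) == 0) return(empty())
  s2 <- stack$pixel_size_um^2
  areas <- tabulate(cc[cc > 0], nbins = max(cc))
  has_nucleus <- rep(FALSE, max(cc))
  nuc_lab <- cc[nmask & cc > 0]
  has_nucleus[unique(nuc_lab)] <- TRUE
  keep <- which(areas * s2 >= min_cell_area_um2 & has_nucleus)
  if (length(keep) == 0) return(empty())
  remap <- integer(max(cc))
  remap[keep] <- seq_along(keep)      # raster order preserved by labelling
  cells <- matrix(0L, nrow(cc), ncol(cc))
  pos <- cc > 0
  cells[pos] <- remap[cc[pos]]
  border <- vapply(seq_along(keep), function(l) {
    w <- cells == l
    any(w[1, ]) || any(w[nrow(w), ]) || any(w[, 1]) || any(w[, ncol(w)])
  }, logical(1))
  structure(list(cells = cells, n_cells = length(keep), nucleus_mask = nmask,
                 border_cell = border, compensation = compensation,
                 limits = sp$limits),
            class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat(sprintf("cell_partition: %d cell(s)%s\n", x$n_cells,
              if (any(x$border_cell)) sprintf(" (%d at border)",
                                              sum(x$border_cell)) else ""))
  invisible(x)
}
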