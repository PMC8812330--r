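#' Per-region area and perimeter
#'
#' Area is pixel count times `pixel_size_um^2`. Perimeter is the length
#' of the outer boundary chain traced through boundary pixel centres
#' (Moore tracing): orthogonal steps contribute `s`, diagonal steps
#' `s * sqrt(2)`; a single-pixel region has perimeter `4 s` (its pixel
#' edges). This is the one perimeter rule used for every measurement in
#' the package; holes do not contribute.
#'
#' @param labels integer label matrix (0 = background, labels 1..n).
#' @param pixel_size_um pixel edge in micrometres.
#' @return data.frame with `label`, `area_um2`, `perimeter_um`.
#' @export
region_morphometry <- function(labels, pixel_size_um) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0)))
  storage.mode(labels) <- "integer"
  areas <- tabulate(labels[labels > 0], nbins = n)
  chain <- cpp_boundary_chain(labels, n)
  per <- (chain[, 1] + chain[, 2] * sqrt(2)) * pixel_size_um
  per[areas == 1] <- 4 * pixel_size_um
  keep <- areas > 0
  data.frame(label = which(keep), area_um2 = areas[keep] * pixel_size_um^2,
             perimeter_um = per[keep])
}

# majority-overlap assignment of each organelle label to a cell label
assign_by_majority <- function(org_labels, cells) {
  n <- max(org_labels)
  if (n == 0) return(integer(0))
  out <- integer(n)
  idx <- which(org_labels > 0)
  ol <- org_labels[idx]; cl <- cells[idx]
  for (l in seq_len(n)) {
    v <- cl[ol == l]
    if (!length(v)) { out[l] <- 0L; next }
    u <- sort(unique(as.integer(v)))
    counts <- vapply(u, function(x) sum(v == x), integer(1))
    out[l] <- u[which.max(counts)]
  }
  out
}

#' Assemble the per-cell results table
#'
#' One row per cell with the full morphometry and contact statistics:
#' cell area, LD and mitochondria counts, total areas and perimeters, LD
#' area mean and sample standard deviation (`n = 1` gives SD 0), contact
#' count, total and mean contact length, and the contact efficiency
#' (total contact length / total LD perimeter; `NaN` when the cell has
#' no LD perimeter). Lipid droplets are assigned to cells by majority
#' pixel overlap; mitochondria are counted as 4-connected components of
#' the mitochondria mask within the cell; organelles overlapping no cell
#' are excluded (and reported via a message).
#'
#' @param partition a [individualize_cells()] result (or a list with
#'   `cells`, `n_cells`, `border_cell`).
#' @param ld_labels integer LD label matrix ([ld_particles()]
#'   `$ld_labels`).
#' @param mito_mask logical mitochondria mask.
#' @param contacts a [extract_contacts()] result.
#' @param image_id identifier carried into every row.
#' @param pixel_size_um pixel edge in micrometres.
#' @return data.frame, one row per cell.
#' @export
assemble_records <- function(partition, ld_labels, mito_mask, contacts,
                             image_id, pixel_size_um) {
  cells <- partition$cells
  n_cells <- partition$n_cells
  s2 <- pixel_size_um^2
  cell_morph <- region_morphometry(cells, pixel_size_um)
  ld_morph <- region_morphometry(ld_labels, pixel_size_um)
  ld_cell <- assign_by_majority(ld_labels, cells)
  if (any(ld_cell == 0) && length(ld_cell))
    message(sum(ld_cell == 0), " lipid droplet(s) outside all cells (unassigned)")
  ctab <- contacts$table
  rows <- lapply(seq_len(n_cells), function(l) {
    in_cell <- cells == l
    lds <- which(ld_cell == l)
    ldm <- ld_morph[match(lds, ld_morph$label), , drop = FALSE]
    mito_in <- mito_mask & in_cell
    mito_lab <- label_components(mito_in, 4)
    mito_morph <- region_morphometry(mito_lab, pixel_size_um)
    cc <- ctab[ctab$cell_label == l, , drop = FALSE]
    n_ld <- length(lds)
    ld_tot_per <- if (n_ld) sum(ldm$perimeter_um) else 0
    tot_len <- sum(cc$length_um)
    data.frame(
      image_id = image_id,
      cell_label = l,
      border_cell = partition$border_cell[l],
      cell_area_um2 = cell_morph$area_um2[match(l, cell_morph$label)],
      n_ld = n_ld,
      n_mito = max(mito_lab),
      ld_total_area_um2 = if (n_ld) sum(ldm$area_um2) else 0,
      mito_total_area_um2 = sum(mito_in) * s2,
      ld_mean_area_um2 = if (n_ld) mean(ldm$area_um2) else NaN,
      ld_area_sd_um2 = if (n_ld >= 2) sd(ldm$area_um2) else
        if (n_ld == 1) 0 else NaN,
      ld_mean_perimeter_um = if (n_ld) mean(ldm$perimeter_um) else NaN,
      ld_total_perimeter_um = ld_tot_per,
      mito_total_perimeter_um = sum(mito_morph$perimeter_um),
      contact_total_length_um = tot_len,
      contact_mean_length_um = if (nrow(cc)) tot_len / nrow(cc) else 0,
      n_contacts = nrow(cc),
      contact_efficiency = if (ld_tot_per > 0) tot_len / ld_tot_per else NaN)
  })
  if (length(rows)) do.call(rbind, rows) else data.frame(
    image_id = character(0), cell_label = integer(0),
    border_cell = logical(0), cell_area_um2 = numeric(0), n_ld = integer(0),
    n_mito = integer(0), ld_total_area_um2 = numeric(0),
    mito_total_area_um2 = numeric(0), ld_mean_area_um2 = numeric(0),
    ld_area_sd_um2 = numeric(0), ld_mean_perimeter_um = numeric(0),
    ld_total_perimeter_um = numeric(0), mito_total_perimeter_um = numeric(0),
    contact_total_length_um = numeric(0), contact_mean_length_um = numeric(0),
    n_contacts = integer(0), contact_efficiency = numeric(0))
}
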