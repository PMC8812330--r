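#' Analysis configuration
#'
#' All tunable parameters of the batch pipeline, recorded verbatim in
#' the run log. Defaults are the published operating point: compensation
#' 0.2 per cytoplasmic channel, maxima prominence 100, Yen/Otsu/Huang
#' thresholds for LD/mitochondria/cell-mask, colocalization ratio 50%.
#'
#' @param channel_order roles of TIFF planes 1..3.
#' @param compensation named cytoplasmic compensation factors.
#' @param prominence maxima prominence for cell seeding.
#' @param ld_threshold_method,mito_threshold_method,cell_threshold_method
#'   auto-threshold names.
#' @param ratio_percent colocalization intensity-ratio cutoff.
#' @param min_cell_area_um2 particle-analysis area floor for cells.
#' @param pixel_size_um optional calibration override for all images.
#' @param model_dir optional LD classifier directory
#'   ([write_ld_model()]); without it the Yen fallback segments LDs.
#' @param seed seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return Named list of class `contactj_config`.
#' @export
contactj_config <- function(channel_order = c("nucleus", "ld", "mito"),
                            compensation = c(ld = 0.2, mito = 0.2),
                            prominence = 100,
                            ld_threshold_method = "yen",
                            mito_threshold_method = "otsu",
                            cell_threshold_method = "huang",
                            ratio_percent = 50,
                            min_cell_area_um2 = 50,
                            pixel_size_um = NULL,
                            model_dir = NULL,
                            seed = 1) {
  structure(as.list(environment()), class = "contactj_config")
}

#' Analyse one channel stack
#'
#' Runs the full workflow on a single image: cell individualization,
#' LD segmentation (classifier or Yen fallback), mitochondria Otsu
#' mask, colocalization, per-LD contact extraction, and the per-cell
#' results table.
#'
#' @param stack a [channel_stack].
#' @param config a [contactj_config()].
#' @param model optional `ld_classifier` (overrides `config$model_dir`).
#' @param image_id identifier for the results table (defaults to the
#'   stack's source path).
#' @return List of class `contactj_analysis`: `cells`
#'   ([individualize_cells()] result), `ld` ([ld_particles()] result),
#'   `mito_mask`, `coloc`, `contacts` ([extract_contacts()] result),
#'   `records` (per-cell data.frame), `image_id`.
#' @export
analyze_stack <- function(stack, config = contactj_config(), model = NULL,
                          image_id = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.null(image_id))
    image_id <- if (is.na(stack$source_path)) "image"
                else sub("\\.[^.]*$", "", basename(stack$source_path))
  if (is.null(model) && !is.null(config$model_dir))
    model <- read_ld_model(config$model_dir)
  cells <- individualize_cells(stack, prominence = config$prominence,
                               compensation = config$compensation,
                               min_cell_area_um2 = config$min_cell_area_um2)
  ld_mask <- segment_ld(stack$planes$ld, model, bit_depth = stack$bit_depth)
  ld <- ld_particles(ld_mask)
  mito8 <- to_8bit(stack$planes$mito, stack$bit_depth)
  hm <- histogram256(mito8)
  mito_mask <- if (sum(hm$counts > 0) < 2) {
    warning("degenerate mitochondria histogram; empty mask")
    matrix(FALSE, nrow(mito8), ncol(mito8))
  } else mito8 > otsu_threshold(hm)
  params <- colocalization_params(config$ld_threshold_method,
                                  config$mito_threshold_method,
                                  config$ratio_percent)
  coloc <- colocalization_mask(stack$planes$ld, stack$planes$mito, params,
                               bit_depth = stack$bit_depth)
  contacts <- extract_contacts(coloc, ld, cells$cells, stack$pixel_size_um)
  records <- assemble_records(cells, ld$ld_labels, mito_mask, contacts,
                              image_id, stack$pixel_size_um)
  structure(list(cells = cells, ld = ld, mito_mask = mito_mask,
                 coloc = coloc, contacts = contacts, records = records,
                 image_id = image_id),
            class = "contactj_analysis")
}

#' @export
print.contactj_analysis <- function(x, ...) {
  cat(sprintf(
    "contactj_analysis '%s': %d cell(s), %d LD(s), %d contact(s), total %.3f um\n",
    x$image_id, x$cells$n_cells, x$ld$n_ld, nrow(x$contacts$table),
    sum(x$contacts$table$length_um)))
  invisible(x)
}

#' Batch analysis of an image folder
#'
#' Processes every TIFF in `input_dir` through [analyze_stack()],
#' accumulating one results table (one row per cell, with image
#' identifiers for traceability), writing per-image label maps and the
#' per-contact table, and a JSON run log of all parameters. Unreadable
#' images are logged and skipped; an empty folder is an error. With a
#' fixed configuration the results table is byte-identical across
#' reruns.
#'
#' @param input_dir folder of TIFF images.
#' @param output_dir results folder (created).
#' @param config a [contactj_config()].
#' @return Invisibly, the combined per-cell data.frame.
#' @export
run_batch <- function(input_dir, output_dir, config = contactj_config()) {
  files <- sort(list.files(input_dir, pattern = "\\.tiff?$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0)
    stop("no TIFF images found in ", input_dir)
  model <- if (!is.null(config$model_dir)) read_ld_model(config$model_dir)
  all_records <- list(); all_contacts <- list(); label_maps <- list()
  skipped <- character(0)
  for (f in files) {
    res <- tryCatch({
      stack <- read_stack(f, channel_order = config$channel_order,
                          pixel_size_um = config$pixel_size_um)
      analyze_stack(stack, config, model = model)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { skipped <- c(skipped, basename(f)); next }
    all_records[[res$image_id]] <- res$records
    ctab <- res$contacts$table
    if (nrow(ctab)) ctab <- cbind(image_id = res$image_id, ctab)
    all_contacts[[res$image_id]] <- ctab
    label_maps[[res$image_id]] <- list(
      cells = res$cells$cells, ld = res$ld$ld_labels,
      mito = matrix(as.integer(res$mito_mask), nrow(res$mito_mask)),
      contacts = matrix(as.integer(res$contacts$skeleton),
                        nrow(res$contacts$skeleton)))
  }
  if (length(all_records) == 0)
    stop("no image in ", input_dir, " could be analysed")
  records <- do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  contacts <- do.call(rbind, c(all_contacts[vapply(all_contacts, nrow,
                                                   integer(1)) > 0],
                               list(make.row.names = FALSE)))
  if (is.null(contacts))
    contacts <- data.frame(image_id = character(0), contact = integer(0),
                           cell_label = integer(0), ld_label = integer(0),
                           length_um = numeric(0), n_pixels = integer(0))
  write_results(records, output_dir, label_maps = label_maps,
                contacts = contacts,
                params = c(unclass(config)[!vapply(unclass(config), is.null,
                                                   logical(1))],
                           list(n_images = length(files),
                                skipped = skipped)))
  invisible(records)
}
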