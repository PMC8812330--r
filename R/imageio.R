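#' Calibrated multi-channel image stack
#'
#' Container for one confocal section with nucleus, lipid-droplet and
#' mitochondria planes plus the pixel calibration. Planes are numeric
#' matrices of nonnegative integers in `[0, 2^bit_depth - 1]`, all of the
#' same size; indices are 1-based `(row, col)`.
#'
#' @param nucleus,ld,mito 2D intensity matrices of identical dimensions.
#' @param bit_depth one of 8, 12, 16.
#' @param pixel_size_um positive pixel edge length in micrometres.
#' @param source_path provenance string (file of origin), or `NA`.
#' @return An object of class `channel_stack` with elements `planes`
#'   (named list `nucleus`, `ld`, `mito`), `bit_depth`, `pixel_size_um`
#'   and `source_path`.
#' @export
channel_stack <- function(nucleus, ld, mito, bit_depth = 16,
                          pixel_size_um = 0.093, source_path = NA_character_) {
  planes <- list(nucleus = nucleus, ld = ld, mito = mito)
  dims <- lapply(planes, dim)
  if (!all(vapply(planes, is.matrix, logical(1))))
    stop("all channel planes must be 2D matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("channel planes differ in size")
  if (!bit_depth %in% c(8, 12, 16)) stop("bit_depth must be 8, 12 or 16")
  maxv <- 2^bit_depth - 1
  for (p in planes) {
    if (anyNA(p) || min(p) < 0 || max(p) > maxv)
      stop("intensities must lie in [0, 2^bit_depth - 1]")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(planes = planes, bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um,
                 source_path = source_path),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("channel_stack: %d x %d px, %d-bit, pixel %.4g um (%s)\n",
              d[1], d[2], x$bit_depth, x$pixel_size_um,
              ifelse(is.na(x$source_path), "in memory", x$source_path)))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$planes[[1]])

# pixel size from TIFF tags: resolution unit "cm"/"inch" converts directly;
# unitless resolution (ImageJ convention) is taken as pixels per micrometre
pixel_size_from_info <- function(info) {
  xres <- info$x.resolution
  if (is.null(xres) || length(xres) == 0 || is.na(xres) || xres <= 0)
    return(NULL)
  unit <- info$resolution.unit
  if (is.null(unit) || is.na(unit) || identical(unit, "none")) return(1 / xres)
  if (identical(unit, "cm")) return(1e4 / xres)
  if (identical(unit, "inch")) return(25400 / xres)
  NULL
}

#' Read a multi-channel TIFF as a channel stack
#'
#' Reads a single-section TIFF with at least three planes (or one RGB
#' image) and splits the planes by channel role. The pixel size is taken
#' from the `pixel_size_um` argument if given, else from the TIFF
#' resolution tags, else the default confocal calibration of 0.093 um is
#' used with a warning.
#'
#' @param path TIFF file.
#' @param channel_order roles of planes 1..3, a permutation of
#'   `c("nucleus", "ld", "mito")`.
#' @param pixel_size_um optional calibration override (um per pixel).
#' @return A [channel_stack].
#' @export
read_stack <- function(path, channel_order = c("nucleus", "ld", "mito"),
                       pixel_size_um = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                   error = function(e) stop("cannot read image file: ", path,
                                            " (", conditionMessage(e), ")"))
  if (!is.list(imgs)) imgs <- list(imgs)
  if (length(imgs) == 1 && length(dim(imgs[[1]])) == 3) {
    a <- imgs[[1]]                      # RGB(A) image: split channels
    if (dim(a)[3] < 3) stop("format error: fewer than 3 planes in ", path)
    imgs <- lapply(1:3, function(k) {
      at <- attributes(a)
      m <- a[, , k]
      for (nm in setdiff(names(at), c("dim", "dimnames"))) attr(m, nm) <- at[[nm]]
      m
    })
  }
  if (length(imgs) < 3) stop("format error: fewer than 3 planes in ", path)
  if (any(vapply(imgs[1:3], function(m) length(dim(m)) != 2, logical(1))))
    stop("format error: non-2D planes (3D/time series not supported)")
  if (!setequal(channel_order, c("nucleus", "ld", "mito")) ||
      length(channel_order) != 3)
    stop("channel_order must be a permutation of nucleus, ld, mito")
  info <- attributes(imgs[[1]])
  bits <- info$bits.per.sample
  if (is.null(bits) || is.na(bits)) {
    mx <- max(vapply(imgs[1:3], max, numeric(1)))
    bits <- if (mx > 4095) 16 else if (mx > 255) 12 else 8
  }
  if (!bits %in% c(8, 12, 16)) bits <- 16
  # readTIFF(as.is = TRUE) returns integer sample values already
  planes <- setNames(lapply(imgs[1:3], function(m) {
    m <- unclass(m); attributes(m) <- list(dim = dim(m)); m
  }), channel_order)
  ps <- pixel_size_um
  if (is.null(ps)) ps <- pixel_size_from_info(info)
  if (is.null(ps)) {
    ps <- 0.093
    warning("no pixel-size calibration found in ", basename(path),
            "; using default 0.093 um/px")
  }
  channel_stack(planes$nucleus, planes$ld, planes$mito, bit_depth = bits,
                pixel_size_um = ps, source_path = path)
}

#' Write a channel stack to a multi-page TIFF
#'
#' Planes are written in nucleus, ld, mito order. 12-bit data is stored in
#' 16-bit samples. Integer data round-trips losslessly through
#' [read_stack()] (the calibration must then be re-supplied, as TIFF
#' resolution tags are not written).
#'
#' @param stack a [channel_stack].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  store_bits <- if (stack$bit_depth == 8) 8L else 16L
  denom <- 2^store_bits - 1
  tiff::writeTIFF(lapply(stack$planes, function(p) p / denom), path,
                  bits.per.sample = store_bits, compression = "none")
  invisible(path)
}

#' Convert an intensity plane to 8-bit
#'
#' Linear display-range conversion: the plane's `[min, max]` is mapped onto
#' `[0, 255]` with round-half-up. A plane already at 8-bit depth is
#' returned unchanged; a constant plane maps to all zeros.
#'
#' @param plane 2D intensity matrix.
#' @param bit_depth native bit depth of the plane.
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
to_8bit <- function(plane, bit_depth = 16) {
  if (bit_depth == 8) return(plane)
  lo <- min(plane); hi <- max(plane)
  if (hi == lo) return(matrix(0, nrow(plane), ncol(plane)))
  round_half_up((plane - lo) * 255 / (hi - lo))
}

#' Disk-kernel median filter
#'
#' Each pixel is replaced by the median over the circular neighbourhood
#' `{(dy, dx): dy^2 + dx^2 <= radius^2}` (the ImageJ rank-filter kernel;
#' radius 2 uses 13 pixels). Edges are handled by nearest-pixel extension.
#'
#' @param plane 2D matrix.
#' @param radius kernel radius in pixels, `>= 1`.
#' @return Filtered matrix.
#' @export
median_filter <- function(plane, radius = 2) {
  if (!is.numeric(radius) || radius < 1) stop("radius must be >= 1")
  cpp_median_disk(plane, radius)
}

#' Flatten a stack to a single 8-bit plane
#'
#' Reproduces the RGB-then-8-bit flattening used ahead of the whole-cell
#' threshold: each channel is converted to 8-bit and the per-pixel
#' unweighted mean (R + G + B)/3 is taken, rounded half up.
#'
#' @param stack a [channel_stack].
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
flatten_to_8bit <- function(stack) {
  p8 <- lapply(stack$planes, to_8bit, bit_depth = stack$bit_depth)
  round_half_up((p8$nucleus + p8$ld + p8$mito) / 3)
}

#' Write per-cell results, label maps and a run log
#'
#' Writes `results.txt` (tab-separated, one row per cell, decimal point
#' "."), `contacts.csv` when per-contact tables are supplied, one 16-bit
#' label-map TIFF per image and map, and `run_log.json` with all
#' parameters, so that every number is traceable to its image and cell.
#'
#' @param records data.frame of per-cell records ([assemble_records()]).
#' @param out_dir output directory (created if absent).
#' @param label_maps optional named list (per image) of named lists of
#'   integer label matrices, e.g. `list(img1 = list(cells = m, ...))`.
#' @param contacts optional data.frame of per-contact rows.
#' @param params optional named list of run parameters for the log.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(records, out_dir, label_maps = NULL,
                          contacts = NULL, params = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to directory: ", out_dir)
  write.table(records, file.path(out_dir, "results.txt"), sep = "\t",
              quote = FALSE, row.names = FALSE, dec = ".")
  if (!is.null(contacts))
    write.table(contacts, file.path(out_dir, "contacts.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
  for (img in names(label_maps)) {
    maps <- label_maps[[img]]
    for (nm in names(maps)) {
      m <- maps[[nm]]
      tiff::writeTIFF(pmin(m, 65535) / 65535,
                      file.path(out_dir, paste0(img, "_", nm, ".tif")),
                      bits.per.sample = 16L, compression = "none")
    }
  }
  log <- list(written = format(Sys.time(), tz = "UTC"), parameters = params,
              n_records = nrow(records))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
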