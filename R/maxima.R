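#' Prominence-based local maxima
#'
#' Detects one representative pixel per local maximum whose height above
#' the highest saddle connecting it to strictly higher ground exceeds
#' `prominence` (ImageJ Find Maxima noise-tolerance semantics, with
#' 8-connected peak detection). Plateaus yield a single representative,
#' the lexicographically smallest `(row, col)` pixel; a constant image
#' yields exactly one peak.
#'
#' @param plane 2D numeric matrix.
#' @param prominence positive intensity difference.
#' @return Integer matrix with one `(row, col)` pair per peak (1-based),
#'   ordered top-left first.
#' @export
find_maxima <- function(plane, prominence = 100) {
  if (!is.numeric(prominence) || prominence <= 0)
    stop("prominence must be > 0")
  p <- cpp_find_maxima(plane, prominence)
  colnames(p) <- c("row", "col")
  p
}

#' Segmented-particles partition of an intensity landscape
#'
#' Partitions the image into one region per detected maximum by
#' watershed-style flooding on the descending landscape: regions grow
#' from the peaks in order of decreasing intensity (ties resolved in
#' `(row, col)` order, so the partition is bit-reproducible), and
#' one-pixel-wide ridge lines ("limits", label 0) separate adjacent
#' regions. Regions are 4-connected and every non-limit pixel is
#' assigned.
#'
#' @inheritParams find_maxima
#' @return Object of class `maxima_result`: list with `peaks` (as
#'   [find_maxima()]), `particles` (integer label matrix, 0 on limits)
#'   and `limits` (logical ridge mask).
#' @export
segmented_particles <- function(plane, prominence = 100) {
  peaks <- find_maxima(plane, prominence)
  particles <- cpp_flood_particles(plane, peaks)
  structure(list(peaks = peaks, particles = particles,
                 limits = particles == 0L),
            class = "maxima_result")
}

#' @export
print.maxima_result <- function(x, ...) {
  cat(sprintf("maxima_result: %d peak(s), %d x %d px, %d limit pixel(s)\n",
              nrow(x$peaks), nrow(x$particles), ncol(x$particles),
              sum(x$limits)))
  invisible(x)
}

#' Connected-component labelling
#'
#' Labels foreground components in raster order (top-left component gets
#' label 1).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix, 0 = background.
#' @export
label_components <- function(mask, connectivity = 4) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  storage.mode(mask) <- "logical"
  cpp_label(mask, as.integer(connectivity))
}
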