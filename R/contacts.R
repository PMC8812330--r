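#' Colocalization parameters
#'
#' @param ld_threshold_method auto-threshold for the LD channel
#'   (default `"yen"`).
#' @param mito_threshold_method auto-threshold for the mitochondria
#'   channel (default `"otsu"`).
#' @param ratio_percent intensity-ratio cutoff in `[0, 100]`
#'   (default 50).
#' @return Named list of class `coloc_params`.
#' @export
colocalization_params <- function(ld_threshold_method = "yen",
                                  mito_threshold_method = "otsu",
                                  ratio_percent = 50) {
  if (ratio_percent < 0 || ratio_percent > 100)
    stop("ratio_percent must be in [0, 100]")
  structure(list(ld_threshold_method = ld_threshold_method,
                 mito_threshold_method = mito_threshold_method,
                 ratio_percent = ratio_percent),
            class = "coloc_params")
}

#' Colocalization mask of the LD and mitochondria channels
#'
#' Both planes are 8-bit-converted and auto-thresholded (Yen for LD,
#' Otsu for mitochondria by default). A pixel is colocalized iff both
#' intensities are strictly above their channel thresholds and the
#' symmetric intensity ratio `100 * min(I_ld, I_mito) / max(I_ld,
#' I_mito)` is strictly above `ratio_percent`.
#'
#' @param ld_plane,mito_plane 2D intensity matrices of the same size.
#' @param params a [colocalization_params()].
#' @param bit_depth native bit depth of the planes.
#' @return Logical colocalization mask.
#' @export
colocalization_mask <- function(ld_plane, mito_plane,
                                params = colocalization_params(),
                                bit_depth = 16) {
  if (!all(dim(ld_plane) == dim(mito_plane)))
    stop("planes must have the same shape")
  ld8 <- to_8bit(ld_plane, bit_depth)
  mito8 <- to_8bit(mito_plane, bit_depth)
  hl <- histogram256(ld8); hm <- histogram256(mito8)
  if (sum(hl$counts > 0) < 2 || sum(hm$counts > 0) < 2) {
    warning("degenerate channel histogram; empty colocalization mask")
    return(matrix(FALSE, nrow(ld_plane), ncol(ld_plane)))
  }
  t_ld <- switch(params$ld_threshold_method, otsu = otsu_threshold(hl),
                 yen = yen_threshold(hl), huang = huang_threshold(hl),
                 stop("unknown threshold method"))
  t_mito <- switch(params$mito_threshold_method, otsu = otsu_threshold(hm),
                   yen = yen_threshold(hm), huang = huang_threshold(hm),
                   stop("unknown threshold method"))
  mx <- pmax(ld8, mito8)
  ratio <- ifelse(mx > 0, 100 * pmin(ld8, mito8) / mx, 0)
  ld8 > t_ld & mito8 > t_mito & ratio > params$ratio_percent
}

#' Individualize lipid droplets from the LD mask
#'
#' The Euclidean distance transform of the LD mask is used as the
#' landscape for [segmented_particles()], so that touching droplets are
#' split along the neck between their distance maxima (the behaviour of
#' a segmented-particles run on a binary image). Particle regions
#' restricted to the mask define the individual droplets.
#'
#' @param ld_mask logical LD mask.
#' @param prominence prominence on the distance transform (default 0.5,
#'   the binary-image convention).
#' @return List of class `ld_result`: `ld_labels` (labels 1..n inside
#'   the mask), `n_ld`, `particles` (full-image partition used for
#'   contact ownership), `limits`, `peaks`, `mask`.
#' @export
ld_particles <- function(ld_mask, prominence = 0.5) {
  storage.mode(ld_mask) <- "logical"
  if (!any(ld_mask)) {
    z <- matrix(0L, nrow(ld_mask), ncol(ld_mask))
    return(structure(list(ld_labels = z, n_ld = 0L, particles = z,
                          limits = matrix(FALSE, nrow(ld_mask), ncol(ld_mask)),
                          peaks = matrix(integer(0), 0, 2), mask = ld_mask,
                          particle_to_ld = integer(0)),
                     class = "ld_result"))
  }
  edt <- as.matrix(EBImage::distmap(ld_mask * 1))
  sp <- segmented_particles(edt, prominence)
  ld <- sp$particles
  ld[!ld_mask] <- 0L
  present <- sort(unique(ld[ld > 0]))
  remap <- integer(max(sp$particles))
  remap[present] <- seq_along(present)
  pos <- ld > 0
  ld[pos] <- remap[ld[pos]]
  structure(list(ld_labels = ld, n_ld = length(present),
                 particles = sp$particles, limits = sp$limits,
                 peaks = sp$peaks, mask = ld_mask, particle_to_ld = remap),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("ld_result: %d lipid droplet(s), %d mask px\n",
              x$n_ld, sum(x$mask)))
  invisible(x)
}

# total path length (in pixel steps) of one 8-connected skeleton
# component: minimum-spanning-tree weight over pixel adjacencies with
# orthogonal steps 1 and diagonal steps sqrt(2); a single pixel is 1.
skeleton_component_length <- function(px) {
  n <- nrow(px)
  if (n == 1) return(1)
  edges <- NULL; weights <- NULL
  key <- px[, 1] * 1e6 + px[, 2]
  idx <- seq_len(n)
  lookup <- new.env(hash = TRUE, size = n)
  for (k in idx) assign(as.character(key[k]), k, envir = lookup)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in idx) {
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      nb <- as.character((px[k, 1] + d[1]) * 1e6 + (px[k, 2] + d[2]))
      j <- mget(nb, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) {
        from <- c(from, k); to <- c(to, j)
        w <- c(w, if (all(d != 0)) sqrt(2) else 1)
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = idx))
  igraph::E(g)$weight <- w
  sum(igraph::E(igraph::mst(g))$weight)
}

#' Extract linear contact sites
#'
#' The colocalization mask is split per lipid droplet by removing the LD
#' segmented-particles limit pixels (the minimum-image operation), each
#' piece is thinned to a one-pixel-wide 8-connected curve (Zhang-Suen),
#' and each connected skeleton component becomes one contact site. The
#' calibrated length counts traced steps: orthogonal steps contribute
#' `s`, diagonal steps `s * sqrt(2)` (`s` = pixel size); an isolated
#' single-pixel skeleton has length `s`. Each contact is assigned to the
#' lipid droplet of its particles region and to exactly one cell by
#' majority pixel overlap (ties to the lower label).
#'
#' @param coloc logical colocalization mask.
#' @param ld_result an [ld_particles()] result.
#' @param cells integer cell label matrix (0 = no cell).
#' @param pixel_size_um pixel edge in micrometres.
#' @return Object of class `contact_set`: list with `sites` (list of
#'   `contact_site` objects: `pixels`, `length_um`, `ld_label`,
#'   `cell_label`) and `table` (one row per contact).
#' @export
extract_contacts <- function(coloc, ld_result, cells, pixel_size_um) {
  stopifnot(all(dim(coloc) == dim(cells)))
  m <- coloc & !ld_result$limits
  skel <- cpp_thin(m)
  comp <- cpp_label(skel, 8L)
  n <- max(comp)
  sites <- list()
  if (n > 0) {
    cidx <- which(comp > 0, arr.ind = TRUE)
    clab <- comp[comp > 0]
    ord <- order(clab, cidx[, 1], cidx[, 2])
    cidx <- cidx[ord, , drop = FALSE]; clab <- clab[ord]
    majority <- function(v) {
      u <- sort(unique(as.integer(v)))
      counts <- vapply(u, function(x) sum(v == x), integer(1))
      u[which.max(counts)]                   # ties: lower label
    }
    for (k in seq_len(n)) {
      px <- cidx[clab == k, , drop = FALSE]
      len <- skeleton_component_length(px) * pixel_size_um
      part <- majority(ld_result$particles[px])
      ld_lab <- if (part > 0 && part <= length(ld_result$particle_to_ld))
        ld_result$particle_to_ld[part] else 0L
      cell_lab <- majority(cells[px])
      sites[[k]] <- structure(
        list(pixels = px, length_um = len, ld_label = ld_lab,
             cell_label = cell_lab),
        class = "contact_site")
    }
  }
  tab <- if (length(sites)) data.frame(
    contact = seq_along(sites),
    cell_label = vapply(sites, `[[`, integer(1), "cell_label"),
    ld_label = vapply(sites, `[[`, integer(1), "ld_label"),
    length_um = vapply(sites, `[[`, numeric(1), "length_um"),
    n_pixels = vapply(sites, function(s) nrow(s$pixels), integer(1)))
  else data.frame(contact = integer(0), cell_label = integer(0),
                  ld_label = integer(0), length_um = numeric(0),
                  n_pixels = integer(0))
  structure(list(sites = sites, table = tab, skeleton = skel),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d contact(s), total length %.3f um\n",
              nrow(x$table), sum(x$table$length_um)))
  invisible(x)
}
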