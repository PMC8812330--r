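#' Synthetic scene specification
#'
#' Describes a calibrated 3-channel scene emulating the target imaging:
#' DAPI-like elliptical nuclei, BODIPY-like disk lipid droplets, and a
#' TOM20-like mitochondria channel of dilated random-walk filaments plus
#' thin annular bands along planted contact arcs on LD boundaries (so LD
#' and mitochondria signal co-occur there above both channel
#' thresholds). Rendering applies a Gaussian PSF, then Poisson shot
#' noise plus Gaussian read noise, then quantization to `bit_depth`.
#'
#' Geometry defaults mirror the acquisition the package targets:
#' 1024 x 1024 frames at 0.093 um/px; cells of radius ~8 um with ~5
#' droplets of radius 1.0-1.4 um each; contact arcs 0.4-2 um. `snr` is
#' the ratio of the brightest structure amplitude to the total noise
#' standard deviation at that amplitude.
#'
#' @param width,height image size in pixels.
#' @param pixel_size_um calibration (default 0.093).
#' @param n_cells number of cells laid out automatically (ignored when
#'   `cells` is given).
#' @param cells optional explicit geometry: list of cells, each a list
#'   with `center` (row, col), `radius_px`, optional `nucleus` (list
#'   `center`, `radii` (2), `angle`), and `lds`, a list of droplets each
#'   with `center`, `radius_px` and `arcs` (list of `c(theta0, theta1)`
#'   in radians, counter-clockwise from the +col axis).
#' @param n_ld_per_cell,ld_radius_um_range auto-layout droplet count and
#'   radius range.
#' @param arc_prob probability an auto-laid droplet carries one contact
#'   arc.
#' @param arc_length_um_range auto-layout arc length range.
#' @param cell_radius_um,nucleus_radii_um auto-layout cell and nucleus
#'   geometry.
#' @param psf_sigma_px Gaussian PSF sigma (1.5 px ~ 140 nm at the
#'   default calibration).
#' @param snr peak signal-to-noise ratio (default 10).
#' @param read_noise_sd Gaussian read-noise SD on the unit intensity
#'   scale.
#' @param bit_depth output bit depth.
#' @param seed RNG seed; the seed fully determines the scene.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1024, height = 1024, pixel_size_um = 0.093,
                       n_cells = 3, cells = NULL, n_ld_per_cell = 5,
                       ld_radius_um_range = c(1.0, 1.4), arc_prob = 0.7,
                       arc_length_um_range = c(0.4, 2.0),
                       cell_radius_um = 8, nucleus_radii_um = c(3.2, 2.5),
                       psf_sigma_px = 1.5, snr = 10, read_noise_sd = 0.01,
                       bit_depth = 16, seed = 1) {
  structure(as.list(environment()), class = "scene_spec")
}

# deterministic auto layout: rejection-sampled non-overlapping cells,
# droplets in the cytoplasmic ring, one optional arc per droplet
layout_scene <- function(spec) {
  if (!is.null(spec$cells)) return(spec$cells)
  s <- spec$pixel_size_um
  rc <- spec$cell_radius_um / s
  margin <- rc + 4
  cells <- list()
  tries <- 0
  while (length(cells) < spec$n_cells && tries < 4000) {
    tries <- tries + 1
    ctr <- c(runif(1, margin, spec$height - margin),
             runif(1, margin, spec$width - margin))
    ok <- all(vapply(cells, function(cl)
      sqrt(sum((cl$center - ctr)^2)) >= 2 * rc + 12, logical(1)))
    if (!ok) next
    nuc <- list(center = ctr, radii = spec$nucleus_radii_um / s,
                angle = runif(1, 0, pi))
    lds <- list()
    ld_tries <- 0
    while (length(lds) < spec$n_ld_per_cell && ld_tries < 400) {
      ld_tries <- ld_tries + 1
      r_ld <- runif(1, spec$ld_radius_um_range[1],
                    spec$ld_radius_um_range[2]) / s
      rmin <- max(nuc$radii) + r_ld + 4
      rmax <- rc - r_ld - 8
      if (rmax <= rmin) break
      rho <- runif(1, rmin, rmax)
      th <- runif(1, 0, 2 * pi)
      pos <- ctr + rho * c(sin(th), cos(th))
      clear <- all(vapply(lds, function(d)
        sqrt(sum((d$center - pos)^2)) >= d$radius_px + r_ld + 8, logical(1)))
      if (!clear) next
      arcs <- list()
      if (runif(1) < spec$arc_prob) {
        len <- runif(1, spec$arc_length_um_range[1],
                     spec$arc_length_um_range[2])
        dth <- len / (r_ld * s)
        th0 <- runif(1, 0, 2 * pi)
        arcs <- list(c(th0, th0 + dth))
      }
      lds[[length(lds) + 1]] <- list(center = pos, radius_px = r_ld,
                                     arcs = arcs)
    }
    cells[[length(cells) + 1]] <- list(center = ctr, radius_px = rc,
                                       nucleus = nuc, lds = lds)
  }
  if (length(cells) < spec$n_cells)
    stop("scene error: could not place ", spec$n_cells,
         " cells inside the image bounds")
  cells
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the three channels described by a [scene_spec()] and returns
#' them as a [channel_stack] together with the pre-noise ground truth:
#' cell/nucleus/LD label maps, the mitochondria mask, and one row per
#' planted contact arc with its analytic length `radius * dtheta *
#' pixel_size`. The output is fully determined by `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return List with `stack` ([channel_stack]) and `truth` (list:
#'   `cells`, `nuclei`, `ld_labels`, `mito_mask`, `contacts` data.frame
#'   with `cell`, `ld`, `theta0`, `theta1`, `length_um`, and `layout`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  s <- spec$pixel_size_um
  cells <- layout_scene(spec)
  ri <- row(matrix(0, H, W)); ci <- col(matrix(0, H, W))

  # amplitudes on the unit scale; the LD channel has nearly no cytosolic
  # background (BODIPY is lipid-specific) while the mitochondria channel
  # carries a dense filament network plus modest out-of-focus haze --
  # this organelle signal is what the summed-channel cell mask rests on
  # the contact band is dimmer than the filament network: a membrane
  # sliver occupies a fraction of the confocal section thickness, while
  # a mitochondrion contributes its full projection
  bg <- 0.02; ld_haze <- 0.025; mito_haze <- 0.05; nuc_haze <- 0.12
  nuc_amp <- 0.85; ld_amp <- 0.9; mito_amp <- 0.8; arc_amp <- 0.80

  nucleus <- matrix(bg, H, W)
  ldp <- matrix(bg, H, W)
  mito <- matrix(bg, H, W)
  cells_lab <- matrix(0L, H, W)
  nuclei <- matrix(FALSE, H, W)
  ld_lab <- matrix(0L, H, W)
  mito_mask <- matrix(FALSE, H, W)
  contacts <- list()
  ld_id <- 0L
  in_bounds <- function(center, radius)
    center[1] - radius >= 1 && center[1] + radius <= H &&
    center[2] - radius >= 1 && center[2] + radius <= W

  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    if (!in_bounds(cl$center, cl$radius_px))
      stop("scene error: cell ", k, " outside image bounds")
    d2 <- (ri - cl$center[1])^2 + (ci - cl$center[2])^2
    in_cell <- d2 <= cl$radius_px^2
    cells_lab[in_cell] <- k
    ldp[in_cell] <- pmax(ldp[in_cell], ld_haze)
    mito[in_cell] <- pmax(mito[in_cell], mito_haze)
    nucleus[in_cell] <- pmax(nucleus[in_cell], nuc_haze)
    nu <- cl$nucleus
    if (!is.null(nu)) {
      ca <- cos(nu$angle); sa <- sin(nu$angle)
      xr <- (ci - nu$center[2]) * ca + (ri - nu$center[1]) * sa
      yr <- -(ci - nu$center[2]) * sa + (ri - nu$center[1]) * ca
      in_nuc <- (xr / nu$radii[1])^2 + (yr / nu$radii[2])^2 <= 1
      nuclei <- nuclei | in_nuc
      nucleus[in_nuc] <- nuc_amp
    }
    # mitochondrial filaments: dilated random walks in the cytoplasm,
    # kept clear of droplet boundaries so only planted arcs touch LDs
    fil <- matrix(FALSE, H, W)
    n_fil <- max(14, round(pi * cl$radius_px^2 / 1400))
    for (f in seq_len(n_fil)) {
      th <- runif(1, 0, 2 * pi)
      rho <- runif(1, max(nu$radii) + 6, cl$radius_px - 6)
      p <- cl$center + rho * c(sin(th), cos(th))
      ang <- runif(1, 0, 2 * pi)
      for (step in 1:80) {
        ang <- ang + rnorm(1, 0, 0.45)
        p2 <- p + 1.6 * c(sin(ang), cos(ang))
        if (sqrt(sum((p2 - cl$center)^2)) > cl$radius_px - 4) break
        ii <- round(p2[1]); jj <- round(p2[2])
        if (ii >= 2 && ii <= H - 1 && jj >= 2 && jj <= W - 1)
          fil[(ii - 1):(ii + 1), (jj - 1):(jj + 1)] <- TRUE
        p <- p2
      }
    }
    for (d in cl$lds) {
      if (!in_bounds(d$center, d$radius_px + 3))
        stop("scene error: droplet outside image bounds")
      ld_id <- ld_id + 1L
      dd2 <- (ri - d$center[1])^2 + (ci - d$center[2])^2
      in_ld <- dd2 <= d$radius_px^2
      ld_lab[in_ld] <- ld_id
      ldp[in_ld] <- ld_amp
      fil[dd2 <= (d$radius_px + 6)^2] <- FALSE   # clear filaments near LD
      for (a in d$arcs) {
        dth <- (a[2] - a[1]) %% (2 * pi)
        if (dth == 0) dth <- 2 * pi
        # contact fluorescence straddles the droplet surface slightly
        # inward (apposed membranes are far below pixel resolution), so
        # LD and mito intensities are comparable along the band and the
        # symmetric ratio criterion holds there
        bw <- 1.0                          # band half-width, px
        rc <- d$radius_px
        band <- abs(sqrt(dd2) - rc) <= bw
        theta <- atan2(ri - d$center[1], ci - d$center[2])
        # rounded end caps (half-width extension per end) so the thinned
        # centreline of the detected band spans the full planted arc
        cap <- 1.5 * bw / rc
        in_arc <- ((theta - (a[1] - cap)) %% (2 * pi)) <= dth + 2 * cap
        mito[band & in_arc] <- arc_amp
        mito_mask[band & in_arc] <- TRUE
        contacts[[length(contacts) + 1]] <-
          data.frame(cell = k, ld = ld_id, theta0 = a[1], theta1 = a[2],
                     length_um = d$radius_px * dth * s)
      }
    }
    mito[fil] <- mito_amp
    mito_mask <- mito_mask | fil
  }

  blur_noise <- function(x) {
    x <- EBImage::gblur(x, sigma = spec$psf_sigma_px)
    amp <- ld_amp
    var_target <- (amp / spec$snr)^2
    var_pois <- max(var_target - spec$read_noise_sd^2, 1e-6)
    P <- amp / var_pois                     # photons at unit intensity
    x <- rpois(length(x), pmax(x, 0) * P) / P
    x <- x + rnorm(length(x), 0, spec$read_noise_sd)
    maxv <- 2^spec$bit_depth - 1
    m <- matrix(round_half_up(pmax(pmin(x, 1.2), 0) / 1.2 * maxv), H, W)
    m
  }
  stack <- channel_stack(blur_noise(nucleus), blur_noise(ldp),
                         blur_noise(mito), bit_depth = spec$bit_depth,
                         pixel_size_um = s, source_path = "synthetic")
  truth <- list(cells = cells_lab, nuclei = nuclei, ld_labels = ld_lab,
                mito_mask = mito_mask,
                contacts = if (length(contacts)) do.call(rbind, contacts)
                else data.frame(cell = integer(0), ld = integer(0),
                                theta0 = numeric(0), theta1 = numeric(0),
                                length_um = numeric(0)),
                layout = cells)
  list(stack = stack, truth = truth)
}
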