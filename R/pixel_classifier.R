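#' Feature configuration for the pixel classifier
#'
#' The feature stack mirrors a Weka-style trainable segmentation: Gaussian
#' blur, Hessian eigenvalues, membrane projections, Sobel gradient
#' magnitude and differences of Gaussians, each over a ladder of scales.
#'
#' @param kinds subset of `"gaussian_blur"`, `"hessian"`,
#'   `"membrane_projections"`, `"sobel"`, `"difference_of_gaussians"`.
#' @param sigmas positive smoothing scales in pixels.
#' @param membrane_size length of the line kernel for membrane
#'   projections (pixels).
#' @param membrane_patch width of the line kernel (pixels).
#' @return Named list of class `feature_config`.
#' @export
feature_config <- function(kinds = c("gaussian_blur", "hessian",
                                     "membrane_projections", "sobel",
                                     "difference_of_gaussians"),
                           sigmas = c(1, 2, 4, 8, 16),
                           membrane_size = 19, membrane_patch = 3) {
  allowed <- c("gaussian_blur", "hessian", "membrane_projections", "sobel",
               "difference_of_gaussians")
  if (!all(kinds %in% allowed))
    stop("unknown feature kind(s): ", paste(setdiff(kinds, allowed), collapse = ", "))
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  structure(list(kinds = kinds, sigmas = sort(sigmas),
                 membrane_size = membrane_size,
                 membrane_patch = membrane_patch),
            class = "feature_config")
}

conv_replicate <- function(x, k) EBImage::filter2(x, k, boundary = "replicate")

# gblur whose kernel never exceeds the plane (small fixtures, large sigma)
gauss_blur <- function(x, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(x))
  if (rmax %% 2 == 0) rmax <- rmax - 1
  EBImage::gblur(x, sigma = sigma, radius = min(r, rmax))
}

sobel_magnitude <- function(x) {
  kx <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3)   # d/drow
  ky <- t(kx)                                           # d/dcol
  sqrt(conv_replicate(x, kx)^2 + conv_replicate(x, ky)^2)
}

hessian_eigen <- function(x) {
  # finite-difference Hessian; large/small eigenvalue planes
  dr <- matrix(c(1, -2, 1), 3, 1)
  dc <- matrix(c(1, -2, 1), 1, 3)
  dxy <- matrix(c(0.25, 0, -0.25, 0, 0, 0, -0.25, 0, 0.25), 3, 3)
  hrr <- conv_replicate(x, dr)
  hcc <- conv_replicate(x, dc)
  hrc <- conv_replicate(x, dxy)
  tr2 <- (hrr + hcc) / 2
  disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
  list(large = tr2 + disc, small = tr2 - disc)
}

membrane_kernels <- function(size = 19, patch = 3, step_deg = 30) {
  half <- (size - 1) / 2
  angles <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  lapply(angles, function(a) {
    d <- matrix(0, size, size)
    for (i in seq_len(size)) for (j in seq_len(size)) {
      y <- i - half - 1; x <- j - half - 1
      perp <- abs(x * cos(a) + y * sin(a))
      par <- abs(-x * sin(a) + y * cos(a))
      if (perp <= patch / 2 && par <= half + 0.5) d[i, j] <- 1
    }
    d
  })
}

#' Compute the per-pixel feature stack
#'
#' @param plane 2D numeric matrix (any intensity scale).
#' @param config a [feature_config()].
#' @return Object of class `feature_stack`: named list of feature planes,
#'   all the size of `plane`, finite everywhere.
#' @export
compute_features <- function(plane, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  feats <- list(original = plane)
  gs <- NULL
  need_gauss <- any(c("gaussian_blur", "sobel", "hessian",
                      "difference_of_gaussians") %in% config$kinds)
  if (need_gauss)
    gs <- lapply(config$sigmas, function(s) gauss_blur(plane, s))
  if ("gaussian_blur" %in% config$kinds)
    for (k in seq_along(config$sigmas))
      feats[[paste0("gaussian_", config$sigmas[k])]] <- gs[[k]]
  if ("difference_of_gaussians" %in% config$kinds) {
    ns <- length(config$sigmas)
    if (ns >= 2)
      for (a in 1:(ns - 1)) for (b in (a + 1):ns)
        feats[[paste0("dog_", config$sigmas[a], "_", config$sigmas[b])]] <-
          gs[[a]] - gs[[b]]
  }
  if ("sobel" %in% config$kinds)
    for (k in seq_along(config$sigmas))
      feats[[paste0("sobel_", config$sigmas[k])]] <- sobel_magnitude(gs[[k]])
  if ("hessian" %in% config$kinds)
    for (k in seq_along(config$sigmas)) {
      he <- hessian_eigen(gs[[k]])
      feats[[paste0("hessian_large_", config$sigmas[k])]] <- he$large
      feats[[paste0("hessian_small_", config$sigmas[k])]] <- he$small
    }
  if ("membrane_projections" %in% config$kinds) {
    ks <- membrane_kernels(config$membrane_size, config$membrane_patch)
    resp <- lapply(ks, function(k) conv_replicate(plane, k))
    arr <- array(unlist(resp), dim = c(dim(plane), length(resp)))
    feats$membrane_sum <- apply(arr, c(1, 2), sum)
    feats$membrane_mean <- feats$membrane_sum / length(resp)
    feats$membrane_sd <- apply(arr, c(1, 2), sd)
    feats$membrane_max <- apply(arr, c(1, 2), max)
    feats$membrane_min <- apply(arr, c(1, 2), min)
    feats$membrane_median <- apply(arr, c(1, 2), median)
  }
  structure(feats, class = "feature_stack")
}

feature_frame <- function(stack) {
  as.data.frame(lapply(unclass(stack), as.vector), optional = TRUE)
}

#' Train the lipid-droplet pixel classifier
#'
#' Fits a random forest (via ranger, single-threaded and seeded, hence
#' bit-reproducible) on per-pixel feature vectors of the labelled pixels.
#'
#' @param stacks list of training images, each a list with `plane` (2D
#'   matrix) and `labels` (logical matrix: `TRUE` = lipid droplet,
#'   `FALSE` = background, `NA` = unlabelled).
#' @param config a [feature_config()].
#' @param n_trees number of trees (default 200).
#' @param seed training RNG seed.
#' @param max_per_class at most this many labelled pixels are sampled per
#'   class per image (keeps training tractable on dense label masks).
#' @return Object of class `ld_classifier` with elements `forest`,
#'   `config`, `classes`, `seed`.
#' @export
train_ld_classifier <- function(stacks, config = feature_config(),
                                n_trees = 200, seed = 1,
                                max_per_class = 5000) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (!is.null(stacks$plane)) stacks <- list(stacks)
  xs <- list(); ys <- list()
  set.seed(seed)
  for (s in stacks) {
    fs <- compute_features(s$plane, config)
    df <- feature_frame(fs)
    lab <- as.vector(s$labels)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(!is.na(lab) & lab == cls)
      if (length(idx) > max_per_class)
        idx <- sort(sample(idx, max_per_class))
      if (length(idx)) {
        xs[[length(xs) + 1]] <- df[idx, , drop = FALSE]
        ys[[length(ys) + 1]] <- rep(ifelse(cls, "ld", "background"),
                                    length(idx))
      }
    }
  }
  y <- factor(unlist(ys), levels = c("background", "ld"))
  if (length(unique(y)) < 2)
    stop("training labels must contain both classes (ld and background)")
  x <- do.call(rbind, xs)
  forest <- ranger::ranger(
    x = x, y = y, num.trees = n_trees,
    mtry = max(1, floor(sqrt(ncol(x)))),
    seed = seed, num.threads = 1, verbose = FALSE)
  structure(list(forest = forest, config = config,
                 classes = c("background", "ld"), seed = seed),
            class = "ld_classifier")
}

#' @export
print.ld_classifier <- function(x, ...) {
  cat(sprintf("ld_classifier: %d trees, %d features, OOB error %.4f\n",
              x$forest$num.trees, x$forest$num.independent.variables,
              x$forest$prediction.error))
  invisible(x)
}

#' Predict the lipid-droplet mask
#'
#' Per-pixel majority vote of the trained forest on the feature stack of
#' `plane`, computed with the model's own feature configuration.
#'
#' @param plane 2D intensity matrix (LD channel).
#' @param model an [train_ld_classifier()] model.
#' @return Logical LD mask.
#' @export
predict_ld_mask <- function(plane, model) {
  if (!inherits(model, "ld_classifier"))
    stop("model must be an ld_classifier")
  df <- feature_frame(compute_features(plane, model$config))
  if (!identical(colnames(df), model$forest$forest$independent.variable.names))
    stop("model error: feature configuration mismatch")
  pred <- predict(model$forest, data = df, num.threads = 1)$predictions
  matrix(pred == "ld", nrow(plane), ncol(plane))
}

#' Save / load a trained LD classifier
#'
#' The model directory holds the forest (`model.rds`, base-R
#' serialization, lossless round-trip) and a `model.json` sidecar
#' recording the feature configuration, classes and training seed.
#'
#' @param model an `ld_classifier`.
#' @param dir model directory (created if needed).
#' @return `dir` (write) or the restored `ld_classifier` (read).
#' @export
write_ld_model <- function(model, dir) {
  stopifnot(inherits(model, "ld_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$forest, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(config = unclass(model$config), classes = model$classes,
         seed = model$seed, n_trees = model$forest$num.trees),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ld_model
#' @export
read_ld_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- feature_config(kinds = meta$config$kinds,
                        sigmas = meta$config$sigmas,
                        membrane_size = meta$config$membrane_size,
                        membrane_patch = meta$config$membrane_patch)
  structure(list(forest = readRDS(file.path(dir, "model.rds")),
                 config = cfg, classes = meta$classes, seed = meta$seed),
            class = "ld_classifier")
}

#' Segment the lipid-droplet channel
#'
#' With a trained model, predicts the LD mask pixel-wise; without one,
#' falls back to Yen auto-thresholding of the LD plane (the same
#' threshold choice the colocalization step uses for this channel).
#'
#' @param plane LD channel plane.
#' @param model optional `ld_classifier`.
#' @param bit_depth native bit depth of `plane` (fallback path only).
#' @return Logical LD mask.
#' @export
segment_ld <- function(plane, model = NULL, bit_depth = 16) {
  if (!is.null(model)) return(predict_ld_mask(plane, model))
  p8 <- to_8bit(plane, bit_depth)
  h <- histogram256(p8)
  if (sum(h$counts > 0) < 2) {
    warning("degenerate LD histogram; empty LD mask")
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  }
  p8 > yen_threshold(h)
}
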