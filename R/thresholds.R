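#' 256-bin intensity histogram
#'
#' All automatic thresholds operate on 256-bin histograms of 8-bit data
#' (higher depths are 8-bit-converted first), matching ImageJ
#' auto-threshold semantics.
#'
#' @param plane8 integer-valued matrix in `[0, 255]` (see [to_8bit()]).
#' @return Object of class `histogram256`: list with `counts` (length
#'   256, bins 0..255) and `total`.
#' @export
histogram256 <- function(plane8) {
  v <- as.vector(plane8)
  if (anyNA(v) || min(v) < 0 || max(v) > 255)
    stop("histogram256 expects values in [0, 255]")
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts)), class = "histogram256")
}

as_hist256 <- function(hist) {
  if (inherits(hist, "histogram256")) return(hist)
  if (is.numeric(hist) && length(hist) == 256)
    return(structure(list(counts = hist, total = sum(hist)),
                     class = "histogram256"))
  if (is.matrix(hist)) return(histogram256(hist))
  stop("expected a histogram256, a 256-long count vector, or an 8-bit plane")
}

check_nondegenerate <- function(h) {
  if (sum(h$counts > 0) < 2)
    stop("degenerate histogram: fewer than 2 populated bins")
}

#' Otsu automatic threshold
#'
#' Returns the level `t` in 0..255 maximizing the between-class variance
#' of the split `{<= t, > t}`; ties are broken by the smallest maximizing
#' level. Foreground is defined throughout the package as strictly
#' greater than the returned level.
#'
#' @param hist a [histogram256()], a 256-long count vector, or an 8-bit
#'   plane.
#' @return Integer threshold level in 0..255.
#' @export
otsu_threshold <- function(hist) {
  h <- as_hist256(hist); check_nondegenerate(h)
  p <- h$counts / h$total
  bins <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * bins)
  mt <- m0[256]
  # between-class variance for split at t = bins 0..254 (both classes nonempty)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  which.max(bcv) - 1L
}

#' Yen automatic threshold
#'
#' Level maximizing Yen's maximum-correlation criterion (Yen, Chang &
#' Chang 1995), in the ImageJ Auto_Threshold formulation; smallest
#' maximizer on ties. Used for the lipid-droplet channel in the
#' colocalization step.
#'
#' @inheritParams otsu_threshold
#' @return Integer threshold level in 0..255.
#' @export
yen_threshold <- function(hist) {
  h <- as_hist256(hist); check_nondegenerate(h)
  p <- h$counts / h$total
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- ifelse(P1sq * P2sq > 0, -log(P1sq * P2sq), 0) +
    2 * ifelse(P1 * (1 - P1) > 0, log(P1 * (1 - P1)), 0)
  which.max(crit) - 1L
}

#' Huang automatic threshold
#'
#' Level minimizing Huang & Wang's fuzzy measure (Shannon entropy of the
#' fuzzy membership, ImageJ Auto_Threshold "Huang" variant); smallest
#' minimizer on ties. Used for the flattened whole-cell mask.
#'
#' @inheritParams otsu_threshold
#' @return Integer threshold level in 0..255.
#' @export
huang_threshold <- function(hist) {
  h <- as_hist256(hist); check_nondegenerate(h)
  counts <- h$counts
  bins <- 0:255
  first <- min(bins[counts > 0]); last <- max(bins[counts > 0])
  term <- 1 / (last - first)
  csum <- cumsum(counts)
  wsum <- cumsum(counts * bins)
  ent <- rep(Inf, 256)
  shannon <- function(mu) {
    s <- numeric(length(mu))
    inz <- mu > 0 & mu < 1
    m <- mu[inz]
    s[inz] <- -m * log(m) - (1 - m) * log(1 - m)
    s
  }
  for (t in first:(last - 1)) {
    k <- t + 1L
    mu0 <- if (csum[k] > 0) wsum[k] / csum[k] else 0
    n1 <- csum[256] - csum[k]
    mu1 <- if (n1 > 0) (wsum[256] - wsum[k]) / n1 else 0
    lo <- first:t; hi <- (t + 1):last
    mul <- 1 / (1 + term * abs(lo - mu0))
    muh <- 1 / (1 + term * abs(hi - mu1))
    ent[k] <- sum(counts[lo + 1L] * shannon(mul)) +
      sum(counts[hi + 1L] * shannon(muh))
  }
  which.min(ent) - 1L
}

#' Apply a threshold level to an intensity plane
#'
#' The plane is 8-bit-converted and foreground is `intensity > level`
#' (strict, the single inequality convention used package-wide).
#'
#' @param plane 2D intensity matrix.
#' @param level threshold level in 0..255.
#' @param bit_depth native bit depth of `plane`.
#' @return Logical foreground mask of the same size.
#' @export
apply_threshold <- function(plane, level, bit_depth = 8) {
  if (level < 0 || level > 255) stop("level must be in [0, 255]")
  to_8bit(plane, bit_depth) > level
}

#' Automatic threshold of a plane by method name
#'
#' @param plane 2D intensity matrix.
#' @param method one of `"otsu"`, `"yen"`, `"huang"`.
#' @param bit_depth native bit depth of `plane`.
#' @return Integer threshold level in 0..255 (of the 8-bit conversion).
#' @export
auto_threshold <- function(plane, method = c("otsu", "yen", "huang"),
                           bit_depth = 8) {
  method <- match.arg(method)
  h <- histogram256(to_8bit(plane, bit_depth))
  switch(method,
         otsu = otsu_threshold(h),
         yen = yen_threshold(h),
         huang = huang_threshold(h))
}
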