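# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, exhaustive searches) so they share no
# code path with the implementation they check.

# exhaustive 256-split Otsu: maximize between-class variance directly
oracle_otsu <- function(counts) {
  tot <- sum(counts)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    n0 <- sum(counts[1:(t + 1)]); n1 <- tot - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:t) * counts[1:(t + 1)]) / n0
    mu1 <- sum(((t + 1):255) * counts[(t + 2):256]) / n1
    v <- (n0 / tot) * (n1 / tot) * (mu0 - mu1)^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

# exhaustive Yen maximum-correlation criterion
oracle_yen <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    p1 <- sum(p[1:(t + 1)])
    p1sq <- sum(p[1:(t + 1)]^2)
    p2sq <- sum(p^2) - p1sq
    crit <- (if (p1sq * p2sq > 0) -log(p1sq * p2sq) else 0) +
      2 * (if (p1 * (1 - p1) > 0) log(p1 * (1 - p1)) else 0)
    if (crit > best) { best <- crit; bt <- t }
  }
  bt
}

# exhaustive Huang fuzzy-entropy minimizer (naive per-threshold recompute)
oracle_huang <- function(counts) {
  bins <- 0:255
  nz <- bins[counts > 0]
  first <- min(nz); last <- max(nz)
  if (first == last) return(NA_integer_)
  term <- 1 / (last - first)
  sh <- function(mu) {
    out <- numeric(length(mu))
    i <- mu > 0 & mu < 1
    out[i] <- -mu[i] * log(mu[i]) - (1 - mu[i]) * log(1 - mu[i])
    out
  }
  best <- Inf; bt <- NA_integer_
  for (t in first:(last - 1)) {
    lo <- first:t; hi <- (t + 1):last
    n0 <- sum(counts[lo + 1]); n1 <- sum(counts[hi + 1])
    mu0 <- if (n0 > 0) sum(lo * counts[lo + 1]) / n0 else 0
    mu1 <- if (n1 > 0) sum(hi * counts[hi + 1]) / n1 else 0
    ent <- sum(counts[lo + 1] * sh(1 / (1 + term * abs(lo - mu0)))) +
      sum(counts[hi + 1] * sh(1 / (1 + term * abs(hi - mu1))))
    if (ent < best) { best <- ent; bt <- t }
  }
  bt
}

# random multimodal 256-bin histogram with at least two populated bins
random_histogram <- function() {
  counts <- integer(256)
  n_modes <- sample(2:4, 1)
  for (m in seq_len(n_modes)) {
    mu <- sample(0:255, 1); sdv <- runif(1, 2, 40)
    v <- round(rnorm(sample(50:500, 1), mu, sdv))
    v <- v[v >= 0 & v <= 255]
    if (length(v)) counts <- counts + tabulate(v + 1L, 256L)
  }
  if (sum(counts > 0) < 2) counts[c(40, 200)] <- counts[c(40, 200)] + 50L
  counts
}

# brute-force disk median filter with nearest-edge extension
oracle_median_disk <- function(x, radius) {
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  r <- floor(radius)
  for (i in 1:nr) for (j in 1:nc) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > radius^2) next
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      vals <- c(vals, x[ii, jj])
    }
    out[i, j] <- median(vals)
  }
  out
}

# saddle height between two pixels: the highest level h such that both
# lie in one connected component of {plane >= h} (binary search over the
# sorted unique levels, flood fill per level)
oracle_saddle <- function(plane, p1, p2) {
  levels <- sort(unique(as.vector(plane)))
  connected_at <- function(h) {
    m <- plane >= h
    if (!m[p1[1], p1[2]] || !m[p2[1], p2[2]]) return(FALSE)
    lab <- contactr::label_components(m, 8)
    lab[p1[1], p1[2]] == lab[p2[1], p2[2]]
  }
  lo <- 1; hi <- length(levels); best <- levels[1]
  for (h in rev(levels)) {          # highest connecting level
    if (connected_at(h)) return(h)
  }
  levels[1]
}

# two-Gaussian-bump fixture with known peaks and tunable saddle
two_bump_plane <- function(n = 41, a1 = 255, a2 = 250, sigma = 4) {
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  c1 <- c((n + 1) / 2, (n + 1) / 4); c2 <- c((n + 1) / 2, 3 * (n + 1) / 4)
  b1 <- a1 * exp(-((i - c1[1])^2 + (j - c1[2])^2) / (2 * sigma^2))
  b2 <- a2 * exp(-((i - c2[1])^2 + (j - c2[2])^2) / (2 * sigma^2))
  pmax(b1, b2)
}
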