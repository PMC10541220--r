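#' Discretize masked intensities into equal-width gray levels
#'
#' Bins the in-mask intensities of a 2D image into `n_bins` equal-width
#' gray levels spanning the masked minimum to maximum. A constant region
#' (zero range) maps wholly to level 1. Pixels outside the mask are `NA`.
#' Discretization is the prerequisite for the GLSZM and for the
#' histogram-based first-order features (entropy, uniformity).
#'
#' @param image numeric 2D matrix of signal intensities.
#' @param mask logical 2D matrix of the same dimensions; must be nonempty.
#' @param n_bins number of gray levels (>= 2); default 32.
#' @return integer matrix of gray levels in `1..n_bins`, `NA` outside mask.
#' @export
discretize <- function(image, mask, n_bins = 32L) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  if (!any(mask)) stop("discretize: mask is empty")
  if (n_bins < 2) stop("discretize: n_bins must be >= 2")
  x <- image[mask]
  lo <- min(x)
  rng <- max(x) - lo
  out <- matrix(NA_integer_, nrow(image), ncol(image))
  if (rng == 0) {
    out[mask] <- 1L
  } else {
    out[mask] <- pmin(as.integer(floor((x - lo) / rng * n_bins)) + 1L,
                      as.integer(n_bins))
  }
  out
}

#' First-order (intensity) radiomic features of a masked region
#'
#' Computes the 19 first-order features of the catalogue from the in-mask
#' intensities. Conventions: variance and standard deviation are population
#' quantities (divide by N); total energy assumes unit pixel area and so
#' equals energy; entropy and uniformity are computed on the equal-width
#' discretized histogram with `n_bins` levels; skewness is the third
#' standardized moment and kurtosis the fourth (Pearson, not excess; a
#' zero-variance region returns 0 for both); percentiles use the default
#' linear-interpolation quantile definition; robust mean absolute
#' deviation is the mean absolute deviation of the values lying within the
#' 10th-90th percentile range, about their own mean.
#'
#' @param image numeric 2D matrix.
#' @param mask logical 2D matrix; at least 2 in-mask pixels.
#' @param n_bins gray levels used for the histogram-based features.
#' @return named numeric vector of length 19 (catalogue order).
#' @export
first_order_features <- function(image, mask, n_bins = 32L) {
  if (sum(mask) < 2) stop("first_order_features: mask must have >= 2 pixels")
  x <- image[mask]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  inr <- x[x >= q[1] & x <= q[4]]
  gl <- discretize(image, mask, n_bins)[mask]
  p <- tabulate(gl, nbins = n_bins) / n
  p <- p[p > 0]
  vals <- c(
    sum(x^2),                       # energy
    sum(x^2),                       # total energy (unit pixel area)
    -sum(p * log2(p)),              # entropy
    min(x),
    q[1],                           # 10th percentile
    q[4],                           # 90th percentile
    max(x),
    mu,
    stats::median(x),
    q[3] - q[2],                    # interquartile range
    max(x) - min(x),
    mean(abs(x - mu)),              # mean absolute deviation
    mean(abs(inr - mean(inr))),     # robust MAD
    sqrt(mean(x^2)),                # root mean squared
    sqrt(m2),                       # population sd
    if (m2 > 0) m3 / m2^1.5 else 0, # skewness
    if (m2 > 0) m4 / m2^2 else 0,   # kurtosis
    m2,                             # population variance
    sum(p^2)                        # uniformity
  )
  setNames(vals, feature_catalogue()$first_order)
}

#' Gray-level size zone matrix of a discretized masked region
#'
#' A zone is a maximal connected component (default 8-connectivity) of
#' in-mask pixels sharing one gray level. The matrix entry `counts[g, s]`
#' is the number of zones of gray level `g` and size `s` pixels.
#'
#' @param graylevels integer 2D matrix of gray levels, `NA` outside mask
#'   (as returned by [discretize()]).
#' @param mask optional logical matrix restricting the region further.
#' @param connectivity 4 or 8 (default 8).
#' @return object of class `zone_matrix`: list with `counts`
#'   (gray level x zone size), `n_gray_levels`, `n_pixels`, `n_zones`.
#' @export
glszm <- function(graylevels, mask = NULL, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  gl <- graylevels
  if (!is.null(mask)) gl[!mask] <- NA_integer_
  if (!any(!is.na(gl))) stop("glszm: no in-mask pixels")
  storage.mode(gl) <- "integer"
  zones <- .glszm_zones_cpp(gl, as.integer(connectivity))
  g_max <- max(zones[, "level"])
  s_max <- max(zones[, "size"])
  counts <- matrix(0L, g_max, s_max,
                   dimnames = list(level = NULL, size = NULL))
  for (i in seq_len(nrow(zones))) {
    counts[zones[i, "level"], zones[i, "size"]] <-
      counts[zones[i, "level"], zones[i, "size"]] + 1L
  }
  structure(list(counts = counts,
                 n_gray_levels = g_max,
                 n_pixels = sum(!is.na(gl)),
                 n_zones = nrow(zones)),
            class = "zone_matrix")
}

#' GLSZM texture features from a zone matrix
#'
#' The 16 size-zone features of the catalogue, computed from the zone
#' matrix by the standard double sums over gray level `g` and zone size
#' `s`; e.g. small-area emphasis is `sum(counts/s^2)/n_zones` and high
#' gray-level zone emphasis is `sum(counts*g^2)/n_zones`. Gray-level and
#' zone variances use the normalized zone distribution `counts/n_zones`;
#' zone entropy is its Shannon entropy in bits.
#'
#' @param zm a `zone_matrix` from [glszm()]; must contain at least 1 zone.
#' @return named numeric vector of length 16 (catalogue order).
#' @export
glszm_features <- function(zm) {
  stopifnot(inherits(zm, "zone_matrix"))
  if (zm$n_zones < 1) stop("glszm_features: zone matrix has no zones")
  P <- zm$counts
  nz <- zm$n_zones
  np <- zm$n_pixels
  g <- seq_len(nrow(P))
  s <- seq_len(ncol(P))
  G <- matrix(g, nrow(P), ncol(P))            # gray level of each cell
  S <- matrix(s, nrow(P), ncol(P), byrow = TRUE) # zone size of each cell
  p <- P / nz
  mu_g <- sum(p * G)
  mu_s <- sum(p * S)
  pnz <- p[p > 0]
  vals <- c(
    sum(P / S^2) / nz,                      # small-area emphasis
    sum(P * S^2) / nz,                      # large-area emphasis
    sum(rowSums(P)^2) / nz,                 # gray-level non-uniformity
    sum(rowSums(P)^2) / nz^2,               # GLN normalized
    sum(colSums(P)^2) / nz,                 # size-zone non-uniformity
    sum(colSums(P)^2) / nz^2,               # SZN normalized
    nz / np,                                # zone percentage
    sum(p * (G - mu_g)^2),                  # gray-level variance
    sum(p * (S - mu_s)^2),                  # zone variance
    -sum(pnz * log2(pnz)),                  # zone entropy
    sum(P / G^2) / nz,                      # low gray-level zone emphasis
    sum(P * G^2) / nz,                      # high gray-level zone emphasis
    sum(P / (G^2 * S^2)) / nz,              # small-area low gray-level
    sum(P * G^2 / S^2) / nz,                # small-area high gray-level
    sum(P * S^2 / G^2) / nz,                # large-area low gray-level
    sum(P * G^2 * S^2) / nz                 # large-area high gray-level
  )
  setNames(vals, feature_catalogue()$glszm)
}

#' All 35 catalogue features of a masked region
#'
#' Convenience wrapper computing the 19 first-order and 16 GLSZM features
#' of one masked 2D region, in catalogue order. This is the per-timestep,
#' per-territory workhorse of the temporal pipeline.
#'
#' @inheritParams first_order_features
#' @param connectivity zone connectivity for the GLSZM (default 8).
#' @return named numeric vector of length 35.
#' @export
compute_region_features <- function(image, mask, n_bins = 32L,
                                    connectivity = 8L) {
  fo <- first_order_features(image, mask, n_bins)
  zm <- glszm(discretize(image, mask, n_bins), connectivity = connectivity)
  c(fo, glszm_features(zm))
}

#' Greedy correlation-based feature pruning
#'
#' Iterates over features in table (catalogue) order and drops any feature
#' whose absolute Pearson correlation with an already-retained feature
#' exceeds `threshold`. Constant columns have undefined correlation, which
#' is treated as 0 (they are never dropped for correlation). Provided for
#' completeness: the default pipeline ships the fixed 35-feature
#' post-pruning catalogue rather than re-running the pruning.
#'
#' @param feature_table numeric matrix or data frame, samples x features,
#'   with column names; at least 2 rows.
#' @param threshold absolute correlation cutoff in `[0, 1]`.
#' @return character vector of retained feature names, in input order.
#' @export
prune_correlated <- function(feature_table, threshold = 0.95) {
  X <- as.matrix(feature_table)
  if (nrow(X) < 2) stop("prune_correlated: need >= 2 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  retained <- integer(0)
  for (j in seq_len(ncol(X))) {
    if (length(retained) == 0) {
      retained <- j
      next
    }
    r <- suppressWarnings(abs(cor(X[, j], X[, retained, drop = FALSE])))
    r[is.na(r)] <- 0  # constant column(s)
    if (all(r <= threshold)) retained <- c(retained, j)
  }
  colnames(X)[retained]
}
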