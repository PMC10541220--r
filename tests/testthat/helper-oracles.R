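# Independent naive-formula oracles for the radiomics features. These are
# written directly from the standard definitions, using plain loops and a
# zone *list* (not a zone matrix), so they share no code path with the
# package implementation.

oracle_discretize_values <- function(x, n_bins) {
  lo <- min(x)
  rng <- max(x) - lo
  if (rng == 0) return(rep(1L, length(x)))
  pmin(floor((x - lo) / rng * n_bins) + 1L, n_bins)
}

oracle_first_order <- function(x, n_bins = 32L) {
  n <- length(x)
  mu <- sum(x) / n
  cmoment <- function(k) sum((x - mu)^k) / n
  m2 <- cmoment(2)
  lev <- oracle_discretize_values(x, n_bins)
  p <- as.numeric(table(lev)) / n
  q10 <- quantile(x, 0.10, names = FALSE)
  q90 <- quantile(x, 0.90, names = FALSE)
  sub <- x[x >= q10 & x <= q90]
  c(fo_energy = sum(x^2),
    fo_total_energy = sum(x^2),
    fo_entropy = -sum(p * log2(p)),
    fo_minimum = min(x),
    fo_p10 = q10,
    fo_p90 = q90,
    fo_maximum = max(x),
    fo_mean = mu,
    fo_median = median(x),
    fo_interquartile_range = quantile(x, 0.75, names = FALSE) -
      quantile(x, 0.25, names = FALSE),
    fo_range = max(x) - min(x),
    fo_mad = sum(abs(x - mu)) / n,
    fo_rmad = sum(abs(sub - mean(sub))) / length(sub),
    fo_rms = sqrt(sum(x^2) / n),
    fo_sd = sqrt(m2),
    fo_skewness = if (m2 > 0) cmoment(3) / m2^(3 / 2) else 0,
    fo_kurtosis = if (m2 > 0) cmoment(4) / m2^2 else 0,
    fo_variance = m2,
    fo_uniformity = sum(p^2))
}

# Brute-force flood-fill zone enumeration: returns a data frame with one
# row per zone (level, size).
oracle_glszm_zones <- function(gl, connectivity = 8L) {
  nr <- nrow(gl); nc <- ncol(gl)
  visited <- matrix(FALSE, nr, nc)
  if (connectivity == 8L) {
    nbr <- expand.grid(dr = -1:1, dc = -1:1)
    nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  } else {
    nbr <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  zones <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (visited[r, c] || is.na(gl[r, c])) next
    lev <- gl[r, c]
    queue <- list(c(r, c))
    visited[r, c] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (i in seq_len(nrow(nbr))) {
        rr <- cur[1] + nbr$dr[i]; cc <- cur[2] + nbr$dc[i]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (visited[rr, cc] || is.na(gl[rr, cc]) || gl[rr, cc] != lev) next
        visited[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  as.data.frame(do.call(rbind, zones))
}

# Zone-matrix counts from the oracle zone list, padded to given dims.
oracle_zone_counts <- function(zones, g_max = max(zones$level),
                               s_max = max(zones$size)) {
  counts <- matrix(0L, g_max, s_max)
  for (i in seq_len(nrow(zones)))
    counts[zones$level[i], zones$size[i]] <-
      counts[zones$level[i], zones$size[i]] + 1L
  counts
}

# All 16 GLSZM features as direct sums over the zone list.
oracle_glszm_features <- function(zones, n_pixels) {
  nz <- nrow(zones)
  g <- zones$level; s <- zones$size
  gln <- sum(as.numeric(table(g))^2)
  szn <- sum(as.numeric(table(s))^2)
  combo <- table(paste(g, s))
  p_combo <- as.numeric(combo) / nz
  mu_g <- mean(g); mu_s <- mean(s)
  c(szm_small_area_emphasis = sum(1 / s^2) / nz,
    szm_large_area_emphasis = sum(s^2) / nz,
    szm_gray_level_nonuniformity = gln / nz,
    szm_gray_level_nonuniformity_norm = gln / nz^2,
    szm_size_zone_nonuniformity = szn / nz,
    szm_size_zone_nonuniformity_norm = szn / nz^2,
    szm_zone_percentage = nz / n_pixels,
    szm_gray_level_variance = mean((g - mu_g)^2),
    szm_zone_variance = mean((s - mu_s)^2),
    szm_zone_entropy = -sum(p_combo * log2(p_combo)),
    szm_low_gray_level_zone_emphasis = sum(1 / g^2) / nz,
    szm_high_gray_level_zone_emphasis = sum(g^2) / nz,
    szm_small_area_low_gray_level_emphasis = sum(1 / (g^2 * s^2)) / nz,
    szm_small_area_high_gray_level_emphasis = sum(g^2 / s^2) / nz,
    szm_large_area_low_gray_level_emphasis = sum(s^2 / g^2) / nz,
    szm_large_area_high_gray_level_emphasis = sum(g^2 * s^2) / nz)
}

# Random masked patch generator for oracle comparisons.
random_patch <- function(side, seed, n_levels = 4) {
  set.seed(seed)
  image <- matrix(runif(side^2), side, side)
  mask <- matrix(runif(side^2) < 0.8, side, side)
  if (sum(mask) < 4) mask[1:4] <- TRUE
  list(image = image, mask = mask)
}
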