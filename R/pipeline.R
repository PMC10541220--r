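#' Min-max normalize an image sequence over all timesteps
#'
#' Subtracts the global (all-frames, in-mask) minimum and divides by the
#' global range, so the in-mask intensities span `[0, 1]` across the whole
#' sequence; normalizing across timesteps rather than per frame preserves
#' the contrast-enhancement effect. A constant sequence maps to all zeros.
#'
#' @param stack numeric array `[y, x, time]` with at least 2 frames.
#' @param mask logical matrix defining the region whose min/max are used.
#' @return array of the same shape, normalized.
#' @export
normalize_image_sequence <- function(stack, mask) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 2)
  vals <- stack[rep(mask, dim(stack)[3])]
  lo <- min(vals)
  rng <- max(vals) - lo
  if (rng == 0) return(array(0, dim(stack)))
  (stack - lo) / rng
}

#' Arterial input function from a blood-pool mask
#'
#' Mean in-mask signal intensity per frame: the blood-pool enhancement
#' curve used to locate and crop the first-pass window.
#'
#' @param stack numeric array `[y, x, time]`.
#' @param blood_pool_mask logical matrix; must be nonempty.
#' @return numeric vector of length `T`.
#' @export
compute_aif <- function(stack, blood_pool_mask) {
  if (!any(blood_pool_mask)) stop("compute_aif: empty blood-pool mask")
  apply(stack, 3, function(fr) mean(fr[blood_pool_mask]))
}

#' Crop an AIF curve to the first-pass window
#'
#' Locates the first-pass bolus on the arterial input function and
#' returns a half-open frame window containing the first signal-intensity
#' peak and the cycles immediately either side. The baseline is the mean
#' of the first 3 frames; the peak `p` is the first local maximum
#' exceeding baseline + 50% of (global max - baseline); the window foot
#' is the last pre-peak frame at or below baseline + 10% of the
#' peak-above-baseline, and the window end is the first post-peak local
#' minimum (or the first frame falling back below the foot threshold,
#' whichever comes first). Both ends are then extended by `guard_frames`
#' and clipped to the sequence.
#'
#' @param aif numeric AIF curve; must contain an interior first-pass peak.
#' @param guard_frames extra frames either side of the detected support.
#' @return integer vector `c(start, end)`, a half-open window: the frames
#'   used are `start .. end - 1`.
#' @export
crop_first_pass <- function(aif, guard_frames = 1L) {
  n <- length(aif)
  if (n < 5) stop("crop_first_pass: curve too short")
  baseline <- mean(aif[1:3])
  peak_thresh <- baseline + 0.5 * (max(aif) - baseline)
  interior <- 2:(n - 1)
  is_lmax <- aif[interior] >= aif[interior - 1] &
    aif[interior] >= aif[interior + 1]
  cand <- interior[is_lmax & aif[interior] > peak_thresh]
  if (length(cand) == 0)
    stop("crop_first_pass: no first-pass peak found; inspect the curve")
  p <- cand[1]
  foot_thresh <- baseline + 0.1 * (aif[p] - baseline)
  pre <- which(aif[seq_len(p - 1)] <= foot_thresh)
  foot <- if (length(pre)) max(pre) else 1L
  valley <- n
  for (i in seq(p + 1, n)) {
    local_min <- i < n && aif[i] <= aif[i - 1] && aif[i] <= aif[i + 1]
    if (local_min || aif[i] <= foot_thresh) {
      valley <- i
      break
    }
  }
  start <- max(1L, foot - as.integer(guard_frames))
  end_incl <- min(n, valley + as.integer(guard_frames))
  c(start = as.integer(start), end = as.integer(end_incl) + 1L)
}

#' Linearly resample a sequence to k timesteps
#'
#' Linear interpolation at `k` equally spaced positions spanning the
#' original index range; endpoints are preserved exactly. Cropped windows
#' have study-dependent lengths, so every feature sequence is brought to
#' a common temporal length (default 10) before stress/rest subtraction.
#'
#' @param values numeric vector of length >= 2.
#' @param k target length (default 10).
#' @return numeric vector of length `k`.
#' @export
interpolate_to_k <- function(values, k = 10L) {
  if (length(values) < 2) stop("interpolate_to_k: need >= 2 values")
  if (length(values) == k) return(as.numeric(values))
  approx(x = seq_along(values) - 1, y = values,
         xout = seq(0, length(values) - 1, length.out = k))$y
}

#' Extract per-territory radiomic feature sequences from one study
#'
#' Runs the per-study half of the temporal pipeline: for each condition
#' (stress, rest) and slice, the image sequence is min-max normalized
#' over all timesteps (within the myocardium + blood-pool region), the
#' AIF locates the first-pass window, and all 35 catalogue features are
#' computed on each coronary-territory sub-mask at every frame of the
#' window; each feature sequence is then interpolated to `k` timesteps.
#'
#' @param study a `perfusion_study`.
#' @param n_bins gray levels for feature discretization (default 32).
#' @param guard_frames window guard for [crop_first_pass()].
#' @param k common temporal length after interpolation (default 10).
#' @param connectivity GLSZM zone connectivity.
#' @return a named numeric array `[condition(2), slice(3), territory(3),
#'   feature(35), time(k)]` with class `feature_sequences`; per territory
#'   it holds `2 * 3 * 35 * k` values (2,100 at the default `k = 10`).
#' @export
extract_feature_sequences <- function(study, n_bins = 32L,
                                      guard_frames = 1L, k = 10L,
                                      connectivity = 8L) {
  stopifnot(inherits(study, "perfusion_study"))
  cat35 <- feature_catalogue()$all
  out <- array(NA_real_,
               c(2L, 3L, 3L, 35L, k),
               dimnames = list(condition = CONDITIONS, slice = SLICES,
                               territory = TERRITORIES, feature = cat35,
                               time = NULL))
  for (cond in CONDITIONS) {
    for (s in seq_along(SLICES)) {
      stack <- study$condition_stacks[[cond]][, , , s]
      myo <- study$myocardium_masks[, , s]
      bp <- study$blood_pool_mask[, , s]
      norm <- normalize_image_sequence(stack, myo | bp)
      win <- crop_first_pass(compute_aif(norm, bp), guard_frames)
      frames <- seq(win[1], win[2] - 1L)
      terr_masks <- split_myocardium(myo, study$centroid,
                                     study$rv_insertion_angle, SLICES[s])
      for (tr in TERRITORIES) {
        m <- terr_masks[[tr]]
        if (sum(m) < 2)
          stop("extract_feature_sequences: territory mask '", tr,
               "' has fewer than 2 pixels")
        raw <- vapply(frames, function(f)
          compute_region_features(norm[, , f], m, n_bins, connectivity),
          numeric(35L))
        for (j in seq_len(35L))
          out[cond, SLICES[s], tr, j, ] <- interpolate_to_k(raw[j, ], k)
      }
    }
  }
  structure(out, class = c("feature_sequences", "array"))
}

#' Stress-minus-rest delta sequences
#'
#' Elementwise subtraction of the rest feature sequences from the stress
#' ones for identically indexed (slice, territory, feature, timestep)
#' entries, yielding 9 delta-sequence groups per subject (3 slices x 3
#' territories), each holding the 35 features. The two inputs must carry
#' identical dimension names.
#'
#' @param stress numeric array `[slice, territory, feature, time]` (the
#'   stress half of a `feature_sequences` array).
#' @param rest matching rest array.
#' @return delta array of the same shape.
#' @export
delta_sequences <- function(stress, rest) {
  if (!identical(dim(stress), dim(rest)) ||
      !identical(dimnames(stress), dimnames(rest)))
    stop("delta_sequences: stress and rest sequences are not aligned")
  stress - rest
}

#' Per-study delta array from extracted feature sequences
#'
#' @param fs a `feature_sequences` array from [extract_feature_sequences()].
#' @return array `[slice, territory, feature, time]` of stress - rest.
#' @export
study_deltas <- function(fs) {
  delta_sequences(fs["stress", , , , , drop = TRUE],
                  fs["rest", , , , , drop = TRUE])
}

# Flatten one territory's delta array [slice, feature, time] to the fixed
# 1050-channel layout: slice-major, then feature, then timestep.
flatten_territory_deltas <- function(d_sub) {
  as.vector(aperm(d_sub, c(3, 2, 1)))
}

delta_channel_names <- function(k = 10L) {
  cat35 <- feature_catalogue()$all
  unlist(lapply(SLICES, function(s)
    unlist(lapply(cat35, function(f) paste(s, f, paste0("t", seq_len(k)),
                                           sep = "|")))))
}

#' Extract delta sequences for a whole cohort
#'
#' Runs [extract_feature_sequences()] and [study_deltas()] for every
#' subject and stacks the per-territory delta channels into a matrix with
#' one row per (subject, territory). If `config` is given instead of a
#' pre-built list of studies, subjects are synthesized one at a time and
#' discarded after extraction, keeping memory flat for large cohorts.
#'
#' @param cohort list of `perfusion_study` objects, or `NULL`.
#' @param config a [phantom_config()] used to stream-generate subjects
#'   when `cohort` is `NULL`.
#' @param ... passed to [extract_feature_sequences()].
#' @return object of class `territory_deltas`: list with `values`
#'   (matrix, `3 * n_subjects` rows x `35 * 10 * 3 = 1050` named
#'   channels) and `meta` (data frame: subject, territory,
#'   territory_label, patient_label).
#' @export
extract_cohort_deltas <- function(cohort = NULL, config = NULL, ...) {
  if (is.null(cohort) && is.null(config))
    stop("extract_cohort_deltas: provide a cohort or a config")
  get_study <- if (!is.null(cohort)) {
    n <- length(cohort)
    function(i) cohort[[i]]
  } else {
    labels <- draw_cohort_labels(config)
    n <- nrow(labels)
    function(i) {
      defs <- TERRITORIES[unlist(labels[i, TERRITORIES])]
      generate_study(config, labels$subject_id[i],
                     is_positive = labels$is_positive[i],
                     defect_territories = defs,
                     seed = derive_seed(config$seed, i))
    }
  }
  rows <- vector("list", n * 3L)
  meta <- vector("list", n * 3L)
  ch_names <- NULL
  for (i in seq_len(n)) {
    study <- get_study(i)
    fs <- extract_feature_sequences(study, ...)
    d <- study_deltas(fs)
    if (is.null(ch_names)) ch_names <- delta_channel_names(dim(fs)[5])
    for (j in seq_along(TERRITORIES)) {
      tr <- TERRITORIES[j]
      rows[[(i - 1L) * 3L + j]] <- flatten_territory_deltas(d[, tr, , ])
      meta[[(i - 1L) * 3L + j]] <- data.frame(
        subject = study$subject_id, territory = tr,
        territory_label = unname(study$territory_labels[tr]),
        patient_label = study$patient_label)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- ch_names
  structure(list(values = values, meta = do.call(rbind, meta)),
            class = "territory_deltas")
}

#' Fit the cross-subject delta scaler
#'
#' Learns per-channel min and max of the delta sequences across training
#' subjects, separately for each territory (a channel is one
#' (slice, feature, timestep) triple). Applying the scaler maps deltas to
#' `[0, 1]`, removing the negative values introduced by subtraction. The
#' scaler must be fitted on training subjects only; fold-aware fitting
#' inside cross-validation prevents information leaking from test
#' subjects through the normalization constants.
#'
#' @param deltas a `territory_deltas` object.
#' @param subjects character vector of training subject ids; default all.
#' @return object of class `delta_scaler`.
#' @export
fit_delta_scaler <- function(deltas, subjects = NULL) {
  stopifnot(inherits(deltas, "territory_deltas"))
  if (is.null(subjects)) subjects <- unique(deltas$meta$subject)
  keep <- deltas$meta$subject %in% subjects
  if (!any(keep)) stop("fit_delta_scaler: no training rows")
  params <- lapply(TERRITORIES, function(tr) {
    X <- deltas$values[keep & deltas$meta$territory == tr, , drop = FALSE]
    if (nrow(X) == 0) stop("fit_delta_scaler: territory ", tr,
                           " missing from training subjects")
    list(min = apply(X, 2, min), max = apply(X, 2, max))
  })
  structure(list(params = setNames(params, TERRITORIES),
                 channels = colnames(deltas$values),
                 subjects = subjects),
            class = "delta_scaler")
}

#' Apply a fitted delta scaler
#'
#' Min-max scales each row's channels with its territory's training
#' parameters, clipping to `[0, 1]` for out-of-range (test) values.
#' Channels constant on the training set map to 0.
#'
#' @param deltas a `territory_deltas` object.
#' @param scaler a `delta_scaler` from [fit_delta_scaler()].
#' @return a `territory_deltas` object with values in `[0, 1]`.
#' @export
apply_delta_scaler <- function(deltas, scaler) {
  stopifnot(inherits(deltas, "territory_deltas"),
            inherits(scaler, "delta_scaler"))
  if (!identical(colnames(deltas$values), scaler$channels))
    stop("apply_delta_scaler: channel names do not match the scaler")
  out <- deltas$values
  for (tr in TERRITORIES) {
    rows <- which(deltas$meta$territory == tr)
    if (length(rows) == 0) next
    p <- scaler$params[[tr]]
    rng <- p$max - p$min
    scl <- ifelse(rng > 0, 1 / rng, 0)   # constant channel -> 0
    X <- sweep(out[rows, , drop = FALSE], 2, p$min, "-")
    X <- sweep(X, 2, scl, "*")
    out[rows, ] <- pmin(pmax(X, 0), 1)
  }
  structure(list(values = out, meta = deltas$meta),
            class = "territory_deltas")
}

#' Histogram-encode a scaled sequence
#'
#' Counts the values of a `[0, 1]`-scaled temporal sequence into
#' `n_bins` equal-width bins on `[0, 1]` (last bin right-closed). The
#' histogram discards temporal ordering, which is the point: it makes the
#' encoding robust to inter-subject temporal misalignment.
#'
#' @param values numeric vector with entries in `[0, 1]`.
#' @param n_bins number of bins (default 8).
#' @return integer vector of `n_bins` counts summing to `length(values)`.
#' @export
to_histogram <- function(values, n_bins = 8L) {
  if (any(values < 0 | values > 1))
    stop("to_histogram: values outside [0, 1]; scale deltas first")
  idx <- pmin(floor(values * n_bins) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

# Encode every (slice, feature) 10-step scaled sequence of a row matrix
# into 8-bin histograms. Column layout: slice-major, feature, bin.
histogram_encode <- function(values, k = 10L, n_bins = 8L) {
  n_seq <- ncol(values) / k
  stopifnot(n_seq == floor(n_seq))
  out <- matrix(0L, nrow(values), n_seq * n_bins)
  for (q in seq_len(n_seq)) {
    block <- values[, ((q - 1L) * k + 1L):(q * k), drop = FALSE]
    idx <- pmin(floor(block * n_bins) + 1L, n_bins)
    for (b in seq_len(n_bins))
      out[, (q - 1L) * n_bins + b] <- rowSums(idx == b)
  }
  seq_names <- sub("\\|t1$", "",
                   colnames(values)[seq(1, ncol(values), by = k)])
  colnames(out) <- unlist(lapply(seq_names, function(s)
    paste(s, paste0("bin", seq_len(n_bins)), sep = "|")))
  out
}

#' Assemble per-territory histogram feature vectors
#'
#' Final pipeline stage: scales the cohort's delta sequences (fitting the
#' cross-subject scaler on all subjects unless one is supplied) and
#' histogram-encodes each (slice, feature) sequence into 8 bins, giving
#' one vector of `35 features x 8 bins x 3 slices = 840` named entries
#' per (subject, territory).
#'
#' @param deltas a `territory_deltas` object.
#' @param scaler optional pre-fitted [fit_delta_scaler()] (fold-aware use).
#' @param n_bins histogram bins per sequence (default 8).
#' @return object of class `territory_vectors`: list with `values`
#'   (matrix, rows = subject x territory, 840 columns) and `meta`.
#' @export
assemble_territory_vectors <- function(deltas, scaler = NULL, n_bins = 8L) {
  stopifnot(inherits(deltas, "territory_deltas"))
  if (is.null(scaler)) scaler <- fit_delta_scaler(deltas)
  scaled <- apply_delta_scaler(deltas, scaler)
  k <- length(grep("^basal\\|fo_energy\\|t", colnames(deltas$values)))
  values <- histogram_encode(scaled$values, k = k, n_bins = n_bins)
  structure(list(values = values, meta = deltas$meta),
            class = "territory_vectors")
}
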