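#' Gamma-variate first-pass enhancement curve
#'
#' The classical single-bolus enhancement model used throughout first-pass
#' perfusion work: signal stays at `baseline` until the onset frame `t0`,
#' then rises and decays as `baseline + A * (t - t0)^alpha *
#' exp(-(t - t0) / beta)`. The curve has a single interior maximum at
#' `t = t0 + alpha * beta`.
#'
#' @param t frame index (vectorized).
#' @param t0 onset frame.
#' @param alpha shape parameter (> 0).
#' @param beta scale in frames (> 0).
#' @param A amplitude (>= 0).
#' @param baseline pre-contrast signal intensity.
#' @return signal intensity at `t` (same length as `t`).
#' @export
gamma_variate <- function(t, t0, alpha, beta, A, baseline) {
  if (alpha <= 0 || beta <= 0)
    stop("gamma_variate: alpha and beta must be positive")
  if (A < 0) stop("gamma_variate: amplitude must be non-negative")
  dt <- t - t0
  out <- rep(baseline, length(t))
  up <- dt > 0
  out[up] <- baseline + A * dt[up]^alpha * exp(-dt[up] / beta)
  out
}

#' Phantom configuration
#'
#' Bundles every parameter of the synthetic stress/rest perfusion phantom:
#' cohort shape, slice geometry, blood-pool and myocardial enhancement
#' kinetics, the inducible-defect model, and pixel noise. Defaults emulate
#' the cohort the pipeline targets: 92 subjects with a 42% patient-level
#' disease prevalence, and a stress-only perfusion defect that reduces the
#' myocardial enhancement amplitude to `defect_amplitude_fraction` of
#' normal and delays its onset by `defect_delay` frames.
#'
#' @param n_subjects number of subjects in a generated cohort.
#' @param prevalence_patient probability a subject is positive, in `[0,1]`.
#' @param image_size image side length in pixels.
#' @param n_frames frames per sequence (one frame per cardiac cycle, >= 15).
#' @param ring_radii `(inner, outer)` myocardial annulus radii in pixels;
#'   must satisfy `inner < outer < image_size / 2`.
#' @param rv_insertion_angle angle (degrees, counterclockwise from the
#'   image x-axis) of the anterior right-ventricular insertion ray from
#'   which territory sectors are measured.
#' @param aif_params blood-pool kinetics: list with `t0` (onset frame),
#'   `alpha` (shape), `beta` (scale frames), `A` (amplitude), `baseline`.
#' @param myo_params myocardial kinetics, same fields; delayed and damped
#'   relative to the blood pool.
#' @param rest_amplitude_scale myocardial enhancement amplitude at rest as
#'   a fraction of the stress amplitude (hyperaemia raises stress inflow).
#' @param defect_amplitude_fraction stress-defect amplitude multiplier in
#'   `(0, 1]`; 1 means no amplitude reduction.
#' @param defect_delay stress-defect onset delay in frames.
#' @param noise_sigma standard deviation of i.i.d. Gaussian pixel noise.
#' @param seed integer seed from which all phantom randomness derives.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 92L,
                           prevalence_patient = 0.42,
                           image_size = 64L,
                           n_frames = 40L,
                           ring_radii = c(12, 20),
                           rv_insertion_angle = 60,
                           aif_params = list(t0 = 5, alpha = 3, beta = 1.5,
                                             A = 100, baseline = 100),
                           myo_params = list(t0 = 8, alpha = 3, beta = 2.5,
                                             A = 8, baseline = 100),
                           rest_amplitude_scale = 0.7,
                           defect_amplitude_fraction = 0.4,
                           defect_delay = 2L,
                           noise_sigma = 4,
                           seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              prevalence_patient = prevalence_patient,
              image_size = as.integer(image_size),
              n_frames = as.integer(n_frames),
              ring_radii = ring_radii,
              rv_insertion_angle = rv_insertion_angle,
              aif_params = aif_params,
              myo_params = myo_params,
              rest_amplitude_scale = rest_amplitude_scale,
              defect_amplitude_fraction = defect_amplitude_fraction,
              defect_delay = defect_delay,
              noise_sigma = noise_sigma,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (!(ring_radii[1] < ring_radii[2] && ring_radii[2] < image_size / 2))
      stop("phantom_config: need inner < outer < image_size / 2")
    if (n_frames < 15) stop("phantom_config: n_frames must be >= 15")
    if (defect_amplitude_fraction <= 0 || defect_amplitude_fraction > 1)
      stop("phantom_config: defect_amplitude_fraction must be in (0, 1]")
    if (prevalence_patient < 0 || prevalence_patient > 1)
      stop("phantom_config: prevalence_patient must be in [0, 1]")
    for (p in list(aif_params, myo_params))
      if (p$alpha <= 0 || p$beta <= 0)
        stop("phantom_config: kinetic alpha and beta must be positive")
  })
  invisible(cfg)
}

# Annulus + blood-pool geometry shared by all slices of a phantom subject.
phantom_geometry <- function(cfg) {
  n <- cfg$image_size
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  r <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  myo <- r > cfg$ring_radii[1] & r <= cfg$ring_radii[2]
  bp <- r <= 0.6 * cfg$ring_radii[1]
  list(myo = myo, blood_pool = bp, centroid = c(ctr, ctr))
}

#' Generate one synthetic stress/rest perfusion study
#'
#' Builds a three-slice (basal, mid, apical) short-axis phantom: an
#' annular myocardium around a central blood-pool disk, every pixel
#' following a gamma-variate first-pass curve, with i.i.d. Gaussian noise.
#' Defects are inducible-ischaemia style: under stress only, pixels of the
#' affected coronary territory have their enhancement amplitude multiplied
#' by `defect_amplitude_fraction` and their onset delayed by
#' `defect_delay` frames; rest sequences carry no defect. The rest
#' myocardial amplitude is `rest_amplitude_scale` times the stress one.
#'
#' @param config a [phantom_config()].
#' @param subject_id subject identifier string.
#' @param is_positive logical; whether this subject has any defect.
#' @param defect_territories character subset of `c("LAD","LCX","RCA")`;
#'   must be nonempty iff `is_positive`.
#' @param seed RNG seed for this subject's noise (defaults to the config
#'   seed).
#' @return object of class `perfusion_study`: condition stacks
#'   (`[y, x, time, slice]` arrays for stress and rest), myocardium and
#'   blood-pool masks (`[y, x, slice]`), territory and patient labels.
#' @export
generate_study <- function(config, subject_id, is_positive = FALSE,
                           defect_territories = character(0),
                           seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (is_positive != (length(defect_territories) > 0))
    stop("generate_study: defect_territories must be nonempty iff positive")
  if (!all(defect_territories %in% TERRITORIES))
    stop("generate_study: unknown territory in defect_territories")
  geo <- phantom_geometry(config)
  n <- config$image_size
  tt <- seq_len(config$n_frames)
  set.seed(seed)

  stacks <- list()
  for (cond in CONDITIONS) {
    stack <- array(NA_real_, c(n, n, config$n_frames, 3L))
    ap <- config$aif_params
    mp <- config$myo_params
    myo_A <- if (cond == "rest") mp$A * config$rest_amplitude_scale else mp$A
    aif_curve <- gamma_variate(tt, ap$t0, ap$alpha, ap$beta, ap$A,
                               ap$baseline)
    normal_curve <- gamma_variate(tt, mp$t0, mp$alpha, mp$beta, myo_A,
                                  mp$baseline)
    defect_curve <- gamma_variate(tt, mp$t0 + config$defect_delay,
                                  mp$alpha, mp$beta,
                                  myo_A * config$defect_amplitude_fraction,
                                  mp$baseline)
    for (s in seq_along(SLICES)) {
      terr <- split_myocardium(geo$myo, geo$centroid,
                               config$rv_insertion_angle, SLICES[s])
      defect_mask <- matrix(FALSE, n, n)
      if (cond == "stress") {
        for (tr in defect_territories) defect_mask <- defect_mask | terr[[tr]]
      }
      frame_base <- matrix(mp$baseline, n, n)
      for (k in seq_along(tt)) {
        fr <- frame_base
        fr[geo$myo] <- normal_curve[k]
        fr[defect_mask] <- defect_curve[k]
        fr[geo$blood_pool] <- aif_curve[k]
        stack[, , k, s] <- fr
      }
    }
    if (config$noise_sigma > 0) {
      stack <- stack + rnorm(length(stack), sd = config$noise_sigma)
    }
    stacks[[cond]] <- stack
  }

  terr_labels <- setNames(TERRITORIES %in% defect_territories, TERRITORIES)
  structure(list(
    subject_id = subject_id,
    condition_stacks = stacks,
    myocardium_masks = array(geo$myo, c(n, n, 3L)),
    blood_pool_mask = array(geo$blood_pool, c(n, n, 3L)),
    territory_labels = terr_labels,
    patient_label = any(terr_labels),
    rv_insertion_angle = config$rv_insertion_angle,
    centroid = geo$centroid
  ), class = "perfusion_study")
}

#' Draw cohort disease labels
#'
#' Samples each subject's positivity with probability
#' `prevalence_patient`; positive subjects receive 1-3 defect territories
#' chosen uniformly. Seeded from the config so a cohort's labels are
#' reproducible independently of image synthesis.
#'
#' @param config a [phantom_config()].
#' @return data frame with columns `subject_id`, `is_positive`, and
#'   logical `LAD`, `LCX`, `RCA` defect indicators.
#' @export
draw_cohort_labels <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_subjects
  pos <- runif(n) < config$prevalence_patient
  terr <- matrix(FALSE, n, 3, dimnames = list(NULL, TERRITORIES))
  for (i in which(pos)) {
    k <- sample.int(3L, 1L)
    terr[i, sample(TERRITORIES, k)] <- TRUE
  }
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             is_positive = pos, terr)
}

#' Generate a full phantom cohort
#'
#' Draws labels via [draw_cohort_labels()] and synthesizes one
#' [generate_study()] per subject, each with a deterministic per-subject
#' seed derived from the config seed. Identical config and seed yield a
#' bit-identical cohort.
#'
#' @param config a [phantom_config()].
#' @return list of `perfusion_study` objects of length `n_subjects`.
#' @export
generate_cohort <- function(config) {
  labels <- draw_cohort_labels(config)
  lapply(seq_len(nrow(labels)), function(i) {
    defs <- TERRITORIES[unlist(labels[i, TERRITORIES])]
    generate_study(config, labels$subject_id[i],
                   is_positive = labels$is_positive[i],
                   defect_territories = defs,
                   seed = derive_seed(config$seed, i))
  })
}
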