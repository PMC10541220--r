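# Small phantom configurations used across the test suite: reduced image
# size and frame count so per-study extraction stays fast.

small_phantom_config <- function(...) {
  phantom_config(image_size = 48L, n_frames = 28L, ring_radii = c(9, 15),
                 ...)
}

# A tiny extracted cohort shared by several test files; computed once per
# test run and memoised.
.shared <- new.env(parent = emptyenv())

shared_small_deltas <- function() {
  if (is.null(.shared$deltas)) {
    cfg <- small_phantom_config(n_subjects = 16L, seed = 404L)
    .shared$deltas <- extract_cohort_deltas(config = cfg)
  }
  .shared$deltas
}

# Subject-level label permutation: reassigns each subject's (territory,
# patient) label block to another subject, keeping the feature rows fixed.
permute_subject_labels <- function(deltas, seed) {
  set.seed(seed)
  meta <- deltas$meta
  subj <- unique(meta$subject)
  perm <- setNames(sample(subj), subj)
  key_old <- paste(meta$subject, meta$territory)
  key_new <- paste(perm[meta$subject], meta$territory)
  idx <- match(key_new, key_old)
  meta$territory_label <- meta$territory_label[idx]
  meta$patient_label <- meta$patient_label[idx]
  structure(list(values = deltas$values, meta = meta),
            class = "territory_deltas")
}
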