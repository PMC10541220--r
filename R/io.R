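#' Write a perfusion study to a directory as NIfTI volumes
#'
#' Stress and rest stacks are written as 4D NIfTI (`x, y, slice, time`,
#' double precision, lossless for the phantom's float data); masks as
#' 3D uint8 volumes; labels and geometry as a YAML sidecar.
#'
#' @param study a `perfusion_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "perfusion_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in CONDITIONS) {
    arr <- aperm(study$condition_stacks[[cond]], c(1, 2, 4, 3))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                       file.path(dir, paste0(cond, ".nii")))
  }
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(study$myocardium_masks),
                          dim(study$myocardium_masks)), datatype = "uint8"),
    file.path(dir, "myocardium_mask.nii"))
  RNifti::writeNifti(
    RNifti::asNifti(array(as.integer(study$blood_pool_mask),
                          dim(study$blood_pool_mask)), datatype = "uint8"),
    file.path(dir, "blood_pool_mask.nii"))
  yaml::write_yaml(list(
    subject_id = study$subject_id,
    territory_labels = as.list(ifelse(study$territory_labels,
                                      "positive", "negative")),
    patient_label = if (study$patient_label) "positive" else "negative",
    rv_insertion_angle = study$rv_insertion_angle,
    centroid = as.numeric(study$centroid)
  ), file.path(dir, "study.yaml"))
  invisible(dir)
}

#' Read a perfusion study written by [write_study()]
#'
#' @param dir study directory.
#' @return a `perfusion_study`.
#' @export
read_study <- function(dir) {
  sidecar <- file.path(dir, "study.yaml")
  if (!file.exists(sidecar))
    stop("read_study: missing study.yaml in ", dir)
  info <- yaml::read_yaml(sidecar)
  stacks <- list()
  for (cond in CONDITIONS) {
    f <- file.path(dir, paste0(cond, ".nii"))
    if (!file.exists(f)) stop("read_study: missing ", cond, " volume")
    arr <- as.array(RNifti::readNifti(f))
    if (length(dim(arr)) != 4)
      stop("read_study: ", cond, " volume is not 4D")
    stacks[[cond]] <- aperm(arr, c(1, 2, 4, 3))
  }
  read_mask <- function(name) {
    f <- file.path(dir, paste0(name, ".nii"))
    if (!file.exists(f)) stop("read_study: missing mask volume ", name)
    m <- as.array(RNifti::readNifti(f))
    array(m > 0, dim(m))
  }
  terr <- setNames(unlist(info$territory_labels[TERRITORIES]) == "positive",
                   TERRITORIES)
  structure(list(
    subject_id = info$subject_id,
    condition_stacks = stacks,
    myocardium_masks = read_mask("myocardium_mask"),
    blood_pool_mask = read_mask("blood_pool_mask"),
    territory_labels = terr,
    patient_label = info$patient_label == "positive",
    rv_insertion_angle = info$rv_insertion_angle,
    centroid = as.numeric(info$centroid)
  ), class = "perfusion_study")
}

#' Write a phantom cohort to disk
#'
#' One subdirectory per subject plus a `manifest.csv` with the
#' territory and patient labels.
#'
#' @param cohort list of `perfusion_study` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(st) {
    write_study(st, file.path(dir, st$subject_id))
    data.frame(subject_id = st$subject_id,
               LAD = ifelse(st$territory_labels["LAD"], "positive",
                            "negative"),
               LCX = ifelse(st$territory_labels["LCX"], "positive",
                            "negative"),
               RCA = ifelse(st$territory_labels["RCA"], "positive",
                            "negative"),
               patient = ifelse(st$patient_label, "positive", "negative"))
  })
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return list of `perfusion_study` objects.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("read_cohort: missing manifest.csv")
  manifest <- read.csv(mf)
  lapply(manifest$subject_id, function(id)
    read_study(file.path(dir, id)))
}

#' Write territory feature vectors to CSV
#'
#' One row per (subject, territory): labels followed by the 840 named
#' histogram features. Round-trips exactly through [read_features()].
#'
#' @param tv a `territory_vectors` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(tv, path) {
  stopifnot(inherits(tv, "territory_vectors"))
  df <- cbind(tv$meta, as.data.frame(tv$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read territory feature vectors from CSV
#'
#' Validates the schema: the four metadata columns and the full set of
#' feature columns must be present; a missing column is reported by name.
#'
#' @param path CSV written by [write_features()].
#' @return a `territory_vectors` object.
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta_cols <- c("subject", "territory", "territory_label", "patient_label")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing) > 0)
    stop("read_features: missing required column(s): ",
         paste(missing, collapse = ", "))
  feat_cols <- setdiff(names(df), meta_cols)
  if (length(feat_cols) == 0) stop("read_features: no feature columns")
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  meta <- df[, meta_cols]
  meta$territory_label <- as.logical(meta$territory_label)
  meta$patient_label <- as.logical(meta$patient_label)
  structure(list(values = values, meta = meta),
            class = "territory_vectors")
}

#' Write a cross-validation report
#'
#' Emits `metrics.json` (patient sensitivity/specificity, per-fold
#' thresholds), `selections.csv` (fold, selected feature), and a
#' human-readable `report.md` including the feature-type ranking.
#'
#' @param cv a `cv_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(cv, dir) {
  stopifnot(inherits(cv, "cv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    sensitivity = cv$sensitivity,
    specificity = cv$specificity,
    target_specificity = cv$config$target_specificity,
    thresholds = cv$thresholds,
    n_patients = nrow(cv$patient),
    n_territories = nrow(cv$territory)
  ), file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  sel <- do.call(rbind, lapply(seq_along(cv$selections), function(f)
    if (length(cv$selections[[f]]) > 0)
      data.frame(fold = f, feature = cv$selections[[f]])))
  write.csv(sel, file.path(dir, "selections.csv"), row.names = FALSE)
  rk <- feature_ranking(cv)
  rk <- rk[rk$frequency > 0, , drop = FALSE]
  lines <- c(
    "# Territory classification report", "",
    sprintf("- Patients evaluated: %d", nrow(cv$patient)),
    sprintf("- Patient-level sensitivity: %.3f", cv$sensitivity),
    sprintf("- Patient-level specificity: %.3f", cv$specificity),
    sprintf("- Target specificity: %.2f", cv$config$target_specificity),
    sprintf("- Per-fold thresholds: %s",
            paste(sprintf("%.3f", cv$thresholds), collapse = ", ")),
    "", "## Most frequently selected feature types", "",
    sprintf("- %s: %d fold(s)", rk$feature, rk$frequency))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}

#' Write / read a phantom configuration as YAML
#'
#' @param config a [phantom_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); a `phantom_config` (read).
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(phantom_config, raw)
}
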