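#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks for ties. Returns `NA` if
#' either class is absent.
#'
#' @param probs numeric scores.
#' @param labels logical (TRUE = positive).
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc_score <- function(probs, labels) {
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified group K-fold assignment
#'
#' Assigns each subject (group) to one of `k` folds so that every
#' subject's samples fall in a single fold while class proportions stay
#' balanced across folds: subjects are shuffled within each class and
#' dealt round-robin.
#'
#' @param subject_labels named logical vector, one entry per subject
#'   (TRUE = positive subject).
#' @param k number of folds (>= 2, <= number of subjects).
#' @param seed RNG seed.
#' @return named integer vector of fold ids in `1..k`, one per subject.
#' @export
stratified_group_kfold <- function(subject_labels, k, seed = 1L) {
  n <- length(subject_labels)
  if (k < 2 || k > n) stop("stratified_group_kfold: bad number of folds")
  set.seed(seed)
  fold <- setNames(integer(n), names(subject_labels))
  offset <- 0L
  for (cls in c(TRUE, FALSE)) {
    subj <- names(subject_labels)[subject_labels == cls]
    subj <- sample(subj)
    fold[subj] <- ((seq_along(subj) - 1L + offset) %% k) + 1L
    offset <- offset + length(subj)   # continue dealing across classes
  }
  fold
}

default_rf_grid <- function() {
  expand.grid(num_trees = c(100L, 300L),
              max_depth = c(0L, 8L),
              mtry = NA_integer_)
}

#' Fit a balanced random forest
#'
#' Random forest in which every tree's bootstrap draws equal counts from
#' each class (the majority class is downsampled per tree to the minority
#' count), countering class imbalance without reweighting. Predicted
#' class-1 probability is the fraction of trees voting positive.
#'
#' @param X numeric matrix, samples x features.
#' @param y logical labels (TRUE = positive); both classes required.
#' @param hyperparams list with `num_trees`, `max_depth` (0 = unlimited)
#'   and `mtry` (`NA` = floor(sqrt(p))).
#' @param seed RNG seed; identical data, hyperparameters and seed give
#'   identical predictions.
#' @return object of class `balanced_rf`.
#' @export
balanced_rf_fit <- function(X, y,
                            hyperparams = list(num_trees = 300L,
                                               max_depth = 0L,
                                               mtry = NA_integer_),
                            seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2)
    stop("balanced_rf_fit: both classes must be present")
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  n_min <- min(table(yf))
  mtry <- hyperparams$mtry
  if (is.null(mtry) || is.na(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- min(mtry, ncol(X))
  fit <- ranger::ranger(
    x = X, y = yf,
    num.trees = hyperparams$num_trees,
    mtry = mtry,
    max.depth = hyperparams$max_depth,
    replace = TRUE,
    sample.fraction = rep(n_min / length(yf), 2L),
    seed = seed,
    num.threads = 1L
  )
  structure(list(forest = fit, features = colnames(X)),
            class = "balanced_rf")
}

#' Predict positive-vote fractions from a balanced random forest
#'
#' @param object a `balanced_rf` fit.
#' @param newdata numeric matrix with the training features.
#' @param ... unused.
#' @return numeric vector: fraction of trees voting positive per sample.
#' @export
predict.balanced_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  pred <- predict(object$forest, data = newdata, predict.all = TRUE,
                  num.threads = 1L)$predictions
  rowMeans(pred == 2L)   # level 2 = "pos"
}

# Territory-level folds driven by subject-level stratified assignment.
# Returns a list of folds, each with integer train/val row indices.
group_fold_indices <- function(y, groups, k, seed) {
  subj_label <- tapply(y, groups, any)
  fold_of_subj <- stratified_group_kfold(
    setNames(as.logical(subj_label), names(subj_label)), k, seed)
  fold <- fold_of_subj[as.character(groups)]
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), val = which(fold == f)))
}

# Mean validation AUC of a balanced RF on given feature columns across
# pre-computed folds; folds without both classes in train or val are NA.
cv_auc <- function(X, y, folds, cols, hyperparams, seed) {
  aucs <- vapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train
    va <- folds[[f]]$val
    if (length(unique(y[tr])) < 2 || length(unique(y[va])) < 2)
      return(NA_real_)
    fit <- balanced_rf_fit(X[tr, cols, drop = FALSE], y[tr], hyperparams,
                           seed = derive_seed(seed, f))
    auc_score(predict(fit, X[va, cols, drop = FALSE]), y[va])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Sequential forward feature selection under grouped CV
#'
#' Greedy forward selection: at each step the candidate feature whose
#' addition maximizes the mean ROC-AUC of a balanced random forest over
#' stratified group k-fold cross-validation is added. Selection stops at
#' `max_k` features or as soon as no candidate improves the criterion.
#' Ties are broken toward the lowest feature index. An optional
#' univariate screen (`screen_size`) restricts the candidate pool to the
#' features with the strongest single-feature AUC on the training data,
#' bounding the quadratic cost of full forward selection; the screen sees
#' only the data passed in, so fold isolation is preserved by the caller.
#'
#' @param X numeric matrix, samples x features (named columns).
#' @param y logical territory labels.
#' @param groups subject id per sample; all samples of a subject stay on
#'   one side of every split.
#' @param n_folds inner folds (default 10).
#' @param max_k maximum number of features to select (default 50; clipped
#'   to the feature count with a warning).
#' @param seed RNG seed.
#' @param num_trees trees per forest during selection (small by design;
#'   selection ranks candidates, the final model is refit later).
#' @param screen_size optional candidate-pool size; `NULL` = all.
#' @return integer vector of selected column indices, in selection order.
#' @export
sequential_select <- function(X, y, groups, n_folds = 10L, max_k = 50L,
                              seed = 1L, num_trees = 50L,
                              screen_size = NULL) {
  p <- ncol(X)
  if (max_k > p) {
    warning("sequential_select: max_k clipped to feature count")
    max_k <- p
  }
  folds <- group_fold_indices(y, groups, n_folds, derive_seed(seed, 0L))
  candidates <- seq_len(p)
  if (!is.null(screen_size) && screen_size < p) {
    uni <- apply(X, 2, function(v) abs(auc_score(v, y) - 0.5))
    candidates <- sort(order(uni, decreasing = TRUE)[seq_len(screen_size)])
  }
  hyper <- list(num_trees = num_trees, max_depth = 0L, mtry = NA_integer_)
  selected <- integer(0)
  best_score <- 0.5                      # chance-level baseline
  for (step in seq_len(max_k)) {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    scores <- vapply(pool, function(j)
      cv_auc(X, y, folds, c(selected, j), hyper,
             derive_seed(seed, step * 10000L + j)),
      numeric(1))
    best_j <- pool[which.max(scores)]    # which.max -> lowest index on ties
    if (!is.finite(max(scores)) || max(scores) <= best_score) break
    best_score <- max(scores)
    selected <- c(selected, best_j)
  }
  selected
}

#' Grid search for balanced random forest hyperparameters
#'
#' Exhaustive evaluation of a hyperparameter grid by mean inner-CV
#' ROC-AUC on the selected features. Ties are broken toward the smaller
#' model: fewer trees first, then shallower.
#'
#' @param X,y,groups as in [sequential_select()].
#' @param selected integer indices of the selected features.
#' @param grid data frame with columns `num_trees`, `max_depth`, `mtry`.
#' @param n_folds inner folds (default 10).
#' @param seed RNG seed.
#' @return list: `num_trees`, `max_depth`, `mtry`, `auc`.
#' @export
grid_search <- function(X, y, groups, selected, grid = default_rf_grid(),
                        n_folds = 10L, seed = 1L) {
  if (nrow(grid) == 0) stop("grid_search: empty grid")
  folds <- group_fold_indices(y, groups, n_folds, derive_seed(seed, 0L))
  scores <- vapply(seq_len(nrow(grid)), function(i)
    cv_auc(X, y, folds, selected,
           list(num_trees = grid$num_trees[i],
                max_depth = grid$max_depth[i],
                mtry = grid$mtry[i]),
           derive_seed(seed, i)),
    numeric(1))
  # smaller model wins ties: order by -auc, trees, then effective depth
  depth_key <- ifelse(grid$max_depth == 0L, .Machine$integer.max,
                      grid$max_depth)
  best <- order(-scores, grid$num_trees, depth_key)[1]
  list(num_trees = grid$num_trees[best], max_depth = grid$max_depth[best],
       mtry = grid$mtry[best], auc = scores[best])
}

#' Specificity-matched probability threshold
#'
#' Smallest threshold `t` among the sorted unique validation
#' probabilities (plus a sentinel above all of them) such that calling
#' `prob >= t` positive achieves specificity at least
#' `target_specificity` on the validation labels.
#'
#' @param val_probs validation probabilities.
#' @param val_labels logical validation labels; negatives required.
#' @param target_specificity target in `[0, 1]`.
#' @return the calibrated threshold.
#' @export
calibrate_threshold <- function(val_probs, val_labels, target_specificity) {
  if (!any(!val_labels))
    stop("calibrate_threshold: no negatives in the validation set")
  neg <- val_probs[!val_labels]
  cand <- c(sort(unique(val_probs)), max(1, max(val_probs)) + 1e-9)
  for (t in cand) {
    if (mean(neg < t) >= target_specificity) return(t)
  }
  cand[length(cand)]
}

#' Aggregate territory calls to a patient call
#'
#' A patient is positive if any of the three territory calls is positive.
#'
#' @param territory_calls logical vector of exactly 3 calls.
#' @return logical patient call.
#' @export
aggregate_patient <- function(territory_calls) {
  if (length(territory_calls) != 3 || anyNA(territory_calls))
    stop("aggregate_patient: need exactly 3 non-missing territory calls")
  any(territory_calls)
}

#' Sensitivity and specificity of binary calls
#'
#' @param calls logical predictions.
#' @param truth logical reference labels.
#' @return named numeric vector `c(sensitivity, specificity)`; a class
#'   absent from `truth` yields `NA` for its rate.
#' @export
sensitivity_specificity <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  sens <- if (any(truth)) mean(calls[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!calls[!truth]) else NA_real_
  if (anyNA(c(sens, spec)))
    warning("sensitivity_specificity: a class is absent; rate undefined")
  c(sensitivity = sens, specificity = spec)
}

#' McNemar test for paired diagnostic calls
#'
#' Compares two sets of binary calls on the same subjects against a
#' common truth. With `b` subjects correctly called by method A only and
#' `c` by method B only, the asymptotic statistic is
#' `(b - c)^2 / (b + c)` (no continuity correction) referred to
#' chi-squared with 1 df; the exact variant uses the two-sided binomial
#' probability of the observed discordance split. `exact = "auto"`
#' (default) switches to the exact test when `b + c < 25`.
#'
#' @param calls_a,calls_b logical calls from the two methods.
#' @param truth logical reference labels.
#' @param exact `"auto"`, `"never"` or `"always"`.
#' @return list: `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(calls_a, calls_b, truth,
                         exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  stopifnot(length(calls_a) == length(truth),
            length(calls_b) == length(truth))
  ok_a <- calls_a == truth
  ok_b <- calls_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  n <- b + cc
  if (n == 0)
    return(list(statistic = NaN, p_value = 1, b = b, c = cc,
                method = "degenerate"))
  use_exact <- exact == "always" || (exact == "auto" && n < 25)
  stat <- (b - cc)^2 / n
  p <- if (use_exact) min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
       else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, b = b, c = cc,
       method = if (use_exact) "exact-binomial" else "asymptotic")
}

#' Cross-validation configuration
#'
#' @param n_outer_folds outer folds (default 5).
#' @param n_inner_folds inner folds for selection, tuning and threshold
#'   calibration (default 10).
#' @param max_selected_features cap on forward selection (default 50).
#' @param grid hyperparameter grid (`num_trees`, `max_depth`, `mtry`).
#' @param target_specificity specificity the probability threshold is
#'   calibrated to match (default 0.84, a conventional-reader operating
#'   point).
#' @param sfs_num_trees trees per forest during forward selection.
#' @param screen_size candidate-pool size for the univariate screen in
#'   forward selection (`NULL` = no screen).
#' @param seed master seed; every fold and fit derives its own seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(n_outer_folds = 5L, n_inner_folds = 10L,
                      max_selected_features = 50L,
                      grid = default_rf_grid(),
                      target_specificity = 0.84,
                      sfs_num_trees = 50L,
                      screen_size = NULL,
                      seed = 1L) {
  stopifnot(n_outer_folds >= 2, n_inner_folds >= 2,
            target_specificity > 0, target_specificity < 1)
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 max_selected_features = as.integer(max_selected_features),
                 grid = grid,
                 target_specificity = target_specificity,
                 sfs_num_trees = as.integer(sfs_num_trees),
                 screen_size = screen_size,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Nested grouped cross-validation of the territory classifier
#'
#' Outer stratified group K-fold on subjects. Within each outer training
#' fold: the cross-subject delta scaler is fitted (fold-aware), the
#' territory vectors are assembled, sequential feature selection and a
#' hyperparameter grid search run under inner stratified group 10-fold
#' CV, inner out-of-fold probabilities calibrate the probability
#' threshold that matches the target specificity at the patient level
#' (a patient's probability is the maximum over its territories), and
#' the final balanced random forest is refit on the whole outer training
#' fold. The model is then applied to the held-out territories; a patient
#' is called positive if any territory is. Subject-level disjointness of
#' every train/validation split is asserted; a violation is a hard error.
#'
#' @param deltas a `territory_deltas` object (pre-scaling, so the scaler
#'   can be fitted inside each outer fold; preferred), or a
#'   `territory_vectors` object whose values are used as-is (no per-fold
#'   rescaling; appropriate for externally assembled feature tables).
#' @param config a [cv_config()].
#' @return object of class `cv_result`: territory-level out-of-fold
#'   probabilities and calls, patient-level calls, pooled patient
#'   sensitivity and specificity, per-fold thresholds and selected
#'   features, and a fold audit table.
#' @export
nested_cv <- function(deltas, config = cv_config()) {
  stopifnot(inherits(deltas, c("territory_deltas", "territory_vectors")),
            inherits(config, "cv_config"))
  prescaled <- inherits(deltas, "territory_vectors")
  meta <- deltas$meta
  subj <- unique(meta$subject)
  subj_label <- vapply(subj, function(s)
    any(meta$patient_label[meta$subject == s]), logical(1))
  outer <- stratified_group_kfold(setNames(subj_label, subj),
                                  config$n_outer_folds,
                                  derive_seed(config$seed, 1L))
  terr_rows <- list()
  audit <- list()
  thresholds <- numeric(config$n_outer_folds)
  selections <- vector("list", config$n_outer_folds)
  tuned <- vector("list", config$n_outer_folds)

  for (f in seq_len(config$n_outer_folds)) {
    train_subj <- subj[outer[subj] != f]
    test_subj <- subj[outer[subj] == f]
    if (length(intersect(train_subj, test_subj)) > 0)
      stop("nested_cv: subject leakage across the outer split")

    tv <- if (prescaled) deltas else
      assemble_territory_vectors(deltas, fit_delta_scaler(deltas,
                                                          train_subj))
    tr_rows <- which(meta$subject %in% train_subj)
    te_rows <- which(meta$subject %in% test_subj)
    X_tr <- tv$values[tr_rows, , drop = FALSE]
    X_te <- tv$values[te_rows, , drop = FALSE]
    y_tr <- meta$territory_label[tr_rows]
    g_tr <- meta$subject[tr_rows]

    sel <- sequential_select(X_tr, y_tr, g_tr,
                             n_folds = config$n_inner_folds,
                             max_k = config$max_selected_features,
                             seed = derive_seed(config$seed, 100L + f),
                             num_trees = config$sfs_num_trees,
                             screen_size = config$screen_size)
    if (length(sel) == 0) sel <- 1L  # null data: fall back to one feature
    best <- grid_search(X_tr, y_tr, g_tr, sel, config$grid,
                        n_folds = config$n_inner_folds,
                        seed = derive_seed(config$seed, 200L + f))

    # inner out-of-fold probabilities for threshold calibration
    inner <- group_fold_indices(y_tr, g_tr, config$n_inner_folds,
                                derive_seed(config$seed, 300L + f))
    probs_oof <- rep(NA_real_, length(y_tr))
    for (i in seq_along(inner)) {
      itr <- inner[[i]]$train
      iva <- inner[[i]]$val
      if (length(intersect(unique(g_tr[itr]), unique(g_tr[iva]))) > 0)
        stop("nested_cv: subject leakage across an inner split")
      if (length(unique(y_tr[itr])) < 2) next
      fit_i <- balanced_rf_fit(X_tr[itr, sel, drop = FALSE], y_tr[itr],
                               best, derive_seed(config$seed,
                                                 400L + f * 100L + i))
      probs_oof[iva] <- predict(fit_i, X_tr[iva, sel, drop = FALSE])
    }
    cal <- !is.na(probs_oof)
    pat_prob <- tapply(probs_oof[cal], g_tr[cal], max)
    pat_lab <- tapply(meta$patient_label[tr_rows][cal], g_tr[cal], any)
    thr <- calibrate_threshold(as.numeric(pat_prob), as.logical(pat_lab),
                               config$target_specificity)

    final <- balanced_rf_fit(X_tr[, sel, drop = FALSE], y_tr, best,
                             derive_seed(config$seed, 500L + f))
    probs_te <- predict(final, X_te[, sel, drop = FALSE])

    thresholds[f] <- thr
    selections[[f]] <- colnames(X_tr)[sel]
    tuned[[f]] <- best
    terr_rows[[f]] <- data.frame(
      fold = f,
      subject = meta$subject[te_rows],
      territory = meta$territory[te_rows],
      prob = probs_te,
      call = probs_te >= thr,
      territory_label = meta$territory_label[te_rows],
      patient_label = meta$patient_label[te_rows])
    audit[[f]] <- list(outer_train = train_subj, outer_test = test_subj,
                       inner_train = lapply(inner, function(z)
                         unique(g_tr[z$train])),
                       inner_val = lapply(inner, function(z)
                         unique(g_tr[z$val])))
  }

  terr <- do.call(rbind, terr_rows)
  pat <- do.call(rbind, lapply(split(terr, terr$subject), function(d)
    data.frame(subject = d$subject[1], fold = d$fold[1],
               call = aggregate_patient(d$call),
               label = d$patient_label[1])))
  rownames(pat) <- NULL
  ss <- sensitivity_specificity(pat$call, pat$label)
  structure(list(territory = terr, patient = pat,
                 sensitivity = unname(ss["sensitivity"]),
                 specificity = unname(ss["specificity"]),
                 thresholds = thresholds, selections = selections,
                 hyperparams = tuned, outer_folds = outer,
                 audit = audit, config = config),
            class = "cv_result")
}

#' Feature-type selection frequencies across folds
#'
#' Summarizes which base features (aggregated over histogram bins and
#' slices) were selected in how many outer folds: each fold contributes
#' an indicator per base feature name.
#'
#' @param cv a `cv_result` from [nested_cv()].
#' @return data frame `feature`, `frequency`, sorted by descending
#'   frequency then alphabetically.
#' @export
feature_ranking <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  base_names <- sort(unique(feature_catalogue()$all))
  counts <- setNames(rep(0L, length(base_names)), base_names)
  for (sel in cv$selections) {
    bases <- unique(vapply(strsplit(sel, "|", fixed = TRUE),
                           `[`, character(1), 2L))
    counts[bases] <- counts[bases] + 1L
  }
  out <- data.frame(feature = names(counts), frequency = unname(counts))
  out[order(-out$frequency, out$feature), , drop = FALSE]
}
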