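## Evaluation harness: stratified patient-level splitting, cross-validation
## with per-fold re-initialized classifiers and training-only resampling,
## confusion/ranking metrics, and bootstrap confidence intervals.

#' Split plan for the evaluation pipeline
#'
#' The primary layout reserves 20% of patients for evaluating feature
#' selection and 80% for the prediction-model evaluation, via a stratified
#' shuffle at the patient level; the model set is then cross-validated with
#' stratified 10-fold splits.
#'
#' @param select_frac Fraction of patients in the feature-selection set.
#' @param folds Cross-validation folds on the model set.
#' @param stratified Preserve class proportions (always recommended).
#' @param seed Integer seed.
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(select_frac = 0.20, folds = 10L, stratified = TRUE,
                       seed = 1L) {
  stopifnot(select_frac > 0, select_frac < 1, folds >= 2L)
  structure(list(select_frac = select_frac, folds = as.integer(folds),
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_plan")
}

#' Stratified patient-level partition into selection and model sets
#'
#' Disjoint, exhaustive, class-proportion preserving (within one patient per
#' class); performed on patients so no patient can contribute instances to
#' both sets.
#'
#' @param patient_ids Unique patient identifiers.
#' @param patient_labels 0/1 label per patient (1 = any positive instance).
#' @param plan A [split_plan()].
#' @return List with integer vectors `selection` and `model` (patient ids).
#' @export
stratified_partition <- function(patient_ids, patient_labels, plan) {
  stopifnot(inherits(plan, "split_plan"),
            length(patient_ids) == length(patient_labels),
            !anyDuplicated(patient_ids))
  if (length(unique(patient_labels)) < 2L) {
    stopf("both classes must be present among patients")
  }
  sel <- integer(0)
  with_seed(child_seed(plan$seed, "partition"), {
    for (cl in sort(unique(patient_labels))) {
      ids <- patient_ids[patient_labels == cl]
      n_sel <- max(1L, round(plan$select_frac * length(ids)))
      if (n_sel >= length(ids)) {
        stopf("class %s has too few patients (%d) for the split", cl,
              length(ids))
      }
      sel <- c(sel, sample(ids, n_sel))
    }
  })
  list(selection = sort(sel), model = sort(setdiff(patient_ids, sel)))
}

#' Stratified patient-level cross-validation folds
#'
#' @param patient_ids Unique patient identifiers (model set).
#' @param patient_labels 0/1 label per patient.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per patient (named by patient id).
#' @export
make_patient_folds <- function(patient_ids, patient_labels, folds, seed) {
  for (cl in unique(patient_labels)) {
    n_cl <- sum(patient_labels == cl)
    if (n_cl < folds) {
      stopf("class %s has %d patients, fewer than %d folds", cl, n_cl, folds)
    }
  }
  with_seed(child_seed(seed, "folds"), {
    f <- integer(length(patient_ids))
    for (cl in unique(patient_labels)) {
      idx <- which(patient_labels == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    setNames(f, patient_ids)
  })
}

#' Classification metrics
#'
#' Confusion-matrix metrics from thresholded predictions and ranking metrics
#' from scores: accuracy, AUROC, APRC (average precision), F1,
#' frequency-weighted F1, macro F1, PPV and NPV. With single-class labels the
#' ranking metrics are `NA` while the confusion metrics are still returned;
#' an undefined ratio (empty denominator) is `NA`.
#'
#' @param scores Numeric scores (probabilities of the positive class).
#' @param labels 0/1 labels.
#' @param predictions Optional 0/1 predictions (default `scores >= 0.5`).
#' @return Named numeric vector.
#' @export
compute_metrics <- function(scores, labels, predictions = NULL) {
  labels <- as.integer(labels)
  if (is.null(predictions)) predictions <- as.integer(scores >= 0.5)
  tp <- sum(predictions == 1L & labels == 1L)
  fp <- sum(predictions == 1L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  rec <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(ppv) && !is.na(rec) && (ppv + rec) > 0) {
    2 * ppv * rec / (ppv + rec)
  } else if (tp + fp + fn == 0L) NA_real_ else 0
  ## per-class F1 for the negative class
  ppv0 <- safe_div(tn, tn + fn)
  rec0 <- safe_div(tn, tn + fp)
  f1_0 <- if (!is.na(ppv0) && !is.na(rec0) && (ppv0 + rec0) > 0) {
    2 * ppv0 * rec0 / (ppv0 + rec0)
  } else if (tn + fn + fp == 0L) NA_real_ else 0
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  both <- n1 > 0L && n0 > 0L
  c(accuracy = (tp + tn) / length(labels),
    auroc = if (both) auroc(scores, labels) else NA_real_,
    aprc = if (both) average_precision(scores, labels) else NA_real_,
    f1 = f1,
    weighted_f1 = if (both) (n1 * f1 + n0 * f1_0) / (n1 + n0) else NA_real_,
    macro_f1 = if (both) (f1 + f1_0) / 2 else NA_real_,
    ppv = ppv, npv = npv)
}

#' Cross-validate one classifier on the model set
#'
#' Patient-disjoint stratified folds; for each fold a fresh
#' default-hyperparameter classifier is instantiated, the resampling plan is
#' applied to the training fold only, and metrics are computed on the
#' untouched validation fold. Pooled ("microaverage") out-of-fold predictions
#' are returned for bootstrap interval estimation.
#'
#' @param x Feature matrix (model set instances).
#' @param labels 0/1 instance labels.
#' @param patient_ids Patient id per instance (for fold disjointness).
#' @param classifier One of [classifier_names()].
#' @param plan A [split_plan()].
#' @param sampling A [resample_plan()].
#' @param audit Optional audit collector from [new_audit()].
#' @return Object of class `lons_cv`: list with `fold_metrics` (matrix),
#'   `pooled` (scores, labels, predictions), `classifier`.
#' @export
cross_validate <- function(x, labels, patient_ids, classifier,
                           plan = split_plan(), sampling = resample_plan(),
                           audit = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  up <- unique(patient_ids)
  plab <- vapply(up, function(p) max(labels[patient_ids == p]), integer(1L))
  fold_of <- make_patient_folds(up, plab, plan$folds, plan$seed)
  cls <- get_classifier(classifier)

  fold_metrics <- NULL
  sc <- numeric(0); lb <- integer(0); pr <- integer(0)
  for (fi in seq_len(plan$folds)) {
    val_pat <- up[fold_of == fi]
    val <- patient_ids %in% val_pat
    audit_check(audit, "fold_patient_disjoint",
                length(intersect(patient_ids[val], patient_ids[!val])) == 0L)
    if (length(unique(labels[!val])) < 2L) next
    rs <- resample(x[!val, , drop = FALSE], labels[!val], sampling,
                   partition = "train")
    audit_check(audit, "resample_train_only", TRUE)
    model <- cls$fit(rs$x, rs$y, child_seed(plan$seed, classifier, fi))
    p <- cls$predict(model, x[val, , drop = FALSE])
    m <- compute_metrics(p, labels[val])
    fold_metrics <- rbind(fold_metrics, m)
    sc <- c(sc, p); lb <- c(lb, labels[val]); pr <- c(pr, as.integer(p >= 0.5))
  }
  structure(list(fold_metrics = fold_metrics,
                 pooled = list(scores = sc, labels = lb, predictions = pr),
                 classifier = classifier),
            class = "lons_cv")
}

#' Bootstrap confidence interval for a metric
#'
#' Resamples the evaluation instances with replacement `B` times, recomputes
#' the metric on each resample and reports the empirical percentile interval.
#' Resamples containing a single class are redrawn (counted); when the metric
#' is undefined on more than half of the resamples the interval is absent.
#'
#' @param labels 0/1 labels of the evaluation set.
#' @param scores Scores aligned with `labels`.
#' @param predictions 0/1 predictions.
#' @param metric Metric name (a column of [compute_metrics()]).
#' @param B Number of bootstrap turns (default 100).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric vector `c(point, low, high)` (`low`/`high` `NA` when the
#'   interval is absent); attribute `redrawn` counts redrawn resamples.
#' @export
bootstrap_ci <- function(labels, scores, predictions = NULL, metric = "auroc",
                         B = 100L, level = 0.95, seed = 1L) {
  stopifnot(B >= 2L)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  if (is.null(predictions)) predictions <- as.integer(scores >= 0.5)
  point <- compute_metrics(scores, labels, predictions)[[metric]]
  n <- length(labels)
  vals <- numeric(B)
  redrawn <- 0L
  with_seed(child_seed(seed, "boot", metric), {
    for (b in seq_len(B)) {
      for (tries in seq_len(1000L)) {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redrawn <- redrawn + 1L
      }
      vals[b] <- compute_metrics(scores[idx], labels[idx],
                                 predictions[idx])[[metric]]
    }
  })
  ok <- is.finite(vals)
  out <- if (mean(ok) < 0.5) {
    warnf("metric '%s' undefined on %.0f%% of resamples; CI absent",
          metric, 100 * mean(!ok))
    c(point = point, low = NA_real_, high = NA_real_)
  } else {
    qs <- quantile(vals[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE, type = 7)
    c(point = point, low = qs[1L], high = qs[2L])
  }
  attr(out, "redrawn") <- redrawn
  out
}

## ---- leakage audit collector ----

#' Create a leakage-audit collector
#'
#' A mutable collector the harness threads through its stages; every
#' disjointness or training-only assertion increments `checks`, and any
#' failure increments `violations`.
#'
#' @return Environment of class `lons_audit` with counters.
#' @export
new_audit <- function() {
  e <- new.env(parent = emptyenv())
  e$checks <- 0L
  e$violations <- 0L
  class(e) <- "lons_audit"
  e
}

audit_check <- function(audit, what, ok) {
  if (is.null(audit)) return(invisible(NULL))
  audit$checks <- audit$checks + 1L
  if (!isTRUE(ok)) {
    audit$violations <- audit$violations + 1L
    warnf("leakage audit violation: %s", what)
  }
  invisible(NULL)
}

#' @export
print.lons_audit <- function(x, ...) {
  cat(sprintf("Leakage audit: %d checks, %d violations\n",
              x$checks, x$violations))
  invisible(x)
}
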