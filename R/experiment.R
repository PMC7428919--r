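## End-to-end experiment driver: simulate-or-load -> label -> featurize ->
## select -> resample -> cross-validate -> bootstrap, producing report tables
## per (task, window, selector, sampler, classifier) combination.

#' Default experiment configuration
#'
#' @param sim A [sim_config()] (ignored when `data_dir` is given).
#' @param data_dir Optional directory of event tables to load instead of
#'   simulating.
#' @param tasks Tasks to run (`"predict_48h"`, `"detect"`).
#' @param windows Observation windows in hours (default 24; the 3 h window is
#'   supported but outside the default grid).
#' @param selectors Any of `"proposed"`, `"baseline"`, `"chi2"`,
#'   `"mutual_info"`, `"lasso_l1"`, `"extra_trees"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param samplers Sampling method names accepted by [resample_plan()].
#' @param classifiers Subset of [classifier_names()].
#' @param k Specs per vital for the proposed selector (and total/7 for
#'   comparators).
#' @param split A [split_plan()].
#' @param bootstrap_B Bootstrap turns for the 95% intervals.
#' @param cadence_h Instance cadence (detection positives / control grid).
#' @param seed Master seed.
#' @return List of class `lons_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              data_dir = NULL,
                              tasks = c("predict_48h", "detect"),
                              windows = 24,
                              selectors = c("proposed", "baseline"),
                              classifiers = classifier_names(),
                              samplers = "none",
                              k = 3L,
                              split = split_plan(),
                              bootstrap_B = 100L,
                              cadence_h = 24,
                              seed = 1L) {
  structure(list(sim = sim, data_dir = data_dir, tasks = tasks,
                 windows = windows, selectors = selectors,
                 classifiers = classifiers, samplers = samplers, k = k,
                 split = split, bootstrap_B = bootstrap_B,
                 cadence_h = cadence_h, seed = as.integer(seed)),
            class = "lons_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Accepts a structured text file with any of the sections `sim`, `tasks`,
#' `windows`, `selectors`, `classifiers`, `samplers`, `k`, `split`,
#' `bootstrap_B`, `cadence_h`, `seed`, `data_dir`; unspecified entries keep
#' the [experiment_config()] defaults. `sim` and `split` entries are passed
#' to [sim_config()] / [split_plan()].
#'
#' @param path Path to the YAML file.
#' @return A `lons_config`.
#' @export
experiment_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("the 'yaml' package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("sim", "split"))]
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$split)) args$split <- do.call(split_plan, raw$split)
  do.call(experiment_config, args)
}

#' Run the full evaluation experiment
#'
#' Executes the pipeline of the evaluation design: patients are partitioned
#' (stratified, patient-level) into a feature-selection set and a model set;
#' selectors see only the selection set; each classifier is evaluated with
#' patient-disjoint stratified cross-validation on the model set, resampling
#' applied to training folds only, metrics pooled over out-of-fold
#' predictions (microaverage) with bootstrap 95% intervals. A feature
#' importance table (normalized to sum to one) is derived from a gradient
#' boosting model fitted to the selected features of the first task/window.
#'
#' @param config An [experiment_config()].
#' @param cohort Optionally, a pre-generated `lons_cohort` (overrides
#'   `config$sim` / `config$data_dir`).
#' @return Object of class `lons_eval`: list with `report` (one row per
#'   combination and metric set), `selections`, `objective` (selection-split
#'   F per selector/window/task), `importance`, `audit`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "lons_config"))
  audit <- new_audit()
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$data_dir)) {
      read_event_tables(config$data_dir)
    } else {
      generate_cohort(config$sim)
    }
  }
  labels_tab <- build_cohort_labels(cohort)
  cov <- vitals_coverage(cohort$tables$vitals)
  max_w <- max(config$windows)

  report <- list()
  objective <- list()
  selections <- list()
  importance <- NULL

  for (task in config$tasks) {
    inst <- build_instances(labels_tab, cov, task, cadence_h = config$cadence_h,
                            window_h = max_w)
    if (!nrow(inst) || length(unique(inst$label)) < 2L) {
      stopf("stage build_instances produced a degenerate instance set (task %s)",
            task)
    }
    up <- unique(inst$SUBJECT_ID)
    plab <- inst[, .(y = max(label)), by = SUBJECT_ID]
    part <- stratified_partition(plab$SUBJECT_ID, plab$y, config$split)
    audit_check(audit, "selection_model_patient_disjoint",
                length(intersect(part$selection, part$model)) == 0L)
    audit_check(audit, "selection_model_exhaustive",
                setequal(c(part$selection, part$model), up))
    inst_sel <- inst[SUBJECT_ID %in% part$selection]
    inst_mod <- inst[SUBJECT_ID %in% part$model]

    for (w in config$windows) {
      cand <- candidate_specs(w)
      feat_sel <- build_feature_matrix(inst_sel, cohort$tables$vitals, cand)
      sel_list <- list()
      for (sm in config$selectors) {
        sel <- selector_dispatch(sm, feat_sel, inst_sel$label, config, w)
        sel_list[[sm]] <- sel
        selections[[paste(task, w, sm, sep = "/")]] <- sel
        ## objective F of the selected set on the selection split
        fsel <- if (nrow(sel$selected)) {
          fold_ids <- stratified_fold_ids(
            inst_sel$label, min(5L, sum(inst_sel$label == 1L)),
            child_seed(config$seed, "objF", task, w, sm))
          cv_objective(feat_sel$x, inst_sel$label,
                       match(sel$selected$name, colnames(feat_sel$x)),
                       fold_ids)
        } else NA_real_
        objective[[length(objective) + 1L]] <- data.frame(
          task = task, window = w, selector = sm, F = fsel)
      }

      union_specs <- unique(do.call(rbind, lapply(sel_list,
                                                  function(s) s$selected)))
      feat_mod <- build_feature_matrix(inst_mod, cohort$tables$vitals,
                                       union_specs)
      audit_check(audit, "selector_never_sees_model_set",
                  !any(feat_mod$instances$SUBJECT_ID %in% part$selection))

      for (sm in config$selectors) {
        sel <- sel_list[[sm]]
        cols <- match(sel$selected$name, colnames(feat_mod$x))
        if (!length(cols) || anyNA(cols)) next
        xm <- feat_mod$x[, cols, drop = FALSE]
        for (samp in config$samplers) {
          splan <- resample_plan(samp, seed = child_seed(config$seed, "samp",
                                                         task, w, sm, samp))
          for (clf in config$classifiers) {
            cv <- cross_validate(
              xm, inst_mod$label, inst_mod$SUBJECT_ID, clf,
              plan = split_plan(config$split$select_frac, config$split$folds,
                                config$split$stratified,
                                child_seed(config$seed, "cv", task, w, sm,
                                           samp, clf)),
              sampling = splan, audit = audit)
            row <- summarize_cv(cv, config$bootstrap_B,
                                child_seed(config$seed, "boot", task, w, sm,
                                           samp, clf))
            report[[length(report) + 1L]] <- cbind(
              data.frame(task = task, window = w, selector = sm,
                         sampler = samp, classifier = clf), row)
          }
        }
        if (is.null(importance) && sm == config$selectors[1L]) {
          importance <- importance_table(xm, inst_mod$label, sel$selected,
                                         child_seed(config$seed, "imp"))
        }
      }
    }
  }
  structure(list(report = do.call(rbind, report),
                 objective = do.call(rbind, objective),
                 selections = selections, importance = importance,
                 audit = audit, config = config,
                 labels = labels_tab), class = "lons_eval")
}

selector_dispatch <- function(sm, feat_sel, labels, config, w) {
  if (sm == "proposed") {
    forward_select(feat_sel, labels, k = config$k,
                   seed = child_seed(config$seed, "fwd", w))
  } else if (sm == "baseline") {
    bs <- baseline_specs(w)
    structure(list(method = "baseline", selected = bs, per_vital = NULL,
                   window = w), class = "lons_selection")
  } else {
    comparator_select(feat_sel, labels, sm, k_total = 7L * config$k,
                      seed = child_seed(config$seed, "cmp", w, sm))
  }
}

summarize_cv <- function(cv, B, seed) {
  pooled <- cv$pooled
  metrics <- c("accuracy", "auroc", "aprc", "f1", "weighted_f1", "ppv", "npv")
  pt <- compute_metrics(pooled$scores, pooled$labels, pooled$predictions)
  out <- data.frame(mean_fold_auroc = mean(cv$fold_metrics[, "auroc"],
                                           na.rm = TRUE))
  for (m in metrics) {
    ci <- bootstrap_ci(pooled$labels, pooled$scores, pooled$predictions,
                       metric = m, B = B, seed = seed)
    out[[m]] <- pt[[m]]
    out[[paste0(m, "_lo")]] <- ci[["low"]]
    out[[paste0(m, "_hi")]] <- ci[["high"]]
  }
  out
}

## Normalized gain importances of a gradient-boosting fit on the selected
## features (sums to 1).
importance_table <- function(x, labels, specs, seed) {
  sc <- xgb_importance_scores(x, labels, seed)
  if (sum(sc) <= 0) sc <- rep(1 / length(sc), length(sc))
  data.frame(vital = specs$vital, transform = specs$transform,
             stat = specs$stat, window = specs$window,
             name = specs$name, importance = sc / sum(sc),
             row.names = NULL)[order(-sc), ]
}

#' @export
print.lons_eval <- function(x, ...) {
  cat("LONS evaluation report\n")
  cat(sprintf("  %d report rows | audit: %d checks, %d violations\n",
              nrow(x$report), x$audit$checks, x$audit$violations))
  cols <- c("task", "window", "selector", "sampler", "classifier",
            "auroc", "aprc", "f1")
  print(utils::head(x$report[, cols], 12L), digits = 3)
  invisible(x)
}

#' @export
summary.lons_eval <- function(object, ...) {
  agg <- object$report[, c("task", "window", "selector", "classifier",
                           "accuracy", "auroc", "aprc", "f1", "weighted_f1",
                           "ppv", "npv")]
  structure(list(metrics = agg, objective = object$objective,
                 audit = c(checks = object$audit$checks,
                           violations = object$audit$violations)),
            class = "summary.lons_eval")
}

#' @export
print.summary.lons_eval <- function(x, ...) {
  cat("Classifier metrics (microaverage over folds):\n")
  print(x$metrics, digits = 3)
  cat("\nSelection objective F (selection split):\n")
  print(x$objective, digits = 3)
  cat(sprintf("\nLeakage audit: %d checks, %d violations\n",
              x$audit["checks"], x$audit["violations"]))
  invisible(x)
}

#' @export
plot.lons_eval <- function(x, metric = "auroc", ...) {
  rep <- x$report
  lab <- paste(rep$classifier, rep$selector, rep$task, sep = " / ")
  graphics::dotchart(rep[[metric]], labels = lab, xlab = metric,
                     xlim = c(0, 1), pch = 19, cex = 0.7)
  lo <- rep[[paste0(metric, "_lo")]]; hi <- rep[[paste0(metric, "_hi")]]
  if (!is.null(lo)) {
    graphics::segments(lo, seq_len(nrow(rep)), hi, seq_len(nrow(rep)))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report_selectors.csv` (selector comparison rows),
#' `report_models.csv` (classifier grid), `selected_features.json`,
#' `importance.csv` and `metrics.json`.
#'
#' @param eval A `lons_eval`.
#' @param dir Output directory.
#' @return Invisibly, the file paths written.
#' @export
write_eval_report <- function(eval, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "report_models.csv")
  utils::write.csv(eval$report, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "report_selectors.csv")
  utils::write.csv(eval$objective, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "importance.csv")
  utils::write.csv(eval$importance, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "selected_features.json")
  sel <- lapply(eval$selections, function(s) {
    list(method = s$method, window = s$window, specs = s$selected$name)
  })
  jsonlite::write_json(sel, p, auto_unbox = TRUE); paths <- c(paths, p)
  p <- file.path(dir, "metrics.json")
  jsonlite::write_json(eval$report, p, dataframe = "rows", digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
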