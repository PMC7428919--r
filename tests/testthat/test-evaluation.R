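# Evaluation harness: metrics, splits, cross-validation, bootstrap, and the
# end-to-end experiment driver.

test_that("confusion and ranking metrics match hand-computed values", {
  ## TP=2 FP=1 FN=1 TN=6
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.2, 0.3, 0.1, 0.2)
  m <- compute_metrics(scores, labels)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["ppv"]), 2 / 3)
  expect_equal(unname(m["npv"]), 6 / 7)
  expect_equal(unname(m["f1"]), 2 / 3)
  expect_equal(unname(compute_metrics(c(0.1, 0.4, 0.35, 0.8),
                                      c(0, 0, 1, 1))["auroc"]), 0.75)
  perf <- compute_metrics(c(0.1, 0.1, 0.9, 0.9), c(0, 0, 1, 1))
  expect_true(all(perf[c("accuracy", "auroc", "aprc", "f1", "ppv", "npv")] == 1))
  one <- compute_metrics(c(0.2, 0.7), c(0, 0))
  expect_true(is.na(one["auroc"]))
  expect_false(is.na(one["accuracy"]))
})

test_that("metric suite matches oracles on random prediction vectors", {
  set.seed(33)
  for (i in 1:300) {
    n <- sample(6:80, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)
    m <- compute_metrics(s, y)
    o <- oracle_confusion_metrics(s, y)
    expect_equal(unname(m["accuracy"]), unname(o["accuracy"]))
    expect_rel_equal(unname(m["ppv"]), unname(o["ppv"]))
    expect_rel_equal(unname(m["npv"]), unname(o["npv"]))
    expect_equal(unname(m["f1"]), unname(o["f1"]))
    expect_equal(unname(m["auroc"]), oracle_auroc(s, y), tolerance = 1e-9)
    expect_equal(unname(m["aprc"]), oracle_ap(s, y), tolerance = 1e-9)
  }
})

test_that("stratified partition is disjoint, exhaustive and proportion-preserving", {
  ids <- 1:100
  labs <- c(rep(1, 10), rep(0, 90))
  plan <- split_plan(select_frac = 0.2, seed = 4)
  p <- stratified_partition(ids, labs, plan)
  expect_length(intersect(p$selection, p$model), 0)
  expect_setequal(c(p$selection, p$model), ids)
  expect_equal(sum(labs[p$selection] == 1), 2, tolerance = 1)
  expect_identical(stratified_partition(ids, labs, plan), p)
  expect_error(stratified_partition(ids, rep(0, 100), plan), "both classes")
  expect_error(make_patient_folds(1:20, c(rep(1, 5), rep(0, 15)), 10, 1),
               "fewer than")
})

test_that("cross-validation keeps folds patient-disjoint and leak-free", {
  set.seed(9)
  n_pat <- 60
  pat <- rep(1:n_pat, each = 4)
  y_pat <- c(rep(1L, 15), rep(0L, 45))
  y <- y_pat[pat]
  x <- matrix(rnorm(length(pat) * 3), ncol = 3)
  x[, 1] <- y * 10 + rnorm(length(y), 0, 0.1)  # perfectly separable feature
  audit <- new_audit()
  cv <- cross_validate(x, y, pat, "gaussian_nb",
                       plan = split_plan(folds = 5, seed = 2),
                       sampling = resample_plan("none"), audit = audit)
  expect_equal(audit$violations, 0L)
  expect_gt(audit$checks, 0L)
  expect_equal(length(cv$pooled$labels), length(y))
  expect_gt(mean(cv$fold_metrics[, "auroc"]), 0.95)
  ## separable case: logistic regression reaches fold AUROC 1
  cvl <- cross_validate(x, y, pat, "logistic_regression",
                        plan = split_plan(folds = 5, seed = 2))
  expect_equal(mean(cvl$fold_metrics[, "auroc"]), 1)
  ## determinism
  cv2 <- cross_validate(x, y, pat, "gaussian_nb",
                        plan = split_plan(folds = 5, seed = 2),
                        sampling = resample_plan("none"))
  expect_identical(cv$fold_metrics, cv2$fold_metrics)
  expect_error(cross_validate(x, y, pat, "svm"), "unknown classifier")
})

test_that("every registered classifier trains and scores", {
  set.seed(26)
  n <- 160
  y <- rbinom(n, 1, 0.4)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + 2 * y
  for (nm in classifier_names()) {
    cl <- get_classifier(nm)
    fit <- cl$fit(x, y, seed = 3)
    p <- cl$predict(fit, x)
    expect_length(p, n)
    expect_true(all(is.finite(p)) && all(p >= 0) && all(p <= 1), label = nm)
    expect_gt(auroc(p, y), 0.7, label = paste("in-sample auroc of", nm))
  }
})

test_that("bootstrap interval behaviour: degenerate width, determinism, coverage", {
  y <- rep(c(0L, 1L), each = 20)
  s <- c(rep(0.1, 20), rep(0.9, 20))  # perfect classifier
  ci <- bootstrap_ci(y, s, metric = "auroc", B = 50, seed = 1)
  expect_equal(unname(ci["point"]), 1)
  expect_equal(unname(ci["high"] - ci["low"]), 0)
  ci2 <- bootstrap_ci(y, s, metric = "auroc", B = 50, seed = 1)
  expect_identical(ci, ci2)
})

test_that("experiment configuration round-trips through a YAML file", {
  skip_if_not_installed("yaml")
  path <- file.path(tempdir(), "neowarn-config.yaml")
  writeLines(c(
    "sim:", "  n_patients: 80", "  lons_prevalence: 0.2", "  seed: 3",
    "tasks: predict_48h", "windows: 12", "selectors: baseline",
    "classifiers: gaussian_nb", "bootstrap_B: 10", "seed: 4"), path)
  cfg <- experiment_config_from_yaml(path)
  expect_s3_class(cfg, "lons_config")
  expect_equal(cfg$sim$n_patients, 80L)
  expect_equal(cfg$windows, 12)
  expect_equal(cfg$selectors, "baseline")
  expect_equal(cfg$samplers, "none")  # default preserved
  unlink(path)
})

test_that("a small end-to-end experiment is reproducible and leak-audited", {
  cfg <- experiment_config(
    sim = sim_config(n_patients = 160, lons_prevalence = 0.15, seed = 21),
    tasks = "predict_48h", windows = 6,
    selectors = c("proposed", "baseline"),
    classifiers = c("gaussian_nb", "decision_tree"),
    bootstrap_B = 20, seed = 5)
  ev <- run_experiment(cfg)
  expect_s3_class(ev, "lons_eval")
  expect_equal(nrow(ev$report), 4)  # 2 selectors x 2 classifiers
  expect_equal(ev$audit$violations, 0L)
  expect_gt(ev$audit$checks, 10L)
  expect_equal(sum(ev$importance$importance), 1, tolerance = 1e-6)
  expect_true(all(ev$report$auroc >= 0 & ev$report$auroc <= 1))
  expect_true(all(ev$report$auroc_lo <= ev$report$auroc + 1e-12, na.rm = TRUE))

  ev2 <- run_experiment(cfg)
  expect_identical(ev$report, ev2$report)

  dir <- file.path(tempdir(), "neowarn-report")
  paths <- write_eval_report(ev, dir)
  expect_true(all(file.exists(paths)))
  unlink(dir, recursive = TRUE)
})
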