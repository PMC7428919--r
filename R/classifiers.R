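## Registry of the nine classifiers compared by the evaluation harness.
##
## Every entry is a pair of closures (fit, predict) built fresh for each
## cross-validation fold with default hyperparameters — no tuning anywhere.
## Scores returned by predict are probabilities of the positive class (or a
## monotone score mapped through the logistic for margin-based ensembles).

#' Names of the available classifiers
#' @return Character vector of length 9.
#' @export
classifier_names <- function() {
  c("logistic_regression", "gaussian_nb", "decision_tree",
    "gradient_boosting", "adaboost", "bagging", "random_forest",
    "extra_trees", "mlp")
}

#' Classifier registry
#'
#' Returns the fit/predict implementation for one classifier. Fits are
#' deterministic given `seed`. Documented defaults: gradient boosting uses
#' 100 rounds of depth-3 trees at learning rate 0.1; AdaBoost is SAMME with
#' 50 depth-1 stumps; bagging aggregates 25 bootstrap CART trees; the random
#' forest and extremely randomized trees use 300 trees; the multilayer
#' perceptron is a single hidden layer of 16 units with L2 weight decay 1e-4
#' on standardized inputs.
#'
#' @param name One of [classifier_names()].
#' @return List with elements `fit(x, y, seed)` and `predict(model, x)`.
#' @export
get_classifier <- function(name) {
  if (!name %in% classifier_names()) stopf("unknown classifier '%s'", name)
  switch(name,
    ## L2-regularized logistic regression on standardized features, fitted
    ## along a warm-started ridge path (the numerically reliable way to reach
    ## a small penalty with glmnet) and evaluated at lambda = max(1/n, path
    ## minimum); regularization keeps coefficients finite under separation
    logistic_regression = list(
      fit = function(x, y, seed) {
        x <- as.matrix(x)
        keep <- apply(x, 2L, function(cc) sd(cc) > 0)
        if (sum(keep) < 2L) keep <- rep(TRUE, ncol(x))
        fit <- glmnet::glmnet(x[, keep, drop = FALSE], factor(y, c(0L, 1L)),
                              family = "binomial", alpha = 0,
                              nlambda = 40L, lambda.min.ratio = 1e-4,
                              standardize = TRUE)
        list(fit = fit, keep = keep,
             s = max(1 / length(y), min(fit$lambda)))
      },
      predict = function(m, x) {
        as.numeric(predict(m$fit, as.matrix(x)[, m$keep, drop = FALSE],
                           s = m$s, type = "response"))
      }),
    gaussian_nb = list(
      fit = function(x, y, seed) gnb_fit(x, y),
      predict = function(m, x) gnb_predict(m, x)),
    decision_tree = list(
      fit = function(x, y, seed) {
        df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(x)))
        df$.y <- factor(y, levels = c(0L, 1L))
        with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class"))
      },
      predict = function(m, x) {
        df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(x)))
        as.numeric(predict(m, df, type = "prob")[, "1"])
      }),
    gradient_boosting = list(
      fit = function(x, y, seed) {
        with_seed(seed, {
          xm <- as.matrix(x); colnames(xm) <- paste0("f", seq_len(ncol(xm)))
          xgboost::xgb.train(
            params = list(objective = "binary:logistic", max_depth = 3L,
                          eta = 0.1, nthread = 1L),
            data = xgboost::xgb.DMatrix(xm, label = y), nrounds = 100L,
            verbose = 0L)
        })
      },
      predict = function(m, x) {
        xm <- as.matrix(x); colnames(xm) <- paste0("f", seq_len(ncol(xm)))
        as.numeric(predict(m, xgboost::xgb.DMatrix(xm)))
      }),
    adaboost = list(
      fit = function(x, y, seed) adaboost_fit(x, y, m_rounds = 50L, seed),
      predict = function(m, x) adaboost_predict(m, x)),
    bagging = list(
      fit = function(x, y, seed) bagging_fit(x, y, n_bags = 25L, seed),
      predict = function(m, x) bagging_predict(m, x)),
    random_forest = list(
      fit = function(x, y, seed) ranger_fit(x, y, seed, extratrees = FALSE),
      predict = function(m, x) ranger_prob(m, x)),
    extra_trees = list(
      fit = function(x, y, seed) ranger_fit(x, y, seed, extratrees = TRUE),
      predict = function(m, x) ranger_prob(m, x)),
    mlp = list(
      fit = function(x, y, seed) {
        x <- as.matrix(x)
        ctr <- colMeans(x)
        scl <- apply(x, 2L, sd); scl[scl == 0 | !is.finite(scl)] <- 1
        xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
        fit <- with_seed(seed, nnet::nnet(
          xs, y, size = 16L, decay = 1e-4, maxit = 200L, trace = FALSE,
          entropy = TRUE, MaxNWts = 10000L))
        list(fit = fit, ctr = ctr, scl = scl)
      },
      predict = function(m, x) {
        xs <- sweep(sweep(as.matrix(x), 2L, m$ctr), 2L, m$scl, "/")
        as.numeric(predict(m$fit, xs))
      })
  )
}

## ---- SAMME AdaBoost with CART stumps ----

adaboost_fit <- function(x, y, m_rounds, seed) {
  df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(y, levels = c(0L, 1L))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(m_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1L,
                                                         cp = -1, minsplit = 2L,
                                                         xval = 0L))
      pred <- as.integer(predict(fit, df, type = "class") == "1")
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 0.5 || err <= 1e-12) {
        if (err <= 1e-12) { stumps[[m]] <- fit; alphas[m] <- 10 }
        break
      }
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[m]] <- fit; alphas[m] <- alpha
      w <- w * exp(alpha * ifelse(pred != y, 1, -1))
      w <- w / sum(w)
    }
  })
  list(stumps = stumps, alphas = alphas)
}

adaboost_predict <- function(model, x) {
  df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(df)))
  if (!length(model$stumps)) return(rep(0.5, nrow(df)))
  margin <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pm <- as.integer(predict(model$stumps[[m]], df, type = "class") == "1")
    margin <- margin + model$alphas[m] * (2 * pm - 1)
  }
  plogis(margin)
}

## ---- bootstrap-aggregated CART ----

bagging_fit <- function(x, y, n_bags, seed) {
  df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(y, levels = c(0L, 1L))
  with_seed(seed, {
    lapply(seq_len(n_bags), function(b) {
      idx <- sample.int(nrow(df), replace = TRUE)
      rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class")
    })
  })
}

bagging_predict <- function(model, x) {
  df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(df)))
  p <- vapply(model, function(fit) {
    pr <- predict(fit, df, type = "prob")
    if ("1" %in% colnames(pr)) as.numeric(pr[, "1"]) else rep(0, nrow(df))
  }, numeric(nrow(df)))
  rowMeans(matrix(p, nrow = nrow(df)))
}

## ---- ranger-backed forests ----

ranger_fit <- function(x, y, seed, extratrees) {
  df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(y, levels = c(0L, 1L))
  ranger::ranger(
    dependent.variable.name = ".y", data = df, num.trees = 300L,
    probability = TRUE,
    splitrule = if (extratrees) "extratrees" else "gini",
    num.random.splits = 1L,
    replace = !extratrees,
    sample.fraction = if (extratrees) 1 else 0.632,
    num.threads = 1L,
    seed = child_seed(seed, "ranger"))
}

ranger_prob <- function(model, x) {
  df <- as.data.frame(x); names(df) <- paste0("f", seq_len(ncol(df)))
  pr <- predict(model, df, num.threads = 1L)$predictions
  as.numeric(pr[, "1"])
}
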