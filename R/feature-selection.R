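## Feature selection: the per-vital greedy forward algorithm with objective
## F = AUROC + average precision, and six comparator selectors.

#' Area under the ROC curve by pairwise concordance
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted one half (equivalently the rank-sum / Mann-Whitney form).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (at least one of each class).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("auroc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise integral of precision over recall: `sum_k (R_k - R_{k-1}) P_k`
#' across descending unique score thresholds (tied scores enter as one step).
#'
#' @inheritParams auroc
#' @return Average precision in [0, 1].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L || all(labels == 1L)) stopf("average_precision needs both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_tie]
  nn <- cum_n[last_of_tie]
  prec <- tp / nn
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' The combined selection objective F
#'
#' `F = AUROC + average precision`, the joint criterion that scores the
#' ranking quality for the majority and minority class at the same time.
#' Maximum 2 for a perfect ranking.
#'
#' @inheritParams auroc
#' @return F in [0, 2].
#' @export
objective_f <- function(scores, labels) {
  auroc(scores, labels) + average_precision(scores, labels)
}

## ---- internal Gaussian naive Bayes (base model of the wrapper) ----

col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1L)
}

gnb_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  ## per-feature variance floor, independent of which columns are selected
  ## (keeps the model additive across features)
  eps <- 1e-9 * pmax(col_vars(x), 1e-3)
  fit <- list(eps = eps, classes = c(0L, 1L))
  for (cl in c(0L, 1L)) {
    xc <- x[y == cl, , drop = FALSE]
    fit[[paste0("mu", cl)]] <- colMeans(xc)
    v <- col_vars(xc)
    v[!is.finite(v)] <- 0
    fit[[paste0("var", cl)]] <- v + eps
    fit[[paste0("logprior", cl)]] <- log(nrow(xc) / nrow(x))
  }
  class(fit) <- "neowarn_gnb"
  fit
}

gnb_predict <- function(fit, x) {
  x <- as.matrix(x)
  ll <- function(cl) {
    mu <- fit[[paste0("mu", cl)]]; v <- fit[[paste0("var", cl)]]
    -0.5 * rowSums(sweep(sweep(x, 2L, mu)^2, 2L, v, "/") +
                     rep(log(2 * pi * v), each = nrow(x))) +
      fit[[paste0("logprior", cl)]]
  }
  l0 <- ll(0L); l1 <- ll(1L)
  1 / (1 + exp(pmin(700, pmax(-700, l0 - l1))))
}

## Stratified fold ids over instances.
stratified_fold_ids <- function(labels, k, seed) {
  with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
}

## Additive evaluation of the Gaussian-NB objective: because the naive-Bayes
## log-likelihood is a sum over features, the per-fold per-feature
## log-likelihood ratios can be precomputed once and any candidate subset is
## then scored with one rowSums. Rankings (hence F) are identical to fitting
## gnb_fit on the subset.
make_additive_cv <- function(x, labels, fold_ids) {
  k <- max(fold_ids)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  folds <- lapply(seq_len(k), function(fi) {
    tr <- fold_ids != fi
    ytr <- labels[tr]; yval <- labels[!tr]
    if (length(unique(ytr)) < 2L || length(unique(yval)) < 2L) return(NULL)
    xtr <- x[tr, , drop = FALSE]; xval <- x[!tr, , drop = FALSE]
    eps <- 1e-9 * pmax(col_vars(xtr), 1e-3)
    par <- lapply(c(0L, 1L), function(cl) {
      xc <- xtr[ytr == cl, , drop = FALSE]
      v <- col_vars(xc); v[!is.finite(v)] <- 0
      list(mu = colMeans(xc), v = v + eps, lp = log(nrow(xc) / nrow(xtr)))
    })
    d0 <- sweep(xval, 2L, par[[1L]]$mu)^2
    d1 <- sweep(xval, 2L, par[[2L]]$mu)^2
    llr <- 0.5 * (sweep(d0, 2L, par[[1L]]$v, "/") -
                    sweep(d1, 2L, par[[2L]]$v, "/")) +
      rep(0.5 * log(par[[1L]]$v / par[[2L]]$v), each = nrow(xval))
    list(llr = llr, yval = yval, dprior = par[[2L]]$lp - par[[1L]]$lp)
  })
  function(cols) {
    fs <- vapply(folds, function(f) {
      if (is.null(f)) return(NA_real_)
      s <- rowSums(f$llr[, cols, drop = FALSE]) + f$dprior
      objective_f(pmin(700, pmax(-700, s)), f$yval)
    }, numeric(1L))
    mean(fs, na.rm = TRUE)
  }
}

## Mean cross-validated F of the Gaussian NB on a column subset.
cv_objective <- function(x, labels, cols, fold_ids) {
  k <- max(fold_ids)
  fs <- numeric(k)
  for (fi in seq_len(k)) {
    tr <- fold_ids != fi
    if (length(unique(labels[!tr])) < 2L || length(unique(labels[tr])) < 2L) {
      fs[fi] <- NA_real_
      next
    }
    fit <- gnb_fit(x[tr, cols, drop = FALSE], labels[tr])
    p <- gnb_predict(fit, x[!tr, cols, drop = FALSE])
    fs[fi] <- objective_f(p, labels[!tr])
  }
  mean(fs, na.rm = TRUE)
}

#' Greedy per-vital forward feature selection
#'
#' For each vital sign, starts from the empty set and greedily adds, up to
#' `k` times, the candidate spec of that vital that maximizes the mean
#' cross-validated objective `F = AUROC + average precision` of a Gaussian
#' naive Bayes base model, stopping early when no candidate improves F. The
#' union of the per-vital selections is the selected feature set. With
#' `per_vital = FALSE` a single global greedy loop over all candidates is run
#' instead.
#'
#' @param features A `lons_features` from [build_feature_matrix()] computed on
#'   the feature-selection data split only.
#' @param labels 0/1 instance labels aligned with the feature rows.
#' @param k Maximum number of specs selected per vital (default 3, matching
#'   the three statistics reported per vital sign).
#' @param folds Internal stratified cross-validation folds (default 5).
#' @param seed Seed for the internal fold assignment.
#' @param per_vital Per-vital greedy loops (default) or one global loop.
#' @return Object of class `lons_selection` with the ordered selected specs,
#'   the per-step F trace (non-decreasing) and method metadata.
#' @export
forward_select <- function(features, labels, k = 3L, folds = 5L, seed = 1L,
                           per_vital = TRUE) {
  stopifnot(inherits(features, "lons_features"))
  x <- features$x
  specs <- features$specs
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  folds <- min(folds, sum(labels == 1L), sum(labels == 0L))
  fold_ids <- stratified_fold_ids(labels, folds, child_seed(seed, "fs-folds"))
  eval_f <- make_additive_cv(x, labels, fold_ids)

  groups <- if (per_vital) split(seq_len(nrow(specs)), specs$vital) else
    list(all = seq_len(nrow(specs)))
  sel_idx <- integer(0)
  per_vital_out <- list()
  for (gname in names(groups)) {
    cand <- groups[[gname]]
    kk <- min(k, length(cand))
    if (k > length(cand)) {
      warnf("k = %d exceeds the %d candidates for %s; selecting all",
            k, length(cand), gname)
    }
    chosen <- integer(0)
    trace <- numeric(0)
    f_cur <- -Inf
    for (step in seq_len(kk)) {
      remaining <- setdiff(cand, chosen)
      fvals <- vapply(remaining, function(ci) eval_f(c(chosen, ci)),
                      numeric(1L))
      best <- which.max(fvals)  # ties: first candidate in canonical order
      if (!length(best) || !is.finite(fvals[best]) || fvals[best] <= f_cur) {
        break
      }
      chosen <- c(chosen, remaining[best])
      f_cur <- fvals[best]
      trace <- c(trace, f_cur)
    }
    per_vital_out[[gname]] <- list(specs = specs[chosen, , drop = FALSE],
                                   trace = trace)
    sel_idx <- c(sel_idx, chosen)
  }
  structure(list(
    method = "proposed", selected = specs[sel_idx, , drop = FALSE],
    per_vital = per_vital_out, k = k, folds = folds, seed = seed,
    window = unique(specs$window)), class = "lons_selection")
}

#' Comparator feature selectors
#'
#' Ranks all candidate specs by the score of an established filter or
#' embedded method and keeps the top `k_total`:
#' `chi2` (features min-max scaled to non-negative, class-conditional
#' chi-squared statistic), `mutual_info` (nearest-neighbour estimator for
#' continuous features against the discrete label, k = 3 neighbours),
#' `lasso_l1` (absolute coefficients of an L1-penalized logistic model on
#' standardized features, penalty `lambda = 1/n`), `extra_trees`,
#' `random_forest` (impurity importances) and `gradient_boosting` (gain
#' importance).
#'
#' @param features A `lons_features` (feature-selection split).
#' @param labels 0/1 labels.
#' @param method One of `"chi2"`, `"mutual_info"`, `"lasso_l1"`,
#'   `"extra_trees"`, `"random_forest"`, `"gradient_boosting"`.
#' @param k_total Number of specs retained (default 21 = 3 per vital).
#' @param seed Seed for the stochastic methods.
#' @return A `lons_selection` with the ranked selected specs and raw scores.
#' @export
comparator_select <- function(features, labels,
                              method = c("chi2", "mutual_info", "lasso_l1",
                                         "extra_trees", "random_forest",
                                         "gradient_boosting"),
                              k_total = 21L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(features, "lons_features"))
  x <- features$x
  labels <- as.integer(labels)
  scores <- switch(method,
    chi2 = chi2_scores(x, labels),
    mutual_info = mutual_info_scores(x, labels, k = 3L, seed = seed),
    lasso_l1 = lasso_scores(x, labels),
    extra_trees = tree_importance(x, labels, seed, extratrees = TRUE),
    random_forest = tree_importance(x, labels, seed, extratrees = FALSE),
    gradient_boosting = xgb_importance_scores(x, labels, seed)
  )
  ord <- order(-scores, seq_along(scores))  # ties: canonical spec order
  keep <- ord[seq_len(min(k_total, length(ord)))]
  structure(list(
    method = method, selected = features$specs[keep, , drop = FALSE],
    scores = setNames(scores, colnames(x)), k = k_total, seed = seed,
    window = unique(features$specs$window)), class = "lons_selection")
}

## sklearn-style chi-squared score: features scaled to [0, 1] (chi2 demands
## non-negativity), observed = per-class feature sums.
chi2_scores <- function(x, labels) {
  rng <- apply(x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2L, rng[1L, ]), 2L, span, "/")
  out <- numeric(ncol(x))
  pi1 <- mean(labels == 1L)
  obs1 <- colSums(xs[labels == 1L, , drop = FALSE])
  obs0 <- colSums(xs[labels == 0L, , drop = FALSE])
  tot <- obs1 + obs0
  e1 <- tot * pi1; e0 <- tot * (1 - pi1)
  chi <- (obs1 - e1)^2 / pmax(e1, 1e-12) + (obs0 - e0)^2 / pmax(e0, 1e-12)
  chi[tot == 0] <- 0
  chi
}

## kNN mutual information between a continuous feature and the discrete
## label (Ross 2014): for each point, the distance to its k-th neighbour
## within its own class defines a radius; m_i counts all points within it.
mutual_info_scores <- function(x, labels, k = 3L, seed = 1L) {
  n <- nrow(x)
  out <- numeric(ncol(x))
  with_seed(child_seed(seed, "mi"), {
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      v <- v + rnorm(n, 0, 1e-10 * max(sd(v), 1e-12))  # break heavy ties
      mi <- 0
      psi_nc <- 0; psi_m <- 0
      ok <- TRUE
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        if (length(idx) <= k) { ok <- FALSE; break }
        vc <- sort(v[idx])
        pos <- findInterval(v[idx], vc)
        ## distance to k-th nearest neighbour within class via sorted scan
        d <- vapply(seq_along(idx), function(i) {
          xi <- v[idx][i]
          lo <- pos[i]
          cand <- vc[max(1L, lo - k):min(length(vc), lo + k)]
          sort(abs(cand - xi))[k + 1L]  # self included at distance 0
        }, numeric(1L))
        sv <- sort(v)
        ## count (self-inclusive) within a radius strictly below the k-th
        ## within-class neighbour distance
        m <- findInterval(v[idx] + d - 1e-15, sv) -
          findInterval(v[idx] - d + 1e-15, sv)
        m <- pmax(m, 1L)
        psi_nc <- psi_nc + length(idx) * digamma(length(idx))
        psi_m <- psi_m + sum(digamma(m))
      }
      out[j] <- if (ok) {
        max(0, digamma(n) + digamma(k) - (psi_nc + psi_m) / n)
      } else 0
    }
  })
  out
}

lasso_scores <- function(x, labels) {
  keep <- apply(x, 2L, sd) > 0
  b <- rep(0, ncol(x))
  if (sum(keep) >= 2L) {
    fit <- glmnet::glmnet(x[, keep, drop = FALSE], factor(labels),
                          family = "binomial", alpha = 1,
                          lambda = 1 / nrow(x), standardize = TRUE)
    b[keep] <- abs(as.numeric(fit$beta))
  }
  b
}

tree_importance <- function(x, labels, seed, extratrees) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(labels)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df, num.trees = 300L,
    importance = "impurity",
    splitrule = if (extratrees) "extratrees" else "gini",
    num.random.splits = 1L,
    replace = !extratrees,
    sample.fraction = if (extratrees) 1 else 0.632,
    seed = child_seed(seed, "trees"))
  as.numeric(fit$variable.importance)
}

xgb_importance_scores <- function(x, labels, seed) {
  with_seed(child_seed(seed, "xgb"), {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    dtrain <- xgboost::xgb.DMatrix(x, label = labels)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L,
                    eta = 0.3, nthread = 1L),
      data = dtrain, nrounds = 50L, verbose = 0L)
    imp <- xgboost::xgb.importance(model = fit)
    out <- setNames(rep(0, ncol(x)), colnames(x))
    out[imp$Feature] <- imp$Gain
    as.numeric(out)
  })
}

#' @export
print.lons_selection <- function(x, ...) {
  cat(sprintf("Feature selection (%s): %d specs selected\n",
              x$method, nrow(x$selected)))
  if (!is.null(x$per_vital)) {
    for (v in names(x$per_vital)) {
      pv <- x$per_vital[[v]]
      if (!nrow(pv$specs)) next
      cat(sprintf("  %-18s %s  (F: %s)\n", v,
                  paste(paste(pv$specs$transform, pv$specs$stat), collapse = ", "),
                  paste(sprintf("%.3f", pv$trace), collapse = " -> ")))
    }
  } else {
    print(utils::head(x$selected[, c("name"), drop = FALSE], 10L))
  }
  invisible(x)
}

#' @export
plot.lons_selection <- function(x, ...) {
  if (is.null(x$per_vital)) {
    barplot(sort(utils::head(x$scores[x$selected$name], 20L)), horiz = TRUE,
            las = 1, main = paste("Selector scores:", x$method))
    return(invisible(x))
  }
  traces <- lapply(x$per_vital, `[[`, "trace")
  traces <- traces[vapply(traces, length, 1L) > 0]
  ylim <- range(unlist(traces))
  plot(NULL, xlim = c(1, max(vapply(traces, length, 1L))), ylim = ylim,
       xlab = "greedy step", ylab = "objective F", main = "Forward-selection F trace")
  for (i in seq_along(traces)) {
    lines(seq_along(traces[[i]]), traces[[i]], type = "b", col = i)
  }
  legend("bottomright", legend = names(traces), col = seq_along(traces),
         lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
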