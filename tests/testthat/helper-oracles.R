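# First-principles reference implementations used as independent oracles.
# Deliberately naive (loops, textbook formulas); they never share code with
# the package's computation paths.

oracle_mean <- function(v) sum(v) / length(v)
oracle_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_sd <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  m <- oracle_mean(v)
  sqrt(sum((v - m)^2) / (n - 1))
}
oracle_skewness <- function(v) {
  n <- length(v)
  if (n < 3) return(NA_real_)
  m <- oracle_mean(v)
  m2 <- sum((v - m)^2) / n
  if (m2 == 0) return(NA_real_)
  (sum((v - m)^3) / n) / m2^1.5
}
oracle_kurtosis <- function(v) {
  n <- length(v)
  if (n < 4) return(NA_real_)
  m <- oracle_mean(v)
  m2 <- sum((v - m)^2) / n
  if (m2 == 0) return(NA_real_)
  (sum((v - m)^4) / n) / m2^2 - 3
}
oracle_slope <- function(v, t) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  mt <- oracle_mean(t); mv <- oracle_mean(v)
  den <- sum((t - mt)^2)
  if (den == 0) return(NA_real_)
  sum((t - mt) * (v - mv)) / den
}
oracle_delta <- function(v) {
  n <- length(v)
  if (n < 2) return(NA_real_)
  v[n] - v[n - 1]
}

# plug-in KDE entropy with Gaussian kernel: per-point density evaluated
# directly from the kernel-sum definition
oracle_kde_entropy <- function(v, h) {
  n <- length(v)
  total <- 0
  for (i in seq_len(n)) {
    fi <- sum(exp(-0.5 * ((v[i] - v) / h)^2)) / sqrt(2 * pi)
    total <- total + log(fi / (n * h))
  }
  -total / n
}

# AUROC by explicit enumeration of positive-negative pairs
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# average precision: precision at each threshold step, tied scores grouped
oracle_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  ap <- 0; prev_rec <- 0
  for (th in thr) {
    sel <- scores >= th
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

oracle_confusion_metrics <- function(scores, labels, thr = 0.5) {
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else 0
  c(accuracy = (tp + tn) / length(labels),
    ppv = prec,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA,
    f1 = f1)
}

# a small hand-built vitals chart for matrix tests
toy_vitals <- function() {
  data.frame(
    SUBJECT_ID = 1L,
    CHARTTIME = c(76, 80, 84, 88, 92),
    VITAL = "heart_rate",
    VALUENUM = c(140, 150, 130, 145, 135))
}

expect_rel_equal <- function(got, want, tol = 1e-9) {
  if (is.na(want)) {
    expect_true(is.na(got))
  } else {
    expect_equal(got, want, tolerance = tol)
  }
}
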