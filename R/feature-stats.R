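## Statistical primitives for windowed vital-sign features.
##
## Conventions (documented here once):
##  * sd uses the n-1 sample denominator;
##  * skewness is the moment coefficient g1 = m3 / m2^{3/2} and kurtosis the
##    excess moment coefficient g2 = m4 / m2^2 - 3 (central moments with the
##    1/n denominator), the conventions of common scientific-computing stacks;
##  * the scalar "delta" statistic is last value minus second-to-last value;
##    the "delta"/"absolute_delta" series transforms are the successive
##    (absolute) difference series;
##  * degenerate computations (too few observations, zero variance where a
##    ratio requires it) return NA, which the matrix builder maps to zero
##    imputation with a mask entry.

#' Three-sigma quality filter
#'
#' Removes observations lying more than three standard deviations from the
#' per-series mean. Series with fewer than three observations, or with zero
#' spread, pass unchanged.
#'
#' @param series Data frame with columns `time`, `value`.
#' @return The filtered series.
#' @export
three_sigma_filter <- function(series) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  if (nrow(series) < 3L) return(series)
  m <- mean(series$value)
  s <- sd(series$value)
  if (!is.finite(s) || s == 0) return(series)
  series[abs(series$value - m) <= 3 * s, , drop = FALSE]
}

#' Last-observation-carried-forward imputation onto a time grid
#'
#' Each grid time takes the most recent observed value at or before it; grid
#' times preceding the first observation stay missing (`NA`) and are
#' zero-imputed later at the matrix level.
#'
#' @param series Data frame with columns `time`, `value` (times ascending).
#' @param grid Ascending numeric vector of grid times.
#' @return Data frame with columns `time` (the grid) and `value`.
#' @export
locf_impute <- function(series, grid) {
  stopifnot(!is.unsorted(grid))
  if (nrow(series) == 0L) {
    return(data.frame(time = grid, value = rep(NA_real_, length(grid))))
  }
  idx <- findInterval(grid, series$time)
  val <- ifelse(idx == 0L, NA_real_, series$value[pmax(idx, 1L)])
  data.frame(time = grid, value = val)
}

#' Series transforms
#'
#' `raw` is the identity; `delta` the successive-difference series (length
#' n-1); `absolute_delta` its absolute value. A length-1 input under a
#' difference transform yields an empty series (zero-imputed downstream).
#'
#' @param values Numeric vector (ordered in time).
#' @param kind `"raw"`, `"delta"` or `"absolute_delta"`.
#' @return Numeric vector.
#' @export
transform_series <- function(values, kind = c("raw", "delta", "absolute_delta")) {
  kind <- match.arg(kind)
  switch(kind,
         raw = values,
         delta = diff(values),
         absolute_delta = abs(diff(values)))
}

#' Normality gate
#'
#' Chooses the goodness-of-fit test by sample size — Shapiro-Wilk below 5000
#' observations, Kolmogorov-Smirnov (against a normal with moment-estimated
#' parameters) at 5000 or more — and declares normality at the 0.05 level.
#' Fewer than three values, or a degenerate (zero-spread) sample, is
#' not-normal by convention.
#'
#' @param values Numeric vector.
#' @return List with `is_normal` (logical), `p` (p-value, `NA` when
#'   untestable) and `test` (`"shapiro"`, `"ks"` or `"none"`).
#' @export
normality_gate <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || values[which.max(values)] == values[which.min(values)]) {
    return(list(is_normal = FALSE, p = NA_real_, test = "none"))
  }
  if (n < 5000L) {
    p <- swilk_p(values)
    list(is_normal = p >= 0.05, p = p, test = "shapiro")
  } else {
    p <- suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))$p.value)
    list(is_normal = p >= 0.05, p = p, test = "ks")
  }
}

## Shapiro-Wilk p-value through the stats C routine without the htest
## plumbing; numerically identical to shapiro.test(x)$p.value. The call
## overhead matters: the featurizer gates hundreds of thousands of windows.
swilk_env <- new.env(parent = emptyenv())
swilk_p <- function(x) {
  swilk_p_sorted(sort.int(x, method = "quick"))
}
swilk_p_sorted <- function(x) {
  sym <- swilk_env$sym
  if (is.null(sym)) {
    sym <- get("C_SWilk", envir = getNamespace("stats"))
    swilk_env$sym <- sym
  }
  rng <- x[length(x)] - x[1L]
  if (rng < 1e-10) x <- x / rng
  .Call(sym, x)[2L]
}

#' Differential entropy of a sample
#'
#' When the sample passes the normality gate, uses the closed-form Gaussian
#' differential entropy 0.5 * log(2 * pi * e * s^2); otherwise a plug-in
#' estimate `-mean(log fhat(x_i))` with a Gaussian kernel density and
#' Silverman's rule-of-thumb bandwidth (`stats::bw.nrd0`). The kernel density
#' is evaluated exactly for samples up to 256 values and on a 512-point
#' binned grid (linear interpolation at the sample points) for larger
#' samples. Degenerate samples (fewer than three distinct values, or zero
#' spread) return `NA` (zero-imputed downstream).
#'
#' @param values Numeric vector.
#' @return Entropy in nats, or `NA_real_`.
#' @export
estimate_entropy <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) return(NA_real_)
  xs <- sort.int(values, method = "quick")  # shared by gate, bandwidth, KDE
  if (xs[1L] == xs[n] || sum(diff(xs) > 0) < 2L) return(NA_real_)
  s <- sd(xs)
  if (!is.finite(s) || s == 0) return(NA_real_)
  is_normal <- if (n < 5000L) {
    swilk_p_sorted(xs) >= 0.05
  } else {
    suppressWarnings(
      ks.test(values, "pnorm", mean(values), s)$p.value) >= 0.05
  }
  if (is_normal) return(0.5 * log(2 * pi * exp(1) * s^2))
  h <- silverman_bw_sorted(xs, s)
  if (!is.finite(h) || h <= 0) return(NA_real_)
  if (n <= 256L) {
    f <- rowMeans(dnorm(outer(xs, xs, "-") / h)) / h
  } else {
    d <- density(xs, bw = h, n = 512L)
    f <- approx(d$x, d$y, xout = xs, rule = 2L)$y
  }
  f <- pmax(f, .Machine$double.xmin)
  -mean(log(f))
}

## Silverman rule-of-thumb bandwidth, identical to stats::bw.nrd0 but without
## the quantile() dispatch overhead (type-7 quartiles computed directly).
silverman_bw <- function(x, s = sd(x)) {
  silverman_bw_sorted(sort.int(x, method = "quick"), s)
}
silverman_bw_sorted <- function(xs, s) {
  n <- length(xs)
  q7 <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    xs[lo + 1L] + (h - lo) * (xs[min(n, lo + 2L)] - xs[lo + 1L])
  }
  iqr <- q7(0.75) - q7(0.25)
  lo <- min(s, iqr / 1.34)
  if (!is.finite(lo) || lo == 0) {
    lo <- if (s > 0) s else if (abs(xs[1L]) > 0) abs(xs[1L]) else 1
  }
  0.9 * lo * n^(-0.2)
}

#' One windowed statistic
#'
#' Computes a single scalar statistic over a window of ordered observations.
#' `slope` is the least-squares slope of value against time (per hour) and
#' requires `times`; `delta` is the last minus the second-to-last value;
#' `entropy` delegates to [estimate_entropy()]. Degenerate inputs return
#' `NA_real_` (mapped to zero imputation with a mask entry by the matrix
#' builder).
#'
#' @param values Numeric vector, ordered in time.
#' @param stat One of `"mean"`, `"median"`, `"min"`, `"max"`, `"sd"`,
#'   `"skewness"`, `"kurtosis"`, `"slope"`, `"entropy"`, `"delta"`,
#'   `"absolute_delta"`.
#' @param times Observation times in hours (required for `slope`).
#' @return Numeric scalar or `NA_real_`.
#' @export
window_statistic <- function(values, stat, times = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) return(NA_real_)
  switch(stat,
    mean = mean(values),
    median = median(values),
    min = min(values),
    max = max(values),
    sd = if (n >= 2L) sd(values) else NA_real_,
    skewness = {
      if (n < 3L) return(NA_real_)
      m2 <- mean((values - mean(values))^2)
      if (m2 == 0) return(NA_real_)
      mean((values - mean(values))^3) / m2^1.5
    },
    kurtosis = {
      if (n < 4L) return(NA_real_)
      m2 <- mean((values - mean(values))^2)
      if (m2 == 0) return(NA_real_)
      mean((values - mean(values))^4) / m2^2 - 3
    },
    slope = {
      if (is.null(times)) stopf("slope requires observation times")
      if (n < 2L) return(NA_real_)
      vt <- var(times)
      if (!is.finite(vt) || vt == 0) return(NA_real_)
      cov(times, values) / vt
    },
    entropy = estimate_entropy(values),
    delta = if (n >= 2L) values[n] - values[n - 1L] else NA_real_,
    absolute_delta = if (n >= 2L) abs(values[n] - values[n - 1L]) else NA_real_,
    stopf("unknown statistic '%s'", stat)
  )
}

#' Association between two vitals on a common grid
#'
#' `correlation` uses Pearson's coefficient when both inputs pass the
#' normality gate and Spearman's otherwise. `cross_correlation` scans
#' normalized cross-correlations over lags up to half the series length (both
#' directions) and returns the value of largest magnitude, sign preserved
#' (ties broken toward the smallest, then positive, lag). Zero variance in
#' either input, or fewer than three aligned points, returns `NA`.
#'
#' @param x,y Equal-length numeric vectors on a common LOCF grid.
#' @param mode `"correlation"` or `"cross_correlation"`.
#' @return Numeric scalar in [-1, 1] or `NA_real_`.
#' @export
paired_association <- function(x, y, mode = c("correlation",
                                              "cross_correlation")) {
  mode <- match.arg(mode)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  if (mode == "correlation") {
    use_pearson <- normality_gate(x)$is_normal && normality_gate(y)$is_normal
    return(cor(x, y, method = if (use_pearson) "pearson" else "spearman"))
  }
  fast_ccf_max(x, y)
}

## Maximum-magnitude normalized cross-correlation over lags up to n/2, sign
## preserved; ties broken toward the smallest, then positive, lag. All lag
## cross-products come from one zero-padded FFT cross-correlation on globally
## centred data; per-lag segment moments come from prefix sums. Segments with
## (numerically) zero variance are skipped.
fast_ccf_max <- function(x, y) {
  n <- length(x)
  x <- x - mean(x); y <- y - mean(y)
  tol <- 1e-12 * max(mean(x^2), mean(y^2), 1e-300)
  max_lag <- floor(n / 2)
  lags <- 0:max_lag
  m <- n - lags

  ## zero-padded circular FFT cross-correlation (convolve() without its
  ## argument-dispatch overhead); padding to 2n keeps lags alias-free
  np <- 2L * n
  cc <- Re(stats::fft(stats::fft(c(x, numeric(n))) *
                        Conj(stats::fft(c(y, numeric(n)))),
                      inverse = TRUE)) / np
  sxy_pos <- c(cc[1L], cc[2L * n - lags[-1L] + 1L])  # sum x[i] y[i+lag]
  sxy_neg <- c(cc[1L], cc[1L + lags[-1L]])           # sum x[i+lag] y[i]

  px <- cumsum(x); pxx <- cumsum(x * x)
  py <- cumsum(y); pyy <- cumsum(y * y)
  head_s <- function(p) p[m]                  # sums over 1..m
  tail_s <- function(p) p[n] - c(0, p[lags[-1L]])  # sums over (lag+1)..n

  seg <- function(sx, sxx, sy, syy, sxy) {
    vx <- sxx - sx * sx / m
    vy <- syy - sy * sy / m
    r <- (sxy - sx * sy / m) / sqrt(pmax(vx, 0) * pmax(vy, 0))
    r[m < 3L | vx <= tol * m | vy <= tol * m] <- NA_real_
    pmin(1, pmax(-1, r))
  }
  r_pos <- seg(head_s(px), head_s(pxx), tail_s(py), tail_s(pyy), sxy_pos)
  r_neg <- seg(tail_s(px), tail_s(pxx), head_s(py), head_s(pyy), sxy_neg)

  ## scan order: increasing lag, positive direction first
  r_all <- c(rbind(r_pos, r_neg))[-2L]
  best <- NA_real_; best_abs <- -Inf
  for (r in r_all) {
    if (!is.na(r) && abs(r) > best_abs + 1e-12) {
      best_abs <- abs(r); best <- r
    }
  }
  best
}

## covariance helper kept explicit for clarity in slope
cov <- stats::cov
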