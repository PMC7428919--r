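# Windowed statistic primitives: quality filtering, imputation, transforms,
# normality gating, entropy, associations.

test_that("three-sigma filter removes gross outliers and respects degenerate cases", {
  set.seed(1)
  ser <- data.frame(time = 1:51, value = c(rnorm(50, 140, 5), 400))
  out <- three_sigma_filter(ser)
  expect_false(400 %in% out$value)
  expect_equal(nrow(out), 50)
  ## recompute the rule by hand: every kept point within 3 SD
  expect_true(all(abs(out$value - mean(ser$value)) <= 3 * sd(ser$value)))

  const <- data.frame(time = 1:5, value = rep(37, 5))
  expect_identical(three_sigma_filter(const), const)
  two <- data.frame(time = 1:2, value = c(1, 1000))
  expect_identical(three_sigma_filter(two), two)
})

test_that("LOCF carries the last prior observation onto the grid", {
  ser <- data.frame(time = c(1, 4), value = c(120, 130))
  out <- locf_impute(ser, 1:5)
  expect_equal(out$value, c(120, 120, 120, 130, 130))
  expect_true(is.na(locf_impute(ser, 0.5)$value))
  empty <- data.frame(time = numeric(), value = numeric())
  expect_true(all(is.na(locf_impute(empty, 1:3)$value)))
})

test_that("series transforms follow the difference-series definitions", {
  expect_equal(transform_series(c(3, 5, 4), "delta"), c(2, -1))
  expect_equal(transform_series(c(3, 5, 4), "absolute_delta"), c(2, 1))
  x <- rnorm(10)
  expect_identical(transform_series(x, "raw"), x)
  expect_length(transform_series(3, "delta"), 0)
})

test_that("normality gate picks the test by sample size and matches stats::shapiro.test", {
  set.seed(42)
  x <- rnorm(100)
  g <- normality_gate(x)
  expect_true(g$is_normal)
  expect_equal(g$test, "shapiro")
  expect_equal(g$p, shapiro.test(x)$p.value, tolerance = 1e-12)

  e <- normality_gate(rexp(100))
  expect_false(e$is_normal)

  big <- rnorm(5000)
  expect_equal(normality_gate(big)$test, "ks")
  expect_equal(normality_gate(rnorm(4999))$test, "shapiro")

  expect_false(normality_gate(c(1, 2))$is_normal)
  expect_false(normality_gate(rep(1, 10))$is_normal)
})

test_that("every window statistic matches its first-principles oracle", {
  set.seed(7)
  for (rep in 1:300) {
    n <- sample(1:40, 1)
    v <- rnorm(n, mean = sample(c(0, 100), 1), sd = sample(c(0.5, 20), 1))
    t <- sort(runif(n, 0, 24))
    expect_rel_equal(window_statistic(v, "mean"), oracle_mean(v))
    expect_rel_equal(window_statistic(v, "median"), oracle_median(v))
    expect_rel_equal(window_statistic(v, "min"), min(v))
    expect_rel_equal(window_statistic(v, "max"), max(v))
    expect_rel_equal(window_statistic(v, "sd"), oracle_sd(v))
    expect_rel_equal(window_statistic(v, "skewness"), oracle_skewness(v))
    expect_rel_equal(window_statistic(v, "kurtosis"), oracle_kurtosis(v))
    expect_rel_equal(window_statistic(v, "slope", t), oracle_slope(v, t))
    expect_rel_equal(window_statistic(v, "delta"), oracle_delta(v))
    expect_rel_equal(window_statistic(v, "absolute_delta"),
                     abs(oracle_delta(v)))
  }
  expect_equal(window_statistic(c(1, 2, 3), "skewness"), 0)
  expect_equal(window_statistic(c(1, 3), "slope", c(0, 1)), 2)
  expect_equal(window_statistic(c(140, 150, 130), "delta"), -20)
  expect_error(window_statistic(1:3, "no_such_stat"), "unknown")
})

test_that("translation invariance holds where expected", {
  set.seed(3)
  v <- rnorm(20); t <- sort(runif(20, 0, 24)); k <- 17.3
  for (s in c("sd", "skewness", "kurtosis", "delta", "absolute_delta")) {
    expect_equal(window_statistic(v + k, s), window_statistic(v, s),
                 tolerance = 1e-9)
  }
  expect_equal(window_statistic(v + k, "slope", t),
               window_statistic(v, "slope", t), tolerance = 1e-9)
  for (s in c("mean", "median", "min", "max")) {
    expect_equal(window_statistic(v + k, s), window_statistic(v, s) + k,
                 tolerance = 1e-9)
  }
})

test_that("entropy uses the closed form under normality and exact KDE otherwise", {
  set.seed(11)
  x <- rnorm(100, sd = 3)
  if (normality_gate(x)$is_normal) {
    expect_equal(estimate_entropy(x), 0.5 * log(2 * pi * exp(1) * var(x)),
                 tolerance = 1e-12)
  }
  u <- runif(200)  # rejected by the gate -> KDE branch
  expect_false(normality_gate(u)$is_normal)
  h <- bw.nrd0(u)
  expect_equal(estimate_entropy(u), oracle_kde_entropy(u, h),
               tolerance = 1e-9)
  expect_true(is.na(estimate_entropy(rep(5, 10))))
})

test_that("silverman bandwidth matches stats::bw.nrd0", {
  set.seed(5)
  for (n in c(5, 24, 101)) {
    x <- rnorm(n)
    expect_equal(neowarn:::silverman_bw(x), bw.nrd0(x), tolerance = 1e-12)
  }
})

test_that("paired associations: perfect linear, lag recovery, rank invariance", {
  x <- seq(0, 10, length.out = 24)
  expect_equal(paired_association(x, 2 * x + 1, "correlation"), 1)

  set.seed(8)
  xs <- rnorm(40)
  ys <- c(rnorm(2), xs)[1:40]  # y = x delayed by 2 grid steps
  expect_equal(abs(paired_association(xs, ys, "cross_correlation")), 1,
               tolerance = 1e-9)

  xm <- sort(rexp(30))
  ym <- xm^3  # rank-preserving nonlinear map, clearly non-normal
  expect_equal(paired_association(xm, ym, "correlation"), 1)

  expect_true(is.na(paired_association(rep(1, 10), rnorm(10), "correlation")))
})

test_that("cross-correlation scan equals a brute-force lag enumeration", {
  naive_ccf <- function(x, y) {
    n <- length(x); best <- NA_real_; ba <- -Inf
    for (l in 0:floor(n / 2)) for (s in if (l == 0) 1 else c(1, -1)) {
      if (s == 1) { xa <- x[1:(n - l)]; ya <- y[(1 + l):n] }
      else { xa <- x[(1 + l):n]; ya <- y[1:(n - l)] }
      if (length(xa) < 3 || sd(xa) == 0 || sd(ya) == 0) next
      r <- cor(xa, ya)
      if (is.finite(r) && abs(r) > ba + 1e-12) { ba <- abs(r); best <- r }
    }
    best
  }
  set.seed(21)
  for (rep in 1:120) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (runif(1) < 0.3) y <- c(rnorm(2), x)[1:n]
    expect_equal(paired_association(x, y, "cross_correlation"),
                 naive_ccf(x, y), tolerance = 1e-7)
  }
})
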