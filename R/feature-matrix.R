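## Windowed feature-matrix construction.
##
## Each instance (patient, reference time t) is summarized by statistics of
## each vital over the half-open window (t - w, t]. Univariate statistics are
## computed on the raw irregular samples; the two association statistics are
## computed on a 15-minute LOCF grid (values carried forward from the full
## pre-t history, so no look-ahead occurs). Cells that cannot be computed are
## zero-imputed and recorded in a mask as `never_measured` (no observation in
## the window) or `degenerate_computation` (observations present, statistic
## undefined).

series_statistics <- function() {
  c("mean", "median", "min", "max", "sd", "skewness", "kurtosis", "slope",
    "entropy")
}

#' Full candidate feature-spec table for one window
#'
#' Enumerates, for each vital: the nine series statistics under the `raw`,
#' `delta` and `absolute_delta` transforms, the two scalar recency statistics
#' (`delta`, `absolute_delta` of the two most recent observations), and the
#' two association statistics (`correlation`, `cross_correlation` with the
#' vital's partner signal). 31 specs per vital, 217 in total.
#'
#' @param window_h Observation window in hours (3, 6, 12 or 24 in the default
#'   experiment grid).
#' @param vitals Vitals to enumerate (default all seven).
#' @param include_assoc Include the paired association specs.
#' @return data.frame with columns `vital`, `transform`, `stat`, `window`,
#'   `name`.
#' @export
candidate_specs <- function(window_h, vitals = vital_names(),
                            include_assoc = TRUE) {
  rows <- list()
  for (v in vitals) {
    for (tr in c("raw", "delta", "absolute_delta")) {
      rows[[length(rows) + 1L]] <- data.frame(
        vital = v, transform = tr, stat = series_statistics())
    }
    rows[[length(rows) + 1L]] <- data.frame(
      vital = v, transform = "raw", stat = c("delta", "absolute_delta"))
    if (include_assoc) {
      rows[[length(rows) + 1L]] <- data.frame(
        vital = v, transform = "raw",
        stat = c("correlation", "cross_correlation"))
    }
  }
  out <- do.call(rbind, rows)
  out$window <- window_h
  out$name <- spec_names(out)
  out
}

#' Baseline feature specs
#'
#' The comparison baseline: mean, minimum, maximum, standard deviation and
#' median of each vital on the raw samples — 35 specs.
#'
#' @param window_h Observation window in hours.
#' @return data.frame as in [candidate_specs()].
#' @export
baseline_specs <- function(window_h) {
  out <- expand.grid(stat = c("mean", "min", "max", "sd", "median"),
                     vital = vital_names(), stringsAsFactors = FALSE)
  out <- data.frame(vital = out$vital, transform = "raw", stat = out$stat,
                    window = window_h)
  out$name <- spec_names(out)
  out[order(match(out$vital, vital_names())), ]
}

#' Canonical feature column names
#'
#' `<vital>__<transform>__<stat>__<window>h`.
#'
#' @param specs Spec data frame (`vital`, `transform`, `stat`, `window`).
#' @return Character vector.
#' @export
spec_names <- function(specs) {
  paste(specs$vital, specs$transform, specs$stat,
        paste0(format(specs$window, trim = TRUE), "h"), sep = "__")
}

#' Default association partner for each vital
#'
#' Associations pair each non-heart-rate vital with heart rate (the reference
#' signal); heart rate itself pairs with oxygen saturation.
#'
#' @return Named character vector.
#' @export
association_partners <- function() {
  p <- setNames(rep("heart_rate", 7L), vital_names())
  p[["heart_rate"]] <- "oxygen_saturation"
  p
}

## Cohort-level three-sigma filter (per patient, per vital), vectorized.
filter_vitals_3sigma <- function(V) {
  V <- data.table::as.data.table(V)
  V[, `:=`(gmu = mean(VALUENUM), gsd = sd(VALUENUM), n_obs = .N),
    by = .(SUBJECT_ID, VITAL)]
  keep <- V$n_obs < 3L | !is.finite(V$gsd) | V$gsd == 0 |
    abs(V$VALUENUM - V$gmu) <= 3 * V$gsd
  V <- V[keep]
  V[, c("gmu", "gsd", "n_obs") := NULL]
  V[]
}

#' Build the instance-by-feature matrix
#'
#' Computes every requested feature spec for every instance from observations
#' in the half-open window `(t_ref - window, t_ref]`, with zero imputation and
#' a missingness-provenance mask. Deterministic given its inputs; perturbing
#' observations after an instance's reference time never changes its row.
#'
#' @param instances Instance table from [build_instances()] (columns
#'   `instance_id`, `SUBJECT_ID`, `t_ref`, `label`).
#' @param vitals Vitals chart table (`SUBJECT_ID`, `CHARTTIME`, `VITAL`,
#'   `VALUENUM`).
#' @param specs Spec data frame from [candidate_specs()], [baseline_specs()]
#'   or a subset thereof; may mix windows.
#' @param grid_step_h LOCF grid spacing for the association statistics
#'   (default 0.25 h = 15 min).
#' @param three_sigma Apply the per-patient three-sigma quality filter first.
#' @param partners Association partner map, see [association_partners()].
#' @return Object of class `lons_features`: list with numeric matrix `x`
#'   (instances x specs, zero-imputed), character matrix `mask` (`"ok"`,
#'   `"never_measured"`, `"degenerate_computation"`), `specs` and `instances`.
#' @export
build_feature_matrix <- function(instances, vitals, specs,
                                 grid_step_h = 0.25, three_sigma = TRUE,
                                 partners = association_partners()) {
  inst <- data.table::as.data.table(instances)
  stopifnot(all(c("instance_id", "SUBJECT_ID", "t_ref") %in% names(inst)))
  specs <- as.data.frame(specs)
  V <- data.table::as.data.table(vitals)[VITAL %in% unique(
    c(specs$vital, partners[unique(specs$vital)]))]
  V <- V[is.finite(VALUENUM)]
  if (three_sigma) V <- filter_vitals_3sigma(V)
  data.table::setkey(V, SUBJECT_ID, VITAL, CHARTTIME)

  n_i <- nrow(inst)
  n_s <- nrow(specs)
  X <- matrix(0, n_i, n_s, dimnames = list(NULL, specs$name))
  M <- matrix("never_measured", n_i, n_s, dimnames = list(NULL, specs$name))
  if (n_i == 0L || n_s == 0L) {
    return(structure(list(x = X, mask = M, specs = specs,
                          instances = as.data.frame(inst)),
                     class = "lons_features"))
  }
  row_of <- function(ids) match(ids, inst$instance_id)

  for (w in unique(specs$window)) {
    sw <- specs[specs$window == w, , drop = FALSE]
    I <- inst[, .(instance_id, SUBJECT_ID, lo = t_ref - w, hi = t_ref)]
    win <- V[I, on = .(SUBJECT_ID, CHARTTIME > lo, CHARTTIME <= hi),
             .(instance_id = i.instance_id, VITAL = x.VITAL,
               tm = x.CHARTTIME, v = x.VALUENUM), nomatch = NULL]
    data.table::setorder(win, instance_id, VITAL, tm)
    present <- unique(win[, .(instance_id, VITAL)])

    for (tr in intersect(c("raw", "delta", "absolute_delta"),
                         unique(sw$transform))) {
      st_scalar <- sw$stat[sw$transform == tr &
                             !sw$stat %in% c("correlation", "cross_correlation")]
      if (!length(st_scalar)) next
      g <- if (tr == "raw") win else {
        gd <- data.table::copy(win)
        ## successive differences; group starts masked (table is sorted by
        ## instance, vital, time, so one global shift suffices)
        gd[, dv := v - data.table::shift(v)]
        gd[!duplicated(gd, by = c("instance_id", "VITAL")), dv := NA_real_]
        gd <- gd[!is.na(dv), .(instance_id, VITAL, tm,
                               v = if (tr == "absolute_delta") abs(dv) else dv)]
        gd
      }
      res <- bulk_window_stats(g, st_scalar)
      ## groups with observations but no computable transform/stat are
      ## degenerate, not never-measured
      res <- res[present, on = .(instance_id, VITAL)]
      cells <- cells_from_stats(res, sw[sw$transform == tr, , drop = FALSE],
                                st_scalar)
      if (nrow(cells)) {
        rr <- row_of(cells$instance_id)
        cc <- match(cells$name, colnames(X))
        ok <- !is.na(cells$value)
        X[cbind(rr[ok], cc[ok])] <- cells$value[ok]
        M[cbind(rr[ok], cc[ok])] <- "ok"
        M[cbind(rr[!ok], cc[!ok])] <- "degenerate_computation"
      }
    }

    assoc <- sw[sw$stat %in% c("correlation", "cross_correlation"), ,
                drop = FALSE]
    if (nrow(assoc)) {
      ares <- bulk_associations(inst, V, unique(assoc$vital), partners, w,
                                grid_step_h)
      ares <- ares[present, on = c(instance_id = "instance_id",
                                   vital = "VITAL")]
      for (mode in unique(assoc$stat)) {
        am <- data.table::as.data.table(
          assoc[assoc$stat == mode, c("vital", "name"), drop = FALSE])
        sub <- ares[am, on = "vital", allow.cartesian = TRUE]
        val <- if (mode == "correlation") sub$correlation else
          sub$cross_correlation
        rr <- row_of(sub$instance_id)
        cc <- match(sub$name, colnames(X))
        ok <- !is.na(val)
        X[cbind(rr[ok], cc[ok])] <- val[ok]
        M[cbind(rr[ok], cc[ok])] <- "ok"
        M[cbind(rr[!ok], cc[!ok])] <- "degenerate_computation"
      }
    }
  }
  structure(list(x = X, mask = M, specs = specs,
                 instances = as.data.frame(inst)),
            class = "lons_features")
}

## Vectorized per-group statistics over a long (instance_id, VITAL, tm, v)
## table. Two centred passes keep the higher moments numerically stable.
bulk_window_stats <- function(g, stats_wanted) {
  if (nrow(g) == 0L) {
    out <- data.table::data.table(instance_id = integer(), VITAL = character())
    for (s in stats_wanted) out[, (s) := numeric()]
    return(out)
  }
  st1 <- g[, .(n_obs = .N, mean = mean(v), median = median(v),
               min = min(v), max = max(v), mt = mean(tm)),
           by = .(instance_id, VITAL)]
  need2 <- any(stats_wanted %in% c("sd", "skewness", "kurtosis", "slope",
                                   "delta", "absolute_delta", "entropy"))
  if (need2) {
    g2 <- st1[, .(instance_id, VITAL, mu = mean, mt)][
      g, on = .(instance_id, VITAL)]
    ## precompute centred columns so the grouped sums stay gforce-optimized
    g2[, `:=`(d = v - mu, dt = tm - mt)]
    g2[, `:=`(d2 = d^2, d3 = d^2 * d, d4 = d^2 * d^2, dt2 = dt^2,
              dtv = dt * d)]
    g2[, dl := v - data.table::shift(v)]
    g2[!duplicated(g2, by = c("instance_id", "VITAL")), dl := NA_real_]
    st2 <- g2[, .(s2 = sum(d2), s3 = sum(d3), s4 = sum(d4),
                  stt = sum(dt2), stv = sum(dtv),
                  dlast = data.table::last(dl)),
              by = .(instance_id, VITAL)]
    st1 <- st1[st2, on = .(instance_id, VITAL)]
    n <- st1$n_obs
    m2 <- st1$s2 / n
    st1[, sd := data.table::fifelse(n >= 2L, sqrt(s2 / (n - 1L)), NA_real_)]
    st1[, skewness := data.table::fifelse(
      n >= 3L & m2 > 0, (s3 / n) / m2^1.5, NA_real_)]
    st1[, kurtosis := data.table::fifelse(
      n >= 4L & m2 > 0, (s4 / n) / m2^2 - 3, NA_real_)]
    st1[, slope := data.table::fifelse(
      n >= 2L & st1$stt > 0, stv / stt, NA_real_)]
    st1[, delta := dlast]
    st1[, absolute_delta := abs(dlast)]
  }
  if ("entropy" %in% stats_wanted) {
    en <- g[, .(entropy = estimate_entropy(v)), by = .(instance_id, VITAL)]
    st1 <- st1[en, on = .(instance_id, VITAL)]
  }
  keep_cols <- c("instance_id", "VITAL", intersect(stats_wanted, names(st1)))
  st1[, ..keep_cols]
}

## Associations for all requested vitals of one window on the LOCF grid.
## Complete grids (the overwhelming majority) go through a batched path that
## computes every instance's correlation and cross-correlation with matrix
## arithmetic and one multivariate FFT; grids with missing cells fall back to
## the scalar definitions. Both paths implement identical formulas and tie
## rules.
bulk_associations <- function(inst, V, vitals_needed, partners, w,
                              grid_step_h) {
  grid_rel <- seq(-w + grid_step_h, 0, by = grid_step_h)
  n_pts <- length(grid_rel)
  n_inst <- nrow(inst)
  G <- inst[rep(seq_len(n_inst), each = n_pts), .(instance_id, SUBJECT_ID)]
  G[, CHARTTIME := rep(inst$t_ref, each = n_pts) + rep(grid_rel, n_inst)]
  G[, row_ord := .I]
  data.table::setkey(G, SUBJECT_ID, CHARTTIME)

  locf_one <- function(vname) {
    Vv <- V[VITAL == vname, .(SUBJECT_ID, CHARTTIME, VALUENUM)]
    data.table::setkey(Vv, SUBJECT_ID, CHARTTIME)
    res <- Vv[G, on = .(SUBJECT_ID, CHARTTIME), roll = Inf,
              .(row_ord = i.row_ord, val = VALUENUM)]
    matrix(res$val[order(res$row_ord)], nrow = n_pts)
  }
  all_v <- unique(c(vitals_needed, partners[vitals_needed]))
  series <- lapply(setNames(all_v, all_v), locf_one)

  out <- list()
  for (vname in vitals_needed) {
    A <- series[[vname]]
    B <- series[[partners[[vname]]]]
    corr <- rep(NA_real_, n_inst)
    ccf <- rep(NA_real_, n_inst)

    complete <- !colAnyNA(A) & !colAnyNA(B)
    sda <- col_sds(A); sdb <- col_sds(B)
    batch <- which(complete & sda > 0 & sdb > 0)
    if (length(batch)) {
      Ab <- A[, batch, drop = FALSE]; Bb <- B[, batch, drop = FALSE]
      gate <- vapply(seq_along(batch), function(j) {
        normality_gate(Ab[, j])$is_normal && normality_gate(Bb[, j])$is_normal
      }, logical(1L))
      Ar <- Ab; Br <- Bb
      if (any(!gate)) {
        Ar[, !gate] <- apply(Ab[, !gate, drop = FALSE], 2L, rank,
                             ties.method = "average")
        Br[, !gate] <- apply(Bb[, !gate, drop = FALSE], 2L, rank,
                             ties.method = "average")
      }
      A0 <- sweep(Ar, 2L, colMeans(Ar)); B0 <- sweep(Br, 2L, colMeans(Br))
      den <- sqrt(colSums(A0^2) * colSums(B0^2))
      corr[batch] <- ifelse(den > 0, colSums(A0 * B0) / den, NA_real_)
      ccf[batch] <- batched_ccf_max(Ab, Bb)
    }
    scalar <- which(complete & !(sda > 0 & sdb > 0) |
                      (!complete & (colSums(!is.na(A) & !is.na(B)) >= 3L)))
    for (j in scalar) {
      keep <- is.finite(A[, j]) & is.finite(B[, j])
      corr[j] <- paired_association(A[keep, j], B[keep, j], "correlation")
      ccf[j] <- paired_association(A[keep, j], B[keep, j],
                                   "cross_correlation")
    }
    out[[vname]] <- data.table::data.table(
      instance_id = inst$instance_id, vital = vname,
      correlation = corr, cross_correlation = ccf)
  }
  data.table::rbindlist(out)
}

colAnyNA <- function(m) colSums(is.na(m)) > 0L

col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1L)
  sqrt(pmax(v, 0))
}

## Batched version of fast_ccf_max over the columns of A and B (same grid
## length): one multivariate FFT gives all cross-products; prefix sums give
## all segment moments; the scan applies the identical
## smallest-lag / positive-direction-first tie rule.
batched_ccf_max <- function(A, B) {
  n <- nrow(A); nc <- ncol(A)
  A0 <- sweep(A, 2L, colMeans(A)); B0 <- sweep(B, 2L, colMeans(B))
  tol <- pmax(1e-12 * pmax(colMeans(A0^2), colMeans(B0^2)), 1e-300)
  np <- 2L * n
  pad <- matrix(0, n, nc)
  FA <- stats::mvfft(rbind(A0, pad))
  FB <- stats::mvfft(rbind(B0, pad))
  CC <- Re(stats::mvfft(FA * Conj(FB), inverse = TRUE)) / np

  cA <- apply(A0, 2L, cumsum); cA2 <- apply(A0^2, 2L, cumsum)
  cB <- apply(B0, 2L, cumsum); cB2 <- apply(B0^2, 2L, cumsum)
  tot <- function(cm) cm[n, ]

  max_lag <- floor(n / 2)
  best <- rep(NA_real_, nc); best_abs <- rep(-Inf, nc)
  consider <- function(r) {
    upd <- !is.na(r) & abs(r) > best_abs + 1e-12
    best_abs[upd] <<- abs(r[upd])
    best[upd] <<- pmin(1, pmax(-1, r[upd]))
  }
  seg_r_vec <- function(sx, sxx, sy, syy, sxy, m) {
    vx <- sxx - sx^2 / m
    vy <- syy - sy^2 / m
    r <- (sxy - sx * sy / m) / sqrt(pmax(vx, 0) * pmax(vy, 0))
    r[m < 3L | vx <= tol * m | vy <= tol * m] <- NA_real_
    r
  }
  for (lag in 0:max_lag) {
    m <- n - lag
    hA <- cA[m, ]; hA2 <- cA2[m, ]           # sums over 1..m
    hB <- cB[m, ]; hB2 <- cB2[m, ]
    tA <- tot(cA) - (if (lag) cA[lag, ] else 0)   # sums over (lag+1)..n
    tA2 <- tot(cA2) - (if (lag) cA2[lag, ] else 0)
    tB <- tot(cB) - (if (lag) cB[lag, ] else 0)
    tB2 <- tot(cB2) - (if (lag) cB2[lag, ] else 0)
    sxy_pos <- if (lag) CC[np - lag + 1L, ] else CC[1L, ]
    consider(seg_r_vec(hA, hA2, tB, tB2, sxy_pos, m))
    if (lag) {
      sxy_neg <- CC[1L + lag, ]
      consider(seg_r_vec(tA, tA2, hB, hB2, sxy_neg, m))
    }
  }
  best
}

## Turn a per-(instance, vital) statistic table into long cell updates
## (instance_id, name, value) for the spec rows of one transform.
cells_from_stats <- function(res, sw_tr, stats_wanted) {
  out <- list()
  for (s in intersect(stats_wanted, sw_tr$stat)) {
    spec_row <- sw_tr[sw_tr$stat == s, , drop = FALSE]
    val <- if (s %in% names(res)) res[[s]] else rep(NA_real_, nrow(res))
    hit <- match(res$VITAL, spec_row$vital)
    sel <- !is.na(hit)
    if (!any(sel)) next
    out[[s]] <- data.table::data.table(
      instance_id = res$instance_id[sel],
      name = spec_row$name[hit[sel]],
      value = val[sel])
  }
  if (!length(out)) {
    return(data.table::data.table(instance_id = integer(), name = character(),
                                  value = numeric()))
  }
  data.table::rbindlist(out)
}

#' @export
print.lons_features <- function(x, ...) {
  cat(sprintf("Feature matrix: %d instances x %d features\n",
              nrow(x$x), ncol(x$x)))
  tab <- table(factor(x$mask, levels = c("ok", "never_measured",
                                         "degenerate_computation")))
  cat(sprintf("  cells ok %.1f%% | never measured %.1f%% | degenerate %.1f%%\n",
              100 * tab[1L] / length(x$mask), 100 * tab[2L] / length(x$mask),
              100 * tab[3L] / length(x$mask)))
  invisible(x)
}

#' Write a feature matrix (and its mask) to CSV
#'
#' @param features A `lons_features`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_feature_matrix <- function(features, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- file.path(dir, "features.csv")
  fm <- file.path(dir, "mask.csv")
  data.table::fwrite(cbind(features$instances["instance_id"],
                           as.data.frame(features$x)), fx)
  data.table::fwrite(cbind(features$instances["instance_id"],
                           as.data.frame(features$mask)), fm)
  invisible(c(fx, fm))
}
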