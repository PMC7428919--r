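# Feature-matrix construction: spec enumeration, no-lookahead, masks, and
# cell-by-cell agreement with the scalar statistic path.

test_that("spec enumerations have the documented shapes", {
  cs <- candidate_specs(24)
  expect_equal(nrow(cs), 7 * 31)
  expect_true(all(vital_names() %in% cs$vital))
  bs <- baseline_specs(24)
  expect_equal(nrow(bs), 35)
  expect_true("body_temperature__raw__median__24h" %in% bs$name)
  expect_false(any(grepl("delta|entropy", bs$stat)))
  expect_true(all(bs$transform == "raw"))
})

test_that("a hand-built window reproduces the direct statistic definitions", {
  v <- toy_vitals()
  inst <- data.frame(instance_id = 1L, SUBJECT_ID = 1L, t_ref = 96, label = 0L)
  specs <- candidate_specs(24, vitals = "heart_rate", include_assoc = FALSE)
  fm <- build_feature_matrix(inst, v, specs, three_sigma = FALSE)
  x <- fm$x[1, ]
  expect_equal(x[["heart_rate__raw__mean__24h"]], mean(v$VALUENUM))
  expect_equal(x[["heart_rate__raw__sd__24h"]], sd(v$VALUENUM))
  expect_equal(x[["heart_rate__raw__min__24h"]], 130)
  expect_equal(x[["heart_rate__raw__delta__24h"]], 135 - 145)
  expect_equal(x[["heart_rate__raw__slope__24h"]],
               oracle_slope(v$VALUENUM, v$CHARTTIME))
  dl <- diff(v$VALUENUM)
  expect_equal(x[["heart_rate__delta__mean__24h"]], mean(dl))
  expect_equal(x[["heart_rate__absolute_delta__max__24h"]], max(abs(dl)))
})

test_that("instances before any charting give fully masked zero rows", {
  v <- toy_vitals()
  inst <- data.frame(instance_id = 1:2, SUBJECT_ID = c(1L, 1L),
                     t_ref = c(50, 96), label = 0L)
  specs <- candidate_specs(24, vitals = "heart_rate")
  fm <- build_feature_matrix(inst, v, specs, three_sigma = FALSE)
  expect_true(all(fm$x[1, ] == 0))
  expect_true(all(fm$mask[1, ] == "never_measured"))
  expect_true(any(fm$mask[2, ] == "ok"))
})

test_that("degenerate computations are zero-imputed and masked as such", {
  v <- data.frame(SUBJECT_ID = 1L, CHARTTIME = 95, VITAL = "heart_rate",
                  VALUENUM = 140)  # single observation
  inst <- data.frame(instance_id = 1L, SUBJECT_ID = 1L, t_ref = 96, label = 0L)
  specs <- candidate_specs(24, vitals = "heart_rate", include_assoc = FALSE)
  fm <- build_feature_matrix(inst, v, specs, three_sigma = FALSE)
  expect_equal(unname(fm$x[1, "heart_rate__raw__mean__24h"]), 140)
  expect_equal(unname(fm$mask[1, "heart_rate__raw__sd__24h"]),
               "degenerate_computation")
  expect_equal(unname(fm$x[1, "heart_rate__raw__sd__24h"]), 0)
  ## delta transform of a length-1 series is empty -> degenerate
  expect_equal(unname(fm$mask[1, "heart_rate__delta__mean__24h"]),
               "degenerate_computation")
  ## zero cells always explained by the mask
  expect_true(all(fm$mask[fm$x == 0 & fm$mask == "ok"] == "ok"))
})

test_that("no look-ahead: future observations never change a feature row", {
  co <- generate_cohort(sim_config(n_patients = 12, lons_prevalence = 0.2,
                                   seed = 13))
  v <- as.data.frame(co$tables$vitals)
  inst <- data.frame(instance_id = 1:3, SUBJECT_ID = c(1L, 2L, 3L),
                     t_ref = c(120, 120, 120), label = 0L)
  specs <- candidate_specs(12)
  base <- build_feature_matrix(inst, v, specs)
  v2 <- v
  fut <- v2$CHARTTIME > 120
  v2$VALUENUM[fut] <- v2$VALUENUM[fut] + rnorm(sum(fut), 0, 50)
  pert <- build_feature_matrix(inst, v2, specs)
  expect_equal(base$x, pert$x)
  expect_identical(base$mask, pert$mask)
})

test_that("bulk matrix equals the per-cell scalar recomputation", {
  co <- generate_cohort(sim_config(n_patients = 25, lons_prevalence = 0.2,
                                   seed = 17, missingness = 0.3))
  lab <- build_cohort_labels(co)
  cov <- vitals_coverage(co$tables$vitals)
  inst <- build_instances(lab, cov, "predict_48h", cadence_h = 48)
  inst <- inst[seq_len(min(40, nrow(inst))), ]
  specs <- candidate_specs(6, include_assoc = FALSE)
  fm <- build_feature_matrix(inst, co$tables$vitals, specs)

  V <- as.data.frame(neowarn:::filter_vitals_3sigma(co$tables$vitals))
  for (ri in seq_len(nrow(inst))) {
    id <- inst$SUBJECT_ID[ri]; t0 <- inst$t_ref[ri]
    for (si in sample(nrow(specs), 60)) {
      sp <- specs[si, ]
      sel <- V$SUBJECT_ID == id & V$VITAL == sp$vital &
        V$CHARTTIME > t0 - sp$window & V$CHARTTIME <= t0
      vv <- V$VALUENUM[sel][order(V$CHARTTIME[sel])]
      tt <- sort(V$CHARTTIME[sel])
      if (length(vv) == 0) {
        expect_equal(unname(fm$mask[ri, sp$name]), "never_measured")
        next
      }
      vs <- transform_series(vv, sp$transform)
      ts <- if (sp$transform == "raw") tt else tt[-1]
      want <- if (length(vs) == 0) NA_real_ else
        window_statistic(vs, sp$stat, ts)
      if (is.na(want)) {
        expect_equal(unname(fm$mask[ri, sp$name]), "degenerate_computation")
        expect_equal(unname(fm$x[ri, sp$name]), 0)
      } else {
        expect_equal(unname(fm$x[ri, sp$name]), want, tolerance = 1e-9)
      }
    }
  }
})

test_that("association columns agree with the scalar paired_association path", {
  co <- generate_cohort(sim_config(n_patients = 10, lons_prevalence = 0.3,
                                   seed = 23))
  lab <- build_cohort_labels(co)
  cov <- vitals_coverage(co$tables$vitals)
  inst <- build_instances(lab, cov, "predict_48h", cadence_h = 96)
  inst <- inst[seq_len(min(12, nrow(inst))), ]
  specs <- candidate_specs(6)
  specs <- specs[specs$stat %in% c("correlation", "cross_correlation"), ]
  fm <- build_feature_matrix(inst, co$tables$vitals, specs)

  V <- as.data.frame(neowarn:::filter_vitals_3sigma(co$tables$vitals))
  partners <- association_partners()
  grid_rel <- seq(-6 + 0.25, 0, by = 0.25)
  for (ri in seq_len(nrow(inst))) {
    id <- inst$SUBJECT_ID[ri]; t0 <- inst$t_ref[ri]
    for (vn in c("heart_rate", "body_temperature")) {
      locf <- function(vname) {
        s <- V[V$SUBJECT_ID == id & V$VITAL == vname, ]
        s <- s[order(s$CHARTTIME), ]
        locf_impute(data.frame(time = s$CHARTTIME, value = s$VALUENUM),
                    t0 + grid_rel)$value
      }
      a <- locf(vn); b <- locf(partners[[vn]])
      for (mode in c("correlation", "cross_correlation")) {
        nm <- paste0(vn, "__raw__", mode, "__6h")
        want <- paired_association(a, b, mode)
        if (is.na(want)) {
          expect_true(fm$mask[ri, nm] != "ok")
        } else if (fm$mask[ri, nm] == "ok") {
          expect_equal(unname(fm$x[ri, nm]), want, tolerance = 1e-9)
        }
      }
    }
  }
})
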