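# Synthetic cohort generator: determinism, schema consistency, planted
# deterioration behaviour.

test_that("empty and degenerate configurations are handled", {
  co <- generate_cohort(sim_config(n_patients = 0))
  expect_equal(nrow(co$tables$patients), 0)
  expect_equal(nrow(co$truth), 0)
  expect_error(sim_config(n_patients = -1), "n_patients")
  expect_error(sim_config(lons_prevalence = 0), "prevalence")
  expect_error(sim_config(lons_prevalence = 1.2), "prevalence")
  expect_error(sim_config(ramp_h = 0), "ramp")
  expect_error(sim_config(cadence_min = -5), "cadence")
})

test_that("identical (config, seed) pairs reproduce identical cohorts", {
  cfg <- sim_config(n_patients = 60, lons_prevalence = 0.1, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$tables$vitals, b$tables$vitals)
  expect_identical(a$tables$prescriptions, b$tables$prescriptions)
  expect_identical(a$truth, b$truth)
})

test_that("group sizes replay the documented first RNG draw", {
  cfg <- sim_config(n_patients = 1000, lons_prevalence = 0.05,
                    other_sepsis_frac = 0.02, seed = 1)
  co <- generate_cohort(cfg)
  ## independent replay of the stream: the generator's first consumption is
  ## runif(n_patients) compared against the prevalence thresholds
  set.seed(1)
  gs <- runif(1000)
  expect_equal(sum(co$truth$group == "clinical_lons"), sum(gs < 0.05))
  expect_equal(sum(co$truth$group == "proven_sepsis"),
               sum(gs >= 0.05 & gs < 0.07))
})

test_that("event tables are group-consistent", {
  co <- generate_cohort(sim_config(n_patients = 150, lons_prevalence = 0.15,
                                   seed = 3))
  tr <- as.data.frame(co$truth)
  controls <- tr$SUBJECT_ID[tr$group == "control"]
  sepsis <- tr$SUBJECT_ID[tr$group != "control"]
  lons <- tr$SUBJECT_ID[tr$group == "clinical_lons"]

  expect_false(any(co$tables$microbiology$SUBJECT_ID %in% controls))
  expect_false(any(co$tables$prescriptions$SUBJECT_ID %in% controls))
  expect_false(any(normalize_icd9(co$tables$diagnoses$ICD9_CODE[
    co$tables$diagnoses$SUBJECT_ID %in% controls]) |>
      neowarn:::is_sepsis_code()))

  expect_true(all(co$tables$microbiology$SPEC_TYPE_DESC == "BLOOD CULTURE"))
  rx <- as.data.frame(co$tables$prescriptions)
  expect_true(all(rx$ROUTE[rx$SUBJECT_ID %in% lons] %in% c("IV", "PO")))
  expect_true(all(vapply(lons, function(id) {
    any(rx$SUBJECT_ID == id & rx$ROUTE == "IV")
  }, logical(1))))

  ## onsets present iff sepsis group, and inside the LONS window
  expect_true(all(is.na(tr$onset_h[tr$group == "control"])))
  expect_true(all(!is.na(tr$onset_h[tr$group != "control"])))
  expect_true(all(tr$onset_h[tr$group != "control"] >= 72))
  expect_true(all(tr$onset_h[tr$group != "control"] <= 120 * 24))

  ## all seven vitals charted
  expect_setequal(unique(co$tables$vitals$VITAL), vital_names())
})

test_that("null deterioration leaves a series unchanged", {
  set.seed(2)
  ser <- data.frame(time = sort(runif(80, 0, 200)), value = rnorm(80, 140, 6))
  out <- inject_deterioration(ser, onset = 150,
                              params = list(drift = 0, sd_factor = 1,
                                            dip_depth = 0, dip_rate = 0),
                              ramp_h = 48)
  expect_identical(out, ser)
  expect_error(inject_deterioration(ser, onset = -5, list(drift = 1)),
               "precedes")
})

test_that("observations before the ramp are never modified", {
  set.seed(4)
  ser <- data.frame(time = sort(runif(100, 0, 200)), value = rnorm(100, 90, 3))
  out <- inject_deterioration(ser, onset = 180,
                              params = list(drift = -10, sd_factor = 2,
                                            dip_depth = 3, dip_rate = 0.5),
                              ramp_h = 48)
  pre <- ser$time < 180 - 48
  expect_identical(out$value[pre], ser$value[pre])
  expect_false(identical(out$value[!pre], ser$value[!pre]))
})

test_that("Monte-Carlo drift and SD-inflation recover configured effect sizes", {
  set.seed(99)
  n_rep <- 220
  drift_est <- numeric(n_rep)
  sd_ratio <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tt <- seq(0.5, 200, by = 0.8)
    base <- rnorm(length(tt), 150, 6)
    ser <- data.frame(time = tt, value = base)
    onset <- 180
    d <- inject_deterioration(ser, onset, list(drift = 20), ramp_h = 48)
    drift_est[i] <- mean(d$value[d$time > onset - 1 & d$time <= onset]) -
      mean(d$value[d$time > onset - 96 & d$time <= onset - 48])
    s <- inject_deterioration(ser, onset, list(sd_factor = 3), ramp_h = 48)
    sd_ratio[i] <- sd(s$value[s$time > onset - 48 & s$time <= onset]) /
      sd(s$value[s$time <= onset - 48])
  }
  expect_equal(mean(drift_est), 20, tolerance = 0.05)
  expect_equal(mean(sd_ratio), 3, tolerance = 0.12)
})

test_that("event tables round-trip losslessly through CSV", {
  co <- generate_cohort(sim_config(n_patients = 40, lons_prevalence = 0.15,
                                   seed = 5))
  dir <- file.path(tempdir(), "neowarn-roundtrip")
  write_event_tables(co, dir)
  back <- read_event_tables(dir)
  for (nm in names(co$tables)) {
    expect_equal(as.data.frame(co$tables[[nm]]),
                 as.data.frame(back$tables[[nm]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(as.data.frame(co$truth)$onset_h, as.data.frame(back$truth)$onset_h,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
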