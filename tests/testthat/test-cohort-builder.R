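# Phenotyping and onset labeling: ICD-9 grouping, event-pair onset
# extraction, LONS window filter, instance construction.

test_that("ICD-9 grouping matches the diagnostic code families in both dialects", {
  di <- data.frame(
    SUBJECT_ID = c(1, 2, 3, 3, 4, 5, 6, 7),
    ICD9_CODE = c("038.9", "V30.00", "99591", "V29.0", "78552", "771.81",
                  "785.51", "7718"))
  g <- assign_diagnosis_groups(di)
  got <- setNames(g$group, g$SUBJECT_ID)
  expect_equal(got[["1"]], "sepsis")    # septicemia prefix, dotted
  expect_equal(got[["2"]], "control")   # V-code only
  expect_equal(got[["3"]], "sepsis")    # SIRS 995.91 dotless
  expect_equal(got[["4"]], "sepsis")    # septic shock dotless exact
  expect_equal(got[["5"]], "sepsis")    # perinatal infection dotted
  expect_equal(got[["6"]], "control")   # 785.51 is NOT septic shock
  expect_equal(got[["7"]], "sepsis")    # perinatal infection dotless
})

test_that("malformed codes are rejected with a warning, order does not matter", {
  di <- data.frame(SUBJECT_ID = c(1, 1, 2),
                   ICD9_CODE = c("garbage!", "0389", "V3000"))
  expect_warning(g <- assign_diagnosis_groups(di), "malformed")
  expect_equal(g$group[g$SUBJECT_ID == 1], "sepsis")
  suppressWarnings({
    g2 <- assign_diagnosis_groups(di[c(3, 2, 1), ])
  })
  expect_equal(as.data.frame(g), as.data.frame(g2))
})

test_that("dotless normalization inserts the dot at the 3-digit root", {
  expect_equal(normalize_icd9(c("0389", "99591", "78552", "038")),
               c("038.9", "995.91", "785.52", "038"))
  expect_equal(normalize_icd9("V3000"), "V30.00")
  expect_true(is.na(normalize_icd9("not-a-code")))
})

test_that("onset extraction enumerates culture/antibiotic pairs correctly", {
  pol <- onset_policy(window_h = 24)
  mk_micro <- function(times) data.frame(SUBJECT_ID = 1, CHARTTIME = times,
                                         SPEC_TYPE_DESC = "BLOOD CULTURE")
  mk_rx <- function(times, route = "IV", drug = "Vancomycin") {
    data.frame(SUBJECT_ID = rep(1, length(times)), STARTDATE = times,
               DRUG = rep(drug, length(times)), ROUTE = rep(route, length(times)))
  }
  ## simple coincident pair: earliest of pair
  expect_equal(extract_onset_time(mk_micro(100), mk_rx(101), pol), 100)
  ## culture only -> absent
  expect_true(is.na(extract_onset_time(mk_micro(100), mk_rx(numeric(0)), pol)))
  ## first culture unpaired (gap > w), second pairs: onset at second pair
  expect_equal(extract_onset_time(mk_micro(c(80, 190)), mk_rx(200), pol), 190)
  ## oral route or non-broad-spectrum drug never pairs
  expect_true(is.na(extract_onset_time(mk_micro(100), mk_rx(101, route = "PO"),
                                       pol)))
  expect_true(is.na(extract_onset_time(mk_micro(100),
                                       mk_rx(101, drug = "Caffeine"), pol)))
  ## antibiotic before culture also pairs; earliest of the two is the onset
  expect_equal(extract_onset_time(mk_micro(100), mk_rx(90), pol), 90)
  ## alternative combine rules
  expect_equal(extract_onset_time(mk_micro(100), mk_rx(90),
                                  onset_policy(combine = "culture_time")), 100)
  expect_equal(extract_onset_time(mk_micro(100), mk_rx(90),
                                  onset_policy(combine = "antibiotic_time")), 90)
})

test_that("LONS eligibility window is inclusive at 72 h and 120 d", {
  expect_equal(filter_lons_eligibility(50), "excluded")
  expect_equal(filter_lons_eligibility(72), "clinical_lons")
  expect_equal(filter_lons_eligibility(120 * 24), "clinical_lons")
  expect_equal(filter_lons_eligibility(121 * 24), "excluded")
  expect_equal(filter_lons_eligibility(-4), "excluded")
  expect_true(is.na(filter_lons_eligibility(NA)))
})

test_that("instance grids satisfy the eligibility and history constraints", {
  labels <- data.frame(
    SUBJECT_ID = c(1, 2, 3),
    group = c("control", "clinical_lons", "clinical_lons"),
    onset_h = c(NA, 100, 200))
  coverage <- data.frame(SUBJECT_ID = c(1, 2, 3), first_h = c(72, 0, 0),
                         last_h = c(168, 180, 300))
  ## control stay 72-168 h, cadence 24, window 24 -> negatives at 96..168
  neg <- build_instances(labels, coverage, "predict_48h", cadence_h = 24,
                         window_h = 24)
  expect_equal(neg$t_ref[neg$SUBJECT_ID == 1], c(96, 120, 144, 168))
  expect_true(all(neg$label[neg$SUBJECT_ID == 1] == 0))
  ## onset 100: predict instance would sit at 52 h < 72 h -> dropped
  expect_false(2 %in% neg$SUBJECT_ID[neg$label == 1])
  ## onset 200: one positive at 152
  expect_equal(neg$t_ref[neg$SUBJECT_ID == 3 & neg$label == 1], 152)
  ## detection positives at cadence over [onset - 48, onset]
  det <- build_instances(labels, coverage, "detect", cadence_h = 24,
                         window_h = 24)
  expect_equal(det$t_ref[det$SUBJECT_ID == 3 & det$label == 1],
               c(152, 176, 200))
  ## sepsis patients contribute no negatives in either task
  expect_false(any(det$label == 0 & det$SUBJECT_ID %in% c(2, 3)))
  expect_error(build_instances(labels, coverage, "both"), "arg")
})

test_that("extracted onsets match ground truth on a synthetic cohort", {
  co <- generate_cohort(sim_config(n_patients = 250, lons_prevalence = 0.15,
                                   seed = 31))
  lab <- build_cohort_labels(co)
  tr <- as.data.frame(co$truth)
  m <- merge(as.data.frame(lab), tr, by = "SUBJECT_ID",
             suffixes = c("_lab", "_truth"))
  lons <- m[m$group_truth == "clinical_lons", ]
  expect_gt(nrow(lons), 20)
  expect_true(all(lons$group_lab == "clinical_lons"))
  ## recovery within the 2 h culture-placement jitter
  expect_true(all(abs(lons$onset_h_lab - lons$onset_h_truth) <= 2))
  ## diagnosed sepsis without an IV antibiotic pair stays out of modelling
  expect_true(all(m$group_lab[m$group_truth == "proven_sepsis"]
                  %in% c("proven_sepsis", "excluded")))
})
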