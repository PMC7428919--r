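## Cohort phenotyping and onset labeling.
##
## Groups patients from ICD-9-CM discharge codes, dates the sepsis onset from
## the coincidence of a blood-culture order and an intravenous broad-spectrum
## antibiotic start, applies the LONS eligibility window (72 h to 120 d after
## birth), and expands labeled patients into reference-time instances for the
## 48-h-ahead prediction and 0-48 h detection tasks.

#' Onset-dating policy
#'
#' Controls how the blood-culture and antibiotic event streams are combined
#' into a single onset timestamp.
#'
#' @param window_h Coincidence window `w` in hours: a culture time and an IV
#'   broad-spectrum antibiotic start form a valid pair when they lie within
#'   `w` hours of each other.
#' @param combine How to date the onset from the earliest valid pair:
#'   `"earliest_of_pair"` (default; minimum of the two times), `"culture_time"`
#'   or `"antibiotic_time"`.
#' @param drug_patterns Case-insensitive regular expressions identifying
#'   broad-spectrum antibiotics in the `DRUG` column.
#' @return Object of class `onset_policy`.
#' @export
onset_policy <- function(window_h = 24,
                         combine = c("earliest_of_pair", "culture_time",
                                     "antibiotic_time"),
                         drug_patterns = c("vancomycin", "gentamicin",
                                           "ampicillin", "cefotaxime",
                                           "ceftazidime", "meropenem",
                                           "piperacillin", "amikacin",
                                           "cefepime", "oxacillin")) {
  combine <- match.arg(combine)
  if (!(window_h > 0)) stopf("coincidence window must be positive")
  if (length(drug_patterns) == 0L) stopf("drug pattern list must be non-empty")
  structure(list(window_h = window_h, combine = combine,
                 drug_patterns = drug_patterns), class = "onset_policy")
}

#' Normalize an ICD-9-CM code to the dotted dialect
#'
#' Accepts both dotted ("038.9") and dotless ("0389") code strings and inserts
#' the dot after the 3-character root (4-character root for V-codes, which is
#' the standard ICD-9 rule; E-codes keep a 4-character root as well).
#' Malformed codes return `NA`.
#'
#' @param code Character vector of codes.
#' @return Character vector of dotted codes (`NA` where malformed).
#' @export
normalize_icd9 <- function(code) {
  code <- toupper(trimws(as.character(code)))
  out <- rep(NA_character_, length(code))
  ok <- grepl("^[VE0-9][0-9]{0,2}(\\.[0-9]{0,2})?[0-9]*$", code) & nzchar(code)
  ## already dotted and well-formed
  dotted <- ok & grepl("\\.", code)
  out[dotted] <- code[dotted]
  plain <- ok & !grepl("\\.", code)
  root_len <- ifelse(substr(code, 1L, 1L) %in% c("V", "E"), 4L, 3L)
  ## E-codes use a 4-digit root; V-codes a 2-digit+letter root (3 chars).
  root_len[substr(code, 1L, 1L) == "V"] <- 3L
  idx <- which(plain)
  for (i in idx) {
    cc <- code[i]
    rl <- root_len[i]
    out[i] <- if (nchar(cc) <= rl) cc else
      paste0(substr(cc, 1L, rl), ".", substr(cc, rl + 1L, nchar(cc)))
  }
  out
}

## Sepsis code test on dotted codes: prefixes 038, 771, 995.9; exact 785.52.
is_sepsis_code <- function(dotted) {
  !is.na(dotted) & (
    startsWith(dotted, "038") | startsWith(dotted, "771") |
      startsWith(dotted, "995.9") | dotted == "785.52")
}

#' Assign diagnosis groups from ICD-9-CM codes
#'
#' A patient belongs to the sepsis group when any of their codes matches
#' prefix 038 (septicemia), 771 (perinatal infections), 995.9 (systemic
#' inflammatory response syndrome) or equals 785.52 (septic shock), after
#' normalizing dotted/dotless dialects; otherwise to the control group.
#' Malformed code rows are rejected with a warning.
#'
#' @param diagnoses Data frame with columns `SUBJECT_ID`, `ICD9_CODE`.
#' @return data.table with columns `SUBJECT_ID`, `group`
#'   (`"sepsis"`/`"control"`).
#' @export
assign_diagnosis_groups <- function(diagnoses) {
  dt <- data.table::as.data.table(diagnoses)
  stopifnot(all(c("SUBJECT_ID", "ICD9_CODE") %in% names(dt)))
  dotted <- normalize_icd9(dt$ICD9_CODE)
  bad <- is.na(dotted) & !is.na(dt$ICD9_CODE)
  if (any(bad)) {
    warnf("%d malformed ICD-9 code row(s) rejected (e.g. '%s')",
          sum(bad), dt$ICD9_CODE[which(bad)[1L]])
  }
  dt <- dt[!bad]
  dt[, sepsis := is_sepsis_code(normalize_icd9(ICD9_CODE))]
  out <- dt[, .(group = if (any(sepsis)) "sepsis" else "control"),
            by = SUBJECT_ID]
  data.table::setkey(out, SUBJECT_ID)
  out[]
}

#' Extract the sepsis-onset time for one patient from event timing
#'
#' Enumerates (blood-culture, IV broad-spectrum antibiotic) time pairs lying
#' within the policy's coincidence window and dates the onset from the
#' earliest valid pair. Absence of any valid pair is a legitimate result
#' (`NA`), not an error.
#'
#' @param micro Microbiology rows for one patient (`CHARTTIME`,
#'   `SPEC_TYPE_DESC`); only rows marked `"BLOOD CULTURE"` count.
#' @param rx Prescription rows for one patient (`STARTDATE`, `DRUG`, `ROUTE`);
#'   only IV routes whose drug matches the policy's broad-spectrum patterns
#'   count.
#' @param policy An [onset_policy()].
#' @return Onset time in hours after birth, or `NA_real_`.
#' @export
extract_onset_time <- function(micro, rx, policy = onset_policy()) {
  stopifnot(inherits(policy, "onset_policy"))
  micro <- data.table::as.data.table(micro)
  rx <- data.table::as.data.table(rx)
  t_cult <- if (nrow(micro)) {
    sort(micro$CHARTTIME[toupper(micro$SPEC_TYPE_DESC) == "BLOOD CULTURE"])
  } else numeric(0)
  pat <- paste0("(", paste(policy$drug_patterns, collapse = ")|("), ")")
  t_abx <- if (nrow(rx)) {
    sort(rx$STARTDATE[toupper(rx$ROUTE) == "IV" &
                        grepl(pat, rx$DRUG, ignore.case = TRUE)])
  } else numeric(0)
  if (!length(t_cult) || !length(t_abx)) return(NA_real_)
  best <- Inf
  for (tc in t_cult) {
    near <- t_abx[abs(t_abx - tc) <= policy$window_h]
    if (!length(near)) next
    ta <- near[which.min(abs(near - tc))]
    cand <- switch(policy$combine,
                   earliest_of_pair = min(tc, ta),
                   culture_time = tc,
                   antibiotic_time = ta)
    if (cand < best) best <- cand
  }
  if (is.finite(best)) best else NA_real_
}

#' Apply the LONS eligibility window to a labeled onset
#'
#' Late-onset neonatal sepsis is defined by an onset between 72 hours and
#' 120 days after birth (both boundaries inclusive). Onsets outside the
#' window — or preceding birth — mark the patient as excluded.
#'
#' @param onset_h Onset time in hours after birth (may be `NA`).
#' @param birth_h Birth time on the same axis (default 0).
#' @return `"clinical_lons"` when the onset is eligible, `"excluded"`
#'   otherwise, `NA` when `onset_h` is `NA`.
#' @export
filter_lons_eligibility <- function(onset_h, birth_h = 0) {
  rel <- onset_h - birth_h
  ifelse(is.na(rel), NA_character_,
         ifelse(rel >= 72 & rel <= 120 * 24, "clinical_lons", "excluded"))
}

#' Build per-patient cohort labels from event tables
#'
#' Combines [assign_diagnosis_groups()], [extract_onset_time()] and
#' [filter_lons_eligibility()]: sepsis-coded patients with an eligible onset
#' become `clinical_lons`; sepsis-coded patients whose onset cannot be dated
#' from events become `proven_sepsis` (diagnosed, timing not established,
#' excluded from modelling); sepsis-coded patients with an onset outside the
#' LONS window become `excluded`; everyone else is a `control`.
#'
#' @param cohort A `lons_cohort` (from [generate_cohort()] or
#'   [read_event_tables()]).
#' @param policy An [onset_policy()].
#' @return data.table with columns `SUBJECT_ID`, `group`, `onset_h`.
#' @export
build_cohort_labels <- function(cohort, policy = onset_policy()) {
  stopifnot(inherits(cohort, "lons_cohort"))
  grp <- assign_diagnosis_groups(cohort$tables$diagnoses)
  pats <- cohort$tables$patients
  lab <- data.table::data.table(SUBJECT_ID = pats$SUBJECT_ID)
  lab <- grp[lab, on = "SUBJECT_ID"]
  lab[is.na(group), group := "control"]
  lab[, onset_h := NA_real_]

  sep_ids <- lab[group == "sepsis", SUBJECT_ID]
  micro <- cohort$tables$microbiology
  rx <- cohort$tables$prescriptions
  for (id in sep_ids) {
    t0 <- extract_onset_time(micro[SUBJECT_ID == id], rx[SUBJECT_ID == id],
                             policy)
    data.table::set(lab, which(lab$SUBJECT_ID == id), "onset_h", t0)
  }
  lab[group == "sepsis",
      group := data.table::fifelse(is.na(onset_h), "proven_sepsis",
                                   filter_lons_eligibility(onset_h))]
  lab[group %in% c("excluded", "proven_sepsis"), onset_h := onset_h]
  data.table::setkey(lab, SUBJECT_ID)
  lab[]
}

#' Expand cohort labels into labeled reference-time instances
#'
#' For the `predict_48h` task each clinical-LONS patient contributes one
#' positive instance at `t = onset - 48` h (dropped when `t < 72` h or when
#' the observation window would reach before charting starts). For the
#' `detect` task positives are laid out at `cadence_h` spacing over
#' `[onset - 48, onset]`. Negatives come from control patients only, at
#' `cadence_h` spacing over their stay, subject to `t >= 72` h and at least
#' `window_h` of charted history; sepsis-group patients never contribute
#' negatives. No instance references data after its own reference time.
#'
#' @param labels Output of [build_cohort_labels()].
#' @param coverage Per-patient charting span: data frame with `SUBJECT_ID`,
#'   `first_h`, `last_h` (see [vitals_coverage()]).
#' @param task `"predict_48h"` or `"detect"`.
#' @param cadence_h Spacing of detection positives and of control negatives.
#' @param window_h Largest observation window that will be used downstream.
#' @return data.table with columns `instance_id`, `SUBJECT_ID`, `t_ref`
#'   (hours after birth), `task`, `label` (0/1).
#' @export
build_instances <- function(labels, coverage, task = c("predict_48h", "detect"),
                            cadence_h = 24, window_h = 24) {
  task <- match.arg(task)
  lab <- data.table::as.data.table(labels)
  cov <- data.table::as.data.table(coverage)
  lab <- cov[lab, on = "SUBJECT_ID"]

  grid_start <- function(first_h) pmax(72, first_h + window_h)

  pos <- lab[group == "clinical_lons" & !is.na(onset_h) & !is.na(first_h)]
  pos_rows <- if (task == "predict_48h") {
    p <- pos[, .(SUBJECT_ID, t_ref = onset_h - 48, first_h)]
    p[t_ref >= 72 & t_ref >= first_h + window_h, .(SUBJECT_ID, t_ref)]
  } else {
    if (nrow(pos)) pos[, {
      lo <- max(onset_h - 48, grid_start(first_h))
      tt <- if (lo <= onset_h) rev(seq(onset_h, lo, by = -cadence_h)) else numeric(0)
      list(t_ref = tt)
    }, by = SUBJECT_ID] else data.table::data.table(SUBJECT_ID = integer(),
                                                    t_ref = numeric())
  }
  if (nrow(pos_rows)) pos_rows[, label := 1L]

  neg <- lab[group == "control" & !is.na(first_h)]
  neg_rows <- if (nrow(neg)) neg[, {
    lo <- grid_start(first_h)
    tt <- if (lo <= last_h) seq(lo, last_h, by = cadence_h) else numeric(0)
    list(t_ref = tt)
  }, by = SUBJECT_ID] else data.table::data.table(SUBJECT_ID = integer(),
                                                  t_ref = numeric())
  if (nrow(neg_rows)) neg_rows[, label := 0L]

  out <- data.table::rbindlist(list(
    pos_rows[, .(SUBJECT_ID, t_ref, label)],
    neg_rows[, .(SUBJECT_ID, t_ref, label)]), use.names = TRUE)
  data.table::setorder(out, SUBJECT_ID, t_ref)
  out[, task := task]
  out[, instance_id := seq_len(.N)]
  data.table::setcolorder(out, c("instance_id", "SUBJECT_ID", "t_ref", "task",
                                 "label"))
  out[]
}

#' Charting coverage per patient
#'
#' First and last vital-sign observation time per patient, used to bound
#' instance placement.
#'
#' @param vitals Vitals chart table (`SUBJECT_ID`, `CHARTTIME`, ...).
#' @return data.table with `SUBJECT_ID`, `first_h`, `last_h`.
#' @export
vitals_coverage <- function(vitals) {
  dt <- data.table::as.data.table(vitals)
  out <- dt[, .(first_h = min(CHARTTIME), last_h = max(CHARTTIME)),
            by = SUBJECT_ID]
  data.table::setkey(out, SUBJECT_ID)
  out[]
}
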