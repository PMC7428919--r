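## Synthetic MIMIC-III-shaped NICU cohort generator.
##
## Produces the five event tables used downstream (vitals chart, microbiology,
## prescriptions, diagnoses, demographics) plus a ground-truth table, with a
## configurable physiological deterioration signature planted before each
## sepsis patient's onset. Everything is deterministic given (config, seed).

#' The seven noninvasive vital signs
#'
#' Canonical vital-sign names used throughout the package, in canonical order.
#'
#' @return Character vector of length 7.
#' @export
vital_names <- function() {
  c("heart_rate", "respiratory_rate", "oxygen_saturation",
    "systolic_bp", "mean_bp", "diastolic_bp", "body_temperature")
}

#' Default per-vital deterioration effect sizes
#'
#' Effect sizes applied over the pre-onset ramp: `drift` is the additive change
#' reached at onset (bpm, breaths/min, %, mmHg or degrees C depending on the
#' vital; negative values model hypotension), `sd_factor` multiplies the
#' observation-level standard deviation uniformly across the ramp (instability),
#' and `dip_depth` / `dip_rate` control transient downward excursions
#' (desaturation-style dips; per-observation probability `dip_rate` at onset,
#' ramping up linearly, mean depth `dip_depth` in the vital's units).
#'
#' The defaults encode the qualitative pre-sepsis signature reported for
#' neonates: tachycardia drift, desaturation dips with widened oxygen-saturation
#' variability, temperature instability, and blood-pressure excursions.
#'
#' @return Named list (one element per vital) of effect-size lists.
#' @export
deterioration_defaults <- function() {
  list(
    heart_rate         = list(drift = 20,  sd_factor = 1.15, dip_depth = 0, dip_rate = 0),
    respiratory_rate   = list(drift = 5,   sd_factor = 1.15, dip_depth = 0, dip_rate = 0),
    oxygen_saturation  = list(drift = -1,  sd_factor = 1.5,  dip_depth = 4, dip_rate = 0.25),
    systolic_bp        = list(drift = -8,  sd_factor = 1.2,  dip_depth = 0, dip_rate = 0),
    mean_bp            = list(drift = -8,  sd_factor = 1.2,  dip_depth = 0, dip_rate = 0),
    diastolic_bp       = list(drift = -8,  sd_factor = 1.2,  dip_depth = 0, dip_rate = 0),
    body_temperature   = list(drift = 0,   sd_factor = 1.5,  dip_depth = 0, dip_rate = 0)
  )
}

#' Simulation configuration for the synthetic NICU cohort
#'
#' Distribution centers default to the published population characteristics of
#' the NICU cohort the schemas emulate: clinical-LONS gestational age centred
#' at 30 weeks and birth weight at 0.80 kg versus 34 weeks / 2.02 kg for
#' controls, with lengths of stay centred at 87.9 and 13.3 days respectively.
#'
#' @param n_patients Number of patients to simulate.
#' @param lons_prevalence Fraction of patients in the clinical-LONS group,
#'   in (0, 1). The modelling default is 0.05; the real-cohort clinical
#'   prevalence (21/2798, about 0.0075) can be requested instead.
#' @param other_sepsis_frac Fraction of patients carrying a sepsis diagnosis
#'   code and a blood culture but no coincident intravenous antibiotic, so that
#'   no onset can be dated from events (they phenotype as `proven_sepsis` and
#'   are excluded from modelling).
#' @param seed Integer seed; identical `(config, seed)` pairs reproduce
#'   identical cohorts.
#' @param cadence_min Mean inter-observation interval per vital, minutes.
#'   Either a single number or a named vector over [vital_names()].
#' @param cadence_jitter Fractional jitter of the inter-observation gaps.
#' @param missingness Probability that a scheduled observation is absent.
#' @param ramp_h Length of the pre-onset deterioration ramp in hours. Effects
#'   grow linearly from zero at `onset - ramp_h` to full size at onset and are
#'   sustained afterwards. The default (96 h) makes physiological change
#'   precede the event-dated clinical onset by more than the 48 h prediction
#'   horizon, as observed in real cohorts where charted deterioration leads the
#'   culture/antibiotic response.
#' @param deterioration Per-vital effect sizes, see [deterioration_defaults()].
#' @param ga_weeks,bw_kg Group-wise distribution parameters (median and IQR
#'   bounds) for gestational age and birth weight.
#' @param los_days Group-wise median length of stay in days.
#' @param male_p Group-wise probability of male sex.
#' @param culture_jitter_h Blood-culture placement jitter around the true
#'   onset (uniform on +/- this many hours).
#' @param abx_delay_h Range of the IV antibiotic start delay after culture.
#' @param antibiotics Broad-spectrum antibiotic names used in synthetic
#'   prescriptions.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       lons_prevalence = 0.05,
                       other_sepsis_frac = 0.02,
                       seed = 1L,
                       cadence_min = 60,
                       cadence_jitter = 0.3,
                       missingness = 0.1,
                       ramp_h = 96,
                       deterioration = deterioration_defaults(),
                       ga_weeks = list(lons    = c(median = 30, lo = 27,   hi = 34.5),
                                       control = c(median = 34, lo = 33.5, hi = 34.5)),
                       bw_kg = list(lons = 0.80, control = 2.02),
                       los_days = list(lons = 87.9, control = 13.3),
                       male_p = list(lons = 0.619, control = 0.515),
                       culture_jitter_h = 2,
                       abx_delay_h = c(0, 12),
                       antibiotics = c("Vancomycin", "Gentamicin", "Ampicillin",
                                       "Cefotaxime", "Meropenem")) {
  if (!is_count(n_patients)) stopf("n_patients must be a non-negative integer")
  if (!is_prob(lons_prevalence)) stopf("lons_prevalence must lie in (0, 1)")
  if (!(ramp_h > 0)) stopf("ramp_h must be positive")
  if (length(cadence_min) == 1L) {
    cadence_min <- setNames(rep(cadence_min, 7L), vital_names())
  }
  if (any(cadence_min <= 0)) stopf("all cadences must be positive")
  stopifnot(missingness >= 0, missingness < 1, length(antibiotics) >= 1L)
  structure(list(
    n_patients = as.integer(n_patients), lons_prevalence = lons_prevalence,
    other_sepsis_frac = other_sepsis_frac, seed = as.integer(seed),
    cadence_min = cadence_min[vital_names()], cadence_jitter = cadence_jitter,
    missingness = missingness, ramp_h = ramp_h, deterioration = deterioration,
    ga_weeks = ga_weeks, bw_kg = bw_kg, los_days = los_days, male_p = male_p,
    culture_jitter_h = culture_jitter_h, abx_delay_h = abx_delay_h,
    antibiotics = antibiotics
  ), class = "sim_config")
}

## Vital-sign baseline model conditioned on gestational age (weeks).
## Mean arterial pressure approximates GA in mmHg, a standard NICU rule of
## thumb; the remaining centres sit in published preterm reference ranges.
## `between` is the between-patient SD of the personal baseline, `within` the
## observation-level SD; each patient additionally carries a lognormal
## within-noise scale (sdlog 0.25), reflecting that charting variability
## differs between infants.
baseline_params <- function(vital, ga) {
  switch(vital,
    heart_rate        = list(mu = 155 - 1.2 * (ga - 30), between = 8,  within = 7),
    respiratory_rate  = list(mu = 48,                    between = 6,  within = 8),
    oxygen_saturation = list(mu = 96.5,                  between = 1.2, within = 1.5),
    systolic_bp       = list(mu = ga + 12,               between = 4.5, within = 5),
    mean_bp           = list(mu = ga,                    between = 4,  within = 4),
    diastolic_bp      = list(mu = ga - 8,                between = 4,  within = 4),
    body_temperature  = list(mu = 36.8,                  between = 0.2, within = 0.18),
    stopf("unknown vital '%s'", vital)
  )
}

#' Inject a pre-onset deterioration signature into one vital-sign series
#'
#' Observations strictly before `onset - ramp_h` are unchanged. Within the
#' ramp, an additive drift grows linearly to its configured full size at onset
#' (and is sustained after onset), observation noise is inflated by a constant
#' factor `sd_factor` (estimated from the pre-ramp observation SD), and
#' transient downward dips of mean depth `dip_depth` occur with per-observation
#' probability ramping to `dip_rate` at onset. With all effect sizes at their
#' null values (`drift = 0`, `sd_factor = 1`, `dip_depth = 0` or
#' `dip_rate = 0`) the series values are returned unchanged.
#'
#' @param series Data frame with numeric columns `time` (hours after birth,
#'   strictly increasing) and `value`.
#' @param onset Onset time in hours after birth; must fall within the series'
#'   time span.
#' @param params List with elements `drift`, `sd_factor`, `dip_depth`,
#'   `dip_rate` (missing elements default to the null effect).
#' @param ramp_h Ramp length in hours (> 0).
#'
#' @return The series with modified values (same rows, same times).
#' @export
inject_deterioration <- function(series, onset, params, ramp_h = 96) {
  stopifnot(is.data.frame(series), all(c("time", "value") %in% names(series)))
  if (!(ramp_h > 0)) stopf("ramp_h must be positive")
  if (nrow(series) == 0L) return(series)
  if (onset < series$time[1L]) stopf("onset precedes the first observation")
  p <- list(drift = 0, sd_factor = 1, dip_depth = 0, dip_rate = 0)
  p[names(params)] <- params

  tt <- series$time
  g <- pmin(1, pmax(0, (tt - (onset - ramp_h)) / ramp_h))
  in_ramp <- g > 0
  v <- series$value

  if (any(in_ramp)) {
    v[in_ramp] <- v[in_ramp] + p$drift * g[in_ramp]
    if (p$sd_factor != 1) {
      pre <- v[!in_ramp]
      sigma <- if (length(pre) >= 2L) sd(pre) else 0
      extra <- sigma * sqrt(max(0, p$sd_factor^2 - 1))
      v[in_ramp] <- v[in_ramp] + rnorm(sum(in_ramp), 0, extra)
    }
    if (p$dip_depth > 0 && p$dip_rate > 0) {
      hit <- runif(sum(in_ramp)) < p$dip_rate * g[in_ramp]
      depth <- p$dip_depth * (0.5 + 0.5 * rexp(sum(in_ramp)))
      v[in_ramp] <- v[in_ramp] - hit * depth
    }
  }
  series$value <- v
  series
}

## Truncated normal draw via rejection-free clamping (tails are negligible at
## the ranges used; clamping keeps values physiological).
rnorm_trunc <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, rnorm(n, mean, sd)))

## Sepsis and benign ICD-9-CM codes in the dotless MIMIC-III dialect.
sepsis_icd_pool <- c("0380", "03811", "0389", "7718", "77181", "99591", "78552")
benign_icd_pool <- c("V3000", "V3101", "7746", "76518", "7470")

#' Generate a synthetic NICU cohort with known ground truth
#'
#' Simulates demographics, irregularly sampled vital-sign charts for all seven
#' vitals, and group-consistent diagnosis / microbiology / prescription events:
#' sepsis patients receive a sepsis ICD-9 code, one blood-culture row placed
#' within `culture_jitter_h` of the true onset and at least one intravenous
#' broad-spectrum antibiotic order shortly after; controls receive none of
#' these. Clinical-LONS patients carry the planted deterioration signature of
#' the configuration.
#'
#' @param config A [sim_config()].
#' @return Object of class `lons_cohort`: list with `tables` (named list of
#'   data.tables: `vitals`, `microbiology`, `prescriptions`, `diagnoses`,
#'   `patients`) and `truth` (ground-truth data.table with `SUBJECT_ID`,
#'   `group`, `onset_h`, `planted`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  empty <- empty_cohort(config)
  if (n == 0L) return(empty)

  with_seed(config$seed, {
    ## --- group assignment: documented first draw of the RNG stream ---
    gs <- runif(n)
    group <- ifelse(gs < config$lons_prevalence, "clinical_lons",
             ifelse(gs < config$lons_prevalence + config$other_sepsis_frac,
                    "proven_sepsis", "control"))
    is_sep <- group != "control"

    ## --- demographics ---
    ga_par <- function(g) {
      p <- if (g == "control") config$ga_weeks$control else config$ga_weeks$lons
      c(p[["median"]], (p[["hi"]] - p[["lo"]]) / 1.349)
    }
    ga <- numeric(n)
    for (g in unique(group)) {
      idx <- group == g
      pp <- ga_par(g)
      ga[idx] <- rnorm_trunc(sum(idx), pp[1L], max(pp[2L], 0.75), 23, 42)
    }
    ## log-linear birth-weight model through the group medians, with a
    ## group-level multiplier matching the published LONS median (0.80 kg)
    bw <- exp(-7.171 + 0.2316 * ga + rnorm(n, 0, 0.18))
    bw[is_sep] <- bw[is_sep] * (config$bw_kg$lons / 0.92)
    bw <- pmin(4.5, pmax(0.35, bw))
    male_p <- ifelse(is_sep, config$male_p$lons, config$male_p$control)
    sex <- ifelse(runif(n) < male_p, "M", "F")

    los_med <- ifelse(is_sep, config$los_days$lons, config$los_days$control)
    los_h <- 24 * pmin(ifelse(is_sep, 120, 60),
                       pmax(ifelse(is_sep, 10, 4.5), rlnorm(n, log(los_med), 0.55)))

    onset_h <- rep(NA_real_, n)
    lo <- pmax(72, 0.2 * los_h[is_sep]); hi <- pmin(120 * 24, 0.9 * los_h[is_sep])
    onset_h[is_sep] <- to_minutes(lo + runif(sum(is_sep)) * (hi - lo))

    patients <- data.table::data.table(
      SUBJECT_ID = seq_len(n), BIRTHTIME = 0, GA_WEEKS = round(ga, 1),
      BW_KG = round(bw, 2), SEX = sex)

    ## --- vital-sign charts ---
    vit_list <- vector("list", 7L)
    for (vi in seq_along(vital_names())) {
      v <- vital_names()[vi]
      cad_h <- config$cadence_min[[v]] / 60
      n_obs <- pmax(2L, as.integer(ceiling(los_h / cad_h * 1.2)))
      pid <- rep(seq_len(n), n_obs)
      jit <- config$cadence_jitter
      gaps <- cad_h * (1 - jit + 2 * jit * runif(sum(n_obs)))
      dtv <- data.table::data.table(SUBJECT_ID = pid, gap = gaps)
      dtv[, CHARTTIME := cumsum(gap), by = SUBJECT_ID]
      dtv[, gap := NULL]
      dtv <- dtv[CHARTTIME <= los_h[SUBJECT_ID]]
      if (config$missingness > 0) dtv <- dtv[runif(.N) >= config$missingness]
      dtv[, CHARTTIME := to_minutes(CHARTTIME)]
      dtv <- unique(dtv, by = c("SUBJECT_ID", "CHARTTIME"))

      bp <- baseline_params(v, ga)
      pmu <- bp$mu + rnorm(n, 0, bp$between)
      psig <- bp$within * rlnorm(n, 0, 0.25)
      dtv[, VALUENUM := pmu[SUBJECT_ID] + rnorm(.N, 0, 1) * psig[SUBJECT_ID]]
      if (v == "oxygen_saturation") dtv[, VALUENUM := pmin(100, VALUENUM)]

      ## plant deterioration in sepsis patients (vectorized form of
      ## inject_deterioration: ramped drift, constant SD inflation over the
      ## ramp using the pre-ramp observation SD, ramped dip probability)
      eff0 <- list(drift = 0, sd_factor = 1, dip_depth = 0, dip_rate = 0)
      eff <- config$deterioration[[v]]
      eff0[names(eff)] <- eff
      eff <- eff0
      if (any(is_sep) && (eff$drift != 0 || eff$sd_factor != 1 ||
                          (eff$dip_depth > 0 && eff$dip_rate > 0))) {
        ons <- onset_h[dtv$SUBJECT_ID]
        g <- pmin(1, pmax(0, (dtv$CHARTTIME - (ons - config$ramp_h)) /
                            config$ramp_h))
        g[is.na(g)] <- 0
        in_ramp <- g > 0
        if (eff$drift != 0) {
          dtv[in_ramp, VALUENUM := VALUENUM + eff$drift * g[in_ramp]]
        }
        if (eff$sd_factor != 1) {
          pre <- dtv[!is.na(ons) & !in_ramp,
                     .(sig = sd(VALUENUM)), by = SUBJECT_ID]
          sig <- setNames(pre$sig, pre$SUBJECT_ID)[as.character(dtv$SUBJECT_ID)]
          sig[is.na(sig)] <- 0
          extra <- sig * sqrt(max(0, eff$sd_factor^2 - 1))
          dtv[in_ramp, VALUENUM := VALUENUM +
                rnorm(.N, 0, 1) * extra[in_ramp]]
        }
        if (eff$dip_depth > 0 && eff$dip_rate > 0) {
          nr <- sum(in_ramp)
          hit <- runif(nr) < eff$dip_rate * g[in_ramp]
          depth <- eff$dip_depth * (0.5 + 0.5 * rexp(nr))
          dtv[in_ramp, VALUENUM := VALUENUM - hit * depth]
        }
      }
      dtv[, VITAL := v]
      vit_list[[vi]] <- dtv
    }
    vitals <- data.table::rbindlist(vit_list)[, .(SUBJECT_ID, CHARTTIME, VITAL, VALUENUM)]
    vitals[, VALUENUM := round(VALUENUM, 2)]
    data.table::setkey(vitals, SUBJECT_ID, VITAL, CHARTTIME)

    ## --- events ---
    sep_idx <- which(is_sep)
    lons_idx <- which(group == "clinical_lons")
    oth_idx <- which(group == "proven_sepsis")

    diagnoses <- data.table::data.table(
      SUBJECT_ID = c(sep_idx, seq_len(n)),
      ICD9_CODE = c(sample(sepsis_icd_pool, length(sep_idx), replace = TRUE),
                    sample(benign_icd_pool, n, replace = TRUE)))
    data.table::setkey(diagnoses, SUBJECT_ID)

    cult_t <- to_minutes(onset_h[sep_idx] +
                           runif(length(sep_idx), -config$culture_jitter_h,
                                 config$culture_jitter_h))
    microbiology <- data.table::data.table(
      SUBJECT_ID = sep_idx, CHARTTIME = pmax(0, cult_t),
      SPEC_TYPE_DESC = "BLOOD CULTURE")

    abx_t <- to_minutes(pmax(0, cult_t) +
                          runif(length(sep_idx), config$abx_delay_h[1L],
                                config$abx_delay_h[2L]))
    route <- ifelse(sep_idx %in% lons_idx, "IV", "PO")
    prescriptions <- data.table::data.table(
      SUBJECT_ID = sep_idx, STARTDATE = abx_t,
      DRUG = sample(config$antibiotics, length(sep_idx), replace = TRUE),
      ROUTE = route)
    ## clinical-LONS patients get a second (follow-up) IV antibiotic order
    if (length(lons_idx)) {
      fu <- data.table::data.table(
        SUBJECT_ID = lons_idx,
        STARTDATE = to_minutes(abx_t[sep_idx %in% lons_idx] + runif(length(lons_idx), 12, 36)),
        DRUG = sample(config$antibiotics, length(lons_idx), replace = TRUE),
        ROUTE = "IV")
      prescriptions <- data.table::rbindlist(list(prescriptions, fu))
    }
    data.table::setkey(prescriptions, SUBJECT_ID, STARTDATE)

    truth <- data.table::data.table(
      SUBJECT_ID = seq_len(n), group = group, onset_h = onset_h,
      planted = paste(planted_features(config$deterioration), collapse = ";"))

    structure(list(
      tables = list(vitals = vitals, microbiology = microbiology,
                    prescriptions = prescriptions, diagnoses = diagnoses,
                    patients = patients),
      truth = truth, config = config), class = "lons_cohort")
  })
}

## Feature specs the configured deterioration makes informative.
planted_features <- function(det) {
  out <- character(0)
  for (v in names(det)) {
    e <- det[[v]]
    if (!is.null(e$drift) && e$drift != 0) out <- c(out, paste0(v, "__raw__mean"))
    if ((!is.null(e$sd_factor) && e$sd_factor != 1) ||
        (!is.null(e$dip_depth) && e$dip_depth > 0 && e$dip_rate > 0)) {
      out <- c(out, paste0(v, "__raw__sd"))
    }
  }
  out
}

empty_cohort <- function(config) {
  structure(list(
    tables = list(
      vitals = data.table::data.table(SUBJECT_ID = integer(), CHARTTIME = numeric(),
                                      VITAL = character(), VALUENUM = numeric()),
      microbiology = data.table::data.table(SUBJECT_ID = integer(), CHARTTIME = numeric(),
                                            SPEC_TYPE_DESC = character()),
      prescriptions = data.table::data.table(SUBJECT_ID = integer(), STARTDATE = numeric(),
                                             DRUG = character(), ROUTE = character()),
      diagnoses = data.table::data.table(SUBJECT_ID = integer(), ICD9_CODE = character()),
      patients = data.table::data.table(SUBJECT_ID = integer(), BIRTHTIME = numeric(),
                                        GA_WEEKS = numeric(), BW_KG = numeric(),
                                        SEX = character())),
    truth = data.table::data.table(SUBJECT_ID = integer(), group = character(),
                                   onset_h = numeric(), planted = character()),
    config = config), class = "lons_cohort")
}

#' @export
print.lons_cohort <- function(x, ...) {
  tab <- table(factor(x$truth$group,
                      levels = c("clinical_lons", "proven_sepsis", "control")))
  cat("Synthetic NICU cohort:", nrow(x$tables$patients), "patients\n")
  cat(sprintf("  clinical LONS %d | proven sepsis %d | control %d\n",
              tab[1L], tab[2L], tab[3L]))
  cat(sprintf("  vitals chart rows: %s\n",
              format(nrow(x$tables$vitals), big.mark = ",")))
  invisible(x)
}

#' Write cohort event tables to CSV files
#'
#' Writes `VITALS.csv`, `MICROBIOLOGYEVENTS.csv`, `PRESCRIPTIONS.csv`,
#' `DIAGNOSES_ICD.csv`, `PATIENTS.csv` and `GROUND_TRUTH.csv` into `dir`.
#' Files round-trip losslessly through [read_event_tables()]. Times are hours
#' after birth at minute resolution.
#'
#' @param cohort A `lons_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_event_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lons_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stopf("directory '%s' is not writable", dir)
  files <- c(vitals = "VITALS.csv", microbiology = "MICROBIOLOGYEVENTS.csv",
             prescriptions = "PRESCRIPTIONS.csv", diagnoses = "DIAGNOSES_ICD.csv",
             patients = "PATIENTS.csv")
  paths <- character(0)
  for (nm in names(files)) {
    p <- file.path(dir, files[[nm]])
    data.table::fwrite(cohort$tables[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "GROUND_TRUTH.csv")
  data.table::fwrite(cohort$truth, p)
  invisible(c(paths, p))
}

#' Read cohort event tables from a directory of CSV files
#'
#' Counterpart of [write_event_tables()]; also accepts real-schema exports
#' with the same column names. The ground-truth file is optional.
#'
#' @param dir Directory containing the CSV files.
#' @return A `lons_cohort` (with `truth = NULL` when no ground-truth file is
#'   present, and `config = NULL`).
#' @export
read_event_tables <- function(dir) {
  req <- c(vitals = "VITALS.csv", microbiology = "MICROBIOLOGYEVENTS.csv",
           prescriptions = "PRESCRIPTIONS.csv", diagnoses = "DIAGNOSES_ICD.csv",
           patients = "PATIENTS.csv")
  tabs <- list()
  for (nm in names(req)) {
    p <- file.path(dir, req[[nm]])
    if (!file.exists(p)) stopf("missing table file '%s'", p)
    tabs[[nm]] <- data.table::fread(p, colClasses = list(character = intersect(
      c("VITAL", "SPEC_TYPE_DESC", "DRUG", "ROUTE", "ICD9_CODE", "SEX"),
      names(data.table::fread(p, nrows = 0L)))))
  }
  data.table::setkey(tabs$vitals, SUBJECT_ID, VITAL, CHARTTIME)
  data.table::setkey(tabs$diagnoses, SUBJECT_ID)
  data.table::setkey(tabs$prescriptions, SUBJECT_ID, STARTDATE)
  truth <- NULL
  tp <- file.path(dir, "GROUND_TRUTH.csv")
  if (file.exists(tp)) truth <- data.table::fread(tp, colClasses = list(
    character = c("group", "planted")))
  structure(list(tables = tabs, truth = truth, config = NULL),
            class = "lons_cohort")
}
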