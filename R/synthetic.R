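#' Generate a synthetic patient registry for an annual head-and-neck cohort
#'
#' Draws tumor localizations from the eight ICD-10-based categories, by
#' default with the mixing weights of a typical annual manual-registry cohort
#' (see [localization_table()]). A configurable fraction of patients carry an
#' exclusion-triggering feature (carcinoma in situ, second primary,
#' recurrent/residual disease, palliative intent, non-squamous histology, or
#' an initial consultation outside the target year), emulating the raw
#' registry before study criteria are applied.
#'
#' @param n_patients Number of patients (>= 1).
#' @param localization_weights Probability vector over the eight localization
#'   categories (must sum to 1 within 1e-9).
#' @param seed Integer seed; identical inputs give identical output.
#' @param exclusion_frac Fraction of patients given an exclusion-triggering
#'   feature.
#' @param year Target initial-consultation year.
#' @return A tibble with one row per patient: `patient_id`, `icd10_code`,
#'   `localization`, `histology`, `tumor_order`, `intent`,
#'   `initial_consult_year`.
#' @export
generate_cohort <- function(n_patients,
                            localization_weights = localization_table()$weight,
                            seed = 1L,
                            exclusion_frac = 0,
                            year = 2020L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (length(localization_weights) != 8) {
    stop("`localization_weights` must have length 8 (one per category)",
         call. = FALSE)
  }
  if (abs(sum(localization_weights) - 1) > 1e-9) {
    stop("`localization_weights` must sum to 1", call. = FALSE)
  }
  assert_prob(exclusion_frac, "exclusion_frac")
  n <- as.integer(n_patients)

  withr::with_seed(seed, {
    loc <- sample(localization_levels(), n, replace = TRUE,
                  prob = localization_weights)
    reg <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      icd10_code = representative_icd10(loc),
      localization = loc,
      histology = "scc",
      tumor_order = "first_primary",
      intent = "curative",
      initial_consult_year = as.integer(year)
    )
    excl <- which(stats::runif(n) < exclusion_frac)
    if (length(excl)) {
      trigger <- sample(
        c("cis", "second_primary", "recurrence", "residual", "palliative",
          "non_scc", "other_year"),
        length(excl), replace = TRUE,
        prob = c(0.2, 0.15, 0.2, 0.05, 0.15, 0.2, 0.05)
      )
      reg$histology[excl][trigger == "cis"] <- "cis"
      reg$tumor_order[excl][trigger == "second_primary"] <- "second_primary"
      reg$tumor_order[excl][trigger == "recurrence"] <- "recurrence"
      reg$tumor_order[excl][trigger == "residual"] <- "residual"
      reg$intent[excl][trigger == "palliative"] <- "palliative"
      n_non <- sum(trigger == "non_scc")
      if (n_non) {
        reg$histology[excl][trigger == "non_scc"] <- sample(
          c("melanoma", "thyroid", "skin", "sarcoma", "neuroendocrine",
            "hematologic"), n_non, replace = TRUE)
      }
      reg$initial_consult_year[excl][trigger == "other_year"] <-
        as.integer(year) - 1L
    }
    reg
  })
}

#' Care-pathway configuration for the event-log generator
#'
#' Waiting-time medians (days), treatment-modality probabilities and pathway
#' scheduling parameters. Defaults reproduce the marginal pattern of a
#' tertiary head-and-neck service: a median of 5 days from referral
#' (scheduling order) to initial consultation and 2 days from consultation to
#' the weekly multidisciplinary team meeting (MDT, Wednesdays), roughly half
#' the cohort undergoing surgery, three quarters radiotherapy and a fifth
#' systemic therapy.
#'
#' @param mdt_weekday Weekday of the weekly MDT (0 = Sunday ... 6 = Saturday).
#' @param referral_to_consult_median,mdt_to_treatment_median Median waiting
#'   times in days (referral letter to initial consultation; MDT to first
#'   treatment).
#' @param consult_weekday_weights Sampling weights for the initial
#'   consultation's weekday (Monday..Friday). New patients are booked early
#'   in the week so most reach the Wednesday tumor board within two days.
#' @param consult_to_mdt_min Minimum number of days between consultation and
#'   the first eligible weekly MDT.
#' @param surgery_to_adjuvant_median Median days from surgery to the start of
#'   adjuvant therapy.
#' @param p_surgery,p_rt,p_systemic Marginal modality probabilities (a patient
#'   with no modality drawn is assigned radiotherapy).
#' @param rt_fractions Number of weekday radiotherapy fractions.
#' @param systemic_cycles,systemic_cycle_gap_days Number of systemic
#'   administrations and the gap between consecutive ones.
#' @param second_round_gap_days,second_round_cycles Gap before, and length of,
#'   an injected second systemic round (used only when the discrepancy profile
#'   enables it).
#' @param p_neck_dissection Probability a surgical patient has a neck
#'   dissection.
#' @param p_physio_given_nd Probability a neck-dissection patient has a
#'   postoperative physiotherapy contact.
#' @param p_dental_given_rt Probability a radiotherapy patient has a dental
#'   team consultation before radiotherapy starts.
#' @param p_unplanned_reop,p_planned_reop,p_complication Per-surgical-patient
#'   event probabilities.
#' @return A list of class `pathway_config`.
#' @export
pathway_config <- function(mdt_weekday = 3L,
                           referral_to_consult_median = 5,
                           consult_weekday_weights = c(0.4, 0.3, 0.1, 0.1, 0.1),
                           consult_to_mdt_min = 1L,
                           mdt_to_treatment_median = 16,
                           surgery_to_adjuvant_median = 38,
                           p_surgery = 0.52,
                           p_rt = 0.78,
                           p_systemic = 0.20,
                           rt_fractions = 30L,
                           systemic_cycles = 3L,
                           systemic_cycle_gap_days = 21L,
                           second_round_gap_days = 150L,
                           second_round_cycles = 2L,
                           p_neck_dissection = 0.5,
                           p_physio_given_nd = 0.59,
                           p_dental_given_rt = 0.86,
                           p_unplanned_reop = 0.068,
                           p_planned_reop = 0.03,
                           p_complication = 0.25) {
  cfg <- as.list(environment())
  for (nm in grep("^p_", names(cfg), value = TRUE)) assert_prob(cfg[[nm]], nm)
  stopifnot(mdt_weekday %in% 0:6, rt_fractions >= 1, systemic_cycles >= 1,
            length(consult_weekday_weights) == 5,
            all(consult_weekday_weights >= 0),
            sum(consult_weekday_weights) > 0,
            consult_to_mdt_min >= 0)
  for (nm in grep("median$", names(cfg), value = TRUE)) {
    if (is.null(cfg[[nm]]) || !is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop(sprintf("`%s` must be a day count >= 1", nm), call. = FALSE)
    }
  }
  structure(cfg, class = "pathway_config")
}

#' Event types recognised in a care-pathway event log
#' @return Character vector of event-type names.
#' @export
event_types <- function() {
  c("scheduling_order", "scanned_referral_letter", "initial_consult",
    "mdt_meeting", "surgery", "neck_dissection", "reoperation",
    "complication", "rt_fraction", "systemic_admin", "dental_consult",
    "physio_inpatient_form", "physio_outpatient_contact",
    "physio_external_referral")
}

#' Generate a ground-truth care-pathway event log
#'
#' For every registry patient, lays out the pathway: a scheduling order, the
#' scanned referral letter, the initial consultation, a weekly-scheduled MDT,
#' then surgery and/or radiotherapy fractions and/or systemic administrations
#' with supporting events (dental consultation before radiotherapy,
#' postoperative physiotherapy, reoperations, complications).
#'
#' Two discrepancy modes live at the event level and are driven by `profile`:
#' with probability `p_referral_offset` the scanned letter carries a referral
#' date 1-3 days before the scheduling order (the general practitioner wrote
#' the letter before the hospital acted on it); with probability
#' `p_physio_outpatient` physiotherapy happens only outpatient/externally (no
#' inpatient form is ever filed); with probability `p_second_systemic_round` a
#' systemic patient receives a later second round of administrations.
#'
#' @param registry Tibble from [generate_cohort()].
#' @param pathway A [pathway_config()].
#' @param profile A [discrepancy_profile()]; the identity profile injects
#'   nothing.
#' @param seed Integer seed.
#' @return A tibble of care events: `patient_id`, `event_type`, `event_date`
#'   (Date), `setting` (`inpatient`/`outpatient`/`external`), `planned_flag`
#'   (logical; meaningful for reoperations, NA elsewhere), sorted by patient
#'   and date.
#' @export
generate_event_log <- function(registry,
                               pathway = pathway_config(),
                               profile = discrepancy_profile(),
                               seed = 1L) {
  if (!nrow(registry)) stop("`registry` must be non-empty", call. = FALSE)
  if (!inherits(pathway, "pathway_config")) {
    stop("`pathway` must be created by pathway_config()", call. = FALSE)
  }
  stopifnot(inherits(profile, "discrepancy_profile"))

  withr::with_seed(seed, {
    n <- nrow(registry)
    id <- registry$patient_id

    # diagnostic phase ------------------------------------------------------
    # consult day: weekday weighted toward early week, uniform over the year
    consult <- as.Date(vapply(seq_len(n), function(i) {
      wd <- year_weekdays(registry$initial_consult_year[i])
      w <- pathway$consult_weekday_weights[as.POSIXlt(wd)$wday]
      as.numeric(sample(wd, 1, prob = w))
    }, numeric(1)), origin = "1970-01-01")
    # the letter's written referral date anchors the manual waiting time; the
    # scheduling order (the engine's referral proxy) precedes it by 1-3 days
    # when the offset mode is active
    letter <- consult - rwait_days(n, pathway$referral_to_consult_median,
                                   spread_mu = 1.3, spread_size = 4)
    offset <- ifelse(
      stats::runif(n) < profile$p_referral_offset,
      sample(profile$referral_offset_days, n, replace = TRUE,
             prob = profile$referral_offset_weights),
      0L
    )
    sched <- letter - offset
    # first weekly MDT at least consult_to_mdt_min days after consult
    mdt <- next_weekday(consult + pathway$consult_to_mdt_min - 1,
                        pathway$mdt_weekday)

    # treatment phase -------------------------------------------------------
    has_surg <- stats::runif(n) < pathway$p_surgery
    has_rt <- stats::runif(n) < pathway$p_rt
    has_syst <- stats::runif(n) < pathway$p_systemic
    has_rt[!has_surg & !has_rt & !has_syst] <- TRUE
    tx_start <- mdt + rwait_days(n, pathway$mdt_to_treatment_median,
                                 spread_mu = 8, spread_size = 2, min = 2)

    surg_date <- as.Date(ifelse(has_surg, tx_start, NA), origin = "1970-01-01")
    adj_wait <- rwait_days(n, pathway$surgery_to_adjuvant_median,
                           spread_mu = 6, spread_size = 4, min = 10)
    rt_start <- as.Date(ifelse(
      has_rt, ifelse(has_surg, surg_date + adj_wait, tx_start), NA
    ), origin = "1970-01-01")
    syst_start <- as.Date(ifelse(
      has_syst,
      ifelse(has_rt, rt_start,                       # concurrent chemoradiation
             ifelse(has_surg, surg_date + adj_wait, tx_start)),
      NA
    ), origin = "1970-01-01")

    has_nd <- has_surg & stats::runif(n) < pathway$p_neck_dissection
    has_physio <- has_nd & stats::runif(n) < pathway$p_physio_given_nd
    physio_out <- has_physio & stats::runif(n) < profile$p_physio_outpatient
    physio_date <- surg_date + sample(1:5, n, replace = TRUE)
    has_dental <- has_rt & stats::runif(n) < pathway$p_dental_given_rt
    dental_date <- pmax(consult + 1,
                        rt_start - rwait_days(n, 10, spread_mu = 3, min = 1))
    has_unpl <- has_surg & stats::runif(n) < pathway$p_unplanned_reop
    has_plan <- has_surg & stats::runif(n) < pathway$p_planned_reop
    reop_date <- surg_date + sample(3:10, n, replace = TRUE)
    has_compl <- has_surg & stats::runif(n) < pathway$p_complication
    compl_date <- surg_date + sample(1:7, n, replace = TRUE)
    second_round <- has_syst & stats::runif(n) < profile$p_second_systemic_round

    one_per_patient <- function(keep, type, date, setting, planned = NA) {
      tibble::tibble(
        patient_id = id[keep], event_type = type,
        event_date = date[keep], setting = setting,
        planned_flag = planned
      )
    }
    all_pat <- rep(TRUE, n)
    events <- list(
      one_per_patient(all_pat, "scheduling_order", sched, "outpatient"),
      one_per_patient(all_pat, "scanned_referral_letter", letter, "outpatient"),
      one_per_patient(all_pat, "initial_consult", consult, "outpatient"),
      one_per_patient(all_pat, "mdt_meeting", mdt, "outpatient"),
      one_per_patient(has_surg, "surgery", surg_date, "inpatient"),
      one_per_patient(has_nd, "neck_dissection", surg_date, "inpatient"),
      one_per_patient(has_unpl, "reoperation", reop_date, "inpatient", FALSE),
      one_per_patient(has_plan, "reoperation", reop_date + 2, "inpatient", TRUE),
      one_per_patient(has_compl, "complication", compl_date, "inpatient"),
      one_per_patient(has_dental, "dental_consult", dental_date, "outpatient"),
      one_per_patient(has_physio & !physio_out, "physio_inpatient_form",
                      physio_date, "inpatient"),
      one_per_patient(physio_out, "physio_outpatient_contact",
                      physio_date, "outpatient"),
      one_per_patient(physio_out, "physio_external_referral",
                      physio_date + 7, "external")
    )

    # radiotherapy fractions: consecutive weekdays from rt_start
    if (any(has_rt)) {
      k <- as.integer(pathway$rt_fractions)
      grid <- tidyr::expand_grid(
        i = which(has_rt), off = 0:(ceiling(k * 7 / 5) + 3)
      )
      grid$event_date <- rt_start[grid$i] + grid$off
      grid <- grid[as.POSIXlt(grid$event_date)$wday %in% 1:5, ]
      grid <- dplyr::slice_head(dplyr::group_by(grid, .data$i), n = k)
      grid <- dplyr::ungroup(grid)
      events <- c(events, list(tibble::tibble(
        patient_id = id[grid$i], event_type = "rt_fraction",
        event_date = grid$event_date, setting = "outpatient",
        planned_flag = NA
      )))
    }

    # systemic administrations: first round, plus an optional second round
    syst_rows <- function(keep, start, cycles) {
      grid <- tidyr::expand_grid(i = which(keep), cyc = seq_len(cycles) - 1L)
      tibble::tibble(
        patient_id = id[grid$i], event_type = "systemic_admin",
        event_date = start[grid$i] + grid$cyc * pathway$systemic_cycle_gap_days,
        setting = "outpatient", planned_flag = NA
      )
    }
    if (any(has_syst)) {
      events <- c(events, list(
        syst_rows(has_syst, syst_start, pathway$systemic_cycles)
      ))
    }
    if (any(second_round)) {
      round1_end <- syst_start +
        (pathway$systemic_cycles - 1L) * pathway$systemic_cycle_gap_days
      start2 <- round1_end + pathway$second_round_gap_days +
        sample(0:30, n, replace = TRUE)
      events <- c(events, list(
        syst_rows(second_round, start2, pathway$second_round_cycles)
      ))
    }

    out <- dplyr::bind_rows(events)
    out$planned_flag <- as.logical(out$planned_flag)
    dplyr::arrange(out, .data$patient_id, .data$event_date, .data$event_type)
  })
}

#' @noRd
abstract_date_vars <- function() {
  c("date_referral", "date_initial_visit", "date_mdt_pretreat",
    "date_surgery", "rt_start", "rt_end", "syst_start", "syst_end",
    "date_dental", "date_physio")
}

#' @noRd
abstract_flag_vars <- function() {
  c("surgical_treatment", "neck_dissection", "rt_flag", "systemic_flag",
    "dental_flag", "physio_flag", "complication_flag", "unplanned_reop_flag")
}

#' Column names of the shared patient-abstract schema
#' @return Character vector of column names used by both the manually
#'   abstracted (MED) and automatically extracted (AED) datasets.
#' @export
abstract_schema <- function() {
  c("patient_id", "localization", "intent",
    abstract_date_vars(), abstract_flag_vars())
}

# Last systemic administration of the first treatment round: segments the
# sorted administration dates at gaps > gap_days and returns the end of the
# first segment.
#' @noRd
first_round_end <- function(dates, gap_days = 42) {
  d <- sort(dates)
  if (length(d) <= 1) return(d[1])
  brk <- which(diff(as.numeric(d)) > gap_days)
  if (length(brk)) d[brk[1]] else d[length(d)]
}

#' Derive a simulated manually-abstracted dataset (MED) from an event log
#'
#' Emulates registry abstraction by data-entry clerks reading the full chart:
#' the referral date is taken from the scanned referral letter, physiotherapy
#' is detected from contacts in any setting (inpatient form, outpatient,
#' external referral), the systemic end date is the end of the primary
#' treatment round, and conditional variables follow registry recording
#' practice (neck dissection, complications and reoperations are recorded
#' only for surgical patients; dental and physiotherapy contacts only when
#' they occurred).
#'
#' The discrepancy profile then injects abstraction/extraction error modes:
#' the one-day initial-visit shift, the 7-day-early pre-treatment MDT choice,
#' per-variable date jitter, categorical/boolean recording errors, and
#' per-variable missingness. With the identity profile the result is the
#' ground-truth abstract.
#'
#' @param log Event tibble from [generate_event_log()].
#' @param registry Tibble from [generate_cohort()].
#' @param profile A [discrepancy_profile()].
#' @param seed Integer seed for the injected errors.
#' @return A tibble in the [abstract_schema()] layout, one row per registry
#'   patient.
#' @export
derive_manual_abstract <- function(log, registry,
                                   profile = discrepancy_profile(),
                                   seed = 1L) {
  stopifnot(inherits(profile, "discrepancy_profile"))
  if (!all(log$patient_id %in% registry$patient_id)) {
    stop("event log contains patient_ids absent from the registry",
         call. = FALSE)
  }

  per_patient <- function(type) {
    ev <- log[log$event_type %in% type, c("patient_id", "event_date")]
    split(ev$event_date, factor(ev$patient_id, levels = registry$patient_id))
  }
  min_or_na <- function(lst) {
    as.Date(vapply(lst, function(d) {
      if (length(d)) as.numeric(min(d)) else NA_real_
    }, numeric(1)), origin = "1970-01-01")
  }

  letter <- min_or_na(per_patient("scanned_referral_letter"))
  consult <- min_or_na(per_patient("initial_consult"))
  surg <- min_or_na(per_patient("surgery"))
  rt_dates <- per_patient("rt_fraction")
  syst_dates <- per_patient("systemic_admin")
  mdt_dates <- per_patient("mdt_meeting")

  rt_s <- min_or_na(rt_dates)
  rt_e <- as.Date(vapply(rt_dates, function(d) {
    if (length(d)) as.numeric(max(d)) else NA_real_
  }, numeric(1)), origin = "1970-01-01")
  sy_s <- min_or_na(syst_dates)
  sy_e <- as.Date(vapply(syst_dates, function(d) {
    if (length(d)) as.numeric(first_round_end(d)) else NA_real_
  }, numeric(1)), origin = "1970-01-01")

  tx_start <- pmin(surg, rt_s, sy_s, na.rm = TRUE)
  mdt_pre <- as.Date(mapply(function(mdts, tx, cons) {
    if (!length(mdts)) return(NA_real_)
    if (!is.na(tx)) {
      pre <- mdts[mdts < tx]
      if (length(pre)) as.numeric(max(pre)) else NA_real_
    } else {
      post <- mdts[is.na(cons) | mdts >= cons]
      if (length(post)) as.numeric(min(post)) else NA_real_
    }
  }, mdt_dates, as.list(tx_start), as.list(consult)), origin = "1970-01-01")

  physio_all <- min_or_na(per_patient(
    c("physio_inpatient_form", "physio_outpatient_contact",
      "physio_external_referral")))
  dental <- min_or_na(per_patient("dental_consult"))
  nd <- lengths(per_patient("neck_dissection")) > 0
  compl <- lengths(per_patient("complication")) > 0
  unpl <- log[log$event_type == "reoperation" & !is.na(log$planned_flag) &
                !log$planned_flag, ]
  unpl_flag <- registry$patient_id %in% unpl$patient_id
  surgical <- !is.na(surg)

  med <- tibble::tibble(
    patient_id = registry$patient_id,
    localization = registry$localization,
    intent = registry$intent,
    date_referral = letter,
    date_initial_visit = consult,
    date_mdt_pretreat = mdt_pre,
    date_surgery = surg,
    rt_start = rt_s,
    rt_end = rt_e,
    syst_start = sy_s,
    syst_end = sy_e,
    date_dental = dental,
    date_physio = physio_all,
    surgical_treatment = surgical,
    neck_dissection = ifelse(surgical, nd, NA),
    rt_flag = !is.na(rt_s),
    systemic_flag = !is.na(sy_s),
    dental_flag = ifelse(!is.na(dental), TRUE, NA),
    physio_flag = ifelse(!is.na(physio_all), TRUE, NA),
    complication_flag = ifelse(surgical, compl, NA),
    unplanned_reop_flag = ifelse(surgical, unpl_flag, NA)
  )

  withr::with_seed(seed, {
    n <- nrow(med)
    shift <- stats::runif(n) < profile$p_initial_visit_shift
    med$date_initial_visit[shift] <- med$date_initial_visit[shift] - 1
    early <- stats::runif(n) < profile$p_extra_mdt
    med$date_mdt_pretreat[early] <- med$date_mdt_pretreat[early] - 7

    for (var in names(profile$date_jitter)) {
      hit <- stats::runif(n) < profile$date_jitter[[var]]
      jit <- sample(c(-3:-1, 1:3), n, replace = TRUE)
      med[[var]][hit] <- med[[var]][hit] + jit[hit]
    }
    for (var in names(profile$flip_rates)) {
      hit <- stats::runif(n) < profile$flip_rates[[var]]
      if (var == "localization") {
        med$localization[hit] <- vapply(med$localization[hit], function(l) {
          sample(setdiff(localization_levels(), l), 1)
        }, character(1))
      } else if (var == "intent") {
        med$intent[hit] <- ifelse(med$intent[hit] == "curative",
                                  "palliative", "curative")
      } else {
        med[[var]][hit] <- !med[[var]][hit]
      }
    }
    for (var in names(profile$missingness)) {
      hit <- stats::runif(n) < profile$missingness[[var]]
      med[[var]][hit] <- NA
    }
    med
  })
}
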