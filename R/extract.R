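#' Extraction rules for the automated dashboard engine
#'
#' @param icd10_inclusion Character vector of ICD-10 code prefixes a patient
#'   must match to be extracted; defaults to the head-and-neck set.
#' @param systemic_round_cutoff_weeks Gap (weeks) between consecutive
#'   systemic administrations beyond which a later administration is
#'   considered part of another treatment round and excluded from the end
#'   date. Must be >= 1; `Inf` disables the cutoff and reproduces naive
#'   last-administration logic.
#' @param mdt_selection Which multidisciplinary team meeting counts as the
#'   pre-treatment MDT: `"last_before_treatment"` (default: the engine's
#'   rule) or `"first_after_diagnosis"` (the abstractor's reading).
#' @param same_day_strict Logical; if `TRUE` (default) "prior to treatment"
#'   comparisons are strict, so a same-day MDT does not qualify.
#' @return A list of class `extraction_rules`.
#' @export
extraction_rules <- function(icd10_inclusion = icd10_inclusion_set(),
                             systemic_round_cutoff_weeks = 6,
                             mdt_selection = c("last_before_treatment",
                                               "first_after_diagnosis"),
                             same_day_strict = TRUE) {
  if (!is.numeric(systemic_round_cutoff_weeks) ||
      systemic_round_cutoff_weeks < 1) {
    stop("`systemic_round_cutoff_weeks` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      icd10_inclusion = icd10_inclusion,
      systemic_round_cutoff_weeks = systemic_round_cutoff_weeks,
      mdt_selection = match.arg(mdt_selection),
      same_day_strict = isTRUE(same_day_strict)
    ),
    class = "extraction_rules"
  )
}

#' Referral date as seen by the extraction engine
#'
#' The actual referral date lives only in the scanned referral letter (a PDF),
#' which structured extraction cannot read; the engine's proxy is the
#' administrative assistant's first action, the order scheduling the
#' appointment.
#'
#' @param events Event tibble for a single patient.
#' @return The earliest `scheduling_order` date, or `NA` if the patient has
#'   none. `scanned_referral_letter` events are never consulted.
#' @export
select_referral_date <- function(events) {
  d <- events$event_date[events$event_type == "scheduling_order"]
  if (length(d)) min(d) else as.Date(NA)
}

#' Treatment start: earliest treatment event with its modality
#'
#' The first radiotherapy fraction signals the onset of the therapeutic phase
#' provided no surgical procedure precedes it; likewise for systemic therapy.
#' Same-day ties resolve surgery > radiotherapy > systemic.
#'
#' @param events Event tibble for a single patient.
#' @return A list with `date` and `modality` (`"surgery"`, `"rt"`,
#'   `"systemic"`), or `NULL` when the patient has no treatment event.
#' @export
determine_treatment_start <- function(events) {
  firsts <- c(
    surgery = min_date(events, "surgery"),
    rt = min_date(events, "rt_fraction"),
    systemic = min_date(events, "systemic_admin")
  )
  if (all(is.na(firsts))) return(NULL)
  # which.min on the priority-ordered vector implements the tie-break
  i <- which.min(firsts)
  list(date = as.Date(firsts[[i]], origin = "1970-01-01"),
       modality = names(firsts)[i])
}

#' @noRd
min_date <- function(events, type) {
  d <- events$event_date[events$event_type == type]
  if (length(d)) as.numeric(min(d)) else NA_real_
}

#' Select the pre-treatment multidisciplinary team meeting
#'
#' Under the engine's default rule the pre-treatment MDT is the last MDT
#' strictly before (or on, when `same_day_strict = FALSE`) the treatment
#' start — when a patient is re-discussed in an additional weekly MDT just
#' before treatment, that later MDT is the one selected. The alternative
#' `"first_after_diagnosis"` rule returns the earliest MDT on or after the
#' initial consultation.
#'
#' @param events Event tibble for a single patient.
#' @param treatment_start Date the first treatment event occurred (non-NA).
#' @param rules An [extraction_rules()].
#' @return The selected MDT date, or `NA` when no MDT qualifies.
#' @export
select_pretreatment_mdt <- function(events, treatment_start,
                                    rules = extraction_rules()) {
  stopifnot(!is.na(treatment_start))
  mdts <- events$event_date[events$event_type == "mdt_meeting"]
  if (!length(mdts)) return(as.Date(NA))
  if (rules$mdt_selection == "last_before_treatment") {
    ok <- if (rules$same_day_strict) mdts < treatment_start
          else mdts <= treatment_start
    if (any(ok)) max(mdts[ok]) else as.Date(NA)
  } else {
    consult <- min_date(events, "initial_consult")
    ok <- if (is.na(consult)) rep(TRUE, length(mdts))
          else as.numeric(mdts) >= consult
    if (any(ok)) min(mdts[ok]) else as.Date(NA)
  }
}

#' Radiotherapy window
#'
#' @param events Event tibble for a single patient.
#' @return A list with `start` and `end` (min and max `rt_fraction` dates),
#'   or `NULL` when the patient has no fractions.
#' @export
derive_rt_window <- function(events) {
  d <- events$event_date[events$event_type == "rt_fraction"]
  if (!length(d)) return(NULL)
  list(start = min(d), end = max(d))
}

#' Systemic-therapy window with a between-round cutoff
#'
#' The start is the first systemic administration. The end is the last
#' administration of the maximal run beginning at the start in which
#' consecutive administrations are at most `systemic_round_cutoff_weeks`
#' apart; administrations beyond a longer gap belong to a later round (e.g.
#' re-treatment for recurrence) and are excluded. With the cutoff disabled
#' (`Inf`) the end is simply the last administration, which lets a second
#' round contaminate the end date.
#'
#' @param events Event tibble for a single patient.
#' @param rules An [extraction_rules()].
#' @return A list with `start` and `end`, or `NULL` with no administrations.
#' @export
derive_systemic_window <- function(events, rules = extraction_rules()) {
  d <- sort(events$event_date[events$event_type == "systemic_admin"])
  if (!length(d)) return(NULL)
  cutoff_days <- rules$systemic_round_cutoff_weeks * 7
  gaps <- diff(as.numeric(d))
  brk <- which(gaps > cutoff_days)
  end <- if (length(brk)) d[brk[1]] else d[length(d)]
  list(start = d[1], end = end)
}

#' Physiotherapy detection as the engine sees it
#'
#' Detection relies on the physiotherapist's structured form, which exists
#' only for inpatient care: outpatient contacts and external referrals leave
#' no extractable trace, so they are deliberately ignored here (this is the
#' input-side capture gap, reproduced on purpose).
#'
#' @param events Event tibble for a single patient.
#' @return A list with `flag` (any inpatient form filed) and `date` (earliest
#'   such form, `NA` when `flag` is `FALSE`).
#' @export
detect_physiotherapy <- function(events) {
  d <- events$event_date[events$event_type == "physio_inpatient_form"]
  list(flag = length(d) > 0, date = if (length(d)) min(d) else as.Date(NA))
}

#' Extract a single patient abstract from the event log
#'
#' Composes the field-level extraction rules into one row of the shared
#' abstract schema. Localization is derived from the registry's ICD-10 code
#' via the fixed mapping table; treatment intent is read from the structured
#' registry field.
#'
#' @param events Event tibble for a single patient (may be empty).
#' @param registry_row One-row registry tibble for the same patient.
#' @param rules An [extraction_rules()].
#' @return A one-row tibble in the [abstract_schema()] layout.
#' @export
extract_abstract <- function(events, registry_row,
                             rules = extraction_rules()) {
  if (nrow(registry_row) != 1) {
    stop("patient not found in registry (or duplicated)", call. = FALSE)
  }
  tx <- determine_treatment_start(events)
  rt <- derive_rt_window(events)
  sy <- derive_systemic_window(events, rules)
  ph <- detect_physiotherapy(events)
  surg <- events$event_date[events$event_type == "surgery"]
  dent <- events$event_date[events$event_type == "dental_consult"]
  unpl <- any(events$event_type == "reoperation" &
                !is.na(events$planned_flag) & !events$planned_flag)

  tibble::tibble(
    patient_id = registry_row$patient_id,
    localization = localization_from_icd10(registry_row$icd10_code),
    intent = registry_row$intent,
    date_referral = select_referral_date(events),
    date_initial_visit = {
      d <- events$event_date[events$event_type == "initial_consult"]
      if (length(d)) min(d) else as.Date(NA)
    },
    date_mdt_pretreat = if (is.null(tx)) as.Date(NA) else
      select_pretreatment_mdt(events, tx$date, rules),
    date_surgery = if (length(surg)) min(surg) else as.Date(NA),
    rt_start = if (is.null(rt)) as.Date(NA) else rt$start,
    rt_end = if (is.null(rt)) as.Date(NA) else rt$end,
    syst_start = if (is.null(sy)) as.Date(NA) else sy$start,
    syst_end = if (is.null(sy)) as.Date(NA) else sy$end,
    date_dental = if (length(dent)) min(dent) else as.Date(NA),
    date_physio = ph$date,
    surgical_treatment = length(surg) > 0,
    neck_dissection = any(events$event_type == "neck_dissection"),
    rt_flag = !is.null(rt),
    systemic_flag = !is.null(sy),
    dental_flag = length(dent) > 0,
    physio_flag = ph$flag,
    complication_flag = any(events$event_type == "complication"),
    unplanned_reop_flag = unpl
  )
}

#' Extract the automated dataset (AED) for a whole event log
#'
#' Applies ICD-10 inclusion (code-prefix match against
#' `rules$icd10_inclusion`) and runs [extract_abstract()] for every included
#' registry patient. Vectorised internally; field-level semantics are
#' identical to the per-patient operations.
#'
#' @param log Event tibble.
#' @param registry Registry tibble; every log patient must appear in it.
#' @param rules An [extraction_rules()].
#' @return A tibble in the [abstract_schema()] layout, one row per included
#'   patient.
#' @export
extract_dataset <- function(log, registry, rules = extraction_rules()) {
  if (!all(log$patient_id %in% registry$patient_id)) {
    stop("event log contains patient_ids absent from the registry",
         call. = FALSE)
  }
  inc <- registry[substr(registry$icd10_code, 1, 3) %in%
                    rules$icd10_inclusion, ]
  ids <- inc$patient_id
  f <- factor(log$patient_id, levels = ids)
  keep <- !is.na(f)
  split_events <- split(log[keep, ], f[keep])
  out <- dplyr::bind_rows(lapply(ids, function(pid) {
    extract_abstract(split_events[[pid]], inc[inc$patient_id == pid, ], rules)
  }))
  out
}
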