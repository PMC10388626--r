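# Small in-code fixture builders shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

day0 <- as.Date("2020-01-06")  # a Monday

# Build an event tibble for one patient from type = day-offset pairs.
mk_events <- function(..., id = "P1", planned = NULL) {
  spec <- list(...)
  if (!length(spec)) {
    return(tibble::tibble(patient_id = character(), event_type = character(),
                          event_date = as.Date(character()),
                          setting = character(), planned_flag = logical()))
  }
  types <- names(spec)
  out <- tibble::tibble(
    patient_id = id,
    event_type = rep(types, lengths(spec)),
    event_date = day0 + unlist(spec, use.names = FALSE),
    setting = "outpatient",
    planned_flag = NA
  )
  if (!is.null(planned)) out$planned_flag <- planned
  out
}

# One-row registry.
mk_registry <- function(id = "P1", icd10 = "C32.9", histology = "scc",
                        tumor_order = "first_primary", intent = "curative",
                        year = 2020L) {
  tibble::tibble(
    patient_id = id, icd10_code = icd10,
    localization = carepathqi::localization_from_icd10(icd10),
    histology = histology, tumor_order = tumor_order, intent = intent,
    initial_consult_year = year
  )
}

# Random one-patient event set (<= max_events events) for oracle checks.
random_events <- function(max_events = 20) {
  n <- sample.int(max_events, 1)
  tibble::tibble(
    patient_id = "P1",
    event_type = sample(carepathqi::event_types(), n, replace = TRUE),
    event_date = day0 + sample.int(400, n, replace = TRUE),
    setting = "outpatient",
    planned_flag = NA
  )
}

# Minimal abstract tibble; unspecified schema columns are NA.
mk_abstract <- function(n, ...) {
  cols <- list(...)
  out <- tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)))
  for (v in setdiff(carepathqi::abstract_schema(), "patient_id")) {
    out[[v]] <- if (v %in% names(cols)) cols[[v]]
    else if (grepl("^date|start|end$", v)) as.Date(rep(NA, n))
    else if (v %in% c("localization", "intent")) NA_character_
    else NA
  }
  out
}

# A linked_dataset whose agreement cells are exactly (n_agree / n_compared)
# for one variable, with optional extra one-sided-missing rows.
mk_linked_cell <- function(variable, n_agree, n_compared,
                           n_med_only_present = 0, n_aed_only_present = 0) {
  n <- n_compared + n_med_only_present + n_aed_only_present
  ids <- sprintf("P%04d", seq_len(n))
  m <- a <- rep(NA_character_, n)
  m[seq_len(n_compared)] <- sprintf("v%d", seq_len(n_compared))
  a[seq_len(n_compared)] <- ifelse(seq_len(n_compared) <= n_agree,
                                   m[seq_len(n_compared)], "other")
  if (n_med_only_present > 0) {
    m[n_compared + seq_len(n_med_only_present)] <- "m"
  }
  if (n_aed_only_present > 0) {
    a[n_compared + n_med_only_present + seq_len(n_aed_only_present)] <- "a"
  }
  med <- tibble::tibble(patient_id = ids)
  aed <- tibble::tibble(patient_id = ids)
  med[[variable]] <- m
  aed[[variable]] <- a
  carepathqi::link_datasets(med, aed)
}

# An indicator result row from printed numerator/denominator counts, using
# the package's percentage arithmetic.
pct_row <- function(id, num, den) {
  tibble::tibble(
    id = id, kind = "proportion",
    numerator = as.integer(num), denominator = as.integer(den),
    pct = carepathqi::round_half_away(100 * num / den, 1),
    median_days = NA_real_
  )
}

median_row <- function(id, days) {
  tibble::tibble(
    id = id, kind = "median_days", numerator = NA_integer_,
    denominator = 1L, pct = NA_real_, median_days = days
  )
}
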