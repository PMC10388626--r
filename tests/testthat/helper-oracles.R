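# Independent brute-force reference implementations used to cross-check the
# package's vectorised/rule-based code. These deliberately use plain loops
# and direct scans, not the package's own helpers.

oracle_referral <- function(events) {
  best <- as.Date(NA)
  for (i in seq_len(nrow(events))) {
    if (events$event_type[i] == "scheduling_order") {
      d <- events$event_date[i]
      if (is.na(best) || d < best) best <- d
    }
  }
  best
}

oracle_tx_start <- function(events) {
  prio <- c(surgery = 1, rt_fraction = 2, systemic_admin = 3)
  best_date <- as.Date(NA)
  best_prio <- Inf
  for (i in seq_len(nrow(events))) {
    ty <- events$event_type[i]
    if (!ty %in% names(prio)) next
    d <- events$event_date[i]
    if (is.na(best_date) || d < best_date ||
        (d == best_date && prio[[ty]] < best_prio)) {
      best_date <- d
      best_prio <- prio[[ty]]
    }
  }
  if (is.na(best_date)) NULL else
    list(date = best_date,
         modality = c("surgery", "rt", "systemic")[best_prio])
}

oracle_mdt_last_before <- function(events, tx_start, strict = TRUE) {
  best <- as.Date(NA)
  for (i in seq_len(nrow(events))) {
    if (events$event_type[i] != "mdt_meeting") next
    d <- events$event_date[i]
    ok <- if (strict) d < tx_start else d <= tx_start
    if (ok && (is.na(best) || d > best)) best <- d
  }
  best
}

oracle_rt_window <- function(events) {
  d <- c()
  for (i in seq_len(nrow(events))) {
    if (events$event_type[i] == "rt_fraction") d <- c(d, events$event_date[i])
  }
  if (!length(d)) return(NULL)
  d <- as.Date(d, origin = "1970-01-01")
  list(start = min(d), end = max(d))
}

# O(n^2)-style segmentation: walk the sorted administrations and stop at the
# first gap exceeding the cutoff.
oracle_syst_window <- function(events, cutoff_weeks) {
  d <- sort(events$event_date[events$event_type == "systemic_admin"])
  if (!length(d)) return(NULL)
  end <- d[1]
  for (i in seq_along(d)[-1]) {
    if (as.numeric(d[i] - d[i - 1]) <= cutoff_weeks * 7) end <- d[i]
    else break
  }
  list(start = d[1], end = end)
}

oracle_physio <- function(events) {
  d <- c()
  for (i in seq_len(nrow(events))) {
    if (events$event_type[i] == "physio_inpatient_form") {
      d <- c(d, events$event_date[i])
    }
  }
  if (!length(d)) list(flag = FALSE, date = as.Date(NA))
  else list(flag = TRUE, date = as.Date(min(d), origin = "1970-01-01"))
}

# Row-by-row agreement loop over a linked pairs tibble.
oracle_agreement <- function(pairs, variable) {
  m <- pairs[[paste0(variable, "_med")]]
  a <- pairs[[paste0(variable, "_aed")]]
  n_compared <- 0L
  n_agree <- 0L
  for (i in seq_along(m)) {
    if (!is.na(m[i]) && !is.na(a[i])) {
      n_compared <- n_compared + 1L
      if (m[i] == a[i]) n_agree <- n_agree + 1L
    }
  }
  list(n_compared = n_compared, n_agree = n_agree)
}

# Direct evaluation of the kappa formula, written out long-hand.
oracle_kappa <- function(x) {
  n <- sum(x)
  po <- sum(diag(x)) / n
  pe <- 0
  for (i in seq_len(nrow(x))) pe <- pe + sum(x[i, ]) * sum(x[, i]) / n^2
  (po - pe) / (1 - pe)
}

# Independent re-implementation of the study criteria as one predicate.
oracle_included <- function(reg_row, visit_year, year) {
  visit_year == year &&
    reg_row$localization %in% carepathqi::localization_levels() &&
    reg_row$intent == "curative" &&
    reg_row$histology != "cis" &&
    reg_row$tumor_order == "first_primary" &&
    !reg_row$histology %in% c("melanoma", "thyroid", "skin", "sarcoma",
                              "neuroendocrine", "hematologic")
}

# Row-loop indicator counting for the windowed date indicators.
oracle_window_indicator <- function(df, from, to, window) {
  num <- 0L
  den <- 0L
  for (i in seq_len(nrow(df))) {
    a <- df[[from]][i]
    b <- df[[to]][i]
    if (!is.na(a) && !is.na(b)) {
      den <- den + 1L
      if (as.numeric(b - a) <= window) num <- num + 1L
    }
  }
  list(numerator = num, denominator = den)
}
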