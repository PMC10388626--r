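#' @noRd
tx_start_col <- function(df) {
  pmin(df$date_surgery, df$rt_start, df$syst_start, na.rm = TRUE)
}

#' @noRd
adjuvant_start_col <- function(df) {
  rt <- df$rt_start
  sy <- df$syst_start
  rt[!is.na(rt) & !is.na(df$date_surgery) & rt <= df$date_surgery] <- NA
  sy[!is.na(sy) & !is.na(df$date_surgery) & sy <= df$date_surgery] <- NA
  pmin(rt, sy, na.rm = TRUE)
}

#' @noRd
within_window <- function(days, window, boundary) {
  if (boundary == "inclusive") days <= window else days < window
}

# Per-indicator denominator / numerator predicates, each a function of the
# abstract tibble returning a logical vector. The numerator is always
# evaluated on top of the denominator, so numerator <= denominator holds by
# construction. "Prior to" comparisons are strict; windows honour the
# definition's boundary (inclusive by default, so "within 30 days" means
# <= 30).
#' @noRd
indicator_predicates <- function(id) {
  switch(
    id,
    mdt_before_treatment = list(
      den = function(df, w, b) {
        df$intent %in% "curative" & !is.na(tx_start_col(df))
      },
      num = function(df, w, b) {
        !is.na(df$date_mdt_pretreat) &
          df$date_mdt_pretreat < tx_start_col(df)
      }
    ),
    treatment_within_30d = list(
      den = function(df, w, b) {
        !is.na(df$date_initial_visit) & !is.na(tx_start_col(df))
      },
      num = function(df, w, b) {
        within_window(as.numeric(tx_start_col(df) - df$date_initial_visit),
                      w, b)
      }
    ),
    adjuvant_within_6w = list(
      den = function(df, w, b) {
        df$surgical_treatment %in% TRUE & !is.na(df$date_surgery) &
          !is.na(adjuvant_start_col(df))
      },
      num = function(df, w, b) {
        within_window(as.numeric(adjuvant_start_col(df) - df$date_surgery),
                      w, b)
      }
    ),
    initial_visit_within_7d = list(
      den = function(df, w, b) {
        !is.na(df$date_referral) & !is.na(df$date_initial_visit)
      },
      num = function(df, w, b) {
        within_window(as.numeric(df$date_initial_visit - df$date_referral),
                      w, b)
      }
    ),
    dental_before_rt = list(
      den = function(df, w, b) df$intent %in% "curative" & !is.na(df$rt_start),
      # a documented consult with an unrecorded date still counts; the date,
      # when present, must verify the ordering
      num = function(df, w, b) {
        df$dental_flag %in% TRUE &
          (is.na(df$date_dental) | df$date_dental < df$rt_start)
      }
    ),
    physio_after_neck_dissection = list(
      den = function(df, w, b) df$neck_dissection %in% TRUE,
      num = function(df, w, b) {
        df$physio_flag %in% TRUE &
          (is.na(df$date_physio) | is.na(df$date_surgery) |
             df$date_physio >= df$date_surgery)
      }
    ),
    unplanned_reoperation = list(
      den = function(df, w, b) df$surgical_treatment %in% TRUE,
      num = function(df, w, b) df$unplanned_reop_flag %in% TRUE
    ),
    median_consult_to_mdt = list(
      days = function(df) {
        as.numeric(df$date_mdt_pretreat - df$date_initial_visit)
      }
    ),
    median_referral_to_mdt = list(
      days = function(df) as.numeric(df$date_mdt_pretreat - df$date_referral)
    ),
    median_referral_to_consult = list(
      days = function(df) {
        as.numeric(df$date_initial_visit - df$date_referral)
      }
    ),
    stop(sprintf("unknown indicator id `%s`", id), call. = FALSE)
  )
}

#' Construct a quality-indicator definition
#'
#' @param id Indicator id (one of the builtin ids).
#' @param description Human-readable description.
#' @param kind `"proportion"` or `"median_days"`.
#' @param window_days Window length in days for windowed indicators, else
#'   `NA`.
#' @param boundary `"inclusive"` (default: "within 30 days" means <= 30) or
#'   `"exclusive"`.
#' @return An object of class `indicator_definition`.
#' @export
indicator_definition <- function(id, description,
                                 kind = c("proportion", "median_days"),
                                 window_days = NA_real_,
                                 boundary = c("inclusive", "exclusive")) {
  kind <- match.arg(kind)
  boundary <- match.arg(boundary)
  indicator_predicates(id)  # validates the id
  structure(
    list(id = id, description = description, kind = kind,
         window_days = window_days, boundary = boundary),
    class = "indicator_definition"
  )
}

#' The ten builtin head-and-neck audit indicators
#'
#' Seven proportion indicators — multidisciplinary team meeting prior to
#' curative treatment; treatment start within 30 days of the initial visit;
#' adjuvant therapy within 6 weeks (42 days) of surgery; initial visit
#' within 7 days of referral; dental team consultation before radiotherapy;
#' physiotherapist contact after neck dissection; unplanned reoperation
#' after surgery — and three median waiting times: initial consultation to
#' MDT, referral to MDT, and referral to initial consultation.
#'
#' @return A named list of [indicator_definition()] objects, length 10.
#' @export
builtin_definitions <- function() {
  defs <- list(
    indicator_definition(
      "mdt_before_treatment",
      "Patients discussed in a MDT prior to curative treatment"),
    indicator_definition(
      "treatment_within_30d",
      "Treatment started within 30 days after the initial appointment",
      window_days = 30),
    indicator_definition(
      "adjuvant_within_6w",
      "Adjuvant therapy started within 6 weeks after surgical treatment",
      window_days = 42),
    indicator_definition(
      "initial_visit_within_7d",
      "Initial appointment within 7 days after referral",
      window_days = 7),
    indicator_definition(
      "dental_before_rt",
      "Curative patients seen by a dental team prior to radiotherapy"),
    indicator_definition(
      "physio_after_neck_dissection",
      "Patients seen by a physiotherapist after a neck dissection"),
    indicator_definition(
      "unplanned_reoperation",
      "Unplanned reoperation after surgical treatment"),
    indicator_definition(
      "median_consult_to_mdt",
      "Median time from initial consultation until MDT",
      kind = "median_days"),
    indicator_definition(
      "median_referral_to_mdt",
      "Median time from referral until MDT",
      kind = "median_days"),
    indicator_definition(
      "median_referral_to_consult",
      "Median time from referral until initial consultation",
      kind = "median_days")
  )
  stats::setNames(defs, vapply(defs, `[[`, character(1), "id"))
}

#' Compute one quality indicator on a patient-abstract dataset
#'
#' For proportion indicators, the denominator counts rows where the fields
#' the denominator predicate requires are non-missing and the predicate
#' holds; the numerator counts the subset also meeting the numerator
#' predicate. For median indicators, the median is taken over rows with both
#' dates present. An empty denominator yields a `NA` percentage.
#'
#' @param abstracts Tibble in the [abstract_schema()] layout (usually after
#'   [apply_criteria()]).
#' @param definition An [indicator_definition()].
#' @return A one-row tibble: `id`, `kind`, `numerator`, `denominator`,
#'   `pct` (half-away-from-zero, 1 decimal) and `median_days`.
#' @export
compute_indicator <- function(abstracts, definition) {
  stopifnot(inherits(definition, "indicator_definition"))
  pred <- indicator_predicates(definition$id)
  if (definition$kind == "proportion") {
    den <- pred$den(abstracts, definition$window_days, definition$boundary)
    num <- den & pred$num(abstracts, definition$window_days,
                          definition$boundary)
    den[is.na(den)] <- FALSE
    num[is.na(num)] <- FALSE
    n_den <- sum(den)
    n_num <- sum(num)
    tibble::tibble(
      id = definition$id, kind = "proportion",
      numerator = n_num, denominator = n_den,
      pct = if (n_den > 0) round_half_away(100 * n_num / n_den, 1)
            else NA_real_,
      median_days = NA_real_
    )
  } else {
    days <- pred$days(abstracts)
    days <- days[!is.na(days)]
    tibble::tibble(
      id = definition$id, kind = "median_days",
      numerator = NA_integer_, denominator = length(days),
      pct = NA_real_,
      median_days = if (length(days)) stats::median(days) else NA_real_
    )
  }
}

#' Compute a set of indicators
#'
#' @param abstracts Tibble in the [abstract_schema()] layout.
#' @param definitions List of [indicator_definition()]s; defaults to the ten
#'   builtin ones.
#' @return A tibble with one [compute_indicator()] row per definition.
#' @export
compute_indicators <- function(abstracts,
                               definitions = builtin_definitions()) {
  dplyr::bind_rows(lapply(definitions, function(d) {
    compute_indicator(abstracts, d)
  }))
}

#' Compare a manual and an automatic indicator result
#'
#' The difference is automatic minus manual, computed on the rounded
#' one-decimal percentages (or in days for median indicators): positive
#' means the automatic result is higher (or later).
#'
#' @param manual,automatic One-row results from [compute_indicator()] for
#'   the same indicator id.
#' @return A one-row tibble: `id`, `kind`, manual and automatic
#'   numerator/denominator/percentage (or medians) and `difference`.
#' @export
compare_results <- function(manual, automatic) {
  if (!identical(manual$id, automatic$id)) {
    stop("indicator ids do not match", call. = FALSE)
  }
  diff <- if (manual$kind == "proportion") {
    automatic$pct - manual$pct
  } else {
    automatic$median_days - manual$median_days
  }
  tibble::tibble(
    id = manual$id, kind = manual$kind,
    manual_numerator = manual$numerator,
    manual_denominator = manual$denominator,
    manual_value = if (manual$kind == "proportion") manual$pct
                   else manual$median_days,
    automatic_numerator = automatic$numerator,
    automatic_denominator = automatic$denominator,
    automatic_value = if (automatic$kind == "proportion") automatic$pct
                      else automatic$median_days,
    difference = diff
  )
}

#' Manual-versus-automatic comparison table
#'
#' @param manual_results,automatic_results Tibbles from
#'   [compute_indicators()] on the manual and automatic datasets.
#' @return A tibble with one [compare_results()] row per shared indicator.
#' @export
comparison_table <- function(manual_results, automatic_results) {
  ids <- intersect(manual_results$id, automatic_results$id)
  dplyr::bind_rows(lapply(ids, function(i) {
    compare_results(manual_results[manual_results$id == i, ],
                    automatic_results[automatic_results$id == i, ])
  }))
}

#' Serialize indicator definitions to YAML
#'
#' @param definitions List of [indicator_definition()]s.
#' @param path Optional file path; when `NULL` the YAML string is returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
definitions_to_yaml <- function(definitions, path = NULL) {
  plain <- lapply(definitions, unclass)
  txt <- yaml::as.yaml(plain)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read indicator definitions from YAML
#'
#' @param path File path or a YAML string produced by
#'   [definitions_to_yaml()].
#' @return A named list of [indicator_definition()]s.
#' @export
definitions_from_yaml <- function(path) {
  plain <- if (file.exists(path)) yaml::read_yaml(path)
           else yaml::yaml.load(path)
  lapply(plain, function(d) {
    indicator_definition(
      id = d$id, description = d$description, kind = d$kind,
      window_days = d$window_days %||% NA_real_,
      boundary = d$boundary %||% "inclusive"
    )
  })
}
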