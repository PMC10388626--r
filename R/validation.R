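#' Link the manually and automatically extracted datasets
#'
#' Exact linkage on the unique patient identifier, with a three-group
#' linkage indicator: `linked` (present in both), `med_only` (only in the
#' manual dataset) and `aed_only` (only in the automatic dataset).
#'
#' @param med,aed Tibbles in the [abstract_schema()] layout with unique
#'   `patient_id` within each source.
#' @return An object of class `linked_dataset`: a list with `pairs` (inner
#'   join, MED columns suffixed `_med`, AED columns `_aed`), `indicator`
#'   (tibble of `patient_id`, `group`), and counts `n_med`, `n_aed`,
#'   `n_linked`.
#' @export
link_datasets <- function(med, aed) {
  if (anyDuplicated(med$patient_id)) {
    stop("duplicate patient_id in MED", call. = FALSE)
  }
  if (anyDuplicated(aed$patient_id)) {
    stop("duplicate patient_id in AED", call. = FALSE)
  }
  pairs <- dplyr::inner_join(med, aed, by = "patient_id",
                             suffix = c("_med", "_aed"))
  indicator <- tibble::tibble(
    patient_id = union(med$patient_id, aed$patient_id)
  )
  indicator$group <- dplyr::case_when(
    indicator$patient_id %in% med$patient_id &
      indicator$patient_id %in% aed$patient_id ~ "linked",
    indicator$patient_id %in% med$patient_id ~ "med_only",
    TRUE ~ "aed_only"
  )
  structure(
    list(pairs = pairs, indicator = indicator,
         n_med = nrow(med), n_aed = nrow(aed), n_linked = nrow(pairs)),
    class = "linked_dataset"
  )
}

#' @export
print.linked_dataset <- function(x, ...) {
  cat(sprintf(
    "<linked_dataset> %d linked | %d MED-only | %d AED-only (coverage %.2f%%)\n",
    x$n_linked, x$n_med - x$n_linked, x$n_aed - x$n_linked, coverage(x)))
  invisible(x)
}

#' Coverage of the automatic dataset
#'
#' Linked records as a percentage of the manual (reference) records, rounded
#' half-away-from-zero to two decimals.
#'
#' @param linked A [link_datasets()] result.
#' @return Numeric scalar percentage.
#' @export
coverage <- function(linked) {
  stopifnot(inherits(linked, "linked_dataset"))
  if (linked$n_med == 0) {
    stop("coverage is undefined: the MED is empty", call. = FALSE)
  }
  round_half_away(100 * linked$n_linked / linked$n_med, 2)
}

#' Per-variable agreement between the linked datasets
#'
#' Agreement is exact equality among linked pairs where the variable is
#' non-missing in both sources: same calendar day for dates, same code for
#' categories, same value for booleans. The percentage is computed over the
#' compared pairs only and rounded half-away-from-zero to one decimal, the
#' standardized calculation applicable to nominal, categorical and numeric
#' items alike.
#'
#' @param linked A [link_datasets()] result.
#' @param variable Variable name from the shared abstract schema.
#' @param comparator Optional function of (med_values, aed_values) returning
#'   a logical vector; defaults to exact equality.
#' @return A one-row tibble: `variable`, `n_manual_present`,
#'   `n_auto_present`, `n_compared`, `n_agree`, `pct_agreement`.
#' @export
compute_agreement <- function(linked, variable, comparator = NULL) {
  stopifnot(inherits(linked, "linked_dataset"))
  vm <- paste0(variable, "_med")
  va <- paste0(variable, "_aed")
  if (!vm %in% names(linked$pairs) || !va %in% names(linked$pairs)) {
    stop(sprintf("variable `%s` not present in both schemas", variable),
         call. = FALSE)
  }
  m <- linked$pairs[[vm]]
  a <- linked$pairs[[va]]
  both <- !is.na(m) & !is.na(a)
  agree <- if (is.null(comparator)) m[both] == a[both] else
    comparator(m[both], a[both])
  n_compared <- sum(both)
  n_agree <- sum(agree)
  tibble::tibble(
    variable = variable,
    n_manual_present = sum(!is.na(m)),
    n_auto_present = sum(!is.na(a)),
    n_compared = n_compared,
    n_agree = n_agree,
    pct_agreement = if (n_compared > 0) {
      round_half_away(100 * n_agree / n_compared, 1)
    } else {
      NA_real_
    }
  )
}

#' Agreement table over many variables
#'
#' @param linked A [link_datasets()] result.
#' @param variables Character vector of variable names; defaults to every
#'   shared abstract variable except the identifier.
#' @return A tibble with one [compute_agreement()] row per variable.
#' @export
agreement_table <- function(linked,
                            variables = setdiff(abstract_schema(),
                                                "patient_id")) {
  dplyr::bind_rows(lapply(variables, function(v) {
    compute_agreement(linked, v)
  }))
}

#' Day differences between disagreeing manual and automatic dates
#'
#' For linked pairs where a date variable is present in both sources but the
#' dates differ, the difference manual minus automatic in whole days. A
#' negative number means the manually extracted date is earlier than the
#' automatically extracted one. Agreeing pairs (difference zero) are not
#' part of the distribution.
#'
#' @param linked A [link_datasets()] result.
#' @param variable A date variable from the shared schema.
#' @return A tibble of class `date_diff_distribution` with columns
#'   `patient_id` and `diff_days`.
#' @export
date_diff_distribution <- function(linked, variable) {
  stopifnot(inherits(linked, "linked_dataset"))
  if (!variable %in% abstract_date_vars()) {
    stop(sprintf("`%s` is not a date variable", variable), call. = FALSE)
  }
  m <- linked$pairs[[paste0(variable, "_med")]]
  a <- linked$pairs[[paste0(variable, "_aed")]]
  both <- !is.na(m) & !is.na(a)
  d <- as.integer(m[both] - a[both])
  keep <- d != 0
  out <- tibble::tibble(
    patient_id = linked$pairs$patient_id[both][keep],
    diff_days = d[keep]
  )
  attr(out, "variable") <- variable
  class(out) <- c("date_diff_distribution", class(out))
  out
}

#' Cross-tabulate a categorical variable across the linked sources
#'
#' @param linked A [link_datasets()] result.
#' @param variable Categorical variable name.
#' @param levels Optional level set for both margins.
#' @return A square contingency `table` (manual rows, automatic columns) over
#'   pairs with the variable present in both sources.
#' @export
linked_crosstab <- function(linked, variable, levels = NULL) {
  m <- linked$pairs[[paste0(variable, "_med")]]
  a <- linked$pairs[[paste0(variable, "_aed")]]
  both <- !is.na(m) & !is.na(a)
  if (is.null(levels)) levels <- sort(union(m[both], a[both]))
  table(manual = factor(m[both], levels = levels),
        automatic = factor(a[both], levels = levels))
}

#' Cohen's kappa with a large-sample test of kappa = 0
#'
#' Chance-corrected agreement for a square cross-tabulation:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the observed
#' agreement (trace over total) and \eqn{p_e = \sum_i r_i c_i / N^2} the
#' chance agreement from the margins. The p-value is a two-tailed normal
#' test of \eqn{\kappa = 0} using the asymptotic null standard error
#' \deqn{SE_0 = \frac{\sqrt{p_e + p_e^2 - \sum_i \hat p_{i\cdot}
#'   \hat p_{\cdot i} (\hat p_{i\cdot} + \hat p_{\cdot i})}}
#'   {(1 - p_e)\sqrt{N}}}
#' (the standard large-sample expression for testing no agreement beyond
#' chance).
#'
#' @param cross_tab Square numeric matrix or `table` of counts with total
#'   greater than zero.
#' @return A list with `kappa`, `se0`, `z`, `p_value`, `p_observed`,
#'   `p_expected`, `n`.
#' @export
cohen_kappa <- function(cross_tab) {
  x <- as.matrix(cross_tab)
  if (nrow(x) != ncol(x)) stop("cross_tab must be square", call. = FALSE)
  if (any(x < 0) || any(is.na(x))) {
    stop("cross_tab must contain non-negative counts", call. = FALSE)
  }
  n <- sum(x)
  if (n == 0) stop("cross_tab is all zero", call. = FALSE)
  p <- x / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps) {
    stop("degenerate marginals: expected agreement is 1, kappa undefined",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt(pe + pe^2 - sum(pr * pc * (pr + pc))) / ((1 - pe) * sqrt(n))
  z <- kappa / se0
  list(kappa = kappa, se0 = se0, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       p_observed = po, p_expected = pe, n = n)
}
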