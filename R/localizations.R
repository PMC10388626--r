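#' Tumor localization categories and their ICD-10 code prefixes
#'
#' The eight head-and-neck localization categories used throughout the
#' package, with the ICD-10 code prefixes that map to each and the default
#' cohort mixing weights (the manual-registry localization distribution of a
#' typical annual head-and-neck cohort: roughly 31% oral cavity, 25%
#' oropharynx, 23% larynx, with the remaining sites splitting the rest).
#'
#' @return A tibble with columns `localization`, `icd10_prefixes`
#'   (list-column of character vectors) and `weight` (sums to 1).
#' @export
localization_table <- function() {
  tibble::tibble(
    localization = c(
      "oral_cavity", "oropharynx", "nasopharynx", "hypopharynx",
      "larynx", "nasal_sinus", "salivary_gland", "unknown_primary"
    ),
    icd10_prefixes = list(
      c("C00", "C02", "C03", "C04", "C05", "C06"),
      c("C01", "C09", "C10"),
      "C11",
      c("C12", "C13"),
      "C32",
      c("C30", "C31"),
      c("C07", "C08"),
      "C77"
    ),
    weight = c(82, 66, 4, 14, 60, 16, 17, 3) / 262
  )
}

#' Localization categories
#' @return Character vector of the eight category names.
#' @export
localization_levels <- function() localization_table()$localization

#' Map ICD-10 codes to localization categories
#'
#' @param icd10 Character vector of ICD-10 codes (e.g. `"C04.9"`).
#' @return Character vector of localization categories; `NA` where the code
#'   prefix is outside the fixed head-and-neck mapping table.
#' @export
localization_from_icd10 <- function(icd10) {
  tab <- localization_table()
  lookup <- stats::setNames(
    rep(tab$localization, lengths(tab$icd10_prefixes)),
    unlist(tab$icd10_prefixes)
  )
  unname(lookup[substr(icd10, 1, 3)])
}

#' ICD-10 inclusion prefixes used by the extraction engine
#' @return Character vector of three-character code prefixes.
#' @export
icd10_inclusion_set <- function() {
  sort(unique(unlist(localization_table()$icd10_prefixes)))
}

# One representative full code per localization, used by the generator.
#' @noRd
representative_icd10 <- function(localization) {
  codes <- c(
    oral_cavity = "C04.9", oropharynx = "C09.9", nasopharynx = "C11.9",
    hypopharynx = "C13.9", larynx = "C32.9", nasal_sinus = "C31.9",
    salivary_gland = "C07.9", unknown_primary = "C77.0"
  )
  unname(codes[localization])
}

#' @noRd
histology_levels <- function() {
  c("scc", "cis", "melanoma", "thyroid", "skin", "sarcoma",
    "neuroendocrine", "hematologic", "other")
}

#' @noRd
tumor_order_levels <- function() {
  c("first_primary", "second_primary", "recurrence", "residual")
}
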