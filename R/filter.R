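#' Apply study inclusion and exclusion criteria
#'
#' Inclusion: (a) initial consultation for head-and-neck cancer in the target
#' year, (b) treated for a head-and-neck carcinoma at one of the eight
#' recognised localizations, (c) treated with curative intent. Exclusion:
#' (a) carcinoma in situ, (b) second primary, (c) residual or recurrent
#' disease, (d) non-squamous histology (mucosal melanoma, thyroid, skin,
#' sarcoma, neuroendocrine, hematologic). Each patient's disposition label
#' records the first failing criterion in the fixed order inclusion a-c then
#' exclusion a-d; patients passing everything are labelled `"included"`.
#'
#' The consultation year is evaluated on the dataset's own
#' `date_initial_visit`, falling back to the registry's
#' `initial_consult_year` when the date is missing. Histology, tumor order
#' and treatment intent are judged on the registry coding: the abstract's
#' own `intent` column is one of the variables under validation, and a
#' recording error in it must not silently remove the patient from the
#' analysed cohort.
#'
#' @param abstracts Tibble in the [abstract_schema()] layout.
#' @param registry Registry tibble covering every abstract patient.
#' @param year Target consultation year.
#' @return A list with `abstracts` (the included rows) and `disposition`
#'   (tibble of `patient_id`, `disposition`).
#' @export
apply_criteria <- function(abstracts, registry, year = 2020L) {
  if (!all(abstracts$patient_id %in% registry$patient_id)) {
    stop("registry does not cover all abstract patient_ids", call. = FALSE)
  }
  reg <- registry[match(abstracts$patient_id, registry$patient_id), ]
  if (!all(reg$histology %in% histology_levels())) {
    stop("unknown histology value in registry", call. = FALSE)
  }
  if (!all(reg$tumor_order %in% tumor_order_levels())) {
    stop("unknown tumor_order value in registry", call. = FALSE)
  }

  visit_year <- ifelse(
    is.na(abstracts$date_initial_visit),
    reg$initial_consult_year,
    as.integer(format(abstracts$date_initial_visit, "%Y"))
  )
  # intent is judged on the registry coding; the abstract's intent column is
  # itself a measured variable under validation and recording errors in it
  # must not silently change the analysed cohort
  intent <- reg$intent

  disposition <- rep("included", nrow(abstracts))
  checks <- list(
    "inclusion-a" = visit_year != year,
    "inclusion-b" = !(abstracts$localization %in% localization_levels()) &
      !(reg$localization %in% localization_levels()),
    "inclusion-c" = intent != "curative",
    "exclusion-a" = reg$histology == "cis",
    "exclusion-b" = reg$tumor_order == "second_primary",
    "exclusion-c" = reg$tumor_order %in% c("recurrence", "residual"),
    "exclusion-d" = reg$histology %in%
      c("melanoma", "thyroid", "skin", "sarcoma", "neuroendocrine",
        "hematologic")
  )
  for (lab in names(checks)) {
    fail <- checks[[lab]] & disposition == "included"
    disposition[fail] <- lab
  }

  list(
    abstracts = abstracts[disposition == "included", ],
    disposition = tibble::tibble(
      patient_id = abstracts$patient_id,
      disposition = disposition
    )
  )
}
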