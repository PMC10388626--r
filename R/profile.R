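#' Discrepancy profile for the synthetic MED/AED comparison
#'
#' Configures the error modes injected between the ground-truth event log, the
#' simulated manually-abstracted dataset (MED) and the material the extraction
#' engine sees. All probabilities default to zero, so
#' `discrepancy_profile()` is the identity profile: with it, the MED equals
#' the ground-truth abstract and downstream agreement is 100% on every
#' variable.
#'
#' The modes mirror the discrepancies documented when a real head-and-neck
#' dashboard was validated against registry abstraction:
#' \describe{
#'   \item{referral_offset}{The true referral date lives in a scanned letter;
#'     the engine can only use the scheduling order. With probability
#'     `p_referral_offset` the abstracted referral date precedes the
#'     scheduling order by an offset drawn from `referral_offset_days`
#'     (weights `referral_offset_weights`), producing the characteristic 1-3
#'     day disagreements.}
#'   \item{initial_visit_shift}{Systematic one-day discrepancy on the initial
#'     visit date (an extraction-logic off-by-one), applied with probability
#'     `p_initial_visit_shift`.}
#'   \item{extra MDT}{With probability `p_extra_mdt` the abstractor's chosen
#'     pre-treatment multidisciplinary team meeting is one weekly cycle (7
#'     days) before the last MDT preceding treatment, which is the one the
#'     engine selects.}
#'   \item{outpatient physiotherapy}{With probability `p_physio_outpatient` a
#'     patient's physiotherapy happens only in the outpatient/external
#'     setting, where no inpatient form exists for the engine to detect.}
#'   \item{second systemic round}{With probability `p_second_systemic_round` a
#'     systemic-therapy patient receives a later second round whose
#'     administrations can contaminate the extracted end date unless a
#'     between-round cutoff is applied.}
#'   \item{jitter/flip/missingness}{`date_jitter`, `flip_rates` and
#'     `missingness` are named lists (by abstract variable) of small
#'     per-variable rates: random +/-1..3 day shifts on MED dates, random
#'     categorical/boolean recording errors in the MED, and MED values set to
#'     missing.}
#' }
#'
#' @param p_referral_offset Probability the referral-date offset is applied.
#' @param referral_offset_days Integer offsets the scanned letter's referral
#'   date precedes the scheduling order by.
#' @param referral_offset_weights Sampling weights for the offsets.
#' @param p_initial_visit_shift Probability of the one-day initial-visit
#'   discrepancy.
#' @param p_extra_mdt Probability the abstractor's MDT is 7 days early.
#' @param p_physio_outpatient Probability physiotherapy is outpatient-only.
#' @param p_second_systemic_round Probability of a later systemic round.
#' @param p_missing_from_aed Probability a patient's diagnosis code was never
#'   recorded electronically, so the patient is absent from the automatically
#'   extracted dataset entirely.
#' @param date_jitter,flip_rates,missingness Named lists of per-variable
#'   rates in \[0, 1\] (see Details).
#' @return An object of class `discrepancy_profile`.
#' @seealso [study_profile()] for a profile calibrated to the published
#'   validation study's observed disagreement rates.
#' @examples
#' discrepancy_profile() # identity profile
#' discrepancy_profile(p_referral_offset = 0.46)
#' @export
discrepancy_profile <- function(p_referral_offset = 0,
                                referral_offset_days = 1:3,
                                referral_offset_weights = c(0.5, 0.3, 0.2),
                                p_initial_visit_shift = 0,
                                p_extra_mdt = 0,
                                p_physio_outpatient = 0,
                                p_second_systemic_round = 0,
                                p_missing_from_aed = 0,
                                date_jitter = list(),
                                flip_rates = list(),
                                missingness = list()) {
  assert_prob(p_referral_offset, "p_referral_offset")
  assert_prob(p_initial_visit_shift, "p_initial_visit_shift")
  assert_prob(p_extra_mdt, "p_extra_mdt")
  assert_prob(p_physio_outpatient, "p_physio_outpatient")
  assert_prob(p_second_systemic_round, "p_second_systemic_round")
  assert_prob(p_missing_from_aed, "p_missing_from_aed")
  stopifnot(length(referral_offset_days) == length(referral_offset_weights),
            all(referral_offset_days >= 1))
  for (nm in names(date_jitter)) assert_prob(date_jitter[[nm]], nm)
  for (nm in names(flip_rates)) assert_prob(flip_rates[[nm]], nm)
  for (nm in names(missingness)) assert_prob(missingness[[nm]], nm)
  structure(
    list(
      p_referral_offset = p_referral_offset,
      referral_offset_days = as.integer(referral_offset_days),
      referral_offset_weights = referral_offset_weights /
        sum(referral_offset_weights),
      p_initial_visit_shift = p_initial_visit_shift,
      p_extra_mdt = p_extra_mdt,
      p_physio_outpatient = p_physio_outpatient,
      p_second_systemic_round = p_second_systemic_round,
      p_missing_from_aed = p_missing_from_aed,
      date_jitter = date_jitter,
      flip_rates = flip_rates,
      missingness = missingness
    ),
    class = "discrepancy_profile"
  )
}

#' @export
print.discrepancy_profile <- function(x, ...) {
  cat("<discrepancy_profile>\n")
  scalars <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  for (nm in names(scalars)) cat(sprintf("  %s: %g\n", nm, scalars[[nm]]))
  for (nm in c("date_jitter", "flip_rates", "missingness")) {
    if (length(x[[nm]])) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(names(x[[nm]]), unlist(x[[nm]]),
                        sep = "=", collapse = ", ")))
    }
  }
  invisible(x)
}

#' Is a profile the identity (no injected discrepancies)?
#' @param profile A [discrepancy_profile()].
#' @return Logical scalar.
#' @export
is_identity_profile <- function(profile) {
  scalars <- c(profile$p_referral_offset, profile$p_initial_visit_shift,
               profile$p_extra_mdt, profile$p_physio_outpatient,
               profile$p_second_systemic_round, profile$p_missing_from_aed)
  all(scalars == 0) && !length(profile$date_jitter) &&
    !length(profile$flip_rates) && !length(profile$missingness)
}

#' Discrepancy profile calibrated to the published validation study
#'
#' Per-mode rates chosen so that the synthetic MED/AED comparison reproduces,
#' in expectation, the disagreement pattern the real-world validation
#' observed: about 46% disagreement on the referral date, 12% on the initial
#' visit date, 17% on the pre-treatment MDT date, 39% of systemic patients
#' with a contaminating second round, 45% of physiotherapy happening outside
#' the inpatient form's reach, plus small per-variable recording-error and
#' missingness rates matching the published per-variable agreement and
#' presence counts.
#'
#' @return An object of class `discrepancy_profile`.
#' @export
study_profile <- function() {
  discrepancy_profile(
    p_referral_offset = 0.46,
    p_initial_visit_shift = 0.12,
    p_extra_mdt = 0.17,
    p_physio_outpatient = 0.45,
    p_second_systemic_round = 0.39,
    p_missing_from_aed = 5 / 330,
    date_jitter = list(
      date_surgery = 0.016,
      rt_start = 0.076,
      rt_end = 0.044,
      date_dental = 0.012,
      date_physio = 0.8
    ),
    flip_rates = list(
      localization = 0.031,
      intent = 0.042,
      surgical_treatment = 0.107,
      neck_dissection = 0.129,
      rt_flag = 0.053,
      systemic_flag = 0.042,
      dental_flag = 0.032,
      complication_flag = 0.106,
      unplanned_reop_flag = 0.033
    ),
    missingness = list(
      date_referral = 0.004,
      date_mdt_pretreat = 0.027,
      date_dental = 0.075,
      date_physio = 0.07
    )
  )
}
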