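test_that("generate_cohort validates its inputs", {
  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(10, localization_weights = c(0.5, 0.5)),
               "length 8")
  expect_error(generate_cohort(10, localization_weights = rep(0.2, 8)),
               "sum to 1")
  expect_error(discrepancy_profile(p_referral_offset = 1.5), "probability")
})

test_that("a one-patient cohort is a single well-formed row", {
  reg <- generate_cohort(1, seed = 5)
  expect_equal(nrow(reg), 1)
  expect_equal(localization_from_icd10(reg$icd10_code), reg$localization)
})

test_that("localization frequencies follow the sampling weights", {
  # uniform weights: every category within 3 binomial SDs of n/8, checked
  # against a direct tally of the sample
  n <- 10000
  reg <- generate_cohort(n, localization_weights = rep(1 / 8, 8), seed = 42)
  tally <- table(factor(reg$localization, levels = localization_levels()))
  sd3 <- 3 * sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(as.numeric(tally) - n / 8) < sd3))

  # default weights: the oral-cavity fraction matches its cohort weight
  reg2 <- generate_cohort(n, seed = 7)
  w_oral <- localization_table()$weight[1]
  expect_lt(abs(mean(reg2$localization == "oral_cavity") - w_oral),
            3 * sqrt(w_oral * (1 - w_oral) / n))
})

test_that("exclusion-triggering features appear at the configured rate", {
  reg <- generate_cohort(4000, seed = 11, exclusion_frac = 0.25)
  triggered <- reg$histology != "scc" | reg$tumor_order != "first_primary" |
    reg$intent != "curative" | reg$initial_consult_year != 2020
  expect_lt(abs(mean(triggered) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("generation is deterministic under a fixed seed", {
  reg1 <- generate_cohort(60, seed = 3, exclusion_frac = 0.2)
  reg2 <- generate_cohort(60, seed = 3, exclusion_frac = 0.2)
  expect_identical(reg1, reg2)
  log1 <- generate_event_log(reg1, seed = 4, profile = study_profile())
  log2 <- generate_event_log(reg2, seed = 4, profile = study_profile())
  expect_identical(log1, log2)
  med1 <- derive_manual_abstract(log1, reg1, study_profile(), seed = 5)
  med2 <- derive_manual_abstract(log2, reg2, study_profile(), seed = 5)
  expect_identical(med1, med2)
})

test_that("event logs respect the pathway's temporal ordering", {
  reg <- generate_cohort(150, seed = 9)
  log <- generate_event_log(reg, seed = 10, profile = study_profile())
  expect_true(all(log$patient_id %in% reg$patient_id))
  expect_true(all(log$event_type %in% event_types()))

  per <- split(log, log$patient_id)
  for (ev in per) {
    get1 <- function(t) ev$event_date[ev$event_type == t][1]
    sched <- min(ev$event_date[ev$event_type == "scheduling_order"])
    expect_true(all(ev$event_date >= sched))  # scheduling order is earliest
    expect_lte(get1("scanned_referral_letter"), get1("initial_consult"))
    expect_lte(get1("initial_consult"), min(
      ev$event_date[ev$event_type == "mdt_meeting"]))
    tx <- ev$event_date[ev$event_type %in%
                          c("surgery", "rt_fraction", "systemic_admin")]
    expect_lt(min(ev$event_date[ev$event_type == "mdt_meeting"]), min(tx))
    if (any(ev$event_type == "surgery") &&
        any(ev$event_type == "rt_fraction")) {
      expect_lt(get1("surgery"),
                min(ev$event_date[ev$event_type == "rt_fraction"]))
    }
  }
})

test_that("MDT meetings land on the configured weekday", {
  reg <- generate_cohort(100, seed = 21)
  for (wd in c(2L, 3L)) {
    log <- generate_event_log(reg, pathway_config(mdt_weekday = wd),
                              seed = 22)
    mdts <- log$event_date[log$event_type == "mdt_meeting"]
    expect_true(all(as.POSIXlt(mdts)$wday == wd))
  }
})

test_that("the emitted referral-to-consult waiting time has the configured median", {
  reg <- generate_cohort(500, seed = 31)
  log <- generate_event_log(reg, pathway_config(referral_to_consult_median = 5),
                            seed = 32)
  # recompute the statistic directly from the emitted events
  letters <- log[log$event_type == "scanned_referral_letter", ]
  consults <- log[log$event_type == "initial_consult", ]
  gap <- as.numeric(consults$event_date[match(letters$patient_id,
                                              consults$patient_id)] -
                      letters$event_date)
  expect_lte(abs(stats::median(gap) - 5), 1)
})

test_that("rt fractions and systemic administrations form contiguous runs", {
  reg <- generate_cohort(80, seed = 41)
  log <- generate_event_log(reg, pathway_config(rt_fractions = 10), seed = 42)
  rt <- split(log$event_date[log$event_type == "rt_fraction"],
              log$patient_id[log$event_type == "rt_fraction"])
  for (d in rt) {
    d <- sort(d)
    expect_length(d, 10)
    expect_true(all(diff(d) <= 3))  # weekday-contiguous: gaps of 1-3 days
  }
  sy <- split(log$event_date[log$event_type == "systemic_admin"],
              log$patient_id[log$event_type == "systemic_admin"])
  for (d in sy) expect_true(all(diff(sort(d)) == 21))
})

test_that("identity profile reproduces the ground truth; forced modes flip it", {
  reg <- generate_cohort(120, seed = 51)
  log <- generate_event_log(reg, seed = 52)
  med <- derive_manual_abstract(log, reg, discrepancy_profile(), seed = 53)
  aed <- extract_dataset(log, reg)
  linked <- link_datasets(med, aed)
  agr <- agreement_table(linked)
  expect_true(all(agr$pct_agreement == 100))

  # every physiotherapy contact is visible to the abstractor even when it is
  # outpatient-only
  log_out <- generate_event_log(
    reg, profile = discrepancy_profile(p_physio_outpatient = 1), seed = 52)
  med_out <- derive_manual_abstract(log_out, reg, discrepancy_profile())
  has_physio <- vapply(split(log_out, log_out$patient_id), function(ev) {
    any(grepl("^physio", ev$event_type))
  }, logical(1))[med_out$patient_id]
  expect_identical(med_out$physio_flag %in% TRUE, unname(has_physio))
  # ... but never to the inpatient-form-based engine
  aed_out <- extract_dataset(log_out, reg)
  expect_false(any(aed_out$physio_flag))
})

test_that("the referral-offset rate is recovered by counting differing rows", {
  reg <- generate_cohort(1000, seed = 61)
  log <- generate_event_log(
    reg, profile = discrepancy_profile(p_referral_offset = 0.5), seed = 62)
  med <- derive_manual_abstract(log, reg, discrepancy_profile())
  sched <- log[log$event_type == "scheduling_order", ]
  differs <- med$date_referral !=
    sched$event_date[match(med$patient_id, sched$patient_id)]
  expect_lt(abs(mean(differs) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("every abstract patient appears in the registry", {
  reg <- generate_cohort(40, seed = 71)
  log <- generate_event_log(reg, seed = 72)
  med <- derive_manual_abstract(log, reg, discrepancy_profile())
  expect_setequal(med$patient_id, reg$patient_id)
  expect_error(derive_manual_abstract(
    dplyr::mutate(log, patient_id = paste0("Z", patient_id)), reg,
    discrepancy_profile()), "absent from the registry")
})
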