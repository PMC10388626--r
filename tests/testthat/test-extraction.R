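test_that("the referral proxy is the earliest scheduling order, never the letter", {
  ev <- mk_events(scheduling_order = c(3, 10))
  expect_equal(select_referral_date(ev), day0 + 3)
  # the scanned letter is a PDF: invisible to structured extraction
  ev2 <- mk_events(scanned_referral_letter = 0)
  expect_true(is.na(select_referral_date(ev2)))
})

test_that("treatment start picks the earliest modality with surgery-first ties", {
  ev <- mk_events(surgery = 20, rt_fraction = 40)
  tx <- determine_treatment_start(ev)
  expect_equal(tx$date, day0 + 20)
  expect_equal(tx$modality, "surgery")

  expect_null(determine_treatment_start(mk_events(mdt_meeting = 5)))

  tie <- mk_events(systemic_admin = 15, rt_fraction = 15, surgery = 15)
  expect_equal(determine_treatment_start(tie)$modality, "surgery")
  tie2 <- mk_events(systemic_admin = 15, rt_fraction = 15)
  expect_equal(determine_treatment_start(tie2)$modality, "rt")
})

test_that("pre-treatment MDT selection: last-before-treatment vs first-after-diagnosis", {
  ev <- mk_events(initial_consult = 2, mdt_meeting = c(10, 17))
  tx <- day0 + 20
  expect_equal(select_pretreatment_mdt(ev, tx), day0 + 17)
  expect_equal(
    select_pretreatment_mdt(
      ev, tx, extraction_rules(mdt_selection = "first_after_diagnosis")),
    day0 + 10)  # 7-day divergence between the two readings

  # single MDT after treatment start does not qualify under the default
  late <- mk_events(mdt_meeting = 25)
  expect_true(is.na(select_pretreatment_mdt(late, tx)))

  # same-day policy
  same <- mk_events(mdt_meeting = 20)
  expect_true(is.na(select_pretreatment_mdt(same, tx)))
  expect_equal(
    select_pretreatment_mdt(same, tx,
                            extraction_rules(same_day_strict = FALSE)),
    day0 + 20)
})

test_that("radiotherapy window is the min/max of fraction dates", {
  one <- mk_events(rt_fraction = 8)
  w <- derive_rt_window(one)
  expect_equal(w$start, w$end)
  expect_null(derive_rt_window(mk_events(surgery = 1)))
})

test_that("systemic window stops at the between-round cutoff", {
  ev <- mk_events(systemic_admin = c(0, 21, 42, 200))
  w <- derive_systemic_window(ev, extraction_rules(
    systemic_round_cutoff_weeks = 6))
  expect_equal(w$start, day0)
  expect_equal(w$end, day0 + 42)  # the day-200 round is a later round

  # disabling the cutoff reproduces naive last-administration logic
  w_inf <- derive_systemic_window(ev, extraction_rules(
    systemic_round_cutoff_weeks = Inf))
  expect_equal(w_inf$end, day0 + 200)

  expect_error(extraction_rules(systemic_round_cutoff_weeks = 0.5), ">= 1")
})

test_that("physiotherapy detection sees only the inpatient form", {
  out_only <- mk_events(physio_outpatient_contact = 30)
  res <- detect_physiotherapy(out_only)
  expect_false(res$flag)
  expect_true(is.na(res$date))

  inp <- mk_events(physio_inpatient_form = c(31, 28))
  res2 <- detect_physiotherapy(inp)
  expect_true(res2$flag)
  expect_equal(res2$date, day0 + 28)
})

test_that("an empty event list yields an all-null abstract", {
  reg <- mk_registry()
  ab <- extract_abstract(mk_events()[0, ], reg)
  for (v in c("date_referral", "date_initial_visit", "date_surgery",
              "rt_start", "syst_end", "date_physio")) {
    expect_true(is.na(ab[[v]]))
  }
  for (v in c("surgical_treatment", "rt_flag", "physio_flag",
              "unplanned_reop_flag")) {
    expect_false(ab[[v]])
  }
  expect_error(extract_abstract(mk_events(), reg[0, ]), "not found")
})

test_that("a full-pathway patient extracts field by field as hand-derived", {
  ev <- dplyr::bind_rows(
    mk_events(scheduling_order = 0, scanned_referral_letter = 1,
              initial_consult = 7, mdt_meeting = c(9, 16)),
    mk_events(surgery = 23, neck_dissection = 23, complication = 25,
              dental_consult = 15, physio_inpatient_form = 26),
    mk_events(reoperation = 28, planned = FALSE),
    mk_events(rt_fraction = c(60, 61, 62)),
    mk_events(systemic_admin = c(60, 81, 250))
  )
  ab <- extract_abstract(ev, mk_registry(icd10 = "C04.9"))
  expect_equal(ab$localization, "oral_cavity")
  expect_equal(ab$date_referral, day0 + 0)        # scheduling order, not letter
  expect_equal(ab$date_initial_visit, day0 + 7)
  expect_equal(ab$date_mdt_pretreat, day0 + 16)   # last MDT before surgery
  expect_equal(ab$date_surgery, day0 + 23)
  expect_equal(ab$rt_start, day0 + 60)
  expect_equal(ab$rt_end, day0 + 62)
  expect_equal(ab$syst_start, day0 + 60)
  expect_equal(ab$syst_end, day0 + 81)            # day-250 admin: second round
  expect_equal(ab$date_dental, day0 + 15)
  expect_equal(ab$date_physio, day0 + 26)
  expect_true(all(unlist(ab[abstract_schema()[14:21]])))
})

test_that("field rules match exhaustive-scan oracles on random small patients", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      ev <- random_events()
      expect_identical(select_referral_date(ev), oracle_referral(ev))
      expect_identical(determine_treatment_start(ev), oracle_tx_start(ev))
      expect_identical(derive_rt_window(ev), oracle_rt_window(ev))
      cutoff <- sample(c(2, 6, 10), 1)
      expect_identical(
        derive_systemic_window(ev, extraction_rules(
          systemic_round_cutoff_weeks = cutoff)),
        oracle_syst_window(ev, cutoff))
      expect_identical(detect_physiotherapy(ev), oracle_physio(ev))
      tx <- determine_treatment_start(ev)
      if (!is.null(tx)) {
        expect_identical(select_pretreatment_mdt(ev, tx$date),
                         oracle_mdt_last_before(ev, tx$date))
      }
    }
  })
})

test_that("extraction is idempotent and order-invariant", {
  reg <- generate_cohort(60, seed = 81)
  log <- generate_event_log(reg, seed = 82, profile = study_profile())
  a1 <- extract_dataset(log, reg)
  a2 <- extract_dataset(log, reg)
  expect_identical(a1, a2)
  perm <- withr::with_seed(5, log[sample.int(nrow(log)), ])
  a3 <- extract_dataset(perm, reg)
  expect_identical(a1, a3)
})

test_that("extracted windows are sane and the MDT precedes treatment", {
  reg <- generate_cohort(120, seed = 91)
  log <- generate_event_log(reg, seed = 92, profile = study_profile())
  aed <- extract_dataset(log, reg)
  both_rt <- !is.na(aed$rt_start) & !is.na(aed$rt_end)
  expect_true(all(aed$rt_start[both_rt] <= aed$rt_end[both_rt]))
  both_sy <- !is.na(aed$syst_start) & !is.na(aed$syst_end)
  expect_true(all(aed$syst_start[both_sy] <= aed$syst_end[both_sy]))
  tx <- pmin(aed$date_surgery, aed$rt_start, aed$syst_start, na.rm = TRUE)
  has <- !is.na(aed$date_mdt_pretreat) & !is.na(tx)
  expect_true(all(aed$date_mdt_pretreat[has] < tx[has]))
})

test_that("ICD-10 inclusion filters the extracted dataset", {
  reg <- dplyr::bind_rows(mk_registry(id = "P1", icd10 = "C32.9"),
                          mk_registry(id = "P2", icd10 = "C50.1"))
  log <- dplyr::bind_rows(mk_events(initial_consult = 0, id = "P1"),
                          mk_events(initial_consult = 0, id = "P2"))
  aed <- extract_dataset(log, reg)
  expect_identical(aed$patient_id, "P1")
})
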