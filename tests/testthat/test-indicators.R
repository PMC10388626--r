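test_that("the builtin set has seven proportions and three medians", {
  defs <- builtin_definitions()
  expect_length(defs, 10)
  kinds <- vapply(defs, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "proportion"), 7)
  expect_equal(sum(kinds == "median_days"), 3)
  expect_error(indicator_definition("no_such_indicator", "x"), "unknown")
})

test_that("a windowed indicator counts a toy cohort correctly", {
  ab <- mk_abstract(
    4,
    date_initial_visit = day0,
    date_surgery = day0 + c(10, 20, 30, 31)
  )
  res <- compute_indicator(ab, builtin_definitions()$treatment_within_30d)
  expect_equal(res$numerator, 3)
  expect_equal(res$denominator, 4)
  expect_equal(res$pct, 75.0)

  empty <- compute_indicator(mk_abstract(5),
                             builtin_definitions()$treatment_within_30d)
  expect_equal(empty$denominator, 0)
  expect_true(is.na(empty$pct))
})

test_that("percentages from printed-style counts follow registry rounding", {
  ab <- mk_abstract(
    261,
    date_initial_visit = day0,
    date_surgery = day0 + c(rep(30, 232), rep(31, 29))
  )
  res <- compute_indicator(ab, builtin_definitions()$treatment_within_30d)
  expect_equal(res$numerator, 232)
  expect_equal(res$denominator, 261)
  expect_equal(res$pct, 88.9)
})

test_that("indicator counts match row-loop oracles on random abstracts", {
  withr::with_seed(19, {
    for (rep in 1:50) {
      n <- sample(20:80, 1)
      ab <- mk_abstract(
        n,
        date_initial_visit = day0 + sample(0:5, n, replace = TRUE),
        date_referral = day0 - sample(0:10, n, replace = TRUE),
        date_surgery = day0 + sample(c(NA, 10:40), n, replace = TRUE),
        surgical_treatment = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
        unplanned_reop_flag = sample(c(TRUE, FALSE, NA), n, replace = TRUE)
      )
      r30 <- compute_indicator(ab, builtin_definitions()$treatment_within_30d)
      o30 <- oracle_window_indicator(ab, "date_initial_visit",
                                     "date_surgery", 30)
      expect_equal(r30$numerator, o30$numerator)
      expect_equal(r30$denominator, o30$denominator)

      r7 <- compute_indicator(ab, builtin_definitions()$initial_visit_within_7d)
      o7 <- oracle_window_indicator(ab, "date_referral",
                                    "date_initial_visit", 7)
      expect_equal(r7$numerator, o7$numerator)
      expect_equal(r7$denominator, o7$denominator)

      reop <- compute_indicator(ab, builtin_definitions()$unplanned_reoperation)
      expect_equal(reop$denominator, sum(ab$surgical_treatment %in% TRUE))
      expect_equal(reop$numerator, sum(ab$surgical_treatment %in% TRUE &
                                         ab$unplanned_reop_flag %in% TRUE))
    }
  })
})

test_that("numerators never exceed denominators on arbitrary data", {
  withr::with_seed(23, {
    reg <- generate_cohort(200, exclusion_frac = 0.3, seed = 29)
    log <- generate_event_log(reg, profile = study_profile(), seed = 31)
    med <- derive_manual_abstract(log, reg, study_profile(), seed = 37)
    res <- compute_indicators(med)
    prop <- res[res$kind == "proportion", ]
    expect_true(all(prop$numerator <= prop$denominator))
    expect_true(all(prop$denominator <= nrow(med)))
  })
})

test_that("relaxing a window never decreases the numerator", {
  reg <- generate_cohort(150, seed = 41)
  log <- generate_event_log(reg, seed = 43)
  med <- derive_manual_abstract(log, reg, discrepancy_profile())
  d30 <- builtin_definitions()$treatment_within_30d
  d31 <- indicator_definition("treatment_within_30d", d30$description,
                              window_days = 31)
  n30 <- compute_indicator(med, d30)$numerator
  n31 <- compute_indicator(med, d31)$numerator
  expect_gte(n31, n30)
  # exclusive boundary is at least as strict as inclusive
  d30x <- indicator_definition("treatment_within_30d", d30$description,
                               window_days = 30, boundary = "exclusive")
  expect_lte(compute_indicator(med, d30x)$numerator, n30)
})

test_that("comparison rows are automatic minus manual on rounded values", {
  man <- pct_row("initial_visit_within_7d", 226, 248)   # 91.1
  aut <- pct_row("initial_visit_within_7d", 232, 252)   # 92.1
  cmp <- compare_results(man, aut)
  expect_equal(cmp$difference, 1.0)

  same <- compare_results(man, man)
  expect_equal(same$difference, 0)

  m1 <- median_row("median_referral_to_consult", 5)
  a1 <- median_row("median_referral_to_consult", 6)
  expect_equal(compare_results(m1, a1)$difference, 1)

  expect_error(compare_results(man, pct_row("dental_before_rt", 1, 2)),
               "do not match")

  withr::with_seed(47, {
    for (rep in 1:20) {
      nm <- sample(100:300, 2)
      dm <- sample(100:300, 2)
      man_r <- pct_row("unplanned_reoperation", min(nm), max(dm))
      aut_r <- pct_row("unplanned_reoperation", min(nm[2], dm[1]), max(dm))
      expect_equal(compare_results(man_r, aut_r)$difference,
                   aut_r$pct - man_r$pct)
    }
  })
})

test_that("definitions round-trip through YAML unchanged", {
  defs <- builtin_definitions()
  txt <- definitions_to_yaml(defs)
  back <- definitions_from_yaml(txt)
  expect_equal(lapply(back, unclass), lapply(defs, unclass))

  path <- withr::local_tempfile(fileext = ".yaml")
  definitions_to_yaml(defs, path)
  expect_equal(lapply(definitions_from_yaml(path), unclass),
               lapply(defs, unclass))
})
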