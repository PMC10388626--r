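---
title: "Validating automated EHR data reuse for care-pathway quality indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated EHR data reuse for care-pathway quality indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carepathqi)
```

## The measurement problem

Hospitals measure the quality of oncologic care with indicators: proportions
of a defined cohort meeting a condition (e.g. "treatment started within 30
days of the initial appointment") or median waiting times between pathway
events. Traditionally the patient-level inputs are abstracted by hand from
charts into a registry — the *manually extracted dataset* (MED). When the
care pathway records its events as structured EHR data, the same abstracts
can be derived automatically by extraction logic — the *automatically
extracted dataset* (AED) — and the indicators computed in real time.

Whether the automatic route is trustworthy is an empirical question. The
standard validation design, which this package implements end to end, is:

1. produce MED and AED for the same annual head-and-neck-oncology cohort;
2. link records exactly on the patient identifier, labelling each record
   `linked`, `med_only` or `aed_only`, and report *coverage*
   ($100 \cdot n_\mathrm{linked} / n_\mathrm{MED}$);
3. apply the study's inclusion/exclusion criteria to both datasets;
4. for every shared variable, compute the *level of agreement* — exact
   matches as a share of linked pairs with the variable present in both
   sources — plus, for dates, the distribution of signed day differences
   (manual − automatic; negative means the manual date is earlier), and,
   for categorical variables, Cohen's kappa;
5. compute each quality indicator on both datasets and report the
   difference (automatic − manual, on rounded values).

Because no real MED/AED pair is public, the package pairs this machinery
with a synthetic event-log generator whose *discrepancy profile* injects
the documented real-world error modes, so that the whole validation chain
can be exercised, and its estimators checked, against known ground truth.

## The synthetic care pathway

`generate_cohort()` draws an annual registry over eight ICD-10-based tumor
localizations (default mixing weights follow a typical manual-registry
cohort: ~31% oral cavity, ~25% oropharynx, ~23% larynx). A configurable
fraction of patients carries an exclusion-triggering feature (carcinoma in
situ, second primary, recurrent/residual disease, palliative intent,
non-squamous histology, consultation outside the target year), emulating
the raw registry before study criteria are applied.

`generate_event_log()` lays out each patient's pathway:

* a **scheduling order** (the administrative booking action), the **scanned
  referral letter**, the **initial consultation**, a weekly **MDT**
  (multidisciplinary team meeting, Wednesdays by default), then treatment:
  surgery and/or radiotherapy fractions and/or systemic administrations,
  with dental consultations before radiotherapy, postoperative
  physiotherapy, reoperations and complications.
* Waiting times are integer day counts `median + (D1 - D2)` with
  `D1, D2` negative-binomial draws, truncated below: a symmetric,
  overdispersed construction whose median is exactly the configured value.
  Defaults: letter-to-consultation median 5 days; MDT-to-treatment median
  16 days with a heavier tail (so roughly nine in ten patients start
  treatment within 30 days of consultation, the realistic service level for
  this indicator).
* Consultation weekdays are weighted toward Monday/Tuesday
  (`consult_weekday_weights`), and each patient is discussed at the first
  weekly MDT at least `consult_to_mdt_min` (default 1) day after
  consultation. An independent consult-to-MDT waiting-time median cannot
  coexist with a fixed-weekday weekly board — forward snapping inflates any
  small target — so the board schedule plus the early-week booking pattern
  *is* the waiting-time model; it yields the observed 2-day median.
* Modality probabilities default to the marginals of a tertiary cohort:
  surgery 0.52, radiotherapy 0.78, systemic 0.20 (patients drawing none are
  assigned radiotherapy); neck dissection in half the surgical patients;
  postoperative physiotherapy in 59% of neck dissections; dental clearance
  in 86% of radiotherapy patients; unplanned reoperation 6.8% of surgery.

## The discrepancy profile

`discrepancy_profile()` defaults to the identity: no injected errors, so
the MED equals the ground truth, the engine recovers everything, and the
whole chain agrees 100% — the end-to-end null test. Each mode mirrors a
documented failure of real-world abstraction or extraction:

| mode | mechanism | where it lives |
|---|---|---|
| `p_referral_offset` | the true referral date exists only inside a scanned PDF; the engine's proxy is the scheduling order, drawn 1–3 days earlier | event log |
| `p_initial_visit_shift` | systematic 1-day shift of the abstracted initial-visit date (an extraction off-by-one observed in practice) | MED derivation |
| `p_extra_mdt` | the abstractor's chosen pre-treatment MDT is one weekly cycle (7 days) before the last MDT preceding treatment, which is what the engine selects | MED derivation |
| `p_physio_outpatient` | physiotherapy happens outpatient/externally, where no inpatient form exists for the engine to detect | event log |
| `p_second_systemic_round` | a later second systemic round whose administrations contaminate the extracted end date unless a between-round cutoff is applied | event log |
| `date_jitter`, `flip_rates`, `missingness` | small per-variable recording errors and missingness in the MED | MED derivation |

The offset sign deserves a note: with the letter dated *after* the
scheduling order, the automatic referral date is the earlier one, manual
waiting times from referral are about one day shorter than automatic ones,
and the referral-date day differences are positive under the
manual-minus-automatic convention. This is the direction the validated
real-world comparison exhibits (manual 5 vs automatic 6 days to
consultation), and it is what the generator reproduces.

`study_profile()` is the calibrated profile: rates chosen once so the
synthetic comparison reproduces, in expectation, the observed disagreement
pattern — 46% on the referral date, 12% on the initial visit, 17% on the
pre-treatment MDT, 39% of systemic patients with a second round, 45% of
physiotherapy invisible to the inpatient form, small (1–13%) per-variable
flip/jitter/missingness rates elsewhere, and a 1.5% chance that a patient's
diagnosis code was never recorded electronically (driving coverage below
100%).

## The extraction engine

The engine implements the corrected dashboard logic, one rule per field:

* **referral date**: earliest scheduling order; the scanned letter is never
  read (structured extraction cannot).
* **treatment start**: earliest of first surgery / first radiotherapy
  fraction / first systemic administration; same-day ties resolve surgery >
  radiotherapy > systemic.
* **pre-treatment MDT**: last MDT strictly before treatment start (a
  same-day MDT does not qualify; `same_day_strict = FALSE` relaxes this).
  The alternative `first_after_diagnosis` reading reproduces the
  abstractor's convention; on a patient re-discussed the week before
  treatment the two readings diverge by exactly one weekly cycle.
* **systemic window**: start = first administration; end = last
  administration of the maximal run from the start with consecutive gaps ≤
  `systemic_round_cutoff_weeks` (default 6 — the conventional adjuvant
  window; `Inf` disables the cutoff and reproduces the naive pre-fix
  logic).
* **physiotherapy**: the inpatient form only, on purpose — this reproduces
  the input-side capture gap rather than fixing it, because the point of
  the validation is to measure its consequences.

Extraction is a pure function of the event multiset: idempotent and
invariant to row order, which the test suite asserts directly.

## Cohort criteria

Inclusion: consultation in the target year; a head-and-neck localization;
curative intent. Exclusion: carcinoma in situ; second primary;
recurrent/residual disease; non-squamous histology. The disposition label
records the first failing criterion in that fixed order. Two design points:

* The year is judged on each dataset's own visit date (registry fallback),
  but histology, tumor order and intent are judged on the registry coding.
  The abstract's `intent` column is itself a variable under validation;
  filtering each dataset on its own recorded intent would silently delete
  exactly the disagreeing records and bias agreement upward — observed
  intent disagreement would be impossible, which contradicts how such
  comparisons actually come out.
* As the criteria are stated, "first primary squamous carcinoma" logically
  subsumes most exclusions; evaluated literally the exclusion labels would
  be unreachable. The package therefore checks only the localization under
  inclusion (b) and lets each exclusion surface under its own label, which
  leaves the filtered set identical and the audit trail informative.

## Statistics

* **Percent agreement** is exact equality (same calendar day, same code,
  same boolean) over linked pairs with the variable present in both
  sources; the same computation applies to nominal, categorical and date
  variables. Percentages round half-away-from-zero (one decimal; coverage
  two decimals) — registry convention, and the reason a cell like 178/204
  prints 87.3.
* **Cohen's kappa** $\kappa = (p_o - p_e)/(1 - p_e)$ with
  $p_e = \sum_i \hat p_{i\cdot}\hat p_{\cdot i}$, computed for categorical
  cross-tabulations only; dates get agreement plus the day-difference
  distribution instead. The test of $\kappa = 0$ uses the asymptotic null
  standard error
  $SE_0 = \sqrt{p_e + p_e^2 - \sum_i \hat p_{i\cdot}\hat p_{\cdot i}
  (\hat p_{i\cdot} + \hat p_{\cdot i})} \big/ \big((1-p_e)\sqrt{N}\big)$
  and a two-tailed normal reference. Degenerate margins ($p_e = 1$) raise
  an error rather than returning a value.
* **Indicators**: seven proportions and three medians
  (`builtin_definitions()`). "Within *k* days" is inclusive (≤ *k*) by
  default and configurable per definition; "prior to" is strict. A
  documented dental or physiotherapy consult whose date is unrecorded still
  counts in the numerator — the date, when present, must verify the
  ordering; requiring it unconditionally would let MED date-missingness
  masquerade as worse care. Differences are computed on the rounded
  one-decimal percentages, matching how such tables are assembled in
  practice.

## Numerical and degenerate-input choices

Empty event sets extract to all-missing dates and `FALSE` flags; an empty
indicator denominator yields a missing percentage rather than an error;
an empty MED makes coverage undefined (error). Conditional variables follow
registry recording practice: neck dissection, complications and
reoperations are recorded in the MED only for surgical patients, dental and
physiotherapy contacts only when they occurred — so "records with data
present" differs by variable exactly as it does in real registries.
All randomness flows from one root seed through fixed per-stage derived
seeds, making every pipeline run reproducible from its persisted
configuration; identical configurations give byte-identical outputs.

## What the tests show — and what they cannot

The suite checks the chain at three levels: field rules, agreement
counting, kappa and indicator counting against independent brute-force
implementations on hundreds of random small instances; the end-to-end null
configuration (identity profile, 262 patients: 100% agreement everywhere,
zero indicator differences); and stochastic recovery — injected
per-variable disagreement rates recovered from 20 replicates of 1000
patients within three binomial standard deviations, and the inpatient-only
physiotherapy gap pushing the automatic indicator below the manual one in
at least 19 of 20 replicates. Simulation sizes (80–1000 patients, 20
replicates) were chosen so the binomial bands are tight relative to the
injected effects.

The generator emulates the *structure* of the discrepancies, not their
full clinical texture: error modes are independent across patients and
variables, waiting times are stationary over the year, there is no
within-week case-mix, no free text, and the terminology is a fixed
eight-row ICD-10 mapping. Passing tests therefore demonstrate that the
estimators and rules are correct and that the documented fault modes have
the claimed directional consequences — not that any particular hospital's
extraction logic is valid. The package's ten indicator definitions encode
one defensible reading of audit definitions that are not fully
computer-interpretable (notably: "started adjuvant therapy" is read as
*received*, and window boundaries as inclusive); where a registry reads
them differently, the definitions are configurable and serializable to
YAML for audit.

## A minimal run

```{r example, eval = FALSE}
res <- run_pipeline(list(
  seed = 42,
  cohort = list(n = 330, exclusion_frac = 68 / 330, n_aed_only = 45),
  profile = unclass(study_profile()),
  rules = list(systemic_round_cutoff_weeks = Inf)  # pre-fix engine
))
res$coverage
res$agreement
res$comparison
```

`scripts/acceptance.R` runs exactly this configuration from the command
line and writes the headline quantities as JSON.
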