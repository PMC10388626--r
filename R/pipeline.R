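#' Default pipeline configuration
#'
#' @return A nested list: `seed`, `year`, `cohort` (size `n`,
#'   `exclusion_frac`, `n_aed_only` dashboard-only patients,
#'   `localization_weights`), `pathway` ([pathway_config()] arguments),
#'   `profile` ([discrepancy_profile()] arguments), `rules`
#'   ([extraction_rules()] arguments) and `out_dir` (optional output
#'   directory; `NULL` keeps everything in memory).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    year = 2020L,
    cohort = list(n = 262L, exclusion_frac = 0, n_aed_only = 0L,
                  localization_weights = localization_table()$weight),
    pathway = list(),
    profile = list(),
    rules = list(),
    out_dir = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every missing field with its default, range-checks all
#' probabilities and day counts through the stage constructors, and returns
#' the fully expanded configuration. Normalization is idempotent:
#' `validate_config(validate_config(x))` equals `validate_config(x)`.
#'
#' @param config Partial configuration list (possibly empty or read from
#'   YAML).
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (!is.list(config)) stop("`config` must be a list", call. = FALSE)
  cfg <- utils::modifyList(default_config(), config)
  # modifyList drops NULL-valued entries; out_dir = NULL is meaningful
  if (!"out_dir" %in% names(cfg)) cfg["out_dir"] <- list(NULL)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!is.numeric(cfg$year) || length(cfg$year) != 1) {
    stop("`year` must be a single integer year", call. = FALSE)
  }
  if (!is.numeric(cfg$cohort$n) || cfg$cohort$n < 1) {
    stop("`cohort$n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cfg$cohort$n_aed_only) || cfg$cohort$n_aed_only < 0) {
    stop("`cohort$n_aed_only` must be a non-negative integer", call. = FALSE)
  }
  assert_prob(cfg$cohort$exclusion_frac, "cohort$exclusion_frac")
  # the stage constructors validate and expand their own argument lists
  cfg$pathway <- unclass(do.call(pathway_config, cfg$pathway))
  cfg$profile <- unclass(do.call(discrepancy_profile, cfg$profile))
  cfg$rules <- unclass(do.call(extraction_rules, cfg$rules))
  cfg$seed <- as.integer(cfg$seed)
  cfg$year <- as.integer(cfg$year)
  cfg$cohort$n <- as.integer(cfg$cohort$n)
  cfg$cohort$n_aed_only <- as.integer(cfg$cohort$n_aed_only)
  cfg
}

#' @noRd
linked_halves <- function(linked) {
  pairs <- linked$pairs
  vars <- setdiff(abstract_schema(), "patient_id")
  med <- pairs[c("patient_id", paste0(vars, "_med"))]
  aed <- pairs[c("patient_id", paste0(vars, "_aed"))]
  names(med) <- names(aed) <- c("patient_id", vars)
  list(med = tibble::as_tibble(med), aed = tibble::as_tibble(aed))
}

#' Run the full simulate-extract-validate-report pipeline
#'
#' Orchestrates the stages: synthetic cohort and event-log generation,
#' manual-abstract derivation (MED), automated extraction (AED), record
#' linkage with coverage, study-criteria filtering of both datasets,
#' per-variable agreement, date-difference distributions, the localization
#' cross-tabulation with Cohen's kappa, and the ten quality indicators
#' compared manual versus automatic. All randomness flows from the root
#' `seed` via fixed per-stage derived seeds, so a run is reproducible from
#' its configuration alone.
#'
#' @param config Configuration list (see [default_config()]); normalized
#'   internally with [validate_config()].
#' @param quiet Suppress per-stage log messages.
#' @return A list with the stage outputs: `config`, `registry`, `events`,
#'   `med`, `aed`, `linked_full`, `coverage`, `disposition_med`,
#'   `disposition_aed`, `linked` (after filtering), `agreement`,
#'   `date_diffs`, `localization_crosstab`, `localization_kappa`,
#'   `manual_indicators`, `automatic_indicators`, `comparison`, `summary`.
#'   When `config$out_dir` is set, all stage outputs are also written there
#'   (events.jsonl, registry.csv, med.csv, aed.csv, truth.csv,
#'   disposition.csv, linkage.csv, agreement.csv, datediffs.csv,
#'   localization_crosstab.csv, indicators.csv, summary.json).
#' @export
run_pipeline <- function(config = list(), quiet = TRUE) {
  cfg <- validate_config(config)
  say <- function(stage, fmt, ...) {
    if (!quiet) {
      message(sprintf("[%s] seed=%d %s", stage, cfg$seed, sprintf(fmt, ...)))
    }
  }
  profile <- do.call(discrepancy_profile, cfg$profile)
  pathway <- do.call(pathway_config, cfg$pathway)
  rules <- do.call(extraction_rules, cfg$rules)

  # --- simulate ------------------------------------------------------------
  registry <- generate_cohort(
    cfg$cohort$n, cfg$cohort$localization_weights,
    seed = derive_seed(cfg$seed, "cohort"),
    exclusion_frac = cfg$cohort$exclusion_frac, year = cfg$year
  )
  if (cfg$cohort$n_aed_only > 0) {
    # dashboard-only patients: ICD-10-included in the EHR but outside the
    # manual registry's population (they fail the study criteria later)
    extra <- generate_cohort(
      cfg$cohort$n_aed_only, cfg$cohort$localization_weights,
      seed = derive_seed(cfg$seed, "extra"), year = cfg$year
    )
    extra$patient_id <- sub("^P", "X", extra$patient_id)
    extra$histology <- "skin"
    registry_all <- dplyr::bind_rows(registry, extra)
  } else {
    registry_all <- registry
  }
  events <- generate_event_log(
    registry_all, pathway, profile, seed = derive_seed(cfg$seed, "events")
  )
  say("simulate", "%d registry rows, %d events",
      nrow(registry_all), nrow(events))

  # --- abstract both ways --------------------------------------------------
  med <- derive_manual_abstract(
    events[events$patient_id %in% registry$patient_id, ], registry,
    profile, seed = derive_seed(cfg$seed, "med")
  )
  in_aed <- withr::with_seed(
    derive_seed(cfg$seed, "aed_membership"),
    stats::runif(nrow(registry_all)) >= profile$p_missing_from_aed
  )
  aed_registry <- registry_all[in_aed, ]
  aed <- extract_dataset(
    events[events$patient_id %in% aed_registry$patient_id, ],
    aed_registry, rules
  )
  say("abstract", "MED %d rows, AED %d rows", nrow(med), nrow(aed))

  # --- link and filter -----------------------------------------------------
  linked_full <- link_datasets(med, aed)
  cov <- coverage(linked_full)
  fmed <- apply_criteria(med, registry_all, cfg$year)
  faed <- apply_criteria(aed, registry_all, cfg$year)
  linked <- link_datasets(fmed$abstracts, faed$abstracts)
  say("link", "coverage %.2f%%, %d linked after criteria", cov,
      linked$n_linked)

  # --- validate ------------------------------------------------------------
  agreement <- agreement_table(linked)
  date_diffs <- lapply(
    stats::setNames(nm = abstract_date_vars()),
    function(v) date_diff_distribution(linked, v)
  )
  crosstab <- linked_crosstab(linked, "localization",
                              levels = localization_levels())
  loc_kappa <- tryCatch(cohen_kappa(crosstab), error = function(e) NULL)

  # --- indicators ----------------------------------------------------------
  halves <- linked_halves(linked)
  iman <- compute_indicators(halves$med)
  iaut <- compute_indicators(halves$aed)
  comparison <- comparison_table(iman, iaut)
  say("indicators", "%d comparison rows", nrow(comparison))

  summary <- list(
    seed = cfg$seed,
    n_med = linked_full$n_med, n_aed = linked_full$n_aed,
    n_linked = linked_full$n_linked,
    coverage = cov,
    n_included = linked$n_linked,
    agreement = agreement,
    localization_kappa = if (!is.null(loc_kappa)) {
      loc_kappa[c("kappa", "p_value", "n")]
    },
    comparison = comparison
  )

  result <- list(
    config = cfg, registry = registry_all, events = events,
    med = med, aed = aed, linked_full = linked_full, coverage = cov,
    disposition_med = fmed$disposition, disposition_aed = faed$disposition,
    linked = linked, agreement = agreement, date_diffs = date_diffs,
    localization_crosstab = crosstab, localization_kappa = loc_kappa,
    manual_indicators = iman, automatic_indicators = iaut,
    comparison = comparison, summary = summary
  )

  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(result, cfg$out_dir, registry_all, profile)
    say("report", "outputs written to %s", cfg$out_dir)
  }
  result
}

#' @noRd
write_pipeline_outputs <- function(result, out_dir, registry_all, profile) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_events_jsonl(result$events, p("events.jsonl"))
  write_patient_csv(result$registry, p("registry.csv"))
  write_patient_csv(result$med, p("med.csv"))
  write_patient_csv(result$aed, p("aed.csv"))
  truth <- derive_manual_abstract(
    result$events[result$events$patient_id %in%
                    result$med$patient_id, ],
    registry_all[registry_all$patient_id %in% result$med$patient_id, ],
    discrepancy_profile()
  )
  write_patient_csv(truth, p("truth.csv"))
  write_patient_csv(
    dplyr::bind_rows(
      med = result$disposition_med, aed = result$disposition_aed,
      .id = "source"),
    p("disposition.csv"))
  write_patient_csv(result$linked_full$indicator, p("linkage.csv"))
  write_patient_csv(result$agreement, p("agreement.csv"))
  dd <- dplyr::bind_rows(
    lapply(result$date_diffs, as.data.frame), .id = "variable")
  write_patient_csv(tibble::as_tibble(dd), p("datediffs.csv"))
  utils::write.csv(as.data.frame(result$localization_crosstab),
                   p("localization_crosstab.csv"), row.names = FALSE)
  write_patient_csv(result$comparison, p("indicators.csv"))
  summary <- result$summary
  summary$agreement <- as.data.frame(summary$agreement)
  summary$comparison <- as.data.frame(summary$comparison)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(out_dir)
}
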