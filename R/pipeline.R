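#' Default modelling column sets
#'
#' The adjustment sets used throughout: maternal models adjust for age,
#' race, clinic (socioeconomic proxy), weight status, daily energy and fat
#' intake and moderate physical activity; neonatal models additionally
#' adjust for gestational age at measurement.
#'
#' @return Character vectors of column names.
#' @export
maternal_covariates <- function() {
  c("age", "race", "clinic", "weight_status", "energy_kcal_per_day",
    "fat_g_per_day", "moderate_pa_pct")
}

#' @rdname maternal_covariates
#' @export
neonatal_covariates <- function() {
  c(maternal_covariates(), "gestational_age_at_measure")
}

#' @rdname maternal_covariates
#' @export
default_outcomes <- function() {
  c("gwg_kg", "thigh_skinfold_mm", "subscap_skinfold_mm",
    "neonate_bodyfat_pct")
}

neonatal_outcomes <- function() {
  c("thigh_skinfold_mm", "subscap_skinfold_mm", "neonate_bodyfat_pct")
}

#' Read a cohort covariate/outcome table
#'
#' Reads the subjects-by-variables CSV consumed by the modelling stage. An
#' optional mapping file (CSV with columns `from`, `to`) renames deposited
#' columns onto the documented schema; every applied renaming is reported
#' with a message so schema discrepancies are logged, never silently
#' patched.
#'
#' @param path Cohort CSV path.
#' @param mapping Optional path to a `from,to` mapping CSV, or a named
#'   character vector (`c(new_name = "old_name")`).
#' @return A validated cohort tibble with `race`, `clinic` and
#'   `weight_status` as factors (reference levels Caucasian, low_income,
#'   lean).
#' @export
read_cohort <- function(path, mapping = NULL) {
  cohort <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_guess()
  ))
  if (!is.null(mapping)) {
    if (is.character(mapping) && is.null(names(mapping))) {
      map_tbl <- readr::read_csv(mapping, col_types = "cc")
      mapping <- setNames(map_tbl$from, map_tbl$to)
    }
    for (new in names(mapping)) {
      old <- mapping[[new]]
      if (!old %in% names(cohort)) {
        abort(sprintf("mapping refers to absent column `%s`.", old))
      }
      inform(sprintf("cohort column `%s` mapped to `%s`.", old, new))
      names(cohort)[names(cohort) == old] <- new
    }
  }
  required <- c("subject_id", "pei_upf", "age", "race", "clinic",
                "weight_status")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table lacks columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (spec in list(c("race", "Caucasian", "AfricanAmerican_other"),
                    c("clinic", "low_income", "high_income"),
                    c("weight_status", "lean", "obese"))) {
    col <- spec[1]
    levels <- spec[-1]
    bad <- setdiff(unique(as.character(cohort[[col]])), levels)
    if (length(bad) > 0) {
      abort(sprintf("`%s` has unknown level(s): %s", col,
                    paste(bad, collapse = ", ")))
    }
    cohort[[col]] <- factor(as.character(cohort[[col]]), levels = levels)
  }
  for (col in intersect(c("pei_upf", "hei2010"), names(cohort))) {
    v <- cohort[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      abort(sprintf("`%s` must lie in [0, 100].", col))
    }
  }
  cohort
}

#' Write a cohort table
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Merge scored dietary indices into a cohort table
#'
#' Replaces the cohort's `pei_upf` column with the value scored from the
#' FFQ by [score_intake()]. Only the energy *share* is carried over by
#' default: shares are robust to the size of the food inventory, whereas
#' absolute energy and fat intakes from a reduced inventory are not
#' comparable to covariates derived from a full one; pass them in
#' `columns` to carry them too.
#'
#' @param cohort A cohort tibble.
#' @param profiles An `intake_profiles` object.
#' @param columns Scored columns to transfer: any of `pei_upf`,
#'   `energy_kcal_per_day`, `fat_g_per_day`.
#' @return The cohort tibble with the scored columns substituted.
#' @export
assemble_cohort <- function(cohort, profiles, columns = "pei_upf") {
  scored <- profiles$subjects %>%
    transmute(.data$subject_id,
              pei_upf = .data$pei_upf,
              energy_kcal_per_day = .data$energy_kcal,
              fat_g_per_day = .data$fat_g)
  missing_subj <- setdiff(cohort$subject_id, scored$subject_id)
  if (length(missing_subj) > 0) {
    abort(sprintf("no scored intake for subject(s): %s",
                  paste(missing_subj, collapse = ", ")))
  }
  idx <- match(cohort$subject_id, scored$subject_id)
  for (col in columns) {
    if (!col %in% names(scored)) abort(sprintf("unknown scored column `%s`.", col))
    cohort[[col]] <- scored[[col]][idx]
  }
  cohort
}

round_report <- function(tbl) {
  # display rounding: one decimal for magnitudes >= 0.1, scientific below
  fmt <- function(x) {
    if (!is.numeric(x)) return(x)
    vapply(x, function(v) {
      if (!is.finite(v)) return(NA_character_)
      if (v == 0) return("0")
      if (abs(v) >= 0.1) formatC(v, format = "f", digits = 1)
      else formatC(v, format = "e", digits = 1)
    }, character(1))
  }
  tbl %>% mutate(across(dplyr::where(is.numeric), fmt))
}

#' Run the full scoring and modelling pipeline
#'
#' Executes, in order: imputation of missing FFQ answers, intake scoring,
#' outcome models (one per configured outcome, with the
#' focal-by-weight-status interaction forced and the focal-by-age
#' interaction screened alongside the other focal interactions),
#' dietary-index comparison, and the single-index p-value table. Every
#' stage writes a CSV report into `out_dir` (models additionally as
#' display-rounded companions), a plain-text log records row counts and
#' seeds, and `run_summary.json` captures the run machine-readably. With
#' identical inputs and seed the outputs are byte-identical.
#'
#' @param config A list (or path to a YAML file) with elements
#'   `instrument`, `composition`, `nova_map`, `responses`, `cohort` (input
#'   paths), `out_dir`, `seed`, and optionally `alpha` (default 0.05) and
#'   logical step toggles `impute`, `score`, `fit`, `compare` (all default
#'   `TRUE`).
#' @return Invisibly, a list with the fitted objects and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, impute = TRUE, score = TRUE, fit = TRUE,
                   compare = TRUE)
  config <- modifyList(defaults, config)
  for (key in c("out_dir", "seed")) {
    if (is.null(config[[key]])) abort(sprintf("config lacks `%s`.", key))
  }
  if (config$fit && !config$score && is.null(config$cohort)) {
    abort("modelling requested without scoring and without a cohort table.")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  written <- character()
  emit <- function(tbl, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(tbl, p, na = "")
    written <<- c(written, p)
    p
  }

  say("upfdiet pipeline, package version %s, seed %d",
      as.character(utils::packageVersion("upfdiet")), config$seed)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      say("stage `%s` FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, log_path)
      abort(sprintf("pipeline aborted at stage `%s`: %s", name,
                    conditionMessage(e)))
    })
  }

  instrument <- stage("read", read_instrument(config$instrument))
  foods <- stage("read", read_food_table(config$composition, config$nova_map))
  responses <- stage("read", read_responses(config$responses, foods, instrument))
  say("read %d response rows for %d subjects, %d food items",
      nrow(responses), length(unique(responses$subject_id)), nrow(foods))
  cohort <- NULL
  if (!is.null(config$cohort)) {
    cohort <- stage("read", read_cohort(config$cohort, config$cohort_mapping))
    say("read cohort table: %d subjects", nrow(cohort))
  }

  imp <- NULL
  if (config$impute) {
    imp <- stage("impute",
                 impute_responses(responses, foods, seed = config$seed))
    say("imputed %d missing cells in %d sweep(s)", sum(imp$oob$n_missing),
        imp$n_iter)
    emit(imp$oob, "imputation_report.csv")
    responses <- imp$responses
  }

  profiles <- NULL
  shares <- NULL
  if (config$score) {
    profiles <- stage("score", score_intake(responses, foods, instrument))
    shares <- group_share_table(profiles)
    say("scored %d subjects; mean PEI-UPF %.2f", nrow(profiles$subjects),
        mean(profiles$subjects$pei_upf))
    emit(profiles$subjects, "intake_subjects.csv")
    emit(shares, "group_shares.csv")
    if (!is.null(cohort)) cohort <- assemble_cohort(cohort, profiles)
  }

  fits <- list()
  comparison <- NULL
  p_table <- NULL
  if (config$fit) {
    if (is.null(cohort)) abort("modelling requires a cohort table.")
    outcomes <- intersect(default_outcomes(), names(cohort))
    candidates <- paste("pei_upf",
                        c("age", "race", "clinic", "moderate_pa_pct",
                          "energy_kcal_per_day", "fat_g_per_day"), sep = ":")
    for (oc in outcomes) {
      covs <- if (oc %in% neonatal_outcomes()) neonatal_covariates()
              else maternal_covariates()
      fits[[oc]] <- stage("fit", fit_ancova(
        cohort, outcome = oc, focal = "pei_upf",
        covariates = setdiff(covs, "weight_status") %>% c("weight_status"),
        forced = "pei_upf:weight_status",
        candidates = candidates, alpha = config$alpha))
      say("fitted %s: adj R^2 %.3f, retained [%s]", oc,
          fits[[oc]]$adj_r_squared,
          paste(fits[[oc]]$design$retained, collapse = ", "))
      emit(tidy(fits[[oc]]), sprintf("model_%s_full.csv", oc))
      emit(round_report(tidy(fits[[oc]])), sprintf("model_%s.csv", oc))
    }
    if (config$compare && "hei2010" %in% names(cohort)) {
      comparison <- bind_rows(lapply(outcomes, function(oc) {
        covs <- if (oc %in% neonatal_outcomes()) neonatal_covariates()
                else maternal_covariates()
        stage("compare", compare_indices(
          cohort, outcome = oc, index_a = "pei_upf", index_b = "hei2010",
          covariates = covs, forced_a = "pei_upf:weight_status"))
      }))
      emit(comparison, "index_comparison.csv")
      indices <- intersect(c("pei_upf", "hei2010", "energy_kcal_per_day",
                             "fat_g_per_day"), names(cohort))
      p_table <- stage("compare", single_index_pvalues(
        cohort, indices = indices, outcomes = outcomes,
        covariates = setdiff(maternal_covariates(),
                             c("energy_kcal_per_day", "fat_g_per_day")),
        neonatal_outcomes = neonatal_outcomes()))
      emit(p_table, "single_index_pvalues.csv")
    }
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("upfdiet")),
    seed = config$seed,
    alpha = config$alpha,
    n_response_rows = nrow(responses),
    n_subjects_scored = if (is.null(profiles)) 0L else nrow(profiles$subjects),
    n_cells_imputed = if (is.null(imp)) 0L else sum(imp$oob$n_missing),
    outcomes_fitted = names(fits),
    files = basename(written)
  )
  json_path <- file.path(config$out_dir, "run_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, log_path)

  invisible(list(imputation = imp, profiles = profiles, shares = shares,
                 fits = fits, comparison = comparison, p_table = p_table,
                 cohort = cohort,
                 files = c(written, json_path, log_path)))
}

#' Write a complete synthetic input bundle
#'
#' Generates a cohort and matching FFQ responses from `config` and writes
#' everything the pipeline consumes — instrument YAML, composition and
#' NOVA-map CSVs, the (masked) response table and the cohort table — into
#' `dir`, so a full [run_pipeline()] invocation can be driven from files
#' alone.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param instrument,foods Instrument and food list to use; the packaged
#'   defaults when omitted.
#' @return Invisibly, a named list of the paths written plus the generated
#'   objects (`cohort`, `targets`, `responses_complete`).
#' @export
write_simulation_bundle <- function(config, dir,
                                    instrument = default_instrument(),
                                    foods = default_food_table()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_responses(config, instrument, foods)
  paths <- list(
    instrument = file.path(dir, "instrument.yaml"),
    composition = file.path(dir, "composition.csv"),
    nova_map = file.path(dir, "nova_map.csv"),
    responses = file.path(dir, "responses.csv"),
    cohort = file.path(dir, "cohort.csv")
  )
  write_instrument(instrument, paths$instrument)
  write_food_table(foods, paths$composition, paths$nova_map)
  write_responses(gen$responses, paths$responses)
  write_cohort(gen$cohort, paths$cohort)
  invisible(c(paths, list(cohort = gen$cohort, targets = gen$targets,
                          responses_complete = gen$responses_complete)))
}
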