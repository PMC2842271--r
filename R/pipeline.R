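#' Pipeline run configuration
#'
#' Exactly one input source must be given: either paths to the four real
#' input tables (recalls, composition, nutrients, subjects; delimited
#' files readable by [readr::read_csv()]) or a synthetic
#' [scenario_config()].
#'
#' @param scenario a [scenario_config()], or `NULL` when reading tables.
#' @param paths named list/character with elements `recalls`,
#'   `composition`, `nutrients`, `subjects`, or `NULL` for synthetic runs.
#' @param scheme a [cutoff_scheme()].
#' @param mix a [sweetener_mix()].
#' @param weighted_quartiles logical, passed to [prepare_cohort()].
#' @param output_dir directory for output tables and the manifest;
#'   created if missing.  `NULL` disables writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, paths = NULL,
                       scheme = cutoff_scheme("cdc"), mix = sweetener_mix(),
                       weighted_quartiles = FALSE, output_dir = NULL) {
  if (is.null(scenario) == is.null(paths)) {
    stop_config("provide exactly one of 'scenario' or 'paths'")
  }
  if (!is.null(paths)) {
    need <- c("recalls", "composition", "nutrients", "subjects")
    if (!all(need %in% names(paths))) {
      stop_config("paths must name: ", paste(need, collapse = ", "))
    }
  }
  structure(list(scenario = scenario, paths = paths, scheme = scheme,
                 mix = mix, weighted_quartiles = weighted_quartiles,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Supported keys: `scenario` (a mapping of [scenario_config()] arguments,
#' with `effect_log_odds` given as per-level odds-ratio lists under
#' `effect_odds_ratios` or log-odds under `effect_log_odds`), `paths`,
#' `scheme` (label or `{scheme: custom, male_cutoff: , female_cutoff: }`),
#' `mix` (mapping of [sweetener_mix()] arguments), `weighted_quartiles`,
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    if (!is.null(sc$effect_odds_ratios)) {
      sc$effect_log_odds <- lapply(sc$effect_odds_ratios,
                                   function(v) log(unlist(v)))
      sc$effect_odds_ratios <- NULL
    } else if (!is.null(sc$effect_log_odds)) {
      sc$effect_log_odds <- lapply(sc$effect_log_odds, unlist)
    }
    scenario <- do.call(scenario_config, sc)
  }
  scheme <- if (is.list(y$scheme)) do.call(cutoff_scheme, y$scheme)
            else cutoff_scheme(y$scheme %||% "cdc")
  mix <- if (is.null(y$mix)) sweetener_mix() else do.call(sweetener_mix, y$mix)
  run_config(scenario = scenario, paths = y$paths, scheme = scheme, mix = mix,
             weighted_quartiles = isTRUE(y$weighted_quartiles),
             output_dir = y$output_dir)
}

read_input_tables <- function(paths) {
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  list(recalls = rd(paths$recalls), composition = rd(paths$composition),
       nutrients = rd(paths$nutrients), subjects = rd(paths$subjects))
}

#' Run the full analysis pipeline
#'
#' Orchestrates: synthetic data generation (or table loading), intake
#' estimation, exclusions and cohort preparation, survey-weighted
#' descriptives by hyperuricemia status, uric-acid mean comparisons with
#' Dunnett reference across fructose/alcohol/fiber groups, crude and
#' adjusted logistic risk models, and the cut-off sensitivity analysis.
#' When `output_dir` is set, all tables are written as CSV together with a
#' JSON manifest (config, seed, cut-offs, quartile cutpoints, model
#' formulas) from which every number is reproducible.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `inputs`,
#'   `intakes`, `exclusion_audit`, `cohort`, `descriptives`,
#'   `mean_tables`, `risk_results`, `sensitivity`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$scenario)) simulate_scenario(config$scenario, config$mix)
    else read_input_tables(config$paths)
  })

  excl <- stage("exclusions",
                exclude_subjects(inputs$subjects, inputs$recalls))
  intakes <- stage("intake_estimation", estimate_intakes(
    excl$recalls, inputs$composition, inputs$nutrients, config$mix,
    energy = excl$subjects
  ))
  cohort <- stage("cohort_prep", prepare_cohort(
    excl$subjects, intakes, config$scheme, config$weighted_quartiles
  ))

  desc_vars <- intersect(
    c("age", "bmi", "energy_kcal", "protein_g", "fat_pct_energy",
      "natural_unbound_g", "added_unbound_g", "all_added_g", "total_g",
      "fiber_g", "vitamin_c_mg", "alcohol_g", "caffeine_mg",
      "total_sugars_g", "uric_mg_dl"),
    names(cohort)
  )
  descriptives <- stage("descriptives",
                        weighted_descriptives(cohort, desc_vars))

  exposures <- c(added_unbound_fructose_q = "added_unbound_fructose_q",
                 all_added_fructose_q = "all_added_fructose_q",
                 total_fructose_q = "total_fructose_q",
                 alcohol_level = "alcohol_level", fiber_q = "fiber_q")
  adjust_for <- function(expo) setdiff(
    c("sex", "age_group", "race", "education", "bmi_category", "energy_q",
      "protein_q", "fat_q", "vitamin_c_q", "fiber_q", "caffeine_q",
      "alcohol_level", "total_fructose_q"),
    expo
  )
  # the 13-variable adjusted model: demographics + intake quartiles +
  # alcohol level + one fructose form (swapped out when it is the exposure)
  adjusted_covars <- function(expo) {
    covs <- adjust_for(expo)
    if (!grepl("fructose", expo)) covs else setdiff(covs, "total_fructose_q")
  }

  mean_tables <- stage("compare_means", {
    lapply(exposures, function(expo) list(
      unadjusted = compare_means(cohort, "uric_mg_dl", expo),
      adjusted = compare_means(cohort, "uric_mg_dl", expo,
                               covariates = adjusted_covars(expo))
    ))
  })
  risk_results <- stage("risk_models", {
    lapply(exposures, function(expo) list(
      unadjusted = fit_logit(cohort, expo),
      adjusted = fit_logit(cohort, expo, covariates = adjusted_covars(expo))
    ))
  })
  sensitivity <- stage("sensitivity",
                       sensitivity_cutoffs(cohort, names(exposures)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fructuric")),
    seed = if (!is.null(config$scenario)) config$scenario$seed else NULL,
    scenario = if (!is.null(config$scenario))
      config$scenario[setdiff(names(config$scenario), "effect_log_odds")]
      else NULL,
    planted_log_odds = if (!is.null(config$scenario))
      config$scenario$effect_log_odds else NULL,
    input_paths = config$paths,
    scheme = unclass(config$scheme),
    sweetener_mix = unclass(config$mix),
    weighted_quartiles = config$weighted_quartiles,
    quartile_cutpoints = attr(cohort, "cutpoints"),
    exclusions = as.list(setNames(excl$audit$n, excl$audit$reason)),
    adjusted_model_covariates = lapply(
      setNames(names(exposures), names(exposures)), adjusted_covars)
  )

  res <- structure(
    list(inputs = inputs, intakes = intakes, exclusion_audit = excl$audit,
         cohort = cohort, descriptives = descriptives,
         mean_tables = mean_tables, risk_results = risk_results,
         sensitivity = sensitivity, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config$output_dir)
  res
}

risk_result_table <- function(rr_list) {
  rows <- list()
  for (expo in names(rr_list)) {
    for (type in c("unadjusted", "adjusted")) {
      rr <- rr_list[[expo]][[type]]
      tab <- rr$table
      rows[[length(rows) + 1L]] <- tibble::tibble(
        exposure = expo, model = type, level = tab$level,
        or = round(tab$or, 3), ci_low = round(tab$ci_low, 3),
        ci_high = round(tab$ci_high, 3), p = tab$p,
        model_p = rr$model_p, gof_p = rr$gof_p
      )
    }
  }
  dplyr::bind_rows(rows)
}

mean_table_rows <- function(mt_list) {
  rows <- list()
  for (expo in names(mt_list)) {
    for (type in c("unadjusted", "adjusted")) {
      mt <- mt_list[[expo]][[type]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        exposure = expo, model = type, group = mt$table$group,
        n = mt$table$n, mean = round(mt$table$mean, 2),
        sd = round(mt$table$sd, 2),
        adjusted_mean = round(mt$table$adjusted_mean, 2),
        p_vs_reference = mt$table$p_vs_reference, model_p = mt$model_p
      )
    }
  }
  dplyr::bind_rows(rows)
}

write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) readr::write_csv(
    x, file.path(output_dir, paste0(name, ".csv")), progress = FALSE)
  wr(tibble::as_tibble(res$intakes), "fructose_intakes")
  wr(attr(res$intakes, "audit"), "imputation_audit")
  wr(res$exclusion_audit, "exclusion_audit")
  cohort_out <- tibble::as_tibble(res$cohort)
  wr(cohort_out, "cohort")
  wr(dplyr::mutate(res$descriptives,
                   dplyr::across(c("mean", "median", "sd"), ~ round(.x, 2))),
     "descriptives")
  wr(mean_table_rows(res$mean_tables), "uric_acid_means")
  wr(risk_result_table(res$risk_results), "odds_ratios")
  wr(dplyr::mutate(res$sensitivity$rates,
                   rate = round(.data$rate, 2)), "sensitivity_rates")
  jsonlite::write_json(res$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", nrow(x$cohort), "subjects in analysis cohort\n")
  prev <- 100 * mean(x$cohort$hyperuricemic)
  cat(sprintf("  hyperuricemia prevalence: %.2f%% (%s scheme)\n", prev,
              attr(x$cohort, "scheme")$label))
  cat("  exposures modelled:", paste(names(x$risk_results), collapse = ", "), "\n")
  invisible(x)
}

#' Cut-off sensitivity analysis
#'
#' Re-classifies the cohort under both the CDC (>8.4/>7.5 mg/dL) and the
#' legacy (>7/>6 mg/dL) schemes, reports prevalence under each, rate
#' tables (% hyperuricemic, weighted and unweighted) by level of each
#' exposure, and refits the crude logistic models under both outcome
#' definitions.
#'
#' @param cohort a [prepare_cohort()] result (any scheme).
#' @param exposures character vector of categorical exposure columns.
#' @return list with `prevalence` (tibble: scheme, rate %), `rates`
#'   (tibble: scheme, exposure, level, weighting, rate %), `risk`
#'   (nested list of crude `risk_result`s by scheme and exposure).
#' @export
sensitivity_cutoffs <- function(cohort,
                                exposures = c("total_fructose_q",
                                              "all_added_fructose_q",
                                              "alcohol_level", "fiber_q")) {
  schemes <- list(cdc = cutoff_scheme("cdc"), legacy = cutoff_scheme("legacy"))
  exposures <- intersect(exposures, names(cohort))
  rates <- list(); prev <- list(); risk <- list()
  for (snm in names(schemes)) {
    status <- classify_hyperuricemia(cohort$uric_mg_dl, cohort$sex,
                                     schemes[[snm]])
    prev[[snm]] <- tibble::tibble(scheme = snm, rate = 100 * mean(status))
    tmp <- cohort
    tmp$hyperuricemic <- status
    risk[[snm]] <- lapply(setNames(exposures, exposures),
                          function(e) fit_logit(tmp, e))
    for (e in exposures) {
      for (lv in sort(unique(cohort[[e]]))) {
        in_l <- cohort[[e]] == lv
        w <- cohort$weight %||% rep(1, nrow(cohort))
        rates[[length(rates) + 1L]] <- tibble::tibble(
          scheme = snm, exposure = e, level = lv,
          weighting = c("unweighted", "weighted"),
          rate = c(100 * mean(status[in_l]),
                   100 * sum(w[in_l] * status[in_l]) / sum(w[in_l]))
        )
      }
    }
  }
  list(prevalence = dplyr::bind_rows(prev), rates = dplyr::bind_rows(rates),
       risk = risk)
}
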