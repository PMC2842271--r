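#' Scenario configuration for the synthetic-data generator
#'
#' Defines a fully reproducible synthetic study: a food/commodity database,
#' a cohort of adult subjects with one-day dietary recalls, and a planted
#' hyperuricemia risk structure.  Defaults emulate the population the
#' analysis targets: U.S. adults aged 20-80, hyperuricemia prevalence near
#' 2.5% under sex-specific cut-offs (>8.4 mg/dL men, >7.5 mg/dL women),
#' alcohol raising risk (level-4 odds ratio 1.8), fiber lowering it
#' (quartile-4 odds ratio 0.45), and fructose null.
#'
#' @param n_subjects number of subjects (>= 40).
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @param prevalence_target target hyperuricemia prevalence in the
#'   generated cohort (default 0.025).
#' @param effect_log_odds named list of per-level log-odds increments
#'   relative to level 1, for exposures `alcohol` (4 levels), `fiber`
#'   (4 quartiles) and `fructose` (4 quartiles).  First element of each
#'   vector must be 0.
#' @param sex_cutoffs named numeric `c(male = , female = )` serum uric acid
#'   cut-offs in mg/dL used when generating concentrations.
#' @param food_db_size number of synthetic foods.
#' @param commodity_db_size number of synthetic commodities (>= 20 so that
#'   all sweetener classes and family structure fit).
#' @param missing_fructose_fraction proportion of fructose-containing
#'   natural commodities whose direct fructose value is withheld (each
#'   keeps a resolvable family link), in `[0, 1)`.
#' @param unreliable_fraction proportion of subjects whose recall is
#'   flagged unreliable (default 0.02).
#' @param disease_fraction proportion of subjects carrying a diabetes,
#'   cancer or heart-disease flag (exercises the exclusion path).
#' @param sweet_factor_sd standard deviation of the latent "sweet diet"
#'   factor that correlates fructose intake with total sugars.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_subjects = 2000,
                            seed = 1L,
                            prevalence_target = 0.025,
                            effect_log_odds = list(
                              alcohol = log(c(1, 0.8, 1.7, 1.8)),
                              fiber = log(c(1, 0.64, 0.55, 0.45)),
                              fructose = c(0, 0, 0, 0)
                            ),
                            sex_cutoffs = c(male = 8.4, female = 7.5),
                            food_db_size = 60L,
                            commodity_db_size = 80L,
                            missing_fructose_fraction = 0.2,
                            unreliable_fraction = 0.02,
                            disease_fraction = 0.06,
                            sweet_factor_sd = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 40) {
    stop_config("n_subjects must be >= 40")
  }
  if (commodity_db_size < 20) {
    stop_config("commodity_db_size must be >= 20 (zero or tiny commodity sets are invalid)")
  }
  if (food_db_size < 8) stop_config("food_db_size must be >= 8")
  check_number(prevalence_target, "prevalence_target", 1e-6, 1 - 1e-6)
  if (missing_fructose_fraction < 0 || missing_fructose_fraction >= 1) {
    stop_config("missing_fructose_fraction must be in [0, 1)")
  }
  allowed <- c("alcohol", "fiber", "fructose")
  if (!all(names(effect_log_odds) %in% allowed)) {
    stop_config("effect_log_odds names must be among: ",
                paste(allowed, collapse = ", "))
  }
  for (nm in names(effect_log_odds)) {
    v <- effect_log_odds[[nm]]
    if (length(v) != 4L || v[1] != 0 || any(!is.finite(v))) {
      stop_config("effect_log_odds$", nm,
                  " must be 4 finite values with first element 0")
    }
  }
  if (!all(c("male", "female") %in% names(sex_cutoffs)) ||
      sex_cutoffs[["male"]] <= sex_cutoffs[["female"]]) {
    stop_config("sex_cutoffs must be named c(male=, female=) with male > female")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      prevalence_target = prevalence_target,
      effect_log_odds = effect_log_odds,
      sex_cutoffs = sex_cutoffs,
      food_db_size = as.integer(food_db_size),
      commodity_db_size = as.integer(commodity_db_size),
      missing_fructose_fraction = missing_fructose_fraction,
      unreliable_fraction = unreliable_fraction,
      disease_fraction = disease_fraction,
      sweet_factor_sd = sweet_factor_sd
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario:", x$n_subjects, "subjects, seed", x$seed, "\n")
  cat("  prevalence target:", x$prevalence_target, "\n")
  cat("  planted ORs (level/quartile 4 vs 1):",
      paste(sprintf("%s=%.3g", names(x$effect_log_odds),
                    exp(vapply(x$effect_log_odds, function(v) v[4], 0))),
            collapse = ", "), "\n")
  invisible(x)
}

# The five added-sugar commodity classes, always present in the synthetic
# nutrient reference.  Nutrient values per 100 g of sugar-solids mass:
# cane/beet sugar is pure sucrose; molasses and the syrups carry free
# fructose readable directly from the reference; corn sweetener free
# fructose is resolved by the disappearance-share partition instead.
added_sugar_commodities <- function() {
  tibble::tibble(
    commodity_id = c("SUGAR_CANE_BEET", "MOLASSES", "CORN_SYRUP",
                     "CORN_SYRUP_BABY", "HONEY", "MAPLE_SYRUP",
                     "SORGHUM_SYRUP"),
    commodity_name = c("sugar, beet/cane", "molasses", "corn syrup",
                       "corn syrup for baby food", "honey",
                       "maple sugar/syrup", "sorghum syrup"),
    fructose_per_100g = c(0, 12.8, NA, NA, 40.9, 0.5, 10),
    carb_per_100g = c(100, 74.7, 100, 100, 82.4, 67, 75),
    sucrose_per_100g = c(100, 29.4, 0, 0, 0.9, 58, 25),
    is_added_sugar = TRUE,
    sweetener_class = c("cane_beet", "cane_beet", "corn_sweetener",
                        "corn_sweetener", "honey", "maple", "sorghum"),
    family_id = NA_character_
  )
}

#' Generate the synthetic food-composition and nutrient-reference tables
#'
#' Builds a commodity vocabulary containing all five added-sugar classes
#' (beet/cane sugar and molasses, corn sweeteners, honey, maple syrup,
#' sorghum syrup) plus natural commodities grouped into families
#' (fruit-like, vegetable-like, grain-like, animal-source).  A configurable
#' fraction of the fructose-containing natural commodities have their
#' direct fructose value withheld but keep a `family_id` pointing to a
#' family member with both fructose and carbohydrate values, exercising
#' ratio imputation.  Foods are mixtures of 1-4 commodities with positive
#' mass fractions summing to at most 1 (the remainder is water).
#'
#' @param config a [scenario_config()].
#' @return list with `composition` (food_id, commodity_id, fraction) and
#'   `nutrients` (the commodity reference).
#' @export
generate_food_db <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop_config("config must be a scenario_config")
  }
  set.seed(config$seed)

  added <- added_sugar_commodities()
  n_nat <- config$commodity_db_size - nrow(added)

  # Natural commodities: ~60% fructose-containing (fruit/vegetable-like),
  # the rest grains/animal-source with zero fructose.
  n_fruity <- max(6L, round(0.6 * n_nat))
  n_plain <- n_nat - n_fruity
  fam_sizes <- pmin(4L, 2L + rpois(n_fruity, 0.7))  # always covers n_fruity
  fam <- rep(seq_along(fam_sizes), fam_sizes)[seq_len(n_fruity)]
  fam_fruct_ratio <- runif(max(fam), 0.05, 0.45)  # fructose / carbohydrate, shared in family
  carb <- round(runif(n_fruity, 5, 75), 2)
  fruct <- round(carb * fam_fruct_ratio[fam] * runif(n_fruity, 0.9, 1.1), 3)
  fruct <- pmin(fruct, carb)
  fruity <- tibble::tibble(
    commodity_id = sprintf("NAT%03d", seq_len(n_fruity)),
    commodity_name = sprintf("natural commodity %d (family %d)", seq_len(n_fruity), fam),
    fructose_per_100g = fruct,
    carb_per_100g = carb,
    sucrose_per_100g = round(runif(n_fruity, 0, 0.3) * carb, 3),
    is_added_sugar = FALSE,
    sweetener_class = "none",
    family_id = NA_character_,
    .family = fam
  )

  # Withhold direct fructose for a fraction of fruity commodities, keeping
  # at least one fully-documented member per family as the imputation donor.
  if (config$missing_fructose_fraction > 0) {
    withhold <- rbinom(n_fruity, 1, config$missing_fructose_fraction) == 1
    donor <- !duplicated(fruity$.family)  # first member of each family
    withhold[donor] <- FALSE
    for (i in which(withhold)) {
      donors <- which(fruity$.family == fruity$.family[i] & !withhold)
      fruity$family_id[i] <- fruity$commodity_id[donors[1L]]
      fruity$fructose_per_100g[i] <- NA_real_
    }
  }
  fruity$.family <- NULL

  plain <- tibble::tibble(
    commodity_id = sprintf("PLN%03d", seq_len(max(0L, n_plain))),
    commodity_name = sprintf("non-fructose commodity %d", seq_len(max(0L, n_plain))),
    fructose_per_100g = 0,
    carb_per_100g = round(runif(max(0L, n_plain), 0, 80), 2),
    sucrose_per_100g = 0,
    is_added_sugar = FALSE,
    sweetener_class = "none",
    family_id = NA_character_
  )
  nutrients <- dplyr::bind_rows(added, fruity, plain)

  # Foods: archetype mixtures over the commodity vocabulary.
  n_food <- config$food_db_size
  archetype <- sample(c("fruit", "beverage", "dessert", "staple", "spread"),
                      n_food, replace = TRUE,
                      prob = c(0.25, 0.2, 0.2, 0.25, 0.1))
  # guarantee every archetype occurs
  archetype[seq_len(5)] <- c("fruit", "beverage", "dessert", "staple", "spread")
  comp <- vector("list", n_food)
  pick <- function(ids, k) ids[sample.int(length(ids), min(k, length(ids)))]
  fruity_ids <- fruity$commodity_id
  plain_ids <- plain$commodity_id
  for (i in seq_len(n_food)) {
    fid <- sprintf("FOOD%03d", i)
    rows <- switch(
      archetype[i],
      fruit = tibble::tibble(commodity_id = pick(fruity_ids, sample(1:2, 1)),
                             fraction = runif(1, 0.5, 1)),
      beverage = tibble::tibble(
        commodity_id = c("CORN_SYRUP", pick(fruity_ids, 1)),
        fraction = c(runif(1, 0.05, 0.13), runif(1, 0.01, 0.1))
      ),
      dessert = tibble::tibble(
        commodity_id = c("SUGAR_CANE_BEET", pick(c(plain_ids, fruity_ids), 2)),
        fraction = c(runif(1, 0.1, 0.35), runif(2, 0.05, 0.3))
      ),
      staple = tibble::tibble(
        commodity_id = pick(if (length(plain_ids)) plain_ids else fruity_ids,
                            sample(1:3, 1)),
        fraction = runif(1, 0.2, 0.9)
      ),
      spread = tibble::tibble(
        commodity_id = pick(c("HONEY", "MAPLE_SYRUP", "MOLASSES",
                              "SORGHUM_SYRUP", "CORN_SYRUP_BABY"), 1),
        fraction = runif(1, 0.3, 0.9)
      )
    )
    # equalize fraction length to rows, renormalise if the mixture exceeds 1
    rows$fraction <- rep_len(rows$fraction, nrow(rows)) *
      runif(nrow(rows), 0.85, 1)
    if (sum(rows$fraction) > 1) rows$fraction <- rows$fraction / (sum(rows$fraction) * 1.02)
    rows$food_id <- fid
    rows$archetype <- archetype[i]
    comp[[i]] <- rows
  }
  composition <- dplyr::bind_rows(comp) |>
    dplyr::distinct(.data$food_id, .data$commodity_id, .keep_all = TRUE) |>
    dplyr::select("food_id", "commodity_id", "fraction", "archetype")

  list(composition = composition, nutrients = nutrients)
}

# Per-food fructose factors (g per g of food): the generator's own ground
# truth arithmetic, aggregated food-wise rather than subject-wise.
food_fructose_factors <- function(composition, nutrients, mix) {
  resolved <- resolve_fructose_table(nutrients)
  composition |>
    dplyr::left_join(nutrients, by = "commodity_id") |>
    dplyr::left_join(resolved, by = "commodity_id") |>
    dplyr::mutate(
      nat = ifelse(!.data$is_added_sugar,
                   .data$fraction * .data$fructose_fraction, 0),
      addunb = dplyr::case_when(
        .data$sweetener_class == "corn_sweetener" ~
          .data$fraction * mix$unbound_fraction,
        .data$is_added_sugar ~ .data$fraction * .data$fructose_fraction,
        TRUE ~ 0
      ),
      addsuc = ifelse(.data$is_added_sugar,
                      .data$fraction * .data$sucrose_per_100g / 100, 0),
      sugar_mass = .data$fraction *
        (.data$sucrose_per_100g + ifelse(is.na(.data$fructose_per_100g), 0,
                                         .data$fructose_per_100g)) / 100
    ) |>
    dplyr::group_by(.data$food_id, .data$archetype) |>
    dplyr::summarise(
      nat_per_g = sum(.data$nat),
      addunb_per_g = sum(.data$addunb),
      addsuc_per_g = sum(.data$addsuc),
      .groups = "drop"
    )
}

#' Generate a synthetic cohort with planted hyperuricemia risk structure
#'
#' Draws demographics and dietary covariates for `n_subjects` adults,
#' constructs one-day dietary recalls whose food choices are driven by a
#' latent "sweet diet" factor (inducing a strong positive correlation
#' between fructose and total sugar intake), derives each subject's true
#' fructose components from per-food factors, and plants a logistic risk
#' model: hyperuricemia status is Bernoulli with log-odds equal to a
#' calibrated intercept plus the configured increments for the subject's
#' alcohol level and fiber/fructose quartiles.  Serum uric acid is then
#' drawn from sex-specific truncated normals above or below the cut-off so
#' that concentration and status are exactly consistent.
#'
#' @param config a [scenario_config()].
#' @param composition,nutrients tables from [generate_food_db()].
#' @param mix [sweetener_mix()] used for the ground-truth corn-sweetener
#'   partition (pass the same mix to [estimate_intakes()]).
#' @return list with `recalls`, `subjects` and `ground_truth` (per-subject
#'   true fructose components, true linear predictor and status, with the
#'   planted odds ratios and calibrated intercept as attributes).
#' @export
generate_cohort <- function(config, composition, nutrients,
                            mix = sweetener_mix()) {
  if (!inherits(config, "scenario_config")) {
    stop_config("config must be a scenario_config")
  }
  set.seed(config$seed + 1L)
  n <- config$n_subjects

  subjects <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = ifelse(rbinom(n, 1, 0.467) == 1, "male", "female"),
    age = sample(20:80, n, replace = TRUE),
    race = sample(c("white", "black", "hispanic", "other"), n, replace = TRUE,
                  prob = c(4533, 1810, 2766, 275) / 9384),
    education = sample(1:3, n, replace = TRUE,
                       prob = c(2777, 2223, 4384) / 9384),
    bmi = round(pmax(16, rnorm(n, 27.7, 6.1)), 1),
    weight = rlnorm(n, meanlog = -0.125, sdlog = 0.5),  # mean ~ 1
    diabetes = rbinom(n, 1, config$disease_fraction / 3) == 1,
    cancer = rbinom(n, 1, config$disease_fraction / 3) == 1,
    heart_disease = rbinom(n, 1, config$disease_fraction / 3) == 1,
    reliable_recall = rbinom(n, 1, 1 - config$unreliable_fraction) == 1
  )

  # Dietary covariates (independent of the sweet-diet factor except where
  # noted); magnitudes follow typical U.S. adult one-day recall scales.
  sweet <- rnorm(n, 0, config$sweet_factor_sd)
  subjects$energy_kcal <- round(rlnorm(n, log(2100), 0.42), 1)
  subjects$protein_g <- round(rlnorm(n, log(78), 0.45), 2)
  subjects$fat_pct_energy <- round(pmin(65, pmax(5, rnorm(n, 33, 9))), 2)
  fiber_density <- rlnorm(n, log(6.7), 0.52)          # g / 1000 kcal
  subjects$fiber_g <- round(fiber_density * subjects$energy_kcal / 1000, 2)
  subjects$vitamin_c_mg <- round(rlnorm(n, log(60), 0.9), 1)
  subjects$caffeine_mg <- round(rlnorm(n, log(130), 1), 1)
  drinker <- rbinom(n, 1, 1 - 6836 / 9384) == 1
  subjects$alcohol_g <- round(ifelse(drinker, rlnorm(n, log(22), 1.1), 0), 2)
  subjects$lactose_g <- round(rlnorm(n, log(11), 0.8), 2)

  # Recalls: each subject eats a handful of foods; sugary foods (beverage,
  # dessert, spread and half the fruits) scale with the sweet-diet factor.
  factors <- food_fructose_factors(composition, nutrients, mix)
  foods_per_subj <- pmax(3L, rpois(n, 8))
  idx <- rep(seq_len(n), foods_per_subj)
  m <- length(idx)
  food_row <- sample.int(nrow(factors), m, replace = TRUE)
  sweet_food <- factors$archetype[food_row] %in% c("beverage", "dessert", "spread", "fruit")
  grams <- rlnorm(m, log(120), 0.6) *
    ifelse(sweet_food, exp(0.8 * sweet[idx]), 1)
  recalls <- tibble::tibble(
    subject_id = subjects$subject_id[idx],
    food_id = factors$food_id[food_row],
    grams_consumed = round(grams, 4),
    reliable = subjects$reliable_recall[idx]
  )

  # Ground truth components from per-food factors (one multiply-add per
  # recall row, aggregated per subject).
  gt <- tibble::tibble(
    subject_id = recalls$subject_id,
    nat = recalls$grams_consumed * factors$nat_per_g[food_row],
    addunb = recalls$grams_consumed * factors$addunb_per_g[food_row],
    addsuc = recalls$grams_consumed * factors$addsuc_per_g[food_row]
  ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      natural_unbound_g = sum(.data$nat),
      added_unbound_g = sum(.data$addunb),
      added_bound_g = 0.5 * sum(.data$addsuc),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      all_added_g = .data$added_unbound_g + .data$added_bound_g,
      total_g = .data$all_added_g + .data$natural_unbound_g
    )
  gt <- subjects |>
    dplyr::select("subject_id") |>
    dplyr::left_join(gt, by = "subject_id")

  # total sugars: added sugar solids + lactose + natural sugars (unbound
  # fructose plus its glucose/sucrose companions in fruit).
  added_solids <- gt$added_unbound_g + 2 * gt$added_bound_g
  subjects$total_sugars_g <- round(
    added_solids + subjects$lactose_g + 2.6 * gt$natural_unbound_g, 2)

  # Planted risk structure on the generator's own exposure coding.
  eff <- config$effect_log_odds
  alcohol_level <- assign_alcohol_level(subjects$alcohol_g)
  fiber_q <- assign_quartiles(fiber_density)$labels
  fructose_q <- assign_quartiles(gt$total_g)$labels
  eta <- (eff$alcohol %||% rep(0, 4))[alcohol_level] +
    (eff$fiber %||% rep(0, 4))[fiber_q] +
    (eff$fructose %||% rep(0, 4))[fructose_q]
  intercept <- uniroot(
    function(b0) mean(plogis(b0 + eta)) - config$prevalence_target,
    lower = -20, upper = 5, tol = 1e-10
  )$root
  p_hyper <- plogis(intercept + eta)
  hyper <- rbinom(n, 1, p_hyper) == 1

  # Uric acid from sex-specific truncated normals around the cut-off.
  cutoff <- ifelse(subjects$sex == "male",
                   config$sex_cutoffs[["male"]], config$sex_cutoffs[["female"]])
  uric <- round(draw_truncnorm_status(
    hyper, cutoff,
    mean_normal = ifelse(subjects$sex == "male", 5.8, 4.7), sd_normal = 1.25,
    sd_hyper = 0.77
  ), 2)
  # keep rounded concentrations on the correct side of the strict cut-off
  uric[hyper] <- pmax(uric[hyper], cutoff[hyper] + 0.01)
  uric[!hyper] <- pmin(uric[!hyper], cutoff[!hyper])
  subjects$uric_mg_dl <- pmax(uric, 0.5)

  ground_truth <- gt |>
    dplyr::mutate(
      alcohol_level = alcohol_level,
      fiber_quartile = fiber_q,
      fructose_quartile = fructose_q,
      true_log_odds = intercept + eta,
      p_hyper = p_hyper,
      hyperuricemic = hyper
    )
  attr(ground_truth, "planted_or") <-
    lapply(config$effect_log_odds, exp)
  attr(ground_truth, "intercept") <- intercept

  list(recalls = recalls, subjects = subjects, ground_truth = ground_truth)
}

# Concentration draws consistent with a known status: below the cut-off
# from a normal truncated to (0, cutoff], above it truncated to
# (cutoff, Inf), via inverse-CDF sampling.
draw_truncnorm_status <- function(status, cutoff, mean_normal, sd_normal,
                                  sd_hyper) {
  n <- length(status)
  u <- runif(n)
  out <- numeric(n)
  lo <- pnorm(0, mean_normal, sd_normal)
  hi <- pnorm(cutoff, mean_normal, sd_normal)
  out[!status] <- qnorm(lo[!status] + u[!status] * (hi[!status] - lo[!status]),
                        mean_normal[!status], sd_normal)
  mh <- cutoff + 0.45
  hih <- pnorm(cutoff, mh, sd_hyper)
  out[status] <- qnorm(hih[status] + u[status] * (1 - hih[status]),
                       mh[status], sd_hyper)
  out
}

#' Write a simulated scenario to disk
#'
#' Writes the four input tables (`recalls.csv`, `composition.csv`,
#' `nutrients.csv`, `subjects.csv`) plus `ground_truth.csv` and a
#' `scenario.yaml` metadata file recording the full configuration
#' including the seed.
#'
#' @param sc a [simulate_scenario()] result.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sc$recalls, file.path(dir, "recalls.csv"), progress = FALSE)
  readr::write_csv(sc$composition, file.path(dir, "composition.csv"),
                   progress = FALSE)
  readr::write_csv(sc$nutrients, file.path(dir, "nutrients.csv"),
                   progress = FALSE)
  readr::write_csv(sc$subjects, file.path(dir, "subjects.csv"),
                   progress = FALSE)
  readr::write_csv(sc$ground_truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  meta <- unclass(sc$config)
  meta$effect_log_odds <- lapply(meta$effect_log_odds, as.numeric)
  meta$sex_cutoffs <- as.list(meta$sex_cutoffs)
  yaml::write_yaml(list(scenario = meta,
                        sweetener_mix = list(
                          shares = sc$mix$shares,
                          fructose_fractions = sc$mix$fructose_fractions)),
                   file.path(dir, "scenario.yaml"))
  invisible(dir)
}

#' Run a complete synthetic scenario
#'
#' Convenience wrapper: generates the food database and the cohort from one
#' configuration, returning all four input tables plus ground truth.
#'
#' @param config a [scenario_config()].
#' @param mix a [sweetener_mix()].
#' @return list with `composition`, `nutrients`, `recalls`, `subjects`,
#'   `ground_truth`, `config`, `mix`.
#' @export
simulate_scenario <- function(config = scenario_config(), mix = sweetener_mix()) {
  db <- generate_food_db(config)
  cohort <- generate_cohort(config, db$composition, db$nutrients, mix)
  c(db, cohort, list(config = config, mix = mix))
}
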