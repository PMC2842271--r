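#' Serum uric acid cut-off schemes
#'
#' Hyperuricemia is classified against sex-specific serum uric acid
#' cut-offs.  Two schemes are provided: the CDC normal-reference upper
#' bounds (>8.4 mg/dL for men, >7.5 mg/dL for women) and the lower
#' "legacy" convention used by some earlier studies (>7 and >6 mg/dL).
#'
#' @param scheme `"cdc"`, `"legacy"`, or `"custom"` (requires
#'   `male_cutoff` and `female_cutoff`).
#' @param male_cutoff,female_cutoff mg/dL cut-offs for a custom scheme;
#'   male must exceed female and both must be positive.
#' @return an object of class `cutoff_scheme` with fields `male_cutoff`,
#'   `female_cutoff`, `label`.
#' @examples
#' cutoff_scheme("cdc")
#' cutoff_scheme("legacy")
#' @export
cutoff_scheme <- function(scheme = c("cdc", "legacy", "custom"),
                          male_cutoff = NULL, female_cutoff = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "cdc") {
    male_cutoff <- 8.4; female_cutoff <- 7.5
  } else if (scheme == "legacy") {
    male_cutoff <- 7.0; female_cutoff <- 6.0
  } else {
    if (is.null(male_cutoff) || is.null(female_cutoff)) {
      stop_config("custom scheme requires male_cutoff and female_cutoff")
    }
  }
  if (!(male_cutoff > female_cutoff && female_cutoff > 0)) {
    stop_config("cut-offs must satisfy male > female > 0")
  }
  structure(list(male_cutoff = male_cutoff, female_cutoff = female_cutoff,
                 label = scheme), class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("Uric acid cut-off scheme '%s': men > %.1f, women > %.1f mg/dL\n",
              x$label, x$male_cutoff, x$female_cutoff))
  invisible(x)
}

#' Classify hyperuricemia against sex-specific cut-offs
#'
#' A subject is hyperuricemic when serum uric acid strictly exceeds the
#' cut-off for their sex (a man at exactly 8.4 mg/dL is not hyperuricemic
#' under the CDC scheme).
#'
#' @param uric_mg_dl serum uric acid concentration, mg/dL (vectorised).
#' @param sex `"male"` or `"female"` (recycled against `uric_mg_dl`).
#' @param scheme a [cutoff_scheme()].
#' @return logical vector.
#' @examples
#' classify_hyperuricemia(8.5, "male", cutoff_scheme("cdc"))   # TRUE
#' classify_hyperuricemia(8.4, "male", cutoff_scheme("cdc"))   # FALSE
#' classify_hyperuricemia(6.1, "female", cutoff_scheme("legacy"))  # TRUE
#' @export
classify_hyperuricemia <- function(uric_mg_dl, sex, scheme = cutoff_scheme("cdc")) {
  if (!inherits(scheme, "cutoff_scheme")) stop_config("scheme must be a cutoff_scheme")
  if (any(!is.finite(uric_mg_dl)) || any(uric_mg_dl <= 0)) {
    stop_domain("uric acid concentration must be positive")
  }
  bad <- !sex %in% c("male", "female")
  if (any(bad)) stop_domain("unknown sex value(s): ", paste(unique(sex[bad]), collapse = ", "))
  cut <- ifelse(sex == "male", scheme$male_cutoff, scheme$female_cutoff)
  uric_mg_dl > cut
}

#' Convert serum uric acid from mg/dL to SI units
#'
#' @param uric_mg_dl concentration in mg/dL (vectorised, non-negative).
#' @return concentration in micromol/L (1 mg/dL = 59.48 micromol/L).
#' @examples
#' to_si(8.4)  # ~ 500
#' @export
to_si <- function(uric_mg_dl) {
  if (any(uric_mg_dl < 0)) stop_domain("concentration must be >= 0")
  uric_mg_dl * 59.48
}

#' Assign quartile exposure labels
#'
#' Labels each value 1-4 by the 25th/50th/75th percentiles (linear
#' interpolation between order statistics), with intervals half-open on
#' the left and closed on the right, so a value exactly at a cutpoint
#' takes the lower label.  Optionally weighted percentiles.
#'
#' @param values numeric vector with at least 4 distinct values.
#' @param weights optional positive weights for weighted percentiles.
#' @return list with `labels` (integer 1-4) and `cutpoints` (the three
#'   percentile values).
#' @examples
#' assign_quartiles(1:8)$cutpoints  # 2.75 4.50 6.25
#' @export
assign_quartiles <- function(values, weights = NULL) {
  if (any(!is.finite(values))) stop_domain("values must be finite")
  if (length(unique(values)) < 4L) {
    stop_domain("quartile assignment needs >= 4 distinct values")
  }
  cut <- weighted_quantile(values, c(0.25, 0.5, 0.75), weights)
  if (is.unsorted(cut)) stop_domain("degenerate distribution: cutpoints not non-decreasing")
  labels <- 1L + (values > cut[1]) + (values > cut[2]) + (values > cut[3])
  list(labels = as.integer(labels), cutpoints = cut)
}

#' Assign alcohol intake level
#'
#' Levels 1-4 correspond to 0, (0, 15], (15, 30] and more than 30 grams
#' of alcohol per day (roughly 0, up to 1, up to 2, and more than 2
#' servings).
#'
#' @param grams_per_day non-negative daily alcohol intake (vectorised).
#' @return integer level 1-4.
#' @examples
#' assign_alcohol_level(c(0, 15, 15.01, 52.4))  # 1 2 3 4
#' @export
assign_alcohol_level <- function(grams_per_day) {
  if (any(grams_per_day < 0)) stop_domain("alcohol grams must be >= 0")
  as.integer(1L + (grams_per_day > 0) + (grams_per_day > 15) +
               (grams_per_day > 30))
}

#' Assign body-weight status category
#'
#' 1 = normal (BMI < 25), 2 = overweight (25 <= BMI < 30), 3 = obese
#' (BMI >= 30).
#'
#' @param bmi body mass index, kg/m^2, positive (vectorised).
#' @return integer category 1-3.
#' @export
assign_bmi_category <- function(bmi) {
  if (any(bmi <= 0)) stop_domain("BMI must be positive")
  as.integer(1L + (bmi >= 25) + (bmi >= 30))
}

#' Assign age group
#'
#' Groups close at 30, 40 and 50 years (integer-year semantics): 1 =
#' 20-30, 2 = 31-40, 3 = 41-50, 4 = over 50.
#'
#' @param age age in years, at least 20 (vectorised).
#' @return integer group 1-4.
#' @export
assign_age_group <- function(age) {
  if (any(age < 20)) stop_domain("age below 20 should have been excluded upstream")
  as.integer(1L + (age > 30) + (age > 40) + (age > 50))
}

#' Apply cohort exclusions
#'
#' Removes subjects outside 20-80 years, with a diabetes, cancer or
#' heart-disease flag, or with an unreliable dietary recall, and drops
#' their recall records.  Counts removed per reason are reported (a
#' subject failing several criteria is counted under each).
#'
#' @param subjects subject table with `subject_id`, `age`, logical
#'   `diabetes`, `cancer`, `heart_disease` columns.
#' @param recalls recall table with `subject_id` and logical `reliable`.
#' @return list with filtered `subjects`, `recalls`, and an `audit` tibble
#'   of per-reason exclusion counts.
#' @export
exclude_subjects <- function(subjects, recalls) {
  stopifnot(all(c("subject_id", "age") %in% names(subjects)))
  flags <- c("diabetes", "cancer", "heart_disease")
  for (f in flags) if (is.null(subjects[[f]])) subjects[[f]] <- FALSE
  unreliable_ids <- unique(recalls$subject_id[!recalls$reliable])
  bad_age <- subjects$age < 20 | subjects$age > 80
  diseased <- subjects$diabetes | subjects$cancer | subjects$heart_disease
  unreliable <- subjects$subject_id %in% unreliable_ids
  keep <- !(bad_age | diseased | unreliable)
  if (!any(keep)) stop_domain("all subjects excluded: empty cohort")
  audit <- tibble::tibble(
    reason = c("age_outside_20_80", "disease_flag", "unreliable_recall", "retained"),
    n = c(sum(bad_age), sum(diseased), sum(unreliable), sum(keep))
  )
  kept_ids <- subjects$subject_id[keep]
  list(
    subjects = subjects[keep, , drop = FALSE],
    recalls = recalls[recalls$subject_id %in% kept_ids & recalls$reliable, ,
                      drop = FALSE],
    audit = audit
  )
}

#' Build the analysis-ready cohort table
#'
#' Joins subject covariates with estimated fructose components, classifies
#' hyperuricemia under the requested cut-off scheme, computes fiber
#' density (g/1000 kcal) before quartiling, and codes every dietary
#' exposure as quartiles (1-4) plus alcohol level, age group and BMI
#' category.  Quartile cutpoints are computed on this cohort (after
#' exclusions), unweighted by default.
#'
#' @param subjects subject table after [exclude_subjects()].
#' @param intakes per-subject [estimate_intakes()] output.
#' @param scheme a [cutoff_scheme()].
#' @param weighted_quartiles use survey weights when computing quartile
#'   cutpoints (default `FALSE`).
#' @return tibble of class `cohort_table` with `hyperuricemic`, `*_q`
#'   quartile columns, `alcohol_level`, `age_group`, `bmi_category`, and
#'   all source columns; the named list of cutpoints used is attached as
#'   attribute `"cutpoints"` and the scheme as `"scheme"`.
#' @export
prepare_cohort <- function(subjects, intakes, scheme = cutoff_scheme("cdc"),
                           weighted_quartiles = FALSE) {
  cohort <- subjects |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(intakes), -dplyr::any_of("energy_kcal")),
      by = "subject_id"
    ) |>
    dplyr::mutate(
      hyperuricemic = classify_hyperuricemia(.data$uric_mg_dl, .data$sex, scheme),
      fiber_per_1000kcal = 1000 * .data$fiber_g / .data$energy_kcal,
      alcohol_level = assign_alcohol_level(.data$alcohol_g),
      age_group = assign_age_group(.data$age),
      bmi_category = assign_bmi_category(.data$bmi)
    )
  w <- if (weighted_quartiles) cohort$weight else NULL
  quart_vars <- c(
    energy_q = "energy_kcal", protein_q = "protein_g",
    fat_q = "fat_pct_energy", fiber_q = "fiber_per_1000kcal",
    vitamin_c_q = "vitamin_c_mg", caffeine_q = "caffeine_mg",
    added_unbound_fructose_q = "added_unbound_g",
    all_added_fructose_q = "all_added_g",
    total_fructose_q = "total_g",
    added_unbound_fructose_pct_q = "added_unbound_pct_energy",
    all_added_fructose_pct_q = "all_added_pct_energy",
    total_fructose_pct_q = "total_pct_energy"
  )
  cutpoints <- list()
  for (nm in names(quart_vars)) {
    src <- quart_vars[[nm]]
    if (!src %in% names(cohort)) next
    q <- assign_quartiles(cohort[[src]], w)
    cohort[[nm]] <- q$labels
    cutpoints[[nm]] <- q$cutpoints
  }
  attr(cohort, "cutpoints") <- cutpoints
  attr(cohort, "scheme") <- scheme
  attr(cohort, "weighted_quartiles") <- weighted_quartiles
  class(cohort) <- c("cohort_table", class(cohort))
  cohort
}
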