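# Hand-built 3-food / 5-commodity fixture.  All expected values in the
# tests are spreadsheet-style hand arithmetic from these numbers.
hand_nutrients <- function() {
  tibble::tibble(
    commodity_id = c("APPLE", "APPLE_JUICE", "WHEAT", "SUGAR_CB", "CORN_SW"),
    fructose_per_100g = c(5.9, NA, 0, 0, NA),
    carb_per_100g = c(13.8, 11.0, 72, 100, 100),
    sucrose_per_100g = c(2.1, 1.0, 0, 100, 0),
    is_added_sugar = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    sweetener_class = c("none", "none", "none", "cane_beet", "corn_sweetener"),
    family_id = c(NA, "APPLE", NA, NA, NA)
  )
}

hand_composition <- function() {
  tibble::tibble(
    food_id = c("JUICE_DRINK", "JUICE_DRINK", "PIE", "PIE", "PIE", "BREAD"),
    commodity_id = c("APPLE_JUICE", "CORN_SW", "APPLE", "WHEAT", "SUGAR_CB",
                     "WHEAT"),
    fraction = c(0.5, 0.06, 0.3, 0.25, 0.15, 0.6)
  )
}

hand_recalls <- function() {
  tibble::tibble(
    subject_id = c("S1", "S1", "S2"),
    food_id = c("JUICE_DRINK", "PIE", "BREAD"),
    grams_consumed = c(200, 100, 150),
    reliable = TRUE
  )
}

hand_mix <- function() sweetener_mix(0.5, 0.4, 0.1, c(0.55, 0.42, 0))

hand_energy <- function() {
  tibble::tibble(subject_id = c("S1", "S2"), energy_kcal = c(2000, 1800))
}

# Minimal subject table for cohort tests: uric acid and covariates only.
make_subjects <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, TRUE),
    age = sample(20:80, n, TRUE),
    race = sample(c("white", "black", "hispanic", "other"), n, TRUE),
    education = sample(1:3, n, TRUE),
    bmi = runif(n, 18, 42),
    uric_mg_dl = runif(n, 2, 11),
    weight = rlnorm(n, 0, 0.4),
    diabetes = FALSE, cancer = FALSE, heart_disease = FALSE
  )
}

# Independent quartile oracle: explicit linear interpolation between order
# statistics plus per-value comparison counting (no call to quantile()).
oracle_quartiles <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  interp <- function(p) {
    pos <- 1 + (n - 1) * p
    lo <- floor(pos)
    hi <- ceiling(pos)
    xs[lo] + (pos - lo) * (xs[hi] - xs[lo])
  }
  cuts <- c(interp(0.25), interp(0.5), interp(0.75))
  labels <- vapply(x, function(v) 1L + sum(v > cuts), integer(1))
  list(labels = labels, cutpoints = cuts)
}
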