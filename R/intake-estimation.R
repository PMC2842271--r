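#' Corn-sweetener mix specification
#'
#' Corn sweeteners appear in commodity vocabularies under only two names
#' (corn syrup, and corn syrup for baby food), so their free-fructose
#' content cannot be read off a nutrient table directly.  Instead, the mass
#' of corn sweetener consumed is apportioned into HFCS-55, HFCS-42 and
#' plain corn syrup according to national sweetener disappearance shares,
#' each component carrying its own unbound-fructose fraction (0.55, 0.42
#' and 0 of sugar-solids mass by default).
#'
#' The disappearance shares have no single authoritative value here and are
#' plain arguments; the defaults are a round HFCS-dominant split typical of
#' the 1999-2004 U.S. sweetener supply.
#'
#' @param share_hfcs55,share_hfcs42,share_corn_syrup non-negative shares of
#'   corn-sweetener mass; must sum to 1 (within 1e-9).
#' @param fructose_fractions unbound (monosaccharide) fructose fraction of
#'   each component, in the order HFCS-55, HFCS-42, corn syrup.
#' @return an object of class `sweetener_mix`.
#' @examples
#' mix <- sweetener_mix(0.5, 0.4, 0.1)
#' partition_corn_sweetener(100, mix)  # 44.3 g unbound fructose
#' @export
sweetener_mix <- function(share_hfcs55 = 0.5, share_hfcs42 = 0.4,
                          share_corn_syrup = 0.1,
                          fructose_fractions = c(0.55, 0.42, 0)) {
  shares <- c(share_hfcs55, share_hfcs42, share_corn_syrup)
  if (any(!is.finite(shares)) || any(shares < 0)) {
    stop_config("sweetener mix shares must be finite and non-negative")
  }
  if (abs(sum(shares) - 1) > 1e-9) {
    stop_config("sweetener mix shares must sum to 1, got ", sum(shares))
  }
  if (length(fructose_fractions) != 3L ||
      any(fructose_fractions < 0 | fructose_fractions > 1)) {
    stop_config("fructose_fractions must be three proportions in [0, 1]")
  }
  structure(
    list(shares = shares, fructose_fractions = fructose_fractions,
         unbound_fraction = sum(shares * fructose_fractions)),
    class = "sweetener_mix"
  )
}

#' @export
print.sweetener_mix <- function(x, ...) {
  cat("Corn sweetener mix (HFCS-55 / HFCS-42 / corn syrup)\n")
  cat("  shares:            ", paste(format(x$shares), collapse = " / "), "\n")
  cat("  fructose fractions:", paste(format(x$fructose_fractions), collapse = " / "), "\n")
  cat("  effective unbound fructose per g solids:", format(x$unbound_fraction), "\n")
  invisible(x)
}

#' Unbound fructose contributed by a corn-sweetener mass
#'
#' @param mass_g grams of corn-sweetener sugar solids consumed (vectorised).
#' @param mix a [sweetener_mix()].
#' @return grams of unbound fructose; the remainder `mass_g - result` is
#'   non-fructose sugar.
#' @export
partition_corn_sweetener <- function(mass_g, mix = sweetener_mix()) {
  if (!inherits(mix, "sweetener_mix")) stop_config("mix must be a sweetener_mix")
  if (any(mass_g < 0)) stop_domain("corn sweetener mass must be >= 0")
  mass_g * mix$unbound_fraction
}

#' Bound fructose from added sucrose
#'
#' Sucrose is a glucose-fructose disaccharide; by convention half of the
#' sucrose mass from added sugars is counted as (bound) fructose.
#'
#' @param added_sucrose_g grams of sucrose from added-sugar commodities
#'   (vectorised).
#' @return grams of bound fructose, `0.5 * added_sucrose_g`.
#' @export
added_bound_fructose <- function(added_sucrose_g) {
  if (any(added_sucrose_g < 0)) stop_domain("added sucrose must be >= 0")
  0.5 * added_sucrose_g
}

#' Decompose recall records into per-subject commodity masses
#'
#' Each recall record (one food eaten by one subject) is expanded through
#' the food-to-commodity composition table and summed, giving the grams of
#' each agricultural commodity each subject consumed.
#'
#' @param recalls data frame with columns `subject_id`, `food_id`,
#'   `grams_consumed`; unreliable records are assumed already excluded.
#' @param composition data frame with columns `food_id`, `commodity_id`,
#'   `fraction` (grams of commodity per gram of food, positive).
#' @return tibble with `subject_id`, `commodity_id`, `mass_g`.
#' @examples
#' comp <- tibble::tibble(food_id = "F1", commodity_id = c("A", "B"),
#'                        fraction = c(0.4, 0.6))
#' rec <- tibble::tibble(subject_id = 1, food_id = "F1", grams_consumed = 100)
#' decompose_recalls(rec, comp)
#' @export
decompose_recalls <- function(recalls, composition) {
  stopifnot(all(c("subject_id", "food_id", "grams_consumed") %in% names(recalls)))
  stopifnot(all(c("food_id", "commodity_id", "fraction") %in% names(composition)))
  if (nrow(recalls) == 0L) {
    return(tibble::tibble(subject_id = recalls$subject_id[0],
                          commodity_id = character(), mass_g = numeric()))
  }
  if (any(recalls$grams_consumed < 0)) stop_domain("grams_consumed must be >= 0")
  unknown <- setdiff(unique(recalls$food_id), unique(composition$food_id))
  if (length(unknown) > 0L) {
    stop_lookup("food id(s) absent from composition table: ",
                paste(head(unknown, 5), collapse = ", "))
  }
  recalls |>
    dplyr::inner_join(composition, by = "food_id", relationship = "many-to-many") |>
    dplyr::mutate(mass_g = .data$grams_consumed * .data$fraction) |>
    dplyr::group_by(.data$subject_id, .data$commodity_id) |>
    dplyr::summarise(mass_g = sum(.data$mass_g), .groups = "drop")
}

#' Resolve a commodity's fructose content, imputing by family ratio
#'
#' When the nutrient reference has no direct fructose value for a
#' fructose-containing commodity, its content is imputed from a related
#' ("family") commodity that has both fructose and carbohydrate values:
#' the family's fructose-to-carbohydrate ratio is applied to the target's
#' own carbohydrate content (e.g. orange juice imputed from orange).
#'
#' @param profile a one-row data frame / list with `commodity_id`,
#'   `fructose_per_100g` (may be `NA`), `carb_per_100g`, `family_id`.
#' @param reference the full nutrient-reference table in which `family_id`
#'   is looked up.
#' @return list with `fraction` (g fructose per g commodity) and
#'   `provenance` (`"direct"` or `"ratio_imputed"`).
#' @examples
#' ref <- tibble::tibble(commodity_id = c("OJ", "OR"),
#'                       fructose_per_100g = c(NA, 2.25),
#'                       carb_per_100g = c(10, 11.54),
#'                       family_id = c("OR", NA))
#' resolve_fructose_fraction(ref[1, ], ref)  # 0.10 * 2.25 / 11.54
#' @export
resolve_fructose_fraction <- function(profile, reference) {
  fr <- profile$fructose_per_100g
  if (length(fr) == 1L && !is.na(fr)) {
    return(list(fraction = fr / 100, provenance = "direct"))
  }
  fam_id <- profile$family_id
  if (is.null(fam_id) || length(fam_id) != 1L || is.na(fam_id)) {
    stop_lookup("commodity ", profile$commodity_id,
                " has no direct fructose value and no family link")
  }
  fam <- reference[reference$commodity_id == fam_id, , drop = FALSE]
  if (nrow(fam) != 1L || is.na(fam$fructose_per_100g) || is.na(fam$carb_per_100g)) {
    stop_lookup("commodity ", profile$commodity_id,
                ": family member ", fam_id, " lacks fructose/carbohydrate values")
  }
  if (fam$carb_per_100g <= 0) {
    stop_lookup("commodity ", profile$commodity_id,
                ": family member ", fam_id, " has zero carbohydrate")
  }
  list(
    fraction = (profile$carb_per_100g / 100) *
      (fam$fructose_per_100g / fam$carb_per_100g),
    provenance = "ratio_imputed"
  )
}

# Vectorised resolution over the whole reference: returns one row per
# commodity with the fraction used (0 for unresolved) and its provenance.
resolve_fructose_table <- function(reference) {
  out <- tibble::tibble(
    commodity_id = reference$commodity_id,
    fructose_fraction = NA_real_,
    provenance = NA_character_
  )
  direct <- !is.na(reference$fructose_per_100g)
  out$fructose_fraction[direct] <- reference$fructose_per_100g[direct] / 100
  out$provenance[direct] <- "direct"
  for (i in which(!direct)) {
    res <- tryCatch(
      resolve_fructose_fraction(reference[i, ], reference),
      fructuric_lookup_error = function(e) NULL
    )
    if (is.null(res)) {
      out$fructose_fraction[i] <- 0
      out$provenance[i] <- "unresolved"
    } else {
      out$fructose_fraction[i] <- res$fraction
      out$provenance[i] <- res$provenance
    }
  }
  out
}

#' Estimate per-subject fructose intake components
#'
#' Implements the individual fructose-intake calculation: recalls are
#' decomposed into commodity masses; naturally occurring unbound fructose
#' is summed over non-added-sugar commodities using direct or
#' ratio-imputed fructose contents; added unbound fructose comes from the
#' corn-sweetener partition plus the direct free-fructose content of the
#' other sweeteners (honey, molasses, syrups); added bound fructose is half
#' the sucrose mass of added-sugar commodities.  Totals and percent of
#' energy (4 kcal per gram of fructose) are derived.
#'
#' @param recalls reliable recall records (`subject_id`, `food_id`,
#'   `grams_consumed`).
#' @param composition food-to-commodity composition table.
#' @param reference commodity nutrient reference (`commodity_id`,
#'   `fructose_per_100g`, `carb_per_100g`, `sucrose_per_100g`,
#'   `is_added_sugar`, `sweetener_class`, `family_id`).
#' @param mix a [sweetener_mix()] for corn-sweetener partitioning.
#' @param energy data frame with `subject_id`, `energy_kcal`; subjects with
#'   zero or missing energy get `NA` percent-energy values and are flagged.
#' @return tibble of class `fructose_intake`, one row per subject with
#'   columns `natural_unbound_g`, `added_unbound_g`, `added_bound_g`,
#'   `all_added_g`, `total_g`, matching `*_pct_energy` columns,
#'   `energy_kcal` and `energy_flag`.  The imputation audit (one row per
#'   commodity: fraction used and provenance) is attached as attribute
#'   `"audit"`.
#' @export
estimate_intakes <- function(recalls, composition, reference,
                             mix = sweetener_mix(), energy) {
  stopifnot(all(c("subject_id", "energy_kcal") %in% names(energy)))
  masses <- decompose_recalls(recalls, composition)
  unknown <- setdiff(unique(masses$commodity_id), reference$commodity_id)
  if (length(unknown) > 0L) {
    stop_lookup("commodity id(s) absent from nutrient reference: ",
                paste(head(unknown, 5), collapse = ", "))
  }
  resolved <- resolve_fructose_table(reference)

  ref <- reference |>
    dplyr::select("commodity_id", "sucrose_per_100g", "is_added_sugar",
                  "sweetener_class") |>
    dplyr::left_join(resolved, by = "commodity_id")

  contrib <- masses |>
    dplyr::left_join(ref, by = "commodity_id") |>
    dplyr::mutate(
      natural_unbound_g = ifelse(!.data$is_added_sugar,
                                 .data$mass_g * .data$fructose_fraction, 0),
      added_unbound_g = dplyr::case_when(
        .data$sweetener_class == "corn_sweetener" ~
          partition_corn_sweetener(.data$mass_g, mix),
        .data$is_added_sugar ~ .data$mass_g * .data$fructose_fraction,
        TRUE ~ 0
      ),
      added_sucrose_g = ifelse(.data$is_added_sugar,
                               .data$mass_g * .data$sucrose_per_100g / 100, 0)
    ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      natural_unbound_g = sum(.data$natural_unbound_g),
      added_unbound_g = sum(.data$added_unbound_g),
      added_sucrose_g = sum(.data$added_sucrose_g),
      .groups = "drop"
    ) |>
    dplyr::mutate(added_bound_g = added_bound_fructose(.data$added_sucrose_g),
                  added_sucrose_g = NULL)

  out <- energy |>
    dplyr::select("subject_id", "energy_kcal") |>
    dplyr::left_join(contrib, by = "subject_id") |>
    dplyr::mutate(
      dplyr::across(c("natural_unbound_g", "added_unbound_g", "added_bound_g"),
                    ~ ifelse(is.na(.x), 0, .x)),
      all_added_g = .data$added_unbound_g + .data$added_bound_g,
      total_g = .data$all_added_g + .data$natural_unbound_g,
      energy_flag = !is.finite(.data$energy_kcal) | .data$energy_kcal <= 0
    )
  pct <- function(g, kcal, bad) ifelse(bad, NA_real_, 100 * 4 * g / kcal)
  out <- out |>
    dplyr::mutate(
      natural_unbound_pct_energy = pct(.data$natural_unbound_g, .data$energy_kcal, .data$energy_flag),
      added_unbound_pct_energy = pct(.data$added_unbound_g, .data$energy_kcal, .data$energy_flag),
      all_added_pct_energy = pct(.data$all_added_g, .data$energy_kcal, .data$energy_flag),
      total_pct_energy = pct(.data$total_g, .data$energy_kcal, .data$energy_flag)
    ) |>
    dplyr::relocate("subject_id")
  attr(out, "audit") <- resolved
  class(out) <- c("fructose_intake", class(out))
  out
}

#' Upper bound on underestimated naturally occurring bound fructose
#'
#' Nutrient references rarely report naturally occurring sucrose, so bound
#' fructose from natural sucrose is not captured by the intake calculation.
#' Its maximum is bounded from population means: the non-added, non-lactose
#' remainder of total sugars is attributed to natural sugars, multiplied by
#' a sucrose-to-total-sugar ratio, and halved (the fructose moiety of
#' sucrose).  A negative remainder clamps to zero: the quantity is a bound,
#' not a balance.
#'
#' @param total_sugars_g mean total sugar intake, g/day.
#' @param added_sugars_g mean added sugar intake, g/day.
#' @param lactose_g mean lactose intake, g/day.
#' @param sucrose_to_sugar_ratio proportion of natural sugars that is
#'   sucrose, in `[0, 1]`.
#' @return grams/day of potentially missed natural bound fructose.
#' @examples
#' natural_bound_underestimate(135.91, 99.86, 14.49, 0.2653)  # 2.86 g
#' @export
natural_bound_underestimate <- function(total_sugars_g, added_sugars_g,
                                        lactose_g, sucrose_to_sugar_ratio) {
  check_number(total_sugars_g, "total_sugars_g", lower = 0)
  check_number(added_sugars_g, "added_sugars_g", lower = 0)
  check_number(lactose_g, "lactose_g", lower = 0)
  check_number(sucrose_to_sugar_ratio, "sucrose_to_sugar_ratio", 0, 1)
  max(0, total_sugars_g - added_sugars_g - lactose_g) *
    sucrose_to_sugar_ratio * 0.5
}
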