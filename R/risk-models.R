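#' Survey-weighted descriptive statistics by stratum
#'
#' Weighted mean, median and SD for each variable within each stratum
#' (typically hyperuricemia status).  Weights follow the frequency-weight
#' convention, so equal weights reproduce the unweighted `mean()`, `sd()`
#' (n-1 denominator) and `median()` exactly.  Empty strata yield `NA`
#' rows rather than errors.
#'
#' @param cohort data frame.
#' @param vars character vector of numeric columns to summarise.
#' @param by name of the stratifying column (default `"hyperuricemic"`).
#' @param weights name of the weight column, or `NULL` for unweighted.
#' @return tibble with one row per variable x stratum: `n`, `mean`,
#'   `median`, `sd`.
#' @export
weighted_descriptives <- function(cohort, vars, by = "hyperuricemic",
                                  weights = "weight") {
  stopifnot(by %in% names(cohort), all(vars %in% names(cohort)))
  w_all <- if (is.null(weights)) rep(1, nrow(cohort)) else cohort[[weights]]
  if (any(w_all <= 0)) stop_domain("weights must be positive")
  strata <- sort(unique(cohort[[by]]))
  out <- list()
  for (s in strata) {
    in_s <- cohort[[by]] == s
    w <- w_all[in_s]
    for (v in vars) {
      x <- cohort[[v]][in_s]
      ok <- is.finite(x)
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = v, stratum = as.character(s), n = sum(ok),
        mean = if (any(ok)) wtd_mean(x[ok], w[ok]) else NA_real_,
        median = if (any(ok)) wtd_median(x[ok], w[ok]) else NA_real_,
        sd = if (sum(ok) > 1) wtd_sd(x[ok], w[ok]) else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Compare group means with a many-to-one (Dunnett) reference
#'
#' Fits a general linear model of a continuous outcome (serum uric acid)
#' on a grouping factor, optionally adjusted for covariates, and tests
#' each group against the lowest group using Dunnett's many-to-one
#' procedure.  Reports raw per-group mean/SD/n, covariate-adjusted means
#' (average predictions with the whole cohort set to each group), the
#' model-level p-value for the grouping term, and Dunnett-adjusted
#' p-values versus group 1.
#'
#' @param cohort data frame.
#' @param outcome name of the continuous outcome column.
#' @param grouping name of the grouping column (coerced to factor; its
#'   first level is the reference).
#' @param covariates character vector of adjustment columns (categorical
#'   ones should already be coded as factors or small integers; integers
#'   with at most 8 distinct values are treated as categorical).
#' @param weights optional name of a weight column for a weighted fit.
#' @return list of class `mean_table` with `table` (per-group tibble:
#'   `n`, `mean`, `sd`, `adjusted_mean`, `p_vs_reference`), `model_p`,
#'   `covariates`, and the fitted `model`.
#' @export
compare_means <- function(cohort, outcome, grouping, covariates = character(),
                          weights = NULL) {
  stopifnot(outcome %in% names(cohort), grouping %in% names(cohort))
  dat <- as.data.frame(cohort)[, unique(c(outcome, grouping, covariates,
                                          weights)), drop = FALSE]
  dat$.grp <- factor(dat[[grouping]])
  if (nlevels(dat$.grp) < 2L) stop_domain("grouping must have >= 2 levels")
  for (cv in covariates) {
    if (is.numeric(dat[[cv]]) && length(unique(dat[[cv]])) <= 8L) {
      dat[[cv]] <- factor(dat[[cv]])
    }
  }
  rhs <- paste(c(".grp", covariates), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  w <- if (is.null(weights)) NULL else dat[[weights]]
  fit <- if (is.null(w)) lm(fml, data = dat) else lm(fml, data = dat, weights = w)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_domain("singular fit; aliased terms: ", paste(bad, collapse = ", "))
  }

  # model-level p for the grouping term (F test against the model without it)
  fml0 <- as.formula(paste(outcome, "~",
                           paste(c("1", covariates), collapse = " + ")))
  fit0 <- if (is.null(w)) lm(fml0, data = dat) else lm(fml0, data = dat, weights = w)
  model_p <- anova(fit0, fit)[2, "Pr(>F)"]

  dunnett <- multcomp::glht(fit, linfct = multcomp::mcp(.grp = "Dunnett"))
  dsum <- summary(dunnett)
  p_dunnett <- as.numeric(dsum$test$pvalues)

  lev <- levels(dat$.grp)
  raw <- dat |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data[[outcome]]),
                     sd = sd(.data[[outcome]]), .groups = "drop")
  adj_mean <- vapply(lev, function(g) {
    nd <- dat
    nd$.grp <- factor(g, levels = lev)
    mean(predict(fit, newdata = nd))
  }, numeric(1))
  tab <- tibble::tibble(
    group = lev, n = raw$n, mean = raw$mean, sd = raw$sd,
    adjusted_mean = adj_mean,
    p_vs_reference = c(NA_real_, p_dunnett)
  )
  structure(list(table = tab, model_p = model_p, covariates = covariates,
                 model = fit), class = "mean_table")
}

#' @export
print.mean_table <- function(x, ...) {
  cat("Group means vs reference (Dunnett-adjusted), model p =",
      format.pval(x$model_p, digits = 3), "\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Logistic regression risk model for hyperuricemia
#'
#' Fits a maximum-likelihood logistic regression of hyperuricemia status
#' on a categorical exposure, crude (exposure only) or adjusted for
#' covariates, using the lowest level of every categorical term as
#' reference.  Reports odds ratios with Wald 95% confidence limits and
#' p-values per non-reference exposure level, the exposure's
#' likelihood-ratio p, and a Hosmer-Lemeshow goodness-of-fit p.
#'
#' @param cohort data frame containing the outcome and all model columns.
#' @param exposure name of the exposure column (coerced to factor).
#' @param covariates character vector of adjustment columns; numeric
#'   columns with at most 8 distinct values are treated as categorical.
#' @param outcome name of the logical/0-1 outcome column.
#' @param weights optional name of a weight column (default unweighted;
#'   descriptive weighting does not extend to the regression by default).
#' @param conf_level confidence level for the Wald limits.
#' @return list of class `risk_result`: `exposure`, `model_type`, `table`
#'   (per non-reference level: `level`, `n`, `cases`, `or`, `ci_low`,
#'   `ci_high`, `p`, `unstable`), `model_p` (likelihood-ratio test of the
#'   exposure), `gof_p`, `covariates`, fitted `model`.
#' @export
fit_logit <- function(cohort, exposure, covariates = character(),
                      outcome = "hyperuricemic", weights = NULL,
                      conf_level = 0.95) {
  stopifnot(outcome %in% names(cohort), exposure %in% names(cohort))
  dat <- as.data.frame(cohort)[, unique(c(outcome, exposure, covariates,
                                          weights)), drop = FALSE]
  dat$.y <- as.integer(dat[[outcome]])
  if (!all(dat$.y %in% 0:1)) stop_domain("outcome must be logical or 0/1")
  dat$.exp <- if (is.factor(dat[[exposure]])) dat[[exposure]]
              else factor(dat[[exposure]])
  empty <- levels(dat$.exp)[table(dat$.exp) == 0L]
  if (length(empty) > 0L) {
    warning("dropping empty exposure level(s): ", paste(empty, collapse = ", "))
    dat$.exp <- droplevels(dat$.exp)
  }
  if (nlevels(dat$.exp) < 2L) stop_domain("exposure must have >= 2 non-empty levels")
  for (cv in covariates) {
    if (is.numeric(dat[[cv]]) && length(unique(dat[[cv]])) <= 8L) {
      dat[[cv]] <- factor(dat[[cv]])
    }
  }
  rhs <- paste(c(".exp", covariates), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  w <- if (is.null(weights)) NULL else dat[[weights]]
  fit <- suppressWarnings(
    if (is.null(w)) glm(fml, data = dat, family = binomial())
    else glm(fml, data = dat, family = binomial(), weights = w)
  )

  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  idx <- grep("^\\.exp", names(cf))
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- unname(cf[idx])
  se_i <- unname(se[idx])
  lev_names <- sub("^\\.exp", "", names(cf)[idx])
  unstable <- abs(est) > 10 | se_i > 10   # quasi-separation heuristic
  if (any(unstable)) {
    warning("possible quasi-separation: Wald intervals unstable for level(s) ",
            paste(lev_names[unstable], collapse = ", "))
  }
  lev <- levels(dat$.exp)
  counts <- dat |>
    dplyr::group_by(.data$.exp) |>
    dplyr::summarise(n = dplyr::n(), cases = sum(.data$.y), .groups = "drop")
  tab <- tibble::tibble(
    level = lev_names,
    n = counts$n[match(lev_names, counts$.exp)],
    cases = counts$cases[match(lev_names, counts$.exp)],
    or = exp(est),
    ci_low = exp(est - z * se_i),
    ci_high = exp(est + z * se_i),
    p = 2 * pnorm(-abs(est / se_i)),
    unstable = unstable
  )

  fml0 <- as.formula(paste(".y ~", paste(c("1", covariates), collapse = " + ")))
  fit0 <- suppressWarnings(
    if (is.null(w)) glm(fml0, data = dat, family = binomial())
    else glm(fml0, data = dat, family = binomial(), weights = w)
  )
  model_p <- anova(fit0, fit, test = "Chisq")[2, "Pr(>Chi)"]
  gof <- tryCatch(suppressWarnings(goodness_of_fit(fit)),
                  error = function(e) NA_real_)

  structure(
    list(exposure = exposure,
         model_type = if (length(covariates)) "adjusted" else "unadjusted",
         reference = lev[1], table = tab, model_p = model_p,
         gof_p = if (is.list(gof)) gof$p_value else gof,
         covariates = covariates, model = fit),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("%s model for exposure '%s' (reference level %s)\n",
              x$model_type, x$exposure, x$reference))
  print(as.data.frame(x$table), digits = 4)
  cat("exposure LRT p =", format.pval(x$model_p, digits = 3),
      "; goodness-of-fit p =", format.pval(x$gof_p, digits = 3), "\n")
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `g` bins by deciles of predicted risk and
#' compares observed and expected case counts with a chi-square statistic
#' on `g - 2` degrees of freedom.  Bins whose boundaries coincide (few
#' distinct predicted probabilities) are collapsed with a warning.
#'
#' @param model a fitted binomial `glm`.
#' @param g number of risk bins (default 10).
#' @return list with `statistic`, `df`, `p_value`, `g_used`.
#' @export
goodness_of_fit <- function(model, g = 10) {
  stopifnot(inherits(model, "glm"))
  p <- fitted(model)
  y <- model$y
  if (length(y) < 10 * g) {
    warning("fewer than ", 10 * g, " observations for ", g, " bins")
  }
  br <- unique(quantile(p, probs = seq(0, 1, length.out = g + 1), type = 7))
  if (length(br) < g + 1) {
    # few distinct predicted probabilities: bin on the distinct values
    # themselves when quantile breaks collapse too far
    n_distinct <- length(unique(p))
    warning("collapsing bins: only ",
            max(length(br) - 1, min(n_distinct, g)),
            " distinct risk bins available")
    bin <- if (length(br) - 1 >= 3) cut(p, breaks = br, include.lowest = TRUE)
           else factor(signif(p, 10))
  } else {
    bin <- cut(p, breaks = br, include.lowest = TRUE)
  }
  g_used <- nlevels(bin)
  if (g_used < 3) stop_domain("too few distinct predicted probabilities for the test")
  obs <- tapply(y, bin, sum)
  exp_ <- tapply(p, bin, sum)
  n_bin <- tapply(y, bin, length)
  stat <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / n_bin)))
  df <- g_used - 2
  list(statistic = unname(stat), df = df,
       p_value = unname(pchisq(stat, df, lower.tail = FALSE)), g_used = g_used)
}

#' Power of a two-group comparison of hyperuricemia proportions
#'
#' Normal-approximation power for a two-sided two-proportion test where
#' the comparison group's odds equal the reference prevalence's odds
#' multiplied by `odds_ratio` (an extreme-group contrast between intake
#' levels).
#'
#' @param prevalence_ref reference-group prevalence, in (0, 1).
#' @param odds_ratio comparison-to-reference odds ratio, positive.
#' @param alpha two-sided significance level.
#' @param n_per_group subjects per group (>= 2).
#' @return power in `[0, 1]`; equals `alpha` when `odds_ratio = 1`.
#' @examples
#' power_two_group(0.025, 2, 0.05, 2346)
#' @export
power_two_group <- function(prevalence_ref, odds_ratio, alpha = 0.05,
                            n_per_group) {
  check_number(prevalence_ref, "prevalence_ref", 1e-12, 1 - 1e-12)
  if (prevalence_ref <= 0 || prevalence_ref >= 1) {
    stop_domain("prevalence must be strictly inside (0, 1)")
  }
  check_number(odds_ratio, "odds_ratio", lower = 1e-12)
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  check_number(n_per_group, "n_per_group", lower = 2)
  p1 <- prevalence_ref
  odds2 <- odds_ratio * p1 / (1 - p1)
  p2 <- odds2 / (1 + odds2)
  delta <- p2 - p1
  pbar <- (p1 + p2) / 2
  se0 <- sqrt(2 * pbar * (1 - pbar))
  se1 <- sqrt(p1 * (1 - p1) + p2 * (1 - p2))
  za <- qnorm(1 - alpha / 2)
  rn <- sqrt(n_per_group)
  pnorm((delta * rn - za * se0) / se1) + pnorm((-delta * rn - za * se0) / se1)
}
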