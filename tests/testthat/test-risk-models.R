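test_that("weighted descriptives reduce to unweighted under equal weights", {
  set.seed(1)
  dat <- tibble::tibble(
    hyperuricemic = rep(c(TRUE, FALSE), each = 50),
    x = rnorm(100), weight = 2
  )
  out <- weighted_descriptives(dat, "x")
  for (s in c("TRUE", "FALSE")) {
    xs <- dat$x[dat$hyperuricemic == (s == "TRUE")]
    row <- out[out$stratum == s, ]
    expect_equal(row$mean, mean(xs))
    expect_equal(row$sd, sd(xs))
    expect_equal(row$median, median(xs))
  }
  # two subjects, weights (1, 3), values (0, 4) -> weighted mean 3
  d2 <- tibble::tibble(hyperuricemic = TRUE, x = c(0, 4), weight = c(1, 3))
  expect_equal(weighted_descriptives(d2, "x")$mean, 3.0)
  expect_error(weighted_descriptives(
    tibble::tibble(hyperuricemic = TRUE, x = 1, weight = 0), "x"),
    class = "fructuric_domain_error")
})

test_that("null strata differ only within sampling error", {
  set.seed(5)
  dat <- tibble::tibble(
    hyperuricemic = rbinom(4000, 1, 0.5) == 1,
    x = rnorm(4000, 10, 2), weight = rlnorm(4000, 0, 0.3)
  )
  out <- weighted_descriptives(dat, "x")
  expect_lt(abs(diff(out$mean)), 4 * 2 / sqrt(2000))
})

test_that("compare_means gives Dunnett-adjusted many-to-one comparisons", {
  set.seed(11)
  n <- 1500
  dat <- tibble::tibble(
    grp = sample(1:4, n, TRUE),
    cov = rnorm(n),
    y = 5 + 0.3 * cov + rnorm(n, 0, 1.4)
  )
  # identical groups: no comparison should be significant
  mt <- compare_means(dat, "y", "grp")
  expect_gt(mt$model_p, 0.05)
  expect_true(all(mt$table$p_vs_reference[-1] > 0.05))
  expect_equal(mt$table$n, as.integer(table(dat$grp)), ignore_attr = TRUE)

  # a +0.5 shift in one group at large n is detected at p < 0.001
  set.seed(12)
  n2 <- 5000
  dat2 <- tibble::tibble(
    grp = rep(1:4, each = n2),
    y = rnorm(4 * n2, 5, 1.4) + 0.5 * (rep(1:4, each = n2) == 3)
  )
  mt2 <- compare_means(dat2, "y", "grp")
  expect_lt(mt2$table$p_vs_reference[3], 0.001)
  expect_lt(mt2$model_p, 0.001)

  # Dunnett adjustment never makes a comparison more significant than the
  # corresponding unadjusted contrast
  fit <- mt$model
  dun <- multcomp::glht(fit, linfct = multcomp::mcp(.grp = "Dunnett"))
  p_adj <- as.numeric(summary(dun)$test$pvalues)
  p_raw <- as.numeric(summary(dun, test = multcomp::univariate())$test$pvalues)
  expect_true(all(p_adj >= p_raw - 1e-3))

  # collinear covariate triggers a singular-fit error naming the term
  dat$cov2 <- dat$cov
  expect_error(compare_means(dat, "y", "grp", covariates = c("cov", "cov2")),
               "cov2", class = "fructuric_domain_error")
})

test_that("adjusted means remove covariate imbalance", {
  set.seed(21)
  n <- 4000
  grp <- sample(1:2, n, TRUE)
  cov <- rnorm(n) + 1.5 * (grp == 2)  # imbalanced covariate, no true effect
  y <- 5 + 0.8 * cov + rnorm(n)
  dat <- tibble::tibble(grp = grp, cov = cov, y = y)
  crude <- compare_means(dat, "y", "grp")
  adj <- compare_means(dat, "y", "grp", covariates = "cov")
  raw_diff <- diff(crude$table$mean)
  adj_diff <- diff(adj$table$adjusted_mean)
  expect_gt(abs(raw_diff), 1.0)
  expect_lt(abs(adj_diff), 0.15)
})

test_that("crude logistic odds ratio equals the 2x2 closed form", {
  dat <- tibble::tibble(
    hyperuricemic = c(rep(TRUE, 50), rep(FALSE, 450),
                      rep(TRUE, 25), rep(FALSE, 475)),
    exposed = c(rep(1, 500), rep(0, 1000 - 500))
  )
  dat$exposed <- factor(dat$exposed, levels = c(0, 1))
  rr <- fit_logit(dat, "exposed")
  expect_equal(rr$table$or, (50 * 475) / (450 * 25), tolerance = 1e-6)
  expect_equal(rr$reference, "0")
  expect_true(all(rr$table$ci_low <= rr$table$or &
                    rr$table$or <= rr$table$ci_high))
})

test_that("null exposures produce odds ratios near one with covering CIs", {
  set.seed(31)
  n <- 20000
  dat <- tibble::tibble(
    hyperuricemic = rbinom(n, 1, 0.05) == 1,
    expo = sample(1:4, n, TRUE)
  )
  rr <- fit_logit(dat, "expo")
  expect_true(all(rr$table$ci_low < 1 & rr$table$ci_high > 1))
  expect_true(all(abs(log(rr$table$or)) < 0.5))
  expect_gt(rr$model_p, 0.01)
})

test_that("quasi-separation is flagged and empty levels dropped", {
  dat <- tibble::tibble(
    hyperuricemic = c(rep(TRUE, 20), rep(FALSE, 80)),
    expo = c(rep("b", 20), rep("a", 80))  # perfect separation
  )
  expect_warning(rr <- fit_logit(dat, "expo"), "quasi-separation")
  expect_true(all(rr$table$unstable))

  dat2 <- tibble::tibble(
    hyperuricemic = rbinom(200, 1, 0.3) == 1,
    expo = factor(sample(c("a", "b"), 200, TRUE), levels = c("a", "b", "c"))
  )
  expect_warning(rr2 <- fit_logit(dat2, "expo"), "empty exposure level")
  expect_equal(nrow(rr2$table), 1L)
})

test_that("Hosmer-Lemeshow test has g-2 degrees of freedom and calibrates", {
  set.seed(41)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-3 + 0.8 * x))
  fit <- glm(y ~ x, family = binomial())
  gof <- goodness_of_fit(fit, g = 10)
  expect_equal(gof$df, 8)
  expect_equal(gof$g_used, 10)

  # correctly specified models: p-values not concentrated near zero
  ps <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-2.5 + 0.7 * x))
    goodness_of_fit(glm(y ~ x, family = binomial()))$p_value
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)

  # strong misspecification is detected most of the time
  ps_bad <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    x <- rnorm(4000)
    y <- rbinom(4000, 1, plogis(-2 + 1.5 * x^2))
    goodness_of_fit(glm(y ~ x, family = binomial()))$p_value
  }, numeric(1))
  expect_gt(mean(ps_bad < 0.05), 0.6)

  # few distinct predicted probabilities collapse bins with a warning
  grp <- sample(1:3, 2000, TRUE)
  yb <- rbinom(2000, 1, c(0.05, 0.1, 0.2)[grp])
  fit2 <- glm(yb ~ factor(grp), family = binomial())
  expect_warning(goodness_of_fit(fit2), "collapsing bins")
})

test_that("two-group power behaves like the normal approximation", {
  # null odds ratio gives power equal to the two-sided alpha
  expect_equal(power_two_group(0.025, 1, 0.05, 1000), 0.05, tolerance = 1e-9)
  # worked case: prevalence 2.5%, OR 2, n = 2346 per group
  pw <- power_two_group(0.025, 2, 0.05, 2346)
  expect_gt(pw, 0.95)
  expect_lt(pw, 1.0)
  # monotone in n and in |log OR|
  ns <- c(200, 500, 1000, 4000)
  expect_true(all(diff(vapply(ns, function(n)
    power_two_group(0.025, 2, 0.05, n), numeric(1))) > 0))
  ors <- c(1.2, 1.5, 2, 3)
  expect_true(all(diff(vapply(ors, function(o)
    power_two_group(0.025, o, 0.05, 2000), numeric(1))) > 0))
  # protective effects mirror harmful ones through the log scale
  expect_gt(power_two_group(0.025, 0.5, 0.05, 5000),
            power_two_group(0.025, 0.75, 0.05, 5000))
  expect_error(power_two_group(0, 2, 0.05, 100),
               class = "fructuric_domain_error")
})
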