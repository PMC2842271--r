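# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("fructuric_domain_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("fructuric_config_error", "error")))
}

stop_lookup <- function(...) {
  stop(errorCondition(paste0(...), class = c("fructuric_lookup_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_domain(name, " must be a single non-missing number")
  }
  if (x < lower || x > upper) {
    stop_domain(name, " must be in [", lower, ", ", upper, "], got ", x)
  }
  invisible(x)
}

#' Weighted quantiles by cumulative-weight inversion
#'
#' Type-7-style linear interpolation on the weighted empirical CDF; with
#' equal weights it reduces exactly to `stats::quantile(type = 7)`.
#'
#' @param x numeric vector.
#' @param probs probabilities in `[0, 1]`.
#' @param w non-negative weights, recycled to `length(x)`; `NULL` for equal.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @keywords internal
#' @noRd
weighted_quantile <- function(x, probs, w = NULL) {
  if (is.null(w)) {
    return(unname(quantile(x, probs, type = 7, names = FALSE)))
  }
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  # positions of order statistics on the [0, 1] scale, weight-proportional
  cw <- cumsum(w)
  n <- length(x)
  if (n == 1L) return(rep(x, length(probs)))
  p_i <- (cw - w) / (sum(w) - w[n])
  p_i <- pmin(p_i, 1)
  vapply(probs, function(p) {
    j <- findInterval(p, p_i, rightmost.closed = TRUE)
    j <- max(1L, min(j, n - 1L))
    if (p_i[j + 1L] == p_i[j]) return(x[j + 1L])
    g <- (p - p_i[j]) / (p_i[j + 1L] - p_i[j])
    (1 - g) * x[j] + g * x[j + 1L]
  }, numeric(1))
}

# Weighted mean / SD / median with frequency-weight convention; equal
# weights reproduce mean(), sd() (n-1 denominator) and median() exactly.
wtd_mean <- function(x, w) sum(w * x) / sum(w)

wtd_sd <- function(x, w) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- wtd_mean(x, w)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(NA_real_)
  sqrt(sum(w * (x - m)^2) / denom)
}

wtd_median <- function(x, w) weighted_quantile(x, 0.5, w)
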