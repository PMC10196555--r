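#' Wilson score interval with continuity correction
#'
#' Confidence interval for a binomial proportion using the Wilson score
#' method with Newcombe's continuity correction, the procedure used to
#' report confidence intervals for allele frequencies estimated from
#' genotyped individuals. By convention the lower bound is 0 when there
#' are no successes and the upper bound is 1 when all trials succeed;
#' bounds are clipped to \[0, 1\].
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return A one-row tibble: `successes`, `n`, `estimate`, `lower`,
#'   `upper`, `confidence`.
#' @examples
#' wilson_ci_cc(5, 10)
#' @export
wilson_ci_cc <- function(successes, n, confidence = 0.95) {
  n <- check_count(n, "n", min = 1L)
  successes <- check_count(successes, "successes")
  if (successes > n) abort("`successes` must not exceed `n`.")
  check_fraction(confidence, "confidence")

  p <- successes / n
  z <- qnorm(1 - (1 - confidence) / 2)
  z2 <- z^2
  denom <- 2 * (n + z2)
  lower <- if (successes == 0) 0 else {
    (2 * n * p + z2 -
       (z * sqrt(z2 - 1 / n + 4 * n * p * (1 - p) + (4 * p - 2)) + 1)) / denom
  }
  upper <- if (successes == n) 1 else {
    (2 * n * p + z2 +
       (z * sqrt(z2 - 1 / n + 4 * n * p * (1 - p) - (4 * p - 2)) + 1)) / denom
  }
  tibble::tibble(
    successes = successes, n = n, estimate = p,
    lower = max(0, lower), upper = min(1, upper),
    confidence = confidence
  )
}

#' Allele frequency from a genotype tally
#'
#' Converts counts of individuals by genotype at a biallelic locus into
#' the resistance-allele frequency `(2 rr + rs) / (2 (ss + rs + rr))`, as
#' used to score the T92C mutation in resistant moths genotyped
#' individually.
#'
#' @param tally Data frame with integer columns `ss`, `rs`, `rr` (one row
#'   per tally; additional columns such as `year` are carried through).
#' @return The input with added columns `n_individuals` and `frequency`.
#' @examples
#' genotype_allele_frequency(tibble::tibble(year = 2016, ss = 2, rs = 6, rr = 2))
#' @export
genotype_allele_frequency <- function(tally) {
  if (!is.data.frame(tally) || !all(c("ss", "rs", "rr") %in% names(tally))) {
    abort("`tally` must be a data frame with columns ss, rs, rr.")
  }
  counts <- tally[c("ss", "rs", "rr")]
  if (any(as.matrix(counts) < 0)) abort("Genotype counts must be >= 0.")
  total <- tally$ss + tally$rs + tally$rr
  if (any(total < 1)) abort("Each genotype tally must contain at least one individual.")
  dplyr::mutate(
    tibble::as_tibble(tally),
    n_individuals = total,
    frequency = (2 * .data$rr + .data$rs) / (2 * total)
  )
}

#' Resistance percentage from diagnostic-dose bioassays
#'
#' Summarises bioassay records (larvae tested and surviving at the
#' diagnostic toxin concentration, e.g. 1 ug Cry1Ac per cm2 diet) for one
#' year: the unweighted mean across sites of the percent surviving, with a
#' site-level bootstrap confidence interval (sites resampled with
#' replacement, as for pooled allele frequencies).
#'
#' @param records Data frame with columns `n_tested` (>= 1) and
#'   `n_surviving` (0..`n_tested`), one row per site.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for a reproducible interval.
#' @param confidence Confidence level (default 0.95).
#' @return A one-row tibble: `n_sites`, `mean_pct`, `lower`, `upper`.
#' @examples
#' rec <- tibble::tibble(n_tested = c(100, 100, 100), n_surviving = c(5, 10, 15))
#' resistance_percentage(rec, seed = 1)
#' @export
resistance_percentage <- function(records, reps = 1000, seed = NULL,
                                  confidence = 0.95) {
  if (!is.data.frame(records) ||
      !all(c("n_tested", "n_surviving") %in% names(records)) ||
      nrow(records) == 0) {
    abort("`records` must be a non-empty data frame with columns n_tested and n_surviving.")
  }
  if (any(records$n_tested < 1)) abort("Every record needs `n_tested` >= 1.")
  if (any(records$n_surviving < 0 | records$n_surviving > records$n_tested)) {
    abort("`n_surviving` must lie in [0, n_tested].")
  }
  pct <- 100 * records$n_surviving / records$n_tested
  boot <- bootstrap_mean_ci(pct, reps = reps, seed = seed,
                            confidence = confidence)
  tibble::tibble(
    n_sites = length(pct), mean_pct = mean(pct),
    lower = boot$lower, upper = boot$upper
  )
}

# Percentile bootstrap CI for a mean over sites (resampling sites with
# replacement). Deterministic under a fixed seed.
bootstrap_mean_ci <- function(values, reps = 1000, seed = NULL,
                              confidence = 0.95) {
  reps <- check_count(reps, "reps", min = 1L)
  check_fraction(confidence, "confidence")
  draw <- function() {
    means <- vapply(
      seq_len(reps),
      function(i) mean(sample(values, replace = TRUE)),
      numeric(1)
    )
    quantile(means, probs = c((1 - confidence) / 2, 1 - (1 - confidence) / 2),
             names = FALSE)
  }
  ci <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(lower = ci[[1]], upper = ci[[2]])
}

#' Linear regression of log-transformed values on a predictor
#'
#' Ordinary least squares of `log10(y)` on `x`, the transformation used to
#' summarise monitoring time series (e.g. resistance frequency against
#' year). All response values must be strictly positive.
#'
#' @param data Data frame containing the variables.
#' @param x,y Unquoted column names of the predictor and the (positive)
#'   response.
#' @return An object of class `log_lm`; see [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(year = 2010:2016, freq = 10^(0.16 * (2010:2016) - 312))
#' glance(log_linear_regression(d, year, freq))
#' @export
log_linear_regression <- function(data, x, y) {
  x <- as_name(enquo(x))
  y <- as_name(enquo(y))
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  if (nrow(data) < 3) abort("Need at least 3 points for the regression.")
  bad <- which(!(data[[y]] > 0))
  if (length(bad)) {
    abort(sprintf("Non-positive response value(s) at %s = %s cannot be log-transformed.",
                  x, paste(data[[x]][bad], collapse = ", ")))
  }
  df <- tibble::tibble(.x = data[[x]], .logy = log10(data[[y]]))
  fit <- lm(.logy ~ .x, data = df)
  structure(list(fit = fit, data = data, x = x, y = y, base = 10),
            class = "log_lm")
}

#' @export
print.log_lm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("log10(%s) = %.4g %s %s %.4g   (R2 = %.3g, df = %d, p = %.3g)\n",
              x$y, g$slope, ifelse(g$intercept < 0, "-", "+"), x$x,
              abs(g$intercept), g$r.squared, g$df, g$p.value))
  invisible(x)
}

#' @describeIn log_linear_regression Coefficient table: `term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`.
#' @param ... Unused.
#' @method tidy log_lm
#' @export
tidy.log_lm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", x$x),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @describeIn log_linear_regression One-row fit summary: `slope`,
#'   `intercept`, `r.squared`, `p.value` (two-sided, for the slope), `df`
#'   (residual, n - 2) and `n`.
#' @method glance log_lm
#' @export
glance.log_lm <- function(x, ...) {
  sm <- summary(x$fit)
  n <- length(sm$residuals)
  tibble::tibble(
    slope = unname(coef(x$fit)[2]),
    intercept = unname(coef(x$fit)[1]),
    r.squared = sm$r.squared,
    p.value = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
    df = n - 2L,
    n = n
  )
}

#' Pearson correlation of log-transformed monitoring metrics
#'
#' Correlation between two strictly positive measurements after log10
#' transformation, with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom — e.g. bioassay survival percentage against
#' DNA-screening allele frequency.
#'
#' @param data Data frame containing the variables.
#' @param x,y Unquoted column names of the two positive measurements.
#' @return A one-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p.value`, `n`.
#' @export
log_pearson_correlation <- function(data, x, y) {
  x <- as_name(enquo(x))
  y <- as_name(enquo(y))
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  if (nrow(data) < 3) abort("Need at least 3 pairs for the correlation.")
  if (any(!(data[[x]] > 0)) || any(!(data[[y]] > 0))) {
    abort("All values must be strictly positive for the log transformation.")
  }
  ct <- cor.test(log10(data[[x]]), log10(data[[y]]), method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate), statistic = unname(ct$statistic),
    df = unname(ct$parameter), p.value = ct$p.value, n = nrow(data)
  )
}

#' Pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance (equal-variance assumption),
#' two-sided, on `n_a + n_b - 2` degrees of freedom — the form used to
#' compare yearly refuge means between monitoring periods.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return A one-row tibble: `statistic` (t), `df`, `p.value`,
#'   `mean_a`, `mean_b`.
#' @examples
#' two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
two_sample_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 values for a pooled t-test.")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}
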