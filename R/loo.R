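#' Ordinary least-squares fit of a univariate linear model
#'
#' @param x Predictor (metabolite concentration), non-constant, `n >= 4`.
#' @param y Response (index values).
#' @return List of class `lm_fit` with `slope`, `intercept`, `r_squared`,
#'   `ss_total`, `sse`, `n`, `p` (= 1 predictor), `fitted`, `residuals`,
#'   `leverages`, and `degenerate` (TRUE when y is constant, in which case
#'   `r_squared` is `NA`).
#' @export
fit_univariate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("length mismatch", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_total <- sum((y - mean(y))^2)
  sse <- sum(res^2)
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    r_squared = if (ss_total > 0) 1 - sse / ss_total else NA_real_,
    ss_total = ss_total, sse = sse, n = n, p = 1L,
    fitted = unname(stats::fitted(fit)), residuals = unname(res),
    leverages = unname(stats::hatvalues(fit)),
    degenerate = ss_total == 0
  ), class = "lm_fit")
}

#' Leave-one-out PRESS and Q-squared
#'
#' PRESS is the sum of squared leave-one-out prediction errors: each
#' observation is predicted from the model refit without it. For least
#' squares this is computed exactly through the hat-matrix shortcut
#' `e_i / (1 - h_ii)` (algebraically identical to n explicit refits).
#' `Q^2 = 1 - PRESS/SS` with SS the total sum of squares of y about its
#' full-sample mean.
#'
#' @param x,y As in [fit_univariate()].
#' @return List with `press`, `q2`, `ss`.
#' @export
loo_press_q2 <- function(x, y) {
  fit <- fit_univariate(x, y)
  if (fit$degenerate) stop("constant response: SS = 0, Q^2 undefined",
                           call. = FALSE)
  h <- fit$leverages
  if (any(h >= 1 - 1e-12)) {
    stop("leave-one-out subset degenerate (leverage ~ 1)", call. = FALSE)
  }
  press <- sum((fit$residuals / (1 - h))^2)
  list(press = press, q2 = 1 - press / fit$ss_total, ss = fit$ss_total)
}

#' Asymptotic Q-squared correction of R-squared
#'
#' An n-dependent shrinkage of the fitted R^2 that approximates the
#' leave-one-out Q^2 without refitting. Variants:
#' \describe{
#'   \item{squared (default)}{`1 - (1 - R^2) * ((n - 1)/(n - p - 1))^2`}
#'   \item{adjusted}{`1 - (1 - R^2) * (n - 1)/(n - p - 1)` (the classical
#'     adjusted R^2)}
#' }
#' Both satisfy `q2_asym <= r_squared`, with equality at `r_squared = 1`,
#' and increase toward `r_squared` as n grows.
#'
#' @param r_squared Fitted coefficient of determination in \[0, 1\].
#' @param n Sample size, `n > p + 1`.
#' @param p Number of predictors (default 1).
#' @param variant `"squared"` or `"adjusted"`.
#' @return The corrected value.
#' @export
#' @examples
#' q2_asymptotic(0.8905, n = 14)  # 0.8715
q2_asymptotic <- function(r_squared, n, p = 1,
                          variant = c("squared", "adjusted")) {
  variant <- match.arg(variant)
  if (r_squared < 0 || r_squared > 1) stop("r_squared must be in [0, 1]",
                                           call. = FALSE)
  if (n <= p + 1) stop("need n > p + 1", call. = FALSE)
  shrink <- (n - 1) / (n - p - 1)
  if (variant == "squared") shrink <- shrink^2
  1 - (1 - r_squared) * shrink
}

#' Four-criterion model acceptance gate
#'
#' The OECD-style minimal validation criteria for a predictive univariate
#' relationship: `0 < Q2asym - Q2 < 1`, `Q2 >= 0.65`, `R2 >= 0.85` and
#' `Q2 - R2 < 0` (strict). A model passes only when all four hold.
#'
#' @param q2 Cross-validated Q^2.
#' @param r2 Fitted R^2.
#' @param q2_asym Asymptotic Q^2.
#' @return List with the four boolean flags (`crit_q2asym_gap`, `crit_q2`,
#'   `crit_r2`, `crit_q2_lt_r2`), the signed differences, and `pass`.
#' @export
validation_gate <- function(q2, r2, q2_asym) {
  gap <- q2_asym - q2
  flags <- list(
    crit_q2asym_gap = gap > 0 && gap < 1,
    crit_q2 = q2 >= 0.65,
    crit_r2 = r2 >= 0.85,
    crit_q2_lt_r2 = (q2 - r2) < 0
  )
  c(flags,
    list(q2_minus_r2 = q2 - r2, q2asym_minus_q2 = gap,
         pass = all(unlist(flags))))
}

#' Leave-one-out validation of a metabolite-index relationship
#'
#' Fits y on x by least squares, runs the exact leave-one-out procedure,
#' computes the asymptotic Q^2 from the fitted R^2, and applies the
#' four-criterion acceptance gate.
#'
#' @param x Metabolite concentrations.
#' @param y Index values (paired with `x`).
#' @param variant Asymptotic-Q^2 variant, see [q2_asymptotic()].
#' @return List of class `loo_report` with `q2`, `r2`, `q2_asym`, `ss`,
#'   `press`, `sse`, `n`, the gate flags and differences, `pass`, and the
#'   recorded `variant`.
#' @export
validate_relationship <- function(x, y, variant = c("squared", "adjusted")) {
  variant <- match.arg(variant)
  fit <- fit_univariate(x, y)
  loo <- loo_press_q2(x, y)
  q2a <- q2_asymptotic(fit$r_squared, fit$n, fit$p, variant)
  gate <- validation_gate(loo$q2, fit$r_squared, q2a)
  structure(c(list(q2 = loo$q2, r2 = fit$r_squared, q2_asym = q2a,
                   ss = loo$ss, press = loo$press, sse = fit$sse,
                   n = fit$n, variant = variant,
                   slope = fit$slope, intercept = fit$intercept),
              gate),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("LOO validation (n = %d, Q2asym variant: %s)\n", x$n, x$variant))
  cat(sprintf("  R2 = %.4f  Q2 = %.4f  Q2asym = %.4f\n", x$r2, x$q2, x$q2_asym))
  cat(sprintf("  SS = %.4f  PRESS = %.4f  Q2 - R2 = %.4f\n",
              x$ss, x$press, x$q2_minus_r2))
  verdict <- function(ok) if (ok) "pass" else "FAIL"
  cat(sprintf("  0 < Q2asym - Q2 < 1 : %s (%.4f)\n",
              verdict(x$crit_q2asym_gap), x$q2asym_minus_q2))
  cat(sprintf("  Q2 >= 0.65          : %s\n", verdict(x$crit_q2)))
  cat(sprintf("  R2 >= 0.85          : %s\n", verdict(x$crit_r2)))
  cat(sprintf("  Q2 - R2 < 0         : %s\n", verdict(x$crit_q2_lt_r2)))
  cat("  verdict:", if (x$pass) "fully predictive (all criteria met)"
      else "not validated", "\n")
  invisible(x)
}

#' Simulate a correlated (x, y) pair with a target population r-squared
#'
#' Utility for power/discrimination studies of the validation gate:
#' `y = sqrt(r2) * x + sqrt(1 - r2) * e` with standard-normal `x` and `e`,
#' so the population squared correlation equals `r2`.
#'
#' @param n Sample size.
#' @param r2 Target population r^2 in \[0, 1\].
#' @return List with `x` and `y`.
#' @export
simulate_correlated_xy <- function(n, r2) {
  if (r2 < 0 || r2 > 1) stop("r2 must be in [0, 1]", call. = FALSE)
  x <- stats::rnorm(n)
  y <- sqrt(r2) * x + sqrt(1 - r2) * stats::rnorm(n)
  list(x = x, y = y)
}
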