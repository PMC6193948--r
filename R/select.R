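# Nested-model comparison: Michaelis-Menten (2 parameters) vs the
# interacting-sites law (4 parameters) by extra-sum-of-squares F-test.

#' Extra-sum-of-squares F statistic for nested weighted fits
#'
#' \deqn{F = \frac{(wssr_{simple} - wssr_{complex})/(p_{complex} - p_{simple})}
#'               {wssr_{complex}/(n - p_{complex})}}
#'
#' A negative numerator (the complex fit worse than the simple one, which
#' can only happen through solver tolerance) is clamped to `F = 0` with a
#' `"clamped"` attribute set. The statistic is invariant to rescaling all
#' weights by a common factor.
#'
#' @param wssr_simple,wssr_complex weighted SSR of the simple / complex fit.
#' @param p_simple,p_complex parameter counts (`p_complex > p_simple`).
#' @param n number of data points (`n > p_complex`).
#' @return The F value (>= 0), with attribute `clamped` (logical).
#' @export
#' @examples
#' f_statistic(10, 5, 2, 4, 20) # 8
f_statistic <- function(wssr_simple, wssr_complex, p_simple, p_complex, n) {
  if (wssr_simple < 0 || wssr_complex < 0)
    stop("wssr values must be non-negative", call. = FALSE)
  if (p_complex <= p_simple)
    stop("'p_complex' must exceed 'p_simple'", call. = FALSE)
  if (n <= p_complex)
    stop(sprintf(
      "not enough points for the F-test: n = %d <= p_complex = %d",
      n, p_complex), call. = FALSE)
  num <- (wssr_simple - wssr_complex) / (p_complex - p_simple)
  den <- wssr_complex / (n - p_complex)
  clamped <- FALSE
  if (num < 0) { num <- 0; clamped <- TRUE }
  f <- if (den == 0) {
    if (num == 0) 0 else Inf  # perfect complex fit
  } else num / den
  attr(f, "clamped") <- clamped
  f
}

#' Compare nested kinetic fits by F-test
#'
#' `anova()` on two `"kinfit"` objects fitted to the same dataset performs
#' the extra-sum-of-squares F-test between the Michaelis-Menten and the
#' interacting-sites fit. The interacting-sites model is selected iff
#' `p_value < alpha`; a boundary tie (`p_value == alpha`) keeps the simpler
#' model (parsimony).
#'
#' @param object,object2 `"kinfit"` objects on the same data, one MM and
#'   one IS (either order).
#' @param alpha significance level (default 0.05, i.e. the 95% confidence
#'   level).
#' @param ... unused.
#' @return An object of class `"kin_model_comparison"` with fields
#'   `f_value`, `df_num`, `df_den`, `p_value`, `alpha`, `selected`
#'   (`"MM"` or `"IS"`), `clamped`, and both fits.
#' @export
anova.kinfit <- function(object, object2, alpha = 0.05, ...) {
  select_model(object, object2, alpha = alpha)
}

#' @rdname anova.kinfit
#' @param fit_mm,fit_is the two fits (order-insensitive; they are matched
#'   by their `model` field).
#' @export
select_model <- function(fit_mm, fit_is, alpha = 0.05) {
  stopifnot(inherits(fit_mm, "kinfit"), inherits(fit_is, "kinfit"))
  if (fit_mm$model == "IS" && fit_is$model == "MM") {
    tmp <- fit_mm; fit_mm <- fit_is; fit_is <- tmp
  }
  if (fit_mm$model != "MM" || fit_is$model != "IS")
    stop("need one MM fit and one IS fit", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  same <- isTRUE(all.equal(fit_mm$data$c0, fit_is$data$c0)) &&
    isTRUE(all.equal(fit_mm$data$v0, fit_is$data$v0)) &&
    isTRUE(all.equal(fit_mm$w, fit_is$w))
  if (!same)
    stop("the two fits were not obtained on the same dataset/weights",
         call. = FALSE)
  n <- fit_mm$n_points
  p_mm <- length(fit_mm$par); p_is <- length(fit_is$par)
  f <- f_statistic(fit_mm$wssr, fit_is$wssr, p_mm, p_is, n)
  df_num <- p_is - p_mm
  df_den <- n - p_is
  p_value <- stats::pf(as.numeric(f), df_num, df_den, lower.tail = FALSE)
  structure(list(
    f_value = as.numeric(f),
    df_num = df_num,
    df_den = df_den,
    p_value = p_value,
    alpha = alpha,
    selected = if (p_value < alpha) "IS" else "MM",
    clamped = attr(f, "clamped"),
    fit_mm = fit_mm,
    fit_is = fit_is
  ), class = "kin_model_comparison")
}

#' Fit both rate laws and select between them
#'
#' Convenience wrapper: fits the MM and IS models on the same dataset with
#' shared weighting and multi-start settings (reusing the MM optimum as the
#' embedded IS start) and runs the F-test.
#'
#' @inheritParams fit_kinetics
#' @inheritParams select_model
#' @return A `"kin_model_comparison"` object.
#' @export
compare_rate_laws <- function(data, weights = c("sd", "uniform", "relative"),
                              cv = 0.05, n_starts = 20, seed = 0,
                              alpha = 0.05, ...) {
  weights <- match.arg(weights)
  fit_mm <- fit_kinetics(data, "MM", weights = weights, cv = cv,
                         n_starts = n_starts, seed = seed, ...)
  fit_is <- fit_kinetics(data, "IS", weights = weights, cv = cv,
                         n_starts = n_starts, seed = seed,
                         mm_fit = fit_mm, ...)
  select_model(fit_mm, fit_is, alpha = alpha)
}

#' @export
print.kin_model_comparison <- function(x, digits = 4, ...) {
  cat("Nested rate-law comparison (extra-sum-of-squares F-test)\n")
  cat(sprintf("  wssr: MM = %s (p = %d), IS = %s (p = %d), n = %d\n",
              format(signif(x$fit_mm$wssr, digits)), length(x$fit_mm$par),
              format(signif(x$fit_is$wssr, digits)), length(x$fit_is$par),
              x$fit_mm$n_points))
  cat(sprintf("  F(%d, %d) = %s, p = %s, alpha = %s\n",
              x$df_num, x$df_den, format(signif(x$f_value, digits)),
              format(signif(x$p_value, digits)), format(x$alpha)))
  cat("  selected model:", x$selected, "\n")
  invisible(x)
}
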