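# Weighted multi-start nonlinear least squares for the MM and
# interacting-sites rate laws. Optimization runs in log-parameter space
# (positivity by construction); the local solver is Levenberg-Marquardt
# (minpack.lm::nls.lm); starts come from a log-scaled Latin hypercube
# around the data-implied parameter scale, plus, for the interacting-sites
# model, the Michaelis-Menten-embedded point (a = 1, b = 1) so that the
# best interacting-sites fit can never be worse than the best MM fit.

model_par_names <- function(model) {
  switch(model, MM = c("Km", "Vmax"), IS = c("Km1", "Vmax1", "a", "b"),
         stop("unknown model '", model, "'", call. = FALSE))
}

model_velocity <- function(model, par, c0) {
  if (model == "MM") {
    par[["Vmax"]] * c0 / (par[["Km"]] + c0)
  } else {
    Km1 <- par[["Km1"]]; Vmax1 <- par[["Vmax1"]]
    a <- par[["a"]]; b <- par[["b"]]
    (2 * Vmax1 * c0 / Km1 + 2 * b * Vmax1 * c0^2 / (a * Km1^2)) /
      (1 + 2 * c0 / Km1 + c0^2 / (a * Km1^2))
  }
}

params_to_vector <- function(params) {
  if (inherits(params, "mm_params")) c(Km = params$Km, Vmax = params$Vmax)
  else if (inherits(params, "is_params"))
    c(Km1 = params$Km1, Vmax1 = params$Vmax1, a = params$a, b = params$b)
  else unlist(params)
}

vector_to_params <- function(model, par) {
  if (model == "MM") mm_params(par[["Km"]], par[["Vmax"]])
  else is_params(par[["Km1"]], par[["Vmax1"]], par[["a"]], par[["b"]])
}

#' Resolve fitting weights for a velocity dataset
#'
#' Implements the weighting policies used throughout the package:
#' `"sd"` takes \eqn{w_i = 1/SD_i^2} from the per-point standard deviation
#' of the average rate; `"uniform"` sets all weights to 1; `"relative"`
#' assumes a constant coefficient of variation, \eqn{w_i = 1/(cv\,v_i)^2}.
#' An SD of zero (or a missing SD) under the `"sd"` policy is an error
#' naming the offending point - it is never silently imputed, because the
#' weighting choice can change which kinetic model the F-test selects.
#'
#' @param data a [velocity_dataset()] (or coercible data.frame).
#' @param weights weighting policy.
#' @param cv coefficient of variation for the `"relative"` policy.
#' @return Numeric vector of weights, one per point.
#' @export
resolve_weights <- function(data, weights = c("sd", "uniform", "relative"),
                            cv = 0.05) {
  data <- as_velocity_dataset(data)
  weights <- match.arg(weights)
  switch(weights,
    uniform = rep(1, nrow(data)),
    relative = {
      if (cv <= 0) stop("'cv' must be positive", call. = FALSE)
      if (any(data$v0 <= 0))
        stop("relative weighting needs strictly positive velocities",
             call. = FALSE)
      1 / (cv * data$v0)^2
    },
    sd = {
      bad <- which(is.na(data$sd) | data$sd == 0)
      if (length(bad))
        stop(sprintf(
          "SD-based weighting impossible: SD missing or zero at point(s) %s (c0 = %s); use weights = 'uniform' or 'relative'",
          paste(bad, collapse = ", "),
          paste(format(data$c0[bad]), collapse = ", ")), call. = FALSE)
      1 / data$sd^2
    })
}

#' Weighted sum of squared residuals
#'
#' \eqn{\sum_i w_i (v_{0,i} - v_{model}(c_{0,i}))^2} with
#' \eqn{w_i = 1/SD_i^2} under the default policy.
#'
#' @param params an [mm_params()] or [is_params()] object.
#' @param data a [velocity_dataset()].
#' @inheritParams resolve_weights
#' @return The weighted SSR (>= 0).
#' @export
weighted_ssr <- function(params, data,
                         weights = c("sd", "uniform", "relative"),
                         cv = 0.05) {
  data <- as_velocity_dataset(data)
  w <- resolve_weights(data, weights, cv)
  model <- if (inherits(params, "mm_params")) "MM" else "IS"
  v_hat <- model_velocity(model, params_to_vector(params), data$c0)
  sum(w * (data$v0 - v_hat)^2)
}

# Data-implied parameter scales used to centre the multi-start hypercube.
start_scales <- function(model, data) {
  cpos <- data$c0[data$c0 > 0]
  km_scale <- if (length(cpos)) stats::median(cpos) else 1
  vmax_scale <- max(data$v0, na.rm = TRUE)
  if (!is.finite(vmax_scale) || vmax_scale <= 0) vmax_scale <- 1
  if (model == "MM") c(Km = km_scale, Vmax = vmax_scale)
  else c(Km1 = km_scale, Vmax1 = vmax_scale / 2, a = 1, b = 1)
}

#' Fit a kinetic rate law by weighted multi-start nonlinear least squares
#'
#' Estimates the parameters of the Michaelis-Menten (`model = "MM"`) or
#' two-site interacting-sites (`model = "IS"`) rate law from replicate
#' initial-velocity data. Minimizes the weighted SSR (weights `1/SD^2` by
#' default) over log-parameters with a Levenberg-Marquardt solver started
#' from `n_starts` points of a log-scaled Latin hypercube spanning
#' `[1e-3, 1e3]` times the data-implied scale of each parameter. For the
#' interacting-sites model one additional start is always the MM-embedded
#' point (`a = 1`, `b = 1`, `Km1 = Km_MM`, `Vmax1 = Vmax_MM / 2`), obtained
#' from an internal MM fit (or from `mm_fit` if supplied), which guarantees
#' the nesting property `wssr(IS) <= wssr(MM)` up to solver tolerance.
#'
#' Standard errors are asymptotic: with \eqn{J} the weighted Jacobian at
#' the optimum, the covariance of the log-parameters is
#' \eqn{s^2 (J^T J)^{-1}} with \eqn{s^2 = wssr/(n - p)}, mapped to the
#' natural scale by the delta method. A singular information matrix yields
#' `NA` standard errors with a warning flag rather than an error.
#'
#' Starts are compared by final weighted SSR; ties (relative difference
#' below `1e-8`) go to the earliest start for reproducibility. A start
#' that exhausts `maxiter` is flagged non-converged but its optimum still
#' competes, since near-flat SSR valleys with several similar minima are a
#' known feature of this model class.
#'
#' @param data a [velocity_dataset()] or data.frame with columns `c0`,
#'   `v0` and optionally `sd`, `n_rep`.
#' @param model `"MM"` (2 parameters) or `"IS"` (4 parameters).
#' @inheritParams resolve_weights
#' @param n_starts number of Latin-hypercube starts (>= 1).
#' @param seed integer seed for the start hypercube (default 0).
#' @param mm_fit optional `"kinfit"` MM fit on the same data, used for the
#'   embedded start of an IS fit.
#' @param maxiter,ftol,ptol Levenberg-Marquardt control (see
#'   [minpack.lm::nls.lm.control()]).
#'
#' @return An object of class `"kinfit"` with components `model`, `params`
#'   (an [mm_params()]/[is_params()] object), `par` (named vector),
#'   `stderr`, `wssr`, `dof`, `n_points`, `weights`, `w`, `data`,
#'   `fitted`, `n_starts`, `converged_starts`, `best_start`, `starts`
#'   (per-start diagnostics).
#' @seealso [anova.kinfit()] for the nested F-test, [select_model()].
#' @export
#' @examples
#' p <- is_params(Km1 = 0.015, Vmax1 = 10.8, a = 266.67, b = 0.7593)
#' grid <- make_concentration_grid(0.015, 4, n_points = 16)
#' d <- simulate_velocity_dataset(p, grid, cv = 0.05, n_rep = 3, seed = 1)
#' fit <- fit_kinetics(d, model = "IS", n_starts = 10)
#' coef(fit)
fit_kinetics <- function(data, model = c("MM", "IS"),
                         weights = c("sd", "uniform", "relative"),
                         cv = 0.05, n_starts = 20, seed = 0,
                         mm_fit = NULL, maxiter = 500,
                         ftol = 1e-12, ptol = 1e-12) {
  data <- as_velocity_dataset(data)
  model <- match.arg(model)
  weights <- match.arg(weights)
  par_names <- model_par_names(model)
  p <- length(par_names)
  n <- nrow(data)
  if (n < p + 1L)
    stop(sprintf("need at least %d points to fit a %d-parameter model",
                 p + 1L, p), call. = FALSE)
  w <- resolve_weights(data, weights, cv)
  sw <- sqrt(w)
  # clamp log-parameters to a huge finite box so a runaway LM step (e.g.
  # the interaction factor drifting to +Inf on null data, where the model
  # is locally flat in it) cannot overflow exp()
  theta_cap <- log(1e15)
  clamp <- function(theta) pmin(pmax(theta, -theta_cap), theta_cap)
  resid_fn <- function(theta) {
    sw * (data$v0 - model_velocity(model,
                                   stats::setNames(exp(clamp(theta)),
                                                   par_names),
                                   data$c0))
  }

  # start list: log-LHS over [1e-3, 1e3] x data-implied scale
  scales <- start_scales(model, data)
  starts <- list()
  if (n_starts >= 1L) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    u <- lhs::randomLHS(n_starts, p)
    for (i in seq_len(n_starts))
      starts[[i]] <- log(scales) + (u[i, ] * 6 - 3) * log(10)
  }
  if (model == "IS") {
    if (is.null(mm_fit))
      mm_fit <- fit_kinetics(data, "MM", weights = weights, cv = cv,
                             n_starts = max(5L, ceiling(n_starts / 4)),
                             seed = seed, maxiter = maxiter,
                             ftol = ftol, ptol = ptol)
    if (!identical(mm_fit$model, "MM"))
      stop("'mm_fit' must be an MM fit", call. = FALSE)
    emb <- log(c(Km1 = unname(coef(mm_fit)[["Km"]]),
                 Vmax1 = unname(coef(mm_fit)[["Vmax"]]) / 2,
                 a = 1, b = 1))
    starts <- c(list(emb), starts)
  }

  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                     ptol = ptol)
  runs <- lapply(seq_along(starts), function(i) {
    fit <- tryCatch(minpack.lm::nls.lm(par = starts[[i]], fn = resid_fn,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit))
      return(list(ok = FALSE, wssr = Inf, converged = FALSE,
                  message = "solver error"))
    list(ok = TRUE, wssr = fit$deviance, theta = fit$par,
         converged = fit$info %in% 1:4, message = fit$message)
  })
  ok <- vapply(runs, `[[`, logical(1), "ok")
  if (!any(ok)) {
    msgs <- vapply(runs, `[[`, character(1), "message")
    stop("no start converged; per-start diagnostics: ",
         paste(sprintf("[%d] %s", seq_along(msgs), msgs), collapse = "; "),
         call. = FALSE)
  }
  wssrs <- vapply(runs, `[[`, numeric(1), "wssr")
  best_w <- min(wssrs)
  tol <- 1e-8 * max(best_w, .Machine$double.eps)
  best <- which(wssrs <= best_w + tol)[1L]  # earliest start on ties
  theta_hat <- clamp(runs[[best]]$theta)
  par_hat <- stats::setNames(exp(theta_hat), par_names)
  wssr <- runs[[best]]$wssr
  dof <- n - p
  fitted <- model_velocity(model, par_hat, data$c0)

  # asymptotic standard errors via central-difference Jacobian in theta
  J <- jacobian_fd(resid_fn, theta_hat)
  info <- crossprod(J)
  s2 <- wssr / dof
  cov_theta <- tryCatch(solve(info) * s2, error = function(e) NULL)
  if (is.null(cov_theta) || any(!is.finite(diag(cov_theta))) ||
      any(diag(cov_theta) < 0)) {
    stderr <- stats::setNames(rep(NA_real_, p), par_names)
    vcov_nat <- matrix(NA_real_, p, p, dimnames = list(par_names, par_names))
    stderr_defined <- FALSE
  } else {
    # delta method: d(exp theta)/d theta = exp(theta)
    D <- diag(par_hat, nrow = p)
    vcov_nat <- D %*% cov_theta %*% D
    dimnames(vcov_nat) <- list(par_names, par_names)
    stderr <- stats::setNames(sqrt(diag(vcov_nat)), par_names)
    stderr_defined <- TRUE
  }

  structure(list(
    model = model,
    params = vector_to_params(model, par_hat),
    par = par_hat,
    stderr = stderr,
    stderr_defined = stderr_defined,
    vcov = vcov_nat,
    wssr = wssr,
    dof = dof,
    n_points = n,
    weights = weights,
    cv = cv,
    w = w,
    data = data,
    fitted = fitted,
    n_starts = length(starts),
    converged_starts = sum(vapply(runs, function(r)
      isTRUE(r$converged), logical(1))),
    best_start = best,
    seed = seed,
    starts = data.frame(
      start = seq_along(runs),
      wssr = wssrs,
      converged = vapply(runs, function(r) isTRUE(r$converged), logical(1))),
    call = match.call()
  ), class = "kinfit")
}

# central-difference Jacobian of a vector-valued function
jacobian_fd <- function(fn, x, h = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  J
}

#' @export
coef.kinfit <- function(object, ...) object$par

#' @export
vcov.kinfit <- function(object, ...) object$vcov

#' @export
deviance.kinfit <- function(object, ...) object$wssr

#' @export
fitted.kinfit <- function(object, ...) object$fitted

#' @export
df.residual.kinfit <- function(object, ...) object$dof

#' Residuals of a kinetic fit
#'
#' @param object a `"kinfit"` object.
#' @param type `"weighted"` (residuals scaled by sqrt of the fitting
#'   weights, the quantities the optimizer minimized) or `"response"`
#'   (raw velocity residuals, U mg^-1).
#' @param ... unused.
#' @export
residuals.kinfit <- function(object, type = c("weighted", "response"), ...) {
  type <- match.arg(type)
  r <- object$data$v0 - object$fitted
  if (type == "weighted") r * sqrt(object$w) else r
}

#' Predicted velocities from a kinetic fit
#'
#' @param object a `"kinfit"` object.
#' @param newdata numeric vector of concentrations (mM), or a data.frame
#'   with a `c0` column; defaults to the fitted concentrations.
#' @param ... unused.
#' @export
predict.kinfit <- function(object, newdata = NULL, ...) {
  c0 <- if (is.null(newdata)) object$data$c0
        else if (is.numeric(newdata)) newdata
        else newdata$c0
  check_concentration(c0)
  model_velocity(object$model, object$par, c0)
}

#' @export
print.kinfit <- function(x, digits = 4, ...) {
  cat(sprintf("%s rate-law fit (weighted NLS, %d starts, %d converged)\n",
              if (x$model == "MM") "Michaelis-Menten"
              else "Interacting-sites", x$n_starts, x$converged_starts))
  est <- format(signif(x$par, digits))
  se <- ifelse(is.na(x$stderr), "NA", format(signif(x$stderr, digits)))
  cat(paste(sprintf("  %-6s %s +/- %s", names(x$par), est, se),
            collapse = "\n"), "\n")
  if (x$model == "IS") {
    d <- derive_secondary_parameters(x$params)
    cat(sprintf("  derived: Km2 = %s mM, Vmax2 = %s U/mg, 2*Vmax2 = %s U/mg\n",
                format(signif(d[["Km2"]], digits)),
                format(signif(d[["Vmax2"]], digits)),
                format(signif(saturating_velocity(x$params), digits))))
  }
  cat(sprintf("  weighted SSR = %s on %d residual df (weights: %s)\n",
              format(signif(x$wssr, digits)), x$dof, x$weights))
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  tab <- cbind(Estimate = object$par, `Std. Error` = object$stderr)
  out <- list(fit = object, coefficients = tab,
              sigma2 = object$wssr / object$dof)
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  reduced chi-square (wssr/dof) = %s\n",
              format(signif(x$sigma2, digits))))
  invisible(x)
}

#' Diagnostic plot of a kinetic fit
#'
#' Plots the data (error bars = SD where available) with the fitted curve
#' on a log concentration axis.
#'
#' @param x a `"kinfit"` object.
#' @param n_curve number of points on the plotted curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kinfit <- function(x, n_curve = 200, ...) {
  d <- x$data
  cpos <- d$c0[d$c0 > 0]
  xx <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = n_curve))
  graphics::plot(d$c0, d$v0, log = "x",
                 xlab = "substrate concentration [mM]",
                 ylab = "initial velocity [U/mg]", ...)
  has_sd <- !is.na(d$sd) & d$sd > 0
  if (any(has_sd))
    graphics::arrows(d$c0[has_sd], d$v0[has_sd] - d$sd[has_sd],
                     d$c0[has_sd], d$v0[has_sd] + d$sd[has_sd],
                     angle = 90, code = 3, length = 0.03)
  graphics::lines(xx, predict(x, xx))
  invisible(x)
}

#' Serializable report of a kinetic fit or model comparison
#'
#' Flattens a `"kinfit"` or `"kin_model_comparison"` object into a plain
#' nested list carrying the estimates, derived secondary constants,
#' weighted SSR, degrees of freedom, standard errors, start diagnostics
#' and the full resolved configuration (weighting policy, seed, starts),
#' suitable for `jsonlite::toJSON()`.
#'
#' @param x a `"kinfit"` or `"kin_model_comparison"` object.
#' @return A nested list of plain vectors.
#' @export
kinfit_report <- function(x) {
  if (inherits(x, "kin_model_comparison")) {
    return(list(kind = "model_comparison",
                f_value = x$f_value, df_num = x$df_num, df_den = x$df_den,
                p_value = x$p_value, alpha = x$alpha, selected = x$selected,
                mm = kinfit_report(x$fit_mm), is = kinfit_report(x$fit_is)))
  }
  stopifnot(inherits(x, "kinfit"))
  rep <- list(kind = "fit", model = x$model, params = as.list(x$par),
              stderr = as.list(x$stderr), wssr = x$wssr, dof = x$dof,
              n_points = x$n_points,
              config = list(weights = x$weights, cv = x$cv, seed = x$seed,
                            n_starts = x$n_starts),
              converged_starts = x$converged_starts,
              best_start = x$best_start)
  if (x$model == "IS")
    rep$derived <- as.list(c(derive_secondary_parameters(x$params),
                             saturating_velocity = saturating_velocity(x$params)))
  rep
}
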