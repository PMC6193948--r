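#' Michaelis-Menten parameter bundle
#'
#' Constructs a validated parameter set for the classical Michaelis-Menten
#' rate law \eqn{v_0(c_0) = V_{max} c_0 / (K_m + c_0)}.
#'
#' @param Km Michaelis constant of the site (mM, > 0).
#' @param Vmax maximal velocity (U mg^-1, > 0).
#'
#' @return An object of class `"mm_params"`: a named list with elements
#'   `Km` and `Vmax`.
#' @seealso [is_params()], [eval_mm()]
#' @export
#' @examples
#' p <- mm_params(Km = 1, Vmax = 10)
#' eval_mm(p, c0 = 1) # half-saturation: 5
mm_params <- function(Km, Vmax) {
  check_positive_scalar(Km, "Km")
  check_positive_scalar(Vmax, "Vmax")
  structure(list(Km = Km, Vmax = Vmax), class = "mm_params")
}

#' Interacting-sites (two-site allosteric) parameter bundle
#'
#' Parameters of the two-site interacting-sites rate law for a dimeric
#' active-site pair in which occupation of one site changes the apparent
#' Michaelis constant and maximal velocity of its neighbour. `Km1` and
#' `Vmax1` describe a site whose partner is free; when both sites are
#' occupied each site behaves with `Km2 = a * Km1` and `Vmax2 = b * Vmax1`.
#' `a > 1` with `b ~ 1` signals negative cooperativity in binding,
#' `a < 1` positive cooperativity.
#'
#' The canonical parameterization is `(Km1, Vmax1, a, b)`; `Km2` and
#' `Vmax2` are derived views obtained with [derive_secondary_parameters()].
#'
#' @param Km1 apparent Michaelis constant of a site with a free neighbour
#'   (mM, > 0).
#' @param Vmax1 apparent maximal velocity of a site with a free neighbour
#'   (U mg^-1, > 0).
#' @param a Michaelis-constant interaction factor (dimensionless, > 0).
#' @param b velocity interaction factor (dimensionless, > 0).
#'
#' @return An object of class `"is_params"`: named list with elements
#'   `Km1`, `Vmax1`, `a`, `b`.
#' @seealso [eval_interacting_sites()], [interaction_factors()],
#'   [saturating_velocity()]
#' @export
#' @examples
#' p <- is_params(Km1 = 0.015, Vmax1 = 10.8, a = 266.67, b = 0.7593)
#' derive_secondary_parameters(p)
is_params <- function(Km1, Vmax1, a, b) {
  check_positive_scalar(Km1, "Km1")
  check_positive_scalar(Vmax1, "Vmax1")
  check_positive_scalar(a, "a")
  check_positive_scalar(b, "b")
  p <- structure(list(Km1 = Km1, Vmax1 = Vmax1, a = a, b = b),
                 class = "is_params")
  d <- derive_secondary_parameters(p)
  if (!all(is.finite(unlist(d))) || any(unlist(d) <= 0))
    stop("derived Km2/Vmax2 must be finite and positive", call. = FALSE)
  p
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single finite positive number", name),
         call. = FALSE)
  invisible(x)
}

check_concentration <- function(c0) {
  if (!is.numeric(c0) || any(!is.finite(c0)) || any(c0 < 0))
    stop("concentrations 'c0' must be finite and non-negative",
         call. = FALSE)
  invisible(c0)
}

#' Evaluate the Michaelis-Menten rate law
#'
#' @param params an [mm_params()] object.
#' @param c0 variable-substrate concentration(s), mM (>= 0); vectorized.
#'
#' @return Initial velocity `Vmax * c0 / (Km + c0)` in U mg^-1.
#' @export
eval_mm <- function(params, c0) {
  stopifnot(inherits(params, "mm_params"))
  check_concentration(c0)
  params$Vmax * c0 / (params$Km + c0)
}

#' Evaluate the two-site interacting-sites rate law
#'
#' Evaluates the velocity of a two-site dimer whose sites interact, in
#' either of the two equivalent printed forms of the rate law:
#'
#' * `form = "eq1"` (interaction-factor form):
#'   \deqn{v_0 = \frac{2 V_{max1} c_0/K_{m1} + 2 b V_{max1} c_0^2/(a K_{m1}^2)}
#'               {1 + 2 c_0/K_{m1} + c_0^2/(a K_{m1}^2)}}
#' * `form = "eq2"` (secondary-constant form, with \eqn{K_{m2} = a K_{m1}},
#'   \eqn{V_{max2} = b V_{max1}}):
#'   \deqn{v_0 = \frac{2 V_{max1} K_{m2} c_0 + 2 V_{max2} c_0^2}
#'               {K_{m1} K_{m2} + 2 K_{m2} c_0 + c_0^2}}
#'
#' Both forms are the same rational function; they agree to floating-point
#' round-off. The velocity is 0 at `c0 = 0`, rises with initial slope
#' `2 Vmax1 / Km1`, and saturates at `2 * Vmax2` (see
#' [saturating_velocity()]). With `a = b = 1` the law reduces to
#' Michaelis-Menten with `Km = Km1` and total `Vmax = 2 * Vmax1`.
#'
#' @param params an [is_params()] object.
#' @param c0 variable-substrate concentration(s), mM (>= 0); vectorized.
#' @param form which printed algebraic expression to evaluate.
#'
#' @return Initial velocity in U mg^-1.
#' @export
#' @examples
#' p <- is_params(Km1 = 0.015, Vmax1 = 10.8, a = 266.67, b = 0.7593)
#' eval_interacting_sites(p, 50) # ~15.63, close to 2*Vmax2 = 16.4
eval_interacting_sites <- function(params, c0, form = c("eq1", "eq2")) {
  stopifnot(inherits(params, "is_params"))
  form <- match.arg(form)
  check_concentration(c0)
  Km1 <- params$Km1; Vmax1 <- params$Vmax1; a <- params$a; b <- params$b
  if (form == "eq1") {
    num <- 2 * Vmax1 * c0 / Km1 + 2 * b * Vmax1 * c0^2 / (a * Km1^2)
    den <- 1 + 2 * c0 / Km1 + c0^2 / (a * Km1^2)
  } else {
    Km2 <- a * Km1
    Vmax2 <- b * Vmax1
    num <- 2 * Vmax1 * Km2 * c0 + 2 * Vmax2 * c0^2
    den <- Km1 * Km2 + 2 * Km2 * c0 + c0^2
  }
  num / den
}

#' Interaction factors from primary and secondary kinetic constants
#'
#' Computes the cooperativity readout of the interacting-sites model:
#' `a = Km2 / Km1` and `b = Vmax2 / Vmax1`. Inverse of
#' [derive_secondary_parameters()] (round-trips to machine precision).
#'
#' @param Km1,Km2 Michaelis constants of a site with the neighbour free /
#'   occupied (mM, > 0).
#' @param Vmax1,Vmax2 maximal velocities with the neighbour free / occupied
#'   (U mg^-1, > 0).
#'
#' @return Named numeric vector `c(a = , b = )`.
#' @export
#' @examples
#' interaction_factors(Km1 = 0.015, Km2 = 4.0, Vmax1 = 10.8, Vmax2 = 8.2)
interaction_factors <- function(Km1, Km2, Vmax1, Vmax2) {
  check_positive_scalar(Km1, "Km1"); check_positive_scalar(Km2, "Km2")
  check_positive_scalar(Vmax1, "Vmax1"); check_positive_scalar(Vmax2, "Vmax2")
  c(a = Km2 / Km1, b = Vmax2 / Vmax1)
}

#' Secondary kinetic constants of the interacting-sites model
#'
#' @param params an [is_params()] object.
#' @return Named numeric vector `c(Km2 = a*Km1, Vmax2 = b*Vmax1)`.
#' @export
derive_secondary_parameters <- function(params) {
  stopifnot(inherits(params, "is_params"))
  c(Km2 = params$a * params$Km1, Vmax2 = params$b * params$Vmax1)
}

#' Saturating velocity of the interacting-sites model
#'
#' The velocity approached as the variable substrate saturates both sites
#' of the dimer: `2 * Vmax2 = 2 * b * Vmax1`. Note the distinction between
#' this hexamer-level maximal activity (two sites per dimer, each running
#' at `Vmax2`) and the per-site constant `Vmax2` itself; both are exposed
#' and neither is silently substituted for the other.
#'
#' @param params an [is_params()] object.
#' @return `2 * b * Vmax1` in U mg^-1.
#' @export
saturating_velocity <- function(params) {
  stopifnot(inherits(params, "is_params"))
  2 * params$b * params$Vmax1
}

#' @export
print.mm_params <- function(x, ...) {
  cat("Michaelis-Menten parameters: Km =", format(x$Km),
      "mM, Vmax =", format(x$Vmax), "U/mg\n")
  invisible(x)
}

#' @export
print.is_params <- function(x, ...) {
  d <- derive_secondary_parameters(x)
  cat("Interacting-sites parameters:\n")
  cat("  Km1 =", format(x$Km1), "mM, Vmax1 =", format(x$Vmax1), "U/mg\n")
  cat("  a =", format(x$a), ", b =", format(x$b),
      " (Km2 =", format(d[["Km2"]]), "mM, Vmax2 =", format(d[["Vmax2"]]),
      "U/mg)\n")
  cat("  saturating velocity 2*Vmax2 =", format(saturating_velocity(x)),
      "U/mg\n")
  invisible(x)
}
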