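#' Replicate initial-velocity dataset
#'
#' Builds the container consumed by [fit_kinetics()]: one row per
#' variable-substrate concentration with the replicate-mean velocity, the
#' standard deviation of the average rate, and the replicate count. Rows
#' are sorted by concentration; duplicate concentrations are allowed
#' (independent measurement series at the same concentration).
#'
#' @param c0 variable-substrate concentration, mM (>= 0).
#' @param v0 mean initial velocity, U mg^-1.
#' @param sd standard deviation of the average rate, U mg^-1 (>= 0), or
#'   `NA` where no replicate spread is available.
#' @param n_rep replicate count per point (>= 1).
#' @param enzyme_form,variable_substrate,co_substrate,co_substrate_conc
#'   assay metadata, stored as attributes (free-form).
#'
#' @return A `data.frame` of class `"velocity_dataset"` with columns
#'   `c0`, `v0`, `sd`, `n_rep`.
#' @export
#' @examples
#' velocity_dataset(c0 = c(0.1, 1, 10), v0 = c(1.8, 9.5, 18.2),
#'                  sd = c(0.1, 0.4, 0.9), n_rep = 3)
velocity_dataset <- function(c0, v0, sd = NA_real_, n_rep = 1L,
                             enzyme_form = NA_character_,
                             variable_substrate = NA_character_,
                             co_substrate = NA_character_,
                             co_substrate_conc = NA_real_) {
  if (length(c0) == 0L) stop("empty dataset: no concentration points",
                             call. = FALSE)
  check_concentration(c0)
  if (!is.numeric(v0) || length(v0) != length(c0))
    stop("'v0' must be numeric and match 'c0' in length", call. = FALSE)
  sd <- rep_len(as.numeric(sd), length(c0))
  n_rep <- rep_len(as.integer(n_rep), length(c0))
  if (any(!is.na(sd) & sd < 0)) stop("'sd' must be >= 0", call. = FALSE)
  if (any(n_rep < 1L)) stop("'n_rep' must be >= 1", call. = FALSE)
  ord <- order(c0)
  out <- data.frame(c0 = c0[ord], v0 = v0[ord], sd = sd[ord],
                    n_rep = n_rep[ord])
  structure(out,
            enzyme_form = enzyme_form,
            variable_substrate = variable_substrate,
            co_substrate = co_substrate,
            co_substrate_conc = co_substrate_conc,
            class = c("velocity_dataset", "data.frame"))
}

as_velocity_dataset <- function(x) {
  if (inherits(x, "velocity_dataset")) return(x)
  if (is.data.frame(x) && all(c("c0", "v0") %in% names(x))) {
    return(velocity_dataset(
      x$c0, x$v0,
      sd = if ("sd" %in% names(x)) x$sd else NA_real_,
      n_rep = if ("n_rep" %in% names(x)) x$n_rep else 1L))
  }
  stop("cannot interpret 'data' as a velocity dataset; need columns c0, v0",
       call. = FALSE)
}

#' Published kinetic parameters of E. coli PNP wild type and double mutant
#'
#' Returns the packaged transcription of the fitted kinetic parameters for
#' hexameric E. coli purine nucleoside phosphorylase: wild type (WT) and
#' the Asp204Ala/Arg217Ala double mutant (DM), assayed with phosphate or
#' nucleoside (Ado, m7Guo) as the variable substrate. Columns give the
#' interacting-sites parameters `Km1`, `Vmax1`, `Km2`, `Vmax2` (mM and
#' U mg^-1) with their reported uncertainties, the printed interaction
#' factors `a` and `b`, and an `approx` flag for entries the source marks
#' as order-of-magnitude only (relative errors above 50%). Rows where the
#' Michaelis-Menten model sufficed carry `NA` secondary constants.
#'
#' @return A `data.frame`, one row per enzyme-form/substrate combination.
#' @export
pnp_kinetic_parameters <- function() {
  path <- system.file("extdata", "pnp_kinetic_parameters.csv",
                      package = "allokin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
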