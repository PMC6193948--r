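# Synthetic-data generators: initial-velocity datasets under MM or
# interacting-sites truth, replicate HDX uptake curves, and cooperative
# two-site titration occupancies. All generators are deterministic given
# their seed.

#' Log-spaced concentration grid spanning both kinetic regimes
#'
#' Emulates an assay design that covers a broad substrate range (in the
#' laboratory, achieved with cuvettes of decreasing path length): a
#' log-uniform grid from `0.1 * Km1` to `max(10 * Km2, 100 * Km1)`, so that
#' both the high-affinity and the low-affinity site are informative.
#'
#' @param Km1 primary Michaelis constant (mM, > 0).
#' @param Km2 secondary Michaelis constant (mM, > 0); defaults to `Km1`.
#' @param n_points grid size (>= 6).
#' @return Strictly increasing numeric vector of concentrations (mM).
#' @export
#' @examples
#' make_concentration_grid(0.015, 4.0, n_points = 16)
make_concentration_grid <- function(Km1, Km2 = Km1, n_points = 12) {
  check_positive_scalar(Km1, "Km1")
  check_positive_scalar(Km2, "Km2")
  if (n_points < 6) stop("'n_points' must be >= 6", call. = FALSE)
  lo <- 0.1 * Km1
  hi <- max(10 * Km2, 100 * Km1)
  exp(seq(log(lo), log(hi), length.out = n_points))
}

noise_sd_law <- function(mode, sigma_abs, cv, v_true) {
  switch(mode,
    absolute = rep(sigma_abs, length(v_true)),
    relative = cv * v_true,
    mixed = sigma_abs + cv * v_true,
    stop("unknown noise mode '", mode, "'", call. = FALSE))
}

#' Simulate a replicate initial-velocity dataset
#'
#' Draws `n_rep` Gaussian replicates per grid concentration around the
#' true rate-law velocity, with per-point noise SD given by the chosen
#' law: `"absolute"` (`sigma_abs`), `"relative"` (`cv * v_true`) or
#' `"mixed"` (`sigma_abs + cv * v_true`). Negative draws are allowed -
#' they are measurement noise, not concentrations. The returned dataset
#' stores the replicate mean, the SD of the average rate and the replicate
#' count.
#'
#' With `sd = "replicate"` (default) the stored SD is the sample SD of the
#' replicate mean, `sd(replicates)/sqrt(n_rep)` (undefined for
#' `n_rep = 1`). With `sd = "true"` it is the exact noise-law SD of the
#' mean, `sd_law(v_true)/sqrt(n_rep)` - useful for operating-characteristic
#' experiments where the weighting step should not add estimation noise.
#'
#' @param params an [mm_params()] or [is_params()] truth object.
#' @param grid concentrations (mM), e.g. from [make_concentration_grid()].
#' @param mode noise law; see above.
#' @param sigma_abs absolute noise component (U mg^-1, >= 0).
#' @param cv relative noise component (dimensionless, >= 0).
#' @param n_rep replicates per concentration (>= 1).
#' @param sd which SD to store: `"replicate"` (estimated) or `"true"`.
#' @param seed integer seed; the output is bit-reproducible given
#'   `(params, grid, noise, seed)`.
#' @return A [velocity_dataset()].
#' @export
simulate_velocity_dataset <- function(params, grid,
                                      mode = c("mixed", "absolute",
                                               "relative"),
                                      sigma_abs = 0, cv = 0.05, n_rep = 3,
                                      sd = c("replicate", "true"),
                                      seed = 0) {
  mode <- match.arg(mode)
  sd <- match.arg(sd)
  check_concentration(grid)
  if (sigma_abs < 0 || cv < 0) stop("noise components must be >= 0",
                                    call. = FALSE)
  if (n_rep < 1) stop("'n_rep' must be >= 1", call. = FALSE)
  model <- if (inherits(params, "mm_params")) "MM" else "IS"
  v_true <- model_velocity(model, params_to_vector(params), grid)
  sd_true <- noise_sd_law(mode, sigma_abs, cv, v_true)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  reps <- matrix(stats::rnorm(length(grid) * n_rep,
                              mean = rep(v_true, each = n_rep),
                              sd = rep(sd_true, each = n_rep)),
                 nrow = n_rep)
  v0 <- colMeans(reps)
  sd_out <- if (sd == "true") sd_true / sqrt(n_rep)
            else if (n_rep >= 2) apply(reps, 2, stats::sd) / sqrt(n_rep)
            else rep(NA_real_, length(grid))
  velocity_dataset(grid, v0, sd = sd_out, n_rep = n_rep)
}

#' Simulate an ensemble of null (Michaelis-Menten truth) datasets
#'
#' Generates `n_datasets` independent datasets from MM truth with seeds
#' `seed + 0, ..., seed + n_datasets - 1`; the workhorse of the F-test
#' type-I-error experiment.
#'
#' @param params an [mm_params()] truth object.
#' @inheritParams simulate_velocity_dataset
#' @param n_datasets ensemble size.
#' @return A list of [velocity_dataset()] objects.
#' @export
simulate_null_ensemble <- function(params, grid, n_datasets,
                                   mode = c("mixed", "absolute",
                                            "relative"),
                                   sigma_abs = 0, cv = 0.05, n_rep = 3,
                                   sd = c("replicate", "true"), seed = 0) {
  stopifnot(inherits(params, "mm_params"))
  mode <- match.arg(mode); sd <- match.arg(sd)
  lapply(seq_len(n_datasets) - 1L, function(i)
    simulate_velocity_dataset(params, grid, mode = mode,
                              sigma_abs = sigma_abs, cv = cv,
                              n_rep = n_rep, sd = sd, seed = seed + i))
}

#' Simulate replicate deuterium-uptake curves for one peptide
#'
#' Expected uptake of a peptide with `n_exchangeable` backbone amides
#' exchanging as independent first-order processes:
#' \deqn{D(t) = \sum_j (1 - e^{-k_j t})}
#' Gaussian noise of SD `noise_sd_da` is added per replicate measurement.
#' Uptake is monotone in time in expectation and bounded by
#' `n_exchangeable`.
#'
#' @param n_exchangeable number of exchangeable amides (>= 1).
#' @param rate_constants per-amide exchange rate constants (s^-1, > 0);
#'   recycled to length `n_exchangeable`.
#' @param timepoints exchange times in seconds (default 10 s, 1 min,
#'   20 min, 1 h, 4 h).
#' @param noise_sd_da replicate noise SD (Da, >= 0).
#' @param n_rep replicates per timepoint.
#' @param peptide_id,start,end,state peptide annotation (1-based inclusive
#'   residue numbering).
#' @param seed integer seed.
#' @return An [uptake_series()] object.
#' @export
#' @examples
#' s <- simulate_hdx_uptake(8, 0.01, noise_sd_da = 0.1, seed = 1)
#' uptake_summary(s)
simulate_hdx_uptake <- function(n_exchangeable, rate_constants,
                                timepoints = c(10, 60, 1200, 3600, 14400),
                                noise_sd_da = 0.1, n_rep = 3,
                                peptide_id = "pep1", start = 1,
                                end = n_exchangeable + 1,
                                state = "apo", seed = 0) {
  if (n_exchangeable < 1) stop("'n_exchangeable' must be >= 1",
                               call. = FALSE)
  if (any(rate_constants <= 0)) stop("rate constants must be > 0",
                                     call. = FALSE)
  if (noise_sd_da < 0) stop("'noise_sd_da' must be >= 0", call. = FALSE)
  k <- rep_len(rate_constants, n_exchangeable)
  expected <- vapply(timepoints, function(t) sum(1 - exp(-k * t)),
                     numeric(1))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  df <- expand.grid(replicate = seq_len(n_rep),
                    time_s = timepoints)
  df$uptake_da <- rep(expected, each = n_rep) +
    stats::rnorm(nrow(df), 0, noise_sd_da)
  uptake_series(peptide_id = peptide_id, start = start, end = end,
                state = state, time_s = df$time_s,
                replicate = df$replicate, uptake_da = df$uptake_da)
}

#' Simulate a cooperative two-site titration of a dimer
#'
#' A thermodynamic stand-in for part-of-the-sites ligand binding: each
#' dimer has two equivalent sites with stepwise association governed by the
#' binding polynomial \eqn{P(c) = 1 + 2 K_1 c + \gamma K_1^2 c^2}, where
#' `coupling` \eqn{\gamma < 1} encodes negative cooperativity (the doubly
#' bound state is penalized) and \eqn{\gamma = 1} recovers two independent
#' sites. For each ligand:protein molar ratio the free-ligand concentration
#' is solved from total-ligand conservation by bisection on `[0, total]`
#' (tolerance `1e-12 * total`), then species fractions and per-site
#' occupancy follow from `P`.
#'
#' This model generates occupancy patterns like those observed
#' crystallographically; it is not a fit to any refined occupancies.
#'
#' @param K1 site association constant for the first binding event
#'   (mM^-1, > 0).
#' @param coupling dimensionless factor on the second stepwise constant
#'   (> 0); `< 1` = negative cooperativity.
#' @param ratios non-negative increasing ligand:dimer molar ratios.
#' @param protein_conc dimer concentration (mM, > 0).
#' @return A `data.frame` with one row per ratio: `ratio`, `total_ligand`,
#'   `free_ligand`, `frac_empty`, `frac_single`, `frac_double`,
#'   `site_occupancy`, `bound_per_dimer`.
#' @export
#' @examples
#' simulate_titration(K1 = 10, coupling = 0.05, ratios = c(0, 0.5, 1, 2),
#'                    protein_conc = 0.5)
simulate_titration <- function(K1, coupling, ratios, protein_conc) {
  check_positive_scalar(K1, "K1")
  check_positive_scalar(coupling, "coupling")
  check_positive_scalar(protein_conc, "protein_conc")
  if (any(ratios < 0) || is.unsorted(ratios))
    stop("'ratios' must be non-negative and increasing", call. = FALSE)

  bound_per_dimer <- function(c) {
    p1 <- 2 * K1 * c
    p2 <- coupling * K1^2 * c^2
    (p1 + 2 * p2) / (1 + p1 + p2)
  }
  out <- lapply(ratios, function(r) {
    total <- r * protein_conc
    if (total == 0) {
      free <- 0
    } else {
      g <- function(c) c + protein_conc * bound_per_dimer(c) - total
      lo <- 0; hi <- total
      tol <- 1e-12 * total
      for (iter in 1:200) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) hi <- mid else lo <- mid
        if (hi - lo <= tol) break
      }
      if (hi - lo > tol)
        stop("bisection for free ligand did not converge", call. = FALSE)
      free <- (lo + hi) / 2
    }
    p1 <- 2 * K1 * free
    p2 <- coupling * K1^2 * free^2
    P <- 1 + p1 + p2
    data.frame(ratio = r, total_ligand = total, free_ligand = free,
               frac_empty = 1 / P, frac_single = p1 / P,
               frac_double = p2 / P,
               site_occupancy = (p1 / 2 + p2) / P,
               bound_per_dimer = bound_per_dimer(free))
  })
  do.call(rbind, out)
}
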