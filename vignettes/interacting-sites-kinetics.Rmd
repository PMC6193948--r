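---
title: "Interacting-sites kinetics, HDX differential uptake and site-filling order: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interacting-sites kinetics, HDX differential uptake and site-filling order: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

# The scientific problem

Hexameric purine nucleoside phosphorylases (PNPs) are trimers of dimers in
which the two active sites of each dimer talk to each other: binding of
substrate at one site changes the affinity and turnover of its neighbour.
In steady-state initial-velocity experiments this shows up as
non-Michaelis-Menten saturation curves; crystallographically it shows up
as *part-of-the-sites* binding, where at moderate ligand:protein ratios
only a subset of the chemically identical sites carries ligand. This
package implements the complete quantitative workflow around that
phenomenology:

1. a two-site **interacting-sites rate law** and the classical
   Michaelis-Menten law, fitted to replicate initial-velocity data by
   weighted nonlinear least squares (`fit_kinetics()`);
2. **nested model selection** between the two laws by the
   extra-sum-of-squares F-test (`anova()` on two fits,
   `compare_rate_laws()`);
3. a **differential HDX-MS significance procedure** with a pooled-SD
   confidence threshold (`significance_threshold()`, `compare_states()`);
4. a **site-class filling-order analysis** of per-chain crystallographic
   ligand occupancies across a titration series (`classify_sites()`,
   `filling_order()`);
5. **synthetic-data generators** for all three data types, so every stage
   of the pipeline is testable without access to raw instrument data.

# The rate laws

With one site of a dimer occupied by the variable substrate (concentration
$c_0$, mM) catalysis proceeds with apparent constants $K_{m1}$ and
$V_{max1}$; when both sites are occupied each site behaves with
$K_{m2} = a K_{m1}$ and $V_{max2} = b V_{max1}$. The velocity of the dimer
is the rational function

$$v_0(c_0) =
  \frac{2 \dfrac{V_{max1} c_0}{K_{m1}}
      + 2 \dfrac{b V_{max1} c_0^2}{a K_{m1}^2}}
       {1 + \dfrac{2 c_0}{K_{m1}} + \dfrac{c_0^2}{a K_{m1}^2}}
= \frac{2 V_{max1} K_{m2} c_0 + 2 V_{max2} c_0^2}
       {K_{m1} K_{m2} + 2 K_{m2} c_0 + c_0^2},$$

two algebraically identical forms both exposed by
`eval_interacting_sites()` (`form = "eq1"` / `"eq2"`). Properties used as
test contracts:

* $v_0(0) = 0$ exactly; the low-concentration slope is $2V_{max1}/K_{m1}$;
* $v_0 \to 2V_{max2}$ as $c_0 \to \infty$ (`saturating_velocity()`);
* with $a = b = 1$ the law collapses to Michaelis-Menten with
  $V_{max} = 2V_{max1}$.

The interaction factors $a$ and $b$ are the cooperativity readout:
$a > 1$ with $b \approx 1$ is negative binding cooperativity (the second
site binds more weakly but turns over similarly). The canonical internal
parameterization is $(K_{m1}, V_{max1}, a, b)$, with $(K_{m2}, V_{max2})$
as derived views — the factors are what the biology is about, and
positivity of all four is structurally guaranteed in log-space fitting.

Monotonicity of $v_0(c_0)$ is deliberately **not** asserted as an
invariant: a degree-2/2 rational function can overshoot its asymptote.
Algebraically, $2V_{max2}\cdot\text{denominator} - \text{numerator} =
2K_{m2}\left(V_{max2}K_{m1} + c_0(2V_{max2} - V_{max1})\right)$, so
$v_0 < 2V_{max2}$ at all finite $c_0$ holds exactly when $b \ge 1/2$; the
test suite asserts the bound only there, and checks the finite-probe
asymptote contracts (0.1% at $c_0 = 10^6 K_{m2}$ and $10^{-6} K_{m1}$) for
moderate interaction factors ($a, b \in [0.05, 20]$, which covers every
parameter set in the packaged table), because the probe error scales like
$|2 - 1/b|\times 10^{-6}$ and $(b/a)\times 10^{-6}$ and genuinely exceeds
0.1% at extreme corners of a $[10^{-3}, 10^3]$ draw box. Form equivalence,
by contrast, is exact algebra and is tested over the full box.

# Weighted fitting

`fit_kinetics()` minimizes
$\sum_i w_i (v_{0,i} - v_{\text{model}}(c_{0,i}))^2$. The default weights
are $w_i = 1/SD_i^2$ with $SD_i$ the standard deviation of the average
rate at point $i$ — in these assays the high-concentration points are
measured in thin cuvettes and are markedly noisier, and the weighting
choice can flip which model the F-test selects, so an SD of zero or a
missing SD under this policy is a hard error naming the point, never a
silent imputation. Alternatives: `weights = "uniform"` ($w_i = 1$) and
`weights = "relative"` ($w_i = 1/(cv\,v_{0,i})^2$, default $cv = 0.05$).
The default mode fits replicate-averaged rates with their SDs; raw
replicates can simply be supplied as duplicate rows if pooled fitting is
wanted.

Numerical choices:

* **Log-space optimization.** All parameters are strictly positive;
  optimizing $\theta = \log(\text{params})$ removes the constraint and
  equalizes scales. Log-parameters are clamped to $\pm\log 10^{15}$ so a
  locally flat direction (e.g. $a \to \infty$ on data that are actually
  Michaelis-Menten) cannot overflow.
* **Local solver.** Levenberg-Marquardt (`minpack.lm::nls.lm`),
  convergence at relative SSR change $10^{-12}$ or 500 iterations; a start
  that hits the cap is flagged non-converged but its optimum still
  competes, because near-degenerate SSR valleys with several similar
  minima are a documented feature of this model class.
* **Multi-start.** `n_starts` points (default 20) of a Latin hypercube in
  log-space spanning $[10^{-3}, 10^3]$ times the data-implied scale
  (median positive concentration for the $K_m$'s, maximal observed
  velocity for the $V_{max}$'s), plus — for the interacting-sites model —
  the MM-embedded start $(K_{m1} = \hat K_m,\ V_{max1} = \hat V_{max}/2,\
  a = b = 1)$ taken from an MM fit of the same data. The embedded start
  guarantees $wssr_{IS} \le wssr_{MM}$ up to solver tolerance, which is
  what makes the F-test numerator well-defined. Ties between starts
  (relative SSR difference $< 10^{-8}$) resolve to the earliest start.
* **Standard errors** are asymptotic: $s^2 (J^TJ)^{-1}$ at the optimum
  with $s^2 = wssr/(n-p)$ and $J$ the weighted Jacobian in log-space
  (central differences), delta-mapped to the natural scale. A singular
  information matrix yields `NA` errors and a flag, not an exception.
  A Monte-Carlo test (200 replicate datasets with exact weights) checks
  the reported errors against the empirical spread of the estimates.

# Model selection

For nested least-squares fits the extra-sum-of-squares statistic

$$F = \frac{(wssr_{MM} - wssr_{IS})/(4-2)}{wssr_{IS}/(n-4)}$$

is referred to $F(2, n-4)$; the interacting-sites model is selected iff
$p < \alpha$ (default $\alpha = 0.05$, the conventional 95% confidence
level). A boundary tie keeps the simpler model. The decision is invariant
to rescaling all SDs by a common factor.

Operating characteristics are verified by simulation rather than assumed:
over 2000 datasets generated under Michaelis-Menten truth (16-point
log grid, 5% CV Gaussian noise) the test selects the richer model in
about 4% of cases, and against a strongly cooperative truth
($a = 100$, $b = 1$, 3% CV) its power exceeds 0.9. These ensembles use
the generator's *known* noise SD as the weighting SD: with SDs estimated
from triplicates the weighted residuals are ratios of a normal to an
independent 2-df chi (heavy-tailed), and the experiment would then measure
that nuisance rather than the F-procedure itself. The fits of real
averaged-replicate data still use the estimated SDs — the operating
characteristics quoted here are for the idealized-weight setting.

Printed F values from fits of unpublished raw datasets cannot be
reproduced and are not asserted anywhere; the simulation-based
characteristics substitute for them.

# Synthetic data: what it emulates, and what it does not

`make_concentration_grid()` emulates a broad-range cuvette design: a
log-uniform grid from $0.1 K_{m1}$ to $\max(10K_{m2}, 100K_{m1})$, so both
kinetic regimes are sampled. `simulate_velocity_dataset()` draws `n_rep`
(default 3 — typical for "measured several times" assay practice)
Gaussian replicates per point with SD law `absolute`, `relative` or
`mixed` ($\sigma = \sigma_{abs} + cv\,v_{true}$; defaults
$\sigma_{abs}=0$ within `relative`, $cv = 0.05$, a realistic
spectrophotometric CV). Gaussian rather than lognormal noise: replicate
scatter of initial slopes is symmetric to good approximation, and negative
draws are legitimate measurement outcomes. The generator does **not**
emulate systematic cuvette-to-cuvette biases, substrate depletion during
the initial slope, or inner-filter effects — passing recovery tests on
synthetic data therefore demonstrates correctness of the estimator, not
robustness to every laboratory artifact.

`simulate_hdx_uptake()` models a peptide's uptake as a sum of independent
first-order exchanges $\sum_j (1 - e^{-k_j t})$ over its amides with
Gaussian replicate noise — adequate for testing the significance
procedure, but it ignores back-exchange, EX1 behaviour and isotope-envelope
effects. `simulate_titration()` is a thermodynamic stand-in for
part-of-the-sites binding: a dimer with binding polynomial
$P = 1 + 2K_1c + \gamma K_1^2c^2$, where coupling $\gamma < 1$ penalizes
double occupancy; free ligand is solved from conservation by bisection on
$[0, \text{total}]$ at tolerance $10^{-12}\times$total (robustness over
speed at this scale). No claim is made that refined crystallographic
occupancies follow this model — it exists to give the filling-order
inference a controllable ground truth.

# HDX differential uptake

Uptake is compared per timepoint between two states measured in
triplicate, without back-exchange correction. The significance threshold
follows the global-threshold practice of pooling replicate variances over
all peptides, states and timepoints (`pooled_sd()`, `"global"` mode;
a per-peptide mode exists for sensitivity analysis) and setting

$$T = z_{(1+\gamma)/2}\; \sigma_{pooled} \sqrt{2/n_{rep}},$$

the two-sided $\gamma$-confidence bound for a difference of two
$n_{rep}$-replicate means. At $\gamma = 0.98$, $n_{rep} = 3$ and a pooled
SD of 0.158 Da this gives the familiar $\pm 0.3$ Da cutoff. The normal
quantile (rather than t) is the standard choice for globally pooled
thresholds, where the pooled SD has hundreds of degrees of freedom;
`method = "t"` is available for per-peptide thresholds. A peptide is
classified *changed* if **any** timepoint is significant — binding effects
on fast-exchanging regions are often visible only at the shortest
exchange time — with direction `increased`/`decreased`/`mixed` by the
sign pattern of the significant deltas. The null false-positive rate per
timepoint is verified by simulation to sit at the nominal 2%.

# Occupancy filling order

Each chain of the hexamer is classified by its own and its dimer
partner's active-site conformation into three symmetry-distinct
environments: `closed`, `open_in_closed_open_dimer`,
`open_in_open_open_dimer`. For a series of structures at increasing
ligand:protein molar ratio, `filling_order()` reports, per class, the
smallest ratio at which the class mean occupancy (unmodelled ligand
counted as 0) reaches a threshold. The default threshold 0.4 is an
editorial choice: it is the smallest occupancy factor reported in the
packaged series, i.e. the weakest signal the source data treat as a
modelled ligand; it is a tunable argument, and for the packaged series the
inferred order is stable for any threshold in (0, 0.5].

The packaged table (`pnp_fa_occupancy()`) transcribes the published
per-chain formycin A occupancies of five ternary-complex structures
(wild type at ratios 0.14 and 0.57; double mutant at 0.4, 0.6 and 1.2).
Hexagonal structures, in which half the hexamer is crystallographically
symmetric, are stored symmetry-expanded (primed chains) so both space
groups share one data model; "no FA" cells are stored as `NA`, not 0, to
keep *unmodelled* distinct from *weakly occupied*. On these fixtures the
wild type fills its closed sites first, while the double mutant fills the
open sites of its closed-open dimers first, then the closed sites, then
the open-open dimer — the reversal of filling order that accompanies the
loss of the protonation residues.

```{r filling-order}
fx <- pnp_fa_occupancy()
filling_order(fx[grepl("^WT", names(fx))])
filling_order(fx[grepl("^DM", names(fx))])
```

# Problem sizes and reproducibility

All randomness flows through explicit integer seeds; datasets, ensembles
and HDX simulations are bit-reproducible from their arguments. The
simulation studies in the test-suite and in `scripts/acceptance.R` use the
sizes of the underlying study design: 100 replicate datasets for parameter
recovery, 2000 null datasets for the F-test size, 500 for its power, and
10,000 peptide-timepoint pairs for the HDX false-positive rate; ensemble
fits use a reduced multi-start count (4-8 starts plus the MM-embedded
start), which the type-I experiment shows to be indistinguishable from the
full 20-start search on these well-conditioned synthetic grids.

# Known limitations

* The interacting-sites law covers exactly two site classes per dimer;
  systems whose kinetics are "even more complicated" (several SSR minima
  of similar depth are a warning sign, surfaced in the per-start
  diagnostics) are outside its scope, and no third model is offered.
* Fitting errors are asymptotic standard errors, not profile-likelihood or
  bootstrap intervals; for strongly correlated parameters such as $a$ the
  spread is wide and honest (mirroring printed uncertainties like
  $267 \pm 232$), but coverage is only approximately nominal.
* The HDX module starts from per-peptide uptake values; spectral
  processing, centroiding and retention-time alignment are upstream and
  out of scope.
* The occupancy module operates on refined occupancy factors; it performs
  no crystallographic computation.
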