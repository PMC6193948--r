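# allokin

Analysis of enzyme kinetics with interacting active sites, and of
part-of-the-sites ligand binding in oligomeric enzymes.

Hexameric purine nucleoside phosphorylases (PNPs) are trimers of dimers
whose paired active sites communicate: occupation of one site changes the
apparent Michaelis constant (factor *a*) and maximal velocity (factor *b*)
of its neighbour. `allokin` is for enzymologists and structural biologists
who need to (i) decide whether initial-velocity data demand this two-site
interacting-sites rate law instead of classical Michaelis–Menten kinetics,
(ii) test whether ligand binding changes local protein dynamics in
differential HDX-MS experiments, and (iii) read the order in which the
symmetry-distinct active sites of a hexamer fill with ligand out of a
series of crystallographic occupancy tables.

## The models

**Kinetics.** The interacting-sites velocity of a dimer at
variable-substrate concentration c₀ is

    v₀(c₀) = (2·Vmax1·Km2·c₀ + 2·Vmax2·c₀²) / (Km1·Km2 + 2·Km2·c₀ + c₀²)

with Km2 = a·Km1 and Vmax2 = b·Vmax1; it saturates at 2·Vmax2 and
collapses to Michaelis–Menten (Vmax = 2·Vmax1) when a = b = 1. Fitting is
weighted nonlinear least squares (weights 1/SD², log-parameter
Levenberg–Marquardt with Latin-hypercube multi-start plus an MM-embedded
start), and model choice is the extra-sum-of-squares F-test at the 95%
confidence level, exposed as `anova()` on two fits.

**HDX.** Differential deuterium uptake between two states is flagged
per timepoint against a global threshold
`z₀.₉₉ · pooled_SD · sqrt(2/n_rep)` — with triplicates and a pooled SD of
0.158 Da this is the familiar ±0.3 Da at 98% confidence.

**Occupancy.** Active sites are classified by their own and their dimer
partner's conformation (closed; open in a closed–open dimer; open in an
open–open dimer), and `filling_order()` reports the molar ratio at which
each class first reaches a threshold occupancy across a titration series.

## Worked example

Simulate a strongly negatively cooperative enzyme (Km1 = 0.015 mM,
Vmax1 = 10.8 U/mg, a ≈ 267, b ≈ 0.76 — wild-type-like values with
phosphate as the variable substrate), fit both rate laws, and test which
one the data support:

```r
library(allokin)

truth <- is_params(Km1 = 0.015, Vmax1 = 10.8, a = 266.67, b = 0.7593)
grid  <- make_concentration_grid(Km1 = 0.015, Km2 = 4.0, n_points = 16)
d     <- simulate_velocity_dataset(truth, grid, mode = "relative",
                                   cv = 0.05, n_rep = 3, seed = 42)
cmp <- compare_rate_laws(d, n_starts = 10, seed = 0)
cmp
#> Nested rate-law comparison (extra-sum-of-squares F-test)
#>   wssr: MM = 333.4 (p = 2), IS = 30.35 (p = 4), n = 16
#>   F(2, 12) = 59.92, p = 5.688e-07, alpha = 0.05
#>   selected model: IS
cmp$fit_is
#> Interacting-sites rate-law fit (weighted NLS, 11 starts, 11 converged)
#>   Km1      0.01473 +/- 7.207e-04
#>   Vmax1   10.85000 +/- 3.239e-01
#>   a      168.60000 +/- 8.125e+01
#>   b        0.71140 +/- 2.532e-02
#>   derived: Km2 = 2.485 mM, Vmax2 = 7.715 U/mg, 2*Vmax2 = 15.43 U/mg
#>   weighted SSR = 30.35 on 12 residual df (weights: sd)
```

The F-test rejects Michaelis–Menten decisively (p ≈ 6·10⁻⁷): the 16-point
dataset carries the curvature signature of two unequal sites. Km1, Vmax1
and b are recovered tightly; the interaction factor a is recovered with
the large uncertainty intrinsic to this parameter (its true spread across
replicate experiments is of the same order as the estimate, which is why
published values like 267 ± 232 carry such wide errors).

The packaged crystallographic occupancy series shows the mutant's
inverted site-filling order:

```r
filling_order(pnp_fa_occupancy()[c("DM-6(P/S)-2FA", "DM-6(P/S)-4FA",
                                   "DM-6(P/S)-6FA")])
#>                  site_class first_ratio max_occupancy
#> 1 open_in_closed_open_dimer         0.4           0.7
#> 2                    closed         0.6           0.7
#> 3   open_in_open_open_dimer         1.2           0.6
```

i.e. the open sites of the closed–open dimers fill first (at ligand:hexamer
ratio 0.4), the closed sites second, the open–open dimer last — whereas the
wild-type series fills its closed sites first. And the HDX threshold:

```r
significance_threshold(0.158, n_rep = 3)   # 98% confidence, triplicates
#> [1] 0.3001139
```

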