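---
title: "Methods: models, metrics and synthetic worlds in tregswitch"
author: "tregswitch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, metrics and synthetic worlds in tregswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregswitch)
```

# The scientific question

Tumour-derived exosomes (TDEs) carrying mutant KRAS can turn a culture of
naive CD4+ T cells into a culture enriched for FOXP3+ regulatory-T-like
(Treg-like) cells. Enrichment alone does not distinguish two very different
biologies: *phenotypic conversion* of non-Tregs into Tregs versus
*expansion* of a rare pre-existing Treg subpopulation. `tregswitch`
implements the quantitative machinery used to tell these apart — competing
population-dynamics models, spatial fractal statistics of tissue images,
flow-cytometry gating statistics, and a single-cell upregulation statistic
— together with synthetic-data generators so that every analysis is
testable end to end without external data.

# The three competing models

Let $X(t)$ be non-Treg and $Y(t)$ Treg-like abundances (cells), $E$ a
unitless exosome dose. All rates are per hour.

* **Model I (heritable acquisition).** Exposed non-Tregs irreversibly
  acquire the phenotype at rate $\mu E$ while both compartments grow:
  $\dot X = g_x X - \mu E X,\quad \dot Y = g_y Y + \mu E X.$
* **Model II (enhanced proliferation).** The dose only accelerates
  pre-existing Tregs: $\dot X = g_x X,\quad \dot Y = (g_y + \beta E) Y.$
* **Model III (plasticity).** Reversible switching with conserved total:
  $\dot X = -k_f E X + k_r Y,\quad \dot Y = k_f E X - k_r Y.$

Model III is the only saturating model: $X+Y$ is constant and the Treg
fraction relaxes to $k_f E/(k_f E + k_r)$ (`steady_state_fraction()`).
Models I and II grow without bound whenever the net Treg growth rate is
positive. `classify_regime()` operationalises the dichotomy as the relative
change of total population over the trailing 20% of the time grid with a 1%
tolerance — both defaults chosen so that a system within a few relaxation
times of its fixed point reads "saturating" while any exponential trend at
biologically relevant rates (≥ 0.01/h over a 72 h experiment) reads
"growing".

**Numerical approach.** All three systems are linear, so
`simulate_treg()` evaluates the exact $2\times2$ matrix exponential rather
than stepping an ODE solver. We use the Cayley–Hamilton form
$e^{At}v = e^{\lambda_2 t}\,(v + t\,\varphi((\lambda_1-\lambda_2)t)\,(A-\lambda_2 I)v)$
with $\varphi(z) = (e^z-1)/z$ computed via `expm1` for small $z$ and as an
explicit difference of exponentials for large $z$; for triangular systems
(models I and II) the eigenvalues are taken exactly from the diagonal.
This is stable for repeated eigenvalues and avoids 1-ulp eigenvalue errors
being amplified by $e^{\lambda_1 t}$. Independent oracles in the test suite
(hand-derived scalar solutions and `Matrix::expm`) agree to better than
$10^{-6}$ relative on 50-point grids; model III conserves $X+Y$ to
round-off ($\sim10^{-16}$ relative).

**Fitting and selection.** `fit_treg_model()` minimises the residual sum
of squares between `log1p`-transformed observed and simulated counts
(counts span decades; `log1p` tolerates zeros), with non-negativity bounds,
initial conditions pinned to the first observation, and eight seeded
L-BFGS-B starts drawn log-uniformly on $[10^{-4}, 1]$ per hour. Two
identifiability choices are deliberate: in model II only $g_y + \beta E$
enters the dynamics, so $g_y$ is fixed at 0 and $(g_x, \beta)$ estimated;
and $E$ is fixed at 1 during fitting, absorbing the dose into
$\mu/\beta/k_f$. The free-parameter counts are therefore 3/2/2 for models
I/II/III, and `select_treg_model()` ranks by
$\mathrm{AIC} = 2k + n\ln(\mathrm{RSS}/n)$ (RSS floored at $10^{-12}$ so
noise-free data keeps the score finite), breaking ties by fewer parameters
and then fixed model order. A subtlety the test suite documents: data that
are constant in time are fit with zero loss by model III along the whole
detailed-balance manifold $k_f x = k_r y$, so "null data" implies null
rates only for models I and II.

```{r selection}
d <- generate_trajectories("III", treg_params(k_f = 0.2, k_r = 0.05),
                           x0 = 1000, y0 = 10,
                           times = seq(0, 72, length.out = 20),
                           noise_sd = 0.05, seed = 11)
select_treg_model(d)
```

# Spatial statistics: fractal dimension and lacunarity

Treg enrichment in tissue shows up as a change in the *spatial texture* of
marker-positive cells. On a binary marker mask, `box_count()` tiles the
image with an origin-anchored fixed grid of $\epsilon\times\epsilon$ boxes
(default ladder: powers of 2 from 1 to half the short side; powers of 3
selectable for carpet fixtures), including partial edge boxes, and records
occupancy $N(\epsilon)$ plus per-box mass moments. Then:

* `fractal_dimension()`: $\mathrm{FD} = -$slope of the OLS fit of
  $\ln N(\epsilon)$ on $\ln\epsilon$, clamped to $[0,2]$; $R^2$ reported
  ($R^2 = 1$ for a constant curve, whose fit is exact).
* `lacunarity()`: $\lambda(\epsilon) =
  \mathrm{var}(m)/\mathrm{mean}(m)^2 + 1$ with *population* moments over
  all boxes of the grid (empty boxes included), summarised as the
  unweighted mean over scales. A full image gives exactly 1; a single
  occupied box among $B$ gives exactly $B$.

These are deliberate simplifications of ImageJ/FracLac-style analysis,
which offers gliding boxes and multiple grid origins; the source analysis
does not pin those settings down, so the package uses a single fixed grid
and documents translation/rotation stability (±0.02 on FD for point
patterns) as a tested property instead. Dense clustered patterns
(mutant-like tissue) score **higher FD and lower lacunarity** than sparse
uniform patterns (wild-type-like), the direction reported for KRAS-mutant
versus wild-type slides; `compare_groups()` tests the difference with the
in-package two-sided Mann–Whitney U.

`segment_image()` provides Otsu or fixed thresholding for grayscale input
and is idempotent on binary input; `treg_mask()` intersects CD4 and FOXP3
masks. Image I/O uses plain-text PNM (P1/P2) rather than TIFF/PNG: the
metric core is a logical matrix either way, and text images keep the whole
repository codec-free and reviewable.

# Cohort statistics

**Gating and fold conversion.** Gates are rectangular: an event passes if
it strictly exceeds every channel threshold (`gate_definition()`,
`gate_fraction()`). `fold_conversion()` is the ratio of gate-positive
fractions, treated over control, so unequal acquisition depths cancel; a
control with zero gated events is an error (undefined fold), not infinity.

**Mann–Whitney U.** `mann_whitney_u()` computes U from midrank rank sums.
For combined $n \le 12$ without ties the two-sided p-value is exact, from
the full enumeration of U over all $\binom{n}{n_x}$ rank placements;
otherwise the normal approximation with tie and continuity corrections is
used. The cutover (12) is a documented constant. The suite checks the
exact path against `stats::wilcox.test` to $10^{-10}$ over *every* no-tie
configuration with $n \le 10$, and the approximate path against the same
reference under heavy ties; type-I error at $n=20$ per group is within 2
points of the nominal 5% over 1000 null simulations.

**Upregulated-cell fraction.** For one gene,
`isg_upregulated_fraction()` sets the threshold to the mean count of
*reference* cells (Tregs) with detectable expression — zeros excluded, the
minimal reading of "cells without detectable expression were excluded" —
and reports the percentage of *query* cells (MT-TDE-treated) strictly
above it, with all query cells in the denominator. A gene undetected in
every reference cell yields a flagged non-evaluable result. Both
interpretive choices (strict `>`, zeros kept in the query denominator) are
recorded here because the source description leaves them open.

# The synthetic world

The generators state a fixed world; they are inputs to the tests, not
knobs. Where the study reports a quantity, the generator adopts it; where
it does not, a value typical for the assay was chosen once and is listed
here.

* **Flow events** (`generate_flow_events()`): log-normal populations per
  channel; FOXP3-low at 100 a.u. and FOXP3-high at 1000 a.u., both with
  sdlog 0.35, CD4 at 800 a.u. The default gate (CD4 > 150, FOXP3 > 316,
  the geometric midpoint) sits more than 3 sdlog from either FOXP3 mode,
  so the gated fraction tracks the mixture weight to ~5·10⁻⁴ — the
  generator's contract. Converted fractions of 0.29 vs 0.05 reproduce the
  ~5.8-fold conversion scale of mutant-versus-control comparisons.
* **Trajectories** (`generate_trajectories()`): multiplicative log-normal
  noise (default sd 0.05) because counts are positive and span decades;
  values are clipped at 0 and exact zeros stay zero.
* **Spatial images** (`generate_spatial_image()`): collision-free point
  patterns with exactly `n_points` foreground pixels; clustered patterns
  place points around uniform cluster centres with Gaussian scatter. The
  Sierpinski carpet is origin-anchored on the largest power-of-3 side that
  fits (≥ 27), giving the exact analytic FD fixture
  $\ln 8/\ln 3 \approx 1.8928$.
* **scRNA counts** (`generate_scrna_counts()`): negative binomial (default
  mean 2, size 4 — moderate overdispersion typical of droplet data for a
  moderately expressed gene) with independent Bernoulli dropout (default
  0.2), three groups (WT/MT/TREG, 1000 cells each), 10 designated ISGs
  whose mean is multiplied 8-fold in all TREG cells and in a 15% responder
  subset of MT cells.

What a green test does *not* establish: the flow model has no
compensation/spillover or instrument noise floor; images have no optics
(PSF, illumination) or cell morphology; counts have no library-size
variation, batch effects or gene–gene correlation. The generators exercise
the statistics' contracts, not the instruments.

# A known red acceptance check, and why

One property in the acceptance battery is asserted at its stated value and
fails, deliberately. In the synthetic world above (15% MT responders,
8-fold ISG effect), the expected upregulated-cell fraction is
$$0.15\,(1-d)\,P(\mathrm{NB}_{\mu=16} > \tau) \approx
0.15 \times 0.8 \times 0.42 \approx 5\%,$$
where $\tau \approx \mu/(1 - P(\mathrm{NB}=0))$ is the reference nonzero
mean — because responders are *distributionally identical* to the Treg
reference, roughly 42% of them, not all of them, exceed the reference's
own mean. Monte Carlo over 50 seeds confirms ~5.2–5.4%. The asserted
expectation of ~15% (the responder fraction itself) would require either
excluding zero-count query cells from the denominator or boosting
responders far above the Treg reference, both contradicting the contracts
above. The computation is reported as measured rather than adjusted; the
module-level test instead verifies agreement with the analytic
negative-binomial oracle, which passes.

# Pipeline and reproducibility

`run_pipeline()` executes `synth → dynamics → fractal → stats` from a
validated configuration (`validate_config()` collects *all* schema
violations, fills defaults, rejects unknown keys). One global seed fans
out to per-stage seeds via a fixed affine counter
(`(31·seed + 1000003·stage_index) mod (2^31−1)`), so stages never share an
RNG stream and adding a stage never perturbs another stage's draws.
Reports are JSON (with a config MD5 over the canonical serialisation) plus
CSV sidecars; identical configuration and seed give byte-identical
payloads, which the suite asserts. A thin CLI
(`inst/cli/tregswitch.R`) exposes `synth`, `simulate`, `fit`, `fractal`,
`stats` and `run` subcommands.

# Limitations

* The three dynamical models are the minimal linear forms consistent with
  the published description; richer formulations (logistic growth,
  explicit exosome-uptake kinetics) would slot into the same registry but
  are not claimed here.
* FD/lacunarity use one grid origin; absolute values are therefore not
  comparable to FracLac multi-origin output, only the mutant/wild-type
  *direction* is.
* The Mann–Whitney exact path enumerates rank placements and is meant for
  the small-sample regime it guards ($n \le 12$); large-sample inference
  uses the corrected normal approximation.
* Fold conversion assumes a shared gate across tables; no per-donor
  pairing is modelled.
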