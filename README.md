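# tregswitch

Quantitative tools for studies of **Treg phenotypic conversion**: cultures
of naive CD4+ T cells exposed to tumour-derived exosomes (TDEs) that become
enriched for FOXP3+ regulatory-T-like cells. The central question such
studies must answer is whether enrichment reflects *conversion* of
non-Tregs or *expansion* of pre-existing Tregs — two explanations with very
different immunological consequences. `tregswitch` implements, with
synthetic-data generators for every input type:

* **Population dynamics & model selection** — three competing linear models
  for non-Treg ($X$) / Treg ($Y$) abundances:
  * I (heritable acquisition): $\dot X = g_x X - \mu E X$, $\dot Y = g_y Y + \mu E X$
  * II (enhanced proliferation): $\dot X = g_x X$, $\dot Y = (g_y + \beta E)Y$
  * III (plasticity): $\dot X = -k_f E X + k_r Y$, $\dot Y = k_f E X - k_r Y$

  Model III uniquely saturates (conserved total, Treg fraction
  $\to k_f E/(k_f E + k_r)$); models I–II keep growing. Exact closed-form
  simulation, bounded multi-start least-squares fitting on `log1p` counts,
  and AIC ranking (`simulate_treg`, `fit_treg_model`, `select_treg_model`,
  `classify_regime`).
* **Spatial texture of tissue images** — box-counting fractal dimension
  (FD) and fixed-grid lacunarity ($\lambda(\epsilon) =
  \mathrm{var}/\mathrm{mean}^2 + 1$) of binary marker masks, with Otsu /
  fixed segmentation, CD4∧FOXP3 mask intersection, and Mann–Whitney group
  comparison (`box_count`, `fractal_dimension`, `lacunarity`,
  `compare_groups`). Dense clustered (mutant-like) tissue scores higher FD
  and lower lacunarity than sparse uniform (wild-type-like) tissue.
* **Cohort statistics** — rectangular gating and fold conversion of
  CD4+FOXP3+ fractions (`gate_fraction`, `fold_conversion`); a two-sided
  Mann–Whitney U with exact small-sample enumeration
  (`mann_whitney_u`); and the per-gene upregulated-cell-fraction statistic
  for single-cell counts, thresholded at the reference group's nonzero
  mean (`isg_upregulated_fraction`).
* **Reproducible pipeline** — validated configs, per-stage seed fan-out,
  JSON reports (`validate_config`, `run_pipeline`) and a CLI
  (`inst/cli/tregswitch.R`).

## Worked example

Generate a noisy saturating time course from the plasticity model, then let
model selection recover the generating mechanism:

```r
library(tregswitch)
d <- generate_trajectories("III", treg_params(k_f = 0.2, k_r = 0.05),
                           x0 = 1000, y0 = 10,
                           times = seq(0, 72, length.out = 20),
                           noise_sd = 0.05, seed = 11)
select_treg_model(d)
#> <treg_model_ranking>
#>   1. III_plasticity    AIC   -254.494  loss 0.06245
#>   2. I_mutation        AIC    -45.884  loss 10.93
#>   3. II_proliferation  AIC     48.477  loss 121.6
steady_state_fraction(treg_params(k_f = 0.2, k_r = 0.05))
#> [1] 0.8
```

The plasticity model wins by ~209 AIC points over the nearest alternative,
and its analytic fixed point says 80% of the culture ends up Treg-like —
the saturating signature that distinguishes conversion from proliferation.

Flow-style fold conversion (29% vs 5% converted fractions at 10⁵ events
reproduce a ~5.8-fold enrichment):

```r
fold_conversion(
  generate_flow_events(1e5, 0.29, condition = "MT-TDE", seed = 81),
  generate_flow_events(1e5, 0.05, condition = "control", seed = 82))
#> <conversion_result> 0.2911 (n=100000) vs 0.0505 (n=100000): fold = 5.761
```

Fractal metrics on an exact fixture (Sierpinski carpet,
FD $= \ln 8/\ln 3 \approx 1.8928$):

```r
fractal_metrics(generate_spatial_image(81, "sierpinski_carpet"), base = 3)
#> <fractal_metrics> fd: 1.893  lacunarity: 1.354  r2: 1
```

Single-cell upregulated-cell fraction (MT-treated cells above the Treg
reference's nonzero-mean threshold):

```r
cm <- generate_scrna_counts(scrna_config(), seed = 7)
isg_upregulated_fraction(cm, "G1", "MT", "TREG")
#> <upregulation_result> G1: threshold 16.191 (ref n=796, 204 excluded),
#>   5.1% of 1000 query cells above
```

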