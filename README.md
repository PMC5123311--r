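# hemorheo

Pharmacodynamic analysis of dipyrone (metamizole) effects on piglet
hemorheological parameters.

Dipyrone is a pyrazolone NSAID whose active metabolites
(4-methylaminoantipyrine, 4MAA, and 4-aminoantipyrine, 4AA) affect blood
cells and plasma coagulation. In the eight-piglet single-dose study design
this package models, blood is sampled from 36 h before to 72 h after a
100 mg/kg intramuscular dose, and the question is twofold: which blood
parameters (Hb, Hct, RBC, WBC, MCV, MCH, Plt, PT, APTT, APTT ratio,
fibrinogen, closure times) change significantly after dosing, and can a
composite of those parameters track the plasma concentration of 4MAA?

The package is aimed at veterinary pharmacologists and biostatisticians
designing or re-analysing small-animal PK/PD studies of this shape. It
provides:

* **AUEC effect analysis.** For each parameter, the area under the effect
  curve by the linear trapezoidal rule over the baseline window *B*
  (−36–0 h) and the post-dose window *A* (0–72 h), and the
  baseline-normalized change ratio

  ```
  A/B ratio = (B/36 − A/72) / (B/36)
  ```

  i.e. the fractional drop of the time-averaged post-dose level relative
  to the time-averaged baseline (positive = decrease after dosing).
  Significance of the change is assessed by a two-sided paired Student's
  *t* test on per-animal time-averaged levels; between-animal variability
  is summarised as RSD% (100·SD/mean) per window.

* **Composite hemorheological indices.** `PT + (Hb + Hct)/RBC^APTT_ratio`
  and `MCV + PT`, evaluated on cohort-mean curves, with squared Pearson
  correlation against metabolite concentration.

* **Leave-one-out model validation.** Exact LOO of the univariate
  metabolite↔index regression via the hat-matrix identity
  `e_i/(1 − h_ii)`, giving PRESS, `Q² = 1 − PRESS/SS`, the asymptotic
  `Q²asym = 1 − (1 − R²)·((n−1)/(n−2))²`, and the four OECD-style
  acceptance criteria: `0 < Q²asym − Q² < 1`, `Q² ≥ 0.65`, `R² ≥ 0.85`,
  `Q² − R² < 0`. A model is "fully predictive" only if all four hold.

* **A synthetic-cohort generator.** Because the study's raw per-timepoint
  data were never published, a calibrated simulator reproduces the study
  conditions: 8 piglets, the printed sampling schedule, per-parameter
  effect templates matching the published dynamic ranges and effect
  timings (e.g. Hb 12.35 → 9.14 g/dL, WBC 14.71 → 24.67 ×10⁹/L recovering
  by 72 h, Plt peaking at 10 h, fibrinogen dipping at 6 h), lognormal
  between-animal baselines, multiplicative residual noise, and an
  analytic one-compartment 4MAA/4AA metabolite model.

## Worked example

```r
library(hemorheo)

cfg <- default_study_config(seed = 1)   # the calibrated 8-piglet study
dataset <- simulate_cohort(cfg)
effect <- make_effect_table(dataset)
effect[effect$parameter == "Hb", c("parameter", "ab_ratio", "p_value")]
#>   parameter  ab_ratio      p_value
#> 4        Hb 0.2464948 5.518740e-06
```

Hb's time-averaged level fell by ~25% after dosing (the template's
closed-form value is 0.239; one noisy 8-animal cohort estimates 0.246),
and the paired test finds the change highly significant. Applying the
same ratio definition to the study's published AUEC pairs reproduces all
nine published ratios exactly:

```r
ref <- dipyrone_reference_effects()
round(ab_ratio(ref$A_mean, ref$B_mean), 3)
#> [1]  0.197  0.186  0.303  0.650  0.153  0.148  0.211 -0.330  0.195
```

The LOO gate on a simulated metabolite↔index relationship:

```r
rep <- run_pipeline(cfg)
rep$validation[["4MAA_composite"]][c("q2", "r2", "pass")]
#> $q2        0.5796
#> $r2        0.6871
#> $pass      FALSE
```

At the default noise level and n = 13 time points the synthetic 4MAA
relationship is strong but below the gate thresholds, while 4AA is flatly
unrelated (R² ≈ 0.06) — the same qualitative contrast the study reported.

## The analysis workflow

The numbered scripts under `analysis/` run the full study re-analysis,
writing every intermediate table under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + metabolites (seed 1)
Rscript analysis/02_effect_table.R  # AUEC table, significance, closure check
Rscript analysis/03_indices.R       # composite and MCV+PT index curves
Rscript analysis/04_validation.R    # LOO validation and gate verdicts
```

Each stage reads only the previous stage's CSVs, so every reported number
is recomputable from the emitted files.

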