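# transportddi

Transporter-mediated drug–drug interaction (DDI) assessment, from raw in
vitro assay plates to a quantitative prediction of how much a perpetrator
drug will raise a victim drug's plasma exposure.

Metformin is the canonical victim: it is cleared almost entirely by active
renal secretion — uptake from blood by OCT2 on the basolateral membrane of
proximal tubule cells and efflux into urine by MATE1 on the apical membrane
— and its AUC rises clinically when co-dosed with cimetidine, trimethoprim
or pyrimethamine. `transportddi` implements the full in-vitro-to-in-vivo
workflow used to attribute such interactions to a specific transporter:

1. **Uptake processing** — convert scintillation counts (dpm) from
   transfected-cell plates into protein-normalised uptake activities
   (pmol/mg), subtract the vector-control background, compute uptake-ratio
   QC and find the linear incubation window.
2. **Kinetics** — fit the Michaelis–Menten model
   `v = Vmax·S/(Km + S)` for Km/Vmax, and four- or five-parameter logistic
   curves to percent-of-control inhibition data for IC50, converted to an
   absolute inhibition constant via Cheng–Prusoff,
   `Ki = IC50/(1 + S/Km)` (≈ IC50 when the probe is run at `S ≤ Km/10`).
3. **Permeability** — bidirectional Caco-2 apparent permeability
   `Papp = Q/(t·A·C0)` with mass balance, lucifer-yellow integrity gating
   (pass iff `Papp,LY ≤ 1.0 × 10⁻⁶ cm/s`) and an equivalence-style test for
   inhibitor effects on absorptive flux.
4. **Static DDI model** — the adapted Rowland–Matin mechanistic static
   equation for the victim AUC fold-change when a fraction `fe` of its
   clearance runs through the inhibited pathway:

   ```
   fold-ΔAUC = 1 / [ fe / (1 + [I]/Ki) + (1 − fe) ]
   ```

   with `[I]` the unbound Cmax of the perpetrator (systemic) or the
   dose-in-250-mL `[I2]` (intestinal), plus the regulatory ratio screens
   `[I]/Ki ≥ 0.1` and `[I2]/Ki ≥ 10`, and scoring against observed
   clinical AUC changes.
5. **Synthetic data** — plate-level simulators with known ground truth
   (Michaelis–Menten uptake, logistic inhibition, transwell flux,
   configurable lognormal noise), so every estimator in the package is
   validated by parameter recovery.

Everything is tidyverse-native: functions take data frames, return
tibbles, and fitted objects support `tidy()`, `glance()`, `augment()` and
`autoplot()`.

## Worked example

Simulate a noisy OCT2 kinetic plate, fit it, then run the bundled
metformin case study:

```r
library(transportddi)
library(dplyr)

truth <- assay_truth("OCT2", km_true = 1608, vmax_true = 32918,
                     noise_cv = 0.05)
sim_kinetic_plate(truth, concs = c(1, 10, 100, 300, 1000, 3000, 10000),
                  time = 5, seed = 1) |>
  corrected_activities() |>
  fit_michaelis_menten(transporter = "OCT2")
#> Michaelis-Menten fit (OCT2)
#>   Km   = 1540 +/- 41.1 umol/L
#>   Vmax = 3.192e+04 +/- 274 pmol/min/mg
```

The fitted Km (1540 μmol/L) recovers the simulated truth (1608 μmol/L)
to within the uncertainty expected at 5% well-level noise. The static
model then turns measured Ki values and clinical pharmacokinetics into
predicted metformin AUC fold-increases, under either the intravenous
(`fe = 0.66`) or oral (`fe = 0.39`) fraction-excreted scenario:

```r
inputs <- metformin_ddi_inputs()
preds <- predict_ddi(inputs$perpetrators, inputs$ki, fe = c(0.66, 0.39))
preds |>
  filter(transporter == "MATE1") |>
  transmute(perpetrator, study, fe_used, fold_auc = round(fold_auc, 2))
#>    perpetrator   study           fe_used fold_auc
#>  1 cimetidine    metformin_250mg    0.66     2.32
#>  2 cimetidine    metformin_250mg    0.39     1.51
#>  3 cimetidine    metformin_500mg    0.66     2.03
#>  4 cimetidine    metformin_500mg    0.39     1.43
#>  5 trimethoprim  metformin_500mg    0.66     1.98
#>  6 trimethoprim  metformin_500mg    0.39     1.41
#>  7 trimethoprim  metformin_850mg    0.66     1.69
#>  8 trimethoprim  metformin_850mg    0.39     1.32
#>  9 pyrimethamine metformin_250mg    0.66     1.85
#> 10 pyrimethamine metformin_250mg    0.39     1.37

concordance_range(compare_to_observed(preds, inputs$observed))
#>   transporter fe_used n_pairs delta_min delta_max
#> 1 MATE1          0.39       5      1.70      11.1
#> 2 MATE1          0.66       5     38.7       86.3
#> 3 OCT2           0.39       5     28.8       53.2
#> 4 OCT2           0.66       5     28.0       52.7
```

Reading the output: MATE1 inhibition predicts clinically meaningful
AUC increases (up to 2.32-fold for cimetidine) while OCT2 inhibition
predicts essentially none (≤ 1.04-fold) — the renal efflux step, not the
uptake step, is the liable mechanism. The concordance table gives the
spread of |predicted − observed| in percentage points of AUC increase
across the five clinical studies: the oral-mass-balance `fe` of 0.39
brings every MATE1 prediction within ~11 points of the observed change,
whereas the intravenous `fe` of 0.66 over-predicts by up to ~86 points.

`run_ddi_pipeline(ddi_pipeline_config(out_dir = "out"))` chains the
simulate → process → fit → predict → compare stages and writes per-stage
CSV artifacts plus a Markdown report.

## Acceptance script

`scripts/acceptance.R` recomputes the headline static-model quantities
from the bundled input tables by running `predict_ddi()` from scratch and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — simulators, uptake processing, kinetics/inhibition fitting,
  permeability, static DDI engine, pipeline orchestration, plotting.
- `inst/extdata/` — the case-study input tables (perpetrator
  pharmacokinetics, transporter Ki values, observed clinical AUC changes,
  victim disposition fractions).
- `vignettes/transporter-ddi-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the simulator does and does not
  emulate, numerical decisions and limitations.
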