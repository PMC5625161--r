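---
title: "Methods: from uptake plates to static DDI predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from uptake plates to static DDI predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportddi)
```

## The problem

A drug cleared mainly by active renal secretion is vulnerable to
drug–drug interactions at the transporters that carry it: basolateral
uptake into proximal tubule cells (OCT2) and apical efflux into urine
(MATE1, MATE2-K). The package implements the standard in-vitro-to-in-vivo
chain for attributing a clinically observed AUC increase to one of these
steps: measure each transporter's kinetics and each perpetrator's
inhibitory potency in transfected cell lines, check that intestinal
absorption is not the explanation using Caco-2 monolayers, and feed the
resulting inhibition constants into a mechanistic static model of the
victim's exposure change.

## The static model

If a fraction $f_e$ of the victim's total clearance proceeds through the
inhibited pathway, and an inhibitor at concentration $[I]$ with
inhibition constant $K_i$ scales that pathway by $1/(1+[I]/K_i)$
(competitive inhibition at the site of transport), the AUC ratio is

$$\mathrm{fold\ \Delta AUC} = \frac{1}{\dfrac{f_e}{1+[I]/K_i} + (1-f_e)}.$$

`fold_auc()` evaluates this directly. Two properties are useful sanity
anchors and are enforced by tests: the prediction is exactly 1 at
$[I]=0$, and it saturates at $1/(1-f_e)$ as $[I]\to\infty$ (complete
loss of the inhibitable pathway).

Assumptions worth stating:

* **Competitive inhibition** throughout; no mechanism discrimination is
  attempted. This is why IC50 values measured at probe concentrations
  far below Km can stand in for $K_i$ (Cheng–Prusoff, below).
* **$[I]$ = unbound systemic Cmax** for renal transporters
  (`cmax_free()` = total Cmax × $f_u$): for passively equilibrating,
  facilitatively transported perpetrators the intracellular
  concentration tracks unbound plasma.
* For intestinal exposure the conventional worst case
  $[I_2]$ = dose dissolved in 250 mL (`i2_gut()`) is used, with the
  regulatory concern thresholds $[I]/K_i \ge 0.1$ (systemic) and
  $[I_2]/K_i \ge 10$ (gut) exposed as configurable cut-offs in
  `ratio_screen()` and `predict_ddi()`.

### The two fe scenarios

`derive_fe()` composes $f_e$ as (renal fraction of total clearance) ×
(active fraction of renal clearance). For metformin the renal fraction
is 0.88 when determined from intravenous mass balance but 0.52 from
urinary recovery after oral dosing; with 75% of renal clearance active,
that gives $f_e = 0.66$ (iv) or $0.39$ (oral), both reported at 2
decimal places. The discrepancy is real, not noise: metformin shows
flip-flop pharmacokinetics (absorption slower than elimination), so
during an oral dose absorption proceeds in parallel with renal
elimination and the fraction of the circulating dose available to the
inhibitable pathway is smaller. The package treats $f_e$ as a scenario
axis — `predict_ddi()` produces a row per (perpetrator, Cmax,
transporter, fe) — rather than choosing one value.

### Scoring predictions against clinic

`compare_to_observed()` pairs each prediction with the clinical study it
corresponds to (by perpetrator and study label) and reports
$|100(\mathrm{pred}-1) - 100(\mathrm{obs}-1)|$: the absolute difference
in **percent AUC increase**, in percentage points. This definition was
chosen deliberately — it is the one under which the bundled case study's
concordance summary lands on the documented 39–86 point (fe 0.66) and
2–11 point (fe 0.39) ranges — and a relative alternative
(`metric = "relative_fold_error"`) is provided without asserting that
either is canonical.

## Curve fitting

### Michaelis–Menten

`fit_michaelis_menten()` fits $v = V_{max} S/(K_m+S)$ by nonlinear least
squares (`nls()` with the self-starting `SSmicmen`), reporting asymptotic
standard errors. Numerical choices: `scaleOffset = 1` in the control so
that exactly-fitting (noise-free) data converge instead of tripping the
zero-residual stopping criterion; a singular variance matrix (again the
noise-free case) yields `NA` standard errors rather than an error;
designs with fewer than 4 distinct concentrations, essentially constant
rates, or a fitted Km outside the tested range raise warnings because Km
is then poorly identified or unidentifiable.

### 4/5-parameter logistic inhibition curves

`fit_logistic()` fits

$$y = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}{\left(1+(x/x_{mid})^{h}\right)^{s}}$$

with $s=1$ for the symmetric 4PL. Decisions that matter:

* **Fitting scale.** The midpoint is parameterised as
  $\log_{10} x_{mid}$; vehicle (zero-concentration) wells cannot sit on
  a log axis, so the model function maps $x=0$ to the upper plateau and
  vehicle rows act as an anchor for `top`.
* **Reported IC50.** Always the concentration where the fitted curve
  crosses $(\mathrm{top}+\mathrm{bottom})/2$. For the 4PL this equals
  $x_{mid}$; for the asymmetric 5PL it is
  $x_{mid}(2^{1/s}-1)^{1/h}$, derived from the fitted parameters.
* **Bounds and starts.** Constrained (`port`) fitting with bottom ∈
  [−20, 50]%, top ∈ [50, 150]%, hill ∈ (0, 10], asymmetry ∈ [0.2, 5];
  plateaus start at the extreme-concentration means, the midpoint at the
  concentration pair bracketing the half-response, hill at 1. Because
  `port` occasionally declares false convergence from an unlucky start,
  the fit retries over a small grid of hill/midpoint starts and keeps
  the lowest-RSS solution, preferring cleanly converged ones; the
  convergence flag is carried into `glance()`.
* **Model selection.** `model = "auto"` fits both and selects by
  small-sample-corrected AIC. Note that with condition-level means (7–9
  points per occasion) the 5PL's AICc penalty is infinite at $n \le k+1$,
  so auto-selection effectively prefers the 4PL unless the design is
  rich; an explicit `model = "5PL"` is honoured regardless.
* **Censoring.** If no tested concentration pulls the mean response
  below 80% of control, no IC50 is reported; the result is censored at
  the highest tested concentration instead of returning an extrapolated
  number.

### Cheng–Prusoff and occasions

`cheng_prusoff_ki()` applies $K_i = IC_{50}/(1+S/K_m)$ and also reports
whether the assay met the $S \le K_m/10$ condition under which
$IC_{50} \approx K_i$ (at $S = K_m/10$ the correction is 9%; the
simulator refuses to generate inhibition plates violating the condition
unless overridden). `aggregate_occasions()` summarises independent
experimental repeats as the arithmetic mean ± SD of occasion-level
IC50s — the SD is interpreted as between-occasion variability of
separately fitted IC50s, not the SE of a pooled fit, and that assumption
is recorded here because summary tables in the literature are often
ambiguous on the point.

## Uptake processing

Counts are converted as pmol = dpm / (specific activity) /
(fraction of lysate counted). The default specific activity, 22.2
dpm/pmol, corresponds to a dosing solution of 37 kBq/mL at 100 μmol/L;
the default counted fraction is 300/400 μL. Whether raw data were
already aliquot-corrected varies between laboratories, so
`correct_aliquot` is a switch, not an assumption. Activities are
protein-normalised per well, replicates are averaged per condition
before vector-control correction, and replicate SDs of the two cell
lines propagate in quadrature. **Negative corrected activities are
retained and flagged**, never clamped: clamping at zero would bias the
bottom plateau of inhibition curves upward.

`assess_linearity()` encodes an explicit rule for a judgement usually
made by eye: starting from the earliest time, the longest prefix window
(≥ 3 points) over which a through-origin line achieves uncentered
R² ≥ 0.95 with every point within 15% of the line. The chosen assay time
is the last time in that window (maximum signal at maintained
linearity). The thresholds are arguments; the defaults reproduce
sensible windows on simulated saturating timecourses.

## Permeability

`Papp = Q/(t \cdot A \cdot C_0)` from the single end-point receiver
amount, since receivers are sampled once; the formula depends only on
amount, time, area and donor concentration, never on compartment-volume
bookkeeping (a tested invariant). A warning is raised when the receiver
concentration exceeds 10% of donor (sink-condition failure, standard
practice). The lucifer-yellow integrity gate passes a well iff its
marker Papp ≤ 1.0 × 10⁻⁶ cm/s — boundary inclusive — and failing wells
are excluded from every aggregate. `inhibitor_effect_test()` compares
arms on the log scale (Welch t) and declares "no change" only when the
90% CI of the fold-change sits inside 0.8–1.25, the conventional
bioequivalence band; an interval excluding 1 is a "change", anything
else "inconclusive".

## What the simulator emulates — and what it does not

`sim_*` generators reproduce the assay **designs**: paired transporter /
vector-control wells in triplicate, saturable Michaelis–Menten uptake
with a passive background expressed as `control_fraction` (the uptake
ratio is $(1+c)/c$), logistic suppression of only the transporter-mediated
component by inhibitors, per-occasion lognormal multipliers on the true
IC50, and transwell geometry defaults of 0.12 cm², 90 μL apical / 210 μL
basolateral, 90-minute incubations, with a stated loss fraction setting
the mass-balance truth.

Noise defaults are the package's statement of a realistic world and are
not tuned to tests: multiplicative lognormal dpm noise with CV 0.05
(scintillation counts of this magnitude are strictly positive with
roughly constant CV — the distributional form is a stand-in, flagged
here, since count-level data rarely ship with replicate distributions),
protein per well normal with CV 0.05 truncated at zero (BCA variation is
small and additive), and a 5% mass-balance loss. Departure from time
linearity is modelled phenomenologically as exponential saturation of
cumulative uptake with time constant `linear_tau` (default `Inf`,
i.e. linear); no intracellular model is claimed.

Not emulated: proton-antiport driving forces for the MATE transporters
(the ammonium-chloride prepulse is an experimental device, not a model
component here), intracellular accumulation, plate-position or drift
effects, and pH/micelle effects of biorelevant matrices (the matrix is
carried as a label only). A green recovery test therefore establishes
that the estimators are correct **given** Michaelis–Menten transport
with multiplicative noise — not that real plates obey that model.

## Known limitations

* The static model is deliberately not a PBPK model: no dynamics, no
  transporter interplay, no active-uptake-limited intracellular
  concentrations. Its value is transparency — every input is a printed
  number.
* MATE2-K is measurable in vitro and supported by the fitting stack, but
  the bundled prediction grid covers OCT2 and MATE1 only, reflecting
  proteomic evidence that MATE2-K contributes little to renal metformin
  handling.
* Two-site or substrate-inhibition kinetics and global (Dixon-style)
  Ki estimation are out of scope.
* Perpetrator molecular weights are user-supplied inputs; the bundled
  values are validated in tests against the documented $[I_2]$
  concentrations rather than asserted from any single source.
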