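# Kinetic and inhibition ground truths used across tests.  Km/Vmax pairs
# are realistic per-transporter values for metformin uptake; IC50s span the
# potency range of the three perpetrator drugs.  All serve as *synthetic
# truths* for recovery testing, not as fitted results.
kinetic_truths <- list(
  OCT1   = list(km = 5422, vmax = 9370,   concs = c(10, 30, 100, 300, 1000, 3000, 10000), time = 10),
  OCT2   = list(km = 1608, vmax = 32918,  concs = c(1, 10, 100, 300, 1000, 3000, 10000), time = 5),
  MATE1  = list(km = 4565, vmax = 141000, concs = c(10, 30, 100, 300, 1000, 3000, 10000), time = 1.5),
  MATE2K = list(km = 2986, vmax = 32147,  concs = c(10, 30, 100, 300, 1000, 3000, 10000), time = 1.5)
)

ic50_truths <- c(cimetidine_mate1 = 1.22, trimethoprim_mate1 = 2.64,
                 pyrimethamine_mate1 = 0.131, cimetidine_oct2 = 207)

noiseless_assay <- function(transporter = "OCT2", ...) {
  kt <- kinetic_truths[[transporter]]
  assay_truth(transporter, km_true = kt$km, vmax_true = kt$vmax,
              noise_cv = 0, protein_cv = 0, ...)
}

# reference logistic curve written independently of the package internals
logistic5_ref <- function(conc, ic50, hill, bottom = 0, top = 100, s = 1) {
  xmid <- ic50 / (2^(1 / s) - 1)^(1 / hill)
  ifelse(conc == 0, top,
         bottom + (top - bottom) / (1 + (conc / xmid)^hill)^s)
}

# 7-point half-log inhibitor series bracketing an IC50
inhibitor_series <- function(ic50) 10^seq(log10(ic50) - 2, log10(ic50) + 2,
                                          length.out = 7)

fit_ic50_from_plate <- function(assay, inh, concs, model = "auto",
                                time = 1.5, seed = NULL) {
  sim_inhibition_plate(assay, inh, concs, probe_conc = 100, time = time,
                       seed = seed) |>
    corrected_activities() |>
    inhibition_responses() |>
    fit_logistic(model = model)
}
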