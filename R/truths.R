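#' Ground-truth parameter sets for simulated transporter assays
#'
#' These constructors hold the "stated world" from which the simulators in
#' [sim_kinetic_plate()], [sim_inhibition_plate()] and [sim_transwell_plate()]
#' draw plates: the Michaelis-Menten parameters of a transporter cell line,
#' the logistic inhibition curve of an inhibitor, or the permeability of a
#' Caco-2 monolayer.  Because the truth is known, every downstream estimator
#' can be validated by parameter recovery.
#'
#' @param transporter Transporter label (`"OCT1"`, `"OCT2"`, `"MATE1"`,
#'   `"MATE2K"`).
#' @param km_true Michaelis constant, umol/L.  Must be positive.
#' @param vmax_true Maximal transport velocity, pmol/min/mg protein.
#' @param control_fraction Passive/background uptake in vector-control cells,
#'   expressed as a fraction of the transporter-mediated rate at the same
#'   substrate concentration.  In `[0, 1)`; the uptake ratio of a simulated
#'   plate is `(1 + control_fraction) / control_fraction`.
#' @param protein_per_well Nominal lysate protein per well, mg.
#' @param protein_cv Well-to-well coefficient of variation of protein mass
#'   (normal, truncated at zero).
#' @param noise_cv Multiplicative lognormal CV applied to well dpm.
#' @param linear_tau Time constant (min) of the optional exponential
#'   saturation of cumulative uptake; `Inf` (default) keeps uptake linear in
#'   time.  Effective incubation time is `tau * (1 - exp(-t / tau))`.
#' @return An object of class `assay_truth`.
#' @examples
#' assay_truth("OCT2", km_true = 1608, vmax_true = 32918)
#' @export
assay_truth <- function(transporter = "OCT2", km_true = 1608,
                        vmax_true = 32918, control_fraction = 1 / 18,
                        protein_per_well = 0.1, protein_cv = 0.05,
                        noise_cv = 0.05, linear_tau = Inf) {
  stopifnot(km_true > 0, vmax_true > 0, noise_cv >= 0,
            control_fraction >= 0, control_fraction < 1,
            protein_per_well > 0, protein_cv >= 0, linear_tau > 0)
  structure(
    list(transporter = transporter, km_true = km_true, vmax_true = vmax_true,
         control_fraction = control_fraction,
         protein_per_well = protein_per_well, protein_cv = protein_cv,
         noise_cv = noise_cv, linear_tau = linear_tau),
    class = "assay_truth"
  )
}

#' @rdname assay_truth
#' @param ic50_true True half-maximal inhibitory concentration, umol/L.
#' @param hill_true Hill slope (> 0).
#' @param bottom_true,top_true Lower and upper plateaus of the inhibition
#'   curve, percent of vehicle control.
#' @param asymmetry_true Asymmetry exponent of the five-parameter logistic;
#'   1 gives the symmetric four-parameter curve.
#' @param occasions Number of independent experimental occasions.
#' @param occasion_cv Lognormal CV of the occasion-level multiplier on
#'   `ic50_true`, modelling between-occasion potency variation.
#' @export
inhibition_truth <- function(ic50_true, hill_true = 1, bottom_true = 0,
                             top_true = 100, asymmetry_true = 1,
                             occasions = 1, occasion_cv = 0) {
  stopifnot(ic50_true > 0, hill_true > 0, bottom_true < top_true,
            asymmetry_true > 0, occasions >= 1, occasion_cv >= 0)
  structure(
    list(ic50_true = ic50_true, hill_true = hill_true,
         bottom_true = bottom_true, top_true = top_true,
         asymmetry_true = asymmetry_true, occasions = occasions,
         occasion_cv = occasion_cv),
    class = "inhibition_truth"
  )
}

#' @rdname assay_truth
#' @param papp_true True apparent permeability, cm/s (same value both
#'   directions; the paracellular route is direction-symmetric).
#' @param area Insert membrane surface area, cm^2.
#' @param donor_volume_ab,donor_volume_ba Donor compartment volumes, uL
#'   (apical donor for A-B, basolateral donor for B-A).
#' @param duration Incubation time, seconds.
#' @param ly_papp_true True lucifer-yellow permeability, cm/s (the
#'   paracellular integrity marker).
#' @param loss_fraction Fraction of the initial donor amount lost to
#'   non-specific binding / cell accumulation, setting the mass-balance
#'   truth at `100 * (1 - loss_fraction)` percent.
#' @export
transwell_truth <- function(papp_true = 0.5e-6, area = 0.12,
                            donor_volume_ab = 90, donor_volume_ba = 210,
                            duration = 5400, ly_papp_true = 0.4e-6,
                            loss_fraction = 0.05, noise_cv = 0.05) {
  stopifnot(papp_true >= 0, area > 0, duration > 0, ly_papp_true >= 0,
            loss_fraction >= 0, loss_fraction < 1, noise_cv >= 0,
            donor_volume_ab > 0, donor_volume_ba > 0)
  structure(
    list(papp_true = papp_true, area = area,
         donor_volume_ab = donor_volume_ab, donor_volume_ba = donor_volume_ba,
         duration = duration, ly_papp_true = ly_papp_true,
         loss_fraction = loss_fraction, noise_cv = noise_cv),
    class = "transwell_truth"
  )
}
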