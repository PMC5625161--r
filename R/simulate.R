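#' Simulate transporter uptake plates with known ground truth
#'
#' Plate-level generators emulating radiolabelled uptake assays in
#' transporter-transfected cells run alongside vector-control cells.
#' Each condition produces paired transporter and control wells: the
#' transporter well accumulates the Michaelis-Menten transport component
#' plus passive background, the control well only the background.  Well
#' amounts are converted to scintillation counts (dpm) through the probe's
#' specific activity and the counted lysate fraction, then perturbed by
#' multiplicative lognormal noise of CV `truth$noise_cv`.
#'
#' `sim_uptake_timecourse()` varies incubation time at one substrate
#' concentration (the time-linearity design); `sim_kinetic_plate()` varies
#' substrate concentration at one fixed time inside the linear window (the
#' Km design); `sim_inhibition_plate()` varies inhibitor concentration at a
#' fixed probe concentration and time (the IC50 design).
#'
#' @param truth,assay An [assay_truth()] object.
#' @param probe_conc Probe substrate concentration, umol/L.
#' @param times Incubation times, minutes.
#' @param time Single incubation time, minutes.
#' @param concs Substrate concentrations, umol/L.
#' @param replicates Wells per (condition, cell line).
#' @param sa Specific activity, dpm/pmol (default [specific_activity()]).
#' @param lysate_fraction Fraction of the lysate volume counted.
#' @param seed Integer seed; identical seed and truth give identical plates.
#' @return A tibble with one row per well: `well_id`, `cell_line`
#'   (`"transporter"` or `"vector_control"`), `transporter`, `probe_conc`,
#'   `inhibitor`, `inhibitor_conc`, `time`, `dpm`, `protein`,
#'   `lysate_fraction_counted`, `occasion`.
#' @examples
#' truth <- assay_truth("OCT2", km_true = 1608, vmax_true = 32918,
#'                      noise_cv = 0)
#' sim_kinetic_plate(truth, concs = c(10, 100, 1000, 10000), time = 5)
#' @export
sim_uptake_timecourse <- function(truth, probe_conc = 100,
                                  times = c(1, 2, 3, 5, 10, 15),
                                  replicates = 3,
                                  sa = specific_activity(),
                                  lysate_fraction = 300 / 400,
                                  seed = NULL) {
  stopifnot(inherits(truth, "assay_truth"))
  if (length(times) == 0 || any(times <= 0))
    abort("`times` must be a non-empty vector of positive minutes.")
  if (probe_conc <= 0) abort("`probe_conc` must be positive.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(
    time = times,
    cell_line = c("transporter", "vector_control"),
    rep = seq_len(replicates)
  )
  sim_wells(truth, grid, probe_conc = probe_conc, inhibitor = NA_character_,
            inhibitor_conc = NA_real_, inhibition_factor = 1,
            sa = sa, lysate_fraction = lysate_fraction, occasion = 1L)
}

#' @rdname sim_uptake_timecourse
#' @export
sim_kinetic_plate <- function(truth,
                              concs = c(10, 30, 100, 300, 1000, 3000, 10000),
                              time = 5, replicates = 3,
                              sa = specific_activity(),
                              lysate_fraction = 300 / 400, seed = NULL) {
  stopifnot(inherits(truth, "assay_truth"))
  if (length(concs) == 0 || any(concs <= 0))
    abort("`concs` must be a non-empty vector of positive concentrations.")
  if (time <= 0) abort("`time` must be positive.")
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(
    probe_conc = concs,
    cell_line = c("transporter", "vector_control"),
    rep = seq_len(replicates)
  )
  grid$time <- time
  sim_wells(truth, grid, inhibitor = NA_character_,
            inhibitor_conc = NA_real_, inhibition_factor = 1,
            sa = sa, lysate_fraction = lysate_fraction, occasion = 1L)
}

#' @rdname sim_uptake_timecourse
#' @param inh An [inhibition_truth()] object for the simulated inhibitor.
#' @param inhibitor_concs Inhibitor concentrations, umol/L; a zero (vehicle)
#'   level is prepended if absent.
#' @param inhibitor Inhibitor label carried into the well table.
#' @param allow_high_probe Permit `probe_conc > km_true / 10`.  The default
#'   enforces the condition under which IC50 approximates Ki
#'   (Cheng-Prusoff with `[S] << Km`).
#' @export
sim_inhibition_plate <- function(assay, inh, inhibitor_concs,
                                 probe_conc = 100, time = 2,
                                 replicates = 3, inhibitor = "inhibitor",
                                 sa = specific_activity(),
                                 lysate_fraction = 300 / 400,
                                 allow_high_probe = FALSE, seed = NULL) {
  stopifnot(inherits(assay, "assay_truth"), inherits(inh, "inhibition_truth"))
  if (length(inhibitor_concs) == 0)
    abort("`inhibitor_concs` must be non-empty.")
  if (any(inhibitor_concs < 0)) abort("Inhibitor concentrations must be >= 0.")
  if (probe_conc > assay$km_true / 10 && !allow_high_probe)
    abort(paste0(
      "`probe_conc` exceeds km_true / 10, so fitted IC50 would not ",
      "approximate Ki; set `allow_high_probe = TRUE` to override."
    ))
  if (!is.null(seed)) set.seed(seed)

  concs <- sort(unique(c(0, inhibitor_concs)))
  out <- purrr::map(seq_len(inh$occasions), function(occ) {
    ic50_occ <- inh$ic50_true * ln_noise(1, inh$occasion_cv)
    grid <- tidyr::expand_grid(
      inhibitor_conc = concs,
      cell_line = c("transporter", "vector_control"),
      rep = seq_len(replicates)
    )
    grid$time <- time
    fac <- logistic5(grid$inhibitor_conc, bottom = inh$bottom_true,
                     top = inh$top_true, ic50 = ic50_occ,
                     hill = inh$hill_true, asymmetry = inh$asymmetry_true) / 100
    sim_wells(assay, grid, probe_conc = probe_conc, inhibitor = inhibitor,
              inhibition_factor = fac, sa = sa,
              lysate_fraction = lysate_fraction, occasion = as.integer(occ))
  })
  bind_rows(out)
}

# Core well builder shared by the three uptake designs.  The inhibition
# factor scales only the transporter-mediated component; the passive
# background (control_fraction) is assumed insensitive to the inhibitor.
sim_wells <- function(truth, grid, probe_conc = NULL, inhibitor,
                      inhibitor_conc = NULL, inhibition_factor, sa,
                      lysate_fraction, occasion) {
  if (!"probe_conc" %in% names(grid)) grid$probe_conc <- probe_conc
  if (!"inhibitor_conc" %in% names(grid)) grid$inhibitor_conc <- inhibitor_conc

  mm_rate <- truth$vmax_true * grid$probe_conc / (truth$km_true + grid$probe_conc)
  t_eff <- effective_time(grid$time, truth$linear_tau)
  protein <- protein_draw(nrow(grid), truth$protein_per_well, truth$protein_cv)
  carrier <- ifelse(grid$cell_line == "transporter",
                    inhibition_factor + truth$control_fraction,
                    truth$control_fraction)
  pmol <- mm_rate * carrier * t_eff * protein
  dpm <- pmol * sa * lysate_fraction * ln_noise(nrow(grid), truth$noise_cv)

  tibble(
    well_id = sprintf("%s_o%d_w%03d", truth$transporter, occasion,
                      seq_len(nrow(grid))),
    cell_line = grid$cell_line,
    transporter = truth$transporter,
    probe_conc = grid$probe_conc,
    inhibitor = if ("inhibitor" %in% names(grid)) grid$inhibitor else inhibitor,
    inhibitor_conc = grid$inhibitor_conc,
    time = grid$time,
    dpm = dpm,
    protein = protein,
    lysate_fraction_counted = lysate_fraction,
    occasion = occasion
  )
}

effective_time <- function(t, tau) {
  if (is.infinite(tau)) t else tau * (1 - exp(-t / tau))
}

# Five-parameter logistic in concentration space, parameterised by the true
# half-maximal concentration (not the inflection xmid).  conc = 0 gives top.
logistic5 <- function(conc, bottom, top, ic50, hill, asymmetry = 1) {
  xmid <- ic50 / (2^(1 / asymmetry) - 1)^(1 / hill)
  frac <- ifelse(conc == 0, 0, exp(hill * (log(conc) - log(xmid))))
  bottom + (top - bottom) / (1 + frac)^asymmetry
}

#' Simulate a bidirectional Caco-2 transwell plate
#'
#' Generates end-point receiver amounts for apical-to-basolateral (A-B) and
#' basolateral-to-apical (B-A) transport with a known true apparent
#' permeability, a stated mass-balance loss fraction, and a lucifer-yellow
#' paracellular marker (100 umol/L in every donor) for integrity gating.
#' Receiver amount follows `Q = Papp * A * C0 * t` (units harmonised to
#' pmol with C0 in umol/L and t in seconds); the end-of-assay donor amount
#' is the initial donor amount minus receiver transfer minus the stated
#' loss.  Noise is multiplicative lognormal on measured amounts.
#'
#' @param truth A [transwell_truth()] object.
#' @param metformin_concs Donor concentrations, umol/L.
#' @param directions Subset of `c("AB", "BA")`.
#' @param replicates Wells per (concentration, direction).
#' @param inhibitor Optional inhibitor label for the plate.
#' @param matrix Assay matrix label, `"buffer"` or `"fassif_hsa"`.
#' @param ly_donor_conc Lucifer-yellow donor concentration, umol/L.
#' @param seed Integer seed.
#' @return A tibble with one row per well: geometry, `c0`,
#'   `receiver_amount` and `donor_amount_end` (pmol), and
#'   `ly_receiver_amount` (pmol-equivalent fluorescence).
#' @examples
#' tw <- transwell_truth(papp_true = 0.5e-6, noise_cv = 0)
#' sim_transwell_plate(tw, metformin_concs = 10000)
#' @export
sim_transwell_plate <- function(truth, metformin_concs = c(10, 100, 1000, 10000),
                                directions = c("AB", "BA"), replicates = 3,
                                inhibitor = NA_character_, matrix = "buffer",
                                ly_donor_conc = 100, seed = NULL) {
  stopifnot(inherits(truth, "transwell_truth"))
  if (any(metformin_concs <= 0)) abort("Donor concentrations must be positive.")
  directions <- match.arg(directions, c("AB", "BA"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(
    c0 = metformin_concs, direction = directions, rep = seq_len(replicates)
  )
  donor_vol <- ifelse(grid$direction == "AB",
                      truth$donor_volume_ab, truth$donor_volume_ba)
  receiver_vol <- ifelse(grid$direction == "AB",
                         truth$donor_volume_ba, truth$donor_volume_ab)
  n <- nrow(grid)

  # Q [pmol] = Papp [cm/s] * A [cm2] * C0 [pmol/cm3 = 1000 * umol/L] * t [s]
  q <- truth$papp_true * truth$area * grid$c0 * 1000 * truth$duration
  q_ly <- truth$ly_papp_true * truth$area * ly_donor_conc * 1000 * truth$duration
  initial <- grid$c0 * donor_vol # umol/L * uL = pmol
  receiver <- q * ln_noise(n, truth$noise_cv)
  donor_end <- pmax(initial * (1 - truth$loss_fraction) - q, 0) *
    ln_noise(n, truth$noise_cv)

  tibble(
    well_id = sprintf("tw_%s_w%03d", grid$direction, seq_len(n)),
    direction = grid$direction,
    c0 = grid$c0,
    donor_volume = donor_vol,
    receiver_volume = receiver_vol,
    area = truth$area,
    duration = truth$duration,
    receiver_amount = receiver,
    donor_amount_end = donor_end,
    ly_donor_conc = ly_donor_conc,
    ly_receiver_amount = q_ly * ln_noise(n, truth$noise_cv),
    inhibitor = inhibitor,
    matrix = matrix
  )
}
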