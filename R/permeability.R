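#' Apparent permeability from an end-point transwell measurement
#'
#' `Papp = (dQ/dt) / (A * C0)` with the flux taken from the single
#' end-point receiver amount: `Papp = Q / (t * A * C0)`.  Units are
#' harmonised to cm/s with `Q` in pmol, `t` in seconds, `A` in cm^2 and
#' `C0` in umol/L (1 umol/L = 1000 pmol/cm^3).
#'
#' @param receiver_amount Amount in the receiver compartment at the end of
#'   the incubation, pmol (whole compartment; see [aliquot_to_compartment()]
#'   if only an aliquot was sampled).
#' @param duration Incubation time, seconds.
#' @param area Membrane surface area, cm^2.
#' @param c0 Donor concentration at t = 0, umol/L.
#' @param receiver_volume Optional receiver volume (uL) used to check sink
#'   conditions: a warning is raised if the receiver concentration exceeds
#'   `sink_threshold` of the donor concentration.
#' @param sink_threshold Receiver/donor concentration ratio above which the
#'   end-point flux approximation degrades.
#' @return Apparent permeability, cm/s.
#' @examples
#' apparent_permeability(3240, duration = 5400, area = 0.12, c0 = 10000)
#' # 5e-07 cm/s
#' @export
apparent_permeability <- function(receiver_amount, duration, area, c0,
                                  receiver_volume = NULL,
                                  sink_threshold = 0.1) {
  if (any(duration <= 0) || any(area <= 0) || any(c0 <= 0))
    abort("`duration`, `area` and `c0` must be positive.")
  if (any(receiver_amount < 0)) abort("`receiver_amount` must be >= 0.")
  if (!is.null(receiver_volume)) {
    receiver_conc <- receiver_amount / receiver_volume # pmol/uL = umol/L
    if (any(receiver_conc > sink_threshold * c0))
      warn("Receiver concentration exceeds the sink-condition threshold; end-point Papp may underestimate the true permeability.")
  }
  receiver_amount / (duration * area * c0 * 1000)
}

#' @rdname apparent_permeability
#' @param aliquot_amount Amount measured in the sampled aliquot, pmol.
#' @param aliquot_volume,compartment_volume Sampled and total receiver
#'   volumes, uL.
#' @export
aliquot_to_compartment <- function(aliquot_amount, aliquot_volume,
                                   compartment_volume) {
  stopifnot(all(aliquot_volume > 0), all(compartment_volume >= aliquot_volume))
  aliquot_amount * compartment_volume / aliquot_volume
}

#' Mass balance (percent recovery) of a transwell well
#'
#' @param receiver_amount,donor_amount_end End-of-assay amounts, pmol;
#'   `donor_amount_end = NA` yields `NA` recovery.
#' @param initial_donor_amount Donor amount at t = 0, pmol.
#' @return Percent recovery.
#' @examples
#' mass_balance(100, 900, 1000) # 100
#' @export
mass_balance <- function(receiver_amount, donor_amount_end,
                         initial_donor_amount) {
  if (any(initial_donor_amount <= 0))
    abort("`initial_donor_amount` must be positive.")
  100 * (receiver_amount + donor_amount_end) / initial_donor_amount
}

#' Monolayer integrity gate on lucifer-yellow permeability
#'
#' A well is acceptable when the paracellular marker's Papp does not exceed
#' the threshold (boundary inclusive): `ly_papp <= 1.0e-6` cm/s by default.
#'
#' @param ly_papp Lucifer-yellow apparent permeability, cm/s.
#' @param threshold Acceptance threshold, cm/s.
#' @return Logical pass/fail per well.
#' @export
integrity_gate <- function(ly_papp, threshold = 1.0e-6) {
  if (any(ly_papp < 0)) abort("`ly_papp` must be >= 0.")
  ly_papp <= threshold
}

#' Efflux ratio of bidirectional permeabilities
#'
#' @param papp_ba,papp_ab Mean B-A and A-B apparent permeabilities, cm/s.
#' @return `papp_ba / papp_ab`.
#' @export
efflux_ratio <- function(papp_ba, papp_ab) {
  if (any(papp_ab <= 0))
    abort("A-B Papp must be positive for an efflux ratio.")
  papp_ba / papp_ab
}

#' Per-well and per-condition processing of a transwell plate
#'
#' `process_transwell()` computes, for each well, the metformin and
#' lucifer-yellow apparent permeabilities, the mass balance and the
#' integrity verdict.  `permeability_summary()` then aggregates
#' integrity-passing wells per condition (direction, donor concentration,
#' inhibitor, matrix) into mean Papp (reported on the conventional 1e-6
#' cm/s scale), SD, n, mean mass balance, and the efflux ratio where both
#' directions are present.
#'
#' @param records Transwell well table (see [sim_transwell_plate()] for
#'   the column contract).
#' @param ly_threshold Integrity threshold for lucifer-yellow Papp, cm/s.
#' @param sink_threshold Passed to [apparent_permeability()].
#' @return For `process_transwell()`, the input with `papp`, `ly_papp`,
#'   `mass_balance_pct` and `integrity_pass` appended; for
#'   `permeability_summary()`, one row per condition x direction with
#'   `papp_mean_1e6`, `papp_sd_1e6`, `n_wells`, `mass_balance_pct` and
#'   `efflux_ratio`.
#' @examples
#' tw <- transwell_truth(noise_cv = 0)
#' sim_transwell_plate(tw, metformin_concs = 10000) |>
#'   process_transwell() |>
#'   permeability_summary()
#' @export
process_transwell <- function(records, ly_threshold = 1.0e-6,
                              sink_threshold = 0.1) {
  rec <- as_tibble(records)
  need <- c("direction", "c0", "donor_volume", "area", "duration",
            "receiver_amount", "ly_receiver_amount")
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0)
    abort(paste0("`records` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (!"ly_donor_conc" %in% names(rec)) rec$ly_donor_conc <- 100
  if (!"donor_amount_end" %in% names(rec)) rec$donor_amount_end <- NA_real_

  rec |>
    mutate(
      papp = apparent_permeability(
        .data$receiver_amount, .data$duration, .data$area, .data$c0,
        receiver_volume = if ("receiver_volume" %in% names(rec))
          .data$receiver_volume else NULL,
        sink_threshold = sink_threshold
      ),
      ly_papp = apparent_permeability(
        .data$ly_receiver_amount, .data$duration, .data$area,
        .data$ly_donor_conc
      ),
      mass_balance_pct = dplyr::if_else(
        is.na(.data$donor_amount_end), NA_real_,
        mass_balance(.data$receiver_amount, .data$donor_amount_end,
                     .data$c0 * .data$donor_volume)
      ),
      integrity_pass = integrity_gate(.data$ly_papp, ly_threshold)
    )
}

#' @rdname process_transwell
#' @param processed Output of `process_transwell()`.
#' @export
permeability_summary <- function(processed) {
  ok <- processed |> filter(.data$integrity_pass)
  if (nrow(ok) == 0)
    abort("All wells failed the integrity gate; nothing to summarise.")

  keys <- intersect(c("c0", "inhibitor", "matrix"), names(ok))
  summ <- ok |>
    group_by(across(dplyr::all_of(c(keys, "direction")))) |>
    summarise(
      papp_mean_1e6 = mean(.data$papp) * 1e6,
      papp_sd_1e6 = if (n() > 1) sd(.data$papp) * 1e6 else NA_real_,
      n_wells = n(),
      mass_balance_pct = mean(.data$mass_balance_pct),
      .groups = "drop"
    )

  # efflux ratio only where both directions exist for a condition
  wide <- summ |>
    select(dplyr::all_of(keys), "direction", "papp_mean_1e6") |>
    tidyr::pivot_wider(names_from = "direction", values_from = "papp_mean_1e6")
  if (all(c("AB", "BA") %in% names(wide))) {
    wide <- wide |>
      mutate(efflux_ratio = efflux_ratio(.data$BA, .data$AB)) |>
      select(dplyr::all_of(keys), "efflux_ratio")
    summ <- left_join(summ, wide, by = keys)
  } else {
    summ$efflux_ratio <- NA_real_
  }
  summ
}

#' Test for an inhibitor effect on apparent permeability
#'
#' Compares per-well Papp values with and without inhibitor by a Welch
#' two-sample t-test on the log scale, reporting the geometric fold-change
#' with its confidence interval.  The verdict is `"no_change"` when the
#' interval lies entirely inside the equivalence band (default 0.8-1.25,
#' the conventional bioequivalence bound), `"change"` when it excludes 1,
#' and `"inconclusive"` otherwise.
#'
#' @param papp_with,papp_without Numeric vectors of per-well Papp values
#'   (integrity-passing wells only), cm/s; at least 3 wells per arm.
#' @param equivalence Lower and upper fold-change equivalence bounds.
#' @param conf Confidence level of the fold-change interval.
#' @return One-row tibble: `fold_change`, `conf_low`, `conf_high`,
#'   `p_value`, `verdict`.
#' @export
inhibitor_effect_test <- function(papp_with, papp_without,
                                  equivalence = c(0.8, 1.25), conf = 0.90) {
  if (length(papp_with) < 3 || length(papp_without) < 3)
    abort("Need at least 3 wells per arm.")
  if (any(c(papp_with, papp_without) <= 0))
    abort("Papp values must be positive for the log-scale comparison.")

  lw <- log(papp_with); lo <- log(papp_without)
  if (sd(lw) == 0 && sd(lo) == 0) {
    fc <- exp(mean(lw) - mean(lo))
    return(tibble(fold_change = fc, conf_low = fc, conf_high = fc,
                  p_value = if (fc == 1) 1 else 0,
                  verdict = if (fc >= equivalence[1] && fc <= equivalence[2])
                    "no_change" else "change"))
  }
  tt <- t.test(lw, lo, conf.level = conf)
  ci <- exp(tt$conf.int)
  fc <- exp(mean(lw) - mean(lo))
  verdict <- if (ci[1] >= equivalence[1] && ci[2] <= equivalence[2]) {
    "no_change"
  } else if (ci[1] > 1 || ci[2] < 1) {
    "change"
  } else {
    "inconclusive"
  }
  tibble(fold_change = fc, conf_low = ci[1], conf_high = ci[2],
         p_value = tt$p.value, verdict = verdict)
}
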