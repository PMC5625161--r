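#' Specific activity of the radiolabelled probe
#'
#' Converts a stated radioactive concentration and chemical concentration of
#' the dosing solution into dpm per pmol of probe.  The default corresponds
#' to a 14C probe dosed at 37 kBq/mL and 100 umol/L: 37,000 Bq/mL x 60
#' dpm/Bq / 100,000 pmol/mL = 22.2 dpm/pmol.
#'
#' @param kbq_per_ml Radioactive concentration of the dosing solution.
#' @param conc_umol_l Chemical concentration of the dosing solution.
#' @return Specific activity in dpm/pmol.
#' @examples
#' specific_activity() # 22.2
#' @export
specific_activity <- function(kbq_per_ml = 37, conc_umol_l = 100) {
  stopifnot(kbq_per_ml > 0, conc_umol_l > 0)
  kbq_per_ml * 1000 * 60 / (conc_umol_l * 1000)
}

#' Convert scintillation counts to probe amount
#'
#' Divides well dpm by the probe specific activity and scales the counted
#' lysate aliquot back to the whole lysate (e.g. 300 of 400 uL counted gives
#' `lysate_fraction_counted = 0.75`).
#'
#' @param dpm Counts, disintegrations per minute.
#' @param sa Specific activity, dpm/pmol.
#' @param lysate_fraction_counted Fraction of the lysate counted, in (0, 1].
#' @return Amount in pmol.
#' @examples
#' dpm_to_pmol(22200, sa = 22.2) # 1333.3 pmol (default 0.75 aliquot)
#' @export
dpm_to_pmol <- function(dpm, sa = specific_activity(),
                        lysate_fraction_counted = 300 / 400) {
  if (any(sa <= 0)) abort("`sa` must be positive.")
  if (any(lysate_fraction_counted <= 0 | lysate_fraction_counted > 1))
    abort("`lysate_fraction_counted` must be in (0, 1].")
  if (any(dpm < 0)) abort("`dpm` must be non-negative.")
  dpm / sa / lysate_fraction_counted
}

#' Per-well uptake activities and rates
#'
#' Converts a raw well table (one row per well, as produced by the
#' simulators or read from CSV) into probe amount (pmol), uptake activity
#' normalised to well protein (pmol/mg), and uptake rate additionally
#' normalised to incubation time (pmol/min/mg).
#'
#' @param wells Well table with columns `dpm`, `protein`, `time` and
#'   (optionally) `lysate_fraction_counted`.
#' @param sa Specific activity, dpm/pmol.
#' @param correct_aliquot If `FALSE`, the counted-aliquot fraction is
#'   ignored (treated as 1); whether raw data were already aliquot-corrected
#'   varies between laboratories, so this is a switch rather than a fact.
#' @return The input tibble with `pmol`, `pmol_per_mg` and
#'   `pmol_per_min_per_mg` columns appended.
#' @export
well_activities <- function(wells, sa = specific_activity(),
                            correct_aliquot = TRUE) {
  wells <- as_tibble(wells)
  need <- c("dpm", "protein", "time")
  missing <- setdiff(need, names(wells))
  if (length(missing) > 0)
    abort(paste0("`wells` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (any(wells$protein <= 0)) abort("`protein` must be positive.")
  if (any(wells$time <= 0)) abort("`time` must be positive.")
  frac <- if (correct_aliquot && "lysate_fraction_counted" %in% names(wells))
    wells$lysate_fraction_counted else 1
  wells |>
    mutate(
      pmol = dpm_to_pmol(.data$dpm, sa = sa, lysate_fraction_counted = frac),
      pmol_per_mg = .data$pmol / .data$protein,
      pmol_per_min_per_mg = .data$pmol_per_mg / .data$time
    )
}

#' Vector-control correction of a single condition
#'
#' Transporter-mediated activity is the activity in transporter-expressing
#' cells minus that in matched vector-control (mock-transfected) cells.
#' Negative corrected values are returned as-is (clamping would bias the
#' bottom plateau of inhibition curves); the table-level
#' [corrected_activities()] flags them.
#'
#' @param transporter_mean,control_mean Mean uptake activity (pmol/mg) in
#'   transporter and vector-control cells for the same condition.
#' @return Corrected activity, same units.
#' @export
control_correct <- function(transporter_mean, control_mean) {
  transporter_mean - control_mean
}

#' @rdname control_correct
#' @details `uptake_ratio()` is the transporter / control activity ratio,
#'   the standard QC statistic for transfected-cell assays (a functional
#'   plate needs a ratio well above 1).
#' @export
uptake_ratio <- function(transporter_mean, control_mean) {
  if (any(control_mean <= 0))
    abort("`control_mean` must be positive for an uptake ratio.")
  transporter_mean / control_mean
}

#' Condition-level corrected activities
#'
#' Aggregates replicate wells (mean and SD per condition and cell line),
#' pairs transporter wells with matched vector-control wells, and returns
#' the control-corrected activity, the corrected rate, the uptake ratio and
#' a flag for conditions where the correction went negative.  Replicate SDs
#' of the two cell lines are propagated in quadrature.
#'
#' @param wells A well table (see [well_activities()] for required columns,
#'   plus `cell_line` and the condition keys `transporter`, `probe_conc`,
#'   `inhibitor`, `inhibitor_conc`, `time`, `occasion`).
#' @inheritParams well_activities
#' @return A tibble with one row per condition: replicate means/SDs per
#'   cell line, `corrected` (pmol/mg), `corrected_rate` (pmol/min/mg),
#'   `corrected_sd`, `uptake_ratio` and `negative_corrected`.
#' @examples
#' truth <- assay_truth(noise_cv = 0, protein_cv = 0)
#' wells <- sim_kinetic_plate(truth, concs = c(10, 100, 1000), time = 5)
#' corrected_activities(wells)
#' @export
corrected_activities <- function(wells, sa = specific_activity(),
                                 correct_aliquot = TRUE) {
  keys <- intersect(
    c("transporter", "probe_conc", "inhibitor", "inhibitor_conc", "time",
      "occasion"),
    names(wells)
  )
  if (!"cell_line" %in% names(wells)) abort("`wells` needs a `cell_line` column.")

  summ <- well_activities(wells, sa = sa, correct_aliquot = correct_aliquot) |>
    group_by(across(dplyr::all_of(c(keys, "cell_line")))) |>
    summarise(
      mean_activity = mean(.data$pmol_per_mg),
      sd_activity = if (n() > 1) sd(.data$pmol_per_mg) else NA_real_,
      n_wells = n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "cell_line",
      values_from = c("mean_activity", "sd_activity", "n_wells")
    )

  for (col in c("mean_activity_vector_control", "sd_activity_vector_control",
                "n_wells_vector_control")) {
    if (!col %in% names(summ)) summ[[col]] <- NA_real_
  }
  if (!"mean_activity_transporter" %in% names(summ))
    abort("No transporter-cell wells found.")

  summ |>
    mutate(
      corrected = control_correct(
        .data$mean_activity_transporter,
        dplyr::coalesce(.data$mean_activity_vector_control, 0)
      ),
      corrected_sd = sqrt(
        dplyr::coalesce(.data$sd_activity_transporter, 0)^2 +
          dplyr::coalesce(.data$sd_activity_vector_control, 0)^2
      ),
      corrected_rate = .data$corrected / .data$time,
      uptake_ratio = dplyr::if_else(
        !is.na(.data$mean_activity_vector_control) &
          .data$mean_activity_vector_control > 0,
        .data$mean_activity_transporter / .data$mean_activity_vector_control,
        NA_real_
      ),
      negative_corrected = .data$corrected < 0
    )
}

#' Assess time-linearity of a corrected uptake timecourse
#'
#' Uptake assays must be run inside the window where cumulative uptake is
#' still linear in time.  Starting from the earliest time point, this fits a
#' through-origin straight line to corrected activity versus time over
#' successively shorter prefixes and returns the longest prefix (at least 3
#' points) for which the uncentered R-squared meets `r2_threshold` and every
#' point lies within `max_rel_dev` relative deviation of the fitted line.
#' The chosen assay time is the last time inside the window (maximum signal
#' at maintained linearity).
#'
#' @param timecourse A tibble with columns `time` and `corrected`
#'   (pmol/mg), one row per time point, optionally `uptake_ratio`.
#' @param r2_threshold Minimum uncentered R-squared for acceptance.
#' @param max_rel_dev Maximum per-point relative deviation from the line.
#' @return One-row tibble: `t_min`, `t_max`, `chosen_time`, `r_squared`,
#'   `slope` (pmol/min/mg), `uptake_ratio_at_chosen_time` (NA if no ratio
#'   column supplied).
#' @export
assess_linearity <- function(timecourse, r2_threshold = 0.95,
                             max_rel_dev = 0.15) {
  tc <- as_tibble(timecourse) |> arrange(.data$time)
  if (nrow(tc) < 3)
    abort("Linearity assessment needs at least 3 time points.")
  if (all(tc$corrected == 0))
    abort("All corrected activities are zero; linearity is undefined.")

  window <- NULL
  for (k in rev(seq(3, nrow(tc)))) {
    t <- tc$time[1:k]
    y <- tc$corrected[1:k]
    slope <- sum(t * y) / sum(t^2)
    if (slope <= 0) next
    fitted <- slope * t
    r2 <- 1 - sum((y - fitted)^2) / sum(y^2)
    if (r2 >= r2_threshold && all(abs(y - fitted) / fitted <= max_rel_dev)) {
      window <- list(k = k, slope = slope, r2 = r2)
      break
    }
  }
  if (is.null(window))
    abort("No through-origin linear window found at the given thresholds.")

  chosen <- tc$time[window$k]
  tibble(
    t_min = tc$time[1],
    t_max = chosen,
    chosen_time = chosen,
    r_squared = window$r2,
    slope = window$slope,
    uptake_ratio_at_chosen_time =
      if ("uptake_ratio" %in% names(tc)) tc$uptake_ratio[window$k] else NA_real_
  )
}
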