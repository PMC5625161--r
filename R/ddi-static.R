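#' Fraction of clearance excreted via inhibitable renal transport
#'
#' The static model's `fe` is the fraction of total victim-drug clearance
#' that proceeds through the inhibitable (active renal secretory) pathway:
#' the renal fraction of total clearance times the active (non-filtration)
#' fraction of renal clearance.  For metformin the renal fraction is 0.88
#' from intravenous mass balance but only 0.52 from oral urinary recovery -
#' a consequence of flip-flop kinetics, where absorption continues in
#' parallel with elimination - giving `fe` of 0.66 and 0.39 respectively
#' with an active fraction of 0.75.
#'
#' @param renal_fraction Fraction of total plasma clearance that is renal,
#'   in \[0, 1\].
#' @param active_fraction Fraction of renal clearance due to active
#'   transport (the remainder being passive filtration), in \[0, 1\].
#' @return `renal_fraction * active_fraction`, reported at 2 decimal
#'   places.
#' @examples
#' derive_fe(0.88, 0.75) # 0.66 (intravenous)
#' derive_fe(0.52, 0.75) # 0.39 (oral)
#' @export
derive_fe <- function(renal_fraction, active_fraction) {
  if (any(renal_fraction < 0 | renal_fraction > 1) ||
      any(active_fraction < 0 | active_fraction > 1))
    abort("Both fractions must lie in [0, 1].")
  round(renal_fraction * active_fraction, 2)
}

#' Unbound maximal plasma concentration
#'
#' The systemic inhibitor concentration `[I]` of the static model is the
#' clinically measured total Cmax multiplied by the plasma fraction
#' unbound.
#'
#' @param cmax_total Total (bound + unbound) Cmax, umol/L.
#' @param fu Fraction unbound in plasma, in (0, 1].
#' @return Unbound Cmax, umol/L.
#' @examples
#' cmax_free(9.6, 0.80) # 7.68
#' @export
cmax_free <- function(cmax_total, fu) {
  if (any(cmax_total < 0)) abort("`cmax_total` must be >= 0.")
  if (any(fu <= 0 | fu > 1)) abort("`fu` must be in (0, 1].")
  cmax_total * fu
}

#' Theoretical intestinal luminal inhibitor concentration
#'
#' `[I2]` is the oral dose dissolved in a nominal 250 mL of intestinal
#' fluid, the standard regulatory worst case for luminal exposure of
#' intestinal transporters.
#'
#' @param dose_mg Oral dose, mg.
#' @param mw Molecular weight, g/mol.
#' @param volume_ml Nominal dissolution volume, mL (default 250).
#' @return Concentration in umol/L (full precision; conventionally rounded
#'   to the nearest integer for reporting).
#' @examples
#' round(i2_gut(400, 252.34)) # 6341
#' @export
i2_gut <- function(dose_mg, mw, volume_ml = 250) {
  if (any(mw <= 0)) abort("`mw` must be positive.")
  if (any(dose_mg < 0) || any(volume_ml <= 0))
    abort("`dose_mg` must be >= 0 and `volume_ml` positive.")
  (dose_mg / 1000 / mw) / (volume_ml / 1000) * 1e6
}

#' Exposure-ratio screen against a regulatory cut-off
#'
#' Computes `[I] / Ki` and flags whether it reaches the cut-off that
#' triggers DDI concern in the basic static framework: 0.1 for systemic
#' (unbound Cmax) exposure, 10 for intestinal luminal (`[I2]`) exposure.
#'
#' @param i Inhibitor concentration, umol/L.
#' @param ki Inhibition constant, umol/L.
#' @param cutoff Decision threshold on the ratio.
#' @return A tibble with `ratio` and `flag` (`ratio >= cutoff`).
#' @examples
#' ratio_screen(6341, 275, cutoff = 10)   # gut: ratio 23, flagged
#' ratio_screen(7.68, 207, cutoff = 0.1)  # systemic OCT2: 0.037, clear
#' @export
ratio_screen <- function(i, ki, cutoff = 0.1) {
  if (any(ki <= 0)) abort("`ki` must be positive.")
  if (any(i < 0)) abort("`i` must be >= 0.")
  tibble(ratio = i / ki, flag = i / ki >= cutoff)
}

#' Mechanistic static prediction of victim-drug AUC fold-change
#'
#' The adapted Rowland-Matin static model: if a fraction `fe` of victim
#' clearance runs through the inhibited pathway and the inhibitor reduces
#' that pathway by `1 / (1 + I/Ki)`, then
#'
#' \deqn{Fold\Delta AUC = \frac{1}{\frac{fe}{1 + I/K_i} + (1 - fe)}}
#'
#' The prediction is bounded: 1 at `I = 0` and `1 / (1 - fe)` as
#' `I` grows without limit (complete pathway inhibition).
#'
#' @param fe Fraction of victim clearance via the inhibited pathway, in
#'   \[0, 1\].
#' @param i Inhibitor concentration at the site of interaction, umol/L
#'   (unbound Cmax for renal basolateral/apical transporters).
#' @param ki Inhibition constant, umol/L.
#' @return Predicted fold-change in AUC (full precision; report at 2
#'   decimal places).
#' @examples
#' fold_auc(0.66, 7.68, 1.22) # 2.32 after rounding
#' @export
fold_auc <- function(fe, i, ki) {
  if (any(fe < 0 | fe > 1)) abort("`fe` must be in [0, 1].")
  if (any(ki <= 0)) abort("`ki` must be positive.")
  if (any(i < 0)) abort("`i` must be >= 0.")
  1 / (fe / (1 + i / ki) + (1 - fe))
}

#' Static DDI predictions for a perpetrator panel
#'
#' Builds the full cross-product of perpetrator clinical scenarios x
#' transporters x fe scenarios and evaluates the systemic ratio screen and
#' the static fold-AUC model for each row.  A perpetrator lacking a Ki for
#' a requested transporter yields a row with an `error` note rather than
#' failing the whole grid.
#'
#' @param perpetrators Tibble with one row per perpetrator x clinical
#'   Cmax: columns `perpetrator`, `study`, `dose_mg`, `mw`, `fu`,
#'   `cmax_total` (umol/L).
#' @param ki_table Tibble with columns `inhibitor`, `transporter`, `ki`
#'   (umol/L), e.g. Ki values from [aggregate_occasions()].
#' @param transporters Transporters to predict for (default the renal
#'   pair, OCT2 and MATE1).
#' @param fe Numeric vector of fe scenarios.
#' @param systemic_cutoff Ratio cut-off for the systemic flag.
#' @return A tibble with one row per scenario: `i_unbound`,
#'   `ratio_systemic`, `flag_systemic`, `fold_auc` (full precision) and
#'   `error`.
#' @examples
#' inputs <- metformin_ddi_inputs()
#' predict_ddi(inputs$perpetrators, inputs$ki, fe = c(0.66, 0.39))
#' @export
predict_ddi <- function(perpetrators, ki_table,
                        transporters = c("OCT2", "MATE1"),
                        fe = c(0.66, 0.39), systemic_cutoff = 0.1) {
  stopifnot(all(c("perpetrator", "fu", "cmax_total") %in% names(perpetrators)))
  stopifnot(all(c("inhibitor", "transporter", "ki") %in% names(ki_table)))

  grid <- tidyr::expand_grid(
    perpetrators,
    transporter = transporters,
    fe_used = fe
  ) |>
    left_join(
      ki_table |> select("inhibitor", "transporter", "ki"),
      by = c(perpetrator = "inhibitor", "transporter")
    )

  grid |>
    mutate(
      i_unbound = cmax_free(.data$cmax_total, .data$fu),
      ratio_systemic = dplyr::if_else(is.na(.data$ki), NA_real_,
                                      .data$i_unbound / .data$ki),
      flag_systemic = .data$ratio_systemic >= systemic_cutoff,
      fold_auc = dplyr::if_else(
        is.na(.data$ki), NA_real_,
        fold_auc(.data$fe_used, .data$i_unbound,
                 dplyr::coalesce(.data$ki, 1))
      ),
      error = dplyr::if_else(
        is.na(.data$ki),
        paste0("no Ki for ", .data$perpetrator, " on ", .data$transporter),
        NA_character_
      )
    )
}

#' Score static predictions against observed clinical AUC changes
#'
#' Pairs each prediction with the clinical observation from the matching
#' interaction study (by perpetrator and study label) and reports the
#' concordance metric: the absolute difference in percent AUC increase,
#' `|100 (predicted - 1) - 100 (observed - 1)|` percentage points.  An
#' alternative relative metric (`|predicted - observed| / observed`) is
#' available behind `metric`.
#'
#' @param predictions Output of [predict_ddi()].
#' @param observed Tibble with `perpetrator`, `study`,
#'   `observed_fold_auc`.
#' @param metric `"percent_increase_diff"` (percentage points, default) or
#'   `"relative_fold_error"` (percent of observed fold-change).
#' @return The prediction rows joined to observations with a `delta`
#'   column; predictions without a matching observation carry `unmatched =
#'   TRUE` and `delta = NA`.
#' @seealso [concordance_range()] for the per-scenario min-max summary.
#' @export
compare_to_observed <- function(predictions, observed,
                                metric = c("percent_increase_diff",
                                           "relative_fold_error")) {
  metric <- match.arg(metric)
  stopifnot(all(c("perpetrator", "study", "observed_fold_auc")
                %in% names(observed)))
  out <- predictions |>
    left_join(observed, by = c("perpetrator", "study")) |>
    mutate(
      unmatched = is.na(.data$observed_fold_auc),
      delta = dplyr::case_when(
        .data$unmatched | is.na(.data$fold_auc) ~ NA_real_,
        metric == "percent_increase_diff" ~
          abs(100 * (.data$fold_auc - 1) - 100 * (.data$observed_fold_auc - 1)),
        TRUE ~
          100 * abs(.data$fold_auc - .data$observed_fold_auc) /
            .data$observed_fold_auc
      )
    )
  attr(out, "metric") <- metric
  out
}

#' @rdname compare_to_observed
#' @param comparison Output of `compare_to_observed()`.
#' @return For `concordance_range()`, one row per (transporter, fe
#'   scenario) with the minimum and maximum `delta` over matched pairs.
#' @export
concordance_range <- function(comparison) {
  comparison |>
    filter(!.data$unmatched, !is.na(.data$delta)) |>
    group_by(.data$transporter, .data$fe_used) |>
    summarise(
      n_pairs = n(),
      delta_min = min(.data$delta),
      delta_max = max(.data$delta),
      .groups = "drop"
    )
}

#' Bundled clinical and in vitro inputs for the metformin DDI case study
#'
#' Returns the input tables for the worked example shipped with the
#' package: the perpetrator panel (cimetidine, trimethoprim,
#' pyrimethamine) with doses, molecular weights, plasma fraction unbound,
#' clinical total Cmax values and supplied enterocyte concentrations; the
#' transporter inhibition constants (IC50, equal to Ki under the low-probe
#' condition); the observed clinical metformin AUC fold-increases; and the
#' victim disposition fractions from which `fe` is derived.
#'
#' @return A list of tibbles: `perpetrators`, `ki`, `observed`,
#'   `disposition`.
#' @examples
#' metformin_ddi_inputs()$perpetrators
#' @export
metformin_ddi_inputs <- function() {
  path <- function(f) system.file("extdata", f, package = "transportddi",
                                  mustWork = TRUE)
  read <- function(f) readr::read_csv(path(f), show_col_types = FALSE)
  list(
    perpetrators = read("perpetrators.csv"),
    ki = read("transporter_ki.csv"),
    observed = read("observed_auc.csv"),
    disposition = read("victim_disposition.csv")
  )
}
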