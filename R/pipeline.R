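#' Pipeline configuration
#'
#' Bundles the stage toggles, simulation truths, assay design and static-
#' model settings for [run_ddi_pipeline()].  Defaults describe the packaged
#' case study: an OCT2 kinetic plate, a cimetidine-on-MATE1 inhibition
#' assay over three occasions, a bidirectional Caco-2 plate, and static
#' predictions from the bundled clinical inputs under the intravenous and
#' oral fe scenarios.
#'
#' @param out_dir Directory for per-stage artifacts (created if absent).
#' @param seed Integer seed governing all simulation stages.
#' @param stages Stages to run, a subset of `"simulate"`, `"process"`,
#'   `"fit"`, `"predict"`, `"compare"`, `"report"`.  Later stages read the
#'   CSV artifacts of earlier ones from `out_dir`, so any stage can run
#'   alone against prior artifacts.
#' @param assay,inhibition,transwell Truth objects for the simulate stage.
#' @param kinetic_concs,inhibitor_concs,probe_conc,kinetic_time,
#'   inhibition_time Assay design for the simulated plates (umol/L,
#'   minutes).
#' @param inhibitor Inhibitor label for the simulated inhibition plates.
#' @param fe Fraction-excreted scenarios for the predict stage.
#' @param inputs Clinical/in vitro input tables for predict/compare;
#'   defaults to [metformin_ddi_inputs()].
#' @return A `ddi_pipeline_config` list.
#' @export
ddi_pipeline_config <- function(out_dir, seed = 1L,
                                stages = c("simulate", "process", "fit",
                                           "predict", "compare", "report"),
                                assay = assay_truth("OCT2", km_true = 1608,
                                                    vmax_true = 32918,
                                                    control_fraction = 1 / 17),
                                inhibition = inhibition_truth(
                                  ic50_true = 1.22, occasions = 3,
                                  occasion_cv = 0.05),
                                transwell = transwell_truth(),
                                kinetic_concs = c(1, 10, 100, 300, 1000,
                                                  3000, 10000),
                                inhibitor_concs = c(0.1, 0.3, 1, 3, 10, 30,
                                                    100),
                                probe_conc = 100,
                                kinetic_time = 5, inhibition_time = 5,
                                inhibitor = "cimetidine",
                                fe = c(0.66, 0.39), inputs = NULL) {
  if (missing(out_dir)) abort("`out_dir` is required.")
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(inherits(assay, "assay_truth"),
            inherits(inhibition, "inhibition_truth"),
            inherits(transwell, "transwell_truth"),
            all(fe >= 0 & fe <= 1))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         assay = assay, inhibition = inhibition, transwell = transwell,
         kinetic_concs = kinetic_concs, inhibitor_concs = inhibitor_concs,
         probe_conc = probe_conc, kinetic_time = kinetic_time,
         inhibition_time = inhibition_time, inhibitor = inhibitor,
         fe = fe, inputs = inputs),
    class = "ddi_pipeline_config"
  )
}

#' Run the end-to-end DDI assessment pipeline
#'
#' Executes the enabled stages in order - simulate plates, process wells
#' into corrected activities, fit kinetics and inhibition curves, run the
#' static AUC predictions, compare against observed clinical changes, and
#' write a Markdown report - leaving one CSV artifact per stage in
#' `config$out_dir`.  Re-running with the same configuration and seed
#' reproduces identical artifacts.
#'
#' @param config A [ddi_pipeline_config()].
#' @return Invisibly, a named list of the stage results (tibbles/fits) and
#'   `paths` of written artifacts.
#' @export
run_ddi_pipeline <- function(config) {
  if (!inherits(config, "ddi_pipeline_config"))
    abort("`config` must be created by ddi_pipeline_config().")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  res <- list(paths = character())
  keep <- function(p) res$paths <<- c(res$paths, p)

  if ("simulate" %in% config$stages) {
    set.seed(config$seed)
    kinetic <- sim_kinetic_plate(config$assay, concs = config$kinetic_concs,
                                 time = config$kinetic_time)
    inhib <- sim_inhibition_plate(config$assay, config$inhibition,
                                  config$inhibitor_concs,
                                  probe_conc = config$probe_conc,
                                  time = config$inhibition_time,
                                  inhibitor = config$inhibitor)
    transwell <- sim_transwell_plate(config$transwell)
    readr::write_csv(kinetic, art("wells_kinetic.csv"))
    readr::write_csv(inhib, art("wells_inhibition.csv"))
    readr::write_csv(transwell, art("wells_transwell.csv"))
    keep(art(c("wells_kinetic.csv", "wells_inhibition.csv",
               "wells_transwell.csv")))
    res$wells <- list(kinetic = kinetic, inhibition = inhib,
                      transwell = transwell)
  }

  if ("process" %in% config$stages) {
    kinetic <- res$wells$kinetic %||%
      readr::read_csv(art("wells_kinetic.csv"), show_col_types = FALSE)
    inhib <- res$wells$inhibition %||%
      readr::read_csv(art("wells_inhibition.csv"), show_col_types = FALSE)
    tw <- res$wells$transwell %||%
      readr::read_csv(art("wells_transwell.csv"), show_col_types = FALSE)
    v <- bind_rows(validate_wells(kinetic), validate_wells(inhib))
    if (nrow(v) > 0)
      warn(paste0(nrow(v), " well-table validation issue(s); see ",
                  art("validation.csv")))
    readr::write_csv(v, art("validation.csv"))
    res$corrected_kinetic <- corrected_activities(kinetic)
    res$responses <- corrected_activities(inhib) |> inhibition_responses()
    res$permeability <- process_transwell(tw) |> permeability_summary()
    readr::write_csv(res$corrected_kinetic, art("corrected_kinetic.csv"))
    readr::write_csv(res$responses, art("inhibition_responses.csv"))
    readr::write_csv(res$permeability, art("permeability_summary.csv"))
    keep(art(c("validation.csv", "corrected_kinetic.csv",
               "inhibition_responses.csv", "permeability_summary.csv")))
  }

  if ("fit" %in% config$stages) {
    ck <- res$corrected_kinetic %||%
      readr::read_csv(art("corrected_kinetic.csv"), show_col_types = FALSE)
    rs <- res$responses %||%
      readr::read_csv(art("inhibition_responses.csv"), show_col_types = FALSE)
    mm <- fit_michaelis_menten(ck, transporter = config$assay$transporter)
    occ_fits <- rs |>
      dplyr::group_split(.data$occasion) |>
      purrr::map(\(d) fit_logistic(d, inhibitor = config$inhibitor,
                                   transporter = config$assay$transporter))
    agg <- aggregate_occasions(occ_fits, probe_conc = config$probe_conc,
                               km = mm$km)
    res$mm_fit <- mm
    res$ic50 <- agg
    readr::write_csv(tidy(mm), art("kinetic_fit.csv"))
    readr::write_csv(agg |> select(-"per_occasion_ic50"),
                     art("inhibition_fit.csv"))
    jsonlite::write_json(
      list(km = mm$km, km_se = mm$km_se, vmax = mm$vmax,
           vmax_se = mm$vmax_se, converged = mm$converged,
           per_occasion_ic50 = agg$per_occasion_ic50[[1]],
           ic50_mean = agg$ic50_mean, ic50_sd = agg$ic50_sd,
           models = purrr::map_chr(occ_fits, \(f) f$model %||% NA_character_)),
      art("fit_report.json"), auto_unbox = TRUE, digits = NA
    )
    keep(art(c("kinetic_fit.csv", "inhibition_fit.csv", "fit_report.json")))
  }

  inputs <- config$inputs %||% metformin_ddi_inputs()
  if ("predict" %in% config$stages) {
    res$predictions <- predict_ddi(inputs$perpetrators, inputs$ki,
                                   fe = config$fe)
    readr::write_csv(res$predictions, art("predictions.csv"))
    keep(art("predictions.csv"))
  }

  if ("compare" %in% config$stages) {
    preds <- res$predictions %||%
      readr::read_csv(art("predictions.csv"), show_col_types = FALSE)
    res$comparison <- compare_to_observed(preds, inputs$observed)
    res$concordance <- concordance_range(res$comparison)
    readr::write_csv(res$comparison, art("comparison.csv"))
    readr::write_csv(res$concordance, art("concordance.csv"))
    keep(art(c("comparison.csv", "concordance.csv")))
  }

  if ("report" %in% config$stages) {
    p <- art("report.md")
    lines <- c(
      "# Transporter DDI assessment report", "",
      paste0("Seed: ", config$seed), ""
    )
    if (!is.null(res$mm_fit))
      lines <- c(lines, sprintf(
        "Kinetics (%s): Km = %.4g +/- %.3g umol/L, Vmax = %.4g +/- %.3g pmol/min/mg",
        config$assay$transporter, res$mm_fit$km, res$mm_fit$km_se,
        res$mm_fit$vmax, res$mm_fit$vmax_se), "")
    if (!is.null(res$ic50))
      lines <- c(lines, sprintf(
        "Inhibition (%s on %s): IC50 = %.4g +/- %.3g umol/L over %d occasions (Ki = %.4g)",
        config$inhibitor, config$assay$transporter, res$ic50$ic50_mean,
        res$ic50$ic50_sd, res$ic50$n_occasions, res$ic50$ki), "")
    if (!is.null(res$predictions)) {
      lines <- c(lines, "## Predicted AUC fold-changes", "",
                 "perpetrator | study | transporter | fe | fold-AUC",
                 "--- | --- | --- | --- | ---",
                 sprintf("%s | %s | %s | %.2f | %.2f",
                         res$predictions$perpetrator, res$predictions$study,
                         res$predictions$transporter,
                         res$predictions$fe_used,
                         round(res$predictions$fold_auc, 2)), "")
    }
    if (!is.null(res$concordance))
      lines <- c(lines, "## Concordance with observed (percentage points)", "",
                 sprintf("%s, fe %.2f: %.0f-%.0f over %d pairs",
                         res$concordance$transporter,
                         res$concordance$fe_used, res$concordance$delta_min,
                         res$concordance$delta_max, res$concordance$n_pairs))
    writeLines(lines, p)
    keep(p)
  }
  invisible(res)
}

#' Validate a well table against the CSV column contract
#'
#' Schema and row-level checks for raw uptake well tables: required
#' columns present, `cell_line` levels recognised, `dpm` non-negative,
#' `protein` and `time` positive, counted lysate fraction in (0, 1].
#' Report-only: returns the violations rather than failing.
#'
#' @param wells A data frame to check.
#' @return A tibble of violations (`column`, `row`, `message`); zero rows
#'   when the table is valid.
#' @export
validate_wells <- function(wells) {
  v <- list()
  note <- function(column, row, message)
    v[[length(v) + 1]] <<- tibble(column = column, row = row,
                                  message = message)
  required <- c("cell_line", "transporter", "probe_conc", "time", "dpm",
                "protein")
  for (col in setdiff(required, names(wells)))
    note(col, NA_integer_, "required column missing")
  chk <- function(col, bad, msg) {
    if (!col %in% names(wells)) return()
    for (i in which(bad(wells[[col]]))) note(col, i, msg)
  }
  chk("dpm", \(x) !is.na(x) & x < 0, "negative dpm")
  chk("protein", \(x) !is.na(x) & x <= 0, "non-positive protein mass")
  chk("time", \(x) !is.na(x) & x <= 0, "non-positive incubation time")
  chk("lysate_fraction_counted", \(x) !is.na(x) & (x <= 0 | x > 1),
      "lysate fraction outside (0, 1]")
  chk("cell_line",
      \(x) !is.na(x) & !x %in% c("transporter", "vector_control"),
      "unrecognised cell_line level")
  if (length(v) == 0)
    return(tibble(column = character(), row = integer(),
                  message = character()))
  bind_rows(v)
}
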