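#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_hline labs scale_x_log10 position_dodge facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Diagnostic plot of a Michaelis-Menten fit
#'
#' Corrected uptake rate against substrate concentration with the fitted
#' saturation curve.
#'
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(s = exp(seq(log(min(object$data$s)),
                             log(max(object$data$s)), length.out = 200)))
  grid$v <- object$vmax * grid$s / (object$km + grid$s)
  ggplot(object$data, aes(x = .data$s, y = .data$v)) +
    geom_line(data = grid, colour = "steelblue") +
    geom_point() +
    scale_x_log10() +
    labs(x = "Substrate concentration (umol/L)",
         y = "Corrected uptake rate (pmol/min/mg)",
         title = sprintf("Km = %.3g umol/L, Vmax = %.3g pmol/min/mg",
                         object$km, object$vmax),
         subtitle = object$transporter)
}

#' Diagnostic plot of a logistic inhibition fit
#'
#' Percent-of-control activity against inhibitor concentration (log axis;
#' vehicle wells drawn at the left edge) with the fitted 4/5PL curve.
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  d <- object$data
  pos <- d$conc[d$conc > 0]
  floor_conc <- min(pos) / 10
  d$conc_plot <- pmax(d$conc, floor_conc)
  p <- ggplot(d, aes(x = .data$conc_plot, y = .data$percent)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "Inhibitor concentration (umol/L)",
         y = "Activity (% vehicle control)",
         subtitle = paste(object$inhibitor, object$transporter, sep = " / "))
  if (!object$censored) {
    grid <- tibble(conc = exp(seq(log(floor_conc), log(max(pos)),
                                  length.out = 200)))
    grid$percent <- predict(object$fit,
                            newdata = data.frame(x = grid$conc))
    p <- p + geom_line(data = grid, aes(x = .data$conc), colour = "firebrick") +
      labs(title = sprintf("%s fit: IC50 = %.3g umol/L", object$model,
                           object$ic50))
  } else {
    p <- p + labs(title = sprintf("No inhibition; IC50 > %g umol/L",
                                  object$censor_limit))
  }
  p
}

#' Predicted versus observed AUC fold-changes
#'
#' Dot plot of static-model predictions per perpetrator scenario, faceted
#' by transporter, with the observed clinical fold-change overlaid where a
#' comparison table is supplied.
#'
#' @param predictions Output of [predict_ddi()] or
#'   [compare_to_observed()].
#' @return A ggplot.
#' @export
plot_predictions <- function(predictions) {
  d <- predictions |>
    filter(!is.na(.data$fold_auc)) |>
    mutate(scenario = paste0(.data$perpetrator, "\n", .data$study),
           fe = factor(.data$fe_used))
  p <- ggplot(d, aes(x = .data$scenario, y = .data$fold_auc,
                     colour = .data$fe)) +
    geom_point(position = position_dodge(width = 0.4), size = 2) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    facet_wrap(~transporter) +
    labs(x = NULL, y = "Predicted AUC fold-change", colour = "fe")
  if ("observed_fold_auc" %in% names(d))
    p <- p + geom_point(aes(y = .data$observed_fold_auc), colour = "black",
                        shape = 4, size = 3)
  p
}
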