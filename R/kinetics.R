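#' Fit Michaelis-Menten kinetics to corrected uptake rates
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` to
#' vector-control-corrected uptake rates, returning point estimates with
#' asymptotic standard errors from the fit.
#'
#' @param data A data frame of condition-level rates, e.g. the output of
#'   [corrected_activities()] on a kinetic plate.
#' @param conc,rate Columns holding substrate concentration (umol/L) and
#'   corrected uptake rate (pmol/min/mg).
#' @param transporter Optional transporter label stored on the fit.
#' @return An object of class `mm_fit` with elements `km`, `vmax`,
#'   `km_se`, `vmax_se`, `converged`, `data` and the underlying `nls` fit.
#'   Use [tidy()] / [glance()] / [augment()] to extract results.
#' @examples
#' truth <- assay_truth("OCT2", km_true = 1608, vmax_true = 32918,
#'                      noise_cv = 0, protein_cv = 0)
#' plate <- sim_kinetic_plate(truth, time = 5)
#' fit <- corrected_activities(plate) |> fit_michaelis_menten()
#' tidy(fit)
#' @export
fit_michaelis_menten <- function(data, conc = probe_conc,
                                 rate = corrected_rate,
                                 transporter = NULL) {
  s <- dplyr::pull(data, {{ conc }})
  v <- dplyr::pull(data, {{ rate }})
  keep <- is.finite(s) & is.finite(v)
  s <- s[keep]; v <- v[keep]
  if (length(unique(s)) < 4)
    warn("Fewer than 4 distinct concentrations; Km may be poorly determined.")
  if (diff(range(v)) < 1e-10 * max(abs(v)))
    warn("Rates are essentially constant across concentrations; Km is unidentifiable.")

  df <- tibble(s = s, v = v)
  fit <- tryCatch(
    nls(v ~ SSmicmen(s, vmax, km), data = df,
        control = nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      abort(
        paste0("Michaelis-Menten fit failed to converge: ",
               conditionMessage(e)),
        class = "transportddi_fit_error",
        n = length(s), conc_range = range(s), rate_range = range(v)
      )
    }
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  km <- unname(est["km"])
  if (km < min(s) || km > max(s))
    warn("Fitted Km lies outside the tested concentration range.")

  structure(
    list(
      km = km, vmax = unname(est["vmax"]),
      km_se = unname(se["km"]), vmax_se = unname(se["vmax"]),
      converged = fit$convInfo$isConv %||% TRUE,
      transporter = transporter, fit = fit, data = df
    ),
    class = "mm_fit"
  )
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("km", "vmax"),
    estimate = c(x$km, x$vmax),
    std.error = c(x$km_se, x$vmax_se)
  )
}

#' @export
glance.mm_fit <- function(x, ...) {
  res <- stats::resid(x$fit)
  obs <- x$data$v
  tibble(
    n = length(obs),
    sigma = stats::sigma(x$fit),
    r.squared = 1 - sum(res^2) / sum((obs - mean(obs))^2),
    AIC = AIC(x$fit),
    converged = x$converged
  )
}

#' @export
augment.mm_fit <- function(x, ...) {
  x$data |>
    mutate(.fitted = stats::fitted(x$fit), .resid = stats::resid(x$fit))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit",
      if (!is.null(x$transporter)) paste0("(", x$transporter, ")"), "\n")
  cat(sprintf("  Km   = %.4g +/- %.3g umol/L\n", x$km, x$km_se))
  cat(sprintf("  Vmax = %.4g +/- %.3g pmol/min/mg\n", x$vmax, x$vmax_se))
  invisible(x)
}

#' Percent of vehicle-control activity
#'
#' Expresses a corrected (transporter-mediated) activity in the presence of
#' inhibitor as a percentage of the corrected activity of vehicle wells.
#'
#' @param inhibited,vehicle Corrected activities, pmol/mg.
#' @return Percent of control.
#' @export
percent_control <- function(inhibited, vehicle) {
  if (any(vehicle <= 0))
    abort("Vehicle corrected activity must be positive.")
  100 * inhibited / vehicle
}

#' @rdname percent_control
#' @details `inhibition_responses()` applies the conversion to a
#'   condition-level table from [corrected_activities()], using the
#'   zero-inhibitor rows of each occasion as the vehicle anchor.
#' @param corrected Output of [corrected_activities()] on an inhibition
#'   plate (columns `inhibitor_conc`, `corrected`, `occasion`).
#' @export
inhibition_responses <- function(corrected) {
  corrected |>
    group_by(across(dplyr::any_of(c("transporter", "inhibitor", "occasion")))) |>
    mutate(
      vehicle_activity = mean(.data$corrected[.data$inhibitor_conc == 0]),
      percent = percent_control(.data$corrected, .data$vehicle_activity)
    ) |>
    ungroup()
}

# 4/5PL mean functions on a log10(xmid) scale; conc = 0 maps to `top`.
pl_curve <- function(conc, bottom, top, hill, lx, log_s = 0) {
  s <- exp(log_s)
  frac <- ifelse(conc == 0, 0, exp(hill * log(10) * (log10(conc) - lx)))
  bottom + (top - bottom) / (1 + frac)^s
}

#' Fit a four- or five-parameter logistic inhibition curve
#'
#' Fits percent-of-control activity against inhibitor concentration with
#' the symmetric four-parameter logistic
#' `y = bottom + (top - bottom) / (1 + (x / xmid)^hill)` or its asymmetric
#' five-parameter extension (`... / (1 + (x / xmid)^hill)^s`).  The curve is
#' fitted on log10(concentration); vehicle (zero-concentration) wells enter
#' as an anchor for the upper plateau rather than as a point on the log
#' axis.  The reported IC50 is the concentration at which the fitted curve
#' crosses `(top + bottom) / 2` - identical to `xmid` for the 4PL, derived
#' from the fitted parameters for the 5PL.
#'
#' With `model = "auto"` both curves are fitted and the one with the lower
#' small-sample-corrected AIC is kept.  If no tested concentration reduces
#' the response below 80% of control, the IC50 is censored at the highest
#' tested concentration (`censored = TRUE`, `ic50 = NA`).
#'
#' @param data A data frame with inhibitor concentrations and percent
#'   responses, e.g. from [inhibition_responses()].
#' @param conc,response Columns with inhibitor concentration (umol/L) and
#'   percent-of-control activity.
#' @param model `"4PL"`, `"5PL"` or `"auto"` (corrected-AIC selection).
#' @param bounds Named list of parameter bounds used by the constrained
#'   fit; defaults stabilise partial curves: bottom in \[-20, 50\], top in
#'   \[50, 150\] percent, hill in (0, 10\].
#' @param inhibitor,transporter Optional labels stored on the fit.
#' @return An object of class `logistic_fit`; use [tidy()] / [glance()].
#' @examples
#' a <- assay_truth("MATE1", km_true = 4565, vmax_true = 141000,
#'                  noise_cv = 0, protein_cv = 0)
#' i <- inhibition_truth(ic50_true = 1.22)
#' plate <- sim_inhibition_plate(a, i, c(0.1, 0.3, 1, 3, 10, 30, 100),
#'                               probe_conc = 100, time = 1.5)
#' fit <- corrected_activities(plate) |>
#'   inhibition_responses() |>
#'   fit_logistic(model = "4PL")
#' glance(fit)
#' @export
fit_logistic <- function(data, conc = inhibitor_conc, response = percent,
                         model = c("auto", "4PL", "5PL"),
                         bounds = list(bottom = c(-20, 50), top = c(50, 150),
                                       hill = c(1e-3, 10),
                                       asymmetry = c(0.2, 5)),
                         inhibitor = NULL, transporter = NULL) {
  model <- match.arg(model)
  x <- dplyr::pull(data, {{ conc }})
  y <- dplyr::pull(data, {{ response }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x[x > 0])) < 5)
    warn("Fewer than 5 positive inhibitor concentrations; IC50 may be unstable.")

  # no-inhibition censoring: nothing dips below 80% of control
  by_conc <- tapply(y, x, mean)
  if (all(by_conc > 80)) {
    return(structure(
      list(model = NA_character_, censored = TRUE, ic50 = NA_real_,
           ic50_se = NA_real_, censor_limit = max(x),
           params = NULL, fit = NULL, converged = NA,
           inhibitor = inhibitor, transporter = transporter,
           data = tibble(conc = x, percent = y)),
      class = "logistic_fit"
    ))
  }

  fits <- list()
  if (model %in% c("auto", "4PL")) fits[["4PL"]] <- fit_pl(x, y, 5, bounds)
  if (model %in% c("auto", "5PL")) fits[["5PL"]] <- fit_pl(x, y, 6, bounds)
  fits <- purrr::compact(fits)
  if (length(fits) == 0)
    abort("Logistic fit failed to converge for the requested model(s).",
          class = "transportddi_fit_error")
  aiccs <- purrr::map_dbl(fits, "aicc")
  best <- fits[[which.min(aiccs)]]

  structure(
    list(model = best$label, censored = FALSE, ic50 = best$ic50,
         ic50_se = best$ic50_se, censor_limit = NA_real_,
         params = best$params, fit = best$fit, aicc = best$aicc,
         converged = best$converged, inhibitor = inhibitor,
         transporter = transporter,
         data = tibble(conc = x, percent = y)),
    class = "logistic_fit"
  )
}

# constrained 4PL (npar = 5 with lx counted once... npar is the AICc count:
# 4 or 5 curve parameters + sigma)
fit_pl <- function(x, y, npar, bounds) {
  five <- npar == 6
  pos <- x > 0
  ord <- order(x)
  top0 <- mean(y[x <= sort(unique(x))[2]])
  bot0 <- mean(y[x == max(x)])
  top0 <- min(max(top0, bounds$top[1]), bounds$top[2])
  bot0 <- min(max(bot0, bounds$bottom[1]), bounds$bottom[2])
  # concentration bracketing the half-response, on the log axis
  half <- (top0 + bot0) / 2
  xs <- sort(unique(x[pos]))
  ym <- tapply(y[pos], x[pos], mean)[as.character(xs)]
  below <- which(ym < half)
  lx0 <- if (length(below) > 0 && below[1] > 1) {
    i <- below[1]
    mean(log10(xs[c(i - 1, i)]))
  } else log10(stats::median(xs))

  df <- data.frame(x = x, y = y)
  lower <- c(bounds$bottom[1], bounds$top[1], bounds$hill[1],
             log10(min(x[pos])) - 2)
  upper <- c(bounds$bottom[2], bounds$top[2], bounds$hill[2],
             log10(max(x)) + 2)
  start <- list(bottom = bot0, top = top0, hill = 1, lx = lx0)
  if (five) {
    start$log_s <- 0
    lower <- c(lower, log(bounds$asymmetry[1]))
    upper <- c(upper, log(bounds$asymmetry[2]))
  }
  form <- if (five)
    y ~ pl_curve(x, bottom, top, hill, lx, log_s)
  else
    y ~ pl_curve(x, bottom, top, hill, lx)

  # port occasionally reports false convergence from an unlucky start; try a
  # small start grid and keep the lowest-RSS fit, preferring clean converges
  fit <- NULL; fit_rss <- Inf; fit_clean <- FALSE
  for (h0 in c(1, 0.5, 2)) {
    for (dlx in c(0, -0.5, 0.5)) {
      st <- start; st$hill <- h0; st$lx <- start$lx + dlx
      cand <- tryCatch(
        suppressWarnings(
          nls(form, data = df, start = st, algorithm = "port",
              lower = lower, upper = upper,
              control = nls.control(maxiter = 500, warnOnly = TRUE))
        ),
        error = function(e) NULL
      )
      if (is.null(cand)) next
      rss <- sum(stats::resid(cand)^2)
      clean <- isTRUE(cand$convInfo$isConv)
      better <- (clean && !fit_clean) ||
        (clean == fit_clean && rss < fit_rss)
      if (better) {
        fit <- cand; fit_rss <- rss; fit_clean <- clean
      }
    }
    if (fit_clean) break
  }
  if (is.null(fit)) return(NULL)

  est <- as.list(coef(fit))
  # vcov is singular on exactly-fitting (noiseless) data; SEs become NA
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) setNames(rep(NA_real_, length(est)), names(est))
        else sqrt(diag(vc))
  s <- if (five) exp(est$log_s) else 1
  xmid <- 10^est$lx
  ic50 <- xmid * (2^(1 / s) - 1)^(1 / est$hill)
  # delta-method SE on the log10 scale (dominant term: lx)
  ic50_se <- ic50 * log(10) * unname(se["lx"])

  n <- length(y)
  k <- length(est) + 1 # + sigma
  aicc <- AIC(fit) + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf

  params <- tibble(
    term = c("bottom", "top", "hill", "log10_xmid",
             if (five) "asymmetry"),
    estimate = c(est$bottom, est$top, est$hill, est$lx, if (five) s),
    std.error = c(unname(se[c("bottom", "top", "hill", "lx")]),
                  if (five) s * unname(se["log_s"]))
  )
  list(label = if (five) "5PL" else "4PL", ic50 = ic50, ic50_se = ic50_se,
       params = params, fit = fit, aicc = aicc, converged = fit_clean)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  if (x$censored) return(tibble(term = character(), estimate = double(),
                                std.error = double()))
  x$params
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(
    model = x$model, ic50 = x$ic50, ic50_se = x$ic50_se,
    censored = x$censored, censor_limit = x$censor_limit,
    n = nrow(x$data), AICc = if (x$censored) NA_real_ else x$aicc,
    converged = x$converged
  )
}

#' @export
augment.logistic_fit <- function(x, ...) {
  if (x$censored) return(x$data)
  x$data |>
    mutate(.fitted = predict(x$fit, newdata = data.frame(x = .data$conc)),
           .resid = .data$percent - .data$.fitted)
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Logistic inhibition fit: no inhibition observed; IC50 > %g umol/L\n",
                x$censor_limit))
  } else {
    cat(sprintf("%s inhibition fit%s: IC50 = %.4g +/- %.3g umol/L\n",
                x$model,
                if (!is.null(x$inhibitor)) paste0(" (", x$inhibitor, ")") else "",
                x$ic50, x$ic50_se))
  }
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For a competitive inhibitor, `Ki = IC50 / (1 + S / Km)` where `S` is the
#' probe substrate concentration and `Km` its Michaelis constant on the same
#' transporter.  When the probe is run well below Km (`S <= Km / 10`) the
#' correction is negligible and IC50 is reported as equal to Ki, which is
#' the condition inhibition assays are designed to meet.
#'
#' @param ic50 Fitted IC50, umol/L.
#' @param probe_conc Probe substrate concentration in the inhibition assay.
#' @param km Michaelis constant of the probe for the transporter.
#' @return A tibble with `ic50`, `probe_conc`, `km`, `ki` and
#'   `ic50_equals_ki` (TRUE when `probe_conc <= km / 10`).
#' @examples
#' cheng_prusoff_ki(1.22, probe_conc = 100, km = 4565)
#' @export
cheng_prusoff_ki <- function(ic50, probe_conc, km) {
  if (any(km <= 0)) abort("`km` must be positive.")
  if (any(probe_conc < 0) || any(ic50 <= 0))
    abort("`ic50` must be positive and `probe_conc` non-negative.")
  tibble(
    ic50 = ic50, probe_conc = probe_conc, km = km,
    ki = ic50 / (1 + probe_conc / km),
    ic50_equals_ki = probe_conc <= km / 10
  )
}

#' Aggregate per-occasion IC50 fits
#'
#' Combines independent experimental occasions of the same
#' inhibitor-transporter pair into a mean (+/- SD) IC50, optionally
#' appending the Cheng-Prusoff Ki for a stated probe concentration and Km.
#'
#' @param fits A list of `logistic_fit` objects, one per occasion, all for
#'   the same inhibitor and transporter.
#' @param probe_conc,km If both supplied, `ki` columns are added via
#'   [cheng_prusoff_ki()] using the mean IC50.
#' @return One-row tibble: labels, `n_occasions`, `per_occasion_ic50`
#'   (list-column), `ic50_mean`, `ic50_sd` (NA for a single occasion),
#'   and optionally `ki`, `ic50_equals_ki`.
#' @export
aggregate_occasions <- function(fits, probe_conc = NULL, km = NULL) {
  if (inherits(fits, "logistic_fit")) fits <- list(fits)
  if (length(fits) < 1) abort("Need at least one occasion.")
  labs <- purrr::map(fits, \(f) list(inhibitor = f$inhibitor %||% NA_character_,
                                     transporter = f$transporter %||% NA_character_))
  inhs <- unique(purrr::map_chr(labs, "inhibitor"))
  trs <- unique(purrr::map_chr(labs, "transporter"))
  if (length(inhs) > 1 || length(trs) > 1)
    abort("All occasions must share the same inhibitor and transporter.")
  ic50s <- purrr::map_dbl(fits, "ic50")
  if (any(is.na(ic50s)))
    abort("Cannot aggregate censored occasions (IC50 not determined).")

  out <- tibble(
    inhibitor = inhs, transporter = trs,
    n_occasions = length(ic50s),
    per_occasion_ic50 = list(ic50s),
    ic50_mean = mean(ic50s),
    ic50_sd = if (length(ic50s) > 1) sd(ic50s) else NA_real_
  )
  if (!is.null(probe_conc) && !is.null(km)) {
    cp <- cheng_prusoff_ki(out$ic50_mean, probe_conc, km)
    out$ki <- cp$ki
    out$ic50_equals_ki <- cp$ic50_equals_ki
  }
  out
}
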