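test_that("noiseless kinetic plates recover Km and Vmax for all transporters", {
  for (tr in names(kinetic_truths)) {
    kt <- kinetic_truths[[tr]]
    fit <- sim_kinetic_plate(noiseless_assay(tr), concs = kt$concs,
                             time = kt$time) |>
      corrected_activities() |>
      fit_michaelis_menten(transporter = tr)
    expect_lt(abs(fit$km - kt$km) / kt$km, 1e-3)
    expect_lt(abs(fit$vmax - kt$vmax) / kt$vmax, 1e-3)
    expect_true(fit$converged)
  }
})

test_that("the fitted curve satisfies the half-saturation identity", {
  fit <- sim_kinetic_plate(noiseless_assay("OCT2"),
                           concs = kinetic_truths$OCT2$concs, time = 5) |>
    corrected_activities() |>
    fit_michaelis_menten()
  v_at_km <- fit$vmax * fit$km / (fit$km + fit$km)
  expect_equal(v_at_km, fit$vmax / 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_gt(glance(fit)$r.squared, 0.999)
})

test_that("degenerate saturating-only designs are flagged or fail", {
  flat <- tibble::tibble(probe_conc = c(5000, 7000, 10000, 20000),
                         corrected_rate = rep(100, 4))
  w <- testthat::capture_warnings(try(fit_michaelis_menten(flat),
                                      silent = TRUE))
  expect_true(any(grepl("unidentifiable", w)))
})

test_that("percent control follows the ratio identities", {
  expect_equal(percent_control(50, 50), 100)
  expect_equal(percent_control(0, 50), 0)
  expect_equal(percent_control(25, 50), 50)
  expect_error(percent_control(10, 0))
})

test_that("noiseless inhibition plates recover the true IC50", {
  for (nm in names(ic50_truths)) {
    ic50 <- ic50_truths[[nm]]
    tr <- if (grepl("mate1", nm)) "MATE1" else "OCT2"
    fit <- fit_ic50_from_plate(noiseless_assay(tr), inhibition_truth(ic50),
                               inhibitor_series(ic50), model = "4PL")
    expect_lt(abs(fit$ic50 - ic50) / ic50, 1e-3)
    expect_equal(fit$model, "4PL")
  }
})

test_that("a 5PL-generated curve is recovered by the 5PL model", {
  inh <- inhibition_truth(0.131, hill_true = 1.3, asymmetry_true = 2)
  fit <- fit_ic50_from_plate(noiseless_assay("MATE1"), inh,
                             inhibitor_series(0.131), model = "5PL")
  expect_lt(abs(fit$ic50 - 0.131) / 0.131, 1e-3)
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "asymmetry"], 2,
               tolerance = 1e-3)
})

test_that("for the symmetric 4PL the fitted midpoint equals the reported IC50", {
  fit <- fit_ic50_from_plate(noiseless_assay("MATE1"), inhibition_truth(1.22),
                             inhibitor_series(1.22), model = "4PL")
  xmid <- 10^tidy(fit)$estimate[tidy(fit)$term == "log10_xmid"]
  expect_equal(fit$ic50, xmid)
})

test_that("flat response curves give a censored IC50", {
  resp <- tibble::tibble(inhibitor_conc = c(0, 1, 3, 10, 30, 100),
                         percent = c(100, 101, 99, 98, 100, 97))
  fit <- fit_logistic(resp)
  expect_true(fit$censored)
  expect_true(is.na(fit$ic50))
  expect_equal(fit$censor_limit, 100)
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("IC50 fitting is invariant to a rescaling of concentration units", {
  set.seed(11)
  resp <- tibble::tibble(
    inhibitor_conc = c(0, inhibitor_series(1.22)),
    percent = logistic5_ref(c(0, inhibitor_series(1.22)), 1.22, 1.1) +
      rnorm(8, 0, 1)
  )
  f1 <- fit_logistic(resp)
  f2 <- fit_logistic(dplyr::mutate(resp, inhibitor_conc = inhibitor_conc * 1000))
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-3)
})

test_that("the least-squares IC50 matches a brute-force grid oracle", {
  set.seed(7)
  concs <- c(0, inhibitor_series(2))
  resp <- tibble::tibble(
    inhibitor_conc = concs,
    percent = logistic5_ref(concs, 2, 1) + rnorm(length(concs), 0, 2)
  )
  fit <- fit_logistic(resp, model = "4PL")
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)

  # exhaustive grid over (IC50, hill) at the fitted plateaus
  grid <- expand.grid(lic50 = seq(log10(2) - 1, log10(2) + 1, length.out = 401),
                      hill = seq(0.3, 3, length.out = 271))
  sse <- vapply(seq_len(nrow(grid)), function(j) {
    yhat <- logistic5_ref(concs, 10^grid$lic50[j], grid$hill[j],
                          bottom = est["bottom"], top = est["top"])
    sum((resp$percent - yhat)^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_lt(abs(log10(fit$ic50) - best$lic50), 2 * diff(range(grid$lic50)) / 400)
  expect_lt(abs(est["hill"] - best$hill), 2 * diff(range(grid$hill)) / 270)
})

test_that("median recovery under realistic noise stays within 10 percent", {
  km_err <- vapply(1:20, function(s) {
    truth <- assay_truth("OCT2", km_true = 1608, vmax_true = 32918,
                         noise_cv = 0.05)
    fit <- sim_kinetic_plate(truth, concs = kinetic_truths$OCT2$concs,
                             time = 5, seed = s) |>
      corrected_activities() |>
      fit_michaelis_menten()
    abs(fit$km - 1608) / 1608
  }, numeric(1))
  expect_lte(median(km_err), 0.10)

  ic_err <- vapply(1:20, function(s) {
    fit <- fit_ic50_from_plate(
      assay_truth("MATE1", km_true = 4565, vmax_true = 141000,
                  noise_cv = 0.05),
      inhibition_truth(1.22), inhibitor_series(1.22), model = "4PL", seed = s
    )
    abs(fit$ic50 - 1.22) / 1.22
  }, numeric(1))
  expect_lte(median(ic_err), 0.10)
})

test_that("Cheng-Prusoff conversion is exact, monotone and bounded by IC50", {
  cp <- cheng_prusoff_ki(1.22, probe_conc = 100, km = 4565)
  expect_equal(cp$ki, 1.22 / (1 + 100 / 4565))
  expect_equal(cp$ki, 1.1939, tolerance = 1e-4)
  expect_true(cp$ic50_equals_ki) # 100 <= 456.5

  expect_equal(cheng_prusoff_ki(5, 1e-9, 100)$ki, 5, tolerance = 1e-9)
  expect_equal(cheng_prusoff_ki(5, 100, 100)$ki, 2.5)

  s_grid <- seq(0, 5000, by = 250)
  kis <- cheng_prusoff_ki(rep(1.22, length(s_grid)), s_grid, 4565)$ki
  expect_true(all(diff(kis) < 0))
  expect_true(all(kis <= 1.22))
  expect_false(cheng_prusoff_ki(1.22, 1000, 4565)$ic50_equals_ki)
  expect_error(cheng_prusoff_ki(1.22, 100, 0))
})

test_that("occasion aggregation reports the mean and SD of per-occasion IC50s", {
  mk <- function(ic50, inhibitor = "cimetidine", transporter = "MATE1") {
    structure(list(ic50 = ic50, inhibitor = inhibitor,
                   transporter = transporter, censored = FALSE),
              class = "logistic_fit")
  }
  agg <- aggregate_occasions(list(mk(1.0), mk(1.2), mk(1.4)),
                             probe_conc = 100, km = 4565)
  expect_equal(agg$ic50_mean, 1.2)
  expect_equal(agg$ic50_sd, 0.2)
  expect_equal(agg$ki, 1.2 / (1 + 100 / 4565))

  single <- aggregate_occasions(mk(1.0))
  expect_true(is.na(single$ic50_sd))
  expect_error(aggregate_occasions(list(mk(1), mk(1, transporter = "OCT2"))),
               "same inhibitor")
})

test_that("three noiseless occasions of the same truth agree exactly", {
  assay <- noiseless_assay("MATE1")
  inh <- inhibition_truth(1.22, occasions = 3, occasion_cv = 0)
  wells <- sim_inhibition_plate(assay, inh, inhibitor_series(1.22),
                                probe_conc = 100, time = 1.5)
  fits <- corrected_activities(wells) |>
    inhibition_responses() |>
    dplyr::group_split(occasion) |>
    lapply(\(d) fit_logistic(d, model = "4PL", inhibitor = "cimetidine",
                             transporter = "MATE1"))
  agg <- aggregate_occasions(fits)
  expect_equal(agg$n_occasions, 3)
  expect_equal(agg$ic50_sd, 0, tolerance = 1e-6)
  expect_equal(agg$ic50_mean, 1.22, tolerance = 1e-3)
})
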