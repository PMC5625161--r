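inputs <- metformin_ddi_inputs()

test_that("fe derivation multiplies the renal and active fractions", {
  expect_equal(derive_fe(0.88, 0.75), 0.66) # intravenous mass balance
  expect_equal(derive_fe(0.52, 0.75), 0.39) # oral urinary recovery
  expect_equal(derive_fe(1, 1), 1)
  expect_error(derive_fe(1.2, 0.5))
  # bundled disposition table reproduces both scenarios
  d <- inputs$disposition
  expect_equal(
    derive_fe(d$renal_fraction_of_total_clearance,
              d$active_fraction_of_renal_clearance),
    c(0.66, 0.39)
  )
})

test_that("unbound Cmax is total Cmax times fraction unbound", {
  expect_equal(cmax_free(9.6, 0.80), 7.68)
  expect_equal(cmax_free(2.29, 0.13), 0.2977)
  expect_equal(cmax_free(5, 1), 5)
  expect_error(cmax_free(5, 0))
})

test_that("intestinal [I2] reproduces the dose-over-250-mL concentrations", {
  p <- dplyr::distinct(inputs$perpetrators, perpetrator, dose_mg, mw)
  i2 <- round(i2_gut(p$dose_mg, p$mw))
  expect_equal(setNames(i2, p$perpetrator),
               c(cimetidine = 6341, trimethoprim = 2756, pyrimethamine = 804))
  expect_equal(i2_gut(0, 250), 0)
  expect_error(i2_gut(100, 0))
})

test_that("ratio screens flag gut but not systemic OCT2 exposure", {
  gut <- ratio_screen(6341, 275, cutoff = 10)
  expect_equal(round(gut$ratio), 23)
  expect_true(gut$flag)
  sys_oct2 <- ratio_screen(7.68, 207, cutoff = 0.1)
  expect_equal(signif(sys_oct2$ratio, 2), 0.037)
  expect_false(sys_oct2$flag)
  sys_mate1 <- ratio_screen(7.68, 1.22, cutoff = 0.1)
  expect_equal(round(sys_mate1$ratio, 2), 6.30)
  expect_true(sys_mate1$flag)
  expect_error(ratio_screen(1, 0))
})

test_that("the static equation evaluates the worked examples", {
  expect_equal(round(fold_auc(0.66, 7.68, 1.22), 2), 2.32)
  expect_equal(round(fold_auc(0.39, 0.298, 0.131), 2), 1.37)
  expect_equal(fold_auc(0.5, 0, 10), 1)
})

test_that("fold-AUC is monotone and respects its closed-form limits", {
  is_grid <- seq(0, 100, length.out = 41)
  vals <- fold_auc(0.66, is_grid, 1.22)
  expect_true(all(diff(vals) > 0))
  fes <- seq(0, 1, by = 0.05)
  expect_true(all(diff(fold_auc(fes, 5, 1.22)) > 0))
  expect_equal(fold_auc(0, 50, 1.22), 1)
  expect_equal(fold_auc(0.66, 1e12, 1.22), 1 / (1 - 0.66), tolerance = 1e-6)
  expect_true(all(fold_auc(0.39, is_grid, 2) <= 1 / (1 - 0.39) + 1e-12))
  expect_true(all(fold_auc(0.39, is_grid, 2) >= 1))
})

test_that("predict_ddi reproduces every printed fold-increase at 2 d.p.", {
  preds <- predict_ddi(inputs$perpetrators, inputs$ki, fe = c(0.66, 0.39))
  m <- preds |>
    dplyr::filter(transporter == "MATE1") |>
    dplyr::arrange(match(perpetrator, c("cimetidine", "trimethoprim",
                                        "pyrimethamine")),
                   study, dplyr::desc(fe_used))
  expect_equal(round(m$fold_auc[m$fe_used == 0.66], 2),
               c(2.32, 2.03, 1.98, 1.69, 1.85))
  expect_equal(round(m$fold_auc[m$fe_used == 0.39], 2),
               c(1.51, 1.43, 1.41, 1.32, 1.37))
  o <- preds |> dplyr::filter(transporter == "OCT2")
  expect_true(all(round(o$fold_auc, 2) >= 1.01 & round(o$fold_auc, 2) <= 1.04))
  # systemic ratio screen: all MATE1 scenarios flagged, no OCT2 scenario
  expect_true(all(m$ratio_systemic >= 0.1) && all(m$flag_systemic))
  expect_true(all(o$ratio_systemic < 0.1) && !any(o$flag_systemic))
})

test_that("a missing Ki yields a per-row error without failing the grid", {
  preds <- predict_ddi(inputs$perpetrators, inputs$ki,
                       transporters = c("MATE1", "MATE2K"))
  bad <- preds |> dplyr::filter(perpetrator == "pyrimethamine",
                                transporter == "MATE2K")
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.na(bad$fold_auc)))
  good <- preds |> dplyr::filter(transporter == "MATE1")
  expect_true(all(is.na(good$error)))
  expect_equal(predict_ddi(inputs$perpetrators[0, ], inputs$ki) |> nrow(), 0)
})

test_that("comparison to observed spans the documented concordance ranges", {
  preds <- predict_ddi(inputs$perpetrators, inputs$ki)
  comp <- compare_to_observed(preds, inputs$observed)
  rng <- concordance_range(comp) |> dplyr::filter(transporter == "MATE1")
  expect_equal(round(rng$delta_min[rng$fe_used == 0.66]), 39)
  expect_equal(round(rng$delta_max[rng$fe_used == 0.66]), 86)
  expect_equal(round(rng$delta_min[rng$fe_used == 0.39]), 2)
  expect_equal(round(rng$delta_max[rng$fe_used == 0.39]), 11)
})

test_that("comparison handles exact agreement and unmatched predictions", {
  preds <- tibble::tibble(perpetrator = c("a", "b"), study = c("s1", "s2"),
                          transporter = "MATE1", fe_used = 0.66,
                          fold_auc = c(1.5, 2))
  obs <- tibble::tibble(perpetrator = "a", study = "s1",
                        observed_fold_auc = 1.5)
  comp <- compare_to_observed(preds, obs)
  expect_equal(comp$delta[1], 0)
  expect_true(comp$unmatched[2])
  rng <- concordance_range(comp)
  expect_equal(rng$n_pairs, 1)
  # worked deltas: 2.32 vs 1.46 -> 86 points; 1.43 vs 1.54 -> 11 points
  p2 <- tibble::tibble(perpetrator = "x", study = "s", transporter = "MATE1",
                       fe_used = 0.66, fold_auc = c(2.32, 1.43))
  o2 <- tibble::tibble(perpetrator = "x", study = "s",
                       observed_fold_auc = c(1.46, 1.54))
  d <- compare_to_observed(p2[1, ], o2[1, ])$delta
  expect_equal(d, 86)
  expect_equal(compare_to_observed(p2[2, ], o2[2, ])$delta, 11)
})

test_that("the relative-error metric is available as an alternative", {
  preds <- predict_ddi(inputs$perpetrators, inputs$ki, fe = 0.39)
  comp <- compare_to_observed(preds, inputs$observed,
                              metric = "relative_fold_error")
  m <- comp |> dplyr::filter(transporter == "MATE1",
                             perpetrator == "pyrimethamine")
  expect_equal(m$delta, 100 * abs(m$fold_auc - 1.39) / 1.39)
})
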