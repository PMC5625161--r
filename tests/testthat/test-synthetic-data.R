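test_that("noiseless timecourse wells carry the Michaelis-Menten expectation", {
  truth <- noiseless_assay("OCT2") # Km 1608, Vmax 32918
  wells <- sim_uptake_timecourse(truth, probe_conc = 100,
                                 times = c(1, 2, 5), replicates = 2)

  # transporter-mediated rate at S = 100: Vmax * S / (Km + S)
  rate <- 32918 * 100 / 1708
  expect_equal(rate, 1927.2834, tolerance = 1e-6)

  w <- well_activities(wells)
  t5 <- w[w$time == 5 & w$cell_line == "transporter", ]
  expect_equal(t5$pmol / t5$protein,
               rep(rate * (1 + truth$control_fraction) * 5, nrow(t5)),
               tolerance = 1e-10)
})

test_that("zero control fraction gives exactly empty control wells", {
  truth <- assay_truth(control_fraction = 0, noise_cv = 0, protein_cv = 0)
  wells <- sim_uptake_timecourse(truth, times = c(1, 5, 15))
  expect_true(all(wells$dpm[wells$cell_line == "vector_control"] == 0))
  expect_true(all(wells$dpm[wells$cell_line == "transporter"] > 0))
})

test_that("generators are deterministic under a fixed seed", {
  truth <- assay_truth(noise_cv = 0.1)
  inh <- inhibition_truth(1.22, occasions = 2, occasion_cv = 0.1)
  tw <- transwell_truth(noise_cv = 0.1)
  a1 <- sim_kinetic_plate(truth, seed = 42)
  a2 <- sim_kinetic_plate(truth, seed = 42)
  b1 <- sim_inhibition_plate(truth, inh, c(1, 10, 100), seed = 42)
  b2 <- sim_inhibition_plate(truth, inh, c(1, 10, 100), seed = 42)
  c1 <- sim_transwell_plate(tw, seed = 42)
  c2 <- sim_transwell_plate(tw, seed = 42)
  expect_identical(a1, a2)
  expect_identical(b1, b2)
  expect_identical(c1, c2)
  expect_false(identical(a1, sim_kinetic_plate(truth, seed = 43)))
})

test_that("plate layout honours replicates and paired cell lines", {
  truth <- assay_truth()
  wells <- sim_kinetic_plate(truth, concs = c(10, 100), replicates = 3)
  counts <- dplyr::count(wells, probe_conc, cell_line)
  expect_true(all(counts$n == 3))
  expect_equal(nrow(counts), 4) # 2 concs x 2 cell lines
})

test_that("single concentration at Km yields half-maximal transport", {
  truth <- noiseless_assay("OCT1") # Km 5422
  wells <- sim_kinetic_plate(truth, concs = 5422, time = 10)
  corr <- corrected_activities(wells)
  expect_equal(corr$corrected_rate, 9370 / 2, tolerance = 1e-10)
})

test_that("inhibition plates scale only the transporter-mediated component", {
  assay <- noiseless_assay("MATE1", control_fraction = 0.05)
  inh <- inhibition_truth(ic50_true = 1.22)
  wells <- sim_inhibition_plate(assay, inh, c(0.1, 1.22, 100),
                                probe_conc = 100, time = 1.5)
  resp <- corrected_activities(wells) |> inhibition_responses()
  expect_equal(resp$percent[resp$inhibitor_conc == 0], 100)
  expect_equal(resp$percent[resp$inhibitor_conc == 1.22], 50,
               tolerance = 1e-9) # symmetric midpoint identity
  # control wells identical across inhibitor levels (background uninhibited)
  ctrl <- wells[wells$cell_line == "vector_control", ]
  expect_equal(length(unique(round(ctrl$dpm, 9))), 1L)
})

test_that("probe concentrations violating the low-substrate condition are rejected", {
  assay <- noiseless_assay("OCT2") # Km 1608, Km/10 = 160.8
  inh <- inhibition_truth(10)
  expect_error(sim_inhibition_plate(assay, inh, c(1, 10), probe_conc = 500),
               "Ki")
  expect_s3_class(
    sim_inhibition_plate(assay, inh, c(1, 10), probe_conc = 500,
                         allow_high_probe = TRUE),
    "tbl_df"
  )
})

test_that("transwell receiver amounts follow Q = Papp * A * C0 * t", {
  tw <- transwell_truth(papp_true = 0.5e-6, area = 0.12, duration = 5400,
                        noise_cv = 0)
  wells <- sim_transwell_plate(tw, metformin_concs = 10000,
                               directions = "AB", replicates = 1)
  expect_equal(wells$receiver_amount, 3240) # pmol, unit-conversion oracle
  # zero permeability moves nothing
  tw0 <- transwell_truth(papp_true = 0, noise_cv = 0)
  w0 <- sim_transwell_plate(tw0, metformin_concs = 100, directions = "AB")
  expect_true(all(w0$receiver_amount == 0))
})

test_that("a leaky simulated monolayer fails the downstream integrity gate", {
  tw <- transwell_truth(ly_papp_true = 2e-6, noise_cv = 0)
  proc <- sim_transwell_plate(tw, metformin_concs = 100) |> process_transwell()
  expect_true(all(!proc$integrity_pass))
})

test_that("invalid designs are rejected", {
  truth <- assay_truth()
  expect_error(sim_uptake_timecourse(truth, times = numeric()))
  expect_error(sim_uptake_timecourse(truth, times = c(1, -2)))
  expect_error(sim_uptake_timecourse(truth, probe_conc = 0))
  expect_error(sim_kinetic_plate(truth, concs = c(-1, 10)))
  expect_error(sim_inhibition_plate(truth, inhibition_truth(1), numeric()))
  expect_error(transwell_truth(duration = 0))
})

test_that("across seeds the mean simulated permeability converges to truth", {
  tw <- transwell_truth(papp_true = 0.5e-6, noise_cv = 0.1)
  papps <- vapply(1:50, function(s) {
    sim_transwell_plate(tw, metformin_concs = 10000, directions = "AB",
                        replicates = 1, seed = s) |>
      process_transwell() |>
      dplyr::pull(papp)
  }, numeric(1))
  sem <- sd(papps) / sqrt(length(papps))
  expect_lt(abs(mean(papps) - 0.5e-6), 3 * sem)
})
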