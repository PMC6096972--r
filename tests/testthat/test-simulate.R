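test_that("noise-free equilibrium concentration conserves mass", {
  tr <- synthetic_truth(1000, 100, pka = 5, ion_class = "acid",
                        epsilon = 0)
  cond <- study_condition(c0 = 5, ph = 4)
  cw <- equilibrium_cw(tr, cond)
  sp <- neutral_fraction(4, 5, "acid")
  dp <- model_dp(1000, 100, sp)
  expect_equal(cw * cond$vw + dp * cw * cond$mp, cond$c0 * cond$vw,
               tolerance = 1e-12)

  # D_P = 0: nothing sorbs
  none <- synthetic_truth(0, 0, ion_class = "neutral", epsilon = 0)
  expect_equal(equilibrium_cw(none, cond), 5)
  # D_P = LSR: mass splits evenly
  half <- synthetic_truth(1000, 0, ion_class = "neutral", epsilon = 0)
  expect_equal(equilibrium_cw(half, cond), 2.5)
  # neutral compounds: identical cw at every pH
  neut <- synthetic_truth(700, 0, ion_class = "neutral", epsilon = 0)
  cws <- vapply(c(4, 7, 10), function(ph)
    equilibrium_cw(neut, study_condition(ph = ph)), numeric(1))
  expect_equal(cws, rep(cws[1], 3))
})

test_that("simulated batches honour the design and the noise contract", {
  tr <- synthetic_truth(1000, 100, pka = 5, ion_class = "acid",
                        epsilon = 0.05, seed = 9)
  cond <- study_condition(ph = 7)
  d <- simulate_batch(tr, cond, n_replicates = 3, sample_times = c(2, 4, 7))
  # 3 replicates x (day 0 + 3 sampling times)
  expect_equal(nrow(d), 12L)
  expect_equal(sum(d$time_days > 0), 9L)     # PE-style: 9 D_P measurements
  dps <- simulate_batch(tr, cond, 3, c(2, 4, 7, 11))
  expect_equal(sum(dps$time_days > 0), 12L)  # PS-style: 12
  expect_true(all(d$cw_ug_per_L > 0))

  # noise-free limit: observations equal the equilibrium value exactly
  tr0 <- synthetic_truth(1000, 100, pka = 5, ion_class = "acid",
                         epsilon = 0, seed = 9)
  d0 <- simulate_batch(tr0, cond)
  expect_equal(d0$cw_ug_per_L[d0$time_days > 0],
               rep(equilibrium_cw(tr0, cond), 9))
  expect_equal(d0$cw_ug_per_L[d0$time_days == 0], rep(5, 3))

  expect_error(synthetic_truth(1, 1, 5, "acid", epsilon = 1),
               "breaks down")
  expect_error(simulate_batch(tr, cond, sample_times = numeric(0)),
               "positive")
})

test_that("identical truth and design give bit-identical data", {
  tr <- synthetic_truth(500, 60, pka = 6, ion_class = "base",
                        epsilon = 0.08, seed = 123)
  cond <- study_condition(ph = 10)
  expect_identical(simulate_batch(tr, cond), simulate_batch(tr, cond))
})

test_that("per-batch substreams isolate compounds from each other", {
  compounds <- read_compound_table(mpsorb_example("compounds_table1.csv"))
  truths <- study_truths("PE")
  full <- generate_study_fixture(compounds, truths, seed = 42)
  # regenerate with one compound dropped: every other row unchanged
  dropped <- generate_study_fixture(compounds,
                                    truths[truths$compound != "Diazinon", ],
                                    seed = 42)
  keep <- full[full$compound != "Diazinon", ]
  rownames(keep) <- rownames(dropped) <- NULL
  expect_identical(keep, dropped)
})

test_that("simulated D_P scatter inflates as sorption weakens", {
  # empirical CV of per-measurement D_P rises monotonically as the true
  # coefficient falls below the liquid-to-solid ratio, and at strong
  # sorption it approaches the analytic error-model prediction
  cond <- study_condition(ph = 7)
  cvs <- vapply(c(1e4, 1e3, 1e2, 1e1), function(kp_true) {
    tr <- synthetic_truth(kp_true, 0, ion_class = "neutral",
                          epsilon = 0.05, seed = 77)
    d <- simulate_batch(tr, cond, n_replicates = 250,
                        sample_times = c(2, 4, 7))
    dp <- dp_from_measurement(cond, d$cw_ug_per_L[d$time_days > 0])
    stats::sd(dp) / abs(mean(dp))
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
  # strong-sorber limit vs the error model's prediction at eps = 5%
  predicted <- relative_error(error_model(0.05, 0.1, 1e-4), 1e4)
  expect_equal(cvs[1], predicted, tolerance = 0.3)
})

test_that("study fixture reproduces the full design and its screens", {
  compounds <- read_compound_table(mpsorb_example("compounds_table1.csv"))
  meas <- generate_study_fixture(compounds, study_truths("PE"), seed = 42)
  # 19 compounds x 3 pH x 3 replicates x (1 + 3 times)
  expect_equal(nrow(meas), 19 * 3 * 3 * 4)
  expect_setequal(unique(meas$ph), c(4, 7, 10))
  # initial concentrations follow the study design
  c0 <- tapply(meas$c0_ug_per_L, meas$compound, unique)
  expect_equal(c0[["Phenanthrene"]], 50)
  expect_equal(c0[["4-Nonylphenol"]], 30)
  expect_equal(c0[["Diazinon"]], 5)
  # every spike respects the <1% solubility screen
  for (nm in names(compounds)) {
    ratio <- solubility_screen(compounds[[nm]], c0[[nm]])
    if (!is.na(ratio)) expect_lt(ratio, 0.01)
  }
  # empty truth table: header-only dataset
  empty <- generate_study_fixture(compounds, study_truths("PE")[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(
    generate_study_fixture(compounds,
                           data.frame(compound = "Unobtainium",
                                      polymer = "PE", kp_n = 1, kp_i = 0)),
    "Unobtainium")
})
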