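test_that("noiseless observations are recovered exactly", {
  ph <- c(4, 7, 10)
  sp <- neutral_fraction(ph, 5, "acid")
  dp <- model_dp(1000, 100, sp)
  fit <- fit_species_k(ph, dp, pka = 5, ion_class = "acid")
  expect_equal(fit$kp_n, 1000, tolerance = 1e-9)
  expect_equal(fit$kp_i, 100, tolerance = 1e-9)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  # the fitted model reproduces the inputs at the design pH values
  expect_equal(model_dp(fit$kp_n, fit$kp_i, sp), dp, tolerance = 1e-9)

  # degenerate but consistent: equal coefficients give a flat D_P curve
  dp_flat <- model_dp(300, 300, sp)
  fit_flat <- fit_species_k(ph, dp_flat, pka = 5, ion_class = "acid")
  expect_equal(fit_flat$kp_n, 300, tolerance = 1e-6)
  expect_equal(fit_flat$kp_i, 300, tolerance = 1e-6)
})

test_that("fit rejects unidentifiable designs", {
  expect_error(fit_species_k(c(7, 7, 7), c(1, 2, 3), 5, "acid"),
               "distinct pH")
  expect_error(fit_species_k(7, 10, 5, "acid"), "distinct pH")
  # pH values differing where speciation does not: f_n numerically flat
  expect_error(fit_species_k(c(13.5, 14), c(10, 12), pka = 1, "acid"),
               "unidentifiable")
})

test_that("solver matches an exhaustive grid-search oracle", {
  # 25 random small instances; integer-step grid over a bracketing box.
  set.seed(101)
  ph <- rep(c(4, 7, 10), each = 3)
  for (i in 1:25) {
    pka <- runif(1, 4, 9)
    cls <- sample(c("acid", "base"), 1)
    truth <- round(runif(2, 0, 250))
    sp <- neutral_fraction(ph, pka, cls)
    y <- model_dp(truth[1], truth[2], sp) + rnorm(length(ph), 0, 20)
    fit <- fit_species_k(ph, y, pka, cls)
    oracle <- grid_nnls(sp$f_n, sp$f_i, y, kmax = 400, step = 1)
    # solver optimum can only be better than the grid's, and by no more
    # than one grid cell's worth of objective curvature
    expect_lte(fit$rss, oracle$rss + 1e-6)
    curvature <- sum(sp$f_n^2 + sp$f_i^2)
    expect_lte(oracle$rss - fit$rss, curvature)
    expect_lt(abs(fit$kp_n - oracle$kn), 1.5)
    expect_lt(abs(fit$kp_i - oracle$ki), 1.5)
  }
})

test_that("interior optima equal the closed-form normal equations", {
  set.seed(202)
  ph <- rep(c(4, 7, 10), each = 3)
  n_checked <- 0
  for (i in 1:40) {
    pka <- runif(1, 4.5, 8.5)
    sp <- neutral_fraction(ph, pka, "acid")
    y <- model_dp(runif(1, 500, 2000), runif(1, 100, 600), sp) +
      rnorm(length(ph), 0, 25)
    # straight 2x2 normal-equation solve, written out independently
    A <- cbind(sp$f_n, sp$f_i)
    beta <- solve(t(A) %*% A, t(A) %*% y)
    if (all(beta > 0)) {
      fit <- fit_species_k(ph, y, pka, "acid")
      expect_equal(fit$kp_n, beta[1], tolerance = 1e-9)
      expect_equal(fit$kp_i, beta[2], tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 25)
})

test_that("negative noisy observations keep coefficients non-negative", {
  ph <- rep(c(4, 7, 10), each = 3)
  sp <- neutral_fraction(ph, 5, "acid")
  # weak sorber drowned in noise: many negative D_P draws
  set.seed(7)
  y <- model_dp(30, 0, sp) + rnorm(length(ph), 0, 200)
  fit <- fit_species_k(ph, y, 5, "acid")
  expect_gte(fit$kp_n, 0)
  expect_gte(fit$kp_i, 0)
})

test_that("parameter recovery from noisy designs meets the error budget", {
  # 200 seeded simulations of the triplicate pH {4,7,10} design at 5%
  # analytical noise, truth K_P,n = 1000, K_P,i = 100 (acid, pKa 5)
  err_n <- err_i <- numeric(200)
  for (s in 1:200) {
    tr <- synthetic_truth(1000, 100, pka = 5, ion_class = "acid",
                          epsilon = 0.05, seed = s)
    obs <- simulate_design_dp(tr)
    fit <- fit_species_k(obs$ph, obs$dp, pka = 5, ion_class = "acid")
    err_n[s] <- abs(fit$kp_n - 1000) / 1000
    err_i[s] <- abs(fit$kp_i - 100) / 100
  }
  expect_lt(median(err_n), 0.05)
  expect_lt(median(err_i), 0.25)
})

test_that("ionic-coefficient recovery degrades as pKa leaves the design window", {
  # the ionized species fades out of the pH {4,7,10} design as an acid's
  # pKa climbs; recovery error of K_P,i must grow monotonically
  med_err <- vapply(c(5, 7, 9, 12), function(pka) {
    errs <- vapply(1:60, function(s) {
      tr <- synthetic_truth(1000, 100, pka = pka, ion_class = "acid",
                            epsilon = 0.05, seed = 5000 + s)
      obs <- simulate_design_dp(tr)
      fit <- fit_species_k(obs$ph, obs$dp, pka = pka, ion_class = "acid")
      abs(fit$kp_i - 100) / 100
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("indeterminate ionic coefficients are flagged", {
  # carbamazepine-like acid, pKa 13.9: f_i < 1e-3 at every tested pH
  ph <- c(4, 7, 10)
  sp <- neutral_fraction(ph, 13.9, "acid")
  fit <- fit_species_k(ph, model_dp(70, 0, sp), pka = 13.9,
                       ion_class = "acid")
  expect_true(fit$kp_i_indeterminate)
  # well-ionized design is not flagged
  fit2 <- fit_species_k(ph, model_dp(70, 10, neutral_fraction(ph, 5, "acid")),
                        pka = 5, ion_class = "acid")
  expect_false(fit2$kp_i_indeterminate)
})

test_that("censoring renders coefficients by the reliability rules", {
  ph <- c(4, 7, 10)
  sp <- neutral_fraction(ph, 5, "acid")

  fit <- fit_species_k(ph, model_dp(1000, 12, sp), pka = 5, "acid")
  ests <- list(aggregate_dp(c(900, 1000, 1100), 4),
               aggregate_dp(c(80, 100, 120), 7),
               aggregate_dp(c(8, 10, 12), 10))
  row <- censor_fit(fit, ests)
  expect_equal(row$kp_i_label, "<5e+01")    # below 50 L/kg: censored token
  expect_true(row$kp_i_censored)
  expect_equal(row$kp_i, 12, tolerance = 1e-6)  # numeric shadow retained
  expect_match(row$kp_n_label, "^1\\.0000")     # numeric, 6 significant digits
  expect_false(any(unlist(row[grepl("cv_flag", names(row))])))

  # exactly 50 is reported numerically: the rule is strictly "below 50"
  fit50 <- fit_species_k(ph, model_dp(600, 50, sp), pka = 5, "acid")
  row50 <- censor_fit(fit50, ests)
  expect_false(row50$kp_i_censored)
  expect_equal(row50$kp_i_label, "5.00000e+01")

  # a CV above 100% raises the warning flag on that pH only
  noisy <- list(aggregate_dp(c(-50, 500, 1000), 4),   # CV ~ 110%
                aggregate_dp(c(80, 100, 120), 7))
  row_cv <- censor_fit(fit, noisy)
  expect_true(row_cv$cv_flag_ph4)
  expect_false(row_cv$cv_flag_ph7)
})
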