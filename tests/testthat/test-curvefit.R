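test_that("noiseless sigmoid parameters are recovered", {
  tt <- seq(0, 72, by = 3)
  y <- sigmoid_od(tt, 0.1, 1.0, 30, 0.1)
  fit <- fit_sigmoid(growth_curve(tt, y))
  expect_equal(fit$status, "converged")
  expect_equal(unname(coef(fit)), c(0.1, 1.0, 30, 0.1), tolerance = 1e-3)
  expect_gt(fit$r2, 0.999)
  expect_equal(length(fitted(fit)), length(tt))
})

test_that("degenerate inputs are rejected or labelled", {
  tt <- seq(0, 72, by = 3)
  flat <- fit_sigmoid(growth_curve(tt, rep(0.1, 25)))
  expect_equal(flat$status, "not_converged")
  expect_error(fit_sigmoid(growth_curve(c(0, 3, 6), c(.1, .2, .3))), "6 points")
  expect_error(growth_curve(tt, c(rep(0.1, 24), NA)), "non-finite")
  expect_error(growth_curve(tt, c(rep(0.1, 24), -0.1)), "negative")
  expect_error(growth_curve(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("refitting a fit's own fitted values is idempotent", {
  cc <- simulate_curve(curve_params(t50 = 25, hill = 0.15),
                       sim_config(noise_sd = 0.01, seed = 4))
  fit1 <- fit_sigmoid(cc)
  fit2 <- fit_sigmoid(growth_curve(cc$times_h, pmax(fit1$fitted_values, 0)))
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-4)
})

test_that("fits agree with the grid-search + polish oracle on noisy curves", {
  set.seed(42)
  for (i in 1:10) {
    mu <- runif(1, 0.03, 0.22)
    cc <- simulate_curve(calibrate_curve(mu),
                         sim_config(noise_sd = 0.005, seed = 500 + i))
    fit <- fit_sigmoid(cc)
    orc <- oracle_sigmoid(cc$times_h, cc$od750)
    expect_equal(unname(coef(fit)), unname(orc), tolerance = 1e-3)
  }
})

test_that("QC passes exactly on converged fits with r2 > 0.85 and abs_ss < 0.1", {
  expect_true(qc_filter(fake_fit(0.9915, 0.02))$pass)
  f <- qc_filter(fake_fit(0.84, 0.02))
  expect_false(f$pass)
  expect_match(f$reasons, "r2 <= 0.85")
  f <- qc_filter(fake_fit(0.99, 0.15))
  expect_false(f$pass)
  expect_match(f$reasons, "abs_ss >= 0.10")
  f <- qc_filter(fake_fit(0.99, 0.02, status = "ambiguous"))
  expect_false(f$pass)
  expect_match(f$reasons, "ambiguous")
  # threshold edges are exclusive
  expect_false(qc_filter(fake_fit(0.85, 0.05))$pass)
  expect_false(qc_filter(fake_fit(0.95, 0.1))$pass)
  expect_true(qc_filter(fake_fit(0.8500001, 0.0999999))$pass)
})

test_that("QC verdicts on real fits are consistent with the computed r2/abs_ss", {
  set.seed(9)
  for (noise in c(0.005, 0.03, 0.08)) {
    for (i in 1:5) {
      cc <- simulate_curve(curve_params(), sim_config(noise_sd = noise))
      fit <- fit_sigmoid(cc)
      qc <- qc_filter(fit)
      expect_identical(qc$pass,
                       fit$status == "converged" && fit$r2 > 0.85 && fit$abs_ss < 0.1)
    }
  }
})

test_that("raising noise never raises the average QC pass rate", {
  rate <- vapply(c(0.005, 0.03, 0.09), function(noise) {
    fits <- lapply(preset_curves(curve_params(), 15, seed0 = 300,
                                 config = sim_config(noise_sd = noise)),
                   fit_sigmoid)
    mean(vapply(fits, function(f) qc_filter(f)$pass, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
})

test_that("morphology triage recognises the preset shapes", {
  classify1 <- function(preset, seed) {
    cc <- simulate_curve(preset, sim_config(seed = seed))
    classify_morphology(cc, fit_sigmoid(cc))
  }
  pres <- curve_presets()
  expect_equal(classify1(pres$robust, 21)$label, "robust")
  expect_equal(classify1(pres$no_growth, 22)$label, "no_growth")
  dp <- classify1(pres$death_phase, 23)
  expect_equal(dp$label, "death_phase")
  expect_true(dp$excluded)
  lp <- classify1(pres$low_plateau, 24)
  expect_equal(lp$label, "low_plateau")
  expect_true(lp$review)
  expect_false(lp$excluded)
  expect_equal(classify1(pres$circadian_strong, 25)$label, "circadian_strong")
  expect_equal(classify1(pres$long_lag, 26)$label, "long_lag")
  expect_equal(classify1(pres$early_plateau, 27)$label, "low_plateau")
})

test_that("fit_wells tabulates parameters, QC and classes per well", {
  curves <- list(
    simulate_curve(curve_params(), sim_config(seed = 31), well = "A1", plate = 1,
                   condition_id = "c1", replicate = 1),
    simulate_curve(curve_params(kn = 0.1), sim_config(seed = 32), well = "A2",
                   plate = 1, condition_id = "c2", replicate = 1))
  fw <- fit_wells(curves)
  expect_equal(nrow(fw$table), 2L)
  expect_equal(fw$table$class, c("robust", "no_growth"))
  expect_equal(fw$table$qc_pass, c(TRUE, FALSE))
  expect_equal(fw$table$well, c("A1", "A2"))
})
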