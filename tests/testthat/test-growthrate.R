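test_that("two-point specific growth rate follows the log-ratio formula", {
  expect_equal(specific_growth_rate(0.1, 0.2, 0, 1), log(2))
  expect_equal(specific_growth_rate(0.5, 0.5, 0, 3), 0)
  expect_equal(specific_growth_rate(0.1, 0.1351, 0, 3), 0.10028, tolerance = 1e-4)
  # scale invariance
  expect_equal(specific_growth_rate(0.1, 0.2, 0, 5),
               specific_growth_rate(0.7, 1.4, 0, 5))
  expect_error(specific_growth_rate(0, 0.1, 0, 1), "positive")
  expect_error(specific_growth_rate(0.1, 0.2, 3, 3), "t2 > t1")
})

test_that("interval rates telescope to the overall log change", {
  tt <- seq(0, 72, by = 3)
  fit <- fit_sigmoid(growth_curve(tt, sigmoid_od(tt, 0.1, 1, 30, 0.1)))
  gr <- mu_max(fit, window_h = c(0, 72))
  total <- sum(gr$mu_series * (gr$t2 - gr$t1))
  od <- fit$fitted_values
  expect_equal(total, log(od[length(od)] / od[1]), tolerance = 1e-10)
  expect_equal(gr$mu_max, max(gr$mu_series))
})

test_that("windowing can only reduce mu_max and flags decreasing curves", {
  tt <- seq(0, 72, by = 3)
  # late-inflection curve: the steep part sits beyond 48 h
  fit <- fit_sigmoid(growth_curve(tt, sigmoid_od(tt, 0.1, 1, 58, 0.12)))
  expect_lte(mu_max(fit, c(0, 24))$mu_max, mu_max(fit, c(0, 72))$mu_max)
  expect_lt(mu_max(fit, c(0, 24))$mu_max, 0.5 * mu_max(fit, c(0, 72))$mu_max)
  # monotone-decreasing fitted series gives a non-positive maximum
  dec <- structure(list(curve = list(times_h = tt),
                        fitted_values = seq(1, 0.4, length.out = 25)),
                   class = "growth_fit")
  expect_lte(mu_max(dec, c(0, 48))$mu_max, 0)
  expect_error(mu_max(dec, c(80, 90)), "window excludes")
})

test_that("mu_max on fitted values is only mildly perturbed by plate-reader noise", {
  mu0 <- mu_max(fit_sigmoid(simulate_curve(curve_params(),
                                           sim_config(noise_sd = 0))))$mu_max
  dev <- vapply(1:20, function(i) {
    cc <- simulate_curve(curve_params(), sim_config(noise_sd = 0.01, seed = 60 + i))
    abs(mu_max(fit_sigmoid(cc))$mu_max - mu0) / mu0
  }, numeric(1))
  # at noise_sd 0.01 a single fitted mu_max moves by ~1.5% on average
  expect_lt(mean(dev), 0.025)
  expect_lt(max(dev), 0.08)
})

test_that("replicate aggregation reports mean, RSD and exclusion accounting", {
  rates <- data.frame(condition_id = "c1", species_id = "sp1",
                      mu_max = c(0.100, 0.102, 0.098), qc_pass = TRUE)
  agg <- aggregate_replicates(rates)
  expect_equal(agg$mu_mean, 0.100)
  expect_equal(agg$rsd_pct, 2.0)
  expect_equal(agg$n_replicates, 3L)
  # identical replicates -> zero RSD
  same <- aggregate_replicates(data.frame(condition_id = "c", mu_max = rep(0.1, 3)))
  expect_equal(same$rsd_pct, 0)
  # one failed replicate is dropped and counted
  rates$qc_pass[2] <- FALSE
  agg <- aggregate_replicates(rates)
  expect_equal(agg$n_replicates, 2L)
  expect_equal(agg$n_excluded, 1L)
  expect_equal(agg$mu_mean, mean(c(0.100, 0.098)))
  # all excluded -> reported, not dropped silently
  allbad <- aggregate_replicates(data.frame(condition_id = "c", mu_max = 0.1,
                                            qc_pass = FALSE))
  expect_equal(allbad$n_replicates, 0L)
  expect_true(is.na(allbad$mu_mean))
})

test_that("Cronbach's alpha matches its defining formula", {
  expect_equal(cronbach_alpha(cbind(1:5, 1:5, 1:5)), 1)
  # frozen hand computation on a 4-condition x 3-replicate matrix:
  # item variances sum 0.0121916667, total variance 0.036025
  M <- rbind(c(0.10, 0.11, 0.09), c(0.20, 0.19, 0.21),
             c(0.15, 0.16, 0.14), c(0.05, 0.06, 0.05))
  expect_equal(cronbach_alpha(M), 0.992366412214, tolerance = 1e-9)
  expect_error(cronbach_alpha(matrix(1, 3, 1)), ">= 2 replicate")
  expect_error(cronbach_alpha(matrix(c(1, 1, 1, 1, 1, 1), 3, 2)), "zero total variance")
})

test_that("alpha of unrelated noise replicates is near zero", {
  a <- vapply(1:100, function(s) {
    set.seed(s)
    cronbach_alpha(cbind(rnorm(50), rnorm(50)))
  }, numeric(1))
  expect_lt(mean(abs(a)), 0.3)
  expect_lt(abs(mean(a)), 0.15)
})
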