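d10 <- generate_bbd(10, 20)
X10 <- build_model_matrix(d10)

test_that("noiseless responses recover the true surface exactly", {
  beta <- true_surface(d10, 0.1, linear = c(Ca = 0.02, Zn = -0.01),
                       interactions = c("Mg:Fe" = 0.005),
                       quadratic = c(Si = -0.003))$beta
  fit <- fit_rsm(d10, as.numeric(X10 %*% beta))
  expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-10)
  expect_equal(fit$df.residual, 180L - 66L)
})

test_that("constant responses yield a pure-intercept fit with no significance", {
  fit <- fit_rsm(d10, rep(0.1, 180))
  expect_equal(unname(coef(fit)[1]), 0.1)
  expect_equal(unname(coef(fit)[-1]), rep(0, 65))
  me <- main_effects(d10, rep(0.1, 180))
  expect_false(any(me$significant))
})

test_that("linear estimates equal scaled contrasts on the balanced design", {
  set.seed(77)
  y <- rnorm(180, 0.1, 0.01)
  fit <- fit_rsm(d10, y)
  # the linear block of X'X is diagonal (64 per factor), so each linear
  # coefficient is the simple contrast sum(x_j * y) / 64
  for (j in colnames(d10$coded)) {
    expect_equal(coef(fit)[[j]], sum(d10$coded[, j] * y) / 64, tolerance = 1e-10)
  }
  # cross-check the whole fit against lm on the same matrix
  lmfit <- lm(y ~ X10 - 1)
  expect_equal(unname(coef(fit)), unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(unname(fit$p), unname(summary(lmfit)$coefficients[, 4]),
               tolerance = 1e-8)
})

test_that("a single injected effect is flagged by both methods and nothing else dominates", {
  set.seed(101)
  y <- 0.10 + 0.02 * d10$coded[, "Ca"] + rnorm(180, 0, 0.002)
  for (method in c("rsm_t", "cluster_anova")) {
    me <- main_effects(d10, y, method = method)
    expect_true(me$significant[me$factor == "Ca"], info = method)
    # at alpha = 0.05 up to a couple of the 9 null factors may fire by chance
    expect_lte(sum(me$significant[me$factor != "Ca"]), 2)
    expect_gt(me$mean_p1[me$factor == "Ca"], me$mean_m1[me$factor == "Ca"])
  }
})

test_that("mean linear estimate is unbiased over replicated noisy screens", {
  est <- p <- numeric(50)
  for (i in 1:50) {
    set.seed(2000 + i)
    y <- 0.10 + 0.02 * d10$coded[, "Ca"] + rnorm(180, 0, 0.005)
    fit <- fit_rsm(d10, y)
    est[i] <- coef(fit)[["Ca"]]
    p[i] <- fit$p[["Ca"]]
  }
  expect_lt(abs(mean(est) - 0.02) / 0.02, 0.10)
  expect_gte(mean(p <= 0.05), 0.95)
})

test_that("interaction effects are recovered and additive surfaces stay clean", {
  set.seed(55)
  y <- 0.1 + 0.03 * d10$coded[, "Ca"] * d10$coded[, "Mg"] + rnorm(180, 0, 0.005)
  for (method in c("rsm_t", "cluster_anova")) {
    ie <- interaction_effects(d10, y, method = method)
    hit <- ie$factor1 == "Ca" & ie$factor2 == "Mg"
    expect_true(ie$significant[hit], info = method)
    expect_lte(sum(ie$significant[!hit]), 3)
  }
  # two simultaneous interactions
  y2 <- 0.1 + 0.02 * d10$coded[, "Ca"] * d10$coded[, "Mg"] +
    0.02 * d10$coded[, "Mg"] * d10$coded[, "Zn"] + rnorm(180, 0, 0.004)
  ie2 <- interaction_effects(d10, y2)
  expect_true(ie2$significant[ie2$factor1 == "Ca" & ie2$factor2 == "Mg"])
  expect_true(ie2$significant[ie2$factor1 == "Mg" & ie2$factor2 == "Zn"])
  # noiseless additive surface: no interaction flagged
  y3 <- as.numeric(X10 %*% true_surface(d10, 0.1, linear = c(Ca = 0.02, Mg = 0.01))$beta)
  expect_false(any(interaction_effects(d10, y3)$significant))
})

test_that("permuted responses reject at close to the nominal rate", {
  set.seed(3141)
  y <- 0.10 + 0.02 * d10$coded[, "Ca"] + rnorm(180, 0, 0.005)
  hits <- 0L
  B <- 400L
  for (b in seq_len(B)) {
    fit <- fit_rsm(d10, sample(y))
    hits <- hits + sum(fit$p[colnames(d10$coded)] <= 0.05)
  }
  frac <- hits / (B * 10)
  se2 <- 2 * sqrt(0.05 * 0.95 / (B * 10))
  expect_gt(frac, 0.05 - se2 - 0.01)
  expect_lt(frac, 0.05 + se2 + 0.01)
})

test_that("QC-excluded runs are dropped and estimability is re-checked", {
  set.seed(12)
  y <- as.numeric(X10 %*% true_surface(d10, 0.1, linear = c(Ca = 0.02))$beta) +
    rnorm(180, 0, 0.001)
  y[sample(180, 20)] <- NA
  fit <- fit_rsm(d10, y)
  expect_equal(fit$n, 160L)
  expect_equal(coef(fit)[["Ca"]], 0.02, tolerance = 0.01)
  # dropping every run where a factor is active makes its terms inestimable
  y2 <- y
  y2[d10$coded[, "Ca"] != 0] <- NA
  expect_error(fit_rsm(d10, y2), "rank deficient")
})

test_that("media ranking reports deviations and baseline improvement", {
  y <- rep(0.061, 180)
  best_row <- 7L
  y[best_row] <- 0.108
  r <- rank_media(d10, y, baseline = 0.061)
  expect_equal(r$improvement_pct, 77.0, tolerance = 0.1)
  expect_equal(r$best_condition, d10$condition_id[best_row])
  nz <- which(d10$coded[best_row, ] != 0)
  for (nm in colnames(d10$coded)[nz]) {
    expect_match(r$best_deviations, nm, fixed = TRUE)
  }
  # all-equal responses: zero improvement, ties broken by row order
  r0 <- rank_media(d10, rep(0.08, 180))
  expect_equal(r0$improvement_pct, 0)
  expect_equal(r0$ranking$condition_id, d10$condition_id)
  # best at the centre point: empty deviation list
  yc <- rep(0.05, 180)
  yc[d10$role == "center"][1] <- 0.2
  expect_equal(rank_media(d10, yc)$best_deviations, "")
  # centre-point baseline is required or supplied
  d3 <- generate_bbd(3, 0)
  expect_error(rank_media(d3, rep(0.1, 12)), "baseline")
  # invariant to monotone rescaling
  set.seed(8)
  yr <- rnorm(180, 0.1, 0.01)
  expect_equal(rank_media(d10, yr)$ranking$condition_id,
               rank_media(d10, 5 * yr + 1)$ranking$condition_id)
})

test_that("effects report bundles methods and supports BH adjustment", {
  set.seed(31)
  y <- 0.1 + 0.02 * d10$coded[, "Ca"] + rnorm(180, 0, 0.004)
  rep1 <- effects_report(d10, y)
  expect_s3_class(rep1$fit, "rsm_fit")
  expect_true(rep1$main$significant[rep1$main$factor == "Ca"])
  repbh <- effects_report(d10, y, adjust = "BH")
  expect_true("p_adj" %in% names(repbh$main))
  expect_lte(sum(repbh$main$significant), sum(rep1$main$significant))
  rad <- radial_export(d10, y)
  expect_equal(nrow(rad), 180L)
  expect_equal(rad$angle_rad[1], 0)
})
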