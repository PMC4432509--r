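test_that("Screen 1 enumerates the full N x P factorial with TAP controls", {
  s1 <- generate_screen1()
  expect_equal(nrow(s1), 63L)
  expect_equal(sum(s1$is_tap_control), 3L)
  expect_equal(nrow(generate_screen1(include_tap = FALSE)), 60L)
  expect_false(any(generate_screen1(include_tap = FALSE)$is_tap_control))
  # NH4Cl level set as shipped
  nh4 <- sort(unique(s1$n_mM[s1$n_source == "NH4Cl"]))
  expect_equal(nh4, c(0, 4.2, 8.4, 12.6, 30))
  # one zero-N row per source is retained; all but the first source flagged
  zero <- s1[!s1$is_tap_control & s1$n_mM == 0, ]
  expect_equal(nrow(zero), 4L * 3L)
  expect_equal(sum(zero$zero_n_duplicate), 3L * 3L)
})

test_that("Screen 1 size follows |sources| x |levels| x |P| + controls", {
  for (case in list(list(n = list(NaNO3 = c(0, 5)), p = c(2, 10), tap = TRUE),
                    list(n = list(NH4Cl = c(1, 2, 3), urea = c(4, 5, 6)),
                         p = c(0, 2, 10), tap = FALSE))) {
    s <- generate_screen1(case$n, case$p, include_tap = case$tap)
    expect_equal(nrow(s),
                 sum(lengths(case$n)) * length(case$p) + if (case$tap) 3L else 0L)
  }
  expect_error(generate_screen1(list(N2gas = c(0, 1))), "unknown nitrogen")
  expect_error(generate_screen1(list(NaNO3 = c(-1, 5))), "non-negative")
})

test_that("ten-factor Box-Behnken design has the printed structure", {
  d <- generate_bbd(10, 20)
  expect_s3_class(d, "bbd_design")
  expect_equal(nrow(d$coded), 180L)
  expect_equal(sum(rowSums(d$coded != 0) == 0), 20L)
  expect_equal(sum(d$role == "center"), 20L)
  # each factor varied in exactly 64 runs, balanced 32/32
  expect_equal(unname(colSums(d$coded != 0)), rep(64L, 10L))
  expect_equal(unname(colSums(d$coded == 1)), rep(32L, 10L))
  expect_equal(unname(colSums(d$coded)), rep(0L, 10L))
  expect_equal(colnames(d$coded),
               c("Ca", "Mg", "Fe", "Mn", "Cu", "Zn", "B", "Se", "V", "Si"))
})

test_that("small and unsupported Box-Behnken cases behave", {
  d3 <- generate_bbd(3, 3)
  expect_equal(nrow(d3$coded), 15L)  # 3 pair blocks x 4 + 3 centres
  expect_error(generate_bbd(8), "no Box-Behnken block table")
  expect_error(generate_bbd(10, -1), "n_center")
})

test_that("coded columns are balanced and the quadratic model is estimable for every supported k", {
  for (k in c(3, 4, 5, 6, 7, 9, 10)) {
    d <- generate_bbd(k, 3)
    expect_equal(unname(colSums(d$coded)), rep(0L, k), info = paste("k =", k))
    expect_equal(unname(colSums(d$coded == 1)), unname(colSums(d$coded == -1)),
                 info = paste("k =", k))
    X <- build_model_matrix(d)
    p <- 1 + 2 * k + k * (k - 1) / 2
    expect_equal(ncol(X), p, info = paste("k =", k))
    expect_equal(qr(X)$rank, p, info = paste("k =", k))
  }
})

test_that("coded levels resolve to concentrations by the twofold rule", {
  facs <- nutrient_factors()
  ca <- facs[facs$name == "Ca", ]
  expect_equal(code_to_concentration(ca, 0), 0.213)
  expect_equal(code_to_concentration(ca, 1), 0.426)
  expect_equal(code_to_concentration(ca, -1), 0.1065)
  expect_equal(code_to_concentration(ca, c(0, 0)), rep(ca$mid_mM, 2))
  expect_error(code_to_concentration(ca, 2), "coded level")
  # refined baseline swaps the Ca/Mg mid-points
  ref <- nutrient_factors("refined")
  expect_equal(ref$mid_mM[ref$name == "Ca"], 0.85)
  expect_equal(ref$mid_mM[ref$name == "Mg"], 1.50)
  # design concentrations consistent with the mapping
  d <- generate_bbd(10, 1)
  expect_equal(sort(unique(d$concentrations_mM[, "Ca"])),
               c(0.1065, 0.213, 0.426))
})

test_that("model matrix has the documented column layout", {
  d <- generate_bbd(10, 20)
  X <- build_model_matrix(d)
  expect_equal(dim(X), c(180L, 66L))
  expect_equal(colnames(X)[1:3], c("(Intercept)", "Ca", "Mg"))
  expect_equal(colnames(X)[12], "Ca:Mg")
  expect_equal(colnames(X)[57], "Ca^2")
  # centre point row
  X0 <- build_model_matrix(matrix(0, 1, 3))
  expect_equal(unname(X0[1, ]), c(1, rep(0, 9)))
  # linear columns mutually orthogonal on the design
  lin <- X[, 2:11]
  g <- crossprod(lin)
  expect_equal(unname(g - diag(diag(g))), matrix(0, 10, 10))
  expect_equal(dim(build_model_matrix(generate_bbd(3, 3))), c(15L, 10L))
})

test_that("design CSV round trips", {
  d <- generate_bbd(10, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_design(d, f)
  back <- read_design(f)
  expect_equal(back$condition_id, d$condition_id)
  expect_equal(as.matrix(back[, colnames(d$coded)]), d$coded,
               ignore_attr = TRUE)
  expect_equal(back$Ca_mM, unname(d$concentrations_mM[, "Ca"]))
})
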