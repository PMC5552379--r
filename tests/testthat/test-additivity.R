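# Theoretical additive ED, composite t-test, interaction index, isobologram.

test_that("theoretical additive ED combines EDs and variances as specified", {
  add <- theoretical_additive(0.88, 0.025, f = 0.38,
                              var_A = 0.042, var_B = 0.025)
  expect_equal(add$z_add, 0.38 * 0.88 + 0.62 * 0.025)
  expect_equal(round(add$z_add, 2), 0.35)
  # direct evaluation of f^2 V(A) + (1-f)^2 V(B)
  expect_equal(add$var_z_add, 0.38^2 * 0.042 + 0.62^2 * 0.025, tolerance = 1e-12)
  expect_equal(add$var_z_add, 0.0156748, tolerance = 1e-7)
  # boundary: f = 1 collapses to drug A
  add1 <- theoretical_additive(0.88, 0.025, f = 1, var_A = 0.042, var_B = 0.025)
  expect_equal(add1$z_add, 0.88)
  expect_equal(add1$var_z_add, 0.042)
})

test_that("composite t reproduces the published intraplantar comparison", {
  res <- composite_t_test(z_add = 0.35, var_z_add = 0.0157, df_add = 103,
                          z_mix = 0.025, var_z_mix = 0.016, df_mix = 80,
                          mode = "paper-compat")
  expect_equal(res$t_critical, 6.4, tolerance = 0.01)   # printed 6.37
  expect_equal(res$t_tabulated, 1.96, tolerance = 1e-12)
  expect_true(res$significant)
  expect_identical(res$verdict, "synergy")
})

test_that("composite t boundary and error cases behave", {
  # identical doses -> t = 0, additive verdict
  res <- composite_t_test(z_add = 0.3, var_z_add = 0.01, z_mix = 0.3,
                          var_z_mix = 0.02, mode = "paper-compat")
  expect_equal(res$t_critical, 0)
  expect_false(res$significant)
  expect_identical(res$verdict, "additive")
  # equal variances in paper-compat mode -> T_tabulated is 1.96
  expect_equal(composite_t_test(0.3, 0.01, Inf, 0.1, 0.01, Inf,
                                mode = "paper-compat")$t_tabulated, 1.96,
               tolerance = 1e-12)
  # significantly larger mixture ED -> flagged sub-additive
  sub <- composite_t_test(z_add = 0.05, var_z_add = 0.001, z_mix = 0.5,
                          var_z_mix = 0.001, mode = "paper-compat")
  expect_identical(sub$verdict, "sub-additive")
  expect_error(composite_t_test(0.3, 0, Inf, 0.1, 0.01, Inf), "var_z_add")
  expect_error(composite_t_test(-1, 0.01, Inf, 0.1, 0.01, Inf), "z_add")
})

test_that("exact mode uses Student critical values at the supplied df", {
  res <- composite_t_test(z_add = 0.35, var_z_add = 0.0157, df_add = 103,
                          z_mix = 0.025, var_z_mix = 0.016, df_mix = 80,
                          mode = "exact")
  expect_equal(res$t_add, qt(0.975, 103))
  expect_equal(res$t_mix, qt(0.975, 80))
  w <- c(0.0157, 0.016) / (0.0157 + 0.016)
  expect_equal(res$t_tabulated, w[1] * res$t_add + w[2] * res$t_mix)
})

test_that("t_critical is antisymmetric under swapping the two EDs", {
  set.seed(5)
  for (i in 1:20) {
    z1 <- runif(1, 0.01, 1); z2 <- runif(1, 0.01, 1)
    v1 <- runif(1, 0.001, 0.1); v2 <- runif(1, 0.001, 0.1)
    a <- composite_t_test(z1, v1, 30, z2, v2, 40)
    b <- composite_t_test(z2, v2, 40, z1, v1, 30)
    expect_equal(a$t_critical, -b$t_critical, tolerance = 1e-12)
    expect_equal(a$t_tabulated, b$t_tabulated, tolerance = 1e-12)
  }
})

test_that("interaction index divides the two composite EDs", {
  expect_equal(interaction_index(0.025, 0.35), 0.025 / 0.35)
  expect_equal(round(interaction_index(0.025, 0.35), 3), 0.071)
  expect_equal(round(interaction_index(0.022, 0.34), 3), 0.065)
  expect_identical(interaction_index(0.3, 0.3), 1)
  expect_error(interaction_index(0, 0.3), "z_mix")
})

test_that("isobologram geometry: additive point on the isobole, observed sums to z_mix", {
  iso <- isobologram_coordinates(0.88, 0.025, f = 0.38, z_mix = 0.025)
  expect_equal(unname(iso$additive_point), c(0.3344, 0.0155))
  # collinearity with the axis intercepts: x/A + y/B = 1 on the isobole
  expect_equal(iso$additive_point[["A"]] / 0.88 + iso$additive_point[["B"]] / 0.025,
               1, tolerance = 1e-9)
  expect_equal(sum(iso$observed_point), 0.025)
  set.seed(9)
  for (i in 1:15) {
    A <- runif(1, 0.05, 2); B <- runif(1, 0.001, 1); f <- runif(1, 0.05, 0.95)
    iso <- isobologram_coordinates(A, B, f, z_mix = runif(1, 0.001, 1))
    expect_equal(iso$additive_point[["A"]] / A + iso$additive_point[["B"]] / B, 1,
                 tolerance = 1e-9)
  }
  sym <- isobologram_coordinates(1, 1, f = 0.5, z_mix = 0.4)
  expect_equal(unname(sym$additive_point), c(0.5, 0.5))
})

test_that("full pipeline on the packaged data finds synergy for both pairs", {
  r1 <- run_full_analysis(analysis_config("sb_ipl", "pha_ipl", "combo_ipl_ipl"))
  r2 <- run_full_analysis(analysis_config("sb_ipl", "pha_it", "combo_ipl_it"))
  expect_identical(r1$result$verdict, "synergy")
  expect_identical(r2$result$verdict, "synergy")
  expect_lt(r1$result$alpha_index, 0.1)
  expect_lt(r2$result$alpha_index, 0.1)
})
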