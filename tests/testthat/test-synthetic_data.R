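test_that("generators are deterministic per seed and independent per stream", {
  expect_identical(gen_gas_profile(5), gen_gas_profile(5))
  expect_identical(gen_porewater_table(5), gen_porewater_table(5))
  expect_identical(gen_keeling_dataset(5), gen_keeling_dataset(5))
  expect_false(identical(gen_keeling_dataset(5)$table,
                         gen_keeling_dataset(6)$table))
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(gen_gas_profile(1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("gas profile carries the expected peak and background structure", {
  g <- gen_gas_profile(seed = 2)
  expect_equal(max(g$h2_uM), 209)
  expect_equal(g$depth_mbsf[which.max(g$h2_uM)], 695)
  expect_equal(max(g$h2_uM[abs(g$depth_mbsf - 818.5) < 0.1]), 26)
  expect_true(all(g$h2_uM[g$below_quantification] < 3))
  # most depths sit at background
  expect_gt(mean(g$below_quantification), 0.7)
  # methane band and the drop past the decollement
  expect_true(all(g$ch4_mM[g$depth_mbsf <= 820.1] >= 1 &
                    g$ch4_mM[g$depth_mbsf <= 820.1] <= 20))
  expect_true(all(g$ch4_mM[g$depth_mbsf > 820.1] < 5))
  # carbon isotope drift and the constant CH4-CO2 fractionation
  expect_lt(mean(g$d13C_ch4_permil[g$depth_mbsf < 700]), -60)
  a <- alpha_from_deltas(g$d13C_ch4_permil, g$d13C_co2_permil)$alpha
  expect_equal(a, rep(0.94, nrow(g)), tolerance = 1e-12)
  # zero peak amplitude: everything below quantification
  g0 <- gen_gas_profile(seed = 2, peak_amplitudes_uM = c(0, 0))
  expect_true(all(g0$below_quantification))
})

test_that("gas-profile headspace deltas fall on the two-endmember line", {
  g <- gen_gas_profile(seed = 9)
  k <- keeling_fit(data.frame(mixing_ratio_ppmv = g$h2_ppmv,
                              dD_h2_permil = g$dD_h2_permil))
  expect_equal(k$intercept_delta, -850, tolerance = 1e-6)
  expect_equal(k$r2, 1, tolerance = 1e-9)
})

test_that("porewater generator's truth is recovered and Cl stays oceanic", {
  gen <- gen_porewater_table(seed = 1)
  expect_true(all(gen$truth$f <= 0.4))
  out <- correct_profile(gen$table)
  expect_equal(out$Cl, rep(gen$truth$endmember[["Cl"]], 12), tolerance = 1e-9)
  # chloride of the mixed rows stays within the oceanic band
  expect_lt(abs(mean(gen$table$Cl) - 559), 7.5)
  # f = 0 rows equal the endmember exactly
  gen0 <- gen_porewater_table(seed = 1, f_max = 0)
  expect_equal(gen0$table$K, rep(gen$truth$endmember[["K"]], 12),
               tolerance = 1e-12)
})

test_that("noise-free generator output is exactly recovered by its estimator", {
  ke <- gen_keeling_dataset(seed = 3, sigma = 0)
  expect_equal(keeling_fit(ke$table)$intercept_delta, ke$truth$delta_source,
               tolerance = 1e-9)
  fb <- gen_fe_h2o_batches(seed = 3, sigma = 0)
  for (d in split(fb$table, fb$table$T_C)) {
    a <- fit_alpha_origin(d$dD_h2o_permil, d$dD_h2_permil)$alpha
    expect_equal(a, unname(fb$truth[paste0("T", d$T_C[1])]),
                 tolerance = 1e-12)
  }
})

test_that("keeling generator defaults recover the source within 3 SE", {
  ke <- gen_keeling_dataset(seed = 1)
  k <- keeling_fit(ke$table)
  expect_lt(abs(k$intercept_delta - ke$truth$delta_source),
            3 * k$stderr_intercept)
})

test_that("sulfur generator respects its construction and observational band", {
  su <- gen_sulfur_records(seed = 6, n = 30)
  # pure juvenile rows sit at (0, 0)
  juv <- gen_sulfur_records(seed = 6, n = 5, f_range = c(1, 1))
  expect_equal(juv$table$d34S_permil, rep(0, 5), tolerance = 1e-9)
  expect_equal(juv$table$cap_delta33, rep(0, 5), tolerance = 1e-9)
  # unmixed rows with the maximum fractionation approach -47.9 permil
  big <- gen_sulfur_records(seed = 6, n = 5, eps_range = c(67.8, 67.8),
                            f_range = c(0, 0))
  expect_equal(big$table$d34S_permil, rep(-47.944, 5), tolerance = 1e-2)
  # CRS-like rows stay in the observed band for moderate juvenile fractions
  mid <- gen_sulfur_records(seed = 6, n = 50, f_range = c(0, 0.3),
                            eps_range = c(32, 68))
  expect_true(all(mid$table$d34S_permil > -50 & mid$table$d34S_permil < 25))
  # stored cap_delta33 recomputes from the deltas without drift
  expect_equal(su$table$cap_delta33,
               cap_delta33(su$table$d33S_permil, su$table$d34S_permil),
               tolerance = 1e-9)
})
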