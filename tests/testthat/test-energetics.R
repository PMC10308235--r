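test_that("ionic strength is the exact half-sum of m z^2", {
  expect_equal(ionic_strength(c("Na+" = 0.5, "Cl-" = 0.5)), 0.5)
  expect_equal(ionic_strength(c("Mg+2" = 0.01, "Cl-" = 0.02)),
               (0.01 * 4 + 0.02) / 2)
  expect_equal(ionic_strength(numeric(0)), 0)
  expect_error(ionic_strength(c(Xx = 0.1)), "no charge")
})

test_that("B-dot activity coefficients match a hand evaluation", {
  expect_equal(bdot_log_gamma(-1, 4.5, 0), 0)       # infinite dilution
  expect_equal(bdot_log_gamma(0, 4.5, 0.7), 0)      # neutral rule
  # hand evaluation of the formula with the shipped 25 degC constants
  I <- 0.7
  hand <- -0.5092 * sqrt(I) / (1 + 0.3283 * 4.5 * sqrt(I)) + 0.041 * I
  expect_equal(bdot_log_gamma(-1, 4.5, I), hand, tolerance = 1e-12)
  expect_equal(hand, -0.16183, tolerance = 1e-4)
})

test_that("weak-acid speciation obeys its limits and is linear in total", {
  # at pH = pKa and I = 0 the two forms have equal activities
  s <- speciate_weak_acid(1, pKa = 4.66, pH = 4.66, I = 0)
  expect_equal(s$a_HA, s$a_A, tolerance = 1e-12)
  # neutral acetic acid activity at deep-prism conditions
  a1 <- speciate_weak_acid(1, pH = 7.9)$a_HA
  expect_gt(a1, 2.8e-7 / 2)
  expect_lt(a1, 2.8e-7 * 2)
  # exact 1000x linearity between 1 mM and 1 uM
  a2 <- speciate_weak_acid(1e-3, pH = 7.9)$a_HA
  expect_equal(a1 / a2, 1000, tolerance = 1e-12)
})

test_that("carbonate speciation has the correct asymptotes and hand value", {
  expect_equal(speciate_carbonate(50, pH = 1)$a_CO2, 0.05, tolerance = 1e-3)
  expect_lt(speciate_carbonate(50, pH = 13)$a_CO2, 1e-6)
  # frozen hand evaluation of the mass balance with the shipped constants
  expect_equal(speciate_carbonate(50, pH = 7.9, I = 0.66)$a_CO2,
               5.66418e-4, tolerance = 1e-5)
})

test_that("reaction table is element-balanced and Hess-closed exactly", {
  rx <- qb_reactions()
  expect_named(rx, c("hydrogenotrophic_methanogenesis", "homoacetogenesis",
                     "acetate_exchange"))
  expect_identical(rx$acetate_exchange$dG0_kJ,
                   rx$homoacetogenesis$dG0_kJ -
                     rx$hydrogenotrophic_methanogenesis$dG0_kJ)  # exact closure
  # Hess identity at arbitrary activities, exact to machine precision
  set.seed(2)
  for (i in 1:10) {
    act <- c(H2 = 10^runif(1, -10, -2), CO2 = 10^runif(1, -5, -1),
             CH4 = 10^runif(1, -5, -1), CH3COOH = 10^runif(1, -12, -4),
             H2O = 1)
    g1 <- delta_g(rx$hydrogenotrophic_methanogenesis, act)
    g2 <- delta_g(rx$homoacetogenesis, act)
    g3 <- delta_g(rx$acetate_exchange, act)
    expect_equal(g3, g2 - g1, tolerance = 1e-12)
  }
  expect_error(reaction_spec("bad", c(H2 = -1, CH4 = 1), 0), "imbalance")
})

test_that("delta_g reduces to dG0 at unit activities and scales per decade", {
  rx <- qb_reactions("hydrogenotrophic_methanogenesis")
  expect_equal(delta_g(rx, c(H2 = 1, CO2 = 1, CH4 = 1, H2O = 1)), rx$dG0_kJ)
  # a tenfold H2 increase lowers dGr of the 4-H2 reactions by 4 RT ln10
  act <- c(H2 = 1e-7, CO2 = 1e-3, CH4 = 5e-3, CH3COOH = 1e-7, H2O = 1)
  act10 <- act; act10[["H2"]] <- 1e-6
  RTln10_4 <- 4 * 8.314 * 298.15 * log(10) / 1000
  for (nm in c("hydrogenotrophic_methanogenesis", "homoacetogenesis")) {
    expect_equal(delta_g(nm, act) - delta_g(nm, act10), RTln10_4,
                 tolerance = 1e-10)
  }
  expect_error(delta_g(rx, c(H2 = 1e-7)), "missing activities")
})

test_that("threshold H2 activities sit at the expected orders of magnitude", {
  cond <- solution_condition(sum_acetate_mM = 1)
  th_m <- threshold_activity("hydrogenotrophic_methanogenesis", cond)
  th_a <- threshold_activity("homoacetogenesis", cond)
  expect_equal(round(th_m$log10_activity), -8)
  expect_equal(round(th_a$log10_activity), -7)
  expect_gt(th_a$activity / th_m$activity, 3)   # about an order of magnitude
  expect_lt(abs(th_m$dG_at_root_kJ), 0.01)      # root-finder contract
  expect_lt(abs(th_a$dG_at_root_kJ), 0.01)
  # verification: dGr at the returned activity is (numerically) zero
  act <- condition_activities(cond, a_H2 = th_a$activity)
  expect_lt(abs(delta_g("homoacetogenesis", act)), 0.01)
})

test_that("threshold finder reports a missing bracket", {
  cond <- solution_condition(sum_acetate_mM = 1)
  expect_error(threshold_activity("acetate_exchange", cond, free_species = "H2"),
               "does not change sign")
})

test_that("energy landscapes reproduce the qualitative competition structure", {
  cond <- solution_condition(sum_acetate_mM = 1)
  grid <- seq(-12, 0, by = 0.5)
  lm_ <- energy_landscape("hydrogenotrophic_methanogenesis", cond,
                          log10_grid = grid)
  la <- energy_landscape("homoacetogenesis", cond, log10_grid = grid)
  lac <- energy_landscape(reverse_reaction(qb_reactions("acetate_exchange")),
                          cond, log10_grid = grid)
  expect_true(all(is.finite(lm_$dG_kJ)))
  # H2-consuming reactions are monotone decreasing in a[H2]
  expect_true(all(diff(lm_$dG_kJ) < 0))
  expect_true(all(diff(la$dG_kJ) < 0))
  # acetoclastic methanogenesis does not involve H2: flat and exergonic
  expect_equal(diff(range(lac$dG_kJ)), 0, tolerance = 1e-12)
  expect_true(all(lac$dG_kJ < 0))
  # both H2 users run at the observed H2 detection limit (~1e-6 M)
  expect_lt(lm_$dG_kJ[lm_$log10_activity == -6], 0)
  expect_lt(la$dG_kJ[la$log10_activity == -6], 0)
  # homoacetogenesis is shut off at the background H2 level (~1e-8 M);
  # methanogenesis sits essentially at equilibrium there
  expect_gt(la$dG_kJ[la$log10_activity == -8], 0)
  expect_lt(abs(lm_$dG_kJ[lm_$log10_activity == -8]), 10)
})
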