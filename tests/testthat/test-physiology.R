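test_that("growth rate and doubling time behave as exact inverses", {
  expect_equal(growth_rate(1, 2, 1), log(2))
  expect_equal(growth_rate(5, 5, 100), 0)
  expect_equal(growth_rate(1.1, 34.1, 240), 0.014308, tolerance = 1e-4)
  expect_equal(doubling_time(log(2)), 1)
  # round trip through an arbitrary doubling time
  for (td in c(35.7, 50.5, 7.3)) {
    expect_equal(doubling_time(growth_rate(1, 2, td)), td, tolerance = 1e-12)
  }
  expect_error(growth_rate(0, 2, 1), "positive")
  expect_error(doubling_time(-0.1), "mu")
})

test_that("uptake rate follows the depletion relation with consumption positive", {
  expect_equal(uptake_rate(100, 100, 0.001, 0.01, 0.014), 0)
  # reconstructed glucose-depletion fixture: ~102 umol/g/h
  v <- uptake_rate(2775, 2301, 0.0021, 0.0656, 0.0137)
  expect_equal(v, 102.3, tolerance = 0.01)
  # linear in mu at fixed depletion
  expect_equal(uptake_rate(100, 50, 0.001, 0.01, 0.028),
               2 * uptake_rate(100, 50, 0.001, 0.01, 0.014))
  # invariant under proportional rescaling of (S - S0, D - D0)
  expect_equal(uptake_rate(200, 100, 0.002, 0.020, 0.014),
               uptake_rate(100, 50, 0.001, 0.010, 0.014))
  expect_error(uptake_rate(1, 1, 0.01, 0.01, 0.014), "exceed")
})

test_that("CO2 uptake from biomass enrichment matches the printed rates and inverts exactly", {
  # nitrate condition: enrichment 21.1%, glucose-only
  expect_equal(co2_uptake(0.211, 102.3, 0), 589.7, tolerance = 0.01 * 589.7)
  # Gln condition: enrichment 14.6%
  expect_equal(co2_uptake(0.146, 80.3, 79.6), 521.8, tolerance = 0.01 * 521.8)
  # biomass at substrate enrichment -> no unlabeled carbon needed
  expect_equal(co2_uptake(0.403, 123, 0), 0)
  expect_error(co2_uptake(0.005, 100, 0), "enrichment")
  # forward relation is the exact inverse
  for (f in c(0.12, 0.211, 0.35)) {
    v <- co2_uptake(f, 102.3, 10)
    expect_equal(f13c_biomass(102.3, 10, v), f, tolerance = 1e-12)
  }
})

test_that("resampled CO2 uptake is reproducible and degenerates correctly", {
  m <- list(f13C_BM = 0.211, vGlc_up = 102.3, vGln_up = 0)
  s0 <- list(f13C_BM = 0, vGlc_up = 0, vGln_up = 0)
  r0 <- resample_co2_uptake(m, s0, n = 10, seed = 1)
  expect_equal(r0$sd, 0)
  expect_equal(r0$mean, co2_uptake(0.211, 102.3, 0))
  s <- list(f13C_BM = 0.011, vGlc_up = 4.3, vGln_up = 0)
  r1 <- resample_co2_uptake(m, s, n = 3000, seed = 7)
  r2 <- resample_co2_uptake(m, s, n = 3000, seed = 7)
  expect_identical(r1$values, r2$values)
  # SD of the same order as the printed +/- 79.3
  expect_gt(r1$sd, 20); expect_lt(r1$sd, 200)
  # resampling converges: SD at n and 4n agree within 3/sqrt(n) relative
  r4 <- resample_co2_uptake(m, s, n = 12000, seed = 11)
  expect_lt(abs(r4$sd - r1$sd) / r1$sd, 3 / sqrt(3000))
})

test_that("depletion fractions reproduce the steady-state feasibility checks", {
  # glucose stays below 20% depletion under both conditions
  ins <- lemna_physiology("INS"); ons <- lemna_physiology("ONS")
  d_ins <- depletion_fraction(ins$vGlc_up[1], log(2) / ins$t_double[1],
                              ins$D0, ins$D, ins$S0_glc)
  d_ons <- depletion_fraction(ons$vGlc_up[1], log(2) / ons$t_double[1],
                              ons$D0, ons$D, ons$S0_glc)
  expect_lt(d_ins, 0.20); expect_lt(d_ons, 0.20)
  # about 40% of medium Gln consumed under the organic nitrogen condition
  d_gln <- depletion_fraction(ons$vGln_up[1], log(2) / ons$t_double[1],
                              ons$D0, ons$D, ons$S0_gln)
  expect_equal(d_gln, 0.40, tolerance = 0.05)
  expect_equal(depletion_fraction(0, 0.014, 0.002, 0.06, 1000), 0)
})

test_that("biomass fluxes are linear in mu and fractions and match the reference table", {
  comp <- default_biomass_composition("INS")
  mu <- log(2) / 50.5
  bf <- biomass_fluxes(comp, mu)
  ref <- lemna_biomass_fluxes("INS")
  expect_equal(stats::setNames(bf$value, bf$flux)[ref$flux],
               stats::setNames(ref$mean, ref$flux), tolerance = 1e-6)
  # cell wall as anhydroglucose polymer: 0.31 g/g at mu 0.0137 -> ~26.2
  cw <- comp
  cw$fractions$g_per_g[cw$fractions$component == "cell_wall"] <- 0.31
  bf2 <- biomass_fluxes(cw, 0.0137)
  expect_equal(bf2$value[bf2$flux == "vHPc_out"], 0.31 / 162.14 * 0.0137 * 1e6,
               tolerance = 1e-9)
  # linearity in mu
  expect_equal(biomass_fluxes(comp, 2 * mu)$value, 2 * bf$value)
  # zero fraction -> zero flux
  z <- comp; z$fractions$g_per_g[z$fractions$component == "starch"] <- 0
  expect_equal(biomass_fluxes(z, mu)$value[bf$flux == "vSt_out"], 0)
  bad <- comp; bad$fractions <- bad$fractions[bad$fractions$component != "protein", ]
  expect_error(biomass_fluxes(bad, mu), "protein")
})

test_that("biomass-flux uncertainty propagation scales with input noise", {
  comp <- default_biomass_composition("INS")
  mu <- log(2) / 50.5
  z <- comp; z$fractions$sd <- 0
  r0 <- propagate_biomass_uncertainty(z, mu, 0, n = 5, seed = 1)
  expect_equal(r0$sd, rep(0, nrow(r0)))
  r1 <- propagate_biomass_uncertainty(comp, mu, 0.001, n = 4000, seed = 2)
  d2 <- comp; d2$fractions$sd <- 2 * d2$fractions$sd
  r2 <- propagate_biomass_uncertainty(d2, mu, 0.002, n = 4000, seed = 3)
  # doubling all input SDs roughly doubles the output SDs
  ratio <- r2$sd / r1$sd
  expect_true(all(ratio > 1.6 & ratio < 2.4))
  # fixed seed reproducibility
  expect_identical(propagate_biomass_uncertainty(comp, mu, 0.001, n = 20, seed = 9),
                   propagate_biomass_uncertainty(comp, mu, 0.001, n = 20, seed = 9))
})
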