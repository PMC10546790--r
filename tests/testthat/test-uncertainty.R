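# A tiny Monte-Carlo ensemble on the toy subnetwork, shared across tests.
toy_mc <- function() {
  fixture("toy_mc", function() {
    prob <- cyto_problem()
    meas <- cyto_measurements(prob, noise_sd = 0.01, seed = 1)
    base <- fit(prob$net, meas, prob$labels, n_restarts = 4, n_polish = 2,
                seed = 2)
    ens <- monte_carlo(prob$net, meas, prob$labels, n_replicates = 6,
                       restarts_per_replicate = 2, seed = 5, base_fit = base,
                       n_polish = 1)
    list(prob = prob, meas = meas, base = base, ens = ens)
  })
}

test_that("zero-noise ensembles collapse onto the base fit", {
  prob <- cyto_problem()
  meas <- cyto_measurements(prob, noise_sd = 0)
  base <- fit(prob$net, meas, prob$labels, n_restarts = 2, n_polish = 1,
              seed = 2)
  ens <- monte_carlo(prob$net, meas, prob$labels, n_replicates = 3,
                     restarts_per_replicate = 0, seed = 5, base_fit = base,
                     n_polish = 0)
  sm <- ensemble_summary(ens)
  expect_lt(max(sm$sd), 1e-6)
  expect_equal(sm$mean, sm$best, tolerance = 1e-5)
})

test_that("ensemble statistics are order-invariant and coherent", {
  x <- toy_mc()
  sm <- ensemble_summary(x$ens)
  expect_equal(nrow(sm), length(x$ens$reactions))
  ens_rev <- x$ens
  ens_rev$members <- rev(ens_rev$members)
  sm2 <- ensemble_summary(ens_rev)
  expect_equal(sm$mean, sm2$mean, tolerance = 1e-12)
  expect_equal(sm$sd, sm2$sd, tolerance = 1e-12)
})

test_that("aggregation commutes with ensemble averaging and tightens degenerate splits", {
  x <- toy_mc()
  # single-reaction combination: SD equals that reaction's ensemble SD
  sm <- ensemble_summary(x$ens)
  a1 <- aggregate_ensemble(x$ens, list(g6pdh = c(vG6PDH = 1)))
  expect_equal(a1$sd, sm$sd[sm$reaction == "vG6PDH"], tolerance = 1e-12)
  # linearity: aggregate of the mean equals mean of the aggregate (exact)
  a2 <- aggregate_ensemble(x$ens, list(comb = c(vPGI = 1, vG6PDH = 2)))
  expect_equal(a2$mean,
               sm$mean[sm$reaction == "vPGI"] + 2 * sm$mean[sm$reaction == "vG6PDH"],
               tolerance = 1e-12)
  expect_error(aggregate_ensemble(x$ens, list(bad = c(nope = 1))), "unknown")
  # constructed anticorrelated degenerate pair: the sum is much tighter
  ens2 <- x$ens
  set.seed(1)
  delta <- stats::rnorm(length(ens2$members), 0, 50)
  for (i in seq_along(ens2$members)) {
    ens2$members[[i]]$net[["vPGI"]] <- ens2$members[[i]]$net[["vPGI"]] + delta[i]
    ens2$members[[i]]$net[["vG6PDH"]] <- ens2$members[[i]]$net[["vG6PDH"]] - delta[i]
  }
  sm2 <- ensemble_summary(ens2)
  a3 <- aggregate_ensemble(ens2, list(tot = c(vPGI = 1, vG6PDH = 1)))
  expect_lt(a3$sd, 0.2 * min(sm2$sd[sm2$reaction %in% c("vPGI", "vG6PDH")]))
})

test_that("flux ratios report ensemble mean and SD with degenerate cases handled", {
  x <- toy_mc()
  r <- flux_ratio(x$ens, "vG6PDH", "vG6PDH")
  expect_equal(r$mean, 1); expect_equal(r$sd, 0); expect_equal(r$best, 1)
  r2 <- flux_ratio(x$ens, "vG6PDH", "vIn")
  truth_ratio <- x$prob$truth$net[["vG6PDH"]] / x$prob$truth$net[["vIn"]]
  expect_lt(abs(r2$mean - truth_ratio), max(4 * r2$sd, 0.05))
  expect_error(flux_ratio(x$ens, "vG6PDH", "nope"), "unknown")
})

test_that("doubling measurement noise increases ensemble spread", {
  prob <- cyto_problem()
  meas1 <- cyto_measurements(prob, noise_sd = 0.01, seed = 1)
  meas2 <- cyto_measurements(prob, noise_sd = 0.02, seed = 1)
  base1 <- fit(prob$net, meas1, prob$labels, n_restarts = 3, n_polish = 1, seed = 2)
  base2 <- fit(prob$net, meas2, prob$labels, n_restarts = 3, n_polish = 1, seed = 2)
  e1 <- monte_carlo(prob$net, meas1, prob$labels, n_replicates = 5,
                    restarts_per_replicate = 1, seed = 5, base_fit = base1,
                    n_polish = 0)
  e2 <- monte_carlo(prob$net, meas2, prob$labels, n_replicates = 5,
                    restarts_per_replicate = 1, seed = 5, base_fit = base2,
                    n_polish = 0)
  m1 <- stats::median(ensemble_summary(e1)$sd)
  m2 <- stats::median(ensemble_summary(e2)$sd)
  expect_gt(m2, m1)
})

test_that("the atmospheric share statistic covers its limiting cases", {
  net <- build_lemna_core("B", "INS")
  pre <- scenario_preset("INS")
  tr <- truth_flux(pre, net)
  # zero exchange with the cellular pool -> all RuBisCO CO2 is atmospheric
  f1 <- tr; f1$xch[["vCO2X"]] <- 0; f1$net[["vCO2X"]] <- -abs(f1$net[["vCO2X"]])
  expect_equal(atmospheric_fraction(f1), 1.0)
  # zero atmospheric influx -> none of it is
  f2 <- tr; f2$net[["vCO2_up"]] <- 0
  expect_equal(atmospheric_fraction(f2), 0.0)
  # configuration A has no such pool
  netA <- build_lemna_core("A", "INS")
  trA <- flux_state(netA, stats::setNames(rep(1, length(netA$reactions)),
                                          names(netA$reactions)))
  expect_error(atmospheric_fraction(trA), "configuration A")
})
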