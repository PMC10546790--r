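test_that("network parsing round-trips and enforces carbon conservation", {
  net <- parse_network(c(
    "# name toy",
    "# metabolite A_x x 2 external",
    "# metabolite B c 2 balanced",
    "# metabolite C_x x 2 external",
    "vA\tA_x#ab\tB#ab\tirr\t0\t100",
    "vB\tB#ab\tC_x#ab\tirr\t0\t100"))
  expect_s3_class(net, "mfa_network")
  expect_length(net$reactions, 2)
  expect_length(validate_carbon_balance(net), 0)
  # dropped atom -> carbon-conservation error naming the reaction
  expect_error(parse_network(c(
    "# name bad",
    "# metabolite A_x x 2 external",
    "# metabolite B_x x 1 external",
    "vBad\tA_x#ab\tB_x#a\tirr\t0\t100")), "vBad")
  # malformed atom map -> parse error naming the line
  expect_error(parse_network(c(
    "# name bad2",
    "# metabolite A_x x 2 external",
    "vX\tA_x#\tA_x#ab\tirr\t0\t1")), "line")
  # serialization round trip
  net2 <- parse_network(write_network_tsv(net))
  expect_equal(names(net2$reactions), names(net$reactions))
  expect_equal(net2$reactions$vA$educts, net$reactions$vA$educts)
})

test_that("shipped network fixtures parse with the reaction count declared in their header", {
  for (cfg in c("A", "B", "C")) {
    path <- system.file("extdata", paste0("lemna_core_", cfg, ".tsv"),
                        package = "lemnaflux")
    lines <- readLines(path)
    declared <- as.integer(sub(".* (\\d+) reactions$", "\\1", lines[1]))
    net <- parse_network(lines)
    expect_length(net$reactions, declared)
    expect_length(validate_carbon_balance(net), 0)
    # fixture matches the programmatic builder
    built <- build_lemna_core(cfg, "INS")
    expect_equal(names(net$reactions), names(built$reactions))
  }
  for (toy in c("toy_linear", "toy_diamond")) {
    net <- read_network(system.file("extdata", paste0(toy, ".tsv"),
                                    package = "lemnaflux"))
    expect_length(validate_carbon_balance(net), 0)
  }
})

test_that("carbon-balance validation reports instead of raising", {
  net <- toy_network("linear")
  # remove a product atom by hand to create a violation
  net$reactions$vOut$products[[1]]$atoms <- "a"
  net$metabolites$C_x$n_carbons <- 1L
  v <- validate_carbon_balance(net)
  expect_true(any(grepl("vOut", v)))
  # reversible reactions are checked once: flipping direction gives the
  # mirror-image violation set
  net2 <- toy_network("twopool")
  expect_length(validate_carbon_balance(net2), 0)
})

test_that("steady-state basis has the expected dimension and precision", {
  # linear chain with fixed feed: fully determined
  lin <- toy_network("linear")
  b <- steady_state_basis(lin)
  expect_equal(b$n_free_net, 0)
  expect_equal(b$expand(numeric(0)), c(vIn = 10, vOut = 10))
  # diamond: exactly one free net flux
  dia <- toy_network("diamond")
  bd <- steady_state_basis(dia)
  expect_equal(bd$n_free_net, 1)
  v <- bd$expand(3)
  S <- stoich_matrix(dia)
  expect_lt(max(abs(S %*% v)), 1e-9)
  # inconsistent fixed fluxes -> infeasibility
  expect_error(steady_state_basis(lin, extra_fixed = c(vOut = 99)),
               "feasible")
  # lemna-core: free-flux count equals reactions - rank(constraints)
  net <- build_lemna_core("B", "INS")
  sinks <- lemna_biomass_fluxes("INS")
  fx <- stats::setNames(sinks$mean, sinks$flux)
  bb <- steady_state_basis(net, extra_fixed = fx)
  S <- stoich_matrix(net)
  nfix <- length(fx) + length(net$fixed)
  A <- rbind(S, matrix(0, nfix + length(net$ratios), ncol(S)))
  rn <- ncol(S)
  i <- nrow(S)
  for (nm in c(names(net$fixed), names(fx))) {
    i <- i + 1; A[i, match(nm, colnames(S))] <- 1
  }
  for (rc in net$ratios) {
    i <- i + 1
    A[i, match(rc$numerator, colnames(S))] <- 1
    A[i, match(rc$denominator, colnames(S))] <- -rc$ratio
  }
  expect_equal(bb$n_free_net, rn - qr(A)$rank)
  # every expansion satisfies steady state and the exact ratio constraints
  set.seed(1)
  for (k in 1:5) {
    v <- bb$expand(stats::rnorm(bb$n_free_net, 0, 50))
    expect_lt(max(abs(S %*% v)) / max(1, max(abs(v))), 1e-9)
    expect_equal(v[["vRBC"]] / v[["vRBO"]], 1000, tolerance = 1e-6)
    expect_equal(v[["vFUM1"]], v[["vFUM2"]], tolerance = 1e-9)
  }
})

test_that("the three CO2-pool configurations differ by exactly the RuBisCO CO2 pool block", {
  A <- build_lemna_core("A", "INS")
  B <- build_lemna_core("B", "INS")
  C <- build_lemna_core("C", "INS")
  expect_setequal(setdiff(names(B$reactions), names(A$reactions)),
                  c("vCO2_up", "vCO2_rel", "vCO2X"))
  expect_setequal(setdiff(names(B$metabolites), names(A$metabolites)),
                  "CO2_RBC")
  # mode A: RuBisCO consumes the cellular pool, and no atmospheric influx
  expect_equal(A$reactions$vRBC$educts[[2]]$met, "CO2")
  expect_false(any(grepl("CO2atm", vapply(A$reactions, function(r)
    paste(vapply(r$educts, `[[`, character(1), "met"), collapse = ","),
    character(1)))))
  expect_equal(B$reactions$vRBC$educts[[2]]$met, "CO2_RBC")
  # C adds the measurement slots only
  expect_equal(names(B$reactions), names(C$reactions))
  expect_setequal(C$measured, c("vGlc_up", "vGln_up", "vCO2_up"))
  expect_length(B$measured, 0)
  # INS fixes the Gln feed at zero; ONS frees it
  expect_equal(B$fixed[["vGln_up"]], 0)
  ons <- build_lemna_core("B", "ONS")
  expect_false("vGln_up" %in% names(ons$fixed))
})

test_that("aggregation maps compartment splits onto merged reactions and keeps steady state", {
  net <- build_lemna_core("B", "INS")
  A <- aggregation_map(net)
  # duplicated reactions combine: 30 + 98.1 -> 128.1
  v <- stats::setNames(rep(0, length(net$reactions)), names(net$reactions))
  v["vG6PDH_c"] <- 30; v["vG6PDH_p"] <- 98.1
  expect_equal(as.numeric((A %*% v)["vG6PDH", ]), 128.1)
  # transporters map to all-zero rows
  for (tp in c("vG6Pt", "vTPt", "vPEPt", "vPGAt")) {
    expect_true(tp %in% rownames(A))
    expect_equal(sum(A[tp, ] != 0), 0)
  }
  # aggregated steady state: S_merged (A v) = 0 for any steady-state v
  sinks <- lemna_biomass_fluxes("INS")
  b <- steady_state_basis(net, extra_fixed = stats::setNames(sinks$mean, sinks$flux))
  Sm <- merged_stoich_matrix(net)
  set.seed(2)
  for (k in 1:5) {
    v <- b$expand(stats::rnorm(b$n_free_net, 0, 50))
    expect_lt(max(abs(Sm %*% (A %*% v))), 1e-8)
  }
})
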