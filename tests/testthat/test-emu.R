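test_that("EMU decomposition finds the minimal system on hand-enumerable toys", {
  lin <- toy_network("linear")
  sys <- emu_decompose(lin, list(list(metabolite = "B", positions = 1:2)))
  expect_equal(sys$n_emu, 2)   # B[1,2] and the substrate EMU A_x[1,2]
  # condensation toy: P[1:4] needs A[1,2], B[1,2] (substrates) and itself
  cnd <- toy_network("condense")
  sys2 <- emu_decompose(cnd, list(list(metabolite = "P", positions = 1:4)))
  expect_equal(sort(names(sys2$recs)),
               sort(c("P[1,2,3,4]", "A[1,2]", "B[1,2]", "X_x[1,2]", "Y_x[1,2]")))
  expect_error(emu_decompose(lin, list(list(metabolite = "B", positions = 1:3))),
               "carbons")
})

test_that("label conservation holds on a linear chain with positional labeling", {
  net <- toy_network("linear")
  fl <- flux_state(net, c(vIn = 10, vOut = 10))
  m <- simulate_mids(net, fl, list(A_x = pure_1c_label()),
                     targets = list(list(metabolite = "B", positions = 1:2,
                                         fragment_id = "B")))
  # position 1 carries pure 13C, position 2 natural abundance
  expect_equal(m$B, c(0, 0.989, 0.011), tolerance = 1e-12)
})

test_that("condensation products are convolutions of their precursors", {
  net <- toy_network("condense")
  fl <- flux_state(net, c(vInX = 10, vInY = 10, vC = 10, vOut = 10))
  labs <- list(X_x = pure_1c_label(),
               Y_x = substrate_label(list(list(fraction = 0.5, positions = 1:2,
                                               purity = 1),
                                          list(fraction = 0.5,
                                               positions = integer(0),
                                               purity = 1))))
  m <- simulate_mids(net, fl, labs,
                     targets = list(list(metabolite = "P", positions = 1:4,
                                         fragment_id = "P")))
  expected <- convolve_mid(label_mid(labs$X_x, 2), label_mid(labs$Y_x, 2))
  expect_equal(m$P, expected, tolerance = 1e-12)
})

test_that("unlabeled feeds give natural skeleton MIDs everywhere", {
  net <- toy_network("cyto")
  basis <- steady_state_basis(net)
  fl <- flux_state(net, basis$expand(10))
  m <- simulate_mids(net, fl, labels = list(), targets = cyto_targets())
  for (tg in cyto_targets()) {
    # binomial at the natural 13C abundance used for substrate labeling
    expected <- Reduce(convolve_mid,
                       rep(list(c(1 - 0.011, 0.011)), length(tg$positions)))
    expect_equal(m[[tg$fragment_id]], expected, tolerance = 1e-9)
  }
})

test_that("EMU and brute-force isotopomer solutions agree on random flux states", {
  net <- toy_network("cyto")
  basis <- steady_state_basis(net)
  labs <- list(Glc_x = glc_80_10_10())
  set.seed(11)
  for (rep in 1:5) {
    fl <- random_cyto_flux(basis, net)
    m <- simulate_mids(net, fl, labs, targets = cyto_targets())
    bf <- brute_force_isotopomers(net, fl, labs, tol = 1e-12)
    for (tg in cyto_targets()) {
      expect_lt(max(abs(m[[tg$fragment_id]] -
                          isotopomer_to_mid(bf[[tg$metabolite]], tg$positions))),
                1e-8)
    }
  }
})

test_that("brute force refuses oversized state spaces and is initialization-independent", {
  big <- parse_network(c(
    "# name big",
    "# metabolite X_x x 22 external",
    "# metabolite A c 22 balanced",
    "# metabolite P_x x 22 external",
    "# fixed vIn 10",
    paste0("vIn\tX_x#", paste(letters[1:22], collapse = ""),
           "\tA#", paste(letters[1:22], collapse = ""), "\tirr\t0\t100"),
    paste0("vOut\tA#", paste(letters[1:22], collapse = ""),
           "\tP_x#", paste(letters[1:22], collapse = ""), "\tirr\t0\t100")))
  fl_big <- flux_state(big, c(vIn = 10, vOut = 10))
  expect_error(brute_force_isotopomers(big, fl_big, list()), "2\\^20")
  toy <- toy_network("condense")
  fl <- flux_state(toy, c(vInX = 10, vInY = 10, vC = 10, vOut = 10))
  labs <- list(X_x = pure_1c_label())
  b1 <- brute_force_isotopomers(toy, fl, labs, tol = 1e-12)
  init <- lapply(b1, function(d) { x <- rep(1 / length(d), length(d)); x })
  b2 <- brute_force_isotopomers(toy, fl, labs, tol = 1e-12, init = init)
  for (m in names(b1)) expect_lt(max(abs(b1[[m]] - b2[[m]])), 1e-10)
})

test_that("MIDs are invariant under global flux scaling", {
  net <- toy_network("cyto")
  basis <- steady_state_basis(net)
  set.seed(3)
  fl <- random_cyto_flux(basis, net)
  fl2 <- flux_state(net, 7.3 * fl$net, 7.3 * fl$xch)
  labs <- list(Glc_x = glc_80_10_10())
  m1 <- simulate_mids(net, fl, labs, targets = cyto_targets())
  m2 <- simulate_mids(net, fl2, labs, targets = cyto_targets())
  for (id in names(m1)) expect_equal(m1[[id]], m2[[id]], tolerance = 1e-10)
})

test_that("exchange flux moves connected pools monotonically toward isotopic equilibrium", {
  net <- toy_network("twopool")
  labs <- list(X_x = pure_1c_label())   # A fed labeled, B fed unlabeled
  target <- list(list(metabolite = "B", positions = 1:2, fragment_id = "B"),
                 list(metabolite = "A", positions = 1:2, fragment_id = "A"))
  prev_gap <- Inf
  for (x in c(0, 1, 5, 25, 125, 625)) {
    fl <- flux_state(net, c(vInX = 10, vInY = 10, vAB = 0, vOutA = 10,
                            vOutB = 10), c(vAB = x))
    m <- simulate_mids(net, fl, labs, targets = target)
    gap <- abs(average_enrichment(m$A) - average_enrichment(m$B))
    expect_lte(gap, prev_gap + 1e-12)
    prev_gap <- gap
  }
  expect_lt(prev_gap, 0.05)   # near-complete mixing at high exchange
})

test_that("13C inflow equals 13C outflow at steady state", {
  net <- toy_network("cyto")
  basis <- steady_state_basis(net)
  labs <- list(Glc_x = glc_80_10_10())
  set.seed(8)
  fl <- random_cyto_flux(basis, net)
  m <- simulate_mids(net, fl, labs, targets = cyto_targets())
  inflow <- fl$net[["vIn"]] * 6 * label_enrichment(labs$Glc_x, 6)
  outflow <- fl$net[["vPGAout"]] * 3 * average_enrichment(m$PGA) +
    fl$net[["vP5Pout"]] * 5 * average_enrichment(m$P5P) +
    fl$net[["vCO2out"]] * m$CO2[2]
  expect_equal(inflow, outflow, tolerance = 1e-9 * inflow)
})

test_that("fumarate-symmetric scrambling mixes the symmetric carbon pairs", {
  # succinate-symmetric step: KG -> OAA with 50:50 scrambling via the paired
  # fumarase routes; positional label on OAA C1 must appear equally on C4
  txt <- c("# name scr",
           "# metabolite KG_x x 5 external",
           "# metabolite Suc c 4 balanced",
           "# metabolite OAA c 4 balanced",
           "# metabolite P_x x 4 external",
           "# metabolite CO2_x x 1 external",
           "# fixed vIn 10",
           "# ratio vF1 vF2 1",
           "vIn\tKG_x#abcde\tSuc#bcde + CO2_x#a\tirr\t0\t100",
           "vF1\tSuc#abcd\tOAA#abcd\tirr\t0\t100",
           "vF2\tSuc#abcd\tOAA#dcba\tirr\t0\t100",
           "vOut\tOAA#abcd\tP_x#abcd\tirr\t0\t100")
  net <- parse_network(txt)
  basis <- steady_state_basis(net)
  fl <- flux_state(net, basis$expand(numeric(basis$n_free_net)))
  # label KG at C2 only -> Suc C1 -> OAA C1 or C4 equally
  lab <- substrate_label(list(list(fraction = 1, positions = 2L, purity = 1)))
  m <- simulate_mids(net, fl, list(KG_x = lab),
                     targets = list(list(metabolite = "OAA", positions = 1,
                                         fragment_id = "O1"),
                                    list(metabolite = "OAA", positions = 4,
                                         fragment_id = "O4")))
  # each terminal carbon is the labeled KG C2 half the time and a
  # natural-abundance carbon the other half
  expect_equal(m$O1[2], 0.5 + 0.5 * 0.011, tolerance = 1e-9)
  expect_equal(m$O4[2], 0.5 + 0.5 * 0.011, tolerance = 1e-9)
})

test_that("zero-flux subnetworks feeding a target raise a diagnostic naming the EMU", {
  net <- toy_network("twopool")
  fl <- flux_state(net, c(vInX = 10, vInY = 0, vAB = -0, vOutA = 10, vOutB = 0))
  # B receives nothing: vInY = 0, vAB net 0, no exchange
  expect_error(
    simulate_mids(net, fl, list(X_x = pure_1c_label()),
                  targets = list(list(metabolite = "B", positions = 1:2,
                                      fragment_id = "B"))),
    "B\\[1,2\\]")
})
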