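#' Reduced central-metabolism reference network for Lemna gibba
#'
#' Builds the compartmentalized atom-transition model of duckweed central
#' carbon metabolism used throughout this package: cytosolic and plastidic
#' glycolysis and pentose-phosphate pathway (oxidative and regenerative steps
#' duplicated in both compartments, since duckweeds lack the xylulose
#' 5-phosphate translocator), hexose/triose/PEP/PGA phosphate translocators,
#' the Calvin-Benson-Bassham cycle with RuBisCO carboxylation and oxygenation
#' plus lumped photorespiration, the mitochondrial TCA cycle with a merged
#' OAA/Mal pool and 50:50 scrambling of the succinate/fumarate-symmetric
#' carbons, reversible PEP carboxylation (PEPC/PEPCK lumped), Gln uptake and
#' the Gln/Glu/2-oxoglutarate interconversions, explicit carbon skeletons for
#' the measured amino acids Val, Ile and Phe, and the 22 lumped biomass sink
#' fluxes. O2 is not tracked; oxygenation consumes RuBP only and is tied to
#' carboxylation by a fixed 1000:1 carboxylation:oxygenation ratio constraint
#' (photorespiration suppressed under photomixotrophy).
#'
#' Three CO2-pool configurations are available:
#' \describe{
#'   \item{A}{a single cellular CO2 pool used by RuBisCO and all other
#'     (de)carboxylations, with net CO2 efflux only — no uptake of
#'     atmospheric CO2 is possible.}
#'   \item{B}{adds a separate `CO2_RBC` pool that supplies RuBisCO, with
#'     independent atmospheric uptake and release reactions and a reversible
#'     exchange with the cellular CO2 pool.}
#'   \item{C}{configuration B plus measurement slots for the uptake fluxes
#'     `vGlc_up`, `vGln_up`, `vCO2_up`, i.e. these rates enter the fit as
#'     flux measurements.}
#' }
#'
#' @param co2_mode `"A"`, `"B"` or `"C"` (see Details).
#' @param nitrogen_mode `"INS"` (inorganic nitrogen: the Gln feed is fixed at
#'   zero) or `"ONS"` (organic nitrogen: Gln uptake is free/measured).
#' @return an `mfa_network`.
#' @export
build_lemna_core <- function(co2_mode = c("B", "A", "C"),
                             nitrogen_mode = c("INS", "ONS")) {
  co2_mode <- match.arg(co2_mode)
  nitrogen_mode <- match.arg(nitrogen_mode)
  M <- function(id, comp, n, bal) sprintf("# metabolite %s %s %d %s", id, comp, n,
                                          if (bal) "balanced" else "external")
  mets <- c(
    M("Glc_x", "x", 6, FALSE), M("Gln_x", "x", 5, FALSE),
    M("CO2atm_x", "x", 1, FALSE), M("CO2out_x", "x", 1, FALSE),
    M("G6P_c", "c", 6, TRUE), M("F6P_c", "c", 6, TRUE), M("TP_c", "c", 3, TRUE),
    M("PGA_c", "c", 3, TRUE), M("PEP_c", "c", 3, TRUE), M("Pyr_c", "c", 3, TRUE),
    M("P5P_c", "c", 5, TRUE), M("E4P_c", "c", 4, TRUE), M("S7P_c", "c", 7, TRUE),
    M("G6P_p", "p", 6, TRUE), M("F6P_p", "p", 6, TRUE), M("TP_p", "p", 3, TRUE),
    M("PGA_p", "p", 3, TRUE), M("PEP_p", "p", 3, TRUE), M("Pyr_p", "p", 3, TRUE),
    M("P5P_p", "p", 5, TRUE), M("E4P_p", "p", 4, TRUE), M("S7P_p", "p", 7, TRUE),
    M("RuBP_p", "p", 5, TRUE), M("PG2_p", "p", 2, TRUE), M("AcCoA_p", "p", 2, TRUE),
    M("Pyr_m", "m", 3, TRUE), M("AcCoA_m", "m", 2, TRUE), M("Cit_m", "m", 6, TRUE),
    M("KG_m", "m", 5, TRUE), M("Suc_m", "m", 4, TRUE),
    M("OAAx", "merged", 4, TRUE), M("CO2", "merged", 1, TRUE),
    M("Gln_c", "c", 5, TRUE), M("Glu_c", "c", 5, TRUE),
    M("Val_c", "c", 5, TRUE), M("Ile_c", "c", 6, TRUE), M("Phe_c", "c", 9, TRUE),
    if (co2_mode != "A") M("CO2_RBC", "p", 1, TRUE),
    # biomass sink pools (external, unbalanced)
    M("Ala_bm", "x", 3, FALSE), M("Glu_bm", "x", 5, FALSE),
    M("Gln_bm", "x", 5, FALSE), M("Ser_bm", "x", 3, FALSE),
    M("Gly_bm", "x", 2, FALSE), M("C1_bm", "x", 1, FALSE),
    M("His_bm", "x", 5, FALSE), M("Phe_bm", "x", 9, FALSE),
    M("Tyr_bm", "x", 9, FALSE), M("Val_bm", "x", 5, FALSE),
    M("Leu_bm", "x", 6, FALSE), M("Ile_bm", "x", 6, FALSE),
    M("Thr_bm", "x", 4, FALSE), M("Asx_bm", "x", 4, FALSE),
    M("Lys_bm", "x", 6, FALSE), M("Glyc_bm", "x", 3, FALSE),
    M("FA_bm", "x", 2, FALSE), M("GlcF_bm", "x", 6, FALSE),
    M("Cit_bm", "x", 6, FALSE), M("Mal_bm", "x", 4, FALSE),
    M("Fruc_bm", "x", 6, FALSE), M("St_bm", "x", 6, FALSE),
    M("CW_bm", "x", 6, FALSE)
  )
  R <- function(id, educts, products, rev = FALSE, lb = NULL, ub = 2000) {
    if (is.null(lb)) lb <- if (rev) -2000 else 0
    paste(id, educts, products, if (rev) "rev" else "irr", lb, ub, sep = "\t")
  }
  co2_rbc <- if (co2_mode == "A") "CO2#f" else "CO2_RBC#f"
  rxns <- c(
    # substrate uptakes
    R("vGlc_up", "Glc_x#abcdef", "G6P_c#abcdef"),
    R("vGln_up", "Gln_x#abcde", "Gln_c#abcde"),
    # glycolysis, cytosol
    R("vPGI_c", "G6P_c#abcdef", "F6P_c#abcdef", rev = TRUE),
    R("vALD_c", "F6P_c#abcdef", "TP_c#cba + TP_c#def", rev = TRUE),
    R("vGAPDH_c", "TP_c#abc", "PGA_c#abc", rev = TRUE),
    R("vENO_c", "PGA_c#abc", "PEP_c#abc", rev = TRUE),
    R("vPK_c", "PEP_c#abc", "Pyr_c#abc"),
    # glycolysis, plastid
    R("vPGI_p", "G6P_p#abcdef", "F6P_p#abcdef", rev = TRUE),
    R("vALD_p", "F6P_p#abcdef", "TP_p#cba + TP_p#def", rev = TRUE),
    R("vGAPDH_p", "TP_p#abc", "PGA_p#abc", rev = TRUE),
    R("vENO_p", "PGA_p#abc", "PEP_p#abc", rev = TRUE),
    R("vPK_p", "PEP_p#abc", "Pyr_p#abc"),
    # oxidative pentose phosphate pathway (duplicated c/p)
    R("vG6PDH_c", "G6P_c#abcdef", "P5P_c#bcdef + CO2#a"),
    R("vG6PDH_p", "G6P_p#abcdef", "P5P_p#bcdef + CO2#a"),
    # regenerative pentose phosphate reactions (duplicated c/p)
    R("vTK1_c", "P5P_c#abcde + P5P_c#fghij", "S7P_c#abfghij + TP_c#cde", rev = TRUE),
    R("vTA_c", "S7P_c#abcdefg + TP_c#hij", "E4P_c#defg + F6P_c#abchij", rev = TRUE),
    R("vTK2_c", "P5P_c#abcde + E4P_c#fghi", "F6P_c#abfghi + TP_c#cde", rev = TRUE),
    R("vTK1_p", "P5P_p#abcde + P5P_p#fghij", "S7P_p#abfghij + TP_p#cde", rev = TRUE),
    R("vTA_p", "S7P_p#abcdefg + TP_p#hij", "E4P_p#defg + F6P_p#abchij", rev = TRUE),
    R("vTK2_p", "P5P_p#abcde + E4P_p#fghi", "F6P_p#abfghi + TP_p#cde", rev = TRUE),
    # phosphate translocators (no pentose-phosphate translocator)
    R("vG6Pt", "G6P_c#abcdef", "G6P_p#abcdef", rev = TRUE),
    R("vTPt", "TP_c#abc", "TP_p#abc", rev = TRUE),
    R("vPEPt", "PEP_c#abc", "PEP_p#abc", rev = TRUE),
    R("vPGAt", "PGA_c#abc", "PGA_p#abc", rev = TRUE),
    # Calvin-Benson-Bassham cycle
    R("vPRK", "P5P_p#abcde", "RuBP_p#abcde"),
    R("vRBC", paste0("RuBP_p#abcde + ", co2_rbc), "PGA_p#cde + PGA_p#fba"),
    R("vRBO", "RuBP_p#abcde", "PGA_p#cde + PG2_p#ba", ub = 10),
    R("vPR", "PG2_p#ab + PG2_p#cd", "PGA_p#abd + CO2#c", ub = 10),
    # pyruvate branch
    R("vPyrT_cm", "Pyr_c#abc", "Pyr_m#abc"),
    R("vPDH_m", "Pyr_m#abc", "AcCoA_m#bc + CO2#a"),
    R("vPDH_p", "Pyr_p#abc", "AcCoA_p#bc + CO2#a"),
    # TCA cycle (mitochondrial; merged OAA/Mal pool)
    R("vCS", "OAAx#abcd + AcCoA_m#ef", "Cit_m#dcbfea"),
    R("vIDH", "Cit_m#abcdef", "KG_m#abcde + CO2#f"),
    R("vKGDH", "KG_m#abcde", "Suc_m#bcde + CO2#a"),
    R("vFUM1", "Suc_m#abcd", "OAAx#abcd"),
    R("vFUM2", "Suc_m#abcd", "OAAx#dcba"),
    # anaplerosis: PEPC forward / PEPCK backward, lumped reversible
    R("vPEPC", "PEP_c#abc + CO2#d", "OAAx#abcd", rev = TRUE),
    # glutamine / glutamate entry
    R("vGlnGlu", "Gln_c#abcde", "Glu_c#abcde", rev = TRUE),
    R("vGluKG", "Glu_c#abcde", "KG_m#abcde", rev = TRUE),
    # cellular CO2 efflux (present in every configuration)
    R("vCO2_out", "CO2#a", "CO2out_x#a"),
    if (co2_mode != "A") c(
      R("vCO2_up", "CO2atm_x#a", "CO2_RBC#a"),
      R("vCO2_rel", "CO2_RBC#a", "CO2out_x#a"),
      R("vCO2X", "CO2#a", "CO2_RBC#a", rev = TRUE)
    ),
    # amino-acid skeleton assembly for the measured analytes Val, Ile, Phe
    R("vValS", "Pyr_p#abc + Pyr_p#def", "Val_c#abecf + CO2#d"),
    R("vIleS", "OAAx#abcd + Pyr_c#efg", "Ile_c#abfcdg + CO2#e"),
    R("vPheS", "PEP_c#abc + PEP_c#def + E4P_c#ghij", "Phe_c#defbcghij + CO2#a"),
    # the 22 biomass sinks
    R("vAlaP", "Pyr_c#abc", "Ala_bm#abc"),
    R("vGluP", "Glu_c#abcde", "Glu_bm#abcde"),
    R("vGlnP", "Gln_c#abcde", "Gln_bm#abcde"),
    R("vSerP", "PGA_c#abc", "Ser_bm#abc"),
    R("vGlyP", "PGA_c#abc", "Gly_bm#ab + C1_bm#c"),
    R("vHisP", "P5P_c#abcde", "His_bm#abcde"),
    R("vPheP", "Phe_c#abcdefghi", "Phe_bm#abcdefghi"),
    R("vTyrP", "PEP_c#abc + PEP_c#def + E4P_c#ghij", "Tyr_bm#defbcghij + CO2#a"),
    R("vValP", "Val_c#abcde", "Val_bm#abcde"),
    R("vLeuP", "Pyr_p#abc + Pyr_p#def + AcCoA_p#gh", "Leu_bm#ghbecf + CO2#a + CO2#d"),
    R("vIleP", "Ile_c#abcdef", "Ile_bm#abcdef"),
    R("vThrP", "OAAx#abcd", "Thr_bm#abcd"),
    R("vAsxP", "OAAx#abcd", "Asx_bm#abcd"),
    R("vLysP", "OAAx#abcd + Pyr_c#efg", "Lys_bm#abcdfg + CO2#e"),
    R("vGlyc_out", "TP_c#abc", "Glyc_bm#abc"),
    R("vFASp", "AcCoA_p#ab", "FA_bm#ab"),
    R("vGlc_out", "G6P_c#abcdef", "GlcF_bm#abcdef"),
    R("vCit_out", "Cit_m#abcdef", "Cit_bm#abcdef"),
    R("vMal_out", "OAAx#abcd", "Mal_bm#abcd"),
    R("vFruc_out", "F6P_c#abcdef", "Fruc_bm#abcdef"),
    R("vSt_out", "G6P_p#abcdef", "St_bm#abcdef"),
    R("vHPc_out", "G6P_c#abcdef", "CW_bm#abcdef")
  )
  header <- c(sprintf("# name lemna_core_%s_%s", co2_mode, nitrogen_mode),
              "# ratio vRBC vRBO 1000",
              "# ratio vFUM1 vFUM2 1",
              if (nitrogen_mode == "INS") "# fixed vGln_up 0",
              if (co2_mode == "C")
                paste("# measured", c("vGlc_up", "vGln_up", "vCO2_up")))
  parse_network(c(header, mets, rxns))
}

.strip_comp <- function(id) sub("_(c|p|m)$", "", id)

#' Linear-combination map onto the uncompartmentalized network view
#'
#' Subcellular splits of parallel pathways (cytosolic vs plastidic glycolysis
#' and pentose-phosphate reactions, plastidic vs mitochondrial pyruvate
#' dehydrogenase) are often poorly resolved by labeling data. This map adds
#' the fluxes of reactions that connect the same metabolite pair in different
#' compartments into one merged reaction, and maps transport reactions
#' between merged pools to all-zero rows. Applied to any steady-state flux
#' vector it yields a steady-state vector on the merged network.
#'
#' @param network an `mfa_network` (typically from [build_lemna_core()]).
#' @return matrix (aggregated reactions x reactions) of 0/1 coefficients,
#'   with aggregated names as row names; transporter rows are all zero.
#' @export
aggregation_map <- function(network) {
  rids <- names(network$reactions)
  is_transport <- vapply(network$reactions, function(r) {
    length(r$educts) == 1L && length(r$products) == 1L &&
      .strip_comp(r$educts[[1]]$met) == .strip_comp(r$products[[1]]$met) &&
      r$educts[[1]]$met != r$products[[1]]$met
  }, logical(1))
  family <- ifelse(is_transport, rids, .strip_comp(rids))
  fams <- unique(family)
  A <- matrix(0, length(fams), length(rids), dimnames = list(fams, rids))
  for (i in seq_along(rids)) {
    if (!is_transport[i]) A[family[i], rids[i]] <- 1
  }
  A
}

#' Merged-network stoichiometric matrix matching [aggregation_map()]
#'
#' @param network an `mfa_network`.
#' @return matrix (merged balanced metabolites x aggregated reactions) such
#'   that `S_merged %*% (aggregation_map(net) %*% v) == 0` for every
#'   steady-state `v`.
#' @export
merged_stoich_matrix <- function(network) {
  S <- stoich_matrix(network)
  met_group <- .strip_comp(rownames(S))
  Sm <- rowsum(S, met_group)
  A <- aggregation_map(network)
  rids <- colnames(S)
  is_agg <- colSums(A != 0) > 0   # transporters have all-zero columns? no: rows
  # map reaction columns onto aggregated columns
  out <- matrix(0, nrow(Sm), nrow(A), dimnames = list(rownames(Sm), rownames(A)))
  for (f in rownames(A)) {
    members <- rids[A[f, ] != 0]
    if (!length(members)) next    # transporter: zero column
    out[, f] <- Sm[, members[1]]  # identical merged stoichiometry by construction
  }
  out
}

#' Toy networks used in examples and verification
#'
#' `toy_network("linear")`: a 2-carbon chain A -> B -> C.
#' `toy_network("diamond")`: one split and one merge with an atom swap on one
#' branch (exactly one free net flux once the feed is fixed).
#' `toy_network("condense")`: two independently labeled 2-carbon feeds
#' condensing into a 4-carbon product (closed-form convolution check).
#' `toy_network("twopool")`: two pools connected by a reversible reaction with
#' differently labeled feeds (exchange-flux equilibration check).
#' `toy_network("cyto")`: a single-compartment glycolysis + pentose-phosphate
#' subnetwork small enough for full-isotopomer enumeration.
#'
#' @param which toy name.
#' @return an `mfa_network`.
#' @export
toy_network <- function(which = c("linear", "diamond", "condense", "twopool", "cyto")) {
  which <- match.arg(which)
  txt <- switch(which,
    linear = c(
      "# name toy_linear",
      "# metabolite A_x x 2 external",
      "# metabolite B c 2 balanced",
      "# metabolite C_x x 2 external",
      "# fixed vIn 10",
      "vIn\tA_x#ab\tB#ab\tirr\t0\t100",
      "vOut\tB#ab\tC_x#ab\tirr\t0\t100"),
    diamond = c(
      "# name toy_diamond",
      "# metabolite S_x x 2 external",
      "# metabolite A c 2 balanced",
      "# metabolite B c 2 balanced",
      "# metabolite C c 2 balanced",
      "# metabolite D c 2 balanced",
      "# metabolite P_x x 2 external",
      "# fixed vIn 10",
      "vIn\tS_x#ab\tA#ab\tirr\t0\t100",
      "v1\tA#ab\tB#ab\tirr\t0\t100",
      "v2\tA#ab\tC#ba\tirr\t0\t100",
      "v3\tB#ab\tD#ab\tirr\t0\t100",
      "v4\tC#ab\tD#ab\tirr\t0\t100",
      "vOut\tD#ab\tP_x#ab\tirr\t0\t100"),
    condense = c(
      "# name toy_condense",
      "# metabolite X_x x 2 external",
      "# metabolite Y_x x 2 external",
      "# metabolite A c 2 balanced",
      "# metabolite B c 2 balanced",
      "# metabolite P c 4 balanced",
      "# metabolite Q_x x 4 external",
      "# fixed vInX 10",
      "# fixed vInY 10",
      "vInX\tX_x#ab\tA#ab\tirr\t0\t100",
      "vInY\tY_x#ab\tB#ab\tirr\t0\t100",
      "vC\tA#ab + B#cd\tP#abcd\tirr\t0\t100",
      "vOut\tP#abcd\tQ_x#abcd\tirr\t0\t100"),
    twopool = c(
      "# name toy_twopool",
      "# metabolite X_x x 2 external",
      "# metabolite Y_x x 2 external",
      "# metabolite A c 2 balanced",
      "# metabolite B c 2 balanced",
      "# metabolite P_x x 2 external",
      "# metabolite Q_x x 2 external",
      "# fixed vInX 10",
      "# fixed vInY 10",
      "# fixed vOutA 10",
      "vInX\tX_x#ab\tA#ab\tirr\t0\t100",
      "vInY\tY_x#ab\tB#ab\tirr\t0\t100",
      "vAB\tA#ab\tB#ab\trev\t-100\t100",
      "vOutA\tA#ab\tP_x#ab\tirr\t0\t100",
      "vOutB\tB#ab\tQ_x#ab\tirr\t0\t100"),
    cyto = c(
      "# name toy_cyto",
      "# metabolite Glc_x x 6 external",
      "# metabolite G6P c 6 balanced",
      "# metabolite F6P c 6 balanced",
      "# metabolite TP c 3 balanced",
      "# metabolite PGA c 3 balanced",
      "# metabolite P5P c 5 balanced",
      "# metabolite E4P c 4 balanced",
      "# metabolite S7P c 7 balanced",
      "# metabolite CO2 c 1 balanced",
      "# metabolite PGA_x x 3 external",
      "# metabolite P5P_x x 5 external",
      "# metabolite CO2_x x 1 external",
      "# fixed vIn 100",
      "# fixed vP5Pout 20",
      "vIn\tGlc_x#abcdef\tG6P#abcdef\tirr\t0\t1000",
      "vPGI\tG6P#abcdef\tF6P#abcdef\trev\t-1000\t1000",
      "vALD\tF6P#abcdef\tTP#cba + TP#def\trev\t-1000\t1000",
      "vGAPDH\tTP#abc\tPGA#abc\trev\t-1000\t1000",
      "vG6PDH\tG6P#abcdef\tP5P#bcdef + CO2#a\tirr\t0\t1000",
      "vTK1\tP5P#abcde + P5P#fghij\tS7P#abfghij + TP#cde\trev\t-1000\t1000",
      "vTA\tS7P#abcdefg + TP#hij\tE4P#defg + F6P#abchij\trev\t-1000\t1000",
      "vTK2\tP5P#abcde + E4P#fghi\tF6P#abfghi + TP#cde\trev\t-1000\t1000",
      "vPGAout\tPGA#abc\tPGA_x#abc\tirr\t0\t1000",
      "vP5Pout\tP5P#abcde\tP5P_x#abcde\tirr\t0\t1000",
      "vCO2out\tCO2#a\tCO2_x#a\tirr\t0\t1000")
  )
  parse_network(txt)
}
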