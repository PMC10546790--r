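#' Default GC-MS fragment panel (27 fragments from 16 analytes)
#'
#' A documented stand-in panel with the structure of the labeling
#' measurements used for flux fitting: proteinogenic amino acids (TBDMS
#' derivatives, typically the \[M-57\] and \[M-85\]-type fragments), glucose
#' units from hydrolyzed starch and cell wall, sucrose glucosyl/fructosyl
#' moieties, the lipid glycerol moiety, and the fatty-acid C1-C2 unit (only
#' the carboxyl-end two carbons of fatty acids carry usable labeling
#' information after hydrogenation). Each fragment maps to a model metabolite
#' and carbon subset; derivative formulas are representative elemental
#' compositions used for natural-isotope correction.
#'
#' @return list of [fragment_spec()] of length 27 covering 16 analytes.
#' @export
panel_default <- function() {
  F <- fragment_spec
  list(
    F("Ala_M57",  "Ala", "Pyr_c", 1:3, "C8H24NO2Si2"),
    F("Ala_M85",  "Ala", "Pyr_c", 2:3, "C8H24NOSi2"),
    F("Gly_M57",  "Gly", "PGA_c", 1:2, "C8H24NO2Si2"),
    F("Gly_M85",  "Gly", "PGA_c", 2,   "C8H24NOSi2"),
    F("Ser_M57",  "Ser", "PGA_c", 1:3, "C14H38NO3Si3"),
    F("Ser_M85",  "Ser", "PGA_c", 2:3, "C14H38NO2Si3"),
    F("Asp_M57",  "Asp", "OAAx",  1:4, "C14H38NO4Si3"),
    F("Asp_M85",  "Asp", "OAAx",  2:4, "C14H38NO3Si3"),
    F("Asp_f302", "Asp", "OAAx",  1:2, "C10H26NO2Si2"),
    F("Thr_M57",  "Thr", "OAAx",  1:4, "C14H38NO3Si3"),
    F("Thr_M85",  "Thr", "OAAx",  2:4, "C14H38NO2Si3"),
    F("Glu_M57",  "Glu", "Glu_c", 1:5, "C14H38NO4Si3"),
    F("Glu_M85",  "Glu", "Glu_c", 2:5, "C14H38NO3Si3"),
    F("Gln_M57",  "Gln", "Gln_c", 1:5, "C14H39N2O3Si3"),
    F("Gln_M85",  "Gln", "Gln_c", 2:5, "C14H39N2O2Si3"),
    F("Phe_M57",  "Phe", "Phe_c", 1:9, "C8H24NO2Si2"),
    F("Phe_f302", "Phe", "Phe_c", 1:2, "C10H26NO2Si2"),
    F("Val_M57",  "Val", "Val_c", 1:5, "C8H24NO2Si2"),
    F("Val_M85",  "Val", "Val_c", 2:5, "C8H24NOSi2"),
    F("Ile_M57",  "Ile", "Ile_c", 1:6, "C8H24NO2Si2"),
    F("Ile_M85",  "Ile", "Ile_c", 2:6, "C8H24NOSi2"),
    F("Glc_st",   "starch_glucose",    "G6P_p", 1:6, "C7H12O7"),
    F("Glc_cw",   "cellwall_glucose",  "G6P_c", 1:6, "C7H12O7"),
    F("Suc_glc",  "sucrose_glucosyl",  "G6P_c", 1:6, "C9H25O6Si3"),
    F("Suc_fru",  "sucrose_fructosyl", "F6P_c", 1:6, "C9H25O6Si3"),
    F("Glyc_tfa", "glycerol",          "TP_c",  1:3, "C6H5F9O6"),
    F("FA_c12",   "fatty_acid_C2",     "AcCoA_p", 1:2, "C1H6O2")
  )
}

#' Default substrate labeling of the flux experiments
#'
#' Medium glucose is a 80:10:10 (mol/mol) mixture of unlabeled,
#' \[1-13C\]- and \[U-13C6\]-glucose (99 atom-% 13C); medium Gln and
#' atmospheric CO2 are unlabeled (natural abundance).
#'
#' @return named list of [substrate_label()] keyed by feed metabolite.
#' @export
default_labels <- function() {
  list(
    Glc_x = substrate_label(list(
      list(fraction = 0.8, positions = integer(0)),
      list(fraction = 0.1, positions = 1L, purity = 0.99),
      list(fraction = 0.1, positions = 1:6, purity = 0.99)
    ))
    # Gln_x and CO2atm_x default to natural abundance
  )
}

#' Scenario preset for synthetic labeling experiments
#'
#' Bundles the experimental design of one growth condition: measured uptake
#' rates, the 22 measured biomass sink fluxes, the substrate labeling, the
#' measurement noise model (Gaussian, SD 0.01 on the fractional scale,
#' matching the SD floor used in fitting), and the unlabeled-inoculum
#' fraction (0.033).
#'
#' @param name `"INS"` or `"ONS"`.
#' @param noise_sd Gaussian measurement noise SD on MID fractions.
#' @param f_inoculum unlabeled inoculum mass fraction in harvested biomass.
#' @return a `scenario_preset` list.
#' @export
scenario_preset <- function(name = c("INS", "ONS"), noise_sd = 0.01,
                            f_inoculum = 0.033) {
  name <- match.arg(name)
  phys <- lemna_physiology(name)
  sinks <- lemna_biomass_fluxes(name)
  structure(list(
    name = name,
    uptakes = data.frame(
      reaction = c("vGlc_up", "vGln_up", "vCO2_up"),
      value = c(phys$vGlc_up[1], phys$vGln_up[1], phys$vCO2_up[1]),
      sd = c(phys$vGlc_up[2], max(phys$vGln_up[2], 1e-6), phys$vCO2_up[2])),
    sinks = stats::setNames(sinks$mean, sinks$flux),
    sink_sds = stats::setNames(sinks$sd, sinks$flux),
    labels = default_labels(),
    noise_sd = noise_sd,
    f_inoculum = f_inoculum
  ), class = "scenario_preset")
}

#' Ground-truth flux state for a scenario preset
#'
#' Constructs a steady-state flux vector on the reference network that
#' reproduces the preset's measured anchors exactly (uptake rates and the 22
#' biomass sink fluxes are fixed at their printed values) and places the
#' remaining free net fluxes at documented operating-point targets by least
#' squares: combined oxidative pentose-phosphate flux at 0.60 of RuBisCO
#' carboxylation, PEP carboxylation running forward under INS and reversed
#' (decarboxylating) under ONS, and — for networks with a separate RuBisCO
#' CO2 pool — an atmospheric share of the RuBisCO CO2 supply of 0.58 (INS)
#' or 0.60 (ONS). Exchange fluxes are drawn from a seeded uniform range,
#' except the CO2-pool exchange, which is set to realize the atmospheric
#' share exactly.
#'
#' @param preset a [scenario_preset()].
#' @param network an `mfa_network` from [build_lemna_core()].
#' @param seed integer seed for the exchange-flux draw.
#' @return a [flux_state()] satisfying `S v = 0` to 1e-9.
#' @export
truth_flux <- function(preset, network, seed = 1L) {
  has_rbc <- "CO2_RBC" %in% names(network$metabolites)
  fixed <- preset$sinks
  fixed["vGlc_up"] <- preset$uptakes$value[preset$uptakes$reaction == "vGlc_up"]
  fixed["vGln_up"] <- preset$uptakes$value[preset$uptakes$reaction == "vGln_up"]
  if (has_rbc)
    fixed["vCO2_up"] <- preset$uptakes$value[preset$uptakes$reaction == "vCO2_up"]
  basis <- steady_state_basis(network, extra_fixed = fixed)
  # operating-point anchors for the free interior fluxes
  oppp <- if (preset$name == "INS") c(c = 30, p = 98.1) else c(c = 40, p = 101.4)
  vrbc <- sum(oppp) / 0.60
  anchors <- c(vG6PDH_c = unname(oppp["c"]), vG6PDH_p = unname(oppp["p"]),
               vRBC = vrbc,
               vPEPC = if (preset$name == "INS") 15 else -20,
               vG6Pt = 60, vTPt = -20, vPGAt = 10, vPK_c = 20,
               if (has_rbc) c(vCO2X = 60))
  anchors <- anchors[names(anchors) %in% basis$reactions]
  C <- matrix(0, length(anchors), length(basis$reactions))
  for (i in seq_along(anchors))
    C[i, match(names(anchors)[i], basis$reactions)] <- 1
  w <- rep(1, length(anchors))
  w[names(anchors) %in% c("vG6PDH_c", "vG6PDH_p", "vRBC", "vPEPC", "vCO2X")] <- 100
  M <- (w * C) %*% basis$N
  d <- w * (anchors - as.numeric(C %*% basis$v0))
  theta <- qr.coef(qr(M), d)
  theta[is.na(theta)] <- 0
  v <- basis$expand(theta)
  if (any(v < basis$lb - 1e-6) || any(v > basis$ub + 1e-6)) {
    bad <- basis$reactions[v < basis$lb - 1e-6 | v > basis$ub + 1e-6]
    stop("truth_flux: infeasible preset; bound violations at ",
         paste(bad, collapse = ", "))
  }
  set.seed(as.integer(seed))
  rev_ids <- reversible_reactions(network)
  xch <- stats::setNames(stats::runif(length(rev_ids), 5, 25), rev_ids)
  if (has_rbc) {
    # realize the atmospheric share of the RuBisCO CO2 supply exactly:
    # share = vCO2_up / (vCO2_up + fwd(vCO2X))
    share <- if (preset$name == "INS") 0.58 else 0.60
    fwd_needed <- fixed[["vCO2_up"]] * (1 - share) / share
    xch["vCO2X"] <- max(fwd_needed - max(v[["vCO2X"]], 0), 0)
  }
  flux_state(network, v, xch)
}

#' Atmospheric share of the RuBisCO CO2 supply
#'
#' In the forward/backward formulation, the fraction of the RuBisCO CO2 pool
#' that derives from atmospheric (unlabeled) CO2 rather than from cellular
#' decarboxylation: `uptake / (uptake + forward exchange inflow)`.
#'
#' @param flux a [flux_state()] on a network with the `CO2_RBC` pool.
#' @return fraction in `[0, 1]`.
#' @export
atmospheric_fraction <- function(flux) {
  if (!("vCO2_up" %in% names(flux$net)))
    stop("atmospheric_fraction: network has no separate RuBisCO CO2 pool (configuration A)")
  up <- max(flux$net[["vCO2_up"]], 0)
  fwd_x <- max(flux$net[["vCO2X"]], 0) + flux$xch[["vCO2X"]]
  up / (up + fwd_x)
}

#' Generate a noisy synthetic measurement set at a ground-truth flux
#'
#' Simulates the fragment MIDs of the panel at the ground truth, applies the
#' forward measurement model — mixing with the unlabeled-inoculum fraction,
#' then convolution with the natural isotopologue distribution of each
#' fragment's derivative formula — and adds seeded Gaussian noise (clipped at
#' zero, renormalized). The returned set carries both the raw mass
#' distributions and the corrected skeleton MIDs obtained by running the
#' corrections in reverse order (derivative deconvolution, then inoculum
#' correction), plus the uptake-rate flux measurements with their SDs.
#'
#' @param truth a [flux_state()].
#' @param network the `mfa_network` the truth lives on.
#' @param panel list of [fragment_spec()] (default [panel_default()]).
#' @param preset a [scenario_preset()].
#' @param seed integer seed for the measurement noise.
#' @return a `measurement_set`: list with `mids` (per fragment: `fragment`,
#'   `raw`, `corrected`, `sd`) and `fluxes` (data.frame reaction/value/sd).
#' @export
generate_measurements <- function(truth, network, panel = panel_default(),
                                  preset, seed = 1L) {
  sim <- simulate_mids(network, truth, preset$labels, targets = panel)
  set.seed(as.integer(seed))
  mids <- vector("list", length(panel))
  names(mids) <- vapply(panel, `[[`, character(1), "fragment_id")
  for (i in seq_along(panel)) {
    frag <- panel[[i]]
    skel <- sim[[frag$fragment_id]]
    mixed <- mix_inoculum(skel, preset$f_inoculum)
    raw <- convolve_mid(mixed, natural_mid(frag$derivative))
    if (preset$noise_sd > 0) {
      raw <- raw + stats::rnorm(length(raw), 0, preset$noise_sd)
      raw <- pmax(raw, 0)
      raw <- raw / sum(raw)
    }
    corr <- correct_derivative(raw, frag)
    corr <- correct_inoculum(corr, preset$f_inoculum)
    # propagate the raw-scale noise SD through the (linearized) corrections:
    # deconvolution amplifies noise by the conditioning of the correction
    # matrix, and the inoculum correction rescales by 1/(1 - f)
    sd_corr <- rep(preset$noise_sd, length(skel))
    if (preset$noise_sd > 0) {
      nat <- natural_mid(frag$derivative)
      if (length(nat) > 1L) {
        nr <- length(raw)
        C <- matrix(0, nr, length(skel))
        for (j in seq_along(skel)) {
          idx <- seq_len(length(nat)) + j - 1L
          keep <- idx <= nr
          C[idx[keep], j] <- nat[keep]
        }
        Ainv <- tryCatch(solve(crossprod(C), t(C)), error = function(e) NULL)
        if (!is.null(Ainv))
          sd_corr <- preset$noise_sd * sqrt(rowSums(Ainv^2))
      }
      sd_corr <- sd_corr / (1 - preset$f_inoculum)
    }
    mids[[i]] <- list(fragment = frag, raw = raw, corrected = corr,
                      sd = sd_corr)
  }
  fluxes <- preset$uptakes
  if (preset$noise_sd > 0) {
    fluxes$value <- stats::rnorm(nrow(fluxes), fluxes$value, fluxes$sd)
  }
  structure(list(mids = mids, fluxes = fluxes, preset_name = preset$name),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement_set: %d fragment MIDs, %d flux measurements (%s)\n",
              length(x$mids), nrow(x$fluxes), x$preset_name))
  invisible(x)
}

#' Write a measurement set to CSV files
#'
#' Emits `measurements_mid.csv` (fragment_id, analyte, metabolite,
#' skeleton_positions, derivative_formula, m0..mk, sd0..sdk of the corrected
#' skeleton MIDs) and `measurements_flux.csv` (reaction, value, sd).
#'
#' @param meas a `measurement_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_measurements <- function(meas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kmax <- max(vapply(meas$mids, function(m) length(m$corrected), integer(1)))
  rows <- lapply(meas$mids, function(m) {
    f <- m$fragment
    pad <- function(x) c(x, rep(NA, kmax - length(x)))
    c(list(fragment_id = f$fragment_id, analyte = f$analyte,
           metabolite = f$metabolite,
           skeleton_positions = paste(f$positions, collapse = ","),
           derivative_formula = f$derivative),
      stats::setNames(as.list(pad(m$corrected)), paste0("m", 0:(kmax - 1))),
      stats::setNames(as.list(pad(m$sd)), paste0("sd", 0:(kmax - 1))))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  p1 <- file.path(dir, "measurements_mid.csv")
  p2 <- file.path(dir, "measurements_flux.csv")
  utils::write.csv(df, p1, row.names = FALSE)
  utils::write.csv(meas$fluxes, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a measurement set from CSV files written by [write_measurements()]
#' @param dir directory containing the CSV pair.
#' @return a `measurement_set` (corrected MIDs only; `raw` set to NULL).
#' @export
read_measurements <- function(dir) {
  df <- utils::read.csv(file.path(dir, "measurements_mid.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  fluxes <- utils::read.csv(file.path(dir, "measurements_flux.csv"),
                            stringsAsFactors = FALSE)
  mids <- vector("list", nrow(df))
  names(mids) <- df$fragment_id
  mcols <- grep("^m[0-9]+$", names(df))
  scols <- grep("^sd[0-9]+$", names(df))
  for (i in seq_len(nrow(df))) {
    pos <- as.integer(strsplit(df$skeleton_positions[i], ",")[[1]])
    frag <- fragment_spec(df$fragment_id[i], df$analyte[i], df$metabolite[i],
                          pos, df$derivative_formula[i])
    v <- as.numeric(df[i, mcols]); v <- v[!is.na(v)]
    s <- as.numeric(df[i, scols]); s <- s[!is.na(s)]
    mids[[i]] <- list(fragment = frag, raw = NULL, corrected = v, sd = s)
  }
  structure(list(mids = mids, fluxes = fluxes, preset_name = NA_character_),
            class = "measurement_set")
}
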