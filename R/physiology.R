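#' Specific growth rate from frond area (or biomass) endpoints
#'
#' For an exponentially growing duckweed culture the specific growth rate is
#' estimated from two measurements of frond surface area (or any quantity
#' proportional to biomass): `mu = (ln At - ln A0) / t`.
#'
#' @param A0 initial frond area (cm^2), or initial biomass; must be > 0.
#' @param At final frond area (cm^2), or final biomass; must be > 0.
#' @param t culture time (h); must be > 0.
#' @return specific growth rate `mu` in h^-1.
#' @seealso [doubling_time()]
#' @examples
#' growth_rate(1.1, 34.1, 240)   # ~0.0143 h^-1
#' @export
growth_rate <- function(A0, At, t) {
  stopifnot(is.numeric(A0), is.numeric(At), is.numeric(t))
  if (any(A0 <= 0) || any(At <= 0) || any(t <= 0))
    stop("growth_rate: A0, At and t must all be positive")
  (log(At) - log(A0)) / t
}

#' Culture doubling time
#'
#' `t_d = ln(2) / mu`, the time for an exponentially growing culture to double.
#'
#' @param mu specific growth rate (h^-1), > 0.
#' @return doubling time in h.
#' @export
doubling_time <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("doubling_time: mu must be > 0")
  log(2) / mu
}

#' Specific substrate uptake rate from medium depletion
#'
#' For an exponentially growing culture the specific uptake rate of a medium
#' substrate is the depleted amount per unit of newly formed dry weight, scaled
#' by the specific growth rate: `v = (S - S0) / (D - D0) * mu`. Consumption is
#' reported as a positive rate (S is the remaining amount, S0 the initial one).
#'
#' @param S0 initial substrate amount in the vessel (umol).
#' @param S final substrate amount in the vessel (umol).
#' @param D0 initial culture dry weight (g).
#' @param D final culture dry weight (g); must exceed `D0`.
#' @param mu specific growth rate (h^-1).
#' @return specific uptake rate in umol g-dw^-1 h^-1 (positive = consumption).
#' @export
uptake_rate <- function(S0, S, D0, D, mu) {
  stopifnot(is.numeric(S0), is.numeric(S), is.numeric(D0), is.numeric(D))
  if (any(D <= D0)) stop("uptake_rate: final dry weight D must exceed D0")
  (S0 - S) / (D - D0) * mu
}

#' Fraction of the initial substrate pool depleted during culture
#'
#' Inverts the uptake-rate relation to express how much of the initially
#' supplied substrate was consumed: `fraction = v * (D - D0) / mu / S0`.
#' Used to verify that substrate supply stayed non-limiting (metabolic
#' steady-state assumption).
#'
#' @inheritParams uptake_rate
#' @param v specific uptake rate (umol g-dw^-1 h^-1).
#' @return depleted fraction of `S0` (0 = none consumed).
#' @export
depletion_fraction <- function(v, mu, D0, D, S0) {
  if (any(S0 <= 0)) stop("depletion_fraction: S0 must be > 0")
  if (any(D <= D0)) stop("depletion_fraction: D must exceed D0")
  v * (D - D0) / mu / S0
}

#' Biomass 13C enrichment expected from carbon-molar uptake fluxes
#'
#' Forward mixing relation: the fractional 13C enrichment of total biomass
#' carbon is the uptake-flux-weighted mean of the enrichments of all carbon
#' sources (glucose contributes 6 carbons per molecule, Gln 5, CO2 one):
#' `f = (6 vGlc e_glc + 5 vGln e_gln + vCO2 e_co2) / (6 vGlc + 5 vGln + vCO2)`.
#'
#' @param vGlc_up,vGln_up,vCO2_up uptake rates (umol g-dw^-1 h^-1).
#' @param e_glc 13C enrichment of medium glucose (fraction; 0.403 for the
#'   40:60 U-13C6:unlabeled design).
#' @param e_gln 13C enrichment of medium Gln (natural abundance by default).
#' @param e_co2 13C enrichment of atmospheric CO2 (natural abundance).
#' @return expected fractional 13C enrichment of biomass carbon.
#' @seealso [co2_uptake()], its exact inverse for `vCO2_up`.
#' @export
f13c_biomass <- function(vGlc_up, vGln_up, vCO2_up, e_glc = 0.403,
                         e_gln = 0.011, e_co2 = 0.011) {
  (6 * vGlc_up * e_glc + 5 * vGln_up * e_gln + vCO2_up * e_co2) /
    (6 * vGlc_up + 5 * vGln_up + vCO2_up)
}

#' Atmospheric CO2 uptake rate from biomass 13C enrichment
#'
#' Rearranges the carbon-source mixing relation ([f13c_biomass()]) for the CO2
#' uptake rate. With glucose as the only labeled carbon source, dilution of the
#' biomass 13C enrichment below the glucose enrichment quantifies the uptake of
#' unlabeled (natural-abundance) carbon:
#' `vCO2 = (6 vGlc (e_glc - f) + 5 vGln (e_nat - f)) / (f - e_nat)`.
#'
#' This is a gross uptake of external CO2, not the net CO2 balance: CO2 can be
#' taken up and released simultaneously.
#'
#' @param f13C_BM measured fractional 13C enrichment of total biomass carbon;
#'   must lie strictly between `e_nat` and `e_glc` for a positive solution.
#' @param vGlc_up,vGln_up measured uptake rates (umol g-dw^-1 h^-1).
#' @param e_glc 13C enrichment of medium glucose (fraction).
#' @param e_nat natural 13C abundance (default 0.011).
#' @return gross atmospheric CO2 uptake rate (umol g-dw^-1 h^-1).
#' @examples
#' co2_uptake(0.211, 102.3, 0)          # ~589 (nitrate-grown cultures)
#' co2_uptake(0.146, 80.3, 79.6)        # ~520 (Gln-grown cultures)
#' @export
co2_uptake <- function(f13C_BM, vGlc_up, vGln_up, e_glc = 0.403, e_nat = 0.011) {
  if (any(f13C_BM <= e_nat))
    stop("co2_uptake: biomass enrichment must exceed natural abundance (infeasible enrichment)")
  (6 * vGlc_up * (e_glc - f13C_BM) + 5 * vGln_up * (e_nat - f13C_BM)) /
    (f13C_BM - e_nat)
}

#' Resampling-based uncertainty for the CO2 uptake rate
#'
#' Gaussian-resamples the measured inputs of [co2_uptake()] (biomass
#' enrichment, glucose and Gln uptake rates) according to their means and
#' standard deviations, applies the rate equation to each draw, and returns the
#' sample mean and standard deviation. Draws with infeasible enrichment
#' (`f13C_BM <= e_nat`) are rejected and redrawn; their count is reported.
#'
#' @param means named list/vector with `f13C_BM`, `vGlc_up`, `vGln_up`.
#' @param sds matching standard deviations (>= 0).
#' @param n number of resampling draws (>= 2).
#' @param seed integer seed; the draw is reproducible.
#' @param e_glc,e_nat substrate/natural enrichments passed to [co2_uptake()].
#' @return list with `mean`, `sd`, `n`, `n_rejected` and the draws `values`.
#' @export
resample_co2_uptake <- function(means, sds, n = 10000, seed = 1L,
                                e_glc = 0.403, e_nat = 0.011) {
  stopifnot(n >= 2)
  means <- as.list(means); sds <- as.list(sds)
  need <- c("f13C_BM", "vGlc_up", "vGln_up")
  if (!all(need %in% names(means)) || !all(need %in% names(sds)))
    stop("resample_co2_uptake: means and sds must name f13C_BM, vGlc_up, vGln_up")
  if (any(unlist(sds[need]) < 0)) stop("resample_co2_uptake: sds must be >= 0")
  set.seed(as.integer(seed))
  vals <- numeric(n)
  n_rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      f <- stats::rnorm(1, means$f13C_BM, sds$f13C_BM)
      if (f > e_nat) break
      n_rejected <- n_rejected + 1L
      if (n_rejected > 1000L * n) stop("resample_co2_uptake: rejection rate too high")
    }
    vg <- stats::rnorm(1, means$vGlc_up, sds$vGlc_up)
    vq <- stats::rnorm(1, means$vGln_up, sds$vGln_up)
    vals[i] <- co2_uptake(f, vg, vq, e_glc = e_glc, e_nat = e_nat)
  }
  list(mean = mean(vals), sd = stats::sd(vals), n = n,
       n_rejected = n_rejected, values = vals)
}

# ---------------------------------------------------------------------------
# Biomass composition -> sink fluxes

#' Reference growth and uptake measurements for Lemna gibba cultures
#'
#' Endpoint physiology of photomixotrophic *Lemna gibba* cultures grown on
#' 100 mL medium with 5 g/L glucose under two nitrogen regimes: INS (inorganic
#' nitrogen, nitrate/ammonium) and ONS (organic nitrogen, 6.85 mM Gln).
#' Values are culture means with standard deviations (n = 3).
#'
#' Initial dry weights are not measured directly; they are reconstructed as
#' `A0 * (dw/area)`, consistent with the observation that the unlabeled
#' inoculum is about 3% of the final harvested dry weight.
#'
#' @param condition `"INS"` or `"ONS"`.
#' @return named list of physiological quantities (areas cm^2, time h, dry
#'   weights g, rates umol g-dw^-1 h^-1, enrichments as fractions), each a
#'   `c(mean, sd)` pair except derived scalars.
#' @export
lemna_physiology <- function(condition = c("INS", "ONS")) {
  condition <- match.arg(condition)
  ref <- list(
    INS = list(
      t = 240, A0 = c(1.1, 0.1), At = c(34.1, 3.5), D_mg = c(65.6, 3.5),
      dw_per_area = c(1.9, 0.1),              # mg/cm^2
      mu = c(0.014, 0.001), t_double = c(50.5, 2.0),
      f13C_BM = c(0.211, 0.011),
      vGlc_up = c(102.3, 4.3), vGln_up = c(0, 0), vCO2_up = c(589.7, 79.3),
      S0_glc = 5 / 180.16 * 0.1 * 1e6,        # umol glucose in 100 mL at 5 g/L
      S0_gln = 0
    ),
    ONS = list(
      t = 192, A0 = c(0.9, 0.1), At = c(27.2, 2.1), D_mg = c(68.1, 3.9),
      dw_per_area = c(2.5, 0.1),
      mu = c(0.019, 0.001), t_double = c(35.7, 1.0),
      f13C_BM = c(0.146, 0.001),
      vGlc_up = c(80.3, 2.5), vGln_up = c(79.6, 2.1), vCO2_up = c(521.8, 56.4),
      S0_glc = 5 / 180.16 * 0.1 * 1e6,
      S0_gln = 6.85e-3 * 0.1 * 1e6            # umol Gln in 100 mL at 6.85 mM
    )
  )[[condition]]
  ref$D0 <- ref$A0[1] * ref$dw_per_area[1] / 1000   # g, reconstructed
  ref$D <- ref$D_mg[1] / 1000                       # g
  ref$condition <- condition
  ref
}

#' Reference biomass sink fluxes (umol g-dw^-1 h^-1)
#'
#' The 22 lumped fluxes from central metabolism into biomass components for
#' the two nitrogen conditions, with standard deviations (n = 3). These are
#' the measured anchors used to constrain the flux model and to parameterize
#' synthetic ground truths.
#'
#' @param condition `"INS"` or `"ONS"`.
#' @return data.frame with columns `flux`, `mean`, `sd`.
#' @export
lemna_biomass_fluxes <- function(condition = c("INS", "ONS")) {
  condition <- match.arg(condition)
  flux <- c("vAlaP", "vGluP", "vGlnP", "vSerP", "vGlyP", "vHisP", "vPheP",
            "vTyrP", "vValP", "vLeuP", "vIleP", "vThrP", "vAsxP", "vLysP",
            "vGlyc_out", "vFASp", "vGlc_out", "vCit_out", "vMal_out",
            "vFruc_out", "vSt_out", "vHPc_out")
  ins <- c(2.92, 6.53, 3.00, 3.04, 1.99, 0.95, 2.26, 1.76, 2.28, 2.93, 1.50,
           2.50, 7.84, 2.20, 2.87, 48.43, 7.17, 5.46, 4.45, 1.74, 5.24, 26.17)
  ins_sd <- c(0.18, 0.26, 0.15, 0.32, 0.07, 0.03, 0.06, 0.05, 0.07, 0.09, 0.04,
              0.08, 0.64, 0.06, 0.05, 0.87, 0.66, 0.57, 0.48, 0.35, 0.61, 0.50)
  ons <- c(4.85, 10.99, 5.00, 4.49, 3.49, 1.65, 4.05, 3.15, 4.01, 5.24, 2.67,
           4.43, 11.88, 3.93, 3.36, 56.67, 10.90, 8.20, 7.18, 2.65, 6.24, 17.76)
  ons_sd <- c(0.20, 0.36, 0.17, 0.27, 0.15, 0.07, 0.18, 0.14, 0.16, 0.22, 0.11,
              0.18, 0.43, 0.17, 0.09, 1.48, 0.85, 0.55, 0.55, 0.24, 0.60, 0.86)
  if (condition == "INS") data.frame(flux = flux, mean = ins, sd = ins_sd)
  else data.frame(flux = flux, mean = ons, sd = ons_sd)
}

#' Default biomass composition consistent with the reference sink fluxes
#'
#' A shipped biomass composition (g component per g dry weight, with SDs) and
#' monomer specification sufficient to regenerate the 22 sink fluxes with
#' [biomass_fluxes()]. The cell wall fraction is accounted for as an
#' anhydroglucose polymer (monomer weight 162.14 g/mol), starch likewise,
#' lipid as triacylglycerol split into fatty-acyl C2 units and the glycerol
#' moiety, and protein via a default amino-acid weight composition
#' (duckweed-literature-average style; users may override). Free metabolites
#' are carried per sink. Fractions other than the cell wall are reconstructed
#' from the reference sink fluxes at the reference growth rate, so that
#' `biomass_fluxes(default_biomass_composition(cond), mu_ref)` reproduces
#' [lemna_biomass_fluxes()] for that condition.
#'
#' @param condition `"INS"` or `"ONS"`.
#' @return list with `fractions` (data.frame: component, g_per_g, sd) and
#'   `monomers` (data.frame: component, sink, mol_per_g).
#' @export
default_biomass_composition <- function(condition = c("INS", "ONS")) {
  condition <- match.arg(condition)
  phys <- lemna_physiology(condition)
  mu <- log(2) / phys$t_double[1]
  bf <- lemna_biomass_fluxes(condition)
  # monomer molecular weights (residue weights for polymers, g/mol)
  mw <- c(
    vAlaP = 89.09, vGluP = 147.13, vGlnP = 146.15, vSerP = 105.09,
    vGlyP = 75.07, vHisP = 155.16, vPheP = 165.19, vTyrP = 181.19,
    vValP = 117.15, vLeuP = 131.17, vIleP = 131.17, vThrP = 119.12,
    vAsxP = 133.10, vLysP = 146.19,
    vGlyc_out = 92.09, vFASp = 127,      # mean fatty-acyl weight per C2 unit
    vGlc_out = 180.16, vCit_out = 192.12, vMal_out = 134.09,
    vFruc_out = 180.16, vSt_out = 162.14, vHPc_out = 162.14
  )
  # component per sink; protein-family sinks grouped under one protein fraction
  protein_sinks <- c("vAlaP", "vGluP", "vGlnP", "vSerP", "vGlyP", "vHisP",
                     "vPheP", "vTyrP", "vValP", "vLeuP", "vIleP", "vThrP",
                     "vAsxP", "vLysP")
  comp_of <- function(s) {
    if (s %in% protein_sinks) "protein"
    else switch(s, vHPc_out = "cell_wall", vSt_out = "starch",
                vFASp = "lipid_acyl", vGlyc_out = "lipid_glycerol",
                s)  # free metabolite components keep the sink name
  }
  g_per_g_sink <- bf$mean * mw[bf$flux] / mu / 1e6   # per-sink mass fraction
  sd_sink <- bf$sd * mw[bf$flux] / mu / 1e6
  comp <- vapply(bf$flux, comp_of, character(1))
  fr <- stats::aggregate(list(g_per_g = g_per_g_sink), list(component = comp), sum)
  fr_sd <- stats::aggregate(list(sd = sd_sink),
                            list(component = comp),
                            function(x) sqrt(sum(x^2)))
  fractions <- merge(fr, fr_sd, by = "component")
  # monomer spec: mol monomer per g of its component
  monomers <- data.frame(
    component = comp, sink = bf$flux,
    mol_per_g = (bf$mean * mw[bf$flux]) /
      vapply(comp, function(cp) sum((bf$mean * mw[bf$flux])[comp == cp]),
             numeric(1)) / mw[bf$flux],
    stringsAsFactors = FALSE
  )
  list(fractions = fractions, monomers = monomers, condition = condition)
}

#' Sink fluxes from biomass composition and growth rate
#'
#' Converts a biomass composition (g component per g dry weight plus a monomer
#' specification) into the lumped fluxes from central metabolism into biomass:
#' for each sink, `flux = sum_over_components( g_per_g * mol_per_g ) * mu * 1e6`
#' in umol g-dw^-1 h^-1. Linear in `mu` and in every composition fraction.
#'
#' @param composition list as returned by [default_biomass_composition()]:
#'   `fractions` (component, g_per_g, sd) and `monomers`
#'   (component, sink, mol_per_g).
#' @param mu specific growth rate (h^-1).
#' @return data.frame with columns `flux`, `value`.
#' @export
biomass_fluxes <- function(composition, mu) {
  fr <- composition$fractions
  mono <- composition$monomers
  missing <- setdiff(mono$component, fr$component)
  if (length(missing))
    stop("biomass_fluxes: composition lacks component(s): ",
         paste(missing, collapse = ", "))
  g <- stats::setNames(fr$g_per_g, fr$component)
  val <- g[mono$component] * mono$mol_per_g * mu * 1e6
  out <- stats::aggregate(list(value = as.numeric(val)),
                          list(flux = mono$sink), sum)
  out[match(unique(mono$sink), out$flux), , drop = FALSE]
}

#' Resampling-based uncertainty of biomass sink fluxes
#'
#' Perturbs the composition fractions and the growth rate with Gaussian noise
#' according to their standard deviations, recomputes [biomass_fluxes()]
#' `n` times, and reports the per-flux mean and standard deviation. Negative
#' perturbed fractions are truncated at zero (and counted).
#'
#' @param composition as for [biomass_fluxes()] (fractions must carry `sd`).
#' @param mu_mean,mu_sd growth rate mean and SD (h^-1).
#' @param n number of repetitions (default 20).
#' @param seed integer seed.
#' @return data.frame `flux`, `mean`, `sd` plus attribute `n_truncated`.
#' @export
propagate_biomass_uncertainty <- function(composition, mu_mean, mu_sd,
                                          n = 20, seed = 1L) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  n_trunc <- 0L
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    comp_i <- composition
    g <- stats::rnorm(nrow(comp_i$fractions), comp_i$fractions$g_per_g,
                      comp_i$fractions$sd)
    n_trunc <- n_trunc + sum(g < 0)
    comp_i$fractions$g_per_g <- pmax(g, 0)
    mu_i <- stats::rnorm(1, mu_mean, mu_sd)
    draws[[i]] <- biomass_fluxes(comp_i, mu_i)$value
  }
  m <- do.call(cbind, draws)
  out <- data.frame(flux = biomass_fluxes(composition, mu_mean)$flux,
                    mean = rowMeans(m), sd = apply(m, 1, stats::sd))
  attr(out, "n_truncated") <- n_trunc
  out
}
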