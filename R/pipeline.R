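#' Physiology report for a growth condition
#'
#' Computes the endpoint physiology of a growth condition from the reference
#' measurements: specific growth rate and doubling time from frond areas,
#' substrate uptake rates, the atmospheric CO2 uptake rate from the biomass
#' 13C enrichment (with resampling-based uncertainty), substrate depletion
#' fractions, and the biomass sink fluxes from the composition.
#'
#' @param condition `"INS"` or `"ONS"`.
#' @param n_resample draws for the CO2-uptake uncertainty.
#' @param seed integer seed.
#' @param out_dir optional directory; if given, writes `physiology.json` and
#'   a `biomass_fluxes.tsv` table.
#' @return list with `growth`, `uptake`, `depletion` and `biomass_fluxes`.
#' @export
run_physiology_report <- function(condition = c("INS", "ONS"),
                                  n_resample = 2000, seed = 1L,
                                  out_dir = NULL) {
  condition <- match.arg(condition)
  phys <- lemna_physiology(condition)
  mu_area <- growth_rate(phys$A0[1], phys$At[1], phys$t)
  mu_ref <- log(2) / phys$t_double[1]
  growth <- list(
    condition = condition,
    mu_from_area = mu_area,
    mu_reference = mu_ref,
    doubling_time = doubling_time(mu_area),
    inoculum_fraction = phys$D0 / phys$D
  )
  vCO2 <- co2_uptake(phys$f13C_BM[1], phys$vGlc_up[1], phys$vGln_up[1])
  rs <- resample_co2_uptake(
    means = list(f13C_BM = phys$f13C_BM[1], vGlc_up = phys$vGlc_up[1],
                 vGln_up = phys$vGln_up[1]),
    sds = list(f13C_BM = phys$f13C_BM[2], vGlc_up = phys$vGlc_up[2],
               vGln_up = phys$vGln_up[2]),
    n = n_resample, seed = seed)
  uptake <- list(
    vGlc_up = phys$vGlc_up[1], vGln_up = phys$vGln_up[1],
    vCO2_up = vCO2, vCO2_up_resampled_mean = rs$mean,
    vCO2_up_resampled_sd = rs$sd,
    gln_carbon_share = 5 * phys$vGln_up[1] /
      (6 * phys$vGlc_up[1] + 5 * phys$vGln_up[1])
  )
  depl <- list(
    glucose = depletion_fraction(phys$vGlc_up[1], mu_ref, phys$D0, phys$D,
                                 phys$S0_glc),
    gln = if (phys$S0_gln > 0)
      depletion_fraction(phys$vGln_up[1], mu_ref, phys$D0, phys$D, phys$S0_gln)
      else 0
  )
  comp <- default_biomass_composition(condition)
  bf <- biomass_fluxes(comp, mu_ref)
  out <- list(growth = growth, uptake = uptake, depletion = depl,
              biomass_fluxes = bf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out[c("growth", "uptake", "depletion")],
                         file.path(out_dir, "physiology.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(bf, file.path(out_dir, "biomass_fluxes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Compare the CO2-pool model configurations on one data set
#'
#' Fits the three CO2-pool configurations (A: cellular CO2 with efflux only;
#' B: separate RuBisCO CO2 pool exchanging with the atmosphere; C: B plus
#' uptake-rate flux measurements) to the same measurement set and tabulates
#' SSR, degrees of freedom and the chi-squared verdict for each.
#'
#' @param meas a `measurement_set`.
#' @param labels substrate labels.
#' @param nitrogen_mode `"INS"` or `"ONS"`.
#' @param sinks named numeric of fixed biomass sink fluxes.
#' @param fixed_uptakes optional named numeric fixed in every configuration
#'   where the reaction exists (e.g. `c(vGlc_up = 102.3)`).
#' @param n_restarts,n_polish,seed fitting controls.
#' @return data.frame with columns `config`, `ssr`, `dof`, `chi2_critical`,
#'   `accepted` plus attribute `fits` (the three fit results).
#' @export
compare_co2_configs <- function(meas, labels, nitrogen_mode = "INS",
                                sinks, fixed_uptakes = NULL,
                                n_restarts = 10, n_polish = 4, seed = 1L) {
  rows <- list(); fits <- list()
  for (cfg in c("A", "B", "C")) {
    net <- build_lemna_core(cfg, nitrogen_mode)
    fixed <- sinks
    if (!is.null(fixed_uptakes)) {
      keep <- names(fixed_uptakes) %in% names(net$reactions) &
        !(names(fixed_uptakes) %in% net$measured)
      fixed <- c(fixed, fixed_uptakes[keep])
    }
    fr <- tryCatch(
      fit(net, meas, labels, fixed = fixed, n_restarts = n_restarts,
          n_polish = n_polish, seed = seed),
      error = function(e) e)
    if (inherits(fr, "error")) {
      rows[[cfg]] <- data.frame(config = cfg, ssr = NA_real_,
                                dof = NA_integer_, chi2_critical = NA_real_,
                                accepted = NA)
    } else {
      fits[[cfg]] <- fr
      rows[[cfg]] <- data.frame(config = cfg, ssr = fr$ssr, dof = fr$dof,
                                chi2_critical = fr$chi2_critical,
                                accepted = fr$accepted)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' End-to-end synthetic flux-analysis run
#'
#' Orchestrates the full pipeline on synthetic data for one scenario:
#' construct the ground truth, simulate and corrupt the measurement panel,
#' correct it, fit the model by multi-start least squares, quantify
#' uncertainty by Monte Carlo, aggregate to the uncompartmentalized view and
#' report the derived statistics (combined oxidative pentose-phosphate flux,
#' its ratio to RuBisCO carboxylation, the atmospheric share of the RuBisCO
#' CO2 supply). Deterministic under a fixed seed.
#'
#' @param preset_name `"INS"` or `"ONS"`.
#' @param co2_mode network configuration (default `"C"`).
#' @param seed integer seed.
#' @param n_restarts restarts for the base fit.
#' @param n_replicates,restarts_per_replicate Monte-Carlo controls.
#' @param fix_uptakes treat the uptake rates as known constants (fixed
#'   fluxes, perturbed in the Monte Carlo) rather than free parameters.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list with `truth`, `meas`, `fit`, `ensemble`, `aggregated`,
#'   `stats` (named numbers), `config`.
#' @export
run_full_pipeline <- function(preset_name = c("INS", "ONS"), co2_mode = "C",
                              seed = 1L, n_restarts = 10,
                              n_replicates = 10, restarts_per_replicate = 20,
                              fix_uptakes = TRUE, out_dir = NULL) {
  preset_name <- match.arg(preset_name)
  preset <- scenario_preset(preset_name)
  net <- build_lemna_core(co2_mode, preset_name)
  truth <- truth_flux(preset, net, seed = seed)
  meas <- generate_measurements(truth, net, panel_default(), preset,
                                seed = seed)
  fixed <- preset$sinks
  perturb <- NULL
  if (fix_uptakes) {
    upt <- stats::setNames(preset$uptakes$value, preset$uptakes$reaction)
    upt_sd <- stats::setNames(preset$uptakes$sd, preset$uptakes$reaction)
    keep <- names(upt) %in% names(net$reactions)
    fixed <- c(fixed, upt[keep])
    perturb <- upt_sd[keep]
  }
  base <- fit(net, meas, preset$labels, fixed = fixed,
              n_restarts = n_restarts, seed = seed)
  ens <- monte_carlo(net, meas, preset$labels, fixed = fixed,
                     perturb_fixed = perturb, n_replicates = n_replicates,
                     restarts_per_replicate = restarts_per_replicate,
                     seed = seed, base_fit = base)
  A <- aggregation_map(net)
  agg <- aggregate_ensemble(ens, A)
  oppp <- flux_ratio(ens, c(vG6PDH_c = 1, vG6PDH_p = 1), "vRBC")
  atm <- vapply(ens$members, atmospheric_fraction, numeric(1))
  oppp_row <- agg[agg$combination == "vG6PDH", ]
  stats_out <- c(
    ssr = base$ssr, dof = base$dof, chi2_critical = base$chi2_critical,
    accepted = as.numeric(base$accepted),
    oppp_combined = oppp_row$mean, oppp_combined_sd = oppp_row$sd,
    oppp_rubisco_ratio = oppp$mean, oppp_rubisco_ratio_sd = oppp$sd,
    atm_fraction = mean(atm), atm_fraction_sd = stats::sd(atm)
  )
  out <- list(truth = truth, meas = meas, fit = base, ensemble = ens,
              aggregated = agg, stats = stats_out,
              config = list(preset = preset_name, co2_mode = co2_mode,
                            seed = seed, n_restarts = n_restarts,
                            n_replicates = n_replicates,
                            restarts_per_replicate = restarts_per_replicate))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_measurements(meas, out_dir)
    utils::write.table(
      data.frame(reaction = names(truth$net), net = as.numeric(truth$net),
                 xch = as.numeric(truth$xch)),
      file.path(out_dir, "truth_flux.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ensemble_summary(ens),
                       file.path(out_dir, "flux_estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(agg, file.path(out_dir, "flux_aggregated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(as.list(stats_out), out$config),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}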