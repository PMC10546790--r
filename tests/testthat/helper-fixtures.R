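# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# pure [1-13C] label (no natural abundance) for exact bookkeeping checks
pure_1c_label <- function() {
  substrate_label(list(list(fraction = 1, positions = 1L, purity = 1)))
}

glc_80_10_10 <- function() default_labels()$Glc_x

# random steady-state flux state on the single-compartment toy subnetwork,
# guaranteed within bounds and with active oxidative PPP flux
random_cyto_flux <- function(basis, net, min_oppp = 1) {
  repeat {
    th <- stats::runif(basis$n_free_net, -20, 40)
    v <- basis$expand(th)
    if (all(v >= basis$lb - 1e-9) && all(v <= basis$ub + 1e-9) &&
        v[["vG6PDH"]] > min_oppp) break
  }
  xch <- stats::setNames(stats::runif(length(reversible_reactions(net)), 0, 30),
                         reversible_reactions(net))
  flux_state(net, v, xch)
}

cyto_targets <- function() {
  list(list(metabolite = "G6P", positions = 1:6, fragment_id = "G6P"),
       list(metabolite = "F6P", positions = 1:6, fragment_id = "F6P"),
       list(metabolite = "PGA", positions = 1:3, fragment_id = "PGA"),
       list(metabolite = "P5P", positions = 1:5, fragment_id = "P5P"),
       list(metabolite = "S7P", positions = 1:7, fragment_id = "S7P"),
       list(metabolite = "CO2", positions = 1, fragment_id = "CO2"))
}

# small synthetic fitting problem on the toy subnetwork, for cheap
# calibration studies: returns network, truth, labels, fragment panel
cyto_problem <- function(seed = 42) {
  net <- toy_network("cyto")
  basis <- steady_state_basis(net)
  set.seed(seed)
  truth <- random_cyto_flux(basis, net)
  list(net = net, truth = truth,
       labels = list(Glc_x = glc_80_10_10()),
       panel = lapply(cyto_targets(), function(t)
         fragment_spec(t$fragment_id, t$fragment_id, t$metabolite,
                       t$positions, "")))
}

# noisy measurement set on the toy subnetwork at a given truth
cyto_measurements <- function(prob, noise_sd = 0.01, seed = 1) {
  sim <- simulate_mids(prob$net, prob$truth, prob$labels, targets = prob$panel)
  set.seed(seed)
  mids <- lapply(prob$panel, function(frag) {
    x <- sim[[frag$fragment_id]]
    if (noise_sd > 0) {
      x <- pmax(x + stats::rnorm(length(x), 0, noise_sd), 0)
      x <- x / sum(x)
    }
    list(fragment = frag, raw = NULL, corrected = x,
         sd = rep(noise_sd, length(x)))
  })
  names(mids) <- vapply(prob$panel, `[[`, character(1), "fragment_id")
  structure(list(mids = mids,
                 fluxes = data.frame(reaction = character(0),
                                     value = numeric(0), sd = numeric(0)),
                 preset_name = "toy"),
            class = "measurement_set")
}

ins_truth_setup <- function() {
  fixture("ins_truth", function() {
    pre <- scenario_preset("INS")
    net <- build_lemna_core("C", "INS")
    list(preset = pre, net = net, truth = truth_flux(pre, net, seed = 1))
  })
}
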