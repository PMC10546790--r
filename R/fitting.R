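#' Apply the measurement-SD floor to a measurement set
#'
#' Standard deviations of mass isotopomer measurements are floored at 0.01 on
#' the fractional enrichment scale. This makes the goodness-of-fit test
#' easier to pass at the expense of wider flux confidence intervals.
#'
#' @param meas a `measurement_set`.
#' @param floor minimum SD on the fractional scale.
#' @return the measurement set with floored MID SDs.
#' @export
apply_sd_floor <- function(meas, floor = 0.01) {
  meas$mids <- lapply(meas$mids, function(m) {
    m$sd <- pmax(m$sd, floor)
    m
  })
  meas
}

# compiled fit problem: everything needed for fast residual evaluation
.fit_problem <- function(network, meas, labels, fixed = NULL,
                         system = NULL, sd_floor = 0.01) {
  meas <- apply_sd_floor(meas, sd_floor)
  panel <- lapply(meas$mids, `[[`, "fragment")
  if (is.null(system)) system <- emu_decompose(network, panel)
  tmpl <- compile_labels(system, labels, network)
  basis <- steady_state_basis(network, extra_fixed = fixed)
  rev_ids <- reversible_reactions(network)
  # flat indices of the target MID entries in the simulation buffer
  obs_idx <- integer(0); obs <- numeric(0); obs_sd <- numeric(0)
  for (i in seq_along(meas$mids)) {
    k <- system$target_keys[[match(names(meas$mids)[i], system$target_ids)]]
    off <- system$emu_off[[k]]; len <- system$emu_len[[k]]
    stopifnot(length(meas$mids[[i]]$corrected) == len)
    obs_idx <- c(obs_idx, (off + 1L):(off + len))
    obs <- c(obs, meas$mids[[i]]$corrected)
    obs_sd <- c(obs_sd, meas$mids[[i]]$sd)
  }
  # flux measurements: only reactions declared measurable by the network
  fm <- meas$fluxes[meas$fluxes$reaction %in% network$measured, , drop = FALSE]
  fm_idx <- match(fm$reaction, basis$reactions)
  list(network = network, meas = meas, system = system, tmpl = tmpl,
       fixed = fixed, basis = basis, rev_ids = rev_ids,
       rev_idx = match(rev_ids, basis$reactions),
       obs_idx = obs_idx, obs = obs, obs_sd = obs_sd,
       fm_idx = fm_idx, fm_val = fm$value, fm_sd = fm$sd,
       n_mid = length(obs), n_groups = length(meas$mids),
       n_fluxmeas = nrow(fm))
}

# Exchange fluxes are optimized on a bounded [0,1) transform
# xch = XCH_SCALE * x01 / (1 - x01). The scale constant (in flux units)
# keeps the transform well-resolved for the large CO2-pool exchange fluxes
# this system exhibits; x01 = 0.5 corresponds to xch = XCH_SCALE.
XCH_SCALE <- 100

#' Map an exchange flux to its bounded optimization coordinate
#' @param xch exchange flux (>= 0), in flux units.
#' @return `x01` in `[0, 1)`: `xch / (XCH_SCALE + xch)`.
#' @export
xch_to_01 <- function(xch) xch / (XCH_SCALE + xch)

#' Inverse of [xch_to_01()]
#' @param x01 bounded coordinate in `[0, 1)`.
#' @return exchange flux.
#' @export
xch_from_01 <- function(x01) XCH_SCALE * x01 / (1 - x01)

# parameter vector = c(theta, x01)
.par_split <- function(prob, par) {
  nf <- prob$basis$n_free_net
  theta <- par[seq_len(nf)]
  x01 <- if (nf > 0) par[-seq_len(nf)] else par
  x01 <- pmin(pmax(x01, 0), 0.998)
  list(theta = theta, xch = xch_from_01(x01))
}

.par_to_flux <- function(prob, par) {
  p <- .par_split(prob, par)
  v <- prob$basis$expand(p$theta)
  xch <- stats::setNames(rep(0, length(v)), names(v))
  xch[prob$rev_ids] <- p$xch
  structure(list(net = v, xch = xch), class = "flux_state")
}

# residual vector: weighted MID residuals, flux-measurement residuals,
# and smooth penalty residuals for net-flux bound violations
.fit_residuals <- function(prob, par, penalty_weight = 10) {
  p <- .par_split(prob, par)
  v <- prob$basis$expand(p$theta)
  # inline .uni_flux to reuse v/xch without building a flux_state
  xch_full <- rep(0, length(v)); xch_full[prob$rev_idx] <- p$xch
  vv <- v[prob$system$uni_idx]; xx <- xch_full[prob$system$uni_idx]
  F <- pmax(ifelse(prob$system$uni_dir == 1L, pmax(vv, 0), pmax(-vv, 0)) + xx, 0)
  F[F < 1e-9] <- 0
  buf <- emu_eval_cpp(prob$system$levels, F, prob$tmpl,
                      as.integer(prob$system$emu_off),
                      as.integer(prob$system$emu_len), 1e-9)
  res <- (buf[prob$obs_idx] - prob$obs) / prob$obs_sd
  if (prob$n_fluxmeas)
    res <- c(res, (v[prob$fm_idx] - prob$fm_val) / prob$fm_sd)
  pen <- pmax(prob$basis$lb - v, 0) + pmax(v - prob$basis$ub, 0)
  c(res, sqrt(penalty_weight) * pen)
}

#' Variance-weighted sum of squared residuals of a flux state
#'
#' `SSR = sum(((sim - obs)/sd)^2)` over all mass isotopomer entries plus
#' `sum(((v - v_meas)/sd)^2)` over the flux measurements declared measurable
#' by the network. Invariant under reordering of measurements.
#'
#' @param flux a [flux_state()].
#' @param meas a `measurement_set` (SD floor is applied).
#' @param network an `mfa_network`.
#' @param labels substrate labels.
#' @param system optional precompiled `emu_system`.
#' @return scalar SSR.
#' @export
ssr <- function(flux, meas, network, labels, system = NULL) {
  prob <- .fit_problem(network, meas, labels, system = system)
  m <- simulate_mids(network, flux, system = prob$system,
                     label_template = prob$tmpl)
  buf_res <- 0
  for (i in seq_along(prob$meas$mids)) {
    id <- names(prob$meas$mids)[i]
    buf_res <- buf_res + sum(((m[[id]] - prob$meas$mids[[i]]$corrected) /
                                prob$meas$mids[[i]]$sd)^2)
  }
  if (prob$n_fluxmeas) {
    v <- flux$net[prob$basis$reactions]
    buf_res <- buf_res + sum(((v[prob$fm_idx] - prob$fm_val) / prob$fm_sd)^2)
  }
  buf_res
}

#' Degrees of freedom of the flux-fitting problem
#'
#' The number of mass isotopomer measurements minus the number of
#' measurement groups, plus the number of measured flux rates, minus the
#' number of free net and exchange fluxes.
#'
#' @param n_mid total MID entries; @param n_groups measurement groups (one
#'   per fragment); @param n_fluxmeas flux measurements; @param n_free_net
#'   free net fluxes; @param n_free_xch free exchange fluxes.
#' @return integer degrees of freedom.
#' @export
dof <- function(n_mid, n_groups, n_fluxmeas, n_free_net, n_free_xch) {
  d <- n_mid - n_groups + n_fluxmeas - (n_free_net + n_free_xch)
  if (d <= 0)
    stop("dof: model is under-determined (", d, " degrees of freedom)")
  as.integer(d)
}

#' Chi-squared goodness-of-fit acceptance
#'
#' A flux solution is statistically acceptable at confidence level
#' `1 - alpha` if its SSR does not exceed the `1 - alpha` quantile of the
#' chi-squared distribution with `dof` degrees of freedom. The boundary
#' `ssr == critical` is accepted (inclusive convention).
#'
#' @param ssr sum of squared residuals.
#' @param dof degrees of freedom (>= 1).
#' @param alpha significance level (default 0.10: the 90% quantile).
#' @return list with `accepted`, `chi2_critical`, `ssr`, `dof`.
#' @export
chi2_test <- function(ssr, dof, alpha = 0.10) {
  stopifnot(dof >= 1)
  crit <- stats::qchisq(1 - alpha, df = dof)
  list(accepted = ssr <= crit, chi2_critical = crit, ssr = ssr, dof = dof)
}

# interior point of the bound box in theta space (quadratic violation descent)
.feasible_theta <- function(basis, margin = 1) {
  if (basis$n_free_net == 0) return(numeric(0))
  obj <- function(th) {
    v <- basis$expand(th)
    sum(pmax(basis$lb + margin - v, 0)^2 + pmax(v - basis$ub + margin, 0)^2)
  }
  stats::nlminb(rep(0, basis$n_free_net), obj)$par
}

#' Multi-start weighted least-squares flux estimation
#'
#' Minimizes the variance-weighted SSR between simulated and measured
#' labeling (plus flux measurements on networks that declare measurable
#' uptakes) over the free net fluxes and the exchange fluxes of all
#' reversible reactions. Exchange fluxes are optimized on the bounded
#' `xch01 = xch/(1+xch)` transform; net-flux bounds are enforced through a
#' smooth quadratic penalty. The optimization is restarted from `n_restarts`
#' randomized start points (free net fluxes perturbed around an interior
#' feasible point, `xch01` uniform on `[0, 0.9]`) using Levenberg-Marquardt
#' least squares, and the minimum-SSR solution is returned together with the
#' full restart log and the chi-squared verdict.
#'
#' @param network an `mfa_network`.
#' @param meas a `measurement_set` (corrected skeleton MIDs).
#' @param labels named list of [substrate_label()] per feed.
#' @param fixed named numeric of fixed net fluxes (e.g. measured biomass
#'   sinks), merged over the network's own fixed set.
#' @param n_restarts number of random restarts (default 100).
#' @param max_iter iteration cap per restart (default 2000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param alpha significance level of the chi-squared test.
#' @param start_box random start points are drawn uniformly in the net-flux
#'   bound box truncated to `[-start_box, start_box]` and projected onto the
#'   steady-state space.
#' @param n_polish basin-refinement rounds applied to the best restart: each
#'   round re-runs the optimizer from the incumbent and from three jittered
#'   copies with geometrically decaying jitter, keeping improvements.
#' @param warm_start optional parameter vector (e.g. a previous fit's `par`)
#'   prepended to the start list.
#' @param system optional precompiled `emu_system` (reused across calls).
#' @return object of class `fit_result`: `flux` (best [flux_state()]), `par`,
#'   `ssr`, `dof`, `chi2_critical`, `accepted`, `restarts` (log data.frame),
#'   `penalty` (residual bound violation of the best solution), `basis`.
#' @export
fit <- function(network, meas, labels, fixed = NULL, n_restarts = 100,
                max_iter = 2000, seed = 1L, alpha = 0.10,
                start_box = 700, n_polish = 6, warm_start = NULL,
                system = NULL) {
  prob <- .fit_problem(network, meas, labels, fixed = fixed, system = system)
  nf <- prob$basis$n_free_net
  nx <- length(prob$rev_ids)
  d <- dof(prob$n_mid, prob$n_groups, prob$n_fluxmeas, nf, nx)
  set.seed(as.integer(seed))
  nres_tot <- prob$n_mid + prob$n_fluxmeas + length(prob$basis$reactions)
  safe_fn <- function(p) {
    tryCatch(.fit_residuals(prob, p),
             error = function(e) rep(1e6, nres_tot))
  }
  nres <- prob$n_mid + prob$n_fluxmeas
  lo <- c(rep(-Inf, nf), rep(0, nx))
  hi <- c(rep(Inf, nf), rep(0.99, nx))
  maxit <- min(max_iter, 1024L)   # nls.lm iteration ceiling
  run_lm <- function(p0, iters = maxit) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = safe_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = iters, ftol = 1e-13, ptol = 1e-11)),
      error = function(e) NULL)
    if (is.null(ans)) return(NULL)
    s <- tryCatch(sum(.fit_residuals(prob, ans$par)[seq_len(nres)]^2),
                  error = function(e) Inf)
    list(par = ans$par, ssr = s, info = ans$info, niter = ans$niter)
  }
  # starts: random flux vectors in the (truncated) bound box, projected onto
  # the steady-state space; starts in a singular labeling system resampled
  lbE <- pmax(prob$basis$lb, -start_box)
  ubE <- pmin(prob$basis$ub, start_box)
  draw_start <- function() {
    for (try in 1:50) {
      vstar <- stats::runif(length(lbE), lbE, ubE)
      th <- as.numeric(crossprod(prob$basis$N, vstar - prob$basis$v0))
      p <- c(th, stats::runif(nx, 0.02, 0.8))
      ok <- tryCatch({ .fit_residuals(prob, p); TRUE },
                     error = function(e) FALSE)
      if (ok) return(p)
    }
    stop("fit: could not draw a feasible start point")
  }
  starts <- lapply(seq_len(n_restarts), function(i) draw_start())
  if (!is.null(warm_start)) starts <- c(list(warm_start), starts)
  log <- data.frame(restart = seq_along(starts), ssr = NA_real_,
                    converged = FALSE, niter = NA_integer_)
  best <- NULL; best_ssr <- Inf
  for (i in seq_along(starts)) {
    a <- run_lm(starts[[i]], iters = min(maxit, 400L))
    if (is.null(a)) next
    log$ssr[i] <- a$ssr
    log$converged[i] <- a$info %in% 1:4
    log$niter[i] <- a$niter
    if (a$ssr < best_ssr) { best_ssr <- a$ssr; best <- a$par }
  }
  if (is.null(best))
    stop("fit: all restarts failed; see the restart log")
  # basin refinement of the incumbent: cycling multi-scale jitter lets the
  # search cross near-degenerate circulation modes (large scale) and still
  # settle the sloppy directions (small scale)
  polish_scales <- rep(c(60, 20, 5, 1), length.out = n_polish)
  for (round in seq_len(n_polish)) {
    a <- run_lm(best)
    if (!is.null(a) && a$ssr < best_ssr) { best_ssr <- a$ssr; best <- a$par }
    for (j in 1:3) {
      p0 <- best + c(stats::rnorm(nf, 0, polish_scales[round]),
                     stats::rnorm(nx, 0, 0.08))
      p0 <- pmin(pmax(p0, lo), hi)
      a <- run_lm(p0, iters = min(maxit, 400L))
      if (!is.null(a) && a$ssr < best_ssr) { best_ssr <- a$ssr; best <- a$par }
    }
  }
  r <- .fit_residuals(prob, best)
  penalty <- sum(r[-seq_len(nres)]^2)
  test <- chi2_test(best_ssr, d, alpha)
  structure(list(flux = .par_to_flux(prob, best), par = best, ssr = best_ssr,
                 dof = d, chi2_critical = test$chi2_critical,
                 accepted = test$accepted, restarts = log, penalty = penalty,
                 n_free_net = nf, n_free_xch = nx, problem = prob),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: SSR = %.3f, dof = %d, chi2(90%%) = %.1f -> %s\n",
              x$ssr, x$dof, x$chi2_critical,
              if (x$accepted) "ACCEPTED" else "REJECTED"))
  cat(sprintf("  %d/%d restarts converged; best restart SSR spread: %.3g\n",
              sum(x$restarts$converged, na.rm = TRUE), nrow(x$restarts),
              diff(range(x$restarts$ssr, na.rm = TRUE))))
  invisible(x)
}

#' Profile a flux of interest across its SSR landscape
#'
#' Parameter-continuation search for alternative optima: the flux of
#' interest is pinned to a grid of values, the remaining parameters are
#' re-optimized from the best-fit solution at each grid point, and the
#' interval where `SSR <= best + tolerance` is reported. A wide flat profile
#' reveals a structurally undetermined flux (e.g. the split of the oxidative
#' pentose-phosphate flux between cytosol and plastid) even when the total
#' across compartments is tightly bounded.
#'
#' @param fitres a [fit()] result.
#' @param flux_of_interest reaction id to pin.
#' @param values grid of pinned values (default: 11 points spanning
#'   best ± 4 * |best| plus a zero crossing).
#' @param tolerance SSR increase defining the interval (default: the 90%
#'   chi-squared quantile with 1 degree of freedom, 2.71).
#' @param restarts re-optimization starts per grid point (warm start plus
#'   `restarts - 1` perturbed).
#' @param seed integer seed.
#' @return list with `profile` (data.frame value/ssr), `interval` (range of
#'   values within tolerance), `best_ssr`.
#' @export
find_alternative_optima <- function(fitres, flux_of_interest, values = NULL,
                                    tolerance = stats::qchisq(0.9, 1),
                                    restarts = 2, seed = 1L) {
  prob <- fitres$problem
  net <- prob$network
  if (!(flux_of_interest %in% names(net$reactions)))
    stop("find_alternative_optima: unknown reaction ", flux_of_interest)
  v_best <- fitres$flux$net
  b0 <- v_best[[flux_of_interest]]
  if (is.null(values)) {
    span <- max(abs(b0) * 2, 20)
    values <- sort(unique(c(b0, seq(b0 - span, b0 + span, length.out = 10))))
  }
  set.seed(as.integer(seed))
  nx <- length(prob$rev_ids)
  x01_best <- if (fitres$n_free_net > 0) fitres$par[-seq_len(fitres$n_free_net)]
              else fitres$par
  out <- data.frame(value = values, ssr = NA_real_)
  for (gi in seq_along(values)) {
    fixed_gi <- stats::setNames(values[gi], flux_of_interest)
    prob_gi <- .fit_problem(net, prob$meas, NULL,
                            fixed = c(prob$fixed, fixed_gi),
                            system = prob$system)
    prob_gi$tmpl <- prob$tmpl
    nf <- prob_gi$basis$n_free_net
    th_warm <- qr.coef(qr(prob_gi$basis$N),
                       v_best[prob_gi$basis$reactions] - prob_gi$basis$v0)
    th_warm[is.na(th_warm)] <- 0
    starts <- c(list(c(th_warm, x01_best)),
                lapply(seq_len(max(restarts - 1, 0)), function(i)
                  c(th_warm + stats::rnorm(nf, 0, 20), stats::runif(nx, 0, 0.9))))
    best <- Inf
    for (st in starts) {
      ans <- tryCatch(
        minpack.lm::nls.lm(par = st, fn = function(p)
          .fit_residuals(prob_gi, p),
          lower = c(rep(-Inf, nf), rep(0, nx)),
          upper = c(rep(Inf, nf), rep(0.99, nx)),
          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(ans)) next
      r <- .fit_residuals(prob_gi, ans$par)
      s <- sum(r[seq_len(prob_gi$n_mid + prob_gi$n_fluxmeas)]^2)
      best <- min(best, s)
    }
    out$ssr[gi] <- best
  }
  ok <- is.finite(out$ssr) & out$ssr <= fitres$ssr + tolerance
  list(profile = out,
       interval = if (any(ok)) range(out$value[ok]) else c(NA_real_, NA_real_),
       best_ssr = fitres$ssr)
}
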