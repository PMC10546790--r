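#' Monte-Carlo flux uncertainty
#'
#' Corrupts the measurement set `n_replicates` times with Gaussian
#' pseudo-random noise — MID entries perturbed with their reported SDs
#' (clipped at zero and renormalized), flux measurements and designated
#' fixed rates perturbed with theirs — and re-fits the model for each
#' replicate by multi-start optimization, warm-started at the base fit. The
#' spread of the resulting best-fit flux vectors yields the statistical
#' uncertainty (standard deviation) of every flux and of any linear
#' combination of fluxes.
#'
#' @param network an `mfa_network`.
#' @param meas a `measurement_set`.
#' @param labels substrate labels.
#' @param fixed named numeric of fixed net fluxes (biomass sinks, and
#'   uptake rates when they are treated as known constants).
#' @param perturb_fixed named numeric of SDs for entries of `fixed` that are
#'   themselves measurements and should be corrupted per replicate.
#' @param n_replicates number of noise replicates (default 20).
#' @param restarts_per_replicate random restarts per replicate fit
#'   (default 50), in addition to the warm start at the base fit.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param base_fit optional precomputed [fit()] on the unperturbed data; if
#'   `NULL` it is computed with `restarts_per_replicate` restarts.
#' @param n_polish polish rounds per replicate fit.
#' @param system optional precompiled `emu_system`.
#' @return object of class `mc_ensemble`: `members` (list of flux_state),
#'   `ssr`, `accepted`, `failed` (flags), `base_fit`, `reactions`.
#' @export
monte_carlo <- function(network, meas, labels, fixed = NULL,
                        perturb_fixed = NULL, n_replicates = 20,
                        restarts_per_replicate = 50, seed = 1L,
                        base_fit = NULL, n_polish = 2, system = NULL) {
  if (is.null(base_fit))
    base_fit <- fit(network, meas, labels, fixed = fixed,
                    n_restarts = restarts_per_replicate, seed = seed,
                    system = system)
  system <- base_fit$problem$system
  members <- vector("list", n_replicates)
  ssrs <- numeric(n_replicates)
  accepted <- logical(n_replicates)
  failed <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    done <- FALSE
    for (attempt in 1:2) {
      rep_seed <- as.integer(seed) + r * 1000L + attempt
      set.seed(rep_seed)
      meas_r <- meas
      for (i in seq_along(meas_r$mids)) {
        m <- meas_r$mids[[i]]
        x <- m$corrected + stats::rnorm(length(m$corrected), 0, m$sd)
        x <- pmax(x, 0)
        if (sum(x) > 0) x <- x / sum(x)
        meas_r$mids[[i]]$corrected <- x
      }
      if (nrow(meas_r$fluxes))
        meas_r$fluxes$value <- stats::rnorm(nrow(meas_r$fluxes),
                                            meas_r$fluxes$value,
                                            meas_r$fluxes$sd)
      fixed_r <- fixed
      if (!is.null(perturb_fixed)) {
        nm <- intersect(names(perturb_fixed), names(fixed_r))
        fixed_r[nm] <- stats::rnorm(length(nm), fixed_r[nm], perturb_fixed[nm])
      }
      fr <- tryCatch(
        fit(network, meas_r, labels, fixed = fixed_r,
            n_restarts = restarts_per_replicate, seed = rep_seed,
            warm_start = base_fit$par, n_polish = n_polish, system = system),
        error = function(e) NULL)
      if (!is.null(fr)) {
        members[[r]] <- fr$flux
        ssrs[r] <- fr$ssr
        accepted[r] <- fr$accepted
        done <- TRUE
        break
      }
    }
    failed[r] <- !done
  }
  if (any(failed))
    warning("monte_carlo: ", sum(failed), " replicate(s) failed after redraw")
  keep <- !failed
  structure(list(members = members[keep], ssr = ssrs[keep],
                 accepted = accepted[keep], failed = failed,
                 base_fit = base_fit,
                 reactions = names(base_fit$flux$net)),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf("mc_ensemble: %d replicates (%d failed), median SSR %.1f\n",
              length(x$members), sum(x$failed), stats::median(x$ssr)))
  invisible(x)
}

# net-flux matrix (replicates x reactions) of an ensemble
.ensemble_matrix <- function(ens) {
  do.call(rbind, lapply(ens$members, function(m) m$net[ens$reactions]))
}

#' Per-flux ensemble mean and standard deviation
#' @param ens an `mc_ensemble`.
#' @return data.frame `reaction`, `best`, `mean`, `sd`.
#' @export
ensemble_summary <- function(ens) {
  M <- .ensemble_matrix(ens)
  data.frame(reaction = ens$reactions,
             best = as.numeric(ens$base_fit$flux$net[ens$reactions]),
             mean = colMeans(M),
             sd = apply(M, 2, stats::sd),
             row.names = NULL)
}

#' Aggregate an ensemble through a linear-combination map
#'
#' Applies a linear-combination matrix (rows = combinations, columns =
#' reactions; e.g. from [aggregation_map()]) to the best fit and to every
#' ensemble member. Because the map is linear, aggregation commutes with
#' averaging, and the member spread directly yields the uncertainty of each
#' combined flux — anticorrelated degenerate splits (such as the
#' cytosolic/plastidic oxidative pentose-phosphate fluxes) combine into a
#' much tighter total than either component.
#'
#' @param ens an `mc_ensemble`.
#' @param comb_map numeric matrix with named rows and columns matching
#'   reaction ids, or a named list of coefficient vectors.
#' @return data.frame `combination`, `best`, `mean`, `sd`.
#' @export
aggregate_ensemble <- function(ens, comb_map) {
  if (is.list(comb_map) && !is.matrix(comb_map)) {
    A <- matrix(0, length(comb_map), length(ens$reactions),
                dimnames = list(names(comb_map), ens$reactions))
    for (nm in names(comb_map)) {
      co <- comb_map[[nm]]
      if (!all(names(co) %in% ens$reactions))
        stop("aggregate_ensemble: unknown reaction in combination ", nm)
      A[nm, names(co)] <- co
    }
    comb_map <- A
  }
  if (!all(colnames(comb_map) %in% ens$reactions))
    stop("aggregate_ensemble: unknown reaction id in combination map")
  A <- matrix(0, nrow(comb_map), length(ens$reactions),
              dimnames = list(rownames(comb_map), ens$reactions))
  A[, colnames(comb_map)] <- comb_map
  M <- .ensemble_matrix(ens) %*% t(A)
  data.frame(combination = rownames(A),
             best = as.numeric(A %*% ens$base_fit$flux$net[ens$reactions]),
             mean = colMeans(M),
             sd = apply(M, 2, stats::sd),
             row.names = NULL)
}

#' Ratio of two flux combinations across an ensemble
#'
#' Evaluates `numerator / denominator` (each a linear combination of fluxes)
#' for the best fit and for every ensemble member, and reports the ensemble
#' mean and standard deviation of the ratio. Members with a zero denominator
#' are excluded with a warning.
#'
#' @param ens an `mc_ensemble`.
#' @param numerator,denominator named coefficient vectors over reactions
#'   (a bare reaction id string is promoted to a unit coefficient).
#' @return list with `best`, `mean`, `sd`, `n_used`.
#' @export
flux_ratio <- function(ens, numerator, denominator) {
  as_coef <- function(x) {
    if (is.character(x)) stats::setNames(rep(1, length(x)), x) else x
  }
  num <- as_coef(numerator); den <- as_coef(denominator)
  if (!all(c(names(num), names(den)) %in% ens$reactions))
    stop("flux_ratio: unknown reaction id")
  M <- .ensemble_matrix(ens)
  nv <- as.numeric(M[, names(num), drop = FALSE] %*% num)
  dv <- as.numeric(M[, names(den), drop = FALSE] %*% den)
  ok <- abs(dv) > 0
  if (!all(ok)) warning("flux_ratio: ", sum(!ok), " member(s) with zero denominator excluded")
  vb <- ens$base_fit$flux$net
  best <- sum(vb[names(num)] * num) / sum(vb[names(den)] * den)
  list(best = best, mean = mean(nv[ok] / dv[ok]),
       sd = stats::sd(nv[ok] / dv[ok]), n_used = sum(ok))
}
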