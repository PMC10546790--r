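#' Flux state of a network
#'
#' Holds a net flux (signed) and an exchange flux (>= 0) for every reaction.
#' Equivalently, forward = max(net, 0) + exchange and backward =
#' max(-net, 0) + exchange. Irreversible reactions have exchange 0.
#'
#' @param network an `mfa_network`.
#' @param net named (or network-ordered) numeric vector of net fluxes.
#' @param xch named numeric of exchange fluxes for reversible reactions
#'   (missing entries are 0).
#' @return object of class `flux_state` with elements `net` and `xch`, both
#'   named over all reactions.
#' @export
flux_state <- function(network, net, xch = NULL) {
  rids <- names(network$reactions)
  if (is.null(names(net))) {
    stopifnot(length(net) == length(rids))
    names(net) <- rids
  }
  net_full <- stats::setNames(rep(0, length(rids)), rids)
  net_full[names(net)] <- net
  xch_full <- stats::setNames(rep(0, length(rids)), rids)
  if (!is.null(xch)) xch_full[names(xch)] <- xch
  rev <- vapply(network$reactions, `[[`, logical(1), "reversible")
  if (any(xch_full[!rev] != 0))
    stop("flux_state: irreversible reactions must have zero exchange flux")
  if (any(xch_full < 0)) stop("flux_state: exchange fluxes must be >= 0")
  structure(list(net = net_full, xch = xch_full), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state over", length(x$net), "reactions; nonzero exchange on",
      sum(x$xch > 0), "\n")
  invisible(x)
}

# unidirectional reaction table for a network
.uni_reactions <- function(network) {
  unis <- list()
  for (r in network$reactions) {
    unis[[length(unis) + 1L]] <- list(id = r$id, dir = 1L,
                                      educts = r$educts, products = r$products)
    if (r$reversible)
      unis[[length(unis) + 1L]] <- list(id = r$id, dir = -1L,
                                        educts = r$products, products = r$educts)
  }
  unis
}

# unidirectional flux vector matching .uni_reactions ordering
.uni_flux <- function(unis, flux, idx = NULL, dir = NULL) {
  if (is.null(idx)) {
    ids <- vapply(unis, `[[`, character(1), "id")
    idx <- match(ids, names(flux$net))
    dir <- vapply(unis, `[[`, integer(1), "dir")
  }
  v <- unname(flux$net)[idx]
  x <- unname(flux$xch)[idx]
  pmax(ifelse(dir == 1L, pmax(v, 0), pmax(-v, 0)) + x, 0)
}

.emu_key <- function(met, pos) paste0(met, "[", paste(pos, collapse = ","), "]")

#' Decompose a network into the EMU system of a set of target fragments
#'
#' Performs the elementary-metabolite-unit decomposition: starting from the
#' measured fragments, it traces each carbon subset backward through the atom
#' maps of all (unidirectional) reactions, collecting the minimal set of EMUs
#' whose mass isotopomer distributions determine the targets. EMUs are
#' organized by size into a cascade of linear systems: within one size the
#' unknown MIDs are coupled linearly through fluxes, with source terms formed
#' from substrate MIDs and convolutions of smaller, already-solved EMUs.
#'
#' @param network an `mfa_network`.
#' @param targets list of [fragment_spec()] (or bare
#'   `list(metabolite=, positions=)` entries).
#' @return an `emu_system` object holding the level structure, flux indexing
#'   and target mapping, ready for [simulate_mids()].
#' @export
emu_decompose <- function(network, targets) {
  mets <- network$metabolites
  unis <- .uni_reactions(network)
  # producer index: met -> list of (uni index, occurrence term index)
  producers <- list()
  for (ui in seq_along(unis)) {
    for (ti in seq_along(unis[[ui]]$products)) {
      m <- unis[[ui]]$products[[ti]]$met
      producers[[m]] <- c(producers[[m]], list(c(ui, ti)))
    }
  }
  # consumption occurrences: met -> named numeric over uni index
  cons <- list()
  for (ui in seq_along(unis)) {
    for (t in unis[[ui]]$educts) {
      cons[[t$met]] <- c(cons[[t$met]], ui)
    }
  }

  registry <- new.env(parent = emptyenv())  # key -> emu record
  queue <- list()
  add_emu <- function(met, pos) {
    pos <- sort(as.integer(pos))
    key <- .emu_key(met, pos)
    if (!is.null(registry[[key]])) return(key)
    m <- mets[[met]]
    if (is.null(m)) stop("emu_decompose: unknown metabolite ", met)
    if (max(pos) > m$n_carbons || min(pos) < 1L)
      stop("emu_decompose: target references unknown carbons of ", met)
    registry[[key]] <- list(met = met, pos = pos, size = length(pos),
                            internal = m$balanced, terms = NULL)
    if (m$balanced) queue[[length(queue) + 1L]] <<- key
    key
  }
  for (tg in targets) add_emu(tg$metabolite, tg$positions)

  while (length(queue)) {
    key <- queue[[1]]; queue <- queue[-1]
    rec <- registry[[key]]
    if (!is.null(rec$terms)) next
    terms <- list()
    for (pr in producers[[rec$met]]) {
      ui <- pr[1]; ti <- pr[2]
      u <- unis[[ui]]
      occ <- u$products[[ti]]
      letters <- strsplit(occ$atoms, "")[[1]][rec$pos]
      sources <- list()
      for (e in u$educts) {
        el <- strsplit(e$atoms, "")[[1]]
        q <- which(el %in% letters)
        if (length(q)) sources[[length(sources) + 1L]] <- list(met = e$met, pos = q)
      }
      found <- sum(vapply(sources, function(s) length(s$pos), integer(1)))
      if (found != length(letters))
        stop("emu_decompose: atoms of ", key, " not traceable through ", u$id)
      skeys <- vapply(sources, function(s) add_emu(s$met, s$pos), character(1))
      terms[[length(terms) + 1L]] <- list(uni = ui, sources = skeys)
    }
    rec$terms <- terms
    registry[[key]] <- rec
  }

  # locale-independent ordering: EMU order fixes floating-point summation
  # order, so it must not depend on the session's collation settings
  keys <- sort(ls(registry, sorted = FALSE), method = "radix")
  recs <- lapply(keys, function(k) registry[[k]])
  names(recs) <- keys
  internal <- vapply(recs, `[[`, logical(1), "internal")
  sizes <- vapply(recs, `[[`, integer(1), "size")
  # global ids: stable ordering (inputs and internals interleaved is fine)
  gid <- stats::setNames(seq_along(keys) - 1L, keys)   # 0-based for C++
  emu_len <- sizes + 1L
  emu_off <- cumsum(c(0L, emu_len[-length(emu_len)]))
  names(emu_off) <- keys

  lvl_sizes <- sort(unique(sizes[internal]))
  levels <- vector("list", length(lvl_sizes))
  for (li in seq_along(lvl_sizes)) {
    L <- lvl_sizes[li]
    unk <- keys[internal & sizes == L]
    row_of <- stats::setNames(seq_along(unk) - 1L, unk)
    ai <- aj <- af <- integer(0); ac <- numeric(0)
    bi <- bk <- bf <- integer(0); bc <- numeric(0)
    src_key <- character(0); src_comps <- list()
    for (k in unk) {
      i <- row_of[[k]]
      rec <- recs[[k]]
      # consumption of the metabolite (total outflow) on the diagonal
      for (ui in cons[[rec$met]]) {
        ai <- c(ai, i); aj <- c(aj, i); af <- c(af, ui - 1L); ac <- c(ac, -1)
      }
      for (tm in rec$terms) {
        s <- tm$sources
        if (length(s) == 1L && recs[[s]]$internal && recs[[s]]$size == L) {
          ai <- c(ai, i); aj <- c(aj, row_of[[s]]); af <- c(af, tm$uni - 1L)
          ac <- c(ac, 1)
        } else {
          s_sorted <- sort(s, method = "radix")
          skey <- paste(s_sorted, collapse = " * ")
          kidx <- match(skey, src_key)
          if (is.na(kidx)) {
            src_key <- c(src_key, skey)
            src_comps[[length(src_comps) + 1L]] <- unname(gid[s_sorted])
            kidx <- length(src_key)
          }
          bi <- c(bi, i); bk <- c(bk, kidx - 1L); bf <- c(bf, tm$uni - 1L)
          bc <- c(bc, 1)
        }
      }
    }
    levels[[li]] <- list(L = L, gids = unname(gid[unk]), keys = unk,
                         ai = ai, aj = aj, af = af, ac = ac,
                         bi = bi, bk = bk, bf = bf, bc = bc,
                         src_comps = src_comps)
  }

  target_keys <- vapply(targets, function(tg)
    .emu_key(tg$metabolite, sort(as.integer(tg$positions))), character(1))
  target_ids <- vapply(targets, function(tg)
    if (!is.null(tg$fragment_id)) tg$fragment_id
    else .emu_key(tg$metabolite, tg$positions), character(1))

  uni_ids <- vapply(unis, `[[`, character(1), "id")
  structure(list(network_name = network$name, unis = unis, recs = recs,
                 gid = gid, emu_off = emu_off, emu_len = emu_len,
                 levels = levels, input_keys = keys[!internal],
                 target_keys = target_keys, target_ids = target_ids,
                 uni_idx = match(uni_ids, names(network$reactions)),
                 uni_dir = vapply(unis, `[[`, integer(1), "dir"),
                 n_emu = length(keys), total_len = sum(emu_len)),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  cat(sprintf("emu_system: %d EMUs (%d substrate inputs), %d size levels, %d targets\n",
              x$n_emu, length(x$input_keys), length(x$levels),
              length(x$target_keys)))
  invisible(x)
}

#' Precompute substrate EMU MIDs for a label specification
#'
#' @param system an `emu_system`.
#' @param labels named list: external metabolite id -> [substrate_label()].
#'   Feeds without an entry are at natural abundance.
#' @param network the network the system was built from (for carbon counts).
#' @return numeric template vector for the simulator (internal EMU slots 0).
#' @export
compile_labels <- function(system, labels, network) {
  tmpl <- numeric(system$total_len)
  nat <- substrate_label(list(list(fraction = 1, positions = integer(0))))
  for (k in system$input_keys) {
    rec <- system$recs[[k]]
    lab <- labels[[rec$met]]
    if (is.null(lab)) lab <- nat
    nC <- network$metabolites[[rec$met]]$n_carbons
    mid <- label_mid(lab, nC, rec$pos)
    off <- system$emu_off[[k]]
    tmpl[(off + 1L):(off + length(mid))] <- mid
  }
  tmpl
}

#' Simulate steady-state fragment MIDs by the EMU cascade
#'
#' Solves the size-ordered EMU linear systems for the given flux state and
#' substrate labeling and returns the mass isotopomer distribution of every
#' target fragment. Deterministic; each returned MID sums to 1. Fluxes below
#' `clamp` are clamped to `clamp` for the solve (with a warning) to avoid
#' exactly singular level systems from zero-flux subnetworks.
#'
#' @param network an `mfa_network`.
#' @param flux a [flux_state()] satisfying steady state.
#' @param labels named list of [substrate_label()] per substrate feed.
#' @param targets list of [fragment_spec()]; alternatively pass a precompiled
#'   `system` (and optionally `label_template`) for repeated evaluation.
#' @param system optional precompiled [emu_decompose()] result.
#' @param label_template optional precompiled [compile_labels()] result.
#' @param clamp singularity guard: fluxes below this are treated as zero, and
#'   an EMU whose total inflow falls below it triggers a diagnostic naming it.
#' @return named list of MID vectors, one per target fragment.
#' @export
simulate_mids <- function(network, flux, labels, targets = NULL,
                          system = NULL, label_template = NULL,
                          clamp = 1e-9) {
  if (is.null(system)) system <- emu_decompose(network, targets)
  if (is.null(label_template))
    label_template <- compile_labels(system, labels, network)
  F <- .uni_flux(system$unis, flux, system$uni_idx, system$uni_dir)
  F[F < clamp] <- 0
  buf <- emu_eval_cpp(system$levels, F, label_template,
                      as.integer(system$emu_off), as.integer(system$emu_len),
                      clamp)
  out <- vector("list", length(system$target_keys))
  names(out) <- system$target_ids
  for (i in seq_along(system$target_keys)) {
    k <- system$target_keys[i]
    off <- system$emu_off[[k]]
    out[[i]] <- buf[(off + 1L):(off + system$emu_len[[k]])]
  }
  out
}

# ---------------------------------------------------------------------------
# Full-isotopomer verification oracle

#' Brute-force full-isotopomer steady-state solution
#'
#' Independent verification oracle for [simulate_mids()]: enumerates the full
#' binary labeling state space of every balanced metabolite (guarded at 2^20
#' states total) and solves the complete isotopomer balance by fixed-point
#' iteration. The fixed point is unique for strictly positive fluxes, so the
#' result is initialization-independent; marginalizing the state
#' distributions must reproduce the EMU MIDs.
#'
#' @param network an `mfa_network`.
#' @param flux a [flux_state()].
#' @param labels named list of [substrate_label()] per feed.
#' @param tol fixed-point convergence tolerance (max absolute change).
#' @param max_iter iteration cap.
#' @param damping under-relaxation factor in (0, 1]; values below 1 stabilize
#'   the iteration for strongly exchange-coupled cycles.
#' @param init optional named list of initial state distributions.
#' @return named list: balanced metabolite -> probability vector over its
#'   `2^n` labeling states (carbon 1 = least significant bit).
#' @export
brute_force_isotopomers <- function(network, flux, labels, tol = 1e-12,
                                    max_iter = 20000, damping = 0.5,
                                    init = NULL) {
  mets <- network$metabolites
  bal <- names(Filter(function(m) m$balanced, mets))
  nstates <- vapply(bal, function(m) 2^mets[[m]]$n_carbons, numeric(1))
  if (sum(nstates) > 2^20)
    stop("brute_force_isotopomers: state count ", sum(nstates), " exceeds 2^20 guard")
  unis <- .uni_reactions(network)
  F <- .uni_flux(unis, flux)
  nat <- substrate_label(list(list(fraction = 1, positions = integer(0))))
  ext_dist <- function(m) {
    lab <- labels[[m]]
    if (is.null(lab)) lab <- nat
    mixture_distribution(lab, mets[[m]]$n_carbons)
  }
  # current distributions
  dist <- stats::setNames(lapply(bal, function(m) {
    d <- numeric(2^mets[[m]]$n_carbons); d[1] <- 1; d
  }), bal)
  if (!is.null(init)) for (m in names(init)) dist[[m]] <- init[[m]]
  ext_cache <- list()
  get_dist <- function(m) {
    if (m %in% bal) return(dist[[m]])
    if (is.null(ext_cache[[m]])) ext_cache[[m]] <<- ext_dist(m)
    ext_cache[[m]]
  }
  # precompute reaction combo maps: for uni u, matrix of joint educt states ->
  # per product occurrence the product state index
  combos <- vector("list", length(unis))
  for (ui in seq_along(unis)) {
    u <- unis[[ui]]
    if (F[ui] <= 0) next
    esizes <- vapply(u$educts, function(t) mets[[t$met]]$n_carbons, integer(1))
    grid <- do.call(expand.grid, lapply(esizes, function(n) 0:(2^n - 1)))
    # letter -> (educt index, bit) lookup
    bit_of <- list()
    for (ei in seq_along(u$educts)) {
      el <- strsplit(u$educts[[ei]]$atoms, "")[[1]]
      for (q in seq_along(el)) bit_of[[el[q]]] <- c(ei, q - 1L)
    }
    pstates <- lapply(u$products, function(pr) {
      pl <- strsplit(pr$atoms, "")[[1]]
      idx <- rep(0, nrow(grid))
      for (pq in seq_along(pl)) {
        src <- bit_of[[pl[pq]]]
        bit <- bitwAnd(grid[[src[1]]] %/% 2^src[2], 1L)
        idx <- idx + bit * 2^(pq - 1L)
      }
      idx + 1L
    })
    combos[[ui]] <- list(grid = grid, pstates = pstates)
  }
  for (iter in seq_len(max_iter)) {
    inflow <- stats::setNames(lapply(bal, function(m) numeric(length(dist[[m]]))), bal)
    total <- stats::setNames(numeric(length(bal)), bal)
    for (ui in seq_along(unis)) {
      u <- unis[[ui]]
      if (F[ui] <= 0 || is.null(combos[[ui]])) next
      cb <- combos[[ui]]
      p <- rep(1, nrow(cb$grid))
      for (ei in seq_along(u$educts))
        p <- p * get_dist(u$educts[[ei]]$met)[cb$grid[[ei]] + 1L]
      for (pi in seq_along(u$products)) {
        m <- u$products[[pi]]$met
        if (!(m %in% bal)) next
        acc <- rowsum(p, cb$pstates[[pi]])
        inflow[[m]][as.integer(rownames(acc))] <-
          inflow[[m]][as.integer(rownames(acc))] + F[ui] * acc[, 1]
        total[m] <- total[m] + F[ui]
      }
    }
    delta <- 0
    for (m in bal) {
      if (total[m] <= 0) next
      new <- (1 - damping) * dist[[m]] + damping * inflow[[m]] / total[m]
      # project back onto the simplex: the physical fixed point is normalized,
      # and renormalization suppresses sub-stochastic collapsed fixed points
      s <- sum(new)
      if (s > 0) new <- new / s
      delta <- max(delta, max(abs(new - dist[[m]])))
      dist[[m]] <- new
    }
    if (delta < tol * damping) break
  }
  if (delta >= tol)
    warning("brute_force_isotopomers: not converged (delta = ", format(delta), ")")
  dist
}

#' Marginalize a full isotopomer distribution to a fragment MID
#' @param state_dist probability vector over `2^n` binary labeling states.
#' @param positions carbon positions of the fragment (default all).
#' @return MID of the fragment.
#' @export
isotopomer_to_mid <- function(state_dist, positions = NULL) {
  n <- as.integer(round(log2(length(state_dist))))
  if (is.null(positions)) positions <- seq_len(n)
  states <- 0:(length(state_dist) - 1L)
  wt <- rep(0L, length(states))
  for (p in positions) wt <- wt + bitwAnd(states %/% 2^(p - 1L), 1L)
  out <- numeric(length(positions) + 1L)
  acc <- rowsum(state_dist, wt)
  out[as.integer(rownames(acc)) + 1L] <- acc[, 1]
  out
}
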