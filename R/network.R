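#' Atom-transition metabolic networks
#'
#' An `mfa_network` holds compartmentalized metabolites, reactions with
#' per-carbon atom maps, substrate feeds, and the constraint set (fixed
#' fluxes, flux-ratio constraints) needed to parameterize steady-state fluxes.
#'
#' @name mfa_network
NULL

# split "Met#abc + Met2#de" into list(list(met=, atoms=), ...)
.parse_side <- function(s, line_no) {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
  lapply(terms, function(tm) {
    parts <- strsplit(tm, "#", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
      stop(sprintf("network parse error at line %d: malformed atom map '%s'",
                   line_no, tm))
    list(met = parts[1], atoms = parts[2])
  })
}

#' Parse an atom-transition network from its TSV serialization
#'
#' The format is UTF-8, tab-delimited. Header lines: `# name <id>`,
#' `# metabolite <id> <compartment> <n_carbons> <balanced|external>`,
#' `# fixed <reaction> <value>`, `# ratio <numerator> <denominator> <value>`,
#' `# measured <reaction>`. Any other `#` line is a comment. Reaction lines:
#' `<id> TAB <educts> TAB <products> TAB <rev|irr> TAB <lb> TAB <ub>`, with
#' `+`-separated terms written `Metabolite#abc` — one lower-case letter per
#' carbon, educt-side letters assigned left-to-right starting at C1.
#'
#' All structural invariants are checked: atom-map letters are unique within
#' each side, atom string lengths match declared carbon counts, every reaction
#' conserves the multiset of atom labels, and every balanced metabolite is
#' both produced and consumed.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return an `mfa_network` object.
#' @seealso [read_network()], [validate_carbon_balance()]
#' @export
parse_network <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  name <- "network"
  mets <- list(); rxns <- list()
  fixed <- numeric(0); ratios <- list(); measured <- character(0)
  for (i in seq_along(text)) {
    line <- trimws(text[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      tok <- strsplit(trimws(sub("^#+", "", line)), "\\s+")[[1]]
      if (length(tok) == 0) next
      key <- tok[1]
      if (key == "name" && length(tok) >= 2) name <- tok[2]
      else if (key == "metabolite") {
        if (length(tok) != 5)
          stop(sprintf("network parse error at line %d: metabolite header needs 4 fields", i))
        mets[[tok[2]]] <- list(id = tok[2], compartment = tok[3],
                               n_carbons = as.integer(tok[4]),
                               balanced = identical(tok[5], "balanced"))
      } else if (key == "fixed") {
        fixed[tok[2]] <- as.numeric(tok[3])
      } else if (key == "ratio") {
        ratios[[length(ratios) + 1L]] <-
          list(numerator = tok[2], denominator = tok[3],
               ratio = as.numeric(tok[4]))
      } else if (key == "measured") {
        measured <- c(measured, tok[2])
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 6)
      stop(sprintf("network parse error at line %d: reaction needs 6 tab fields", i))
    rxns[[f[1]]] <- list(id = f[1],
                         educts = .parse_side(f[2], i),
                         products = .parse_side(f[3], i),
                         reversible = identical(f[4], "rev"),
                         lb = as.numeric(f[5]), ub = as.numeric(f[6]))
  }
  net <- structure(list(name = name, metabolites = mets, reactions = rxns,
                        fixed = fixed, ratios = ratios, measured = measured),
                   class = "mfa_network")
  viol <- validate_carbon_balance(net)
  if (length(viol))
    stop("network validation error:\n  ", paste(viol, collapse = "\n  "))
  net
}

#' Read an atom-transition network from a TSV file
#' @param path file path.
#' @return an `mfa_network`.
#' @export
read_network <- function(path) parse_network(readLines(path, warn = FALSE))

#' Serialize an `mfa_network` to its TSV format
#' @param network an `mfa_network`.
#' @param path optional path; if `NULL` the lines are returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_network_tsv <- function(network, path = NULL) {
  side <- function(terms)
    paste(vapply(terms, function(t) paste0(t$met, "#", t$atoms), character(1)),
          collapse = " + ")
  lines <- c(paste("# name", network$name),
             vapply(network$metabolites, function(m)
               sprintf("# metabolite %s %s %d %s", m$id, m$compartment,
                       m$n_carbons, if (m$balanced) "balanced" else "external"),
               character(1)),
             if (length(network$fixed))
               sprintf("# fixed %s %g", names(network$fixed), network$fixed),
             vapply(network$ratios, function(r)
               sprintf("# ratio %s %s %g", r$numerator, r$denominator, r$ratio),
               character(1)),
             if (length(network$measured)) paste("# measured", network$measured),
             vapply(network$reactions, function(r)
               paste(r$id, side(r$educts), side(r$products),
                     if (r$reversible) "rev" else "irr",
                     format(r$lb, scientific = FALSE),
                     format(r$ub, scientific = FALSE), sep = "\t"),
               character(1)))
  lines <- unname(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.mfa_network <- function(x, ...) {
  nbal <- sum(vapply(x$metabolites, function(m) m$balanced, logical(1)))
  cat(sprintf("mfa_network '%s': %d reactions, %d metabolites (%d balanced), %d fixed fluxes, %d ratio constraints\n",
              x$name, length(x$reactions), length(x$metabolites), nbal,
              length(x$fixed), length(x$ratios)))
  invisible(x)
}

#' Check atom-level carbon conservation of every reaction
#'
#' A reaction conserves carbon if the multiset of atom-map letters on the
#' educt side equals that on the product side; letters must also be unique
#' within a side, and atom strings must match the declared carbon counts.
#' Reversible reactions are checked once (the reverse direction is the mirror
#' image). Reports violations; does not raise.
#'
#' @param network an `mfa_network`.
#' @return character vector of human-readable violations (empty if none).
#' @export
validate_carbon_balance <- function(network) {
  viol <- character(0)
  for (r in network$reactions) {
    for (sd in list(r$educts, r$products)) {
      for (t in sd) {
        m <- network$metabolites[[t$met]]
        if (is.null(m)) {
          viol <- c(viol, sprintf("%s: undeclared metabolite %s", r$id, t$met))
        } else if (nchar(t$atoms) != m$n_carbons) {
          viol <- c(viol, sprintf("%s: atom map '%s' does not match %d carbons of %s",
                                  r$id, t$atoms, m$n_carbons, t$met))
        }
      }
    }
    e_atoms <- unlist(strsplit(vapply(r$educts, `[[`, character(1), "atoms"), ""))
    p_atoms <- unlist(strsplit(vapply(r$products, `[[`, character(1), "atoms"), ""))
    if (anyDuplicated(e_atoms))
      viol <- c(viol, sprintf("%s: duplicate atom label on educt side", r$id))
    if (anyDuplicated(p_atoms))
      viol <- c(viol, sprintf("%s: duplicate atom label on product side", r$id))
    if (!identical(sort(e_atoms), sort(p_atoms)))
      viol <- c(viol, sprintf("%s: carbon not conserved (educts '%s' vs products '%s')",
                              r$id, paste(sort(e_atoms), collapse = ""),
                              paste(sort(p_atoms), collapse = "")))
  }
  # every balanced metabolite must be produced and consumed
  prod <- cons <- character(0)
  for (r in network$reactions) {
    prod <- c(prod, vapply(r$products, `[[`, character(1), "met"))
    cons <- c(cons, vapply(r$educts, `[[`, character(1), "met"))
    if (r$reversible) {
      prod <- c(prod, vapply(r$educts, `[[`, character(1), "met"))
      cons <- c(cons, vapply(r$products, `[[`, character(1), "met"))
    }
  }
  for (m in network$metabolites) {
    if (!m$balanced) next
    if (!(m$id %in% prod) || !(m$id %in% cons))
      viol <- c(viol, sprintf("balanced metabolite %s is not both produced and consumed", m$id))
  }
  for (rc in network$ratios) {
    if (is.null(network$reactions[[rc$numerator]]) ||
        is.null(network$reactions[[rc$denominator]]))
      viol <- c(viol, sprintf("ratio constraint references unknown reaction %s/%s",
                              rc$numerator, rc$denominator))
    else if (!is.finite(rc$ratio) || rc$ratio <= 0)
      viol <- c(viol, sprintf("ratio constraint %s:%s must be positive",
                              rc$numerator, rc$denominator))
  }
  viol
}

#' Stoichiometric matrix over balanced metabolites
#' @param network an `mfa_network`.
#' @return matrix (balanced metabolites x reactions) of net stoichiometric
#'   coefficients.
#' @export
stoich_matrix <- function(network) {
  bal <- names(Filter(function(m) m$balanced, network$metabolites))
  rids <- names(network$reactions)
  S <- matrix(0, length(bal), length(rids), dimnames = list(bal, rids))
  for (r in network$reactions) {
    for (t in r$educts) if (t$met %in% bal)
      S[t$met, r$id] <- S[t$met, r$id] - 1
    for (t in r$products) if (t$met %in% bal)
      S[t$met, r$id] <- S[t$met, r$id] + 1
  }
  S
}

#' Free-flux parameterization of the steady-state flux space
#'
#' Builds the affine map from free net fluxes to the full net-flux vector:
#' stacking the stoichiometric steady-state conditions (S v = 0 on balanced
#' metabolites), the fixed-flux constraints and the flux-ratio constraints
#' into one linear system, it returns a particular solution and an
#' orthonormal null-space basis, so that `v = v0 + N theta` enumerates exactly
#' the steady-state flux vectors. Any expanded vector satisfies `S v = 0` to
#' 1e-9 relative and honours every ratio constraint exactly.
#'
#' @param network an `mfa_network`.
#' @param extra_fixed optional named numeric of additional fixed net fluxes
#'   (merged over the network's own `fixed` set).
#' @param tol rank/feasibility tolerance.
#' @return list with `v0` (particular solution), `N` (null-space basis,
#'   reactions x n_free), `n_free_net`, `n_free_xch` (count of reversible
#'   reactions, whose exchange fluxes are free), `reactions` (ids), `lb`/`ub`
#'   bounds, and `expand(theta)` returning the named full net-flux vector.
#' @export
steady_state_basis <- function(network, extra_fixed = NULL, tol = 1e-9) {
  S <- stoich_matrix(network)
  rids <- colnames(S)
  n <- length(rids)
  fixed <- network$fixed
  if (!is.null(extra_fixed)) fixed[names(extra_fixed)] <- extra_fixed
  A <- S; b <- rep(0, nrow(S))
  for (nm in names(fixed)) {
    if (!(nm %in% rids)) stop("fixed-flux constraint on unknown reaction: ", nm)
    row <- rep(0, n); row[match(nm, rids)] <- 1
    A <- rbind(A, row); b <- c(b, fixed[[nm]])
  }
  for (rc in network$ratios) {
    row <- rep(0, n)
    row[match(rc$numerator, rids)] <- 1
    row[match(rc$denominator, rids)] <- -rc$ratio
    A <- rbind(A, row); b <- c(b, 0)
  }
  qa <- qr(A)
  v0 <- qr.coef(qa, b)
  v0[is.na(v0)] <- 0
  resid <- A %*% v0 - b
  scale <- max(1, max(abs(b)))
  if (max(abs(resid)) > 1e-7 * scale)
    stop("steady_state_basis: inconsistent fixed-flux constraints (no feasible solution); max residual ",
         format(max(abs(resid))))
  # null space of A
  qt <- qr(t(A))
  rank <- qt$rank
  N <- if (rank < n) qr.Q(qt, complete = TRUE)[, (rank + 1L):n, drop = FALSE]
       else matrix(0, n, 0)
  lb <- vapply(network$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(network$reactions, `[[`, numeric(1), "ub")
  n_free_xch <- sum(vapply(network$reactions, `[[`, logical(1), "reversible"))
  expand <- function(theta) {
    v <- as.numeric(v0 + if (length(theta)) N %*% theta else 0)
    names(v) <- rids
    v
  }
  list(v0 = as.numeric(v0), N = N, n_free_net = ncol(N),
       n_free_xch = n_free_xch, reactions = rids,
       lb = unname(lb), ub = unname(ub), expand = expand)
}

#' Reversible reaction ids of a network
#' @param network an `mfa_network`.
#' @return character vector.
#' @export
reversible_reactions <- function(network) {
  names(Filter(function(r) r$reversible, network$reactions))
}
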