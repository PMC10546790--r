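#' @useDynLib lemnaflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Terrestrial isotope abundance table used for natural-isotope corrections.
# Rows: element; entries: mass-shift probabilities for M+0, M+1, M+2 per atom.
# C/H/N are two-isotope elements; O, S, Si have an M+2 isotope; the tiny 36S
# contribution is neglected.
.isotope_abundance <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  S  = c(0.9499, 0.0075, 0.0425),
  Si = c(0.92223, 0.04685, 0.03092),
  F  = 1, P = 1          # monoisotopic in nature
)

#' Natural 13C abundance used throughout the package
#' @return 0.011 (fraction), the rounded natural abundance used in the
#'   carbon-source mixing relations.
#' @export
natural_13c <- function() 0.011

#' Validate and normalize a mass isotopomer distribution
#' @param mid numeric vector m0..mn; must be nonnegative and sum to 1 (1e-9).
#' @param tol tolerance on the sum.
#' @return the MID, unchanged.
#' @keywords internal
check_mid <- function(mid, tol = 1e-9) {
  if (any(mid < -tol)) stop("MID has negative entries")
  if (abs(sum(mid) - 1) > tol) stop("MID does not sum to 1")
  mid
}

#' Convolution of two mass isotopomer distributions
#'
#' The MID of a molecule assembled from two independent moieties is the Cauchy
#' product of their MIDs. Commutative and associative; the result has length
#' `length(a) + length(b) - 1` and sums to 1.
#'
#' @param a,b MID vectors.
#' @return convolved MID.
#' @export
convolve_mid <- function(a, b) {
  as.numeric(stats::convolve(a, rev(b), type = "open"))
}

#' Average fractional 13C enrichment of a fragment
#'
#' `sum(i * m_i) / n` for a MID over `n` carbons, or the per-position average
#' of a positional isotopomer distribution.
#'
#' @param mid MID vector (length n+1 for an n-carbon fragment).
#' @return average enrichment in `[0, 1]`.
#' @export
average_enrichment <- function(mid) {
  n <- length(mid) - 1L
  if (n < 1) stop("average_enrichment: fragment must have at least one carbon")
  sum(seq(0, n) * mid) / n
}

#' Positional isotopomer distribution of a labeled substrate mixture
#'
#' Expands a substrate label specification (a mixture of positional isotopomer
#' species, e.g. 80:10:10 unlabeled : \[1-13C\] : \[U-13C6\] glucose) into a
#' probability vector over all `2^n` binary labeling states. Positions declared
#' labeled in a species carry 13C with the species' isotopic purity; all other
#' positions carry 13C at natural abundance.
#'
#' @param label a substrate label: list of components, each a list with
#'   `fraction` (mole fraction), `positions` (integer vector of 13C-labeled
#'   carbon positions, possibly empty) and optional `purity` (default 0.99).
#'   See [substrate_label()].
#' @param n_carbons number of carbons of the substrate.
#' @param e_nat natural 13C abundance applied to unenriched positions.
#' @return numeric vector of length `2^n_carbons`; state ordering is binary
#'   with carbon 1 as the least significant bit.
#' @export
mixture_distribution <- function(label, n_carbons, e_nat = natural_13c()) {
  fr <- vapply(label, function(cp) cp$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    stop("mixture_distribution: component mole fractions must sum to 1")
  out <- numeric(2^n_carbons)
  for (cp in label) {
    if (length(cp$positions) && max(cp$positions) > n_carbons)
      stop("mixture_distribution: labeled position exceeds n_carbons")
    p <- rep(e_nat, n_carbons)
    purity <- if (is.null(cp$purity)) 0.99 else cp$purity
    p[cp$positions] <- purity
    # probability of each binary state: product over positions
    probs <- 1
    for (i in seq_len(n_carbons)) {
      probs <- c(probs * (1 - p[i]), probs * p[i])
    }
    out <- out + cp$fraction * probs
  }
  out
}

#' Construct a substrate label specification
#'
#' @param components list of `list(fraction=, positions=, purity=)` entries.
#' @return object of class `substrate_label` (a validated list).
#' @examples
#' # the 80:10:10 unlabeled : [1-13C] : [U-13C6] glucose design
#' substrate_label(list(
#'   list(fraction = 0.8, positions = integer(0)),
#'   list(fraction = 0.1, positions = 1L),
#'   list(fraction = 0.1, positions = 1:6)
#' ))
#' @export
substrate_label <- function(components) {
  fr <- vapply(components, function(cp) cp$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop("substrate_label: fractions must sum to 1")
  for (cp in components) {
    purity <- if (is.null(cp$purity)) 0.99 else cp$purity
    if (purity < 0 || purity > 1) stop("substrate_label: purity must be in [0,1]")
  }
  structure(components, class = "substrate_label")
}

#' Marginal MID of a position subset under a substrate label
#'
#' @param label a [substrate_label()].
#' @param n_carbons substrate carbon count.
#' @param positions integer subset of carbons (default all).
#' @inheritParams mixture_distribution
#' @return MID of the selected positions.
#' @export
label_mid <- function(label, n_carbons, positions = seq_len(n_carbons),
                      e_nat = natural_13c()) {
  out <- numeric(length(positions) + 1L)
  for (cp in label) {
    p <- rep(e_nat, n_carbons)
    purity <- if (is.null(cp$purity)) 0.99 else cp$purity
    p[cp$positions] <- purity
    mid <- 1
    for (i in positions) mid <- convolve_mid(mid, c(1 - p[i], p[i]))
    out <- out + cp$fraction * mid
  }
  out
}

#' Average 13C enrichment of a substrate mixture
#' @inheritParams label_mid
#' @return mean per-carbon 13C fraction of the mixture.
#' @export
label_enrichment <- function(label, n_carbons, e_nat = natural_13c()) {
  average_enrichment(label_mid(label, n_carbons, e_nat = e_nat))
}

#' Parse an elemental formula string
#' @param formula e.g. `"C9H21NOSi2"`; counts default to 1.
#' @return named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula))
    return(stats::setNames(integer(0), character(0)))
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  if (!all(el %in% names(.isotope_abundance)))
    stop("parse_formula: unknown element(s): ",
         paste(setdiff(el, names(.isotope_abundance)), collapse = ", "))
  tapply(ct, el, sum)[unique(el)]
}

#' Natural isotopologue mass distribution of an elemental formula
#'
#' Computes the mass-shift distribution caused by naturally occurring heavy
#' isotopes of C, H, N, O, S and Si, by convolving per-atom isotope
#' distributions (fixed published terrestrial abundances).
#'
#' @param formula elemental formula string (e.g. `"C6H12O6"`, `"Si2C8H20"`)
#'   or a named count vector; empty formula gives `[1]`.
#' @param max_shift truncate the distribution at this mass shift (renormalized
#'   is NOT applied; the tail mass beyond `max_shift` is dropped only if
#'   requested). `NULL` keeps the full support.
#' @return numeric vector: probabilities of mass shifts 0, 1, 2, ...
#' @export
natural_mid <- function(formula, max_shift = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  out <- 1
  for (el in names(counts)) {
    per_atom <- .isotope_abundance[[el]]
    for (k in seq_len(counts[[el]])) out <- convolve_mid(out, per_atom)
  }
  if (!is.null(max_shift) && length(out) > max_shift + 1L)
    out <- out[seq_len(max_shift + 1L)]
  as.numeric(out)
}

#' Fragment specification for a GC-MS measurement
#'
#' @param fragment_id unique fragment name.
#' @param analyte analyte (measured compound) name.
#' @param metabolite model metabolite the carbon skeleton maps to.
#' @param positions integer vector of skeleton carbon positions included.
#' @param derivative elemental formula of everything in the measured ion
#'   beyond the skeleton carbons (derivative side chains plus non-carbon
#'   skeleton atoms), used for natural-isotope correction. `""` for none.
#' @return object of class `fragment_spec`.
#' @export
fragment_spec <- function(fragment_id, analyte, metabolite, positions,
                          derivative = "") {
  positions <- as.integer(positions)
  if (length(positions) < 1 || any(positions < 1))
    stop("fragment_spec: positions must be positive integers")
  structure(list(fragment_id = fragment_id, analyte = analyte,
                 metabolite = metabolite, positions = positions,
                 derivative = derivative),
            class = "fragment_spec")
}

#' Correct a raw fragment MID for natural isotopes in the derivative
#'
#' Deconvolves the natural isotopologue distribution of the derivative part of
#' a fragment (side chains and non-carbon skeleton atoms) from the raw
#' measured mass distribution, leaving the MID of the carbon skeleton alone.
#' The deconvolution solves a nonnegative least-squares problem on the full
#' convolution matrix and renormalizes, which is stable also for long,
#' silicon-rich derivative formulas. It is the exact inverse of forward
#' contamination: `correct_derivative(convolve_mid(x, natural_mid(f)), frag)`
#' returns `x` (to 1e-6) for any skeleton MID `x`.
#'
#' @param raw measured mass distribution (length >= skeleton carbons + 1).
#' @param frag a [fragment_spec()].
#' @return corrected skeleton MID (length `length(frag$positions) + 1`).
#' @export
correct_derivative <- function(raw, frag) {
  n_skel <- length(frag$positions)
  if (length(raw) < n_skel + 1L)
    stop("correct_derivative: raw MID shorter than skeleton size")
  nat <- natural_mid(frag$derivative)
  if (length(nat) == 1L) {   # no derivative: identity on the skeleton window
    out <- raw[seq_len(n_skel + 1L)]
    return(out / sum(out))
  }
  # raw = C %*% skeleton, C[i, j] = nat[i - j + 1]
  nr <- length(raw)
  C <- matrix(0, nr, n_skel + 1L)
  for (j in seq_len(n_skel + 1L)) {
    idx <- seq_len(length(nat)) + j - 1L
    keep <- idx <= nr
    C[idx[keep], j] <- nat[keep]
  }
  x <- nnls_solve(C, raw)
  if (sum(x) <= 0) stop("correct_derivative: degenerate deconvolution")
  x / sum(x)
}

# Lawson-Hanson style nonnegative least squares (active set), small problems.
nnls_solve <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Correct a skeleton MID for unlabeled inoculum biomass
#'
#' Harvested biomass contains a small fraction of the unlabeled inoculum
#' fronds (about 3.3% of final dry weight). The measured skeleton MID is a
#' mixture `(1-f) * true + f * natural`; this function inverts the mixture,
#' clips small negatives and renormalizes.
#'
#' @param mid skeleton MID after derivative correction.
#' @param f_unlabeled unlabeled inoculum mass fraction (default 0.033).
#' @param natural_skeleton natural-abundance MID of the skeleton carbons
#'   (defaults to `natural_mid` of `length(mid) - 1` carbons).
#' @return corrected MID.
#' @export
correct_inoculum <- function(mid, f_unlabeled = 0.033,
                             natural_skeleton = NULL) {
  if (f_unlabeled < 0 || f_unlabeled >= 1)
    stop("correct_inoculum: f_unlabeled must be in [0, 1)")
  if (is.null(natural_skeleton))
    natural_skeleton <- natural_mid(c(C = length(mid) - 1L))
  out <- (mid - f_unlabeled * natural_skeleton) / (1 - f_unlabeled)
  out <- pmax(out, 0)
  out / sum(out)
}

#' Forward inoculum mixing (inverse of [correct_inoculum()])
#' @inheritParams correct_inoculum
#' @return mixed MID.
#' @export
mix_inoculum <- function(mid, f_unlabeled = 0.033, natural_skeleton = NULL) {
  if (is.null(natural_skeleton))
    natural_skeleton <- natural_mid(c(C = length(mid) - 1L))
  (1 - f_unlabeled) * mid + f_unlabeled * natural_skeleton
}
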