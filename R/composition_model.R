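# Size and shape from amino-acid composition: V ~ 203 N, A ~ 47 Ns,
# inversion of the surface-area model for alpha, the binary
# hydrophobic/polar (HP) composition model, the minimum chain length for a
# 0.55 surface fraction, and mutation accommodation.

#' Composition profile of a protein chain
#'
#' @param counts named integer vector of residue-type counts (names are
#'   3-letter or 1-letter types; only used to total N and weight the
#'   propensities).
#' @param propensity named numeric vector of per-type surface propensities
#'   in \[0, 1\] (probability of a residue of that type being at the
#'   surface); types missing from it get the mean propensity.
#' @return a `composition_profile`: `counts`, `N`, `Ns` (propensity-
#'   weighted surface-residue estimate).
#' @export
composition_profile <- function(counts, propensity = NULL) {
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  N <- sum(counts)
  if (is.null(propensity)) propensity <- default_surface_propensity()
  p <- propensity[names(counts)]
  p[is.na(p)] <- mean(propensity)
  Ns <- sum(counts * p)
  out <- list(counts = counts, N = N, Ns = Ns,
              propensity = propensity)
  class(out) <- "composition_profile"
  out
}

#' Synthetic default surface-propensity table
#'
#' A packaged, clearly non-canonical stand-in: propensities spread over
#' \[0.25, 0.95\] across the 20 amino-acid types, ordered by a standard
#' hydrophobicity ranking (hydrophobic buried, polar/charged exposed),
#' scaled so the composition-weighted mean is about 0.55 for typical
#' compositions. Supply a measured table for real analyses.
#'
#' @return named numeric vector over the 20 three-letter types.
#' @export
default_surface_propensity <- function() {
  # Kyte-Doolittle order, most hydrophobic (most buried) first
  types <- c("ILE", "VAL", "LEU", "PHE", "CYS", "MET", "ALA", "GLY",
             "THR", "SER", "TRP", "TYR", "PRO", "HIS", "GLU", "GLN",
             "ASP", "ASN", "LYS", "ARG")
  setNames(seq(0.25, 0.95, length.out = length(types)), types)
}

#' Predict volume and surface area from composition
#'
#' \eqn{V \approx 203 N} Angstrom^3 (equivalent radius 3.1 Angstrom per
#' residue at packing density 0.64) and \eqn{A \approx 47 N_s} Angstrom^2,
#' where \eqn{N_s} is the surface-residue count estimated from the
#' propensity-weighted composition.
#'
#' @param profile a [composition_profile()], or a list with `N` and `Ns`.
#' @param v volume per residue (default 203 A^3).
#' @param s area per surface residue (default 47 A^2).
#' @return list: `V` (A^3), `A` (A^2), `N`, `Ns`.
#' @export
predict_size <- function(profile, v = 203, s = 47) {
  list(V = v * profile$N, A = s * profile$Ns,
       N = profile$N, Ns = profile$Ns)
}

#' Aspect ratio from volume, surface area and beta
#'
#' Inverts the surface-area model: finds the unique \eqn{\alpha \in
#' \[1, 50\]} whose model area at the given volume and beta equals A, by
#' bracketed root finding (tolerance 1e-9).
#'
#' @param V volume (A^3); @param A surface area (A^2).
#' @param beta shape exponent.
#' @return alpha.
#' @export
alpha_from_composition <- function(V, A, beta = 0.34) {
  A_sphere <- (36 * pi * V^2)^(1 / 3)
  if (A < A_sphere * (1 - 1e-12))
    stop("sub-spherical area: A below the sphere minimum for this volume")
  if (abs(A - A_sphere) <= 1e-12 * A_sphere) return(1)
  f <- function(alpha) surface_area_model(alpha, beta, V) - A
  if (f(50) < 0) stop("alpha exceeds the search bracket [1, 50]")
  uniroot(f, c(1, 50), tol = 1e-9)$root
}

#' Minimum chain length for a fixed surface fraction
#'
#' With V = vN and A = s f N, the chain length at which the predicted
#' area equals that of the sphere of equivalent volume is
#' \eqn{N_{\min} = 36\pi v^2 / (f^3 s^3)}; the defaults (f = 0.55,
#' v = 203, s = 47) give 270 residues. Shorter chains need a higher
#' surface fraction; longer ones become elliptical.
#'
#' @param f surface fraction Ns/N (default 0.55).
#' @param v volume per residue (A^3); @param s area per surface residue
#'   (A^2).
#' @param round_result round to the nearest integer?
#' @return minimum residue count.
#' @export
minimum_length <- function(f = 0.55, v = 203, s = 47,
                           round_result = TRUE) {
  n <- 36 * pi * v^2 / (f^3 * s^3)
  if (round_result) round(n) else n
}

#' Binary surface/buried (HP) composition model
#'
#' Treats the chain as a binary sequence of surface (polar) and buried
#' (hydrophobic) residues. The binomial mode puts the two classes in
#' equal amounts, so the most frequent composition has
#' \eqn{N_s = N/2}; the implied aspect ratio is solved over a beta grid.
#' Chains below the minimum length for f = 0.5 are flagged sub-spherical.
#'
#' @param N chain length (>= 2).
#' @param beta_grid beta values for the alpha(beta) curve.
#' @param v,s size constants as in [predict_size()].
#' @return list: `Ns`, `curve` (data frame beta, alpha), `feasible`.
#' @export
hp_model <- function(N, beta_grid = seq(0, 1, by = 0.05), v = 203,
                     s = 47) {
  stopifnot(N >= 2)
  Ns <- round(N / 2)
  V <- v * N
  A <- s * Ns
  feasible <- A >= (36 * pi * V^2)^(1 / 3)
  curve <- data.frame(beta = beta_grid, alpha = NA_real_)
  if (feasible) {
    curve$alpha <- vapply(beta_grid, function(b)
      alpha_from_composition(V, A, b), 0)
  }
  list(Ns = Ns, curve = curve, feasible = feasible)
}

#' Shape response to mutations at the surface or core
#'
#' Applies residue insertions/deletions at the surface or in the core, or
#' surface/core swaps, recomputes V and A, and re-solves the aspect
#' ratio. Positive `k` inserts (or swaps core-to-surface), negative
#' deletes (or swaps surface-to-core).
#'
#' @param N,Ns baseline chain length and surface-residue count.
#' @param edit `"surface"`, `"core"` or `"swap"`.
#' @param k signed residue count of the edit.
#' @param beta shape exponent held fixed.
#' @param v,s size constants.
#' @return list: `alpha0`, `alpha`, `delta_alpha`, `N`, `Ns`,
#'   `feasible` (FALSE when the edited area falls below the sphere
#'   minimum).
#' @export
mutation_accommodation <- function(N, Ns, edit = c("surface", "core",
                                                   "swap"),
                                   k = 0, beta = 0.34, v = 203, s = 47) {
  edit <- match.arg(edit)
  N2 <- switch(edit, surface = N + k, core = N + k, swap = N)
  Ns2 <- switch(edit, surface = Ns + k, core = Ns, swap = Ns + k)
  if (N2 < 1 || Ns2 < 0 || Ns2 > N2)
    stop("edit leaves an invalid composition")
  a0 <- tryCatch(alpha_from_composition(v * N, s * Ns, beta),
                 error = function(e) NA_real_)
  a1 <- tryCatch(alpha_from_composition(v * N2, s * Ns2, beta),
                 error = function(e) NA_real_)
  list(alpha0 = a0, alpha = a1, delta_alpha = a1 - a0,
       N = N2, Ns = Ns2, feasible = !is.na(a1))
}
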