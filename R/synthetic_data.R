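# Synthetic-structure generators: uniform-density atom clouds filling a
# prescribed triaxial ellipsoid, touching dimer pairs with known contact
# geometry, and residue scalar patterns. Everything the pipeline needs is
# generated in code, deterministically under a seed.

#' Generator specification for synthetic atom clouds
#'
#' Defaults emulate globular-protein packing: an equivalent radius of
#' 3.1 Angstrom per residue at packing density 0.64 (so about 203
#' Angstrom^3 of ellipsoid volume per residue), 8 atoms per residue, and
#' element frequencies C:N:O:S of roughly 62:17:20:1.
#'
#' @param semi_axes target semi-axes (a, b, c) in Angstrom.
#' @param n_residues residue count; defaults from the 203 A^3/residue
#'   volume law for the requested ellipsoid.
#' @param atoms_per_residue atoms per residue (default 8).
#' @param density packing density in (0, 0.74\] (default 0.64) —
#'   generator metadata, not enforced exactly (atoms are sampled, not
#'   packed).
#' @param seed RNG seed.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(semi_axes = c(30, 20, 10), n_residues = NULL,
                           atoms_per_residue = 8, density = 0.64,
                           seed = 1) {
  stopifnot(all(semi_axes > 0), density > 0, density <= 0.74)
  semi_axes <- sort(semi_axes, decreasing = TRUE)
  if (is.null(n_residues))
    n_residues <- max(1L, round(4 * pi / 3 * prod(semi_axes) / 203))
  out <- list(semi_axes = semi_axes, n_residues = as.integer(n_residues),
              atoms_per_residue = as.integer(atoms_per_residue),
              density = density, seed = seed)
  class(out) <- "generator_spec"
  out
}

.element_mix <- c(C = 0.62, N = 0.17, O = 0.20, S = 0.01)

#' Synthetic atom cloud uniformly filling an ellipsoid
#'
#' Atoms are placed uniformly inside the target ellipsoid (exact
#' rejection-free sampling via the radial cube-root transform), elements
#' drawn from a protein-like C:N:O:S mixture, and one atom per residue
#' flagged as the C-alpha. Deterministic under the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @param n_atoms total atom count; defaults to residues x
#'   atoms-per-residue.
#' @return an [atom_cloud()] with ground-truth attributes `semi_axes`.
#' @export
make_ellipsoid_cloud <- function(spec = generator_spec(),
                                 n_atoms = NULL) {
  set.seed(spec$seed)
  if (is.null(n_atoms))
    n_atoms <- spec$n_residues * spec$atoms_per_residue
  ax <- spec$semi_axes
  # uniform in the unit ball, then affine stretch
  u <- matrix(rnorm(3 * n_atoms), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n_atoms)^(1 / 3)
  P <- sweep(u, 2, ax, "*")
  elem <- sample(names(.element_mix), n_atoms, replace = TRUE,
                 prob = .element_mix)
  resno <- rep(seq_len(spec$n_residues),
               length.out = n_atoms)[order(runif(n_atoms))]
  resno <- sort(resno)
  calpha <- !duplicated(resno) & elem == "C"
  # guarantee one C-alpha per residue: force the first atom of each
  # residue to carbon
  first <- !duplicated(resno)
  elem[first] <- "C"
  calpha <- first
  cl <- atom_cloud(element = elem, x = P[, 1], y = P[, 2], z = P[, 3],
                   resno = resno,
                   resid = sample(names(default_surface_propensity()),
                                  n_atoms, replace = TRUE),
                   calpha = calpha,
                   source = sprintf("synthetic ellipsoid (%.1f,%.1f,%.1f)",
                                    ax[1], ax[2], ax[3]))
  # one residue type per residue
  types <- sample(names(default_surface_propensity()),
                  spec$n_residues, replace = TRUE)
  cl$resid <- types[cl$resno]
  attr(cl, "semi_axes") <- ax
  cl
}

#' Synthetic dimer of two touching ellipsoidal clouds
#'
#' Poses cloud B in external tangency with cloud A along a requested body
#' direction of A (its a, b or c axis by default), labels the chains A
#' and B, and records the ground-truth contact angles.
#'
#' @param specA,specB [generator_spec()]s for the two partners.
#' @param contact `"a"`, `"b"`, `"c"`, or a unit direction in A's body
#'   frame.
#' @return a two-chain [atom_cloud()] with attributes `contact_truth`
#'   (list of theta/phi on each partner) and `ellipsoids` (the posed
#'   ground-truth ellipsoids).
#' @export
make_dimer <- function(specA = generator_spec(c(24, 18, 12), seed = 11),
                       specB = generator_spec(c(24, 18, 12), seed = 12),
                       contact = "c") {
  dirA <- switch(as.character(contact)[1],
                 a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1),
                 as.numeric(contact))
  dirA <- dirA / sqrt(sum(dirA^2))
  clA <- make_ellipsoid_cloud(specA)
  clB <- make_ellipsoid_cloud(specB)
  axA <- specA$semi_axes; axB <- specB$semi_axes
  # surface point of A along dirA; B approaches head-on along -dirA with
  # its own matching-axis pole, so the pair touches at that point
  angA <- suppressWarnings(invert_surface_point(
    ellipsoid(axA[1], axA[2], axA[3]), dirA * axA, tol = Inf))
  pA <- surface_point(ellipsoid(axA[1], axA[2], axA[3]),
                      angA$theta, angA$phi)
  tA <- sqrt(sum(pA^2))
  # distance from B's centre to its surface along -dirA (B unrotated)
  angB <- suppressWarnings(invert_surface_point(
    ellipsoid(axB[1], axB[2], axB[3]), -dirA * axB, tol = Inf))
  pB <- surface_point(ellipsoid(axB[1], axB[2], axB[3]),
                      angB$theta, angB$phi)
  tB <- sqrt(sum(pB^2))
  offset <- dirA * (tA + tB)
  clB$x <- clB$x + offset[1]
  clB$y <- clB$y + offset[2]
  clB$z <- clB$z + offset[3]
  clB$chain <- "B"
  clB$resno <- clB$resno + max(clA$resno)
  out <- rbind(clA, clB)
  class(out) <- class(clA)
  attr(out, "source") <- "synthetic dimer"
  attr(out, "contact_truth") <- list(A = angA, B = angB)
  attr(out, "ellipsoids") <- list(
    A = ellipsoid(axA[1], axA[2], axA[3]),
    B = ellipsoid(axB[1], axB[2], axB[3],
                  centroid = offset))
  out
}

#' Synthetic residue scalar patterns
#'
#' Emulates per-position scalar fields on a structure: `"uniform"` (all
#' equal), `"c-pole-low"` (surface values halved, by default, in a cap
#' around the c-axis poles — the conserved-patch pattern), and
#' `"radial-gradient"` (core values a factor `core_ratio` lower than
#' surface — the core-conservation pattern), plus multiplicative noise.
#'
#' @param cloud an [atom_cloud()].
#' @param pattern `"uniform"`, `"c-pole-low"` or `"radial-gradient"`.
#' @param contrast surface contrast ratio for `"c-pole-low"` (default 2).
#' @param core_ratio core-to-surface ratio for `"radial-gradient"`
#'   (default 4).
#' @param cap_deg angular radius of the c-pole cap, degrees.
#' @param noise_sd multiplicative log-normal noise sd (0 = none).
#' @param seed RNG seed.
#' @return a `residue_scalar_table` (baseline value 1).
#' @export
make_residue_scalars <- function(cloud,
                                 pattern = c("uniform", "c-pole-low",
                                             "radial-gradient"),
                                 contrast = 2, core_ratio = 4,
                                 cap_deg = 30, noise_sd = 0, seed = 1) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  ell <- steric_ellipsoid(cloud)
  m <- fractional_radial_extent(cloud, ell)
  val <- rep(1, nrow(m))
  if (pattern == "c-pole-low") {
    ca <- cloud[cloud$calpha, , drop = FALSE]
    P <- sweep(as.matrix(ca[, c("x", "y", "z")]), 2, ell$centroid)
    B <- P %*% ell$rotation
    ang <- suppressWarnings(invert_surface_point(ell, B, tol = Inf))
    # angular distance from the c poles (theta = 90, phi = 90 or 270)
    p <- surface_point(ell, ang$theta, ang$phi)
    p <- rbind(p)
    u <- p / sqrt(rowSums(p^2))
    polar <- acos(pmin(1, abs(u[, 3]))) * 180 / pi  # 0 at c poles
    val[polar < cap_deg] <- 1 / contrast
  } else if (pattern == "radial-gradient") {
    # linear in m from 1/core_ratio (core) to 1 (surface)
    val <- 1 / core_ratio + (1 - 1 / core_ratio) * pmin(m$value, 1)
  }
  if (noise_sd > 0) val <- val * exp(rnorm(length(val), 0, noise_sd))
  residue_scalar_table(m$residue_index, val)
}
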