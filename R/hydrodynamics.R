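# Dilute-limit hydrodynamics of triaxial ellipsoids: Carlson symmetric
# elliptic integrals (duplication algorithm), per-axis translational and
# rotational diffusion with a hydration layer, inverse-cube-root mass
# scaling laws, and surface-point short-time diffusion.

# physical constants (CGS): Boltzmann in erg/K; 1 mPa.s = 0.01 poise;
# 1 Angstrom = 1e-8 cm
.kB_erg <- 1.380649e-16
.mPas_to_poise <- 0.01
.A_to_cm <- 1e-8

#' Carlson symmetric elliptic integral of the first kind
#'
#' \deqn{R_F(x,y,z) = \frac12 \int_0^\infty
#'   \frac{d\lambda}{\sqrt{(x+\lambda)(y+\lambda)(z+\lambda)}}}
#' evaluated by the duplication algorithm to relative tolerance ~1e-12.
#' Homogeneous of degree -1/2; \eqn{R_F(1,1,1) = 1}.
#'
#' @param x,y,z non-negative arguments, at most one zero.
#' @return value of the integral.
#' @export
carlson_rf <- function(x, y, z) {
  if (any(c(x, y, z) < 0) || sum(c(x, y, z) == 0) > 1)
    stop("carlson_rf: require x,y,z >= 0 with at most one zero")
  errtol <- 1e-12
  repeat {
    mu <- (x + y + z) / 3
    dx <- (mu - x) / mu; dy <- (mu - y) / mu; dz <- (mu - z) / mu
    if (max(abs(c(dx, dy, dz))) < errtol^(1 / 6)) break
    sx <- sqrt(x); sy <- sqrt(y); sz <- sqrt(z)
    lam <- sx * (sy + sz) + sy * sz
    x <- (x + lam) / 4; y <- (y + lam) / 4; z <- (z + lam) / 4
  }
  e2 <- dx * dy - dz * dz
  e3 <- dx * dy * dz
  (1 + (e2 / 24 - 0.1 - 3 * e3 / 44) * e2 + e3 / 14) / sqrt(mu)
}

#' Carlson symmetric elliptic integral of the second kind
#'
#' \deqn{R_D(x,y,z) = \frac32 \int_0^\infty
#'   \frac{d\lambda}{(z+\lambda)\sqrt{(x+\lambda)(y+\lambda)(z+\lambda)}}}
#' by the duplication algorithm. Homogeneous of degree -3/2;
#' \eqn{R_D(1,1,1) = 1}.
#'
#' @param x,y non-negative (at most one zero); z strictly positive.
#' @return value of the integral.
#' @export
carlson_rd <- function(x, y, z) {
  if (any(c(x, y) < 0) || z <= 0 || sum(c(x, y) == 0) > 1)
    stop("carlson_rd: require x,y >= 0 (at most one zero) and z > 0")
  errtol <- 1e-12
  sum_ <- 0; fac <- 1
  repeat {
    mu <- (x + y + 3 * z) / 5
    dx <- (mu - x) / mu; dy <- (mu - y) / mu; dz <- (mu - z) / mu
    if (max(abs(c(dx, dy, dz))) < errtol^(1 / 6)) break
    sx <- sqrt(x); sy <- sqrt(y); sz <- sqrt(z)
    lam <- sx * (sy + sz) + sy * sz
    sum_ <- sum_ + fac / (sz * (z + lam))
    fac <- fac / 4
    x <- (x + lam) / 4; y <- (y + lam) / 4; z <- (z + lam) / 4
  }
  ea <- dx * dy
  eb <- dz * dz
  ec <- ea - eb
  ed <- ea - 6 * eb
  ee <- ed + ec + ec
  3 * sum_ + fac * (1 + ed * (-3 / 14 + 9 / 88 * ed - 4.5 / 26 * dz * ee) +
                      dz * (1 / 6 * ee + dz * (-9 / 22 * ec +
                                                 3 / 26 * dz * ea))) /
    (mu * sqrt(mu))
}

#' Dilute-limit diffusion constants of a hydrated triaxial ellipsoid
#'
#' Dilates the semi-axes by a stationary hydration layer `dH` and evaluates
#' the Perrin-type per-axis translational constants
#' \deqn{D^0_{ta} = \frac{k_B T}{6\pi\eta}\,
#'   \frac{3 R_F(a'^2,b'^2,c'^2) + R_D(b'^2,c'^2,a'^2)\,a'^2}{4}}
#' (and cyclic permutations) and rotational constants
#' \deqn{D^0_{ra} = \frac{k_B T}{8\pi\eta}\,
#'   \frac{R_D(c'^2,a'^2,b'^2)\,b'^2 + R_D(a'^2,b'^2,c'^2)\,c'^2}
#'        {b'^2 + c'^2}}
#' with means taken as arithmetic averages of the three axes. The default
#' hydration width is 2.32 Angstrom for structures without hydrogens and
#' 2.30 Angstrom with.
#'
#' @param ell an `equivalent_ellipsoid` (semi-axes in Angstrom).
#' @param dH hydration layer width in Angstrom; `"auto"` selects by the
#'   `hydrogens` flag.
#' @param T temperature in Kelvin.
#' @param eta solvent viscosity in mPa s.
#' @param hydrogens were hydrogens present in the structure? Used only when
#'   `dH = "auto"`.
#' @return a `hydro_result`: per-axis and mean `Dt` (cm^2/s) and `Dr`
#'   (1/s), the hydrated semi-axes, equivalent radius `r_prime`, and the
#'   provenance (`T`, `eta`, `dH`).
#' @export
dilute_diffusion <- function(ell, dH = "auto", T = 293.15, eta = 1.0016,
                             hydrogens = FALSE) {
  if (identical(dH, "auto")) dH <- if (hydrogens) 2.30 else 2.32
  stopifnot(dH >= 0, T > 0, eta > 0)
  ap <- ell$a + dH; bp <- ell$b + dH; cp <- ell$c + dH
  a2 <- (ap * .A_to_cm)^2; b2 <- (bp * .A_to_cm)^2; c2 <- (cp * .A_to_cm)^2
  kT <- .kB_erg * T
  visc <- eta * .mPas_to_poise
  rf <- carlson_rf(a2, b2, c2)
  rd_a <- carlson_rd(b2, c2, a2)
  rd_b <- carlson_rd(c2, a2, b2)
  rd_c <- carlson_rd(a2, b2, c2)
  pre_t <- kT / (6 * pi * visc)
  Dt <- pre_t * c(a = (3 * rf + rd_a * a2) / 4,
                  b = (3 * rf + rd_b * b2) / 4,
                  c = (3 * rf + rd_c * c2) / 4)
  pre_r <- kT / (8 * pi * visc)
  Dr <- pre_r * c(a = (rd_b * b2 + rd_c * c2) / (b2 + c2),
                  b = (rd_c * c2 + rd_a * a2) / (c2 + a2),
                  c = (rd_a * a2 + rd_b * b2) / (a2 + b2))
  rp <- (ap * bp * cp)^(1 / 3)
  out <- list(Dt = Dt, Dt_mean = mean(Dt),
              Dr = Dr, Dr_mean = mean(Dr),
              T = T, eta = eta, dH = dH,
              a_prime = ap, b_prime = bp, c_prime = cp, r_prime = rp)
  class(out) <- "hydro_result"
  out
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("<hydro_result> T=%.2f K, eta=%.4f mPa.s, dH=%.2f A\n",
              x$T, x$eta, x$dH))
  cat(sprintf("  hydrated semi-axes %.2f / %.2f / %.2f A (r'=%.2f)\n",
              x$a_prime, x$b_prime, x$c_prime, x$r_prime))
  cat(sprintf("  Dt (a,b,c) = %.3e %.3e %.3e cm^2/s  mean %.3e\n",
              x$Dt[1], x$Dt[2], x$Dt[3], x$Dt_mean))
  cat(sprintf("  Dr (a,b,c) = %.3e %.3e %.3e 1/s     mean %.3e\n",
              x$Dr[1], x$Dr[2], x$Dr[3], x$Dr_mean))
  invisible(x)
}

#' Shape-form mean translational diffusion
#'
#' Equivalent closed form of the mean translational constant in terms of
#' the hydrated shape \eqn{(\alpha', \beta')} and equivalent radius
#' \eqn{r' = (a'b'c')^{1/3}}:
#' \deqn{D^0_t = \frac{k_B T}{6\pi\eta r'}
#'   R_F\!\big((\alpha'^{2-\beta'})^{2/3}, (\alpha'^{2\beta'-1})^{2/3},
#'             (\alpha'^{\beta'+1})^{-2/3}\big).}
#' Used as an internal cross-check against the per-axis mean (agreement to
#' 1e-9 relative) and by the mass scaling laws.
#'
#' @param alpha_p,beta_p hydrated shape descriptors.
#' @param r_prime hydrated equivalent radius in Angstrom.
#' @param T temperature (K); @param eta viscosity (mPa s).
#' @return mean translational diffusion constant in cm^2/s.
#' @export
dt_mean_shape <- function(alpha_p, beta_p, r_prime, T = 293.15,
                          eta = 1.0016) {
  kT <- .kB_erg * T
  visc <- eta * .mPas_to_poise
  rf <- carlson_rf((alpha_p^(2 - beta_p))^(2 / 3),
                   (alpha_p^(2 * beta_p - 1))^(2 / 3),
                   (alpha_p^(beta_p + 1))^(-2 / 3))
  kT / (6 * pi * visc * r_prime * .A_to_cm) * rf
}

#' Fit the inverse-cube-root mass scaling law for dilute diffusion
#'
#' Over a log-spaced grid of protein masses, sets the hydrated equivalent
#' volume to \eqn{(4\pi/3) r'^3 = 2.39 M_p} Angstrom^3 at the modal shape
#' (\eqn{\alpha' = 1.65, \beta' = 0.34} by default), computes the mean
#' translational constant, and least-squares fits
#' \eqn{D_t = c\, M_p^{-1/3}} in log-log space. At 20 C and 1.0016 mPa s
#' the translational prefactor is about 252 (in 1e-7 cm^2/s with mass in
#' Da), equivalently about 52 per cube-root residue at ~110 Da/residue.
#' The rotational constant is fitted as \eqn{c_r M_p^{-1}} analogously.
#'
#' @param alpha_p,beta_p hydrated modal shape.
#' @param volume_per_Da hydrated ellipsoid volume per Dalton (A^3/Da).
#' @param T temperature (K); @param eta viscosity (mPa s).
#' @param mass_range mass range in Da; @param n_mass grid size.
#' @param crowding_factor multiplies the translational constants (e.g. the
#'   long-time crowded ratio at cellular volume fraction) before fitting.
#' @return list with `prefactor_t` (1e-7 cm^2/s Da^(1/3)),
#'   `prefactor_t_residue` (per N^(1/3), 110 Da/residue),
#'   `prefactor_r` (1e7/s * Da), and the fitted grid.
#' @export
scaling_law_fit <- function(alpha_p = 1.65, beta_p = 0.34,
                            volume_per_Da = 2.39,
                            T = 293.15, eta = 1.0016,
                            mass_range = c(1e4, 1e6), n_mass = 40,
                            crowding_factor = 1) {
  M <- exp(seq(log(mass_range[1]), log(mass_range[2]), length.out = n_mass))
  rp <- (3 * volume_per_Da * M / (4 * pi))^(1 / 3)
  Dt <- vapply(rp, function(r)
    dt_mean_shape(alpha_p, beta_p, r, T, eta), 0) * crowding_factor
  # ellipsoid with the same (alpha', beta', r'): semi-axes for Dr
  cshape <- rp / alpha_p^((1 + beta_p) / 3)
  Dr <- mapply(function(cc, r) {
    ell <- ellipsoid(alpha_p * cc, alpha_p^beta_p * cc, cc)
    dilute_diffusion(ell, dH = 0, T = T, eta = eta)$Dr_mean
  }, cshape, rp)
  fit_t <- lm(log(Dt) ~ offset(-log(M) / 3))
  fit_r <- lm(log(Dr) ~ offset(-log(M)))
  ct <- exp(coef(fit_t)[[1]]) / 1e-7
  cr <- exp(coef(fit_r)[[1]]) / 1e7
  list(prefactor_t = ct,
       prefactor_t_residue = ct / 110^(1 / 3),
       prefactor_r = cr,
       mass = M, Dt = Dt, Dr = Dr)
}

#' Short-time effective diffusion of a surface point
#'
#' For a point (x, y, z) on the ellipsoid surface (body frame), the
#' rotation-dominated short-time translational constant is
#' \deqn{D_{tp} \approx D_t + \tfrac13\big[D_{ra}(y^2+z^2) +
#'   D_{rb}(x^2+z^2) + D_{rc}(x^2+y^2)\big].}
#' Highest at the a-axis poles (fastest-sweeping points), lowest at the
#' c-axis poles.
#'
#' @param ell an `equivalent_ellipsoid` (Angstrom).
#' @param hydro a `hydro_result` for the same ellipsoid.
#' @param theta polar angle from the a axis, degrees.
#' @param phi azimuth from the b axis toward c, degrees.
#' @return effective translational constant (cm^2/s); vectorized over
#'   `theta`/`phi`.
#' @export
surface_point_diffusion <- function(ell, hydro, theta, phi) {
  p <- surface_point(ell, theta, phi)         # Angstrom, body frame
  p <- rbind(p) * .A_to_cm
  x2 <- p[, 1]^2; y2 <- p[, 2]^2; z2 <- p[, 3]^2
  hydro$Dt_mean + (hydro$Dr["a"] * (y2 + z2) +
                     hydro$Dr["b"] * (x2 + z2) +
                     hydro$Dr["c"] * (x2 + y2)) / 3
}

#' Hydration level implied by a hydration shell
#'
#' Shell volume (dilated minus dry equivalent-ellipsoid volume) times the
#' bound-water density 1.104 g/mL divided by the protein mass.
#'
#' @param ell an `equivalent_ellipsoid` (Angstrom).
#' @param dH hydration width (Angstrom).
#' @param mass_Da protein mass in Da.
#' @param water_density bound-water density in g/mL.
#' @return list: `shell_volume` (A^3), `grams_per_gram`, `n_waters`.
#' @export
hydration_level <- function(ell, dH = 2.3, mass_Da,
                            water_density = 1.104) {
  Vdry <- 4 * pi / 3 * ell$a * ell$b * ell$c
  Vwet <- 4 * pi / 3 * (ell$a + dH) * (ell$b + dH) * (ell$c + dH)
  shell <- Vwet - Vdry
  grams <- shell * 1e-24 * water_density            # g per molecule
  avogadro <- 6.02214076e23
  n_w <- grams / (18.015 / avogadro)
  gg <- if (missing(mass_Da)) NA_real_ else
    grams / (mass_Da / avogadro)
  list(shell_volume = shell, grams_per_gram = gg, n_waters = n_w)
}
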