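test_that("the t-parameterization lands on the surface", {
  ell <- ellipsoid(3, 2, 1)
  expect_equal(unname(surface_point(ell, 0, 0)), c(3, 0, 0),
               tolerance = 1e-12)
  expect_equal(unname(surface_point(ell, 90, 0)), c(0, 2, 0),
               tolerance = 1e-12)
  expect_equal(unname(surface_point(ell, 90, 90)), c(0, 0, 1),
               tolerance = 1e-12)
  set.seed(5)
  th <- runif(500, 0, 180); ph <- runif(500, 0, 360)
  P <- surface_point(ell, th, ph)
  f <- (P[, 1] / 3)^2 + (P[, 2] / 2)^2 + P[, 3]^2
  expect_lt(max(abs(f - 1)), 1e-12)
})

test_that("surface-point inversion is the exact inverse", {
  ell <- ellipsoid(27, 15, 9)
  set.seed(6)
  th <- runif(1e4, 1e-3, 180 - 1e-3); ph <- runif(1e4, 0, 360)
  P <- surface_point(ell, th, ph)
  back <- invert_surface_point(ell, P)
  expect_lt(max(abs(back$theta - th)), 1e-6)
  dphi <- abs(back$phi - ph)
  expect_lt(max(pmin(dphi, 360 - dphi)), 1e-6)
  # poles and wrap-around
  expect_equal(invert_surface_point(ell, c(27, 0, 0))$theta, 0)
  near0 <- invert_surface_point(ell, surface_point(ell, 90, 0.0001))
  near360 <- invert_surface_point(ell, surface_point(ell, 90, 359.9999))
  d <- abs(near0$phi - near360$phi)
  expect_lt(min(d, 360 - d), 1e-3)
  expect_warning(invert_surface_point(ell, c(40, 0, 0)), "off-surface")
})

test_that("geodesic grid distances match great circles on a sphere", {
  R <- 10
  sph <- ellipsoid(R, R, R)
  g <- geodesic_distance_grid(sph, c(90, 0.5))
  expect_equal(g[91, 1], 0)
  expect_equal(g[91, 91], pi * R / 2, tolerance = 0.02)
  expect_equal(g[91, 181], pi * R, tolerance = 0.02)
  # pole-to-pole along a meridian
  g2 <- geodesic_distance_grid(sph, c(0.5, 0.5))
  expect_equal(g2[180, 1], pi * R, tolerance = 0.02)
})

test_that("geodesic grid is near-symmetric and matches a section arc", {
  ell <- ellipsoid(12, 8, 5)
  a2b <- geodesic_distance_grid(ell, c(0.5, 0.5))[91, 1]
  b2a <- geodesic_distance_grid(ell, c(90.5, 0.5))[1, 1]
  expect_equal(a2b, b2a, tolerance = 0.01)
  # quadrant of the b-c principal ellipse (the x = 0 section) against an
  # arc-length quadrature oracle
  quarter <- geodesic_distance_grid(ell, c(90.5, 0.5))[91, 91]
  tt <- seq(0, pi / 2, length.out = 20001)
  arc <- sum(sqrt((8 * sin(tt))^2 + (5 * cos(tt))^2)[-1] * diff(tt))
  expect_equal(quarter, arc, tolerance = 0.03)
})

test_that("gaussian deposits are additive with location-free mass", {
  sph <- ellipsoid(10, 10, 10)
  m0 <- surface_map(sph)
  m1 <- deposit_gaussian(m0, 90, 180)
  idx <- arrayInd(which.max(m1), dim(m1))
  expect_equal(idx[1], 91)
  expect_equal(idx[2], 181)
  # surface mass (pixel values weighted by pixel area ~ sin theta) is
  # independent of deposit location on a sphere; raw pixel sums are not,
  # since the equirectangular grid oversamples the poles
  wts <- matrix(rep(sin(seq(0.5, 179.5) * pi / 180), 360), 180)
  m_eq <- deposit_gaussian(m0, 90, 40)
  m_mid <- deposit_gaussian(m0, 45, 300)
  expect_equal(sum(m_eq * wts), sum(m_mid * wts), tolerance = 0.01)
  # additivity is exact
  both <- deposit_gaussian(m1, 45, 300)
  expect_equal(as.vector(both), as.vector(unclass(m1) + unclass(m_mid) -
                 unclass(m0)), tolerance = 1e-12)
  # antipodal deposits give a symmetric map
  sym <- deposit_gaussian(deposit_gaussian(m0, 90, 90), 90, 270)
  expect_equal(as.vector(sym), as.vector(unclass(sym)[, c(181:360, 1:180)]),
               tolerance = 1e-6)
})

test_that("maps respect the ellipsoid body symmetry", {
  ell <- ellipsoid(9, 6, 4)
  m0 <- surface_map(ell)
  up <- deposit_gaussian(m0, 60.5, 40.5)
  down <- deposit_gaussian(m0, 119.5, 40.5)    # theta -> 180 - theta
  expect_equal(as.vector(unclass(up)[1:180, ]),
               as.vector(unclass(down)[180:1, ]), tolerance = 0.02)
  neg <- deposit_gaussian(m0, 60.5, 319.5)     # phi -> -phi
  expect_equal(as.vector(up), as.vector(unclass(neg)[, 360:1]),
               tolerance = 0.02)
})

test_that("dimer contact centre solves the shrink-to-tangency problem", {
  sA <- ellipsoid(1, 1, 1)
  sB <- ellipsoid(1, 1, 1, centroid = c(1, 0, 0))
  dc <- dimer_contact_centre(sA, sB)
  expect_equal(dc$scale, 0.5, tolerance = 1e-6)
  expect_equal(dc$point, c(0.5, 0, 0), tolerance = 1e-6)
  expect_equal(dc$angles_A$theta, 0, tolerance = 1e-3)
  expect_equal(dc$angles_B$theta, 180, tolerance = 1e-3)

  # prolate pair along their a axes touch at the a poles
  pA <- ellipsoid(3, 1, 1)
  pB <- ellipsoid(3, 1, 1, centroid = c(6, 0, 0))
  dp <- dimer_contact_centre(pA, pB)
  expect_equal(dp$scale, 1, tolerance = 1e-6)
  expect_lt(dp$angles_A$theta, 0.01)

  expect_error(dimer_contact_centre(sA, ellipsoid(1, 1, 1)), "concentric")
})

test_that("tangency scale is bracketed by the overlap predicate", {
  set.seed(8)
  for (k in 1:5) {
    RA <- rotation_about(rnorm(3), runif(1, 0, pi))
    RB <- rotation_about(rnorm(3), runif(1, 0, pi))
    eA <- ellipsoid(3, 2, 1.2, rotation = RA)
    eB <- ellipsoid(2.5, 2, 1, rotation = RB,
                    centroid = rnorm(3) * 1.5 + c(3, 0, 0))
    dc <- dimer_contact_centre(eA, eB)
    s <- dc$scale
    shrink <- function(e, sc) ellipsoid(e$a * sc, e$b * sc, e$c * sc,
                                        rotation = e$rotation,
                                        centroid = e$centroid)
    F_in <- ellipshape:::pw_contact(shrink(eA, s * (1 + 1e-4)),
                                    shrink(eB, s * (1 + 1e-4)))$F
    F_out <- ellipshape:::pw_contact(shrink(eA, s * (1 - 1e-4)),
                                     shrink(eB, s * (1 - 1e-4)))$F
    expect_lt(F_in, 1)      # slightly larger bodies overlap
    expect_gt(F_out, 1)     # slightly smaller bodies separate
    # tangency point sits on both scaled surfaces
    for (e in list(eA, eB)) {
      b <- t(e$rotation) %*% (dc$point - e$centroid) / s
      f <- (b[1] / e$a)^2 + (b[2] / e$b)^2 + (b[3] / e$c)^2
      expect_equal(f, 1, tolerance = 1e-4)
    }
  }
})

test_that("residue-value maps localize synthetic patterns", {
  cl <- make_ellipsoid_cloud(generator_spec(c(24, 16, 10), seed = 21,
                                            n_residues = 250),
                             n_atoms = 4000)
  ell <- steric_ellipsoid(cl)
  # uniform values give a nearly uniform normalized value map
  tab_u <- make_residue_scalars(cl, "uniform")
  mp_u <- map_residue_values(cl, ell, tab_u, flat_degrees = TRUE)
  cnt <- attr(mp_u, "counts")
  ratio <- unclass(mp_u)[cnt > 0.05 * max(cnt)] /
    unclass(cnt)[cnt > 0.05 * max(cnt)]
  expect_lt(diff(range(ratio)), 1e-6)   # value/count ratio is constant

  # c-pole-low pattern: mean value around the c poles is depressed
  tab_c <- make_residue_scalars(cl, "c-pole-low", contrast = 2)
  mp_c <- map_residue_values(cl, ell, tab_c, flat_degrees = TRUE,
                             canonicalize = FALSE)
  cn <- attr(mp_c, "counts")
  avg <- unclass(mp_c) / pmax(unclass(cn), 1e-9)
  pole <- avg[81:100, c(81:100, 261:280)]
  away <- avg[81:100, c(1:20, 171:200)]
  expect_lt(mean(pole), mean(away))

  # canonicalization is idempotent
  mp1 <- map_residue_values(cl, ell, tab_c, flat_degrees = TRUE)
  low1 <- mean(unclass(mp1)[, 1:180]) <= mean(unclass(mp1)[, 181:360])
  expect_true(low1)
})

test_that("surface maps export as plain text matrices", {
  sph <- ellipsoid(5, 5, 5)
  m <- deposit_gaussian(surface_map(sph), 30, 60)
  norm <- normalize_map(m)
  expect_equal(max(norm), 1)
  path <- tempfile(fileext = ".txt")
  write_surface_map(norm, path)
  back <- as.matrix(read.table(path))
  expect_equal(dim(back), c(180L, 360L))
  expect_equal(unname(back), unclass(norm)[1:180, ], tolerance = 1e-6)
})
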