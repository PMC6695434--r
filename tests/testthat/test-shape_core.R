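test_that("inertia tensor matches the solid-sphere closed form", {
  r <- 1.7
  one <- atom_cloud("C", 0, 0, 0)
  I <- inertia_tensor(one)
  expect_equal(unclass(I)[1:9],
               diag(rep(4 * pi / 3 * r^3 * 2 / 5 * r^2, 3))[1:9],
               tolerance = 1e-12)
  expect_equal(attr(I, "M"), 4 * pi / 3 * r^3)

  two <- atom_cloud(c("C", "C"), x = c(-2, 2), y = 0, z = 0,
                    resno = c(1, 2))
  I2 <- inertia_tensor(two)
  expect_lt(I2[1, 1], I2[2, 2])
  expect_equal(I2[2, 2], I2[3, 3])
})

test_that("uniform ellipsoid fills recover the generating semi-axes", {
  cl <- make_ellipsoid_cloud(generator_spec(c(30, 20, 10), seed = 7),
                             n_atoms = 1e5)
  ell <- steric_ellipsoid(cl)
  expect_equal(c(ell$a, ell$b, ell$c), c(30, 20, 10), tolerance = 0.02)
  # inertia tensor close to the continuum formula for the same M
  I <- inertia_tensor(cl)
  ref <- solid_ellipsoid_tensor(30, 20, 10, attr(I, "M"))
  expect_equal(diag(I), diag(ref), tolerance = 0.01)
})

test_that("equivalent ellipsoid is exact for continuum-consistent input", {
  # sphere: single atom collapses to a = b = c = r
  ell1 <- equivalent_ellipsoid(inertia_tensor(atom_cloud("S", 0, 0, 0)))
  expect_equal(c(ell1$a, ell1$b, ell1$c), rep(1.8, 3), tolerance = 1e-12)

  # analytic solid-ellipsoid tensor with M equal to its volume: the
  # semi-axes and the steric volume are both recovered exactly
  a <- 24; b <- 17; c <- 9
  M <- 4 * pi / 3 * a * b * c
  ell <- equivalent_ellipsoid(solid_ellipsoid_tensor(a, b, c, M))
  expect_equal(c(ell$a, ell$b, ell$c), c(a, b, c), tolerance = 1e-12)
  expect_equal(ellipsoid_volume(ell), M, tolerance = 1e-12)

  # degenerate (planar) inertia is rejected
  T_bad <- diag(c(2, 1, 1)); attr(T_bad, "M") <- 1
  expect_error(equivalent_ellipsoid(T_bad, M = 1), "non-ellipsoidal")

  # rotation is orthonormal and right-handed
  expect_lt(max(abs(crossprod(ell$rotation) - diag(3))), 1e-10)
  expect_equal(det(ell$rotation), 1, tolerance = 1e-10)
})

test_that("alpha-beta descriptors and the prolate/oblate boundary", {
  expect_equal(shape_ab(ellipsoid(2, 2, 1))$beta, 1)
  expect_equal(shape_ab(ellipsoid(2, 2, 1))$class, "oblate")
  expect_equal(shape_ab(ellipsoid(2, 1, 1))$beta, 0)
  expect_equal(shape_ab(ellipsoid(2, 1, 1))$class, "prolate")
  s <- shape_ab(ellipsoid(1, 1, 1))
  expect_equal(s$class, "sphere")
  expect_true(is.na(s$beta))

  # the published worked example (semi-axes 23.4, 15.3, 13.9 A)
  s2 <- shape_ab(ellipsoid(23.4, 15.3, 13.9))
  expect_equal(s2$alpha, 1.69, tolerance = 0.01)
  expect_true(s2$beta > 0.18 && s2$beta < 0.19)

  # boundary curve: alpha^beta = b/c identity holds for classified shapes
  expect_equal(s2$alpha^s2$beta, 15.3 / 13.9, tolerance = 1e-9)
  # limits of the boundary formula: 1/2 at alpha -> 1+, increasing in
  # alpha, approaching 1 from below at large alpha
  al <- c(1 + 1e-6, 1.5, 2, 5, 10, 20)
  bb <- beta_boundary(al)
  expect_equal(bb[1], 0.5, tolerance = 1e-5)
  expect_true(all(diff(bb) > 0))
  expect_true(all(bb < 1))
})

test_that("shape descriptors are invariant under rigid rotation", {
  cl <- make_ellipsoid_cloud(generator_spec(c(25, 18, 11), seed = 3),
                             n_atoms = 20000)
  s0 <- shape_ab(steric_ellipsoid(cl))
  for (ang in c(0.4, 1.2)) {
    R <- rotation_about(c(1, 2, 0.5), ang)
    s1 <- shape_ab(steric_ellipsoid(rotate_cloud(cl, R)))
    expect_equal(s1$alpha, s0$alpha, tolerance = 1e-6)
    expect_equal(s1$beta, s0$beta, tolerance = 1e-6)
  }
})

test_that("calliper diameters match closed-form cases", {
  one <- atom_cloud("C", 0, 0, 0)       # radius 1.7
  cal <- calliper(one)
  expect_equal(cal$max, 3.4)
  expect_equal(cal$min, 3.4)
  expect_equal(cal$ratio, 1)

  two <- atom_cloud(c("X1", "X2"), x = c(0, 10), y = 0, z = 0,
                    radius = 1, resno = 1:2)
  cal2 <- calliper(two)
  expect_equal(cal2$max, 12, tolerance = 1e-9)
  expect_equal(cal2$min, 2, tolerance = 1e-9)

  # ellipsoid fill: bare-coordinate ratio approaches a/c
  cl <- make_ellipsoid_cloud(generator_spec(c(30, 20, 10), seed = 4),
                             n_atoms = 4000)
  cal3 <- calliper(cl, pad_radius = FALSE)
  expect_equal(cal3$ratio, 3, tolerance = 0.06)
  expect_gte(cal3$ratio, 1)
})

test_that("surface-area model matches the sphere and the exact integral", {
  V <- 1000
  expect_equal(surface_area_model(1, 0.5, V), (36 * pi * V^2)^(1 / 3))
  expect_equal(isoperimetric_quotient(1, 0.3), 1)
  # monotone increasing in alpha at fixed beta and volume
  for (b in c(0, 0.5, 1)) {
    A <- surface_area_model(seq(1, 4, by = 0.1), b, V)
    expect_true(all(diff(A) > 0))
    expect_true(all(isoperimetric_quotient(seq(1.1, 4, 0.2), b) < 1))
  }
  # alpha = 2, beta = 0.5: within the Thomsen bound of the exact area
  cc <- (3 * V / (4 * pi * 2^1.5))^(1 / 3)
  exact <- ellipsoid_area_exact(2 * cc, 2^0.5 * cc, cc)
  expect_equal(surface_area_model(2, 0.5, V), exact, tolerance = 0.011)
})

test_that("order parameter has the nematic limits", {
  a_axis <- c(1, 0, 0)
  par <- matrix(rep(c(2, 0, 0), 5), ncol = 3, byrow = TRUE)
  expect_equal(order_parameter(par, a_axis), 1)
  perp <- matrix(c(0, 1, 0, 0, 0, 3), ncol = 3, byrow = TRUE)
  expect_equal(order_parameter(perp, a_axis), -0.5)
  set.seed(42)
  v <- matrix(rnorm(3e4), ncol = 3)
  expect_lt(abs(order_parameter(v, a_axis)), 0.02)
  expect_warning(order_parameter(rbind(c(0, 0, 0), c(1, 0, 0)), a_axis),
                 "zero-length")
})

test_that("fractional radial extent is 0 at the core and 1 on the surface", {
  ell <- ellipsoid(3, 2, 1)
  cl <- atom_cloud(c("C", "C", "C"),
                   x = c(0, 0, 3), y = c(0, 2, 0), z = 0,
                   resno = 1:3, calpha = TRUE)
  m <- fractional_radial_extent(cl, ell)
  expect_equal(m$value, c(0, 1, 1), tolerance = 1e-9)
  expect_named(attributes(m)$type_means, "ALA")
})

test_that("shape distribution finds the generating mode", {
  one <- shape_distribution(data.frame(alpha = 1.4, beta = 0.6))
  expect_equal(unname(one$mode), c(1.4, 0.6), tolerance = 0.011)

  two <- shape_distribution(data.frame(
    alpha = c(rep(1.3, 10), rep(2.2, 3)),
    beta = c(rep(0.2, 10), rep(0.8, 3))))
  expect_equal(unname(two$mode[1]), 1.3, tolerance = 0.011)

  set.seed(9)
  samp <- data.frame(alpha = rnorm(300, 1.65, 0.03),
                     beta = rnorm(300, 0.34, 0.03))
  d <- shape_distribution(samp)
  expect_equal(unname(d$mode), c(1.65, 0.34), tolerance = 0.05)
})
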