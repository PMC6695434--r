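test_that("calibration sets soft-contact energies to 1 along each axis", {
  for (al in c(1, 1.6, 2)) {
    cfg <- sim_config(alpha = al)
    ax <- cfg$semi_axes
    expect_equal(4 * pi / 3 * prod(ax), 1, tolerance = 1e-12)
    I3 <- diag(3)
    expect_equal(gay_berne(c(2 * ax[1], 0, 0), I3, I3, cfg)$energy, 1,
                 tolerance = 1e-9)
    expect_equal(gay_berne(c(0, 0, 2 * ax[3]), I3, I3, cfg)$energy, 1,
                 tolerance = 1e-9)
  }
  # spheres: sigma = 2 l and the potential vanishes at r = 2 l (zeta = 1
  # is inside the cutoff, where V = 4 eps (1 - 1) = 0)
  cfgs <- sim_config(alpha = 1)
  ell <- gb_calibrate(cfgs$semi_axes)$ell
  out <- gay_berne(c(2 * ell[1], 0, 0), diag(3), diag(3), cfgs)
  expect_equal(out$sigma, 2 * ell[1], tolerance = 1e-12)
  expect_equal(out$energy, 0, tolerance = 1e-12)
  expect_equal(out$zeta, 1, tolerance = 1e-12)
})

test_that("forces and torques match finite differences", {
  set.seed(13)
  cfg <- sim_config(alpha = 1.78, beta = 0.44)
  h <- 1e-6
  n_checked <- 0
  for (k in 1:40) {
    Ri <- rotation_about(rnorm(3), runif(1, 0, pi))
    Rj <- rotation_about(rnorm(3), runif(1, 0, pi))
    r0 <- rnorm(3); r0 <- r0 / sqrt(sum(r0^2)) * runif(1, 0.8, 1.6)
    g <- gay_berne(r0, Ri, Rj, cfg)
    if (g$energy == 0 || g$capped || g$zeta < 0.35) next
    n_checked <- n_checked + 1
    scale <- max(abs(g$force_j), 1)
    for (d in 1:3) {
      dv <- rep(0, 3); dv[d] <- h
      num <- (gay_berne(r0 + dv, Ri, Rj, cfg)$energy -
                gay_berne(r0 - dv, Ri, Rj, cfg)$energy) / (2 * h)
      expect_equal(g$force_j[d] / scale, -num / scale, tolerance = 1e-5)
    }
    tscale <- max(abs(c(g$torque_i, g$torque_j)), 1)
    for (d in 1:3) {
      ax <- rep(0, 3); ax[d] <- 1
      ni <- (gay_berne(r0, rotation_about(ax, h) %*% Ri, Rj, cfg)$energy -
               gay_berne(r0, rotation_about(ax, -h) %*% Ri, Rj,
                         cfg)$energy) / (2 * h)
      expect_equal(g$torque_i[d] / tscale, -ni / tscale, tolerance = 1e-5)
      nj <- (gay_berne(r0, Ri, rotation_about(ax, h) %*% Rj, cfg)$energy -
               gay_berne(r0, Ri, rotation_about(ax, -h) %*% Rj,
                         cfg)$energy) / (2 * h)
      expect_equal(g$torque_j[d] / tscale, -nj / tscale, tolerance = 1e-5)
    }
  }
  expect_gte(n_checked, 10)
})

test_that("a free Brownian particle recovers D = kT/gamma", {
  cfg <- sim_config(alpha = 1, phi = 0.001, n = 1, ramp_steps = 0,
                    equil_steps = 0, prod_steps = 1e5, sample_every = 5,
                    seed = 3, phi_start = 0.001)
  m <- msd_diffusion(run_dynamics(cfg), window = c(0, 0.1))
  expect_equal(m$D, 1, tolerance = 0.03)
  expect_equal(m$flag, "ok")
})

test_that("a dilute suspension stays at the free-draining limit", {
  cfg <- sim_config(alpha = 1, phi = 0.01, n = 100, ramp_steps = 1000,
                    equil_steps = 1000, prod_steps = 3e4,
                    sample_every = 20, seed = 4)
  m <- msd_diffusion(run_dynamics(cfg), window = c(0, 0.3))
  expect_equal(m$D, 1, tolerance = 0.05)
})

test_that("runs are bit-reproducible under a fixed seed", {
  cfg <- sim_config(alpha = 1.3, phi = 0.2, n = 32, ramp_steps = 500,
                    equil_steps = 500, prod_steps = 2000,
                    sample_every = 10, seed = 17)
  t1 <- run_dynamics(cfg, track_collisions = TRUE)
  t2 <- run_dynamics(cfg, track_collisions = TRUE)
  expect_identical(t1$unwrapped, t2$unwrapped)
  expect_identical(t1$collisions, t2$collisions)
  expect_identical(t1$orientations, t2$orientations)
})

test_that("msd_diffusion recovers known walks and flags ballistic input", {
  set.seed(31)
  D_true <- 0.7
  nf <- 2000; n <- 40; dt <- 0.01
  steps <- array(rnorm(nf * 3 * n, 0, sqrt(2 * D_true * dt)),
                 c(nf, 3, n))
  walk <- list(times = (0:(nf - 1)) * dt,
               unwrapped = aperm(apply(steps, c(2, 3), cumsum),
                                 c(1, 2, 3)))
  m <- msd_diffusion(walk, window = c(0, 0.3))
  expect_equal(m$D, D_true, tolerance = 0.02)
  # two estimators: single-origin vs multi-origin agree
  m1 <- msd_diffusion(walk, window = c(0, 0.3), max_origins = 1)
  expect_equal(m1$D, m$D, tolerance = 0.1)
  # ballistic motion is flagged
  tt <- (0:999) * 0.01
  bal <- list(times = tt,
              unwrapped = array(rep(tt, 3 * 5), c(1000, 3, 5)))
  expect_equal(msd_diffusion(bal)$flag, "superdiffusive")
})

test_that("langevin integrator reproduces free diffusion too", {
  cfg <- sim_config(alpha = 1, phi = 0.005, n = 100, ramp_steps = 0,
                    equil_steps = 0, prod_steps = 3e5, sample_every = 25,
                    seed = 10, phi_start = 0.005,
                    integrator = "langevin")
  # fit beyond the velocity correlation time 1/gamma = 1 (inertial
  # crossover): the MSD slope approaches 6 kT/(m gamma) only for lags
  # >> 1, where single-particle statistics are poor - hence 100 dilute
  # particles and an intercept-absorbing fit over lags 3-10
  m <- msd_diffusion(run_dynamics(cfg), window = c(0.2, 0.67))
  expect_equal(m$D, 1, tolerance = 0.12)
})

test_that("with eps -> 0 crowded particles still diffuse freely", {
  cfg <- sim_config(alpha = 1.3, phi = 0.3, n = 64, eps = 1e-12,
                    ramp_steps = 500, equil_steps = 500,
                    prod_steps = 2e4, sample_every = 10, seed = 23)
  m <- msd_diffusion(suppressWarnings(run_dynamics(cfg)),
                     window = c(0, 0.3))
  expect_equal(m$D, 1, tolerance = 0.05)
})

test_that("production potential energy is stationary and D(phi) decreases", {
  Ds <- c(); eps_drift <- c()
  for (phi in c(0.2, 0.35, 0.5)) {
    cfg <- sim_config(alpha = 1, phi = phi, n = 64, ramp_steps = 3000,
                      equil_steps = 3000, prod_steps = 3e4,
                      sample_every = 30, seed = 29)
    tr <- suppressWarnings(run_dynamics(cfg))
    m <- msd_diffusion(tr)
    Ds <- c(Ds, m$D)
    sl <- coef(lm(tr$epot ~ tr$times))[2] * max(tr$times)
    eps_drift <- c(eps_drift, abs(sl) / (sd(tr$epot) + 1e-12))
  }
  expect_true(all(diff(Ds) < 0))
  expect_lt(min(Ds), 0.5)
  # drift over the production window is within a few noise SDs
  expect_lt(median(eps_drift), 4)
})

test_that("collision events carry valid body-frame contact angles", {
  cfg <- sim_config(alpha = 1.6, phi = 0.3, n = 32, ramp_steps = 1000,
                    equil_steps = 1000, prod_steps = 5000,
                    sample_every = 50, seed = 41)
  tr <- run_dynamics(cfg, track_collisions = TRUE)
  ev <- tr$collisions
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$theta_i >= 0 & ev$theta_i <= 180))
  expect_true(all(ev$phi_i >= 0 & ev$phi_i < 360))
  expect_true(all(ev$i < ev$j))
  rc <- record_collisions(tr, flat_degrees = TRUE)
  expect_s3_class(rc$map, "surface_map")
  expect_gt(sum(rc$map), 0)
})

test_that("sphere collisions are isotropic over the surface", {
  cfg <- sim_config(alpha = 1, phi = 0.35, n = 64, ramp_steps = 2000,
                    equil_steps = 2000, prod_steps = 2e4,
                    sample_every = 100, seed = 47)
  tr <- suppressWarnings(run_dynamics(cfg, track_collisions = TRUE))
  ev <- tr$collisions
  expect_gt(nrow(ev), 200)
  # repeat contacts of the same pair are correlated; the chi-square
  # uniformity test uses each pair's first contact only
  ev <- ev[!duplicated(paste(ev$i, ev$j)), ]
  # equal-area bins in cos(theta) should be uniformly occupied
  ct <- cos(c(ev$theta_i, ev$theta_j) * pi / 180)
  counts <- table(cut(ct, seq(-1, 1, length.out = 7)))
  expect_gt(chisq.test(counts)$p.value, 0.001)
  ph <- c(ev$phi_i, ev$phi_j)
  counts_p <- table(cut(ph, seq(0, 360, by = 60)))
  expect_gt(chisq.test(counts_p)$p.value, 0.001)
})

test_that("triaxial collisions favour the a poles over the c poles", {
  cfg <- sim_config(alpha = 1.78, beta = 0.44, phi = 0.35, n = 64,
                    ramp_steps = 2000, equil_steps = 2000,
                    prod_steps = 3e4, sample_every = 100, seed = 53)
  tr <- suppressWarnings(run_dynamics(cfg, track_collisions = TRUE))
  ev <- tr$collisions
  th <- c(ev$theta_i, ev$theta_j) * pi / 180
  ph <- c(ev$phi_i, ev$phi_j) * pi / 180
  # 30-degree caps around the a poles vs the c poles, solid-angle matched
  u <- abs(cos(th))                       # |x| direction cosine
  w <- abs(sin(th) * sin(ph))             # |z| direction cosine
  cap <- cos(30 * pi / 180)
  n_a <- sum(u > cap)
  n_c <- sum(w > cap)
  expect_gt(nrow(ev), 100)
  bt <- binom.test(c(n_a, n_c))
  expect_gt(n_a, n_c)
  expect_lt(bt$p.value, 0.01)
})
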