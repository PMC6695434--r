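# Reduced-scale Brownian / Langevin dynamics of soft Gay-Berne ellipsoids:
# configuration, length-scale calibration, trajectory container, MSD-based
# diffusion, the phi_c extraction pipeline, and collision recording.

#' Calibrate Gay-Berne length scales to target semi-axes
#'
#' Solves for the per-axis lengths \eqn{\ell_k} such that the pair energy
#' of two aligned particles at face-to-face separation \eqn{2 x_k} along
#' each principal axis equals 1 (the soft-contact condition V(2a) = V(2c)
#' = 1). With \eqn{\sigma_{\min} = \min_k \ell_k} the solution is closed
#' form: \eqn{\zeta_1} solves \eqn{4\epsilon(\zeta^{-12} - \zeta^{-6}) =
#' 1}, then \eqn{\ell_c = 2c/(1+\zeta_1)} and
#' \eqn{\ell_k = x_k + (1-\zeta_1)\ell_c/2}.
#'
#' @param semi_axes length-3 semi-axes (a >= b >= c), simulation units.
#' @param eps energy scale epsilon.
#' @return list: `ell` (la, lb, lc), `zeta1` (the unit-energy zeta),
#'   `sigma_min`.
#' @export
gb_calibrate <- function(semi_axes, eps = 1) {
  x <- sort(semi_axes, decreasing = TRUE)
  u <- (1 + sqrt(1 + 1 / eps)) / 2        # zeta^-6 at V = 1
  zeta1 <- u^(-1 / 6)
  lc <- 2 * x[3] / (1 + zeta1)
  ell <- x + (1 - zeta1) * lc / 2
  ell[3] <- lc
  list(ell = ell, zeta1 = zeta1, sigma_min = min(ell))
}

#' Simulation configuration for the Gay-Berne dynamics
#'
#' Reduced units: unit-volume particles, kT = 1, friction gamma = 1,
#' timestep 1e-4. The desk-scale default is 256 particles with a 1e4-step
#' compression ramp, 1e4-step equilibration and 1e5-step production; the
#' full-scale protocol (8100 particles, 2.5e5 production steps) is reached
#' by overriding `n`, `prod_steps`.
#'
#' @param alpha aspect ratio a/c of the particles.
#' @param beta shape exponent (0 = prolate spheroid, the simulated
#'   default; triaxial shapes are supported by the potential).
#' @param phi target volume fraction in (0, 0.74).
#' @param n particle count.
#' @param eps Gay-Berne energy scale.
#' @param zeta_cut cutoff in zeta space; default 2^(1/6) keeps only the
#'   repulsive branch (soft particles).
#' @param kT thermal energy; @param gamma_t,gamma_r friction factors.
#' @param dt timestep (must be <= 1e-3).
#' @param ramp_steps,equil_steps,prod_steps protocol step counts.
#' @param sample_every production sampling stride.
#' @param integrator `"brownian"` (overdamped Euler-Maruyama) or
#'   `"langevin"` (unit-mass velocity Langevin; rotation overdamped).
#' @param seed RNG seed governing the whole run.
#' @param phi_start initial volume fraction before the compression ramp.
#' @return a `sim_config` list.
#' @export
sim_config <- function(alpha = 1, beta = 0, phi = 0.3, n = 256,
                       eps = 1, zeta_cut = 2^(1 / 6), kT = 1,
                       gamma_t = 1, gamma_r = 1, dt = 1e-4,
                       ramp_steps = 10000, equil_steps = 10000,
                       prod_steps = 100000, sample_every = 100,
                       integrator = c("brownian", "langevin"),
                       seed = 1, phi_start = 0.05) {
  integrator <- match.arg(integrator)
  stopifnot(alpha >= 1, beta >= 0, beta <= 1, phi > 0, phi < 0.74,
            dt <= 1e-3, dt > 0, n >= 1, eps > 0, zeta_cut > 0, kT > 0,
            gamma_t > 0, gamma_r > 0)
  # unit-volume triaxial semi-axes: (4pi/3) a b c = 1
  cc <- (3 / (4 * pi * alpha^(1 + beta)))^(1 / 3)
  semi_axes <- c(alpha * cc, alpha^beta * cc, cc)
  cfg <- list(alpha = alpha, beta = beta, phi = phi, n = n,
              semi_axes = semi_axes, eps = eps, zeta_cut = zeta_cut,
              kT = kT, gamma_t = gamma_t, gamma_r = gamma_r, dt = dt,
              ramp_steps = ramp_steps, equil_steps = equil_steps,
              prod_steps = prod_steps, sample_every = sample_every,
              integrator = integrator, seed = seed,
              phi_start = min(phi_start, phi))
  class(cfg) <- "sim_config"
  cfg
}

#' Gay-Berne pair energy, force and torques
#'
#' The anisotropic pair potential \eqn{V = 4\epsilon(\zeta^{-12} -
#' \zeta^{-6})} for \eqn{\zeta < \zeta_{cut}} (else 0), with
#' \eqn{\zeta = (r - \sigma + \sigma_{\min})/\sigma_{\min}},
#' \eqn{\sigma^{-2} = \tfrac12 \hat r \cdot H^{-1} \cdot \hat r} and
#' \eqn{H = A_i + A_j} built from each particle's orientation. Forces and
#' torques are analytic gradients; overlaps so deep that zeta falls below
#' `zeta_floor` are capped (flagged) for integration safety.
#'
#' @param r centre-to-centre vector (from i to j).
#' @param Ri,Rj 3x3 orientation matrices (columns = body axes), or unit
#'   a-axis vectors for spheroids.
#' @param config a `sim_config` (supplies semi-axes, eps, zeta_cut).
#' @return list: `energy`, `zeta`, `sigma`, `force_j` (= -`force_i`),
#'   `torque_i`, `torque_j`, `capped`.
#' @export
gay_berne <- function(r, Ri, Rj, config) {
  cal <- gb_calibrate(config$semi_axes, config$eps)
  if (is.null(dim(Ri))) Ri <- frame_from_axis(Ri)
  if (is.null(dim(Rj))) Rj <- frame_from_axis(Rj)
  gb_pair_cpp(as.numeric(r), Ri, Rj, cal$ell, config$eps,
              config$zeta_cut)
}

# complete a unit a-axis into a right-handed orthonormal frame
frame_from_axis <- function(e) {
  e <- e / sqrt(sum(e^2))
  h <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b <- h - sum(h * e) * e
  b <- b / sqrt(sum(b^2))
  cbind(e, b, c(e[2] * b[3] - e[3] * b[2],
                e[3] * b[1] - e[1] * b[3],
                e[1] * b[2] - e[2] * b[1]))
}

rand_rotation <- function() {
  # uniform random rotation from quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Run Brownian or Langevin dynamics of soft ellipsoids
#'
#' Random sequential insertion at a dilute start, affine box compression
#' to the target volume fraction over the ramp, equilibration, then
#' production sampling of wrapped and unwrapped positions. Collision
#' onsets (contiguous intervals with zeta below 1 for a pair) can be
#' recorded with body-frame contact angles.
#'
#' @param config a [sim_config()].
#' @param initial optional list with `pos` (n x 3) and `orient`
#'   (n x 9 row-major rotation matrices) to resume from.
#' @param track_collisions record contact events during production?
#' @return a `gb_trajectory`: frame times, wrapped/unwrapped position
#'   arrays (frames x n x 3), final orientations, box length, potential
#'   energy trace, collision events, and the config.
#' @export
run_dynamics <- function(config, initial = NULL,
                         track_collisions = FALSE) {
  set.seed(config$seed)
  v_p <- 4 * pi / 3 * prod(config$semi_axes)
  box_target <- (config$n * v_p / config$phi)^(1 / 3)
  box0 <- (config$n * v_p / config$phi_start)^(1 / 3)
  if (is.null(initial)) {
    pos <- insert_random(config$n, box0, min_sep = 2 * config$semi_axes[3])
    ornt <- t(vapply(seq_len(config$n),
                     function(i) as.numeric(t(rand_rotation())),
                     numeric(9)))
  } else {
    pos <- initial$pos
    ornt <- initial$orient
    box0 <- initial$box %||% box0
  }
  cal <- gb_calibrate(config$semi_axes, config$eps)
  res <- run_gb_cpp(pos, ornt, cal$ell, config$eps, config$zeta_cut,
                    config$kT, config$gamma_t, config$gamma_r, config$dt,
                    box0, box_target, config$ramp_steps,
                    config$equil_steps, config$prod_steps,
                    config$sample_every,
                    config$integrator == "langevin", track_collisions)
  nf <- length(res$times)
  traj <- list(
    times = res$times,
    wrapped = array(res$wrapped, c(nf, 3, config$n)),
    unwrapped = array(res$unwrapped, c(nf, 3, config$n)),
    orientations = res$orientations,
    box = res$box,
    epot = res$epot,
    collisions = collision_events(res$collisions),
    n_capped = res$n_capped,
    config = config)
  class(traj) <- "gb_trajectory"
  if (res$n_capped > 0)
    warning(sprintf("capped repulsion applied %d time(s) (deep overlap)",
                    as.integer(res$n_capped)))
  traj
}

collision_events <- function(mat) {
  if (nrow(mat) == 0L)
    return(data.frame(i = integer(), j = integer(), time = numeric(),
                      theta_i = numeric(), phi_i = numeric(),
                      theta_j = numeric(), phi_j = numeric()))
  data.frame(i = as.integer(mat[, 1]), j = as.integer(mat[, 2]),
             time = mat[, 3], theta_i = mat[, 4], phi_i = mat[, 5],
             theta_j = mat[, 6], phi_j = mat[, 7])
}

# raw array layout from run_gb_cpp is frames x (3 * n) with xyz fastest;
# array() above gives [frame, coord, particle]

insert_random <- function(n, box, min_sep, max_tries = 200L) {
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  while (placed < n) {
    cand <- runif(3, 0, box)
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      d <- d - box * round(d / box)
      ok <- min(rowSums(d^2)) > min_sep^2
    }
    tries <- 1L
    while (!ok && tries < max_tries) {
      cand <- runif(3, 0, box)
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, cand)
      d <- d - box * round(d / box)
      ok <- min(rowSums(d^2)) > min_sep^2
      tries <- tries + 1L
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
  }
  pos
}

#' @export
print.gb_trajectory <- function(x, ...) {
  cat(sprintf(
    "<gb_trajectory> %d particles, %d frames, box %.3f, %s integrator\n",
    x$config$n, length(x$times), x$box, x$config$integrator))
  cat(sprintf("  alpha=%.2f phi=%.3f seed=%d; %d collision event(s)\n",
              x$config$alpha, x$config$phi, x$config$seed,
              nrow(x$collisions)))
  invisible(x)
}

#' Translational diffusion from the mean-squared displacement
#'
#' \eqn{D_t = \langle d^2\rangle / 6t} from the slope of the MSD over a
#' late-time window (default the second half of the lag range), with
#' multiple time origins and a block-averaged (over particle blocks)
#' uncertainty. Trajectories with strongly sub- or super-linear MSD are
#' flagged.
#'
#' @param traj a `gb_trajectory`, or a list with `times` and `unwrapped`
#'   (frames x 3 x n array).
#' @param window fraction range of the maximum lag used for the slope fit
#'   (maximum lag is half the trajectory).
#' @param max_origins cap on the number of time origins averaged per lag.
#' @param n_blocks particle blocks for the uncertainty estimate.
#' @return list: `D`, `se`, `exponent` (log-log slope), `flag`
#'   (`"ok"`, `"subdiffusive"` or `"superdiffusive"`), `msd` data frame.
#' @export
msd_diffusion <- function(traj, window = c(0.5, 1), max_origins = 2000,
                          n_blocks = 8) {
  u <- traj$unwrapped
  tt <- traj$times
  nf <- dim(u)[1]
  n <- dim(u)[3]
  if (nf < 100) stop("need at least 100 frames for msd_diffusion")
  max_lag <- nf %/% 2
  lags <- unique(round(seq(1, max_lag, length.out = min(60, max_lag))))
  msd_pp <- matrix(0, length(lags), n)   # per-particle for blocks
  for (li in seq_along(lags)) {
    k <- lags[li]
    stride <- max(1L, ceiling((nf - k) / max_origins))
    orig <- seq(1L, nf - k, by = stride)
    acc <- numeric(n)
    for (o in orig) {
      d <- matrix(u[o + k, , ] - u[o, , ], nrow = 3)
      acc <- acc + colSums(d^2)
    }
    msd_pp[li, ] <- acc / length(orig)
  }
  msd <- rowMeans(msd_pp)
  lag_t <- tt[lags + 1] - tt[1]
  sel <- lag_t >= window[1] * max(lag_t) & lag_t <= window[2] * max(lag_t)
  if (sum(sel) < 3) sel <- seq_along(lag_t) > length(lag_t) %/% 2
  fit <- lm(msd[sel] ~ lag_t[sel])
  D <- coef(fit)[[2]] / 6
  expo <- coef(lm(log(msd) ~ log(lag_t)))[[2]]
  flag <- if (expo < 0.8) "subdiffusive"
          else if (expo > 1.3) "superdiffusive" else "ok"
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  Db <- vapply(blocks, function(ix) {
    m <- rowMeans(msd_pp[, ix, drop = FALSE])
    coef(lm(m[sel] ~ lag_t[sel]))[[2]] / 6
  }, 0)
  list(D = D, se = sd(Db) / sqrt(length(Db)), exponent = expo,
       flag = flag, msd = data.frame(lag = lag_t, msd = msd),
       window = range(lag_t[sel]))
}

#' Critical volume fraction from a ladder of simulations
#'
#' Runs the dynamics at each requested volume fraction, normalises the
#' MSD-based diffusion constants by the free-draining dilute value
#' kT/gamma (exact for Brownian dynamics without hydrodynamic
#' interactions), and fits the long-time crowding model to extract
#' (phi_c, kappa) via [fit_phi_c()].
#'
#' @param alpha particle aspect ratio.
#' @param phi_values >= 4 volume fractions (spanning phi >= 0.2).
#' @param config base [sim_config()]; its alpha/phi/seed are overridden.
#' @param seed seed for the ladder.
#' @param kappa passed to [fit_phi_c()].
#' @return list: `fit` (a `crowding_fit`), `table` (phi, D, se, ratio).
#' @export
phi_c_pipeline <- function(alpha, phi_values, config = sim_config(),
                           seed = config$seed, kappa = "free") {
  stopifnot(length(phi_values) >= 4)
  D0 <- config$kT / config$gamma_t
  rows <- lapply(seq_along(phi_values), function(k) {
    cfg <- config
    cfg$alpha <- alpha
    cc <- (3 / (4 * pi * alpha^(1 + cfg$beta)))^(1 / 3)
    cfg$semi_axes <- c(alpha * cc, alpha^cfg$beta * cc, cc)
    cfg$phi <- phi_values[k]
    cfg$seed <- seed + 1000 * k
    tr <- suppressWarnings(run_dynamics(cfg))
    m <- msd_diffusion(tr)
    data.frame(phi = phi_values[k], D = m$D, se = m$se,
               ratio = m$D / D0)
  })
  tab <- do.call(rbind, rows)
  fit <- fit_phi_c(tab$phi, pmax(tab$ratio, 1e-6), kappa = kappa)
  list(fit = fit, table = tab)
}

#' Collision map from recorded contact events
#'
#' Deposits every body-frame contact angle of both partners as a Gaussian
#' spot on a theta-phi map of the particle shape.
#'
#' @param traj a `gb_trajectory` run with `track_collisions = TRUE`, or a
#'   data frame of events.
#' @param config the [sim_config()] (defaults to the trajectory's).
#' @param sigma_deg spot width in degrees of arc.
#' @param flat_degrees passed to [deposit_gaussian()].
#' @param max_events cap on the number of events deposited into the map
#'   (the earliest events are kept); the events table is always complete.
#' @return list: `events` data frame, `map` (a `surface_map`).
#' @export
record_collisions <- function(traj, config = NULL, sigma_deg = 10,
                              flat_degrees = FALSE, max_events = 2000) {
  ev_all <- if (is.data.frame(traj)) traj else traj$collisions
  if (is.null(config)) config <- traj$config
  ev <- head(ev_all, max_events)
  ax <- config$semi_axes
  ell <- ellipsoid(ax[1], ax[2], ax[3])
  map <- surface_map(ell)
  ang <- rbind(cbind(ev$theta_i, ev$phi_i), cbind(ev$theta_j, ev$phi_j))
  for (k in seq_len(nrow(ang)))
    map <- deposit_gaussian(map, ang[k, 1], ang[k, 2],
                            sigma_deg = sigma_deg,
                            flat_degrees = flat_degrees)
  list(events = ev_all, map = map)
}
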