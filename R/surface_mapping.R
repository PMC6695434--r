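# Theta-phi surface cartography: the t-parameterization of the ellipsoid
# surface, its inverse, a 180x360 geodesic pixel walk, Gaussian-spot
# deposition, dimer contact centres, and residue-value maps.

#' Surface point from body-frame angles
#'
#' Parameterizes the ellipsoid surface by the polar angle theta from the a
#' axis and azimuth phi from the b axis toward c:
#' \eqn{x = t\cos\theta}, \eqn{y = t\sin\theta\cos\varphi},
#' \eqn{z = t\sin\theta\sin\varphi} with
#' \deqn{t = \frac{abc}{\sqrt{b^2c^2\cos^2\theta + a^2c^2\sin^2\theta
#'   \cos^2\varphi + a^2b^2\sin^2\theta\sin^2\varphi}}.}
#'
#' @param ell an `equivalent_ellipsoid`.
#' @param theta polar angle(s) from the a axis, degrees in \[0, 180\].
#' @param phi azimuth(s) from the b axis toward c, degrees.
#' @return n x 3 matrix of body-frame coordinates (same units as the
#'   semi-axes); a plain vector for a single point.
#' @export
surface_point <- function(ell, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  a <- ell$a; b <- ell$b; c_ <- ell$c
  t <- a * b * c_ / sqrt(b^2 * c_^2 * cos(th)^2 +
                           a^2 * c_^2 * sin(th)^2 * cos(ph)^2 +
                           a^2 * b^2 * sin(th)^2 * sin(ph)^2)
  out <- cbind(x = t * cos(th),
               y = t * sin(th) * cos(ph),
               z = t * sin(th) * sin(ph))
  if (nrow(out) == 1L) out[1, ] else out
}

#' Invert the surface parameterization
#'
#' Maps a body-frame point (projected to the surface if slightly off, with
#' a warning beyond tolerance) back to `(theta, phi)` degrees with
#' `phi` wrapped into \[0, 360).
#'
#' @param ell an `equivalent_ellipsoid`.
#' @param point length-3 body-frame coordinates or n x 3 matrix.
#' @param tol on-surface tolerance for the implicit equation.
#' @return data frame with columns `theta`, `phi` (degrees).
#' @export
invert_surface_point <- function(ell, point, tol = 1e-6) {
  P <- rbind(point)
  f <- sqrt((P[, 1] / ell$a)^2 + (P[, 2] / ell$b)^2 + (P[, 3] / ell$c)^2)
  if (any(abs(f - 1) > tol)) {
    warning("off-surface point(s) projected radially onto the surface")
  }
  # direction through the origin fixes (theta, phi); t is radial
  theta <- acos(pmin(1, pmax(-1, P[, 1] / sqrt(rowSums(P^2))))) * 180 / pi
  phi <- (atan2(P[, 3], P[, 2]) * 180 / pi) %% 360
  phi[abs(sin(theta * pi / 180)) < 1e-12] <- 0
  data.frame(theta = theta, phi = phi)
}

#' An empty 180 x 360 surface map
#'
#' Row i covers theta in \[i-1, i\] degrees (pixel centre i - 0.5); column
#' j covers phi in \[j-1, j\] (centre j - 0.5).
#'
#' @param ell the `equivalent_ellipsoid` the map lives on.
#' @return a `surface_map`: 180 x 360 zero matrix with the ellipsoid and
#'   normalization state attached.
#' @export
surface_map <- function(ell) {
  m <- matrix(0, 180, 360)
  attr(m, "ellipsoid") <- ell
  attr(m, "normalized") <- FALSE
  class(m) <- c("surface_map", "matrix")
  m
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf(
    "<surface_map> 180x360, total mass %.4g, max %.4g at theta=%.1f phi=%.1f%s\n",
    sum(x), max(x),
    arrayInd(which.max(x), dim(x))[1] - 0.5,
    arrayInd(which.max(x), dim(x))[2] - 0.5,
    if (isTRUE(attr(x, "normalized"))) " (max-normalized)" else ""))
  invisible(x)
}

#' @export
plot.surface_map <- function(x, main = "surface map", ...) {
  graphics::image(seq(0.5, 359.5), seq(0.5, 179.5), t(unclass(x))[, 180:1],
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  xlab = expression(phi ~ "(deg, from b)"),
                  ylab = expression(theta ~ "(deg, from a)"),
                  main = main, ...)
  invisible(x)
}

pixel_centres <- function(ell) {
  th <- seq(0.5, 179.5)
  ph <- seq(0.5, 359.5)
  list(theta = th, phi = ph)
}

pixel_of <- function(theta, phi) {
  i <- pmin(180L, pmax(1L, as.integer(floor(theta)) + 1L))
  j <- (as.integer(floor(phi %% 360))) + 1L
  cbind(i, j)
}

#' Geodesic distance field over the 180 x 360 pixel grid
#'
#' Treats the map as an image whose pixel centres are surface points and
#' runs an iterative lowest-value expansion (Dijkstra over the 8-connected
#' pixel graph, wrapping in phi) where each step costs the Cartesian
#' distance between neighbouring pixel-centre surface points. On a sphere
#' this approximates great-circle distances to within a few percent.
#'
#' @param ell an `equivalent_ellipsoid`.
#' @param source c(theta, phi) of the source point in degrees.
#' @param max_distance optional early-stop radius (same units as the
#'   semi-axes); pixels beyond it are returned as `Inf`.
#' @return 180 x 360 matrix of distances.
#' @export
geodesic_distance_grid <- function(ell, source, max_distance = Inf) {
  src <- pixel_of(source[1], source[2])
  d <- geodesic_grid_cpp(ell$a, ell$b, ell$c,
                         src[1, 1] - 1L, src[1, 2] - 1L,
                         max_distance)
  matrix(d, 180, 360, byrow = TRUE)
}

#' Deposit a Gaussian spot on a surface map
#'
#' Adds \eqn{\exp(-g^2 / 2\sigma^2)} to every pixel, where g is the
#' geodesic distance from the deposited point expressed in degrees of arc.
#' The arc conversion divides the Cartesian geodesic length by the local
#' radius t at the deposited point (flag `flat_degrees` instead measures
#' flat pixel offsets). Deposition is additive, so masses accumulate.
#'
#' @param map a `surface_map`.
#' @param theta,phi deposit location, degrees.
#' @param sigma_deg Gaussian standard deviation, degrees of arc
#'   (default 10).
#' @param weight multiplicative weight of the spot.
#' @param flat_degrees use flat (theta, phi) pixel distances instead of
#'   geodesic arc.
#' @return the updated map.
#' @export
deposit_gaussian <- function(map, theta, phi, sigma_deg = 10, weight = 1,
                             flat_degrees = FALSE) {
  ell <- attr(map, "ellipsoid")
  if (flat_degrees) {
    th <- seq(0.5, 179.5); ph <- seq(0.5, 359.5)
    dth <- th - theta
    dph <- abs(ph - phi); dph <- pmin(dph, 360 - dph)
    g2 <- outer(dth^2, dph^2, "+")
    spot <- exp(-g2 / (2 * sigma_deg^2))
  } else {
    r_local <- sqrt(sum(surface_point(ell, theta, phi)^2))
    cutoff <- (4 * sigma_deg) * pi / 180 * r_local
    g <- geodesic_distance_grid(ell, c(theta, phi), max_distance = cutoff)
    g_deg <- g / r_local * 180 / pi
    spot <- exp(-g_deg^2 / (2 * sigma_deg^2))
    spot[!is.finite(g)] <- 0
  }
  out <- unclass(map) + weight * spot
  attributes(out) <- attributes(map)
  out
}

#' Normalize a surface map to its maximum
#'
#' @param map a `surface_map`.
#' @return the map scaled to max 1, flagged normalized.
#' @export
normalize_map <- function(map) {
  mx <- max(map)
  out <- if (mx > 0) unclass(map) / mx else unclass(map)
  attributes(out) <- attributes(map)
  attr(out, "normalized") <- TRUE
  out
}

#' Export a surface map as a plain-text matrix
#'
#' @param map a `surface_map`.
#' @param path output path (180 rows x 360 columns, whitespace-separated).
#' @return `path`, invisibly.
#' @export
write_surface_map <- function(map, path) {
  utils::write.table(unclass(map), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# quadratic form matrix of a posed ellipsoid: (x-ctr)' Q (x-ctr) = 1
ellipsoid_qf <- function(ell, scale = 1) {
  R <- ell$rotation
  R %*% diag(1 / (scale * c(ell$a, ell$b, ell$c))^2) %*% t(R)
}

# Perram-Wertheim contact function of two posed ellipsoids:
# F = max_lambda lambda(1-lambda) r' [lambda B + (1-lambda) A]^{-1} r
# with A, B the shape matrices (R diag(axes^2) R'); F < 1 iff overlapping,
# F = 1 at external tangency.
pw_contact <- function(ellA, ellB) {
  A <- ellA$rotation %*% diag(c(ellA$a, ellA$b, ellA$c)^2) %*%
    t(ellA$rotation)
  B <- ellB$rotation %*% diag(c(ellB$a, ellB$b, ellB$c)^2) %*%
    t(ellB$rotation)
  r <- ellB$centroid - ellA$centroid
  f <- function(l) {
    M <- l * B + (1 - l) * A
    l * (1 - l) * sum(r * solve(M, r))
  }
  opt <- optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-12)
  lam <- opt$maximum
  M <- lam * B + (1 - lam) * A
  # tangency point of the scaled pair lies on the line of centres mapping
  x <- ellA$centroid + (1 - lam) * as.numeric(A %*% solve(M, r))
  list(F = opt$objective, lambda = lam, point = x)
}

#' Contact centre of a dimer by uniform shrinking
#'
#' Scales both posed ellipsoids about their centres by a common factor s
#' until their surfaces just touch (external tangency), then maps the
#' tangency point into each body frame as `(theta, phi)`. The tangency
#' scale follows from the Perram-Wertheim contact function F of the
#' unscaled pair as \eqn{s = \sqrt{F}}, verified by bisection bracketing
#' on the overlap predicate.
#'
#' @param ellA,ellB posed `equivalent_ellipsoid`s (rotation + centroid).
#' @return list: `scale` s, `point` (lab frame), `angles_A`, `angles_B`
#'   (data frames with `theta`, `phi` in degrees).
#' @export
dimer_contact_centre <- function(ellA, ellB) {
  r <- ellB$centroid - ellA$centroid
  if (sqrt(sum(r^2)) < 1e-12) stop("concentric ellipsoids have no contact")
  pw <- pw_contact(ellA, ellB)
  s <- sqrt(pw$F)
  # bisection refinement on the overlap predicate (guards the closed form)
  scaled <- function(e, sc) ellipsoid(e$a * sc, e$b * sc, e$c * sc,
                                      rotation = e$rotation,
                                      centroid = e$centroid)
  pred <- function(sc) pw_contact(scaled(ellA, sc), scaled(ellB, sc))$F - 1
  lo <- s * 0.999; hi <- s * 1.001
  if (pred(lo) > 0 && pred(hi) > 0) hi <- s         # degenerate guard
  s_ref <- tryCatch(uniroot(pred, c(lo, hi), tol = 1e-9)$root,
                    error = function(e) s)
  x <- pw$point
  to_body <- function(e) {
    b <- as.numeric(t(e$rotation) %*% (x - e$centroid)) / s_ref
    invert_surface_point(e, b, tol = 1e-4)
  }
  list(scale = s_ref, point = x,
       angles_A = suppressWarnings(to_body(ellA)),
       angles_B = suppressWarnings(to_body(ellB)))
}

#' Map residue scalar values onto the ellipsoid surface
#'
#' Surface residues (fractional radial extent m >= `surface_min`) have
#' their C-alpha projected radially to the surface and their scalar value
#' deposited as a Gaussian spot. Optionally the map is canonicalized by a
#' 180-degree rotation about the a axis so the hemisphere 0 < phi < 180
#' holds the lower mean value (idempotent).
#'
#' @param cloud an [atom_cloud()].
#' @param ell its `equivalent_ellipsoid`.
#' @param table a `residue_scalar_table` covering the surface residues.
#' @param surface_min surface criterion on m (default 0.75).
#' @param sigma_deg spot width, degrees of arc.
#' @param canonicalize rotate so the low-value face is at 0 < phi < 180.
#' @param flat_degrees passed to [deposit_gaussian()].
#' @return a `surface_map` of accumulated value-weighted spots, with a
#'   parallel unweighted `counts` map attached for averaging.
#' @export
map_residue_values <- function(cloud, ell, table, surface_min = 0.75,
                               sigma_deg = 10, canonicalize = TRUE,
                               flat_degrees = FALSE) {
  m <- fractional_radial_extent(cloud, ell)
  vals <- setNames(table$value, table$residue_index)
  surf <- m$residue_index[m$value >= surface_min]
  surf <- surf[as.character(surf) %in% names(vals)]
  if (length(surf) == 0L) stop("no surface residues meet the criterion")
  ca <- cloud[cloud$calpha & cloud$resno %in% surf, , drop = FALSE]
  P <- sweep(as.matrix(ca[, c("x", "y", "z")]), 2, ell$centroid)
  B <- P %*% ell$rotation
  ang <- suppressWarnings(invert_surface_point(ell, B, tol = Inf))
  map <- surface_map(ell)
  cnt <- surface_map(ell)
  for (k in seq_len(nrow(ang))) {
    w <- vals[as.character(ca$resno[k])]
    map <- deposit_gaussian(map, ang$theta[k], ang$phi[k],
                            sigma_deg = sigma_deg, weight = w,
                            flat_degrees = flat_degrees)
    cnt <- deposit_gaussian(cnt, ang$theta[k], ang$phi[k],
                            sigma_deg = sigma_deg, weight = 1,
                            flat_degrees = flat_degrees)
  }
  if (canonicalize) {
    lower <- mean(unclass(map)[, 1:180])
    upper <- mean(unclass(map)[, 181:360])
    if (lower > upper) {
      # rotate 180 deg about a: phi -> phi + 180
      rot <- function(mm) {
        out <- unclass(mm)[, c(181:360, 1:180)]
        attributes(out) <- attributes(mm)
        out
      }
      map <- rot(map); cnt <- rot(cnt)
    }
  }
  attr(map, "counts") <- cnt
  map
}
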