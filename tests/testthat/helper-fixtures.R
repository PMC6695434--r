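# shared fixtures: tiny hand-built clouds and rotation helpers

five_element_cloud <- function() {
  atom_cloud(element = c("C", "N", "O", "S", "H"),
             x = c(0, 1, 2, 3, 4), y = 0, z = 0,
             resno = c(1, 1, 1, 2, 2),
             resid = c("ALA", "ALA", "ALA", "CYS", "CYS"),
             calpha = c(TRUE, FALSE, FALSE, FALSE, FALSE))
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotate_cloud <- function(cloud, R) {
  P <- as.matrix(cloud[, c("x", "y", "z")]) %*% t(R)
  cloud$x <- P[, 1]; cloud$y <- P[, 2]; cloud$z <- P[, 3]
  cloud
}

# exact surface area of a triaxial ellipsoid by dense spherical-parameter
# quadrature (independent oracle for the Thomsen-type model)
ellipsoid_area_exact <- function(a, b, c, n = 600) {
  th <- (seq_len(n) - 0.5) / n * pi
  ph <- (seq_len(2 * n) - 0.5) / (2 * n) * 2 * pi
  st <- sin(th); ct <- cos(th)
  sp <- sin(ph); cp <- cos(ph)
  # |r_theta x r_phi| for r = (a st cp, b st sp, c ct)
  acc <- 0
  for (i in seq_len(n)) {
    E <- sqrt((b * c * st[i]^2 * cp)^2 + (a * c * st[i]^2 * sp)^2 +
                (a * b * st[i] * ct[i])^2)
    acc <- acc + sum(E)
  }
  acc * (pi / n) * (2 * pi / (2 * n))
}

# analytic inertia tensor of a solid uniform ellipsoid of mass M
solid_ellipsoid_tensor <- function(a, b, c, M) {
  I <- diag(M / 5 * c(b^2 + c^2, a^2 + c^2, a^2 + b^2))
  attr(I, "M") <- M
  attr(I, "centroid") <- c(0, 0, 0)
  I
}
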