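# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# End-to-end distance of a planar all-trans chain by a 2D walk: each bond
# turns the heading by (180 - bond_angle) degrees with alternating sign.
# bonds[i] is the length of the bond arriving at atom i (bonds[1] unused);
# angles[i] is the bond angle centred on atom i.
zigzag_e2e_2d <- function(bonds, angles) {
  n <- length(bonds)
  pos <- matrix(0, n, 2)
  heading <- 0
  sgn <- 1
  for (i in 2:n) {
    if (i > 2) {
      heading <- heading + sgn * (180 - angles[i - 1]) * pi / 180
      sgn <- -sgn
    }
    pos[i, ] <- pos[i - 1, ] + bonds[i] * c(cos(heading), sin(heading))
  }
  sqrt(sum((pos[n, ] - pos[1, ])^2))
}

# Brute-force isoelectric point: grid minimiser of |net charge|
grid_isoelectric <- function(pka1, beta1, pka2, beta2, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  net <- 1 / (1 + 10^((ph - pka2) / beta2)) - 1 / (1 + 10^((pka1 - ph) / beta1))
  ph[which.min(abs(net))]
}

# Exhaustive extrema over a wavelength window (peak-finder oracle)
grid_extrema <- function(wavelengths, theta, window) {
  inside <- wavelengths >= window[1] & wavelengths <= window[2]
  lam <- wavelengths[inside]; th <- theta[inside]
  list(lambda_max = lam[which.max(th)], lambda_min = lam[which.min(th)])
}

# Brute-force dihedral from the textbook two-plane formula (acos + sign),
# distinct from the package's atan2 construction
dihedral_bruteforce <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(pmax(cosphi, -1), 1)) * 180 / pi
  if (sum(pracma::cross(n1, n2) * b2) < 0) phi <- -phi
  phi
}

# random rigid motion applied to a coordinate matrix
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  t(rx %*% ry %*% rz %*% t(coords)) +
    matrix(runif(3, -20, 20), nrow(coords), 3, byrow = TRUE)
}
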