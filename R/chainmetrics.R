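# Conformational descriptors of oligomer structures: end-to-end distance,
# radius of gyration, Shrake-Rupley solvent-accessible surface area, dipole
# moment, and backbone torsion statistics.  Coordinates are handled in
# Angstrom internally; descriptors are reported in nm / nm^2 / Debye.

# Bondi van der Waals radii (Angstrom); X is the side-chain pseudo-atom
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, F = 1.47, Cl = 1.75, X = 2.00)
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                    X = 45.0)  # pseudo-atom ~ CH(CH3)COOH fragment scale

#' Bundle an oligomer conformation
#'
#' @param elements Character vector of element symbols (\code{"X"} marks a
#'   coarse-grained pseudo-atom).
#' @param coords Numeric n x 3 matrix of Cartesian positions in Angstrom.
#' @param charges Optional per-atom partial charges in units of e.
#' @param radii Optional per-atom van der Waals radii in Angstrom;
#'   defaulted from the Bondi set by element.
#' @param masses Optional per-atom masses in amu; defaulted by element.
#' @param backbone Ordered integer indices of the main-chain atoms.
#'
#' @return An object of class \code{conformer}.
#' @export
conformer <- function(elements, coords, charges = NULL, radii = NULL,
                      masses = NULL, backbone = integer(0)) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3L, length(elements) == n)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  lookup <- function(table, what) {
    vals <- unname(table[elements])
    if (anyNA(vals))
      stop("no default ", what, " for element(s): ",
           paste(unique(elements[is.na(vals)]), collapse = ", "))
    vals
  }
  if (is.null(radii)) radii <- lookup(.bondi_radii, "vdW radius")
  if (is.null(masses)) masses <- lookup(.atomic_masses, "mass")
  if (any(radii <= 0)) stop("radii must be positive")
  backbone <- as.integer(backbone)
  if (length(backbone)) {
    if (any(backbone < 1L | backbone > n))
      stop("backbone indices out of range")
    if (anyDuplicated(backbone)) stop("backbone indices must be unique")
  }
  if (!is.null(charges)) stopifnot(length(charges) == n)
  structure(list(elements = elements, coords = unname(coords),
                 charges = charges, radii = radii, masses = masses,
                 backbone = backbone),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms (%d backbone)%s\n",
              nrow(x$coords), length(x$backbone),
              if (is.null(x$charges)) "" else ", charged"))
  invisible(x)
}

#' Read a conformer from a PDB file
#'
#' Parses ATOM/HETATM records (occupancy ignored).  The backbone is taken
#' from \code{backbone_names} matched against atom names, in record order,
#' or can be set afterwards.
#'
#' @param file Path to a PDB file.
#' @param backbone_names Atom names to mark as backbone (e.g.
#'   \code{c("N", "CA", "C")}); \code{NULL} leaves the backbone empty.
#' @return A \code{\link{conformer}}.
#' @export
read_conformer_pdb <- function(file, backbone_names = NULL) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  elements <- trimws(at$elesy)
  blank <- is.na(elements) | elements == ""
  elements[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  coords <- cbind(at$x, at$y, at$z)
  backbone <- if (is.null(backbone_names)) integer(0) else
    which(trimws(at$elety) %in% backbone_names)
  conformer(elements, coords, backbone = backbone)
}

#' Read a conformer from an (extended) XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then one
#' \code{element x y z} row per atom, with an optional fifth column holding
#' a partial charge in e.
#'
#' @param file Path to the XYZ file.
#' @param backbone Optional backbone indices.
#' @return A \code{\link{conformer}}.
#' @export
read_conformer_xyz <- function(file, backbone = integer(0)) {
  lines <- readLines(file)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  body <- utils::read.table(text = lines[3:(2 + n)],
                            col.names = c("el", "x", "y", "z", "q")[
                              seq_len(length(strsplit(trimws(lines[3]),
                                                      "\\s+")[[1]]))],
                            stringsAsFactors = FALSE)
  charges <- if ("q" %in% names(body)) body$q else NULL
  conformer(body$el, cbind(body$x, body$y, body$z),
            charges = charges, backbone = backbone)
}

#' Write a conformer to an extended XYZ file
#'
#' @param conf A \code{\link{conformer}}.
#' @param file Output path.
#' @param comment Comment line (default records the backbone indices).
#' @return \code{file}, invisibly.
#' @export
write_conformer_xyz <- function(conf, file, comment = NULL) {
  if (is.null(comment))
    comment <- paste("backbone:", paste(conf$backbone, collapse = " "))
  rows <- if (is.null(conf$charges))
    sprintf("%-2s %14.8f %14.8f %14.8f", conf$elements,
            conf$coords[, 1], conf$coords[, 2], conf$coords[, 3])
  else
    sprintf("%-2s %14.8f %14.8f %14.8f %10.6f", conf$elements,
            conf$coords[, 1], conf$coords[, 2], conf$coords[, 3],
            conf$charges)
  writeLines(c(nrow(conf$coords), comment, rows), file)
  invisible(file)
}

#' End-to-end distance of the main chain
#'
#' Euclidean distance between the first and last backbone atoms.
#'
#' @param conf A \code{\link{conformer}} with at least two backbone atoms.
#' @return Distance in nm.
#' @export
end_to_end <- function(conf) {
  bb <- conf$backbone
  if (length(bb) < 2L) stop("backbone must contain at least two atoms")
  sqrt(sum((conf$coords[bb[length(bb)], ] - conf$coords[bb[1], ])^2)) / 10
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{cm}|^2 / \sum_i m_i}}, mass-weighted
#' by default; with \code{mass_weighted = FALSE} all atoms weigh equally.
#'
#' @param conf A \code{\link{conformer}} with at least 2 atoms.
#' @param mass_weighted Logical, default \code{TRUE}.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(conf, mass_weighted = TRUE) {
  x <- conf$coords
  stopifnot(nrow(x) >= 2L)
  w <- if (mass_weighted) conf$masses else rep(1, nrow(x))
  cm <- colSums(x * w) / sum(w)
  d2 <- rowSums(sweep(x, 2, cm)^2)
  sqrt(sum(w * d2) / sum(w)) / 10
}

#' Molecular dipole moment from point charges
#'
#' \eqn{\mu = |\sum_i q_i (r_i - r_0)|} converted from e Angstrom to Debye
#' (1 e Angstrom = 4.8032 D).  For a net-neutral system the result is
#' origin-independent; for charged systems the origin convention is part of
#' the result and is reported in the \code{origin} attribute.
#'
#' @param conf A \code{\link{conformer}} with charges.
#' @param origin \code{"center_of_charge"} (default, mean position weighted
#'   by |q|) or \code{"center_of_mass"}.
#' @return Dipole moment in Debye, with attributes \code{origin} and
#'   \code{net_charge}.
#' @export
dipole_moment <- function(conf,
                          origin = c("center_of_charge", "center_of_mass")) {
  origin <- match.arg(origin)
  q <- conf$charges
  if (is.null(q)) stop("conformer has no partial charges")
  x <- conf$coords
  r0 <- if (origin == "center_of_mass") {
    colSums(x * conf$masses) / sum(conf$masses)
  } else if (sum(abs(q)) > 0) {
    colSums(x * abs(q)) / sum(abs(q))
  } else colMeans(x)
  mu_vec <- colSums(sweep(x, 2, r0) * q)
  mu <- sqrt(sum(mu_vec^2)) * 4.8032
  structure(mu, origin = origin, net_charge = sum(q))
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quasi-uniform deterministic test points (Fibonacci lattice) are placed on
#' each atom's solvent-expanded sphere of radius \eqn{r_i + p}; the
#' accessible fraction times \eqn{4\pi (r_i + p)^2} is summed over atoms.
#' Exact duplicate atoms (same centre and radius) are collapsed before the
#' calculation so they are not double counted.
#'
#' @param conf A \code{\link{conformer}} with radii assigned.
#' @param probe_radius Probe radius in nm, default 0.14 (a water molecule).
#' @param n_sphere_points Test points per atom, default 960.
#' @return Total SASA in nm^2, with attribute \code{per_atom} (nm^2, on the
#'   deduplicated atom set, mapped back to input atoms with duplicates 0).
#' @export
sasa <- function(conf, probe_radius = 0.14, n_sphere_points = 960) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 12)
  x <- conf$coords
  r <- conf$radii
  n <- nrow(x)
  # collapse exact duplicates (centre within 1e-6 A and equal radius)
  keep <- rep(TRUE, n)
  if (n > 1L) {
    key <- paste(round(x[, 1], 6), round(x[, 2], 6), round(x[, 3], 6),
                 round(r, 6))
    keep <- !duplicated(key)
  }
  xs <- x[keep, , drop = FALSE]
  rs <- r[keep]
  m <- nrow(xs)
  p <- probe_radius * 10  # nm -> Angstrom
  pts <- fibonacci_sphere(n_sphere_points)
  per_atom <- numeric(m)
  for (i in seq_len(m)) {
    ri <- rs[i] + p
    cand <- which(seq_len(m) != i)
    if (length(cand)) {
      d2 <- rowSums(sweep(xs[cand, , drop = FALSE], 2, xs[i, ])^2)
      cand <- cand[d2 < (ri + rs[cand] + p)^2]
    }
    if (!length(cand)) {
      acc_frac <- 1
    } else {
      sp <- sweep(pts * ri, 2, xs[i, ], `+`)
      buried <- rep(FALSE, n_sphere_points)
      for (j in cand) {
        if (all(buried)) break
        d2j <- rowSums(sweep(sp, 2, xs[j, ])^2)
        buried <- buried | d2j < (rs[j] + p)^2
      }
      acc_frac <- mean(!buried)
    }
    per_atom[i] <- acc_frac * 4 * pi * ri^2
  }
  out <- numeric(n)
  out[keep] <- per_atom
  structure(sum(per_atom) / 100, per_atom = out / 100)  # A^2 -> nm^2
}

# signed dihedral (degrees) for points p1..p4; NA if a triple is collinear
dihedral_angle <- function(p1, p2, p3, p4, tol = 1e-10) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < tol || sum(n2^2) < tol) return(NA_real_)
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(b2n[2] * n1[3] - b2n[3] * n1[2],
          b2n[3] * n1[1] - b2n[1] * n1[3],
          b2n[1] * n1[2] - b2n[2] * n1[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone torsion angles
#'
#' Signed dihedral (degrees, in (-180, 180]) for every four consecutive
#' backbone atoms.  Collinear triples yield \code{NA} (undefined torsion).
#'
#' @param conf A \code{\link{conformer}} with at least 4 backbone atoms.
#' @return Numeric vector of length \code{n_backbone - 3}.
#' @export
backbone_torsions <- function(conf) {
  bb <- conf$backbone
  if (length(bb) < 4L) stop("backbone must contain at least four atoms")
  x <- conf$coords
  vapply(seq_len(length(bb) - 3L), function(i) {
    dihedral_angle(x[bb[i], ], x[bb[i + 1], ], x[bb[i + 2], ], x[bb[i + 3], ])
  }, numeric(1))
}

#' Fraction of transoid backbone torsions
#'
#' Share of defined torsions with \eqn{|\phi| \ge} \code{threshold}.  The
#' default threshold of 150 degrees separates extended, hairpin-strand-like
#' arrangements peaked around +/-180 degrees from turn conformations in the
#' +/-60 to +/-120 degree range.
#'
#' @param torsions Vector of torsion angles in degrees (NAs ignored).
#' @param threshold Transoid cutoff in degrees, default 150.
#' @return Fraction in [0, 1].
#' @export
transoid_fraction <- function(torsions, threshold = 150) {
  t_ok <- torsions[!is.na(torsions)]
  if (!length(t_ok)) return(NA_real_)
  mean(abs(t_ok) >= threshold)
}

#' All descriptors of a conformer at once
#'
#' @param conf A \code{\link{conformer}}.
#' @param probe_radius,n_sphere_points Passed to \code{\link{sasa}}.
#' @param transoid_threshold Passed to \code{\link{transoid_fraction}}.
#' @return A list of class \code{descriptor_set}: \code{end_to_end} (nm),
#'   \code{rg} (nm), \code{sasa} (nm^2), \code{dipole} (Debye or NA when no
#'   charges), \code{torsions} (degrees), \code{transoid_fraction}.
#' @export
describe_conformer <- function(conf, probe_radius = 0.14,
                               n_sphere_points = 960,
                               transoid_threshold = 150) {
  tors <- if (length(conf$backbone) >= 4L) backbone_torsions(conf) else
    numeric(0)
  structure(list(
    end_to_end = if (length(conf$backbone) >= 2L) end_to_end(conf) else NA_real_,
    rg = radius_of_gyration(conf),
    sasa = as.numeric(sasa(conf, probe_radius, n_sphere_points)),
    dipole = if (is.null(conf$charges)) NA_real_ else
      as.numeric(dipole_moment(conf)),
    torsions = tors,
    transoid_fraction = if (length(tors)) transoid_fraction(tors, transoid_threshold)
      else NA_real_),
    class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> Ree %.3f nm, Rg %.3f nm, SASA %.2f nm^2\n",
              x$end_to_end, x$rg, x$sasa))
  if (!is.na(x$dipole)) cat(sprintf("  dipole %.2f D\n", x$dipole))
  if (length(x$torsions))
    cat(sprintf("  %d torsions, transoid fraction %.2f\n",
                length(x$torsions), x$transoid_fraction))
  invisible(x)
}
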