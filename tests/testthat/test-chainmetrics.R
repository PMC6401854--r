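test_that("end-to-end distance is the backbone-terminal separation", {
  two <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 10)),
                   backbone = 1:2)
  expect_equal(end_to_end(two), 1.0)  # 10 A = 1 nm
  # rigid-motion invariance
  moved <- conformer(two$elements, rigid_motion(two$coords, 5),
                     backbone = 1:2)
  expect_equal(end_to_end(moved), 1.0, tolerance = 1e-12)
  expect_error(end_to_end(conformer("C", rbind(c(0, 0, 0)))), "backbone")
})

test_that("radius of gyration matches analytic fixtures", {
  # dumbbell of equal masses 1 nm apart: Rg = half the separation
  dumb <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(10, 0, 0)),
                    backbone = 1:2)
  expect_equal(radius_of_gyration(dumb), 0.5)
  # 8 equal atoms on a cube of edge a: every atom sits at a*sqrt(3)/2 from
  # the centre, so Rg = a*sqrt(3)/2
  a <- 4
  cube <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  conf_cube <- conformer(rep("C", 8), cube)
  expect_equal(radius_of_gyration(conf_cube), a * sqrt(3) / 2 / 10)
  # mass weighting: a heavy atom drags the centre of mass
  mixed <- conformer(c("H", "S"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_lt(radius_of_gyration(mixed), 0.5)
  expect_equal(radius_of_gyration(mixed, mass_weighted = FALSE), 0.5)
  # rotation invariance
  expect_equal(radius_of_gyration(
    conformer(rep("C", 8), rigid_motion(cube, 2))),
    a * sqrt(3) / 2 / 10, tolerance = 1e-12)
})

test_that("dipole moment converts e*Angstrom to Debye", {
  pair <- conformer(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
                    charges = c(1, -1))
  expect_equal(as.numeric(dipole_moment(pair)), 4.8032, tolerance = 1e-6)
  # zero charges give zero dipole
  zero <- conformer(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
                    charges = c(0, 0))
  expect_equal(as.numeric(dipole_moment(zero)), 0)
  # neutral system: translation invariance
  shifted <- conformer(c("H", "H"), pair$coords +
                         matrix(c(5, -3, 8), 2, 3, byrow = TRUE),
                       charges = c(1, -1))
  expect_equal(as.numeric(dipole_moment(shifted)),
               as.numeric(dipole_moment(pair)), tolerance = 1e-12)
  # charged system reports its origin convention
  ion <- conformer(c("N", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
                   charges = c(1, 0.5))
  expect_equal(attr(dipole_moment(ion), "origin"), "center_of_charge")
  expect_equal(attr(dipole_moment(ion), "net_charge"), 1.5)
  expect_error(dipole_moment(conformer("C", rbind(c(0, 0, 0)))), "charges")
})

test_that("SASA matches the analytic sphere and is additive when far apart", {
  # single atom r = 1.5 A, probe 1.4 A: 4*pi*(2.9 A)^2 = 1.0568 nm^2
  one <- conformer("C", rbind(c(0, 0, 0)), radii = 1.5)
  exact <- 4 * pi * 0.29^2
  expect_equal(as.numeric(sasa(one, probe_radius = 0.14)), exact,
               tolerance = 0.01)
  # far-separated atoms: sum of isolated values
  two <- conformer(c("C", "N"), rbind(c(0, 0, 0), c(100, 0, 0)))
  iso <- sum(4 * pi * ((c(1.70, 1.55) + 1.4) / 10)^2)
  expect_equal(as.numeric(sasa(two)), iso, tolerance = 1e-9)
  # a caged atom contributes ~0: centre atom inside an octahedron + cube of
  # large overlapping spheres
  shell <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                 c(0, 0, 2), c(0, 0, -2),
                 as.matrix(expand.grid(c(-2, 2), c(-2, 2), c(-2, 2))) / sqrt(2))
  cage <- conformer(rep("C", 15), rbind(c(0, 0, 0), shell),
                    radii = c(1.5, rep(3, 14)))
  expect_lt(attr(sasa(cage), "per_atom")[1], 1e-6)
  # duplicated atoms are not double counted
  dup <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(1.5, 1.5))
  expect_equal(as.numeric(sasa(dup, probe_radius = 0.14)),
               as.numeric(sasa(one, probe_radius = 0.14)))
})

test_that("SASA converges with the sphere-point count", {
  coil <- make_coil(4, seed = 9)
  s960 <- as.numeric(sasa(coil, n_sphere_points = 960))
  s3840 <- as.numeric(sasa(coil, n_sphere_points = 3840))
  expect_lt(abs(s960 - s3840) / s3840, 0.005)
})

test_that("backbone torsions follow the standard sign convention", {
  mk4 <- function(p4) conformer(rep("C", 4),
                                rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), p4),
                                backbone = 1:4)
  expect_equal(backbone_torsions(mk4(c(2, 1, 0))), 180)   # planar trans
  expect_equal(backbone_torsions(mk4(c(0, 1, 0))), 0)     # planar cis
  expect_equal(backbone_torsions(mk4(c(1, 1, 1))), 90)    # right-handed +90
  expect_equal(backbone_torsions(mk4(c(1, 1, -1))), -90)
  # collinear triple: undefined torsion flagged as NA
  lin <- conformer(rep("C", 4),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
                   backbone = 1:4)
  expect_true(is.na(backbone_torsions(lin)))
  expect_error(backbone_torsions(mk4(c(2, 1, 0))[["coords"]]), "")
})

test_that("torsions agree with the brute-force two-plane oracle", {
  set.seed(31)
  for (i in 1:25) {
    pts <- matrix(rnorm(12), 4, 3)
    conf <- conformer(rep("C", 4), pts, backbone = 1:4)
    got <- backbone_torsions(conf)
    want <- dihedral_bruteforce(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("transoid fraction applies the 150-degree threshold", {
  tors <- c(180, -180, 165, -150, 120, -60, 90, NA)
  expect_equal(transoid_fraction(tors), 4 / 7)
  expect_equal(transoid_fraction(c(NA, NA)), NA_real_)
  expect_equal(transoid_fraction(tors, threshold = 100), 5 / 7)
})

test_that("descriptors are invariant under rigid motion", {
  coil <- make_coil(3, seed = 5)
  moved <- conformer(coil$elements, rigid_motion(coil$coords, 8),
                     backbone = coil$backbone)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(coil),
               tolerance = 1e-10)
  expect_equal(end_to_end(moved), end_to_end(coil), tolerance = 1e-10)
  expect_equal(as.numeric(sasa(moved, n_sphere_points = 240)),
               as.numeric(sasa(coil, n_sphere_points = 240)),
               tolerance = 0.02)
  expect_equal(backbone_torsions(moved), backbone_torsions(coil),
               tolerance = 1e-8)
})
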