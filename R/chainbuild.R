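# Idealised chain building from internal coordinates.
#
# The PAAC main chain repeats a 10-atom motif N-C-C-C(O)-N-C-N-C(O)-C-C
# (tertiary amine, two methylenes, amide, aminal methylene, amide, two
# methylenes).  Chains are generated by the natural extension reference
# frame (NeRF) construction from bond lengths, bond angles and torsions;
# carbonyl oxygens and one side-chain pseudo-atom per repeat unit (standing
# in for the amino-acid CH(R)COOH moiety) are attached afterwards from
# local geometry.

#' Internal-coordinate template of the PAAC backbone repeat unit
#'
#' One row per backbone atom: element, bond length to the previous backbone
#' atom (Angstrom; the first entry links to the previous repeat unit),
#' hybridisation of the atom (setting the bond angle centred on it:
#' tetrahedral 109.5 deg for sp3, 120 deg for trigonal amide/carbonyl
#' centres), and which side atom it carries (\code{"O"} carbonyl oxygen,
#' \code{"R"} side-chain pseudo-atom, \code{""} none).
#'
#' Bond lengths: C-C 1.53, C-N 1.47, amide C-N 1.33 Angstrom.
#'
#' @return A data frame with columns \code{element}, \code{bond},
#'   \code{hyb}, \code{side}.
#' @export
repeat_unit_template <- function() {
  data.frame(
    element = c("N", "C", "C", "C", "N", "C", "N", "C", "C", "C"),
    bond = c(1.47, 1.47, 1.53, 1.53, 1.33, 1.47, 1.47, 1.33, 1.53, 1.53),
    hyb = c("sp3", "sp3", "sp3", "trigonal", "trigonal",
            "sp3", "trigonal", "trigonal", "sp3", "sp3"),
    side = c("R", "", "", "O", "", "", "", "O", "", ""),
    stringsAsFactors = FALSE)
}

.hyb_angle <- c(sp3 = 109.5, trigonal = 120)

# NeRF: place atom D given A, B, C, bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("collinear reference atoms in NeRF placement")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + cbind(bc, m, n) %*% d2
}

# unit vector helper
.unit <- function(v) v / sqrt(sum(v^2))

#' Build a PAAC oligomer chain from internal coordinates
#'
#' Places the backbone by the NeRF construction using the repeat-unit
#' template's bond lengths and angles and the supplied torsions, then
#' attaches carbonyl oxygens (1.23 Angstrom, bisecting the backbone angle)
#' and one side-chain pseudo-atom per repeat on the tertiary amine nitrogen
#' (2.4 Angstrom, element \code{"X"}).
#'
#' @param n_units Number of repeat units, default 10.
#' @param torsions Backbone torsions in degrees, length
#'   \code{10 * n_units - 3}; default all 180 (all-trans).
#' @param template Repeat-unit template, default
#'   \code{\link{repeat_unit_template}}.
#' @param side_atoms Attach side atoms? Default \code{TRUE}.
#' @return A \code{\link{conformer}} whose \code{backbone} indices are the
#'   main-chain atoms in order.
#' @export
build_chain <- function(n_units = 10, torsions = NULL,
                        template = repeat_unit_template(),
                        side_atoms = TRUE) {
  stopifnot(n_units >= 1)
  req <- c("element", "bond", "hyb", "side")
  if (!all(req %in% names(template)) || nrow(template) < 4L)
    stop("invalid template: need columns ", paste(req, collapse = ", "),
         " and at least 4 atoms")
  if (!all(template$hyb %in% names(.hyb_angle)))
    stop("invalid template: unknown hybridisation ",
         paste(setdiff(template$hyb, names(.hyb_angle)), collapse = ", "))
  nt <- nrow(template)
  n_bb <- nt * n_units
  elements <- rep(template$element, n_units)
  bonds <- rep(template$bond, n_units)          # bonds[i] links i-1 -> i
  angles <- .hyb_angle[rep(template$hyb, n_units)]  # angle centred on atom i
  sides <- rep(template$side, n_units)
  if (is.null(torsions)) torsions <- rep(180, n_bb - 3L)
  if (length(torsions) != n_bb - 3L)
    stop("need ", n_bb - 3L, " torsions, got ", length(torsions))
  xyz <- matrix(0, n_bb, 3)
  xyz[2, ] <- c(bonds[2], 0, 0)
  a2 <- angles[2] * pi / 180
  xyz[3, ] <- xyz[2, ] + bonds[3] * c(-cos(a2), sin(a2), 0)
  for (i in 4:n_bb)
    xyz[i, ] <- nerf_place(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                           bonds[i], angles[i - 1], torsions[i - 3])
  if (side_atoms) {
    side_el <- character(0); side_xyz <- NULL
    for (i in which(sides != "")) {
      nb <- c(if (i > 1) i - 1L, if (i < n_bb) i + 1L)
      u <- rowMeans(vapply(nb, function(j) .unit(xyz[j, ] - xyz[i, ]),
                           numeric(3)))
      if (sqrt(sum(u^2)) < 1e-8) {
        ref <- .unit(xyz[nb[1], ] - xyz[i, ])
        u <- .unit(c(-ref[2], ref[1], 0))
        if (sqrt(sum(u^2)) < 1e-8) u <- c(0, 0, 1)
      } else u <- -.unit(u)
      blen <- if (sides[i] == "O") 1.23 else 2.4
      side_el <- c(side_el, if (sides[i] == "O") "O" else "X")
      side_xyz <- rbind(side_xyz, xyz[i, ] + blen * u)
    }
    conformer(c(elements, side_el), rbind(xyz, side_xyz),
              backbone = seq_len(n_bb))
  } else {
    conformer(elements, xyz, backbone = seq_len(n_bb))
  }
}

#' Build the fully extended (all-trans) oligomer
#'
#' All backbone torsions at 180 degrees: the idealised elongated starting
#' geometry of the chain.
#'
#' @inheritParams build_chain
#' @return A \code{\link{conformer}}.
#' @examples
#' ext <- build_extended_chain(n_units = 1)
#' length(ext$backbone)                     # 10 backbone atoms
#' range(abs(backbone_torsions(ext)))       # all 180
#' @export
build_extended_chain <- function(n_units = 10,
                                 template = repeat_unit_template(),
                                 side_atoms = TRUE) {
  build_chain(n_units = n_units, torsions = NULL, template = template,
              side_atoms = side_atoms)
}
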