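# Titration-curve analysis and pH speciation of amphoteric polyelectrolytes.
#
# The repeat unit of a polyamidoamino acid (PAAC) carries one carboxyl and one
# tertiary amine, so a single polymer behaves as a diprotic amphoteric
# polyelectrolyte.  Apparent pKa values depend on the degree of dissociation
# alpha; the Katchalsky-Spitnik parameter beta captures cooperativity between
# neighbouring ionisable units:
#
#   pH = pKa - beta * log10((1 - alpha) / alpha)
#
# with beta = 1 recovering the plain Henderson-Hasselbalch relation.

#' Describe one titratable group of a polyelectrolyte
#'
#' An ionizable group couples an apparent pKa with the Katchalsky-Spitnik
#' cooperativity parameter \code{beta}, the empirical exponent of the modified
#' Henderson-Hasselbalch equation.  \code{beta = 1} corresponds to independent,
#' monomer-like sites; \code{beta > 1} to anticooperative ionisation spread
#' over a wider pH range.
#'
#' @param kind Either \code{"carboxyl-acid"} or \code{"amine-base"}.
#' @param pka Apparent pKa (pH units), strictly between 0 and 14.
#' @param beta Katchalsky-Spitnik parameter, strictly positive. Default 1.
#'
#' @return An object of class \code{ionizable_group}.
#' @examples
#' ionizable_group("amine-base", pka = 7.5, beta = 1.3)
#' @export
ionizable_group <- function(kind = c("carboxyl-acid", "amine-base"), pka, beta = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(pka), length(pka) == 1L, is.finite(pka),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (pka <= 0 || pka >= 14)
    stop("'pka' must lie strictly between 0 and 14, got ", pka)
  if (beta <= 0)
    stop("'beta' must be strictly positive, got ", beta)
  structure(list(kind = kind, pka = pka, beta = beta),
            class = "ionizable_group")
}

#' @export
print.ionizable_group <- function(x, ...) {
  cat(sprintf("<ionizable_group> %s: pKa = %.3f, beta = %.3f\n",
              x$kind, x$pka, x$beta))
  invisible(x)
}

#' Define an amphoteric polymer by its two ionizable groups
#'
#' @param name Polymer name (e.g. \code{"M-l-Ala"}).
#' @param repeat_unit_mass Molar mass of the repeat unit in g/mol.
#' @param acid_group Carboxyl \code{\link{ionizable_group}}.
#' @param base_group Amine \code{\link{ionizable_group}}; its pKa must exceed
#'   the acid group's (pKa1 < pKa2).
#'
#' @return An object of class \code{polymer_spec}.
#' @examples
#' polymer_spec("M-l-Val", 271.32,
#'              ionizable_group("carboxyl-acid", 2.3, 0.8),
#'              ionizable_group("amine-base", 6.8, 1.2))
#' @export
polymer_spec <- function(name, repeat_unit_mass, acid_group, base_group) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(repeat_unit_mass), repeat_unit_mass > 0,
            inherits(acid_group, "ionizable_group"),
            inherits(base_group, "ionizable_group"))
  if (acid_group$kind != "carboxyl-acid")
    stop("'acid_group' must have kind \"carboxyl-acid\"")
  if (base_group$kind != "amine-base")
    stop("'base_group' must have kind \"amine-base\"")
  if (acid_group$pka >= base_group$pka)
    stop("acid pKa1 (", acid_group$pka, ") must be below base pKa2 (",
         base_group$pka, ")")
  structure(list(name = name, repeat_unit_mass = repeat_unit_mass,
                 acid_group = acid_group, base_group = base_group),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("<polymer_spec> %s (repeat unit %.2f g/mol)\n",
              x$name, x$repeat_unit_mass))
  cat(sprintf("  carboxyl: pKa1 = %.2f, beta1 = %.2f\n",
              x$acid_group$pka, x$acid_group$beta))
  cat(sprintf("  amine:    pKa2 = %.2f, beta2 = %.2f\n",
              x$base_group$pka, x$base_group$beta))
  invisible(x)
}

#' Built-in polymer descriptions for the three PAAC homologues
#'
#' Returns the repeat-unit molar masses (MBA 154.17 g/mol plus the amino
#' acid residue) and working acid-base parameters for the alanine-, valine-
#' and leucine-derived PAACs.  The amine pKa2 values are the half-ionization
#' pH of each polymer (8.1, 6.8, 7.3); the carboxyl pKa1 and both beta values
#' are representative defaults for this polymer family, intended for
#' simulation and demonstration, not measured constants.
#'
#' @param name One of \code{"M-l-Ala"}, \code{"M-l-Val"}, \code{"M-l-Leu"}.
#' @return A \code{\link{polymer_spec}}.
#' @examples
#' default_polymer("M-l-Ala")$repeat_unit_mass  # 243.26
#' @export
default_polymer <- function(name = c("M-l-Ala", "M-l-Val", "M-l-Leu")) {
  name <- match.arg(name)
  # repeat unit = MBA (154.17) + amino acid (Ala 89.09, Val 117.15, Leu 131.17)
  params <- list(
    "M-l-Ala" = list(mass = 154.17 + 89.09,  pka2 = 8.1, beta2 = 1.35,
                     lambda_max = 228),
    "M-l-Val" = list(mass = 154.17 + 117.15, pka2 = 6.8, beta2 = 1.20,
                     lambda_max = 234),
    "M-l-Leu" = list(mass = 154.17 + 131.17, pka2 = 7.3, beta2 = 1.25,
                     lambda_max = 231))
  p <- params[[name]]
  spec <- polymer_spec(name, p$mass,
                       ionizable_group("carboxyl-acid", pka = 2.3, beta = 0.8),
                       ionizable_group("amine-base", pka = p$pka2, beta = p$beta2))
  spec$lambda_max <- p$lambda_max
  spec
}

#' Construct a potentiometric titration curve
#'
#' Bundles the raw (added volume, pH) readings with the bookkeeping needed
#' to convert them to degrees of dissociation: titrant concentration and
#' sign, moles of titratable repeat units, and (optionally) the moles of
#' strong acid added when pre-adjusting the starting pH.
#'
#' @param volumes Added titrant volume in mL, monotone non-decreasing.
#' @param ph pH readings, same length as \code{volumes}, in (0, 14).
#' @param titrant_conc Titrant concentration in mol/L.
#' @param titrant_sign \code{+1} for base (forward run), \code{-1} for acid.
#' @param n_repeat_units Moles of titratable repeat units in the vessel.
#' @param n_strong_acid_excess Moles of pre-adjustment strong acid, or
#'   \code{NA} when unknown.
#' @param volume0 Initial sample volume in mL (used for proton-balance
#'   corrections; default 25).
#'
#' @return An object of class \code{titration_curve}.
#' @export
titration_curve <- function(volumes, ph, titrant_conc, titrant_sign = 1,
                            n_repeat_units, n_strong_acid_excess = NA_real_,
                            volume0 = 25) {
  stopifnot(length(volumes) == length(ph),
            is.numeric(titrant_conc), titrant_conc > 0,
            titrant_sign %in% c(-1, 1),
            is.numeric(n_repeat_units), n_repeat_units >= 0,
            volume0 > 0)
  if (is.unsorted(volumes))
    stop("'volumes' must be monotone non-decreasing")
  if (any(ph <= 0 | ph >= 14))
    stop("pH readings must lie strictly between 0 and 14")
  structure(list(volumes = as.numeric(volumes), ph = as.numeric(ph),
                 titrant_conc = titrant_conc, titrant_sign = titrant_sign,
                 n_repeat_units = n_repeat_units,
                 n_strong_acid_excess = n_strong_acid_excess,
                 volume0 = volume0),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d points, %s titration, %.3g M titrant\n",
              length(x$volumes), if (x$titrant_sign > 0) "base" else "acid",
              x$titrant_conc))
  cat(sprintf("  pH %.2f -> %.2f over %.2f mL; %.3g mol repeat units\n",
              x$ph[1], x$ph[length(x$ph)], max(x$volumes), x$n_repeat_units))
  invisible(x)
}

#' Apparent pKa from the Henderson-Hasselbalch relation
#'
#' Inverts \code{pH = pKa - log10((1 - alpha)/alpha)} for pKa at a given
#' degree of dissociation.  For polyelectrolytes the result depends on
#' \code{alpha}; plotting it against \code{alpha} reveals cooperativity.
#'
#' @param alpha Degree of dissociation, strictly inside (0, 1). Vectorised.
#' @param ph Matching pH value(s).
#' @return Apparent pKa value(s): \code{ph + log10((1 - alpha)/alpha)}.
#' @examples
#' apparent_pka(0.5, 6.8)    # 6.8: at half-ionization pH = pKa
#' apparent_pka(0.9, 4.954)  # 4.0
#' @export
apparent_pka <- function(alpha, ph) {
  stopifnot(is.numeric(alpha), is.numeric(ph))
  if (any(alpha <= 0 | alpha >= 1))
    stop("'alpha' must lie strictly inside (0, 1); the log term is undefined at the endpoints")
  ph + log10((1 - alpha) / alpha)
}

#' Fit the modified Henderson-Hasselbalch (Katchalsky-Spitnik) equation
#'
#' Linear least squares of pH against \code{x = log10((1 - alpha)/alpha)}:
#' the slope estimates \code{-beta} and the intercept the apparent pKa at
#' half-ionization.  Points outside \code{alpha_window} are discarded before
#' fitting because the linearisation degenerates near alpha = 0 or 1.
#'
#' @param series An \code{alpha_series} (see \code{\link{compute_alpha}}) or
#'   a data frame with columns \code{alpha} and \code{ph}.
#' @param alpha_window Closed interval of usable alpha values,
#'   default \code{c(0.2, 0.8)}.
#' @return A list of class \code{ks_fit}: \code{pka}, \code{beta},
#'   \code{r_squared}, \code{n_points}, and the underlying \code{lm} fit.
#' @examples
#' a <- seq(0.25, 0.75, length.out = 11)
#' ph <- 7.3 - 1.5 * log10((1 - a) / a)
#' fit_katchalsky_spitnik(data.frame(alpha = a, ph = ph))
#' @export
fit_katchalsky_spitnik <- function(series, alpha_window = c(0.2, 0.8)) {
  stopifnot(length(alpha_window) == 2L, alpha_window[1] < alpha_window[2])
  alpha <- series$alpha
  ph <- series$ph
  keep <- is.finite(alpha) & is.finite(ph) &
    alpha >= alpha_window[1] & alpha <= alpha_window[2]
  if (sum(keep) < 5L)
    stop("insufficient data: need at least 5 points with alpha in [",
         alpha_window[1], ", ", alpha_window[2], "], got ", sum(keep))
  x <- log10((1 - alpha[keep]) / alpha[keep])
  y <- ph[keep]
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(pka = unname(co[1]), beta = -unname(co[2]),
                 r_squared = r2,
                 n_points = sum(keep), lm_fit = fit),
            class = "ks_fit")
}

#' @export
print.ks_fit <- function(x, ...) {
  cat(sprintf("<ks_fit> pKa = %.4f, beta = %.4f (R^2 = %.5f, n = %d)\n",
              x$pka, x$beta, x$r_squared, x$n_points))
  invisible(x)
}

# 5-point moving average (ends padded by shrinking windows)
moving_average <- function(x, k = 5L) {
  n <- length(x)
  if (n < k) return(x)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    mean(x[idx])
  }, numeric(1))
}

#' Locate equivalence points of a titration curve
#'
#' Finds maxima of the first derivative dpH/dV, computed by centred
#' differences after 5-point moving-average smoothing of the pH trace.  When
#' a requested equivalence point cannot be resolved by the derivative, a
#' Gran-plot extrapolation on the preceding strong-base branch is attempted
#' as a fallback.
#'
#' @param curve A \code{\link{titration_curve}}.
#' @param n_expected Number of equivalence points to return (default 2:
#'   end of the carboxyl region, end of the amine region).
#' @param min_separation Minimum titrant-volume separation between reported
#'   equivalence points, in mL (default 5\% of the volume span).
#' @return Numeric vector of equivalence volumes (mL), increasing.
#' @export
locate_equivalence_points <- function(curve, n_expected = 2L,
                                      min_separation = NULL) {
  v <- curve$volumes
  ph <- moving_average(curve$ph, 5L)
  n <- length(v)
  if (n < 7L) stop("too few points to locate equivalence volumes")
  if (is.null(min_separation)) min_separation <- 0.05 * (max(v) - min(v))
  # centred-difference slope at interior points
  dv <- v[3:n] - v[1:(n - 2)]
  ok <- dv > 0
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)][ok] <- (ph[3:n] - ph[1:(n - 2)])[ok] / dv[ok]
  # local maxima of the slope, strongest first
  cand <- which(!is.na(slope))
  is_peak <- vapply(cand, function(i) {
    s <- slope[i]
    left <- slope[max(1, i - 2):(i - 1)]
    right <- slope[(i + 1):min(n, i + 2)]
    all(s >= left, na.rm = TRUE) && all(s >= right, na.rm = TRUE)
  }, logical(1))
  peaks <- cand[is_peak]
  peaks <- peaks[order(slope[peaks], decreasing = TRUE)]
  chosen <- numeric(0)
  for (p in peaks) {
    if (length(chosen) == n_expected) break
    if (all(abs(v[p] - chosen) >= min_separation)) chosen <- c(chosen, v[p])
  }
  if (length(chosen) < n_expected) {
    ve_gran <- gran_equivalence(curve)
    if (!is.na(ve_gran) && all(abs(ve_gran - chosen) >= min_separation))
      chosen <- c(chosen, ve_gran)
  }
  if (length(chosen) < n_expected)
    stop("undetectable equivalence points: found ", length(chosen),
         " of ", n_expected, " (region ", length(chosen) + 1L, " failed)")
  sort(chosen)
}

# Gran-plot estimate of the final equivalence volume of a forward base
# titration: beyond equivalence (V0 + V) * 10^(pH - 14) grows linearly in V
# and extrapolates back to zero at Ve.
gran_equivalence <- function(curve) {
  v <- curve$volumes; ph <- curve$ph
  g <- (curve$volume0 + v) * 10^(ph - 14)
  # use the top quarter of the run where the Gran function is largest
  idx <- which(ph > stats::quantile(ph, 0.85))
  if (length(idx) < 3L) return(NA_real_)
  fit <- stats::lm(g[idx] ~ v[idx])
  ve <- -stats::coef(fit)[1] / stats::coef(fit)[2]
  if (!is.finite(ve) || ve < min(v) || ve > max(v)) return(NA_real_)
  unname(ve)
}

#' Degrees of dissociation from a titration curve
#'
#' Converts a forward base titration of an amphoteric polymer into two
#' alpha series, one per buffering region.  Equivalence volumes are located
#' with \code{\link{locate_equivalence_points}}; within each region the
#' degree of dissociation is the proton-balance-corrected moles of titrant
#' past the region start, divided by the moles of repeat units:
#' \deqn{\alpha(V) = [Q(V) - Q(V_{e1})]/n_{RU} + c,}
#' where \eqn{Q(V) = C V + ([H^+] - [OH^-])(V_0 + V)} accounts for free
#' protons and hydroxide, and \eqn{c} is 1 in the carboxyl region (ending at
#' the first equivalence) and 0 in the amine region.  Alphas are clamped to
#' \code{(eps, 1 - eps)} and values at the clamp bounds are dropped.
#'
#' @param curve A \code{\link{titration_curve}} (forward base titration
#'   covering both buffering regions).
#' @param spec A \code{\link{polymer_spec}} (used only for labelling).
#' @param eps Clamp width for alpha, default 0.01.
#' @return A list with components \code{carboxyl} and \code{amine}, each an
#'   \code{alpha_series} data frame with columns \code{alpha}, \code{ph} and
#'   attribute \code{group}.  With no titratable repeat units both series
#'   are empty and a warning is issued.
#' @export
compute_alpha <- function(curve, spec, eps = 0.01) {
  stopifnot(inherits(curve, "titration_curve"))
  n_ru <- curve$n_repeat_units
  if (n_ru <= 0) {
    warning("no titratable repeat units: returning empty alpha series")
    empty <- alpha_series(numeric(0), numeric(0), "carboxyl-acid")
    return(list(carboxyl = empty,
                amine = alpha_series(numeric(0), numeric(0), "amine-base")))
  }
  ve <- locate_equivalence_points(curve, n_expected = 2L)
  e1 <- ve[1]; e2 <- ve[2]
  v <- curve$volumes; ph <- curve$ph
  vt_l <- (curve$volume0 + v) / 1000            # total volume, L
  q <- curve$titrant_conc * v / 1000 +
    (10^(-ph) - 10^(ph - 14)) * vt_l            # corrected titrant moles
  q_e1 <- stats::approx(v, q, xout = e1, ties = "ordered")$y
  region1 <- v <= e1
  region2 <- v > e1 & v <= e2
  a1 <- (q[region1] - q_e1) / n_ru + 1
  a2 <- (q[region2] - q_e1) / n_ru
  keep1 <- a1 > eps & a1 < 1 - eps
  keep2 <- a2 > eps & a2 < 1 - eps
  list(carboxyl = alpha_series(a1[keep1], ph[region1][keep1], "carboxyl-acid"),
       amine = alpha_series(a2[keep2], ph[region2][keep2], "amine-base"))
}

#' @rdname compute_alpha
#' @param alpha,ph Numeric vectors of equal length.
#' @param group Group kind label.
#' @export
alpha_series <- function(alpha, ph, group = c("carboxyl-acid", "amine-base")) {
  group <- match.arg(group)
  stopifnot(length(alpha) == length(ph))
  out <- data.frame(alpha = as.numeric(alpha), ph = as.numeric(ph))
  attr(out, "group") <- group
  class(out) <- c("alpha_series", "data.frame")
  out
}

#' Half-neutralization pH of an alpha series
#'
#' Estimates the pH at alpha = 0.5, which equals the apparent pKa of the
#' group titrated in that buffering region.  Under the modified
#' Henderson-Hasselbalch model pH is linear in
#' \code{log10((1 - alpha)/alpha)} with the half-neutralization pH as
#' intercept, so when at least five points fall inside \code{window} the
#' intercept of that local regression is used (averaging out reading
#' noise); otherwise the pH is linearly interpolated at alpha = 0.5.
#'
#' @param series An \code{alpha_series}.
#' @param window Alpha interval for the local regression,
#'   default \code{c(0.35, 0.65)}.
#' @return pH at half-neutralization.
#' @export
half_neutralization_ph <- function(series, window = c(0.35, 0.65)) {
  a <- series$alpha; ph <- series$ph
  ord <- order(a)
  a <- a[ord]; ph <- ph[ord]
  if (length(a) < 2L || min(a) > 0.5 || max(a) < 0.5)
    stop("alpha series does not bracket alpha = 0.5")
  near <- a >= window[1] & a <= window[2]
  if (sum(near) >= 5L) {
    x <- log10((1 - a[near]) / a[near])
    unname(stats::coef(stats::lm(ph[near] ~ x))[1])
  } else {
    stats::approx(a, ph, xout = 0.5, ties = "ordered")$y
  }
}

#' pH speciation of the amphoteric repeat unit
#'
#' Computes, on a pH grid, the ionisation state of each group from its
#' Katchalsky-Spitnik parameterisation,
#' \deqn{f_{COO^-} = 1/(1 + 10^{(pK_{a1} - pH)/\beta_1}), \quad
#'       f_{NH^+} = 1/(1 + 10^{(pH - pK_{a2})/\beta_2}),}
#' and the fractions of the four repeat-unit microstates assuming site
#' independence (the beta exponents already absorb nearest-neighbour
#' interactions): cationic (COOH/NH+), zwitterionic (COO-/NH+), uncharged
#' (COOH/NH) and anionic (COO-/NH).  Because pKa1 is far below pKa2 the
#' uncharged microstate is negligible but is kept explicitly so the four
#' fractions sum to one; \code{net_neutral} lumps it with the zwitterion to
#' match the conventional three-state picture.
#'
#' @param spec A \code{\link{polymer_spec}}.
#' @param ph_grid pH values (default \code{seq(0, 14, by = 0.05)}).
#' @return A data frame of class \code{speciation_profile} with columns
#'   \code{ph}, \code{f_coo}, \code{f_nh}, \code{f_cation},
#'   \code{f_zwitterion}, \code{f_neutral}, \code{f_anion},
#'   \code{net_neutral} and \code{net_charge} (mean charge per repeat unit,
#'   \code{f_nh - f_coo}).
#' @examples
#' sp <- speciation(default_polymer("M-l-Val"), ph_grid = c(3, 6.8, 11))
#' sp$f_nh[2]  # 0.5 at pH = pKa2
#' @export
speciation <- function(spec, ph_grid = seq(0, 14, by = 0.05)) {
  stopifnot(inherits(spec, "polymer_spec"))
  f_coo <- fraction_deprotonated_acid(ph_grid, spec$acid_group)
  f_nh <- fraction_protonated_base(ph_grid, spec$base_group)
  out <- data.frame(
    ph = ph_grid,
    f_coo = f_coo,
    f_nh = f_nh,
    f_cation = (1 - f_coo) * f_nh,
    f_zwitterion = f_coo * f_nh,
    f_neutral = (1 - f_coo) * (1 - f_nh),
    f_anion = f_coo * (1 - f_nh))
  out$net_neutral <- out$f_zwitterion + out$f_neutral
  out$net_charge <- f_nh - f_coo
  class(out) <- c("speciation_profile", "data.frame")
  out
}

#' @rdname speciation
#' @param ph pH value(s).
#' @param group An \code{\link{ionizable_group}}.
#' @export
fraction_deprotonated_acid <- function(ph, group) {
  stopifnot(group$kind == "carboxyl-acid")
  1 / (1 + 10^((group$pka - ph) / group$beta))
}

#' @rdname speciation
#' @export
fraction_protonated_base <- function(ph, group) {
  stopifnot(group$kind == "amine-base")
  1 / (1 + 10^((ph - group$pka) / group$beta))
}

#' Isoelectric point of an amphoteric polymer
#'
#' Bisection root of the mean net charge per repeat unit on (0, 14), to a
#' pH tolerance of 1e-6.  For beta1 = beta2 and symmetric pKa values this is
#' the midpoint (pKa1 + pKa2)/2.
#'
#' @param spec A \code{\link{polymer_spec}}.
#' @param tol pH tolerance, default 1e-6.
#' @return The pH at which the net charge vanishes.
#' @examples
#' iep <- isoelectric_point(polymer_spec("toy", 100,
#'   ionizable_group("carboxyl-acid", 3), ionizable_group("amine-base", 7)))
#' # 5.0
#' @export
isoelectric_point <- function(spec, tol = 1e-6) {
  net <- function(ph)
    fraction_protonated_base(ph, spec$base_group) -
      fraction_deprotonated_acid(ph, spec$acid_group)
  lo <- 1e-9; hi <- 14 - 1e-9
  if (net(lo) * net(hi) > 0)
    stop("net charge does not change sign on (0, 14)")
  stats::uniroot(net, c(lo, hi), tol = tol)$root
}
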