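# Circular-dichroism spectrum handling: normalisation to repeat-unit molar
# ellipticity, differential series against an acidic reference, band peak
# extraction, and sigmoid fitting of the pH-driven structuring transition.

#' Construct a CD spectrum
#'
#' @param wavelengths Wavelengths in nm, sorted ascending, all positive.
#' @param ellipticity Ellipticity readings. Raw instrument output is in
#'   mdeg; after \code{\link{to_molar_ellipticity}} the units are
#'   mdeg M^-1 cm^-1 and \code{normalized} is set.
#' @param ph Solution pH.
#' @param path_length Cell path length in cm (default 1).
#' @param mass_conc Polymer mass concentration in mg/mL (optional).
#' @param repeat_unit_conc Repeat-unit molar concentration in mol/L
#'   (optional; derived from \code{mass_conc} when a repeat-unit mass is
#'   supplied to \code{\link{to_molar_ellipticity}}).
#' @param temperature Temperature in degrees C (optional metadata).
#' @param normalized Logical; whether \code{ellipticity} is already molar.
#'
#' @return An object of class \code{cd_spectrum}.
#' @export
cd_spectrum <- function(wavelengths, ellipticity, ph, path_length = 1,
                        mass_conc = NA_real_, repeat_unit_conc = NA_real_,
                        temperature = NA_real_, normalized = FALSE) {
  stopifnot(length(wavelengths) == length(ellipticity),
            is.numeric(ph), length(ph) == 1L,
            path_length > 0)
  if (any(wavelengths <= 0)) stop("wavelengths must be positive")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be sorted strictly ascending")
  structure(list(wavelengths = as.numeric(wavelengths),
                 ellipticity = as.numeric(ellipticity),
                 ph = ph, path_length = path_length,
                 mass_conc = mass_conc, repeat_unit_conc = repeat_unit_conc,
                 temperature = temperature, normalized = normalized),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> pH %.2f, %d points (%.0f-%.0f nm), %s\n",
              x$ph, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths),
              if (x$normalized) "molar ellipticity (mdeg M-1 cm-1)" else "raw mdeg"))
  invisible(x)
}

#' Repeat-unit molar concentration from mass concentration
#'
#' @param mass_conc Mass concentration in mg/mL (equivalently g/L).
#' @param repeat_unit_mass Repeat-unit molar mass in g/mol.
#' @return Concentration in mol/L.
#' @examples
#' repeat_unit_concentration(0.5, 271.32) * 1000  # 1.843 mM (M-l-Val)
#' @export
repeat_unit_concentration <- function(mass_conc, repeat_unit_mass) {
  if (any(mass_conc <= 0) || any(repeat_unit_mass <= 0))
    stop("mass concentration and repeat-unit mass must be positive")
  mass_conc / repeat_unit_mass
}

#' Normalise a raw CD spectrum to repeat-unit molar ellipticity
#'
#' Divides the raw mdeg signal by the repeat-unit molar concentration and
#' path length, yielding theta in mdeg M^-1 cm^-1.
#'
#' @param spec A raw \code{\link{cd_spectrum}}.
#' @param repeat_unit_mass Repeat-unit molar mass in g/mol, used to derive
#'   the molar concentration from \code{mass_conc} when
#'   \code{repeat_unit_conc} is not already set.
#' @return The normalised \code{cd_spectrum}.
#' @export
to_molar_ellipticity <- function(spec, repeat_unit_mass = NULL) {
  stopifnot(inherits(spec, "cd_spectrum"))
  if (spec$normalized) return(spec)
  conc <- spec$repeat_unit_conc
  if (is.na(conc)) {
    if (is.null(repeat_unit_mass) || is.na(spec$mass_conc))
      stop("cannot normalise: repeat-unit molar concentration unknown ",
           "(supply 'repeat_unit_conc' or 'mass_conc' + 'repeat_unit_mass')")
    conc <- repeat_unit_concentration(spec$mass_conc, repeat_unit_mass)
  }
  spec$ellipticity <- spec$ellipticity / (conc * spec$path_length)
  spec$repeat_unit_conc <- conc
  spec$normalized <- TRUE
  spec
}

# interpolate theta at a wavelength
theta_at <- function(spec, wavelength) {
  if (wavelength < min(spec$wavelengths) || wavelength > max(spec$wavelengths))
    stop("wavelength ", wavelength, " nm outside the spectrum range")
  stats::approx(spec$wavelengths, spec$ellipticity, xout = wavelength,
                ties = "ordered")$y
}

#' Differential molar ellipticity series against an acidic reference
#'
#' For each spectrum of a pH series, computes the difference between its
#' molar ellipticity and that of the reference spectrum (the one closest to
#' \code{ref_ph}, required within \code{ref_tol}), evaluated at a fixed
#' wavelength or at each spectrum's positive-peak maximum.
#'
#' @param spectra List of normalised \code{\link{cd_spectrum}} objects.
#' @param ref_ph Reference pH (default 3, the fully amine-protonated state).
#' @param wavelength Either a wavelength in nm or \code{"peak"} to use the
#'   per-spectrum positive-band maximum within \code{window}.
#' @param ref_tol Maximum |pH - ref_ph| for an acceptable reference
#'   spectrum, default 0.2.
#' @param window Wavelength window for peak detection when
#'   \code{wavelength = "peak"}.
#' @return A data frame with columns \code{ph} and \code{delta_theta},
#'   sorted by pH; the reference row is included (delta 0 at the reference).
#' @export
differential_series <- function(spectra, ref_ph = 3, wavelength = 228,
                                ref_tol = 0.2, window = c(200, 280)) {
  stopifnot(length(spectra) >= 2L)
  if (!all(vapply(spectra, function(s) isTRUE(s$normalized), logical(1))))
    stop("all spectra must be normalised (see to_molar_ellipticity)")
  phs <- vapply(spectra, `[[`, numeric(1), "ph")
  iref <- which.min(abs(phs - ref_ph))
  if (abs(phs[iref] - ref_ph) > ref_tol)
    stop("no reference spectrum within ", ref_tol, " pH of ref_ph = ", ref_ph)
  ref <- spectra[[iref]]
  dtheta <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (identical(wavelength, "peak")) {
      pk <- find_peaks(s, window)
      lam <- if (pk$degenerate) mean(window) else pk$lambda_max
    } else lam <- wavelength
    theta_at(s, lam) - theta_at(ref, lam)
  }, numeric(1))
  out <- data.frame(ph = phs, delta_theta = dtheta)
  out[order(out$ph), , drop = FALSE]
}

#' Positive and negative band extrema of a CD spectrum
#'
#' Global maximum and minimum of the ellipticity within a wavelength window,
#' with a flag for the characteristic band ordering (negative band at lower
#' wavelength than the positive band) and a degeneracy flag for flat
#' spectra.
#'
#' @param spec A \code{\link{cd_spectrum}}.
#' @param window Wavelength interval in nm, default \code{c(200, 280)};
#'   must lie inside the data range.
#' @param flat_tol Amplitude below which the spectrum is flagged flat,
#'   default 1e-8 in the spectrum's units.
#' @return A list: \code{lambda_max}, \code{theta_max}, \code{lambda_min},
#'   \code{theta_min}, \code{min_below_max} (is the negative band at lower
#'   wavelength?), \code{degenerate}.
#' @export
find_peaks <- function(spec, window = c(200, 280), flat_tol = 1e-8) {
  stopifnot(inherits(spec, "cd_spectrum"), length(window) == 2L)
  if (window[1] < min(spec$wavelengths) || window[2] > max(spec$wavelengths))
    stop("window [", window[1], ", ", window[2],
         "] nm outside the data range")
  inside <- spec$wavelengths >= window[1] & spec$wavelengths <= window[2]
  lam <- spec$wavelengths[inside]
  th <- spec$ellipticity[inside]
  imax <- which.max(th); imin <- which.min(th)
  list(lambda_max = lam[imax], theta_max = th[imax],
       lambda_min = lam[imin], theta_min = th[imin],
       min_below_max = lam[imin] < lam[imax],
       degenerate = (th[imax] - th[imin]) < flat_tol)
}

# 4-parameter logistic in pH, base 10:
#   y = L + (U - L) / (1 + 10^(m * (ph50 - ph)))
logistic4 <- function(ph, lower, upper, ph50, slope) {
  lower + (upper - lower) / (1 + 10^(slope * (ph50 - ph)))
}

#' Fit a pH sigmoid to a differential-ellipticity series
#'
#' Nonlinear least squares of the 4-parameter base-10 logistic
#' \deqn{\Delta\theta(pH) = L + (U - L)/(1 + 10^{m\,(pH_{50} - pH)}),}
#' whose inflection \eqn{pH_{50}} coincides with amine half-ionization when
#' the structuring amplitude tracks amine deprotonation (for a series
#' proportional to \eqn{1 - f_{NH^+}}, \eqn{pH_{50} = pK_{a2}} and
#' \eqn{m = 1/\beta_2} exactly).  Initialisation: L and U from the 5th/95th
#' percentiles, pH50 from the mid-amplitude crossing, and a multi-start over
#' slopes \code{c(0.5, 1, 2)}; the best converged start (lowest residual sum
#' of squares) wins.
#'
#' @param points Data frame with columns \code{ph} and \code{delta_theta}
#'   (at least 8 points spanning both plateaus).
#' @param slope_starts Slope values for the multi-start, default
#'   \code{c(0.5, 1, 2)}.
#' @param plateau_tol Fraction of the amplitude used to report plateau pH
#'   ranges, default 0.05.
#' @return An object of class \code{sigmoid_fit}: \code{lower_plateau},
#'   \code{upper_plateau}, \code{inflection_ph}, \code{slope},
#'   \code{covariance}, \code{rss}, \code{lower_plateau_range},
#'   \code{upper_plateau_range}, \code{n_points}.
#' @examples
#' ph <- seq(3, 11, by = 0.25)
#' y <- logistic_reference(ph, lower = 0, upper = 1000, ph50 = 6.8, slope = 1)
#' fit_sigmoid(data.frame(ph = ph, delta_theta = y))$inflection_ph  # 6.8
#' @export
fit_sigmoid <- function(points, slope_starts = c(0.5, 1, 2),
                        plateau_tol = 0.05) {
  ph <- points$ph; y <- points$delta_theta
  ok <- is.finite(ph) & is.finite(y)
  ph <- ph[ok]; y <- y[ok]
  if (length(ph) < 8L)
    stop("need at least 8 finite points spanning both plateaus, got ",
         length(ph))
  amp <- diff(range(y))
  if (amp < 1e-12 * max(1, max(abs(y))) || amp == 0)
    stop("zero-amplitude series: no sigmoid transition to fit")
  l0 <- stats::quantile(y, 0.05, names = FALSE)
  u0 <- stats::quantile(y, 0.95, names = FALSE)
  mid <- (l0 + u0) / 2
  ph50_0 <- ph[which.min(abs(y - mid))]
  dat <- data.frame(ph = ph, y = y)
  best <- NULL
  for (m0 in slope_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lower + (upper - lower) / (1 + 10^(slope * (ph50 - ph))),
        data = dat,
        start = list(lower = l0, upper = u0, ph50 = ph50_0, slope = m0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from any start (starts tried: ",
         paste(slope_starts, collapse = ", "), ")")
  co <- stats::coef(best$fit)
  if (co["ph50"] < min(ph) || co["ph50"] > max(ph))
    warning("fitted inflection pH ", round(co["ph50"], 3),
            " lies outside the data range")
  vcov_mat <- tryCatch(stats::vcov(best$fit),
                       error = function(e) matrix(NA_real_, 4, 4))
  amp_fit <- co["upper"] - co["lower"]
  near_low <- abs(y - co["lower"]) < plateau_tol * abs(amp_fit)
  near_up <- abs(y - co["upper"]) < plateau_tol * abs(amp_fit)
  rng <- function(keep) if (any(keep)) range(ph[keep]) else c(NA_real_, NA_real_)
  structure(list(lower_plateau = unname(co["lower"]),
                 upper_plateau = unname(co["upper"]),
                 inflection_ph = unname(co["ph50"]),
                 slope = unname(co["slope"]),
                 covariance = vcov_mat, rss = best$rss,
                 lower_plateau_range = rng(near_low),
                 upper_plateau_range = rng(near_up),
                 n_points = length(ph), nls_fit = best$fit),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> inflection pH %.3f, slope %.3f\n",
              x$inflection_ph, x$slope))
  cat(sprintf("  plateaus: %.1f -> %.1f (RSS %.3g, n = %d)\n",
              x$lower_plateau, x$upper_plateau, x$rss, x$n_points))
  invisible(x)
}

#' Evaluate the reference 4-parameter logistic
#'
#' Convenience wrapper exposing the model fitted by \code{\link{fit_sigmoid}}.
#'
#' @param ph pH values.
#' @param lower,upper Plateau values.
#' @param ph50 Inflection pH.
#' @param slope Steepness per pH unit.
#' @return Model values at \code{ph}.
#' @export
logistic_reference <- function(ph, lower, upper, ph50, slope) {
  logistic4(ph, lower, upper, ph50, slope)
}
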