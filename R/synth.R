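# Synthetic-data generation: titration curves by electroneutrality
# inversion, pH series of CD spectra coupled to amine deprotonation, and
# coiled-chain coordinates.  Everything is deterministic given a seed.

# evaluate code under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Describe a simulated potentiometric titration experiment
#'
#' @param sample_conc Repeat-unit concentration in mol/L (default 0.05).
#' @param volume0 Initial sample volume in mL (default 25).
#' @param titrant_conc Titrant (NaOH) concentration in mol/L (default 0.1).
#' @param strong_acid_excess Moles of strong acid added when pre-adjusting
#'   the starting pH; \code{NULL} means "enough to reach \code{ph_start}"
#'   and is solved from the charge balance.
#' @param ph_start,ph_end pH range of the forward run (defaults 1.7 and
#'   11.8, the pre-adjusted acidic start and basic end).
#' @param ph_step pH grid step (default 0.05).
#' @param ph_noise_sd Gaussian noise on the pH readings (default 0).
#' @param seed Integer seed, used only when \code{ph_noise_sd > 0}.
#' @return An object of class \code{titration_protocol}.
#' @export
titration_protocol <- function(sample_conc = 0.05, volume0 = 25,
                               titrant_conc = 0.1,
                               strong_acid_excess = NULL,
                               ph_start = 1.7, ph_end = 11.8,
                               ph_step = 0.05, ph_noise_sd = 0,
                               seed = 1L) {
  stopifnot(sample_conc >= 0, volume0 > 0, titrant_conc > 0,
            ph_start < ph_end, ph_step > 0, ph_noise_sd >= 0)
  structure(list(sample_conc = sample_conc, volume0 = volume0,
                 titrant_conc = titrant_conc,
                 strong_acid_excess = strong_acid_excess,
                 ph_start = ph_start, ph_end = ph_end, ph_step = ph_step,
                 ph_noise_sd = ph_noise_sd, seed = seed),
            class = "titration_protocol")
}

#' Simulate a forward base titration of an amphoteric polymer
#'
#' Inverts the charge balance of the titration vessel.  At every pH on the
#' grid the added NaOH volume satisfies electroneutrality
#' \deqn{n_{Na} + n_{H^+} + n_{RU} f_{NH^+} = n_{Cl} + n_{OH^-} +
#'       n_{RU} f_{COO^-},}
#' with the free proton/hydroxide amounts computed from the total (diluted)
#' volume and \eqn{K_w = 10^{-14}}; the linear dependence of both sides on
#' the added volume is solved exactly.  The pre-adjustment strong acid is
#' chosen so that the curve starts at \code{ph_start} with zero added base
#' (unless given explicitly).  Optional Gaussian noise is added to the pH
#' readings; volumes stay noise-free and strictly increasing.
#'
#' @param spec A \code{\link{polymer_spec}}; pass \code{NULL} (or a spec
#'   with \code{sample_conc = 0}) for a blank strong-acid/strong-base run.
#' @param protocol A \code{\link{titration_protocol}}.
#' @return A \code{\link{titration_curve}}.
#' @examples
#' p <- titration_protocol(sample_conc = 0.05, ph_noise_sd = 0)
#' curve <- simulate_titration(default_polymer("M-l-Val"), p)
#' @export
simulate_titration <- function(spec, protocol = titration_protocol()) {
  stopifnot(inherits(protocol, "titration_protocol"))
  c_ru <- if (is.null(spec)) 0 else protocol$sample_conc
  v0_l <- protocol$volume0 / 1000
  n_ru <- c_ru * v0_l
  ct <- protocol$titrant_conc
  delta_f <- function(ph) {
    if (is.null(spec) || n_ru == 0) return(rep(0, length(ph)))
    fraction_deprotonated_acid(ph, spec$acid_group) -
      fraction_protonated_base(ph, spec$base_group)
  }
  water <- function(ph) 10^(ph - 14) - 10^(-ph)   # [OH-] - [H+], mol/L
  n_cl <- protocol$strong_acid_excess
  if (is.null(n_cl)) {
    # zero added base at ph_start: n_Cl = -water(ph0)*V0 - n_RU*delta_f(ph0)
    n_cl <- -water(protocol$ph_start) * v0_l - n_ru * delta_f(protocol$ph_start)
    if (n_cl < 0)
      stop("ph_start ", protocol$ph_start,
           " is above the un-acidified sample pH; no strong acid excess can reach it")
  }
  ph_grid <- seq(protocol$ph_start, protocol$ph_end, by = protocol$ph_step)
  d <- water(ph_grid)
  # C*V = n_Cl + n_RU*delta_f + d*(V0 + V)  (volumes in L)
  if (any(ct - d <= 0))
    stop("unreachable pH: titrant concentration too low beyond pH ",
         round(ph_grid[which(ct - d <= 0)[1]], 2))
  v_l <- (n_cl + n_ru * delta_f(ph_grid) + d * v0_l) / (ct - d)
  keep <- v_l >= -1e-12
  v_ml <- pmax(v_l[keep], 0) * 1000
  ph <- ph_grid[keep]
  ord <- order(v_ml)
  v_ml <- v_ml[ord]; ph <- ph[ord]
  if (protocol$ph_noise_sd > 0)
    ph <- with_seed(protocol$seed,
                    ph + stats::rnorm(length(ph), 0, protocol$ph_noise_sd))
  ph <- pmin(pmax(ph, 1e-3), 14 - 1e-3)
  titration_curve(v_ml, ph, titrant_conc = ct, titrant_sign = 1,
                  n_repeat_units = n_ru, n_strong_acid_excess = n_cl,
                  volume0 = protocol$volume0)
}

#' Parameters of a simulated CD pH series
#'
#' The model spectrum is a positive Gaussian band whose amplitude tracks
#' amine deprotonation, plus a negative Gaussian band at lower wavelength
#' whose centre blue-shifts linearly below pH 5:
#' \deqn{\theta(\lambda, pH) = A (1 - f_{NH^+}(pH)) G(\lambda; c^+, w^+)
#'   - B(pH) G(\lambda; c^-(pH), w^-) + \epsilon.}
#'
#' @param ph_values pH values of the series (default \code{seq(3, 11, 0.25)}).
#' @param pos_center,pos_width,pos_amplitude Positive band: centre (nm),
#'   Gaussian width (nm), maximum molar-ellipticity amplitude
#'   (mdeg M^-1 cm^-1).
#' @param neg_center,neg_width,neg_amplitude Negative band parameters.
#' @param neg_blueshift Blue shift of the negative band centre per pH unit
#'   below pH 5, in nm (default 2).
#' @param wavelengths Wavelength grid in nm (default \code{seq(200, 300, 1)}).
#' @param noise_sd Noise standard deviation as a fraction of the positive
#'   amplitude (default 0).
#' @param mass_conc Polymer concentration in mg/mL used to invert the
#'   normalisation into raw mdeg (default 0.5).
#' @param seed Integer seed.
#' @return An object of class \code{cd_series_params}.
#' @export
cd_series_params <- function(ph_values = seq(3, 11, by = 0.25),
                             pos_center = 228, pos_width = 10,
                             pos_amplitude = 1000,
                             neg_center = 212, neg_width = 8,
                             neg_amplitude = 400, neg_blueshift = 2,
                             wavelengths = seq(200, 300, by = 1),
                             noise_sd = 0, mass_conc = 0.5, seed = 1L) {
  stopifnot(pos_center > 195, pos_center < 300, pos_width > 0,
            neg_center > 195, neg_center < 300, neg_width > 0,
            noise_sd >= 0, mass_conc > 0)
  structure(list(ph_values = ph_values, pos_center = pos_center,
                 pos_width = pos_width, pos_amplitude = pos_amplitude,
                 neg_center = neg_center, neg_width = neg_width,
                 neg_amplitude = neg_amplitude, neg_blueshift = neg_blueshift,
                 wavelengths = wavelengths, noise_sd = noise_sd,
                 mass_conc = mass_conc, seed = seed),
            class = "cd_series_params")
}

#' Simulate a pH series of raw CD spectra
#'
#' Generates model molar-ellipticity spectra (see
#' \code{\link{cd_series_params}}) with the structuring amplitude coupled to
#' the amine deprotonation fraction of \code{spec}, then inverts the
#' normalisation (multiplies by repeat-unit molar concentration and path
#' length) to produce raw mdeg spectra as an instrument would record them.
#'
#' @param spec A \code{\link{polymer_spec}} (provides pKa2/beta2 and the
#'   repeat-unit mass used to derive the molar concentration).
#' @param params A \code{\link{cd_series_params}}.
#' @return A list of raw \code{\link{cd_spectrum}} objects, one per pH.
#' @export
simulate_cd_series <- function(spec, params = cd_series_params()) {
  stopifnot(inherits(spec, "polymer_spec"),
            inherits(params, "cd_series_params"))
  conc <- repeat_unit_concentration(params$mass_conc, spec$repeat_unit_mass)
  gauss <- function(lam, center, width) exp(-0.5 * ((lam - center) / width)^2)
  lam <- params$wavelengths
  with_seed(params$seed, {
    lapply(params$ph_values, function(ph) {
      f_nh <- fraction_protonated_base(ph, spec$base_group)
      neg_c <- params$neg_center -
        params$neg_blueshift * max(0, 5 - ph)
      theta <- params$pos_amplitude * (1 - f_nh) *
        gauss(lam, params$pos_center, params$pos_width) -
        params$neg_amplitude * (0.3 + 0.7 * (1 - f_nh)) *
        gauss(lam, neg_c, params$neg_width)
      if (params$noise_sd > 0)
        theta <- theta + stats::rnorm(length(lam), 0,
                                      params$noise_sd * params$pos_amplitude)
      cd_spectrum(lam, theta * conc * 1, ph = ph, path_length = 1,
                  mass_conc = params$mass_conc, repeat_unit_conc = conc,
                  normalized = FALSE)
    })
  })
}

#' Generate a randomly coiled oligomer
#'
#' Re-torsions the extended chain with backbone dihedrals drawn from a
#' mixture emulating hairpin-like folds: with probability
#' \code{p_transoid} (default 0.7) near-trans angles
#' (|angle| = 180 - |N(0, 8 deg)|, random sign), otherwise turn angles
#' uniform in +/-(60, 120) degrees.  Candidate conformations with
#' hard-sphere clashes (non-bonded backbone atoms closer than
#' \code{clash_cutoff}) are rejected and redrawn.
#'
#' @param n_units Number of repeat units, default 10.
#' @param seed Integer seed; the same seed reproduces identical coordinates.
#' @param p_transoid Probability of the near-trans component, default 0.7.
#' @param clash_cutoff Minimum allowed distance (Angstrom) between backbone
#'   atoms more than 3 bonds apart, default 2.0.
#' @param max_attempts Rejection-sampling budget, default 500.
#' @param template Repeat-unit template.
#' @return A \code{\link{conformer}}.
#' @export
make_coil <- function(n_units = 10, seed = 1L, p_transoid = 0.7,
                      clash_cutoff = 2.0, max_attempts = 500,
                      template = repeat_unit_template()) {
  n_tor <- nrow(template) * n_units - 3L
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      trans <- stats::runif(n_tor) < p_transoid
      sign <- ifelse(stats::runif(n_tor) < 0.5, -1, 1)
      tor <- ifelse(trans,
                    sign * (180 - abs(stats::rnorm(n_tor, 0, 8))),
                    sign * stats::runif(n_tor, 60, 120))
      tor <- pmax(pmin(tor, 180), -180)
      conf <- build_chain(n_units, torsions = tor, template = template)
      if (!has_clash(conf, clash_cutoff)) return(conf)
    }
    stop("could not generate a clash-free coil in ", max_attempts,
         " attempts")
  })
}

# hard-sphere self-overlap check on backbone atoms > 3 bonds apart
has_clash <- function(conf, cutoff = 2.0) {
  bb <- conf$backbone
  x <- conf$coords[bb, , drop = FALSE]
  n <- nrow(x)
  if (n < 6L) return(FALSE)
  d <- as.matrix(stats::dist(x))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  any(d[sep > 3] < cutoff)
}
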