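# Pipeline driver: one configuration, staged execution, reproducible
# outputs.  Each output carries a hash of the configuration so reruns can
# be matched to their settings.

#' Assemble a run configuration
#'
#' @param polymer Polymer name (one of the built-ins, see
#'   \code{\link{default_polymer}}) or a \code{\link{polymer_spec}}.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory.
#' @param titration A \code{\link{titration_protocol}} (or a list of
#'   arguments for it).
#' @param cd A \code{\link{cd_series_params}} (or a list of arguments).
#' @param alpha_window Alpha window for the Katchalsky-Spitnik fit.
#' @param cd_wavelength Wavelength (nm) or \code{"peak"} for the
#'   differential series; \code{NULL} uses the polymer's positive-band
#'   maximum when known, else \code{"peak"}.
#' @param n_units Repeat units for the chain stage.
#' @param probe_radius,n_sphere_points SASA settings (nm / count).
#' @param transoid_threshold Transoid cutoff in degrees.
#' @param speciation_step pH grid step for the speciation table.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(polymer = "M-l-Val", seed = 1L,
                       out_dir = tempfile("paac_run_"),
                       titration = titration_protocol(),
                       cd = cd_series_params(),
                       alpha_window = c(0.2, 0.8),
                       cd_wavelength = NULL,
                       n_units = 10,
                       probe_radius = 0.14, n_sphere_points = 960,
                       transoid_threshold = 150,
                       speciation_step = 0.05) {
  spec <- if (inherits(polymer, "polymer_spec")) polymer else
    default_polymer(polymer)
  if (is.list(titration) && !inherits(titration, "titration_protocol"))
    titration <- do.call(titration_protocol, titration)
  if (is.list(cd) && !inherits(cd, "cd_series_params"))
    cd <- do.call(cd_series_params, cd)
  titration$seed <- seed
  cd$seed <- seed
  structure(list(spec = spec, seed = as.integer(seed), out_dir = out_dir,
                 titration = titration, cd = cd,
                 alpha_window = alpha_window,
                 cd_wavelength = cd_wavelength, n_units = n_units,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 transoid_threshold = transoid_threshold,
                 speciation_step = speciation_step),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}; the
#' \code{titration} and \code{cd} keys hold argument lists for
#' \code{\link{titration_protocol}} and \code{\link{cd_series_params}}.
#'
#' @param file YAML path.
#' @param ... Overrides passed on to \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(file, ...) {
  y <- yaml::read_yaml(file)
  args <- utils::modifyList(y, list(...))
  if (!is.null(args$titration))
    args$titration <- do.call(titration_protocol, args$titration)
  if (!is.null(args$cd)) {
    if (!is.null(args$cd$ph_values)) args$cd$ph_values <-
        as.numeric(unlist(args$cd$ph_values))
    args$cd <- do.call(cd_series_params, args$cd)
  }
  do.call(run_config, args)
}

# polynomial rolling hash (mod 2^31 - 1) over the deparsed configuration;
# stable across sessions, for run bookkeeping only
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)[setdiff(names(config), "out_dir")]),
             collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic data
#' generated from the configuration:
#' \describe{
#'   \item{titrate}{simulate the forward base titration, compute the two
#'     alpha series, the half-neutralization pKa values and the
#'     Katchalsky-Spitnik fits.}
#'   \item{speciate}{tabulate the microstate speciation diagram and the
#'     isoelectric point.}
#'   \item{cd}{simulate the CD pH series, normalise, build the
#'     differential-ellipticity series against pH 3 and fit the sigmoid.}
#'   \item{chain}{build the extended chain and a seeded coil and compute
#'     their conformational descriptors.}
#' }
#' The stage name \code{synth} is accepted as an alias that forces the
#' synthetic inputs to be written out alongside the results.  A JSON
#' summary (pKa values, beta values, sigmoid inflection, the
#' |inflection - pKa2| discrepancy, and chain descriptors) is written to
#' \code{out_dir}, every file stamped with the configuration hash.
#'
#' @param config A \code{\link{run_config}}.
#' @param stages Character subset of
#'   \code{c("synth", "titrate", "speciate", "cd", "chain")}.
#' @return The summary list, invisibly; files under \code{config$out_dir}.
#' @export
run_pipeline <- function(config,
                         stages = c("titrate", "speciate", "cd", "chain")) {
  stopifnot(inherits(config, "run_config"))
  known <- c("synth", "titrate", "speciate", "cd", "chain")
  if (length(stages) == 0L)
    stop("no stages requested; choose from: ", paste(known, collapse = ", "))
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  spec <- config$spec
  write_synth <- "synth" %in% stages
  summary <- list(polymer = spec$name, seed = config$seed,
                  config_hash = hash,
                  package_version = as.character(utils::packageVersion("paac")),
                  stages = stages)
  fail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)

  if (any(c("titrate", "synth") %in% stages)) {
    tryCatch({
      curve <- simulate_titration(spec, config$titration)
      if (write_synth)
        write_titration_csv(curve, file.path(config$out_dir,
                                             "titration_curve.csv"))
      alpha <- compute_alpha(curve, spec)
      tab <- alpha_table(alpha)
      tab$config_hash <- hash
      utils::write.csv(tab, file.path(config$out_dir, "alpha_pka.csv"),
                       row.names = FALSE)
      ks1 <- fit_katchalsky_spitnik(alpha$carboxyl, config$alpha_window)
      ks2 <- fit_katchalsky_spitnik(alpha$amine, config$alpha_window)
      summary$titration <- list(
        pka1_half_neutralization = half_neutralization_ph(alpha$carboxyl),
        pka2_half_neutralization = half_neutralization_ph(alpha$amine),
        pka1_ks = ks1$pka, beta1_ks = ks1$beta, r2_1 = ks1$r_squared,
        pka2_ks = ks2$pka, beta2_ks = ks2$beta, r2_2 = ks2$r_squared)
    }, error = function(e) fail("titrate", e))
  }

  if ("speciate" %in% stages) {
    tryCatch({
      sp <- speciation(spec, seq(0, 14, by = config$speciation_step))
      out <- data.frame(pH = sp$ph, f_cation = sp$f_cation,
                        f_zwitterion = sp$f_zwitterion,
                        f_neutral = sp$f_neutral, f_anion = sp$f_anion,
                        net_charge = sp$net_charge, config_hash = hash)
      utils::write.csv(out, file.path(config$out_dir, "speciation.csv"),
                       row.names = FALSE)
      summary$speciation <- list(isoelectric_point = isoelectric_point(spec))
    }, error = function(e) fail("speciate", e))
  }

  if ("cd" %in% stages) {
    tryCatch({
      raw <- simulate_cd_series(spec, config$cd)
      if (write_synth)
        write_cd_series(raw, file.path(config$out_dir, "cd_series"))
      norm <- lapply(raw, to_molar_ellipticity, spec$repeat_unit_mass)
      lam <- config$cd_wavelength %||% spec$lambda_max %||% "peak"
      ds <- differential_series(norm, ref_ph = 3, wavelength = lam)
      ds$config_hash <- hash
      utils::write.csv(ds, file.path(config$out_dir, "differential_series.csv"),
                       row.names = FALSE)
      fit <- fit_sigmoid(ds)
      summary$cd <- list(
        wavelength = if (identical(lam, "peak")) "peak" else lam,
        inflection_ph = fit$inflection_ph, slope = fit$slope,
        lower_plateau = fit$lower_plateau, upper_plateau = fit$upper_plateau,
        inflection_vs_pka2 = abs(fit$inflection_ph - spec$base_group$pka))
      jsonlite::write_json(
        c(summary$cd, list(config_hash = hash)),
        file.path(config$out_dir, "sigmoid_fit.json"),
        auto_unbox = TRUE, digits = NA)
    }, error = function(e) fail("cd", e))
  }

  if ("chain" %in% stages) {
    tryCatch({
      ext <- build_extended_chain(config$n_units)
      coil <- make_coil(config$n_units, seed = config$seed)
      if (write_synth) {
        write_conformer_xyz(ext, file.path(config$out_dir, "chain_extended.xyz"))
        write_conformer_xyz(coil, file.path(config$out_dir, "chain_coil.xyz"))
      }
      dx <- describe_conformer(ext, config$probe_radius,
                               config$n_sphere_points,
                               config$transoid_threshold)
      dc <- describe_conformer(coil, config$probe_radius,
                               config$n_sphere_points,
                               config$transoid_threshold)
      tors <- data.frame(
        index = seq_along(dc$torsions),
        extended_deg = dx$torsions, coil_deg = dc$torsions,
        config_hash = hash)
      utils::write.csv(tors, file.path(config$out_dir, "torsions.csv"),
                       row.names = FALSE)
      strip <- function(d) d[c("end_to_end", "rg", "sasa",
                               "transoid_fraction")]
      summary$chain <- list(extended = strip(dx), coil = strip(dc))
    }, error = function(e) fail("chain", e))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
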