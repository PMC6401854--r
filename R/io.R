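# Plain-text I/O: titration CSVs, CD spectrum files with a YAML manifest,
# and tidy result tables.

#' Read a titration curve from CSV
#'
#' Expects columns \code{volume_mL} and \code{pH}; the experiment metadata
#' (titrant concentration/sign, repeat-unit moles, initial volume) comes
#' from the arguments or from a YAML configuration.
#'
#' @param file CSV path.
#' @param titrant_conc,titrant_sign,n_repeat_units,n_strong_acid_excess,volume0
#'   See \code{\link{titration_curve}}.
#' @return A \code{\link{titration_curve}}.
#' @export
read_titration_csv <- function(file, titrant_conc, titrant_sign = 1,
                               n_repeat_units,
                               n_strong_acid_excess = NA_real_,
                               volume0 = 25) {
  d <- utils::read.csv(file)
  need <- c("volume_mL", "pH")
  if (!all(need %in% names(d)))
    stop("titration CSV must have columns ", paste(need, collapse = ", "))
  titration_curve(d$volume_mL, d$pH, titrant_conc = titrant_conc,
                  titrant_sign = titrant_sign,
                  n_repeat_units = n_repeat_units,
                  n_strong_acid_excess = n_strong_acid_excess,
                  volume0 = volume0)
}

#' Write a titration curve to CSV
#'
#' @param curve A \code{\link{titration_curve}}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_titration_csv <- function(curve, file) {
  utils::write.csv(data.frame(volume_mL = curve$volumes, pH = curve$ph),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a pH series of CD spectra via a YAML manifest
#'
#' The manifest maps data files to recording conditions:
#' \preformatted{
#' path_length: 1
#' mass_conc: 0.5
#' spectra:
#'   - file: ph3.csv
#'     ph: 3.0
#'   - file: ph7.csv
#'     ph: 7.0
#' }
#' Each data file is a two-column CSV/whitespace table
#' \code{wavelength_nm,ellipticity_mdeg} (a header line is optional).
#'
#' @param manifest Path to the YAML manifest; relative data-file paths are
#'   resolved against its directory.
#' @return A list of raw \code{\link{cd_spectrum}} objects.
#' @export
read_cd_series <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  if (is.null(m$spectra)) stop("manifest has no 'spectra' entry")
  base <- dirname(manifest)
  lapply(m$spectra, function(s) {
    path <- s$file
    if (!file.exists(path)) path <- file.path(base, s$file)
    d <- read_two_column(path)
    cd_spectrum(d[[1]], d[[2]], ph = s$ph,
                path_length = m$path_length %||% 1,
                mass_conc = m$mass_conc %||% NA_real_,
                temperature = s$temperature %||% NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-column numeric table, comma- or whitespace-separated, optional header
read_two_column <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,\\s]+")[[1]][1])))
  utils::read.table(path, sep = sep, header = has_header)
}

#' Write a CD pH series and its YAML manifest
#'
#' @param spectra List of \code{\link{cd_spectrum}} objects.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, default \code{"cd"}.
#' @return The manifest path, invisibly.
#' @export
write_cd_series <- function(spectra, dir, prefix = "cd") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    fn <- sprintf("%s_ph%05.2f.csv", prefix, s$ph)
    utils::write.csv(data.frame(wavelength_nm = s$wavelengths,
                                ellipticity_mdeg = s$ellipticity),
                     file.path(dir, fn), row.names = FALSE)
    list(file = fn, ph = s$ph)
  })
  manifest <- file.path(dir, paste0(prefix, "_manifest.yaml"))
  yaml::write_yaml(list(path_length = spectra[[1]]$path_length,
                        mass_conc = spectra[[1]]$mass_conc,
                        spectra = entries), manifest)
  invisible(manifest)
}

#' Tidy table of apparent pKa along a titration
#'
#' Combines the two alpha series of \code{\link{compute_alpha}} with the
#' pointwise apparent pKa of \code{\link{apparent_pka}}.
#'
#' @param alpha Result of \code{\link{compute_alpha}}.
#' @return A data frame with columns \code{group}, \code{alpha}, \code{ph},
#'   \code{pka_apparent}.
#' @export
alpha_table <- function(alpha) {
  one <- function(series) {
    if (!nrow(series)) return(NULL)
    data.frame(group = attr(series, "group"), alpha = series$alpha,
               ph = series$ph,
               pka_apparent = apparent_pka(series$alpha, series$ph))
  }
  rbind(one(alpha$carboxyl), one(alpha$amine))
}
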