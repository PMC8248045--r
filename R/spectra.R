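## Filter spectra and standard weighting spectra ----------------------------
##
## Efficacy is computed from specific extinction spectra: E11(lambda) is the
## extinction a 1 wt% solution or dispersion of the filter would show at a
## 1 cm pathlength; its average over 290-400 nm, <E11>, is the single-number
## efficacy measure used in the filter registry.

.uv_grid <- function(step = 1) seq(290, 400, by = step)

#' Build a filter extinction spectrum
#'
#' @param substance Substance name.
#' @param wavelengths Strictly increasing wavelength grid (nm) covering
#'   at least 290-400 nm.
#' @param e11 Specific extinction at each wavelength (1 wt%, 1 cm); >= 0.
#' @param photostability_factor Static effective-concentration factor in
#'   (0, 1] accounting for photodegradation losses; default 1 (photostable).
#' @return An object of class `filter_spectrum`.
#' @export
filter_spectrum <- function(substance, wavelengths, e11, photostability_factor = 1) {
  stopifnot(length(wavelengths) == length(e11), length(wavelengths) >= 2)
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (min(wavelengths) > 290 || max(wavelengths) < 400) {
    stop("spectrum must cover 290-400 nm", call. = FALSE)
  }
  if (any(e11 < 0)) {
    stop("e11 must be non-negative", call. = FALSE)
  }
  if (photostability_factor <= 0 || photostability_factor > 1) {
    stop("photostability_factor must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(substance = substance, wavelengths = as.numeric(wavelengths),
         e11 = as.numeric(e11), photostability_factor = photostability_factor),
    class = "filter_spectrum"
  )
}

#' @export
print.filter_spectrum <- function(x, ...) {
  cat(sprintf("<filter_spectrum> %s: %d points, %g-%g nm, <E11> %.1f, photostability %.2f\n",
              x$substance, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), mean_e11(x), x$photostability_factor))
  invisible(x)
}

# linear interpolation of a spectrum onto a grid; outside the tabulated
# range the extinction is taken as 0
.e11_at <- function(spectrum, lambda) {
  stats::approx(spectrum$wavelengths, spectrum$e11, xout = lambda,
                rule = 1, yleft = 0, yright = 0)$y
}

#' Mean specific extinction over 290-400 nm
#'
#' Trapezoidal mean of E11 over the UV range: `<E11> = integral / 110`.
#'
#' @param spectrum A [filter_spectrum()].
#' @return The dimensionless `<E11>`.
#' @export
mean_e11 <- function(spectrum) {
  grid <- .uv_grid(0.5)
  vals <- .e11_at(spectrum, grid)
  pracma::trapz(grid, vals) / 110
}

#' Synthesize a Gaussian-band filter spectrum with a target mean extinction
#'
#' Builds an absorption spectrum as a sum of 1-3 Gaussian bands and rescales
#' it analytically so the trapezoidal mean over 290-400 nm equals
#' `target_mean_e11`. Used by the synthetic-data generator to emulate real
#' filter spectra whose `<E11>` values are known but whose full spectra are
#' not published.
#'
#' @param substance Substance name.
#' @param target_mean_e11 Desired `<E11>` (> 0).
#' @param centers Band centers in nm (within or near 290-400).
#' @param widths Band standard deviations in nm.
#' @param weights Relative band weights; default equal.
#' @param photostability_factor See [filter_spectrum()].
#' @param step Grid step in nm; default 1.
#' @return A [filter_spectrum()] whose [mean_e11()] equals the target.
#' @export
#' @examples
#' sp <- gaussian_filter_spectrum("demo", 400, centers = c(310, 350), widths = c(15, 20))
#' mean_e11(sp)
gaussian_filter_spectrum <- function(substance, target_mean_e11,
                                     centers = 330, widths = 20,
                                     weights = rep(1, length(centers)),
                                     photostability_factor = 1,
                                     step = 1) {
  stopifnot(target_mean_e11 > 0, length(centers) == length(widths),
            length(weights) == length(centers), all(widths > 0), all(weights > 0))
  grid <- .uv_grid(step)
  shape <- rowSums(vapply(seq_along(centers), function(i) {
    weights[i] * exp(-0.5 * ((grid - centers[i]) / widths[i])^2)
  }, numeric(length(grid))))
  raw_mean <- pracma::trapz(grid, shape) / 110
  filter_spectrum(substance, grid, shape * (target_mean_e11 / raw_mean),
                  photostability_factor = photostability_factor)
}

## Standard weighting spectra ----------------------------------------------

#' CIE erythema action spectrum
#'
#' The standard piecewise-exponential erythema reference action spectrum:
#' 1 below 298 nm, `10^(0.094 (298 - lambda))` for 298-328 nm and
#' `10^(0.015 (140 - lambda))` for 328-400 nm.
#'
#' @param lambda Wavelengths in nm.
#' @return Relative erythemal effectiveness (unitless, 0-1).
#' @export
erythema_action_spectrum <- function(lambda = .uv_grid()) {
  ifelse(lambda <= 298, 1,
         ifelse(lambda <= 328, 10^(0.094 * (298 - lambda)),
                10^(0.015 * (140 - lambda))))
}

#' Persistent-pigment-darkening (PPD) action spectrum (synthetic)
#'
#' A smooth analytic stand-in for the tabulated PPD action spectrum used in
#' UVA-PF determination: zero below 320 nm, then a gentle exponential
#' decline across the UVA range (about a factor 4 from 320 to 400 nm). The
#' exact standard tabulation is not reproduced; only the support (320-400
#' nm) and the qualitative decline matter for the ranking computed here.
#'
#' @param lambda Wavelengths in nm.
#' @return Relative PPD effectiveness (unitless).
#' @export
ppd_action_spectrum <- function(lambda = .uv_grid()) {
  ifelse(lambda < 320, 0, 10^(-(lambda - 320) / 133))
}

#' Midday midsummer solar source spectrum (synthetic)
#'
#' An analytic stand-in for a midday midsummer terrestrial solar spectral
#' irradiance: a logistic rise around the ozone absorption edge near 308 nm
#' and a gentle linear increase across the UVA. Relative units; only the
#' shape enters the SPF/UVA-PF ratios.
#'
#' @param lambda Wavelengths in nm.
#' @return Relative spectral irradiance (unitless).
#' @export
solar_source_spectrum <- function(lambda = .uv_grid()) {
  (1 / (1 + exp((308 - lambda) / 3.5))) * (0.4 + 0.6 * (lambda - 290) / 110)
}

## Spectrum file I/O --------------------------------------------------------

#' Read a two-column spectrum table
#'
#' Accepts whitespace- or comma-separated tables with columns wavelength_nm
#' and e11 (header optional for whitespace tables).
#'
#' @param path File path.
#' @param substance Substance name; default the file base name.
#' @param photostability_factor See [filter_spectrum()].
#' @return A [filter_spectrum()].
#' @export
read_spectrum <- function(path, substance = NULL,
                          photostability_factor = 1) {
  if (is.null(substance)) {
    substance <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1)
  if (grepl(",", first, fixed = TRUE)) {
    tab <- utils::read.csv(path)
  } else {
    tab <- utils::read.table(path, header = grepl("[A-Za-z]", first))
  }
  filter_spectrum(substance, tab[[1]], tab[[2]],
                  photostability_factor = photostability_factor)
}

#' Write a spectrum as a two-column CSV
#'
#' @param spectrum A [filter_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelengths, e11 = spectrum$e11),
    path, row.names = FALSE
  )
  invisible(path)
}
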