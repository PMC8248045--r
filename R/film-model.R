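## Film model and protection factors ----------------------------------------
##
## A sunscreen film on skin is not a uniform layer; its thickness
## irregularity dominates the gap between in-silico and measured SPF. The
## absorbance of the nominal (mean-thickness) layer follows Beer-Lambert:
##
##   A(lambda) = sum_k E11_k(lambda) * c_k[wt%] * p_k * d / d_ref
##
## with d the mean film thickness implied by the application rate (2 mg/cm2
## of product ~ 20 um ~ 0.002 cm at unit density) and d_ref = 1 cm, the
## pathlength in the definition of E11. The film model then averages the
## transmission 10^(-A h) over a distribution of relative thicknesses h with
## mean 1: a single step (homogeneous), a two-step profile (fraction f_j of
## the area at relative thickness h_j), or a gamma-distributed profile.

#' Define a film irregularity model
#'
#' The default is a two-step profile calibrated once so that a flat-spectrum
#' mono-filter with `<E11> = 271` at 7 wt% yields an SPF of about 15:
#' 40% of the skin area carries a thin film (relative thickness 0.205) and
#' 60% a thick one (1.53), preserving a mean relative thickness of 1.
#'
#' @param kind `"two_step"`, `"homogeneous"` or `"gamma"`.
#' @param fractions Area fractions of the steps (sum to 1); two-step only.
#' @param rel_thickness Relative thicknesses of the steps (>= 0, mean
#'   weighted by `fractions` conventionally 1); two-step only.
#' @param shape Gamma shape parameter k (> 0); the thickness distribution is
#'   Gamma(k, 1/k) with mean 1, giving the closed-form transmission
#'   `(1 + ln(10) A / k)^(-k)`.
#' @param application_mg_cm2 Product application rate; default 2 mg/cm2.
#' @param cm_per_mg_cm2 Film thickness per unit application rate; default
#'   1e-3 cm per mg/cm2 (unit product density).
#' @return An object of class `film_model`.
#' @export
film_model <- function(kind = c("two_step", "homogeneous", "gamma"),
                       fractions = c(0.4, 0.6),
                       rel_thickness = c(0.205, 1.53),
                       shape = 1,
                       application_mg_cm2 = 2,
                       cm_per_mg_cm2 = 1e-3) {
  kind <- match.arg(kind)
  if (kind == "two_step") {
    stopifnot(length(fractions) == length(rel_thickness),
              all(fractions > 0), all(rel_thickness >= 0))
    if (abs(sum(fractions) - 1) > 1e-9) {
      stop("step fractions must sum to 1", call. = FALSE)
    }
  }
  if (kind == "gamma") {
    stopifnot(shape > 0)
  }
  stopifnot(application_mg_cm2 > 0, cm_per_mg_cm2 > 0)
  structure(
    list(kind = kind, fractions = fractions, rel_thickness = rel_thickness,
         shape = shape, application_mg_cm2 = application_mg_cm2,
         cm_per_mg_cm2 = cm_per_mg_cm2),
    class = "film_model"
  )
}

#' @export
print.film_model <- function(x, ...) {
  cat(sprintf("<film_model> %s, %g mg/cm2\n", x$kind, x$application_mg_cm2))
  if (x$kind == "two_step") {
    cat(sprintf("  steps: f = %s at h = %s\n",
                paste(x$fractions, collapse = "/"),
                paste(x$rel_thickness, collapse = "/")))
  }
  if (x$kind == "gamma") {
    cat(sprintf("  gamma shape k = %g\n", x$shape))
  }
  invisible(x)
}

# mean-film absorbance of the formulation at the given wavelengths
.absorbance <- function(formulation, spectra, film, lambda) {
  comps <- formulation$components
  missing <- setdiff(comps$substance, names(spectra))
  if (length(missing) > 0) {
    stop("no spectrum for component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d_rel <- film$application_mg_cm2 * film$cm_per_mg_cm2  # pathlength / 1 cm
  a <- numeric(length(lambda))
  for (i in seq_len(nrow(comps))) {
    sp <- spectra[[comps$substance[i]]]
    a <- a + .e11_at(sp, lambda) * comps$concentration[i] *
      sp$photostability_factor * d_rel
  }
  a
}

# transmission of the film given mean-film absorbance values
.film_transmission <- function(a, film) {
  switch(film$kind,
    homogeneous = 10^(-a),
    two_step = {
      t <- numeric(length(a))
      for (j in seq_along(film$fractions)) {
        t <- t + film$fractions[j] * 10^(-a * film$rel_thickness[j])
      }
      t
    },
    gamma = (1 + log(10) * a / film$shape)^(-film$shape)
  )
}

#' UV transmission of a sunscreen film
#'
#' @param formulation A [formulation()].
#' @param spectra Named list of [filter_spectrum()] for every component.
#' @param film A [film_model()].
#' @param lambda Wavelengths in nm.
#' @return Transmitted fraction at each wavelength, in (0, 1].
#' @export
transmission <- function(formulation, spectra, film = film_model(),
                         lambda = .uv_grid()) {
  .film_transmission(.absorbance(formulation, spectra, film, lambda), film)
}

# generic weighted protection factor: ratio of action-weighted source dose
# without and with the film
.protection_factor <- function(formulation, spectra, film, lambda, source, action) {
  t <- transmission(formulation, spectra, film, lambda)
  w <- source * action
  pracma::trapz(lambda, w) / pracma::trapz(lambda, w * t)
}

#' Simulated sun protection factor
#'
#' `SPF = integral S(l) ser(l) dl / integral S(l) ser(l) T(l) dl` over
#' 290-400 nm, with S the solar source spectrum, ser the erythema action
#' spectrum and T the film transmission.
#'
#' @inheritParams transmission
#' @param source Source spectrum values on `lambda`; default
#'   [solar_source_spectrum()].
#' @param action Action spectrum values on `lambda`; default
#'   [erythema_action_spectrum()].
#' @param step Integration step in nm; default 1.
#' @return The simulated SPF (>= 1).
#' @export
spf <- function(formulation, spectra, film = film_model(),
                source = NULL, action = NULL, step = 1) {
  lambda <- .uv_grid(step)
  if (is.null(source)) source <- solar_source_spectrum(lambda)
  if (is.null(action)) action <- erythema_action_spectrum(lambda)
  .protection_factor(formulation, spectra, film, lambda, source, action)
}

#' Simulated UVA protection factor
#'
#' Same ratio as [spf()] with the PPD action spectrum, whose support is
#' restricted to 320-400 nm.
#'
#' @inheritParams spf
#' @return The simulated UVA-PF (>= 1).
#' @export
uva_pf <- function(formulation, spectra, film = film_model(),
                   source = NULL, action = NULL, step = 1) {
  lambda <- .uv_grid(step)
  if (is.null(source)) source <- solar_source_spectrum(lambda)
  if (is.null(action)) action <- ppd_action_spectrum(lambda)
  .protection_factor(formulation, spectra, film, lambda, source, action)
}
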