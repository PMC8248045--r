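## Formulation ranking ------------------------------------------------------
##
## A formulation's ecorank is the concentration-weighted sum of its filters'
## overall hazard scores; relating it to the theoretical maximum (every
## filter at the chapter-sum maximum of 7.0) gives the percent
## ecofriendliness a. Combining a with the simulated efficacy yields the
## ecofriendliness value  a * (SPF + UVA-PF) / c_total,  with > 200 as the
## pass threshold. One cut-off-failing component zeroes the whole value.

#' Build a sunscreen formulation
#'
#' @param name Formulation label.
#' @param components Data frame (or tibble) with columns `substance` and
#'   `concentration` (active-matter wt%; aqueous/dispersion grades must be
#'   entered as active matter). Two rows may name the same substance.
#' @param spf_class Nominal SPF class label, e.g. `"30"` or `"50"`.
#' @return An object of class `formulation`.
#' @export
#' @examples
#' formulation("demo", data.frame(
#'   substance = c("Ethylhexyl triazone", "Bemotrizinol"),
#'   concentration = c(2.5, 2.5)
#' ), spf_class = "30")
formulation <- function(name, components, spf_class = NA_character_) {
  stopifnot(is.character(name), length(name) == 1, is.data.frame(components),
            all(c("substance", "concentration") %in% names(components)))
  components <- tibble::as_tibble(components[, c("substance", "concentration")])
  if (nrow(components) == 0) {
    stop("formulation must contain at least one component", call. = FALSE)
  }
  if (any(is.na(components$concentration) | components$concentration <= 0)) {
    stop("all concentrations must be > 0 wt%", call. = FALSE)
  }
  if (sum(components$concentration) > 100) {
    stop("total UV filter concentration exceeds 100 wt%", call. = FALSE)
  }
  structure(
    list(name = name, components = components, spf_class = as.character(spf_class)),
    class = "formulation"
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation> %s (SPF class %s), %d component(s), %.1f wt%% total\n",
              x$name, ifelse(is.na(x$spf_class), "-", x$spf_class),
              nrow(x$components), sum(x$components$concentration)))
  print(x$components)
  invisible(x)
}

#' Total UV filter concentration of a formulation
#'
#' @param formulation A [formulation()].
#' @return Total concentration in wt%.
#' @export
total_concentration <- function(formulation) {
  sum(formulation$components$concentration)
}

#' Concentration-weighted ecorank of a formulation
#'
#' Each component's overall hazard score is multiplied by its concentration
#' in wt% and the products are summed. The theoretical maximum replaces every
#' score by the chapter-sum maximum (7.0 by default), i.e.
#' `max_ecorank = 7 * c_total`.
#'
#' @param formulation A [formulation()].
#' @param scores Named list or numeric vector mapping each substance to its
#'   overall hazard score (e.g. `overall_score(d)$overall`).
#' @param max_score Theoretical per-substance maximum; default 7.0.
#' @return A list with `ecorank` and `max_ecorank`.
#' @export
ecorank <- function(formulation, scores, max_score = 7.0) {
  if (is.list(scores)) {
    scores <- vapply(scores, function(s) {
      if (inherits(s, "hazard_score")) s$overall else as.numeric(s)
    }, numeric(1))
  }
  missing <- setdiff(formulation$components$substance, names(scores))
  if (length(missing) > 0) {
    stop("no hazard score for component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conc <- formulation$components$concentration
  sc <- scores[formulation$components$substance]
  list(ecorank = sum(sc * conc), max_ecorank = max_score * sum(conc))
}

#' Percent ecofriendliness of a formulation
#'
#' `a = (1 - ecorank / max_ecorank) * 100`: 100 when every filter carries the
#' minimum possible hazard burden per wt%, 0 when every filter sits at the
#' theoretical maximum.
#'
#' @param ecorank Concentration-weighted hazard sum.
#' @param max_ecorank Its theoretical maximum; must be > 0.
#' @return Percentage in \[0, 100\].
#' @export
ecofriendliness <- function(ecorank, max_ecorank) {
  if (!is.numeric(max_ecorank) || max_ecorank <= 0) {
    stop("max_ecorank must be > 0 (empty formulation?)", call. = FALSE)
  }
  a <- (1 - ecorank / max_ecorank) * 100
  stopifnot(a >= -1e-9, a <= 100 + 1e-9)
  min(max(a, 0), 100)
}

#' Ecofriendliness value of a formulation
#'
#' `a * (SPF + UVA-PF) / c_total`, rewarding formulations that achieve their
#' protection with little material of low hazard. A triggered cut-off zeroes
#' the value outright.
#'
#' @param a Percent ecofriendliness (0-100).
#' @param spf Sun protection factor (>= 1).
#' @param uva_pf UVA protection factor (>= 1).
#' @param c_total Total UV filter concentration in wt% (> 0).
#' @param cutoff_triggered Logical.
#' @return The ecofriendliness (ESP) value.
#' @export
esp_value <- function(a, spf, uva_pf, c_total, cutoff_triggered = FALSE) {
  if (!is.numeric(c_total) || c_total <= 0) {
    stop("c_total must be > 0", call. = FALSE)
  }
  stopifnot(spf >= 1, uva_pf >= 1, a >= 0, a <= 100)
  if (isTRUE(cutoff_triggered)) {
    return(0)
  }
  a * (spf + uva_pf) / c_total
}

#' Evaluate a formulation end to end
#'
#' Runs the cut-off criteria over every component (any failure zeroes the
#' result), scores the components under the requested case, computes
#' ecorank, percent ecofriendliness and the ecofriendliness value, and
#' applies the strict `> threshold` verdict.
#'
#' Efficacy can be supplied directly (`spf`, `uva_pf` — e.g. values from an
#' external simulator or a product label) or computed from filter spectra
#' (`spectra` plus an optional `film`), see [spf()] and [uva_pf()].
#'
#' @param formulation A [formulation()].
#' @param dossiers Named list of [substance_dossier()] covering every
#'   component.
#' @param profile Region profile or name; default `"EU"`.
#' @param case Which data-gap case feeds the scores: `"real"` (default),
#'   `"best"` or `"worst"`.
#' @param spf,uva_pf Protection factors, if supplied externally.
#' @param spectra Named list of [filter_spectrum()] (used when `spf` is
#'   `NULL`).
#' @param film A [film_model()]; default two-step.
#' @param threshold Ecofriendliness pass threshold; default 200.
#' @param max_score Theoretical per-substance score maximum; default 7.0.
#' @return An object of class `esp_result`.
#' @export
evaluate_formulation <- function(formulation, dossiers, profile = "EU",
                                 case = c("real", "best", "worst"),
                                 spf = NULL, uva_pf = NULL,
                                 spectra = NULL, film = film_model(),
                                 threshold = 200, max_score = 7.0) {
  case <- match.arg(case)
  comps <- unique(formulation$components$substance)
  missing <- setdiff(comps, names(dossiers))
  if (length(missing) > 0) {
    stop("no dossier for component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  verdicts <- lapply(dossiers[comps], evaluate_cutoff, profile = profile)
  cutoff_triggered <- any(vapply(verdicts, `[[`, logical(1), "failed"))
  cutoff_reasons <- unlist(lapply(verdicts, function(v) {
    if (v$failed) paste0(v$substance, ": ", paste(v$reasons, collapse = "+")) else character()
  }))

  scores <- vapply(dossiers[comps], function(d) overall_score(d, case)$overall, numeric(1))
  rk <- ecorank(formulation, scores, max_score = max_score)
  a <- ecofriendliness(rk$ecorank, rk$max_ecorank)

  if (is.null(spf) || is.null(uva_pf)) {
    if (is.null(spectra)) {
      stop("supply either spf and uva_pf or filter spectra", call. = FALSE)
    }
    spf <- spf(formulation, spectra, film = film)
    uva_pf <- uva_pf(formulation, spectra, film = film)
  }

  c_total <- total_concentration(formulation)
  esp <- esp_value(a, spf, uva_pf, c_total, cutoff_triggered = cutoff_triggered)
  structure(
    list(
      formulation = formulation$name,
      spf_class = formulation$spf_class,
      case = case,
      c_total = c_total,
      ecorank = rk$ecorank,
      max_ecorank = rk$max_ecorank,
      ecofriendliness_a = a,
      spf = spf,
      uva_pf = uva_pf,
      esp_value = esp,
      cutoff_triggered = cutoff_triggered,
      cutoff_reasons = cutoff_reasons,
      threshold = threshold,
      ecofriendly = esp > threshold
    ),
    class = "esp_result"
  )
}

#' @export
print.esp_result <- function(x, ...) {
  cat(sprintf("<esp_result> %s (%s case)\n", x$formulation, x$case))
  cat(sprintf("  c_total %.1f wt%% | a %.1f%% | SPF %.1f | UVA-PF %.1f\n",
              x$c_total, x$ecofriendliness_a, x$spf, x$uva_pf))
  cat(sprintf("  ecofriendliness value %.1f -> %s",
              x$esp_value, if (x$ecofriendly) "ecofriendly" else "not ecofriendly"))
  if (x$cutoff_triggered) {
    cat(sprintf(" [cut-off: %s]", paste(x$cutoff_reasons, collapse = "; ")))
  }
  cat("\n")
  invisible(x)
}

#' Tabulate evaluation results
#'
#' @param results A list of `esp_result` objects.
#' @return A tibble with one row per formulation.
#' @export
esp_result_table <- function(results) {
  tibble::tibble(
    formulation = vapply(results, `[[`, character(1), "formulation"),
    spf_class = vapply(results, `[[`, character(1), "spf_class"),
    c_total = vapply(results, `[[`, numeric(1), "c_total"),
    spf = vapply(results, `[[`, numeric(1), "spf"),
    uva_pf = vapply(results, `[[`, numeric(1), "uva_pf"),
    ecofriendliness_a = vapply(results, `[[`, numeric(1), "ecofriendliness_a"),
    esp_value = vapply(results, `[[`, numeric(1), "esp_value"),
    cutoff_triggered = vapply(results, `[[`, logical(1), "cutoff_triggered"),
    ecofriendly = vapply(results, `[[`, logical(1), "ecofriendly")
  )
}
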