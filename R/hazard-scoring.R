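## Chapter scoring ----------------------------------------------------------
##
## Each chapter is scored on a 0.25-step ladder: 0.25 (best environmental
## behaviour) up to 1.0 for the two fate chapters, and up to 1.25 for the
## four toxicity chapters (an extra +0.25 escalation for drivers one decade
## below the 1.0 band, capped there so the overall maximum stays 7.0).

# toxicity band edges, ascending; values below the first edge score the
# chapter maximum (1.25), values at/above the last edge score 0.25.
# acute aquatic is special-cased: 0.25 requires EC50 strictly above 100 mg/L.
.tox_breaks <- list(
  acute_aquatic   = c(0.1, 1, 10, 100),     # mg/L
  chronic_aquatic = c(0.01, 0.1, 1, 10),    # mg/L
  sediment        = c(1, 10, 100, 1000),    # mg/kg dw
  terrestrial     = c(1, 10, 100, 1000)     # mg/kg dw
)
.tox_scores <- c(1.25, 1.0, 0.75, 0.5, 0.25)

.chapter_max <- function(chapter) if (chapter %in% .tox_chapters) 1.25 else 1.0

.chapter_score <- function(chapter, score, basis) {
  list(chapter = chapter, score = score, basis = basis)
}

#' Score the biodegradation chapter
#'
#' Biodegradation categories map to fixed scores: readily biodegradable 0.25,
#' (inherently) biodegradable 0.5, partly biodegradable 0.75, poorly
#' biodegradable/persistent 1.0. Inorganic filters do not degrade, so the
#' chapter is scored at the persistent level (1.0) on a surrogate basis.
#'
#' @param class Biodegradation category, or `NA`.
#' @param is_inorganic Logical.
#' @return A list with `chapter`, `score`, `basis`.
#' @export
score_biodegradation <- function(class, is_inorganic = FALSE) {
  if (isTRUE(is_inorganic) || identical(class, "not_applicable")) {
    return(.chapter_score("biodegradation", 1.0, "surrogate"))
  }
  if (is.na(class)) {
    stop("missing biodegradation class for an organic substance; use resolve_chapter()",
         call. = FALSE)
  }
  score <- switch(class,
    readily = 0.25,
    biodegradable = 0.5,
    partly = 0.75,
    poor = 1.0,
    stop("unknown biodegradation class: ", class, call. = FALSE)
  )
  .chapter_score("biodegradation", score, "measured")
}

#' Score the bioaccumulation chapter
#'
#' With a measured bioconcentration factor: BCF < 500 scores 0.25,
#' 500-2000 scores 0.5, 2000-5000 scores 0.75 and >= 5000 scores 1.0.
#' Without a BCF, log Pow serves as a screening surrogate: < 4.5 is treated
#' as not bioaccumulative (0.25), >= 4.5 as bioaccumulative (0.75; the worst
#' case raises this to 1.0, see [resolve_chapter()]).
#'
#' @param bcf Bioconcentration factor, or `NA`.
#' @param log_pow Log Pow surrogate, or `NA`.
#' @return A list with `chapter`, `score`, `basis`.
#' @export
score_bioaccumulation <- function(bcf = NA_real_, log_pow = NA_real_) {
  if (!is.na(bcf)) {
    stopifnot(bcf > 0)
    score <- if (bcf < 500) 0.25 else if (bcf < 2000) 0.5 else if (bcf < 5000) 0.75 else 1.0
    return(.chapter_score("bioaccumulation", score, "measured"))
  }
  if (!is.na(log_pow)) {
    score <- if (log_pow < 4.5) 0.25 else 0.75
    return(.chapter_score("bioaccumulation", score, "surrogate"))
  }
  stop("neither BCF nor log Pow available; use resolve_chapter()", call. = FALSE)
}

#' Score a toxicity chapter from its driving endpoint
#'
#' Maps the most sensitive effect concentration through the chapter's band
#' ladder. Acute aquatic bands (EC50, mg/L): > 100 scores 0.25, 10-100
#' scores 0.5, 1-10 scores 0.75, 0.1-1 scores 1.0. Chronic aquatic bands
#' (NOEC/EC10, mg/L): >= 10 scores 0.25 down to 0.01-0.1 scoring 1.0.
#' Sediment and terrestrial bands (NOEC/EC10, mg/kg dw): >= 1000 scores 0.25
#' down to 1-10 scoring 1.0. A driver a further decade below the 1.0 band
#' escalates by +0.25 to the chapter maximum of 1.25. Tests showing no
#' effects up to the highest tested concentration (or the solubility limit)
#' take the lowest score, 0.25.
#'
#' @param value Driving effect concentration (mg/L or mg/kg dw).
#' @param chapter One of the four toxicity chapters.
#' @param no_effect_at_limit Logical; see above.
#' @return A list with `chapter`, `score`, `basis`.
#' @export
score_toxicity <- function(value, chapter, no_effect_at_limit = FALSE) {
  stopifnot(chapter %in% .tox_chapters)
  if (isTRUE(no_effect_at_limit)) {
    return(.chapter_score(chapter, 0.25, "measured"))
  }
  if (is.na(value) || value <= 0) {
    stop("toxicity driver value must be > 0", call. = FALSE)
  }
  breaks <- .tox_breaks[[chapter]]
  if (chapter == "acute_aquatic" && value <= breaks[4]) {
    # EC50 of exactly 100 mg/L falls in the 0.5 band; 0.25 needs > 100
    idx <- findInterval(value, breaks[1:3])
    score <- .tox_scores[idx + 1]
  } else {
    score <- .tox_scores[findInterval(value, breaks) + 1]
  }
  .chapter_score(chapter, score, "measured")
}

## Case resolution ----------------------------------------------------------

# adsorption/transfer screen: a readily biodegradable substance with low
# sorption potential is assumed not to reach sediment or soil
.low_transfer <- function(dossier) {
  low_koc <- is.na(dossier$log_koc) || dossier$log_koc < 3
  low_pow <- !is.na(dossier$log_pow) && dossier$log_pow < 4.5
  identical(dossier$biodegradation_class, "readily") && low_koc && low_pow
}

#' Resolve one chapter of a dossier under a best/real/worst case
#'
#' When a chapter has reliable measured data, all three cases return the
#' measured score. For a data gap the cases diverge: the best case fills with
#' the chapter minimum (0.25), the worst case with the chapter maximum (1.0
#' for fate, 1.25 for toxicity), and the real case uses screening logic —
#' log Pow as a bioaccumulation surrogate, and for sediment/terrestrial the
#' adsorption/biodegradation transfer screen (readily biodegradable plus
#' log Koc < 3 or absent plus log Pow < 4.5 excuses the missing data at
#' 0.25; otherwise the chapter maximum applies). Missing aquatic toxicity
#' data fill conservatively at the chapter maximum in the real case.
#'
#' @param dossier A [substance_dossier()].
#' @param chapter One chapter name.
#' @param case `"best"`, `"real"` or `"worst"`.
#' @return A list with `chapter`, `score`, `basis`.
#' @export
resolve_chapter <- function(dossier, chapter, case = c("real", "best", "worst")) {
  case <- match.arg(case)
  stopifnot(chapter %in% esp_chapters())
  records <- filter_reliable(dossier$records)

  if (chapter == "biodegradation") {
    if (dossier$is_inorganic) {
      return(score_biodegradation(NA_character_, is_inorganic = TRUE))
    }
    if (!is.na(dossier$biodegradation_class)) {
      return(score_biodegradation(dossier$biodegradation_class))
    }
    return(switch(case,
      best  = .chapter_score(chapter, 0.25, "best_case_fill"),
      real  = .chapter_score(chapter, 1.0, "worst_case_fill"),
      worst = .chapter_score(chapter, 1.0, "worst_case_fill")
    ))
  }

  if (chapter == "bioaccumulation") {
    driver <- select_driver(records, chapter)
    if (!is.null(driver)) {
      return(score_bioaccumulation(bcf = driver$numeric_value))
    }
    if (case == "best") {
      return(.chapter_score(chapter, 0.25, "best_case_fill"))
    }
    if (case == "worst") {
      return(.chapter_score(chapter, 1.0, "worst_case_fill"))
    }
    if (!is.na(dossier$log_pow)) {
      return(score_bioaccumulation(log_pow = dossier$log_pow))
    }
    return(.chapter_score(chapter, 1.0, "worst_case_fill"))
  }

  # toxicity chapters
  driver <- select_driver(records, chapter)
  if (!is.null(driver)) {
    return(score_toxicity(driver$numeric_value, chapter,
                          no_effect_at_limit = isTRUE(driver$no_effect_at_limit)))
  }
  if (case == "best") {
    return(.chapter_score(chapter, 0.25, "best_case_fill"))
  }
  if (case == "real" && chapter %in% c("sediment", "terrestrial") && .low_transfer(dossier)) {
    return(.chapter_score(chapter, 0.25, "surrogate"))
  }
  .chapter_score(chapter, 1.25, "worst_case_fill")
}

## Overall scores -----------------------------------------------------------

#' Overall environmental hazard score of a substance
#'
#' Sums the six resolved chapter scores. The attainable range is 1.5 (all
#' chapters at the 0.25 minimum; ecofriendly) to 7.0 (fate chapters at 1.0,
#' toxicity chapters at 1.25; hazardous).
#'
#' @param dossier A [substance_dossier()].
#' @param case `"best"`, `"real"` or `"worst"`.
#' @return An object of class `hazard_score`: list with `substance`,
#'   `chapters` (six-row tibble of chapter, score, basis), `overall`, `case`.
#' @export
overall_score <- function(dossier, case = c("real", "best", "worst")) {
  case <- match.arg(case)
  chapters <- lapply(esp_chapters(), function(ch) resolve_chapter(dossier, ch, case))
  tab <- tibble::tibble(
    chapter = vapply(chapters, `[[`, character(1), "chapter"),
    score = vapply(chapters, `[[`, numeric(1), "score"),
    basis = vapply(chapters, `[[`, character(1), "basis")
  )
  structure(
    list(substance = dossier$name, chapters = tab, overall = sum(tab$score), case = case),
    class = "hazard_score"
  )
}

#' @export
print.hazard_score <- function(x, ...) {
  cat(sprintf("<hazard_score> %s (%s case): overall %.2f\n", x$substance, x$case, x$overall))
  print(x$chapters)
  invisible(x)
}

#' Best/real/worst hazard score triple
#'
#' Computes the overall hazard score under all three data-gap assumptions.
#' The spread `worst - best` quantifies the uncertainty from missing data and
#' is zero exactly when every chapter is backed by measured evidence.
#'
#' @param dossier A [substance_dossier()].
#' @return An object of class `hazard_triple`: list with `best`, `real`,
#'   `worst` (each a `hazard_score`) and `substance`.
#' @export
hazard_triple <- function(dossier) {
  out <- structure(
    list(
      substance = dossier$name,
      best = overall_score(dossier, "best"),
      real = overall_score(dossier, "real"),
      worst = overall_score(dossier, "worst")
    ),
    class = "hazard_triple"
  )
  stopifnot(out$best$overall <= out$real$overall + 1e-12,
            out$real$overall <= out$worst$overall + 1e-12)
  out
}

#' @export
print.hazard_triple <- function(x, ...) {
  cat(sprintf("<hazard_triple> %s: best %.2f | real %.2f | worst %.2f\n",
              x$substance, x$best$overall, x$real$overall, x$worst$overall))
  invisible(x)
}

#' Tabulate hazard scores of many substances
#'
#' @param triples A list of [hazard_triple()] objects (or a named list of
#'   dossiers, which are scored first).
#' @param by_chapter If `TRUE`, return one row per substance, chapter and
#'   case; otherwise one row per substance with the three overall scores.
#' @return A tibble.
#' @export
hazard_score_table <- function(triples, by_chapter = FALSE) {
  if (length(triples) > 0 && inherits(triples[[1]], "substance_dossier")) {
    triples <- lapply(triples, hazard_triple)
  }
  if (by_chapter) {
    rows <- lapply(triples, function(tr) {
      dplyr::bind_rows(lapply(c("best", "real", "worst"), function(cs) {
        tab <- tr[[cs]]$chapters
        tab$substance <- tr$substance
        tab$case <- cs
        tab
      }))
    })
    out <- dplyr::bind_rows(rows)
    return(out[, c("substance", "chapter", "score", "basis", "case")])
  }
  tibble::tibble(
    substance = vapply(triples, `[[`, character(1), "substance"),
    best = vapply(triples, function(tr) tr$best$overall, numeric(1)),
    real = vapply(triples, function(tr) tr$real$overall, numeric(1)),
    worst = vapply(triples, function(tr) tr$worst$overall, numeric(1))
  )
}

#' Dot-and-range chart of hazard score triples
#'
#' Renders the per-substance overall hazard scores as a dot (real case) with
#' a best-worst uncertainty whisker, the conventional display for this kind
#' of screening assessment.
#'
#' @param triples List of [hazard_triple()] objects or named list of dossiers.
#' @return A ggplot object.
#' @export
plot_hazard_range <- function(triples) {
  tab <- hazard_score_table(triples)
  tab$substance <- stats::reorder(tab$substance, tab$real)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$substance, y = .data$real)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$best, ymax = .data$worst),
                            linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(1.25, 7.25),
                                breaks = seq(1.5, 7, by = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Overall environmental hazard score",
                  caption = "dot: real case; whisker: best-worst range") +
    ggplot2::theme_minimal()
}
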