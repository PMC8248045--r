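#' @keywords internal
"_PACKAGE"

## Shared vocabularies ------------------------------------------------------

#' Environmental assessment chapters
#'
#' The six environmental compartments/endpoints over which every UV filter is
#' assessed: biodegradation and bioaccumulation (environmental fate), plus
#' acute aquatic, chronic aquatic, sediment and chronic terrestrial toxicity.
#'
#' @return Character vector of the six chapter names.
#' @export
#' @examples
#' esp_chapters()
esp_chapters <- function() {
  c("biodegradation", "bioaccumulation", "acute_aquatic",
    "chronic_aquatic", "sediment", "terrestrial")
}

# chapters whose drivers are concentrations mapped through toxicity bands
.tox_chapters <- c("acute_aquatic", "chronic_aquatic", "sediment", "terrestrial")

.biodeg_classes <- c("readily", "biodegradable", "partly", "poor", "not_applicable")

.sources <- c("study", "authority", "literature", "qsar", "expert_judgement")

.cutoff_flags <- c("endocrine_disruptor", "pbt", "vpvb", "acute_toxic", "chronic_toxic")

# expected unit string per chapter (bioaccumulation records carry a BCF)
.chapter_units <- c(
  biodegradation  = "-",
  bioaccumulation = "-",
  acute_aquatic   = "mg/L",
  chronic_aquatic = "mg/L",
  sediment        = "mg/kg dw",
  terrestrial     = "mg/kg dw"
)

## Endpoint records ---------------------------------------------------------

#' Build a table of endpoint records
#'
#' An endpoint record is one piece of environmental evidence for a substance:
#' an effect concentration (EC50, NOEC, EC10 in mg/L or mg/kg dry weight), a
#' bioconcentration factor, or a categorical biodegradation result, together
#' with its Klimisch reliability code (1-4) and provenance.
#'
#' @param chapter Chapter of each record, one of [esp_chapters()].
#' @param numeric_value Positive effect concentration or BCF. `NA` only for
#'   categorical records.
#' @param endpoint_label Free-text endpoint description, e.g.
#'   `"EC50 algae 72h"`.
#' @param quality_code Klimisch reliability code, integer 1-4.
#' @param source Data provenance: `"study"`, `"authority"`, `"literature"`,
#'   `"qsar"` or `"expert_judgement"`.
#' @param value_kind `"numeric"` or `"categorical"`.
#' @param no_effect_at_limit Logical; `TRUE` when the test showed no effects up
#'   to the highest concentration tested (or the solubility limit), in which
#'   case `numeric_value` is that limit concentration.
#' @param unit Unit string; defaults to the chapter's canonical unit
#'   (`"mg/L"` aquatic, `"mg/kg dw"` sediment/soil, `"-"` for BCF).
#'
#' @return A tibble with one row per record and class `esp_records`.
#' @export
#' @examples
#' endpoint_records(
#'   chapter = c("acute_aquatic", "chronic_aquatic"),
#'   numeric_value = c(12, 0.8),
#'   endpoint_label = c("EC50 Daphnia 48h", "NOEC Daphnia 21d"),
#'   quality_code = c(1, 2),
#'   source = "study"
#' )
endpoint_records <- function(chapter, numeric_value, endpoint_label,
                             quality_code, source,
                             value_kind = "numeric",
                             no_effect_at_limit = FALSE,
                             unit = NULL) {
  out <- tibble::tibble(
    chapter = as.character(chapter),
    value_kind = as.character(value_kind),
    numeric_value = as.numeric(numeric_value),
    unit = if (is.null(unit)) unname(.chapter_units[as.character(chapter)]) else as.character(unit),
    endpoint_label = as.character(endpoint_label),
    quality_code = as.integer(quality_code),
    source = as.character(source),
    no_effect_at_limit = as.logical(no_effect_at_limit)
  )
  validate_records(out)
  class(out) <- c("esp_records", class(out))
  out
}

#' @keywords internal
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  bad <- setdiff(records$chapter, esp_chapters())
  if (length(bad) > 0) {
    stop("unknown chapter(s): ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!all(records$quality_code %in% 1:4)) {
    stop("quality_code must be an integer in 1..4", call. = FALSE)
  }
  if (!all(records$source %in% .sources)) {
    stop("source must be one of: ", paste(.sources, collapse = ", "), call. = FALSE)
  }
  num <- records$value_kind == "numeric"
  if (any(num & (is.na(records$numeric_value) | records$numeric_value <= 0))) {
    stop("numeric records require numeric_value > 0", call. = FALSE)
  }
  invisible(records)
}

#' Keep only reliable endpoint records
#'
#' Retains records with Klimisch reliability code 1 ("reliable without
#' restriction") or 2 ("reliable with restrictions"); codes 3-4 are
#' conventionally not used for regulatory conclusions. Order is preserved and
#' the input is not modified.
#'
#' @param records A record table from [endpoint_records()].
#' @return The subset of reliable records.
#' @export
filter_reliable <- function(records) {
  records[records$quality_code %in% c(1L, 2L), , drop = FALSE]
}

#' Select the driving (most sensitive) endpoint of a chapter
#'
#' Returns the record of `chapter` with the lowest effect value, reflecting
#' the hazard-assessment convention that the most sensitive reliable endpoint
#' drives the assessment. Ties are broken by source priority
#' (study > authority > literature > qsar > expert_judgement), then by
#' endpoint label, making the choice independent of input order.
#'
#' @param records A record table, already quality-filtered (see
#'   [filter_reliable()]).
#' @param chapter One chapter name.
#' @return A one-row tibble, or `NULL` when the chapter has no record.
#' @export
select_driver <- function(records, chapter) {
  stopifnot(chapter %in% esp_chapters())
  cand <- records[records$chapter == chapter & records$value_kind == "numeric", , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  pri <- match(cand$source, .sources)
  ord <- order(cand$numeric_value, pri, cand$endpoint_label, method = "radix")
  cand[ord[1], , drop = FALSE]
}

## Substance dossiers -------------------------------------------------------

#' Assemble a substance dossier
#'
#' A dossier holds all environmental evidence for one UV filter: its endpoint
#' records, screening surrogates (log Pow, log Koc), biodegradation category,
#' regulatory cut-off flags and the mean specific extinction `<E11>` used as
#' the efficacy measure.
#'
#' QSAR-derived records are only admitted for the bioaccumulation chapter
#' (QSAR estimation is considered adequate for partitioning/bioaccumulation
#' but not for chronic effect endpoints); QSAR records in other chapters are
#' dropped with a warning.
#'
#' @param name Substance name (INCI).
#' @param inci_abbreviation Short label, e.g. `"OCR"`.
#' @param records Endpoint record table, see [endpoint_records()]. May be
#'   empty.
#' @param is_inorganic Logical; inorganic (mineral) UV filters do not
#'   biodegrade and their biodegradation chapter is scored accordingly.
#' @param log_pow Log octanol-water partition coefficient, or `NA`.
#' @param log_koc Log organic carbon-water sorption coefficient, or `NA`.
#' @param biodegradation_class One of `"readily"`, `"biodegradable"`,
#'   `"partly"`, `"poor"`, `"not_applicable"`, or `NA` when unknown.
#' @param cutoff_flags Character subset of `"endocrine_disruptor"`, `"pbt"`,
#'   `"vpvb"`, `"acute_toxic"`, `"chronic_toxic"`.
#' @param mean_specific_extinction Mean specific extinction `<E11>` over
#'   290-400 nm (extinction of a 1 wt% preparation at 1 cm pathlength), or
#'   `NA`.
#'
#' @return An object of class `substance_dossier`.
#' @export
substance_dossier <- function(name,
                              inci_abbreviation = name,
                              records = endpoint_records(character(), numeric(),
                                                         character(), integer(),
                                                         character()),
                              is_inorganic = FALSE,
                              log_pow = NA_real_,
                              log_koc = NA_real_,
                              biodegradation_class = NA_character_,
                              cutoff_flags = character(),
                              mean_specific_extinction = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  validate_records(records)
  if (!is.na(biodegradation_class) && !biodegradation_class %in% .biodeg_classes) {
    stop("unknown biodegradation_class: ", biodegradation_class, call. = FALSE)
  }
  if (isTRUE(is_inorganic)) {
    if (!is.na(biodegradation_class) && biodegradation_class != "not_applicable") {
      stop("inorganic substances must have biodegradation_class 'not_applicable'",
           call. = FALSE)
    }
    biodegradation_class <- "not_applicable"
  }
  bad_flags <- setdiff(cutoff_flags, .cutoff_flags)
  if (length(bad_flags) > 0) {
    stop("unknown cutoff flag(s): ", paste(bad_flags, collapse = ", "), call. = FALSE)
  }
  if (!is.na(mean_specific_extinction) && mean_specific_extinction <= 0) {
    stop("mean_specific_extinction must be > 0", call. = FALSE)
  }
  # QSAR admissible for bioaccumulation only
  qsar_bad <- records$source == "qsar" & records$chapter != "bioaccumulation"
  if (any(qsar_bad)) {
    warning(sprintf("%s: dropping %d QSAR record(s) outside the bioaccumulation chapter",
                    name, sum(qsar_bad)), call. = FALSE)
    records <- records[!qsar_bad, , drop = FALSE]
  }
  structure(
    list(
      name = name,
      inci_abbreviation = inci_abbreviation,
      is_inorganic = isTRUE(is_inorganic),
      records = records,
      log_pow = as.numeric(log_pow),
      log_koc = as.numeric(log_koc),
      biodegradation_class = biodegradation_class,
      cutoff_flags = sort(unique(cutoff_flags)),
      mean_specific_extinction = as.numeric(mean_specific_extinction)
    ),
    class = "substance_dossier"
  )
}

#' @export
print.substance_dossier <- function(x, ...) {
  cat(sprintf("<substance_dossier> %s (%s)%s\n", x$name, x$inci_abbreviation,
              if (x$is_inorganic) " [inorganic]" else ""))
  cat(sprintf("  records: %d | log Pow: %s | log Koc: %s | biodegradation: %s\n",
              nrow(x$records),
              ifelse(is.na(x$log_pow), "-", format(x$log_pow)),
              ifelse(is.na(x$log_koc), "-", format(x$log_koc)),
              ifelse(is.na(x$biodegradation_class), "-", x$biodegradation_class)))
  if (length(x$cutoff_flags) > 0) {
    cat("  cut-off flags:", paste(x$cutoff_flags, collapse = ", "), "\n")
  }
  if (!is.na(x$mean_specific_extinction)) {
    cat(sprintf("  <E11>: %s\n", format(x$mean_specific_extinction)))
  }
  invisible(x)
}

#' Reliable driver value of a chapter, if any
#'
#' Convenience wrapper: quality-filters a dossier's records and returns the
#' most sensitive record of the chapter.
#'
#' @param dossier A [substance_dossier()].
#' @param chapter One chapter name.
#' @return One-row tibble or `NULL`.
#' @export
dossier_driver <- function(dossier, chapter) {
  select_driver(filter_reliable(dossier$records), chapter)
}
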