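## File input/output and run configuration ----------------------------------
##
## All interchange formats are plain text with explicit unit columns so a
## regulatory reviewer can audit every number: a records CSV (one endpoint
## per row), a substance master CSV (one substance per row), a formulation
## CSV or YAML, and two-column spectrum tables (see read_spectrum()).

.records_cols <- c("substance", "chapter", "value_kind", "numeric_value",
                   "unit", "endpoint_label", "quality_code", "source")

.master_cols <- c("name", "inci_abbreviation", "is_inorganic", "log_pow",
                  "log_koc", "biodegradation_class", "cutoff_flags",
                  "mean_specific_extinction")

# unit strings accepted per chapter
.unit_ok <- function(chapter, unit) {
  want <- .chapter_units[chapter]
  unit == want | (want == "-" & unit %in% c("", "-", "dimensionless"))
}

#' Read substance dossiers from a records CSV and a master CSV
#'
#' The records file has one endpoint per row (columns `substance`,
#' `chapter`, `value_kind`, `numeric_value`, `unit`, `endpoint_label`,
#' `quality_code`, `source`, optional `no_effect_at_limit`); units must be
#' `mg/L` for aquatic chapters, `mg/kg dw` for sediment/soil and
#' dimensionless (`-`) for BCF — any other unit string is rejected. The
#' master file has one substance per row (columns `name`,
#' `inci_abbreviation`, `is_inorganic`, `log_pow`, `log_koc`,
#' `biodegradation_class`, `cutoff_flags` semicolon-separated,
#' `mean_specific_extinction`).
#'
#' @param records_path Path to the records CSV (may be `NULL` for
#'   substances without endpoint records).
#' @param master_path Path to the substance master CSV.
#' @return Named list of [substance_dossier()].
#' @export
read_dossiers <- function(records_path, master_path) {
  master <- readr::read_csv(master_path, show_col_types = FALSE)
  missing_cols <- setdiff(.master_cols, names(master))
  if (length(missing_cols) > 0) {
    stop("master file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  recs <- NULL
  if (!is.null(records_path)) {
    recs <- readr::read_csv(records_path, show_col_types = FALSE)
    missing_cols <- setdiff(.records_cols, names(recs))
    if (length(missing_cols) > 0) {
      stop("records file lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    if (!"no_effect_at_limit" %in% names(recs)) {
      recs$no_effect_at_limit <- FALSE
    }
    bad <- !.unit_ok(recs$chapter, recs$unit)
    if (any(bad)) {
      stop(sprintf("invalid unit(s): %s (row %s)",
                   paste(unique(recs$unit[bad]), collapse = ", "),
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  out <- lapply(seq_len(nrow(master)), function(i) {
    m <- master[i, ]
    sub_recs <- if (is.null(recs)) NULL else recs[recs$substance == m$name, , drop = FALSE]
    records <- if (is.null(sub_recs) || nrow(sub_recs) == 0) {
      endpoint_records(character(), numeric(), character(), integer(), character())
    } else {
      endpoint_records(sub_recs$chapter, sub_recs$numeric_value,
                       sub_recs$endpoint_label, sub_recs$quality_code,
                       sub_recs$source, value_kind = sub_recs$value_kind,
                       no_effect_at_limit = sub_recs$no_effect_at_limit,
                       unit = sub_recs$unit)
    }
    flags <- if (is.na(m$cutoff_flags) || m$cutoff_flags == "") character()
             else strsplit(m$cutoff_flags, ";", fixed = TRUE)[[1]]
    substance_dossier(
      name = m$name,
      inci_abbreviation = m$inci_abbreviation,
      records = records,
      is_inorganic = isTRUE(as.logical(m$is_inorganic)),
      log_pow = m$log_pow,
      log_koc = m$log_koc,
      biodegradation_class = if (is.na(m$biodegradation_class)) NA_character_
                             else as.character(m$biodegradation_class),
      cutoff_flags = trimws(flags),
      mean_specific_extinction = m$mean_specific_extinction
    )
  })
  names(out) <- master$name
  out
}

#' Write substance dossiers to a records CSV and a master CSV
#'
#' Inverse of [read_dossiers()]; a written-then-read dossier set reproduces
#' the in-memory objects.
#'
#' @param dossiers Named list of [substance_dossier()].
#' @param records_path,master_path Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_dossiers <- function(dossiers, records_path, master_path) {
  rec_rows <- lapply(dossiers, function(d) {
    if (nrow(d$records) == 0) return(NULL)
    tab <- tibble::as_tibble(d$records)
    tab$substance <- d$name
    tab[, c(.records_cols, "no_effect_at_limit")]
  })
  recs <- dplyr::bind_rows(rec_rows)
  if (nrow(recs) == 0) {
    recs <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(.records_cols) + 1),
      c(.records_cols, "no_effect_at_limit")))
  }
  readr::write_csv(recs, records_path)
  master <- tibble::tibble(
    name = vapply(dossiers, `[[`, character(1), "name"),
    inci_abbreviation = vapply(dossiers, `[[`, character(1), "inci_abbreviation"),
    is_inorganic = vapply(dossiers, `[[`, logical(1), "is_inorganic"),
    log_pow = vapply(dossiers, `[[`, numeric(1), "log_pow"),
    log_koc = vapply(dossiers, `[[`, numeric(1), "log_koc"),
    biodegradation_class = vapply(dossiers, `[[`, character(1), "biodegradation_class"),
    cutoff_flags = vapply(dossiers, function(d) paste(d$cutoff_flags, collapse = ";"),
                          character(1)),
    mean_specific_extinction = vapply(dossiers, `[[`, numeric(1),
                                      "mean_specific_extinction")
  )
  readr::write_csv(master, master_path)
  invisible(list(records = records_path, master = master_path))
}

#' Read formulations from CSV or YAML
#'
#' CSV layout: columns `formulation`, `substance`, `concentration_wt_pct`,
#' optional `spf_class`. YAML layout: a list of formulations, each with
#' `name`, optional `spf_class`, and `components` as a substance-to-wt%
#' mapping or a list of `{substance, concentration}` entries.
#'
#' @param path Input path; format chosen by extension (`.yml`/`.yaml` vs
#'   anything else as CSV).
#' @return Named list of [formulation()].
#' @export
read_formulations <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    spec <- yaml::read_yaml(path)
    out <- lapply(spec, function(f) {
      comps <- f$components
      if (!is.null(names(comps)) && all(nzchar(names(comps)))) {
        df <- data.frame(substance = names(comps),
                         concentration = as.numeric(unlist(comps)))
      } else {
        df <- data.frame(
          substance = vapply(comps, `[[`, character(1), "substance"),
          concentration = vapply(comps, function(x) as.numeric(x$concentration),
                                 numeric(1)))
      }
      formulation(f$name, df, spf_class = f$spf_class %||% NA_character_)
    })
    names(out) <- vapply(out, `[[`, character(1), "name")
    return(out)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("formulation", "substance", "concentration_wt_pct")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("formulation file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$formulation), function(g) {
    formulation(g$formulation[1],
                data.frame(substance = g$substance,
                           concentration = g$concentration_wt_pct),
                spf_class = if ("spf_class" %in% names(g))
                  as.character(g$spf_class[1]) else NA_character_)
  })
  out[order(names(out))]
}

#' Write formulations to CSV
#'
#' @param formulations Named list of [formulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_formulations <- function(formulations, path) {
  rows <- lapply(formulations, function(f) {
    tibble::tibble(formulation = f$name,
                   substance = f$components$substance,
                   concentration_wt_pct = f$components$concentration,
                   spf_class = f$spf_class)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with any of: `region_profile` (name or full profile fields), `case`,
#' `esp_threshold`, `max_chapter_sum`, `film` (`kind`, `fractions`,
#' `rel_thickness`, `shape`, `application_mg_cm2`), `seed`, and input paths
#' (`dossier_records`, `dossier_master`, `formulations`, `spectra_dir`).
#' Missing fields take the package defaults.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  film_cfg <- cfg$film %||% list()
  film <- film_model(
    kind = film_cfg$kind %||% "two_step",
    fractions = as.numeric(film_cfg$fractions %||% c(0.4, 0.6)),
    rel_thickness = as.numeric(film_cfg$rel_thickness %||% c(0.205, 1.53)),
    shape = film_cfg$shape %||% 1,
    application_mg_cm2 = film_cfg$application_mg_cm2 %||% 2
  )
  profile <- cfg$region_profile %||% "EU"
  if (is.list(profile)) {
    profile <- region_profile(
      name = profile$name %||% "custom",
      ed_enabled = profile$ed_enabled %||% TRUE,
      pbt_enabled = profile$pbt_enabled %||% TRUE,
      vpvb_enabled = profile$vpvb_enabled %||% TRUE,
      acute_threshold_mg_l = profile$acute_threshold_mg_l %||% 0.1,
      chronic_threshold_mg_l = profile$chronic_threshold_mg_l %||% 0.01
    )
  }
  threshold <- cfg$esp_threshold %||% 200
  stopifnot(threshold > 0)
  structure(
    list(
      region_profile = profile,
      case = cfg$case %||% "real",
      esp_threshold = threshold,
      max_chapter_sum = cfg$max_chapter_sum %||% 7.0,
      film = film,
      seed = cfg$seed %||% 1L,
      paths = cfg[intersect(names(cfg), c("dossier_records", "dossier_master",
                                          "formulations", "spectra_dir"))]
    ),
    class = "run_config"
  )
}

#' Write evaluation results to CSV
#'
#' @param results List of `esp_result` objects, or an [esp_result_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esp_results <- function(results, path) {
  tab <- if (is.data.frame(results)) results else esp_result_table(results)
  readr::write_csv(tab, path)
  invisible(path)
}

#' Pretty-print an evaluation report
#'
#' One row per formulation: total concentration, SPF, UVA-PF, percent
#' ecofriendliness, ecofriendliness value, verdict and any triggered
#' cut-offs.
#'
#' @param results List of `esp_result` objects.
#' @return The result table, invisibly.
#' @export
esp_report <- function(results) {
  tab <- esp_result_table(results)
  cat(sprintf("%-12s %8s %6s %7s %7s %8s %8s  %s\n",
              "formulation", "c_total", "SPF", "UVA-PF", "a[%]", "value",
              "verdict", "cut-off"))
  for (r in results) {
    cat(sprintf("%-12s %7.1f%% %6.1f %7.1f %6.1f%% %8.1f %8s  %s\n",
                r$formulation, r$c_total, r$spf, r$uva_pf,
                r$ecofriendliness_a, r$esp_value,
                if (r$ecofriendly) "PASS" else "fail",
                if (r$cutoff_triggered) paste(r$cutoff_reasons, collapse = "; ") else "-"))
  }
  invisible(tab)
}
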