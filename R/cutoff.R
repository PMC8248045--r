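## Cut-off criteria ---------------------------------------------------------
##
## Regulatory exclusion rules that render a UV filter "not ecofriendly at
## all" regardless of its score: confirmed endocrine disruption, PBT or vPvB
## status, acute aquatic toxicity below 0.1 mg/L, or chronic aquatic toxicity
## below 0.01 mg/L. ED and PBT/vPvB criteria are EU concepts and can be
## disabled (or re-thresholded) in non-EU region profiles.

#' Define a region profile for the cut-off criteria
#'
#' @param name Profile name.
#' @param ed_enabled Apply the endocrine-disruptor criterion?
#' @param pbt_enabled Apply the PBT criterion?
#' @param vpvb_enabled Apply the vPvB criterion?
#' @param acute_threshold_mg_l Acute aquatic cut-off (EC/LC50, mg/L); a
#'   reliable driver strictly below this fails.
#' @param chronic_threshold_mg_l Chronic aquatic cut-off (NOEC/EC10, mg/L).
#' @return A list of class `region_profile`.
#' @export
#' @examples
#' region_profile("US-like", ed_enabled = FALSE)
region_profile <- function(name,
                           ed_enabled = TRUE,
                           pbt_enabled = TRUE,
                           vpvb_enabled = TRUE,
                           acute_threshold_mg_l = 0.1,
                           chronic_threshold_mg_l = 0.01) {
  stopifnot(is.character(name), length(name) == 1,
            acute_threshold_mg_l > 0, chronic_threshold_mg_l > 0)
  structure(
    list(name = name, ed_enabled = isTRUE(ed_enabled),
         pbt_enabled = isTRUE(pbt_enabled), vpvb_enabled = isTRUE(vpvb_enabled),
         acute_threshold_mg_l = acute_threshold_mg_l,
         chronic_threshold_mg_l = chronic_threshold_mg_l),
    class = "region_profile"
  )
}

# shipped defaults; "EU" applies all five criteria at the printed thresholds
.builtin_profiles <- function() {
  list(EU = region_profile("EU"))
}

#' Look up a region profile by name
#'
#' @param profile A `region_profile` object or the name of a shipped profile
#'   (currently `"EU"`).
#' @return A `region_profile`.
#' @export
get_region_profile <- function(profile) {
  if (inherits(profile, "region_profile")) {
    return(profile)
  }
  builtin <- .builtin_profiles()
  if (is.character(profile) && length(profile) == 1 && profile %in% names(builtin)) {
    return(builtin[[profile]])
  }
  stop("unknown region profile: ", paste(profile, collapse = ", "), call. = FALSE)
}

#' Evaluate the cut-off criteria for one substance
#'
#' A substance fails when any enabled flag (endocrine disruptor, PBT, vPvB)
#' is set on its dossier, when a flag asserts acute or chronic aquatic
#' toxicity, or when a reliable aquatic driver falls strictly below the
#' profile's acute (EC/LC50 < 0.1 mg/L) or chronic (NOEC/EC10 < 0.01 mg/L)
#' threshold. Values exactly at a threshold do not fail. Only
#' quality-filtered records (Klimisch 1-2) are considered, consistent with
#' the scoring module.
#'
#' @param dossier A [substance_dossier()].
#' @param profile A [region_profile()] or profile name; default `"EU"`.
#' @return A list of class `cutoff_verdict` with `substance`, `failed`,
#'   `reasons` and `region_profile`.
#' @export
evaluate_cutoff <- function(dossier, profile = "EU") {
  profile <- get_region_profile(profile)
  reasons <- character()
  flags <- dossier$cutoff_flags
  if (profile$ed_enabled && "endocrine_disruptor" %in% flags) {
    reasons <- c(reasons, "endocrine_disruptor")
  }
  if (profile$pbt_enabled && "pbt" %in% flags) {
    reasons <- c(reasons, "pbt")
  }
  if (profile$vpvb_enabled && "vpvb" %in% flags) {
    reasons <- c(reasons, "vpvb")
  }
  acute <- dossier_driver(dossier, "acute_aquatic")
  acute_flag <- "acute_toxic" %in% flags ||
    (!is.null(acute) && !isTRUE(acute$no_effect_at_limit) &&
       acute$numeric_value < profile$acute_threshold_mg_l)
  if (acute_flag) {
    reasons <- c(reasons, "acute_lt_0.1")
  }
  chronic <- dossier_driver(dossier, "chronic_aquatic")
  chronic_flag <- "chronic_toxic" %in% flags ||
    (!is.null(chronic) && !isTRUE(chronic$no_effect_at_limit) &&
       chronic$numeric_value < profile$chronic_threshold_mg_l)
  if (chronic_flag) {
    reasons <- c(reasons, "chronic_lt_0.01")
  }
  structure(
    list(substance = dossier$name, failed = length(reasons) > 0,
         reasons = reasons, region_profile = profile$name),
    class = "cutoff_verdict"
  )
}

#' @export
print.cutoff_verdict <- function(x, ...) {
  cat(sprintf("<cutoff_verdict> %s [%s]: %s%s\n", x$substance, x$region_profile,
              if (x$failed) "FAILED" else "passed",
              if (x$failed) paste0(" (", paste(x$reasons, collapse = ", "), ")") else ""))
  invisible(x)
}
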