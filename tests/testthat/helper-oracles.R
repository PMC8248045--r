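# Independent oracles, written as literal if-chains over the band ladders so
# the tests do not share code paths with the implementation.

oracle_tox_score <- function(value, chapter) {
  if (chapter == "acute_aquatic") {
    if (value > 100) return(0.25)
    if (value >= 10) return(0.5)   # 10 <= EC50 <= 100
    if (value >= 1) return(0.75)
    if (value >= 0.1) return(1.0)
    return(1.25)
  }
  if (chapter == "chronic_aquatic") {
    if (value >= 10) return(0.25)
    if (value >= 1) return(0.5)
    if (value >= 0.1) return(0.75)
    if (value >= 0.01) return(1.0)
    return(1.25)
  }
  # sediment / terrestrial, mg/kg dw
  if (value >= 1000) return(0.25)
  if (value >= 100) return(0.5)
  if (value >= 10) return(0.75)
  if (value >= 1) return(1.0)
  1.25
}

oracle_bcf_score <- function(bcf) {
  if (bcf < 500) return(0.25)
  if (bcf < 2000) return(0.5)
  if (bcf < 5000) return(0.75)
  1.0
}

# exhaustive-scan driver selection under the stated tie order
oracle_driver <- function(records, chapter) {
  cand <- records[records$chapter == chapter & records$value_kind == "numeric", ]
  if (nrow(cand) == 0) return(NULL)
  src_rank <- match(cand$source,
                    c("study", "authority", "literature", "qsar", "expert_judgement"))
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    if (is.null(best)) { best <- i; next }
    if (cand$numeric_value[i] < cand$numeric_value[best]) { best <- i; next }
    if (cand$numeric_value[i] == cand$numeric_value[best]) {
      if (src_rank[i] < src_rank[best]) { best <- i; next }
      if (src_rank[i] == src_rank[best] &&
          cand$endpoint_label[i] < cand$endpoint_label[best]) { best <- i }
    }
  }
  cand[best, ]
}

random_records <- function(n, chapters = esp_chapters()[-1], seed = NULL) {
  sources <- c("study", "authority", "literature", "qsar", "expert_judgement")
  gen <- function() {
    ch <- sample(chapters, n, replace = TRUE)
    endpoint_records(
      chapter = ch,
      numeric_value = round(10^stats::runif(n, -3, 4), 4),
      endpoint_label = sample(sprintf("endpoint %02d", 1:20), n, replace = TRUE),
      quality_code = sample(1:4, n, replace = TRUE),
      source = sample(sources, n, replace = TRUE)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
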