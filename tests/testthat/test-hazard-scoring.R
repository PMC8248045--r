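test_that("biodegradation categories map to their scores", {
  expect_equal(score_biodegradation("readily")$score, 0.25)
  expect_equal(score_biodegradation("biodegradable")$score, 0.5)
  expect_equal(score_biodegradation("partly")$score, 0.75)
  expect_equal(score_biodegradation("poor")$score, 1.0)
  inorg <- score_biodegradation(NA_character_, is_inorganic = TRUE)
  expect_equal(inorg$score, 1.0)
  expect_equal(inorg$basis, "surrogate")
  expect_error(score_biodegradation(NA_character_), "missing")
})

test_that("bioaccumulation bands and the log Pow surrogate", {
  expect_equal(score_bioaccumulation(bcf = 300)$score, 0.25)
  expect_equal(score_bioaccumulation(bcf = 500)$score, 0.5)
  expect_equal(score_bioaccumulation(bcf = 1999)$score, 0.5)
  expect_equal(score_bioaccumulation(bcf = 2000)$score, 0.75)
  expect_equal(score_bioaccumulation(bcf = 5000)$score, 1.0)
  sur <- score_bioaccumulation(log_pow = 5.1)
  expect_equal(sur$score, 0.75)
  expect_equal(sur$basis, "surrogate")
  expect_equal(score_bioaccumulation(log_pow = 2)$score, 0.25)
  expect_error(score_bioaccumulation(), "neither")
})

test_that("toxicity band mapping matches the printed ladder and handles edges", {
  # acute aquatic (EC50, mg/L)
  expect_equal(score_toxicity(150, "acute_aquatic")$score, 0.25)
  expect_equal(score_toxicity(100, "acute_aquatic")$score, 0.5)
  expect_equal(score_toxicity(10, "acute_aquatic")$score, 0.5)
  expect_equal(score_toxicity(1, "acute_aquatic")$score, 0.75)
  expect_equal(score_toxicity(0.1, "acute_aquatic")$score, 1.0)
  expect_equal(score_toxicity(0.05, "acute_aquatic")$score, 1.25)
  # chronic aquatic (NOEC/EC10, mg/L)
  expect_equal(score_toxicity(10, "chronic_aquatic")$score, 0.25)
  expect_equal(score_toxicity(0.05, "chronic_aquatic")$score, 1.0)
  expect_equal(score_toxicity(0.005, "chronic_aquatic")$score, 1.25)
  # solids (NOEC/EC10, mg/kg dw)
  expect_equal(score_toxicity(1000, "terrestrial")$score, 0.25)
  expect_equal(score_toxicity(0.5, "sediment")$score, 1.25)
  # no-effect tests at the limit take the lowest score
  expect_equal(score_toxicity(100, "acute_aquatic", no_effect_at_limit = TRUE)$score,
               0.25)
  expect_error(score_toxicity(-1, "acute_aquatic"), "> 0")
  expect_error(score_toxicity(0, "chronic_aquatic"), "> 0")
})

test_that("band mapping agrees with a brute-force oracle on random drivers", {
  withr::with_seed(7, {
    for (ch in c("acute_aquatic", "chronic_aquatic", "sediment", "terrestrial")) {
      vals <- 10^stats::runif(1000, -4, 5)
      got <- vapply(vals, function(v) score_toxicity(v, ch)$score, numeric(1))
      want <- vapply(vals, oracle_tox_score, numeric(1), chapter = ch)
      expect_equal(got, want)
    }
    bcfs <- 10^stats::runif(1000, 0, 5)
    got <- vapply(bcfs, function(b) score_bioaccumulation(bcf = b)$score, numeric(1))
    expect_equal(got, vapply(bcfs, oracle_bcf_score, numeric(1)))
  })
})

test_that("chapter scores are 0.25-multiples within their chapter range and monotone", {
  withr::with_seed(8, {
    for (ch in c("acute_aquatic", "chronic_aquatic", "sediment", "terrestrial")) {
      vals <- sort(10^stats::runif(200, -4, 5), decreasing = TRUE)
      sc <- vapply(vals, function(v) score_toxicity(v, ch)$score, numeric(1))
      expect_true(all(sc %in% seq(0.25, 1.25, by = 0.25)))
      # decreasing driver value (more toxic) never decreases the score
      expect_true(all(diff(sc) >= 0))
    }
    bcfs <- sort(10^stats::runif(200, 0, 5))
    sc <- vapply(bcfs, function(b) score_bioaccumulation(bcf = b)$score, numeric(1))
    expect_true(all(sc %in% c(0.25, 0.5, 0.75, 1.0)))
    expect_true(all(diff(sc) >= 0))
  })
})

test_that("data gaps resolve by case: best fill, worst fill, real screening", {
  # missing sediment data, readily biodegradable, low log Pow -> screen passes
  clean <- substance_dossier("clean", biodegradation_class = "readily",
                             log_pow = 2)
  expect_equal(resolve_chapter(clean, "sediment", "real")$score, 0.25)
  expect_equal(resolve_chapter(clean, "sediment", "best")$score, 0.25)
  expect_equal(resolve_chapter(clean, "sediment", "worst")$score, 1.25)

  # poorly biodegradable, high log Pow -> worst-case fill in the real case
  dirty <- substance_dossier("dirty", biodegradation_class = "poor", log_pow = 6)
  expect_equal(resolve_chapter(dirty, "sediment", "real")$score, 1.25)
  expect_equal(resolve_chapter(dirty, "terrestrial", "real")$score, 1.25)

  # high log Koc alone breaks the screen even for a readily degradable substance
  sorbing <- substance_dossier("sorbing", biodegradation_class = "readily",
                               log_pow = 2, log_koc = 4.2)
  expect_equal(resolve_chapter(sorbing, "terrestrial", "real")$score, 1.25)

  # missing aquatic chapters fill conservatively in the real case
  blank <- substance_dossier("blank")
  expect_equal(resolve_chapter(blank, "acute_aquatic", "real")$score, 1.25)
  expect_equal(resolve_chapter(blank, "acute_aquatic", "best")$score, 0.25)
  expect_equal(resolve_chapter(blank, "bioaccumulation", "real")$score, 1.0)
  expect_equal(resolve_chapter(blank, "bioaccumulation", "worst")$score, 1.0)

  # log Pow surrogate feeds the real case but not the worst case
  greasy <- substance_dossier("greasy", log_pow = 5)
  expect_equal(resolve_chapter(greasy, "bioaccumulation", "real")$score, 0.75)
  expect_equal(resolve_chapter(greasy, "bioaccumulation", "worst")$score, 1.0)

  # a measured chapter is identical in all three cases
  measured <- substance_dossier("m", records = endpoint_records(
    "acute_aquatic", 50, "EC50 fish", 1, "study"))
  for (cs in c("best", "real", "worst")) {
    res <- resolve_chapter(measured, "acute_aquatic", cs)
    expect_equal(res$score, 0.5)
    expect_equal(res$basis, "measured")
  }
})

test_that("an expert-judgement record overrides the conservative fill", {
  d <- substance_dossier("ej", records = endpoint_records(
    "chronic_aquatic", 20, "NOEC weight-of-evidence", 2, "expert_judgement"))
  expect_equal(resolve_chapter(d, "chronic_aquatic", "real")$score, 0.25)
})

test_that("overall score sums six chapters and spans exactly [1.5, 7.0]", {
  best <- dossier_from_chapter_scores("best", 0.25, 0.25, 0.25, 0.25, 0.25, 0.25)
  expect_equal(overall_score(best)$overall, 1.5)
  worst <- dossier_from_chapter_scores("worst", 1.0, 1.0, 1.25, 1.25, 1.25, 1.25,
                                       chronic_aquatic = 1.25)
  expect_equal(overall_score(worst)$overall, 7.0)

  # summation oracle on random dossiers
  for (d in generate_dossiers(20, completeness = 0.6, seed = 3)) {
    hs <- overall_score(d, "real")
    expect_equal(hs$overall, sum(hs$chapters$score))
    expect_gte(hs$overall, 1.5)
    expect_lte(hs$overall, 7.0)
  }
})

test_that("best <= real <= worst for fuzzed dossiers, equal iff fully measured", {
  complete <- dossier_from_chapter_scores("c", 0.5, 0.5, 0.75, 0.5, 0.5, 0.25)
  tr <- hazard_triple(complete)
  expect_equal(tr$best$overall, tr$worst$overall)

  # only one acute record (EC50 > 100): best 1.5, worst fills the other five
  sparse <- substance_dossier("s", records = endpoint_records(
    "acute_aquatic", 150, "EC50 fish", 1, "study"))
  tr <- hazard_triple(sparse)
  expect_equal(tr$best$overall, 1.5)
  expect_equal(tr$worst$overall, 0.25 + 1.0 + 1.0 + 1.25 + 1.25 + 1.25)

  for (d in generate_dossiers(40, completeness = 0.5, seed = 11)) {
    tr <- hazard_triple(d)
    expect_lte(tr$best$overall, tr$real$overall)
    expect_lte(tr$real$overall, tr$worst$overall)
  }
})

test_that("adding a measured chapter never widens the best-worst spread", {
  for (seed in 1:10) {
    d <- generate_dossiers(1, completeness = 0.3, seed = seed)[[1]]
    tr0 <- hazard_triple(d)
    spread0 <- tr0$worst$overall - tr0$best$overall
    # measure one previously missing toxicity chapter
    missing <- setdiff(c("acute_aquatic", "chronic_aquatic", "sediment", "terrestrial"),
                       unique(filter_reliable(d$records)$chapter))
    if (length(missing) == 0) next
    d2 <- d
    extra <- endpoint_records(missing[1], 5, "new study", 1, "study")
    d2$records <- rbind(d$records, extra)
    tr2 <- hazard_triple(d2)
    expect_lte(tr2$worst$overall - tr2$best$overall, spread0)
  }
})
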