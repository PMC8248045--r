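test_that("ecorank is the concentration-weighted score sum with a 7x maximum", {
  f <- formulation("one", data.frame(substance = "A", concentration = 10))
  expect_equal(ecorank(f, c(A = 7.0)), list(ecorank = 70, max_ecorank = 70))
  expect_equal(ecorank(f, c(A = 1.5)), list(ecorank = 15, max_ecorank = 70))
  expect_error(ecorank(f, c(B = 2)), "no hazard score")

  # summation oracle on random five-component formulations
  withr::with_seed(9, {
    for (i in 1:10) {
      subs <- paste0("S", 1:5)
      conc <- round(stats::runif(5, 0.5, 10), 2)
      sc <- stats::setNames(round(stats::runif(5, 1.5, 7), 2), subs)
      f <- formulation("rnd", data.frame(substance = subs, concentration = conc))
      rk <- ecorank(f, sc)
      expect_equal(rk$ecorank, sum(sc * conc))
      expect_equal(rk$max_ecorank, 7 * sum(conc))
    }
  })
})

test_that("percent ecofriendliness follows the defining identity", {
  expect_equal(ecofriendliness(70, 70), 0)
  expect_equal(ecofriendliness(0, 70), 100)
  expect_equal(ecofriendliness(15, 70), (1 - 15 / 70) * 100)
  expect_error(ecofriendliness(1, 0), "max_ecorank")

  # with all scores equal to q, a = (1 - q/7) * 100 independent of composition
  withr::with_seed(10, {
    for (q in c(1.5, 3, 5.25, 7)) {
      n <- sample(2:6, 1)
      conc <- stats::runif(n, 0.5, 8)
      f <- formulation("q", data.frame(substance = paste0("S", 1:n),
                                       concentration = conc))
      sc <- stats::setNames(rep(q, n), paste0("S", 1:n))
      rk <- ecorank(f, sc)
      expect_equal(ecofriendliness(rk$ecorank, rk$max_ecorank), (1 - q / 7) * 100)
    }
  })
})

test_that("the ecofriendliness value combines a, efficacy and concentration", {
  expect_equal(esp_value(100, 30, 10, 10), 400)
  expect_equal(esp_value(100, 30, 10, 10, cutoff_triggered = TRUE), 0)
  expect_error(esp_value(50, 30, 10, 0), "c_total")
  # back-solved from the published SPF-30 example 5 print-out
  expect_equal(esp_value(54.86, 31.5, 24.1, 12.5), 244.0, tolerance = 0.5 / 244)
})

test_that("a is invariant to splitting a component and ESP scales correctly", {
  sc <- c(A = 3, B = 5)
  whole <- formulation("w", data.frame(substance = c("A", "B"),
                                       concentration = c(6, 4)))
  split <- formulation("s", data.frame(substance = c("A", "A", "B"),
                                       concentration = c(2, 4, 4)))
  rw <- ecorank(whole, sc)
  rs <- ecorank(split, sc)
  expect_equal(ecofriendliness(rw$ecorank, rw$max_ecorank),
               ecofriendliness(rs$ecorank, rs$max_ecorank))

  # scaling all concentrations by s leaves a unchanged and divides the
  # efficacy term by the scaled total
  s <- 2.5
  scaled <- formulation("x", data.frame(substance = c("A", "B"),
                                        concentration = s * c(6, 4)))
  rsc <- ecorank(scaled, sc)
  a <- ecofriendliness(rw$ecorank, rw$max_ecorank)
  expect_equal(ecofriendliness(rsc$ecorank, rsc$max_ecorank), a)
  spf2 <- 12; uva2 <- 4  # efficacy recomputed at the higher load
  expect_equal(esp_value(a, spf2, uva2, total_concentration(scaled)),
               a * (spf2 + uva2) / (s * 10))
})

test_that("lowering any component's score strictly raises a and ESP", {
  f <- formulation("f", data.frame(substance = c("A", "B", "C"),
                                   concentration = c(3, 5, 2)))
  sc <- c(A = 4, B = 5, C = 6)
  base <- ecorank(f, sc)
  a0 <- ecofriendliness(base$ecorank, base$max_ecorank)
  for (nm in names(sc)) {
    sc2 <- sc
    sc2[nm] <- sc2[nm] - 1
    rk <- ecorank(f, sc2)
    a1 <- ecofriendliness(rk$ecorank, rk$max_ecorank)
    expect_gt(a1, a0)
    expect_gt(esp_value(a1, 30, 10, 10), esp_value(a0, 30, 10, 10))
  }
})

test_that("formulation evaluation applies the cut-off and the strict threshold", {
  dossiers <- reference_dossiers()
  forms <- reference_formulations()
  # the octocrylene-containing worked example zeroes out
  r <- evaluate_formulation(forms$spf30_ex1, dossiers, spf = 30.4, uva_pf = 10.5)
  expect_equal(r$esp_value, 0)
  expect_false(r$ecofriendly)
  expect_true(r$cutoff_triggered)
  expect_match(r$cutoff_reasons, "OCR")

  # a value exactly at the threshold is not ecofriendly
  one <- substance_dossier("pure", biodegradation_class = "readily", log_pow = 1,
                           records = endpoint_records(
                             rep(c("acute_aquatic", "chronic_aquatic"), 1),
                             c(200, 20), c("EC50", "NOEC"), 1, "study",
                             no_effect_at_limit = TRUE))
  f1 <- formulation("edge", data.frame(substance = "pure", concentration = 10))
  a <- evaluate_formulation(f1, list(pure = one), spf = 15, uva_pf = 5)
  # score: 0.25*4 (biodeg, acute, chronic, sediment/terr screens) + bioacc 0.25 = 1.5
  expect_equal(a$ecofriendliness_a, (1 - 1.5 / 7) * 100)
  thr <- a$ecofriendliness_a * 20 / 10  # with spf+uva = 2*c, esp equals 2a
  r2 <- evaluate_formulation(f1, list(pure = one), spf = 10, uva_pf = 10,
                             threshold = thr)
  expect_equal(r2$esp_value, thr)
  expect_false(r2$ecofriendly)

  # a best-case filter with spf + uva_pf = 2.55 * c_total clears 200
  r3 <- evaluate_formulation(f1, list(pure = one), spf = 15.5, uva_pf = 10)
  expect_equal(r3$esp_value, (1 - 1.5 / 7) * 100 * 25.5 / 10, tolerance = 1e-12)
  expect_true(r3$ecofriendly)

  expect_error(evaluate_formulation(f1, list(), spf = 10, uva_pf = 5),
               "no dossier")
  expect_error(formulation("empty", data.frame(substance = character(),
                                               concentration = numeric())),
               "at least one")
})
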