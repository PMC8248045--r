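flat_spectrum <- function(name, e11, ps = 1) {
  filter_spectrum(name, c(290, 400), c(e11, e11), photostability_factor = ps)
}

mono <- function(conc, name = "A") {
  formulation("mono", data.frame(substance = name, concentration = conc))
}

test_that("mean specific extinction is the trapezoidal mean over 290-400 nm", {
  expect_equal(mean_e11(flat_spectrum("c", 400)), 400)

  # triangular peak: closed-form area (base * height / 2) over the 110 nm span
  tri <- filter_spectrum("t", c(290, 320, 340, 360, 400), c(0, 0, 500, 0, 0))
  expect_equal(mean_e11(tri), (40 * 500 / 2) / 110)

  # synthetic generator hits its target by construction
  sp <- gaussian_filter_spectrum("g", 527, centers = c(310, 352),
                                 widths = c(16, 24))
  expect_equal(mean_e11(sp), 527, tolerance = 1e-9)

  expect_error(filter_spectrum("bad", c(300, 400), c(1, 1)), "290-400")
  expect_error(filter_spectrum("bad", c(290, 400), c(-1, 1)), "non-negative")
})

test_that("film transmission follows the step and gamma formulas", {
  # no filters -> T = 1 everywhere (zero absorbance)
  none <- mono(1e-12)
  sp0 <- list(A = flat_spectrum("A", 1e-9))
  expect_equal(transmission(none, sp0, film_model("homogeneous")),
               rep(1, 111), tolerance = 1e-9)

  # homogeneous Beer-Lambert: A = 1 -> T = 0.1
  # flat E11 = 500 at 1 wt% and 2 mg/cm2 gives A = 500 * 1 * 0.002 = 1
  f <- mono(1)
  sp <- list(A = flat_spectrum("A", 500))
  expect_equal(transmission(f, sp, film_model("homogeneous")),
               rep(0.1, 111))

  # two-step film f = 0.5/0.5 at h = 0/2: T = 0.5 + 0.5 * 10^-2
  two <- film_model("two_step", fractions = c(0.5, 0.5), rel_thickness = c(0, 2))
  expect_equal(transmission(f, sp, two), rep(0.505, 111))

  # gamma closed form (1 + ln10 * A / k)^-k
  g <- film_model("gamma", shape = 2)
  expect_equal(transmission(f, sp, g), rep((1 + log(10) / 2)^-2, 111))

  expect_error(transmission(f, list(), film_model()), "no spectrum")
  expect_error(film_model("two_step", fractions = c(0.5, 0.4)), "sum to 1")
})

test_that("constant transmission gives the trivial protection factors", {
  none <- mono(1e-12)
  sp0 <- list(A = flat_spectrum("A", 1e-9))
  expect_equal(spf(none, sp0), 1, tolerance = 1e-6)
  expect_equal(uva_pf(none, sp0), 1, tolerance = 1e-6)

  # T = 0.1 uniformly -> SPF = 10; T = 0.5 -> UVA-PF = 2
  f1 <- mono(1)
  sp <- list(A = flat_spectrum("A", 500))
  expect_equal(spf(f1, sp, film_model("homogeneous")), 10)
  half <- mono(log10(2) / (500 * 0.002))
  expect_equal(uva_pf(half, sp, film_model("homogeneous")), 2)
})

test_that("homogeneous-film SPF obeys the closed form 10^(E c d)", {
  for (pars in list(c(E = 271, c = 7), c(E = 100, c = 2), c(E = 50, c = 12))) {
    f <- mono(pars[["c"]])
    sp <- list(A = flat_spectrum("A", pars[["E"]]))
    expect_equal(spf(f, sp, film_model("homogeneous")),
                 10^(pars[["E"]] * pars[["c"]] * 0.002),
                 tolerance = 1e-9)
  }
})

test_that("a filter absorbing only below 320 nm leaves UVA-PF at exactly 1", {
  uvb_only <- filter_spectrum("B", c(290, 310, 319.99, 320, 400),
                              c(800, 800, 800, 0, 0))
  f <- mono(5, "B")
  expect_equal(uva_pf(f, list(B = uvb_only)), 1)
  expect_gt(spf(f, list(B = uvb_only)), 1)
})

test_that("film irregularity penalizes SPF relative to a homogeneous film", {
  sp <- reference_spectra()
  f <- reference_formulations()$spf30_ex4
  expect_lte(spf(f, sp, film_model("two_step")),
             spf(f, sp, film_model("homogeneous")))
  expect_lte(spf(f, sp, film_model("gamma", shape = 1)),
             spf(f, sp, film_model("homogeneous")))
})

test_that("SPF and UVA-PF are monotone in every filter concentration", {
  sp <- reference_spectra()
  base <- reference_formulations()$spf50_ex4
  s0 <- spf(base, sp)
  u0 <- uva_pf(base, sp)
  for (i in seq_len(nrow(base$components))) {
    up <- base
    up$components$concentration[i] <- up$components$concentration[i] * 1.3
    expect_gte(spf(up, sp), s0)
    expect_gte(uva_pf(up, sp), u0)
  }
})

test_that("the photostability factor scales like concentration", {
  sp_half <- list(A = flat_spectrum("A", 300, ps = 0.6))
  sp_full <- list(A = flat_spectrum("A", 300, ps = 1))
  expect_equal(spf(mono(5), sp_half, film_model()),
               spf(mono(3), sp_full, film_model()),
               tolerance = 1e-12)
})

test_that("the default two-step calibration and quadrature are stable", {
  # calibration anchor: flat <E11> = 271 mono-filter at 7 wt% lands mid-teens
  cal <- spf(mono(7), list(A = flat_spectrum("A", 271)))
  expect_gt(cal, 13)
  expect_lt(cal, 17)

  # 1 nm integration agrees with a 10x finer grid on a realistic composition
  sp <- reference_spectra()
  f <- reference_formulations()$spf30_ex4
  coarse <- spf(f, sp, step = 1)
  fine <- spf(f, sp, step = 0.1)
  expect_equal(coarse, fine, tolerance = 0.15)
  expect_equal(uva_pf(f, sp, step = 1), uva_pf(f, sp, step = 0.1),
               tolerance = 0.15)
})
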