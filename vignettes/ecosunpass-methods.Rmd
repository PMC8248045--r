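---
title: "Scoring model, data-gap rules and film simulation in ecosunpass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model, data-gap rules and film simulation in ecosunpass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosunpass)
```

## The assessment model

A sunscreen's environmental footprint is dominated by its UV filters, which
can enter surface waters directly during use and soils indirectly through
sludge application. `ecosunpass` ranks UV filter systems by combining two
orthogonal properties of each filter: its environmental hazard profile
across all relevant compartments, and its UV efficacy (how little of it is
needed for a given protection level).

### Chapter scores

Every filter is assessed in six chapters. Scores move in 0.25 steps from
0.25 (best behaviour) upward; the two fate chapters top out at 1.0, the
four toxicity chapters at 1.25:

| Chapter | Driver | 0.25 | 0.5 | 0.75 | 1.0 | 1.25 |
|---|---|---|---|---|---|---|
| Biodegradation | OECD category | readily | biodegradable | partly | poor | — |
| Bioaccumulation | BCF | < 500 | 500–2000 | 2000–5000 | ≥ 5000 | — |
| Acute aquatic | EC50 (mg/L) | > 100 (or no effect at the limit) | 10–100 | 1–10 | 0.1–1 | < 0.1 |
| Chronic aquatic | NOEC/EC10 (mg/L) | ≥ 10 | 1–10 | 0.1–1 | 0.01–0.1 | < 0.01 |
| Sediment | NOEC/EC10 (mg/kg dw) | ≥ 1000 | 100–1000 | 10–100 | 1–10 | < 1 |
| Terrestrial | NOEC/EC10 (mg/kg dw) | ≥ 1000 | 100–1000 | 10–100 | 1–10 | < 1 |

The 1.25 column is the "+0.25" escalation for drivers one decade below the
1.0 band. It is applied once and capped: the attainable overall range must
be exactly 1.5 to 7.0 (`2 × 1.0 + 4 × 1.25`), and an unbounded escalation
would exceed it.

Band boundaries require a convention because printed "≤/≥" band limits
overlap. We use half-open bands, closed on the safe side for the NOEC-type
ladders (a NOEC of exactly 10 mg/L or 1000 mg/kg scores 0.25), while the
acute 0.25 band requires EC50 strictly above 100 mg/L (an EC50 of exactly
100 scores 0.5). Tests pin every edge explicitly, and a brute-force
if-chain oracle checks 1,000 random drivers per chapter.

The most sensitive endpoint drives each chapter: after discarding records
with Klimisch reliability codes 3–4 (codes 1–2 are the conventional
"reliable" set), the record with the lowest effect value wins, with ties
broken by source priority (study > authority > literature > QSAR > expert
judgement) and then by label, so the result is independent of input order.
QSAR estimates are admitted only for bioaccumulation, where they are
considered adequate; QSAR records in effect chapters are dropped at load
time with a warning. Tests showing no effects up to the highest tested
concentration (or the solubility limit) take the lowest score via the
`no_effect_at_limit` flag rather than a solubility comparison, since
solubility is not part of the dossier schema.

### Data gaps: best, real, worst

Missing chapters are resolved three ways, producing a score triple whose
spread is the data-gap uncertainty:

* **best** — every gap filled with the chapter minimum (0.25);
* **worst** — every gap filled with the chapter maximum (1.0 fate, 1.25
  toxicity);
* **real** — screening logic. A missing BCF falls back to log Pow (< 4.5:
  not bioaccumulative, 0.25; ≥ 4.5: bioaccumulative, 0.75 — the worst case
  raises this to the very-bioaccumulative 1.0). Missing sediment or soil
  data are excused at 0.25 when the substance is readily biodegradable
  *and* has low sorption potential (log Koc < 3 or absent, log Pow < 4.5),
  because no relevant transfer to those compartments is then expected;
  otherwise the chapter maximum applies. Missing aquatic chapters fill
  conservatively at the maximum; a documented expert-judgement conclusion
  can override this by entering it as a reliable `expert_judgement` record.

We chose the conjunctive (AND) form of the sediment/soil screen — ready
biodegradability alone does not excuse missing data for a strongly sorbing
substance — as the conservative reading of screening practice. The log Koc
trigger of 3.0 is a conventional screening threshold for sorption.
Inorganic filters do not degrade, so their biodegradation chapter is fixed
at 1.0; their other chapters follow the ordinary band rules.

By construction `best ≤ real ≤ worst` for any dossier (fuzz-tested), and
adding measured data can only narrow the spread.

### Cut-off criteria

Independent of the score, a filter is excluded when it is an endocrine
disruptor, PBT or vPvB, or acutely (EC/LC50 < 0.1 mg/L) or chronically
(NOEC/EC10 < 0.01 mg/L) toxic to aquatic organisms. Values exactly at a
threshold do not fail (strict `<`), and only reliable records are
consulted. The two aquatic thresholds sit one decade below the 1.0-band
floors, so any cut-off-failing driver also carries the 1.25 chapter score.
ED and PBT/vPvB are EU regulatory concepts; `region_profile()` lets users
disable them (or re-threshold the aquatic criteria) outside the EU, and
the shipped `"EU"` profile enables all five. Any criterion failing under a
permissive profile also fails under the EU profile.

### Formulation ranking

With per-filter scores `S_k` and concentrations `c_k` (active-matter wt%):

$$\mathrm{ecorank} = \sum_k S_k c_k, \qquad
  \mathrm{max\text{-}ecorank} = 7.0 \sum_k c_k,$$
$$a = \Big(1 - \frac{\mathrm{ecorank}}{\mathrm{max\text{-}ecorank}}\Big)\cdot 100,
  \qquad \mathrm{value} = \frac{a\,(\mathrm{SPF} + \mathrm{UVA\text{-}PF})}{c_\mathrm{total}}.$$

The theoretical maximum is taken as the chapter-sum ceiling 7.0 per wt%
(configurable), which makes `a = 0` exactly for a uniformly worst filter
system and keeps the baseline composition-independent. `a` is invariant to
splitting a component and to rescaling all concentrations; lowering any
score strictly raises it. A formulation passes when its value strictly
exceeds 200; one cut-off-failing component zeroes the value for the whole
formulation (excluding just that component would understate the product's
impact). The default case feeding the scores is `real`; `best`/`worst` can
be requested to bracket the result.

## The film simulator

Efficacy uses specific extinction spectra: `E11(λ)` is the extinction of a
1 wt% preparation at 1 cm pathlength, and `<E11>`, its trapezoidal mean
over 290–400 nm, is the registry's single-number efficacy. The mean film
absorbance of a composition is Beer–Lambert:

$$A(\lambda) = \sum_k E11_k(\lambda)\, c_k\, p_k \,\frac{d}{1\,\mathrm{cm}},$$

with `p_k` a static photostability factor (default 1; dynamic
photodegradation is out of scope) and `d` the mean film thickness implied
by the application rate — 2 mg/cm² at unit density gives `d = 0.002 cm`.
Real films are irregular, so the transmission averages `10^{-A h}` over a
relative-thickness distribution with mean 1:

* `homogeneous` — `T = 10^{-A}` (useful as an analytic limit:
  with a flat spectrum, `SPF = 10^{E c d}`, asserted to 1e-9);
* `two_step` — `T = Σ_j f_j 10^{-A h_j}` (default: `f = 0.4/0.6`,
  `h = 0.205/1.53`);
* `gamma` — `T = (1 + A \ln 10 / k)^{-k}` for Gamma(`k`, `1/k`)
  thicknesses.

SPF is the ratio of source-times-action-weighted doses without and with
the film on a 1 nm grid over 290–400 nm, using the standard CIE erythema
action spectrum (implemented in its closed piecewise-exponential form);
UVA-PF uses a PPD action spectrum supported on 320–400 nm. The PPD action
spectrum and the midday midsummer source spectrum are smooth *synthetic*
analytic stand-ins (exponential decline and logistic ozone-edge rise,
respectively): only their shape enters the protection-factor ratios, and
no claim is made to reproduce any standard tabulation.

The two-step defaults were calibrated once, analytically, so that a
flat-spectrum mono-filter with `<E11> = 271` at 7 wt% yields SPF ≈ 15, and
are stored in the `film_model()` constructor rather than hard-coded in the
computation. Any irregular film gives SPF at or below the homogeneous film
for the same composition (Jensen's inequality for the convex map
`h ↦ 10^{-Ah}`), and the photostability factor scales exactly like
concentration — both are asserted in the tests.

## Synthetic reference data

The regulatory dossiers and measured spectra behind published per-filter
assessments are not public, so the package generates stand-ins in code:

* `reference_dossiers()` — one fully measured synthetic dossier per
  registry filter, with mid-band driver values tuned so the published
  per-filter anchors hold by construction: overall real-case scores of 3.0
  (ethylhexyl triazone), 5.25 (diethylhexyl butamido triazone), 2.75
  (TiO2) and 4.25 (ZnO), and a chronic aquatic NOEC of 0.005 mg/L for
  octocrylene, tripping the chronic cut-off. All other per-filter
  assignments are plausible inventions, not assessments.
* `reference_spectra()` — Gaussian-band spectra (band positions by coarse
  absorber class: UVB ~308 nm, UVA ~357 nm, broad two-band, mineral
  wide-band) rescaled analytically so `mean_e11()` reproduces each
  registry `<E11>` exactly.
* `generate_dossiers(n, completeness, seed)` — random dossiers for
  property testing: each chapter is measured with probability
  `completeness`, drivers drawn log-uniformly across the full band
  ladders, all randomness flowing from the single seed.

Passing tests on these data therefore demonstrate the *mechanics* —
band mapping, gap filling, cut-off logic, aggregation, simulation — not
agreement with any real filter's regulatory status. In particular the
simulated SPF/UVA-PF of the worked-example compositions are far above the
published values: the synthetic spectra and the mildly irregular two-step
default are much more transmissive-optimistic than a measured film model,
and exact efficacy reproduction is explicitly out of scope. Published
protection factors can always be supplied directly to
`evaluate_formulation()`, which is what the worked examples do.

One bookkeeping caveat: the printed component list of the SPF-30 example 3
sums to 12.0 wt% while its printed overall-concentration row reads
17.0 wt%; the component list is carried as authoritative, and the printed
total is kept only as reference metadata.

## Numerical choices and problem sizes

* Wavelength grid 290–400 nm at 1 nm, trapezoidal integration
  (`pracma::trapz`); `mean_e11()` refines to 0.5 nm, which is exact for
  piecewise-linear spectra. Coarse-vs-fine (0.1 nm) agreement is tested.
* Scores are exact multiples of 0.25; sums are compared exactly.
* Tie-breaks in driver selection are total (value, then source priority,
  then label), so permuting records never changes a result.
* Property suites use fixed seeds and modest sizes chosen for thorough
  coverage at interactive runtimes: 1,000 random drivers per chapter for
  band-oracle equivalence, 30–40 fuzzed dossiers for case-ordering, 24
  filters × 9 formulations for the end-to-end paths.

## Known limitations

* The six chapters are equally weighted by design; no exposure modelling,
  persistence half-lives or metabolite assessment is included.
* The co-formulant classes (emollients, thickeners, preservatives) are out
  of scope: their hazard profiles are too uniform to discriminate and the
  efficacy term does not apply to them.
* ED/PBT/vPvB status is an input flag, not a computed hazard
  identification.
* The film simulator is a screening model; its absolute SPF values should
  not be compared against in-vivo measurements.
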