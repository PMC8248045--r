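# ecosunpass

Environmental hazard scoring and ecofriendliness ranking of sunscreen UV
filters.

Sunscreens reach rivers, lakes and coastal waters directly during use, and
soils indirectly via sludge application; their UV filters are the
formulation ingredients that differ most in environmental behaviour. This
package implements a transparent screening workflow for formulators and
product stewards who need to compare UV filter systems on environmental
grounds without collapsing the assessment to aquatic toxicity alone:

1. **Per-substance hazard scoring.** Each filter is scored in six
   environmental chapters — biodegradation, bioaccumulation, acute aquatic,
   chronic aquatic, sediment and chronic terrestrial toxicity — on a
   0.25-step ladder (0.25 best to 1.0, or 1.25 for toxicity chapters whose
   driver lies a further decade below the worst band). The most sensitive
   reliable endpoint (Klimisch code 1–2) drives each chapter; data gaps are
   filled three ways, giving a *best / real / worst* score triple whose
   spread quantifies the data-gap uncertainty. The overall score is the sum
   over chapters:

   ```
   S = Σ_chapters s_c,   1.5 ≤ S ≤ 7.0
   ```

2. **Cut-off criteria.** A filter that is an endocrine disruptor, PBT or
   vPvB, or acutely (EC/LC50 < 0.1 mg/L) or chronically (NOEC/EC10 <
   0.01 mg/L) toxic to aquatic life is excluded outright; the criteria set
   is region-configurable (the shipped `"EU"` profile enables all five).

3. **Formulation ranking.** For a composition with concentrations `c_k`
   (wt%) and scores `S_k`,

   ```
   ecorank     = Σ_k S_k · c_k          max-ecorank = 7.0 · Σ_k c_k
   a           = (1 − ecorank / max-ecorank) · 100          (% ecofriendliness)
   ESP value   = a · (SPF + UVA-PF) / c_total
   ```

   A formulation is **ecofriendly** when its value exceeds 200 (strict). A
   single cut-off-failing component zeroes the value.

4. **UV efficacy.** SPF and UVA-PF are simulated from filter extinction
   spectra (`E11`, the extinction of a 1 wt% preparation at 1 cm
   pathlength) through a Beer–Lambert step-film model with a configurable
   film irregularity profile, weighted by the CIE erythema action spectrum
   (SPF) or a PPD action spectrum over 320–400 nm (UVA-PF).

Because the underlying regulatory dossiers and measured filter spectra are
not public, the package ships a synthetic reference set: tuned dossiers for
the 24 EU-approved filters (reproducing the published per-filter anchors,
e.g. octocrylene failing the chronic aquatic cut-off) and Gaussian-band
spectra matching each filter's published mean extinction `<E11>`.

## Worked example

```r
library(ecosunpass)

dossiers <- reference_dossiers()      # synthetic 24-filter dossier set
forms    <- reference_formulations()  # the nine worked-example compositions

# per-substance hazard score with uncertainty
hazard_triple(dossiers$EHT)
#> <hazard_triple> EHT: best 3.00 | real 3.00 | worst 3.00

# an octocrylene-containing SPF-30 composition under the EU profile
r <- evaluate_formulation(forms$spf30_ex1, dossiers, profile = "EU",
                          spf = 30.4, uva_pf = 10.5)
r
#> <esp_result> spf30_ex1 (real case)
#>   c_total 28.0 wt% | a 44.1% | SPF 30.4 | UVA-PF 10.5
#>   ecofriendliness value 0.0 -> not ecofriendly [cut-off: OCR: chronic_lt_0.01]
```

The cut-off (octocrylene's chronic aquatic NOEC of 0.005 mg/L, below the
0.01 mg/L criterion) zeroes the value regardless of the composition's 44.1%
ecofriendliness and its protection factors. A low-load composition of
low-hazard filters instead clears the threshold:

```r
r4 <- evaluate_formulation(forms$spf30_ex4, dossiers, spf = 30.7, uva_pf = 12.9)
round(c(a = r4$ecofriendliness_a, esp = r4$esp_value), 1)
#>     a   esp
#>  64.8 256.7
r4$ecofriendly
#> [1] TRUE
```

Protection factors can also be simulated from spectra instead of supplied:

```r
spectra <- reference_spectra()
spf(forms$spf30_ex4, spectra)      # step-film simulation, 290-400 nm, 1 nm grid
```

## Command line

A thin CLI over the same functions lives at `inst/cli/ecosunpass.R`:

```sh
Rscript inst/cli/ecosunpass.R fixtures --out fx --seed 1
Rscript inst/cli/ecosunpass.R score --master fx/dossier_master.csv \
    --records fx/dossier_records.csv --out out
Rscript inst/cli/ecosunpass.R esp --formulations fx/formulations.csv \
    --master fx/dossier_master.csv --records fx/dossier_records.csv --out out
```

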