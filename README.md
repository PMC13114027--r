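# tonomatch

Cochlear-implant electrodes stimulate fixed neural places but are fitted
with fixed default filter bands, so every implanted ear carries a
*frequency-to-place mismatch*: the distance, in semitones, between what a
channel delivers and what its cochlear place "expects". Because cochlear
duct length varies between ears and insertions are not always complete, the
same device produces very different mismatches across patients, and that
mismatch has been linked to poorer early speech perception — most clearly
for phoneme-level (consonant) recognition.

`tonomatch` is an R package for audiology researchers and CI-fitting
methodologists that implements the whole computational chain:

1. **Geometry** — cochlear duct length (CDL) from basal-turn diameter *A*
   and width *B* via an elliptic-circular approximation
   (Ramanujan perimeter on semi-axes *A*/2, *B*/2, scaled by 1.417), and
   exact closed-form conversion between insertion angle θ and arc length,
   `L(θ) = L_tot (1 − e^(−bθ)) / (1 − e^(−bΘ))`, with separate calibrated
   decay rates for the lateral wall and the organ of Corti.
2. **Tonotopy** — the Greenwood map `f(x) = 165.4 (10^(2.1x) − 0.88)` Hz,
   with `x` the relative distance from the apex, forward and inverse.
3. **Electrode model** — a 12-contact straight lateral-wall array (23.1 mm
   contact span, 28 mm array) and the default log-spaced 70–8500 Hz filter
   bank (13 geometric band edges, geometric-mean centres, apex-aligned).
4. **Mismatch** — per-contact semitone deviation `|12·log2(f_place/f_centre)|`,
   a per-ear fourth-order polynomial fit of deviation on angle, evaluated at
   the mid-array contact C6 (the 1–2 kHz speech region) as the ear's scalar
   statistic.
5. **Statistics** — Pearson and covariate-adjusted partial correlations
   (residualisation; `t = r·√(df/(1−r²))`, `df = n − 2 − k`), pooled
   two-sample t-tests, and Bonferroni control over the 4-measure ×
   3-time-point outcome family (corrected threshold 0.05/12 = 0.0042).
6. **Synthetic cohorts** — a seeded generator reproducing a 44-ear adult
   cohort's demographics, geometry, exclusion structure (44 → 38 → 35),
   attrition (35/33/27 at 3/6/12 months) and configurable
   mismatch–outcome effect sizes, so the pipeline is fully testable
   without patient data.

## Worked example

```r
library(tonomatch)

cohort <- simulate_cohort(seed = 7)     # 44 virtual ears
mm     <- compute_cohort_mismatch(cohort)
mm[1:3, c("patient_id", "aid_deg", "coverage_pct",
          "mismatch_c6_semitones", "c6_place_hz")]
#> # A tibble: 3 × 5
#>   patient_id aid_deg coverage_pct mismatch_c6_semitones c6_place_hz
#>   <chr>        <dbl>        <dbl>                 <dbl>       <dbl>
#> 1 P001          584.         81.1                  11.7       1245.
#> 2 P002          498.         73.7                  18.9       1883.
#> 3 P003          528.         76.4                  14.6       1472.
```

Each row is one ear: `aid_deg` is the angular insertion depth of the apical
contact (deeper = larger), `coverage_pct` the inserted fraction of the duct,
and `mismatch_c6_semitones` the fitted semitone deviation at contact C6 —
ear P001, inserted more deeply, shows ~7 semitones less mismatch than the
shallower P002.

```r
fit <- run_full_analysis(cohort)
fit
#> <mismatch_analysis>
#>   cohort: 44 -> 38 -> 35 (geometry / electrode / outcome)
#>   Bonferroni threshold: 0.0042 (alpha = 0.05, m = 12)
#>   partial correlations (mismatch vs score | age, PTA):
#>       measure timepoint  n     r p.value significant_bonferroni
#>  monosyllable        3m 35 -0.50   0.003                   TRUE
#>  monosyllable        6m 33 -0.14   0.460                  FALSE
#>  monosyllable       12m 27 -0.49   0.012                  FALSE
#>     consonant        3m 35 -0.50   0.003                   TRUE
#>     consonant        6m 33 -0.24   0.188                  FALSE
#>     consonant       12m 27 -0.61   0.001                   TRUE
#>          word        3m 35 -0.49   0.004                   TRUE
#>          word        6m 33 -0.34   0.058                  FALSE
#>          word       12m 27 -0.22   0.281                  FALSE
#>      sentence        3m 35 -0.36   0.041                  FALSE
#>      sentence        6m 33 -0.11   0.563                  FALSE
#>      sentence       12m 27 -0.22   0.286                  FALSE
```

The filter keeps all 44 ears for geometry, drops 6 with extracochlear
contacts for electrode-position analysis and 3 second-implant ears for the
outcome analysis. Each outcome cell is the partial correlation between the
C6 mismatch and that speech score, controlling age and preoperative
pure-tone average, with listwise deletion per time point (hence n = 35, 33,
27). Negative r means more mismatch, worse perception; cells below the
0.0042 Bonferroni threshold are flagged. `tidy(fit)` returns the same table
as a tibble, `glance(fit)` a one-row run summary, and `autoplot(fit)` the
corresponding trajectory plot.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/tonomatch.R demo --seed 7 --out report/
```

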