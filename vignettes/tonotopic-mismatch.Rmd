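---
title: "Modelling frequency-to-place mismatch and its relation to speech outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frequency-to-place mismatch and its relation to speech outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonomatch)
```

## The problem

A cochlear implant replaces acoustic hearing with direct electrical
stimulation of the auditory nerve along an electrode array inserted into the
scala tympani. The cochlea is tonotopically organised — an exponential map
from position along the organ of Corti to characteristic frequency, with low
frequencies at the apex — but the default clinical fitting assigns each
electrode a fixed filter band regardless of where that electrode actually
sits in the individual cochlea. The discrepancy between a channel's assigned
centre frequency and the characteristic frequency of the neural place it
stimulates is the *frequency-to-place mismatch*, conventionally expressed in
semitones. Because cochleae differ in size and arrays are not always fully
inserted, the same device produces very different mismatches in different
ears, and mismatch has been proposed as one determinant of post-operative
speech perception, particularly for phoneme-level recognition early after
activation.

`tonomatch` implements the full computational chain from raw cochlear
measurements to covariate-adjusted correlations between mismatch and
longitudinal speech scores, together with a seeded synthetic-cohort
generator so that every stage is testable without patient data.

## The model chain

### Cochlear duct length

The cochlear duct length (CDL) is estimated from two basal-turn
measurements: the diameter *A* and the width *B* (mm). The basal turn is
treated as an ellipse with semi-axes *A*/2 and *B*/2; its perimeter is
computed with Ramanujan's approximation (relative error below 0.05% at
basal-turn axis ratios) and scaled to the full two-and-a-half-turn duct by a
single dimensionless factor:

$$\mathrm{CDL} = s \cdot \pi\,(a+b)\left(1 + \frac{3h}{10+\sqrt{4-3h}}\right),
\qquad h = \left(\frac{a-b}{a+b}\right)^2,\; a = A/2,\; b = B/2 .$$

The default scale $s = 1.417$ is a calibration: it maps the typical adult
measurement pair (*A* = 8.7, *B* = 6.5 mm) to a 34.0 mm duct, the
centre of the range reported by contemporary CT-based studies
(roughly 30–37 mm). The published elliptic-circular closed forms can be
substituted by changing `eca_scale` in `geometry_config()`. The cochlear
height *H* is carried descriptively and never enters computation.

### Angle–length spiral maps

Clinical imaging reports electrode position as an angle from the
round-window reference; mismatch needs arc length. We model cumulative arc
length along the spiral as an exponential-saturation function of angle
$\theta$ (radians):

$$L(\theta) = L_{\mathrm{tot}}\,
\frac{1-e^{-b\theta}}{1-e^{-b\Theta}},\qquad \Theta = 900^\circ,$$

which is strictly increasing, concave (the spiral radius shrinks towards the
apex, so equal angles sweep less arc apically — note the *outer*-wall arc
per radian is largest basally), and exactly invertible. Two decay rates are
used, because the lateral wall and the organ of Corti sit at different
radii:

* `b_lateral = 0.1025` rad⁻¹, calibrated so that an insertion of 74.8% of
  the duct (the typical full insertion of a 28 mm lateral-wall array)
  corresponds to an angular insertion depth (AID) of about 511°;
* `b_oc = 0.140` rad⁻¹, calibrated so a 511° apical contact maps to an
  organ-of-Corti place frequency of about 286 Hz.

Both constants are documented as calibration, not anatomy: they stand in
for the internal angle-to-place table of surgical planning software, and
`geometry_config()` exposes them so a software-specific table can be
matched. The total extent of 900° (2.5 turns) comfortably contains all
realistic insertions; full insertions in the simulated cohorts stay below
720°, matching clinical experience with this array. Angles are handled in
radians internally and degrees at every interface.

### Tonotopy

Place frequency uses the Greenwood frequency–position function with the
standard human constants,

$$f(x) = 165.4\,(10^{2.1x} - 0.88)\ \mathrm{Hz},$$

where $x \in [0,1]$ is the relative distance from the **apex** along the
organ of Corti (the convention must be fixed explicitly; we state it
everywhere as distance-from-apex, so $x = 1$ at the base). The organ-of-Corti
fraction covered at an angle is scale-free under the spiral model, so the
composition angle → place fraction → frequency needs no per-ear length
bookkeeping. The organ-of-Corti length itself defaults to 0.90 of the
lateral-wall CDL (`oc_length_ratio`), used where absolute organ-of-Corti
arc lengths are required.

### Electrode array and default filter bank

The modelled array is a straight lateral-wall design, 28 mm long, with 12
equally spaced contacts spanning 23.1 mm, numbered apex-first (C1 apical to
C12 basal). The contact span and spacing are manufacturer-typical values and
are configurable. The default frequency allocation distributes 70–8500 Hz
logarithmically over the 12 channels: 13 geometric band edges with exact
constant ratio $(8500/70)^{1/12} \approx 1.4918$, channel centres at the
geometric means of their edges (85.5 Hz for C1, 631.6 Hz for C6, 6960 Hz for
C12), apex-aligned so C1 receives the lowest band. Vendor tables that differ
from pure geometric spacing can be supplied in place of the default map.
Partial insertion is modelled as a reduced inserted length of the same
array; contacts whose arc position falls below the round window are flagged
extracochlear and excluded from fitting.

### The mismatch statistic

For each contact the deviation between assigned centre and Greenwood place
frequency is taken in semitones, $s_k = |12\log_2(f_{\mathrm{place}}/
f_{\mathrm{centre}})|$. A fourth-order polynomial of $s$ on insertion angle
is then fitted per ear by ordinary least squares (angles are scaled to
[0, 1] for conditioning; coefficients are reported in the degree basis), and
the ear's scalar mismatch is the fitted curve evaluated at the angle of
contact C6, clamped at zero with a flag should the smoother dip negative.
C6 is used because its place falls in the 1–2 kHz region that carries the
spectral centre of speech information; at cohort-mean geometry the C6 place
is ≈1.7 kHz, inside that band. We fit absolute deviations by default; the
alternative — fit signed deviations, then take the absolute fitted value —
is available via `signed = TRUE` and coincides with the default whenever
all contacts are shifted the same way, which is the case for every
realistic (shallow) insertion under default maps. With fewer than five
intracochlear contacts the quartic is unidentifiable and the raw C6
deviation is used, flagged as a fallback.

Under default maps every cohort-range insertion is *shallow*: the place
frequency at each contact exceeds its assigned centre, so deeper insertion
(larger AID) strictly reduces the C6 statistic. This monotonicity, and the
resulting negative cohort-level correlations of mismatch with AID and with
coverage, are asserted as properties in the test suite.

## The inferential layer

The outcome analysis mirrors standard clinical-correlation practice:

* **Pearson correlations** for the geometry diagnostics (AID vs CDL,
  AID vs mismatch, coverage vs mismatch, CDL vs mismatch).
* **Partial correlations** between mismatch and each speech measure at each
  time point, controlling age and preoperative pure-tone average (PTA), by
  residualisation: both variables are regressed on an intercept plus the
  covariates and the Pearson correlation of the residuals is taken. This is
  algebraically identical to the inverse-correlation-matrix form but gives
  per-covariate diagnostics and a transparent failure mode for
  rank-deficient covariates (the offending column is named).
  Significance uses $t = r\sqrt{\mathrm{df}/(1-r^2)}$ with
  $\mathrm{df} = n - 2 - k$; the df convention is validated by the fact that
  $r = -0.52$, $n = 35$, $k = 2$ reproduces $p = 0.002$ exactly at the
  printed precision.
* **Student's pooled two-sample t-test** (Welch behind a flag) for sex and
  side comparisons of CDL.
* **Bonferroni control** over the 4-measure × 3-time-point family
  ($m = 12$), corrected threshold $0.05/12 = 0.0042$ at four decimals.
* **Listwise deletion per time point**, so the analysable n can differ by
  visit (35/33/27 by default) without discarding complete visits elsewhere.

## The synthetic cohort

No patient-level data are available, so the generator emulates the study
conditions and is itself first-class, tested code:

* 44 ears, 15 male / 29 female; age truncated normal N(66.6, 16.8²) on
  [21, 89] years; preoperative PTA N(97.2, 20.2²) dB HL truncated to
  [40, 130] (a plausible severe-to-profound band; the lower cut keeps
  implant candidacy realistic).
* CDL by sex: N(34.6, 0.9²) mm male, N(33.6, 1.5²) mm female. The implied
  mixture SD (≈1.41 mm) matches the overall spread such cohorts report.
  Basal-turn A and B are back-solved from the drawn CDL through the same
  duct-length formula with a jittered B/A ratio centred at 6.5/8.7, so
  generated records are internally consistent by construction.
* **Insertion depth.** The inserted length is drawn around the nominal
  insertion mark (74.8% of the mean duct, ≈25.4 mm) with an SD solved by
  the delta method so that electrode *coverage* has mean 74.8% and SD 4.6%.
  We deliberately do **not** draw coverage directly and multiply by CDL:
  that construction makes AID a function of coverage alone and destroys the
  negative AID–CDL correlation that a fixed-length array inserted into
  variably sized cochleae must show. Drawing length (the physical quantity)
  yields both the stated coverage moments and corr(AID, CDL) ≈ −0.7, and —
  pleasingly — an AID SD of ≈51°, emerging rather than imposed.
* Six ears are flagged extracochlear (insertion shortfall uniform 10–30%)
  and three as second-implant exclusions; both sets are drawn from the
  female majority so the analysable subset keeps its 15/20 sex split.
  Exclusion and attrition counts (35 → 33 → 27, monotone dropout) are
  exact, not stochastic.
* **Scores.** Each measure × time-point score is a latent linear model:
  standardised age and PTA with coefficients −0.2 (modest confounding,
  configurable), standardised mismatch with a coefficient solved from the
  target partial correlation via
  $\gamma = r\,\sigma_\varepsilon/\sqrt{1-r^2}$, plus unit normal noise,
  rescaled to score points (12 points per latent SD) around per-cell means
  chosen to rise over the first year, bounded to [0, 100]. The default
  targets are the full 4 × 3 grid of effect sizes, strongest for consonant
  perception at 3 months (−0.52). Sentence scores are softly compressed
  above 80 (slope 0.5), which leaves roughly half of 6-month and two-thirds
  of 12-month sentence scores above 80 — a deliberate ceiling that slightly
  attenuates the sentence cells, mirroring how ceiling effects weaken
  sentence-level correlations in practice.

All randomness sits behind one explicit seed per cohort; the generator
restores the caller's RNG state.

### What the generator does and does not emulate

It reproduces the cohort's marginal distributions, exclusion structure,
attrition, and the *targeted* partial-correlation structure with mismatch
arising mechanistically from geometry. It does not model etiology- or
device-specific effects, practice/learning curves within a visit battery,
non-linear age effects, or measurement error in A/B readings. Passing
recovery tests therefore demonstrates that the pipeline estimates what the
generator encodes — not that real ears obey the latent-linear score model.
Because no absolute mean mismatch in semitones is available to anchor the
generator, the mismatch scale is fixed by geometry alone; correlation
targets are invariant to that scale.

## Numerical choices

* Spiral and Greenwood maps use exact closed-form inverses; round trips are
  tested to 1e−9.
* The quartic is fitted on angle/`theta_total` ∈ [0, 1] to keep the
  Vandermonde condition number small; coefficients are returned in the
  degree basis.
* A vectorised cohort-level mismatch kernel (matrix algebra plus one small
  least-squares solve per ear) backs `compute_cohort_mismatch()`; the
  per-ear functions `locate_contacts()` + `fit_mismatch_profile()` are the
  reference path and the two are held equal to machine precision by a test.
* Degenerate inputs fail loudly: A ≤ B, inserted length exceeding the duct,
  frequencies below the apical minimum, rank-deficient covariates (named
  column), zero-variance correlations. An insertion equal to the contact
  span places C12 exactly at the round window (angle 0), the boundary case.
* Problem sizes in the shipped tests: 500 replicate cohorts for parameter
  recovery, 10,000 replicates for the null type-I-error check, 1000-draw
  round-trip properties — all chosen to make Monte-Carlo error a small
  fraction of the tolerance being asserted.

## A worked pass

```{r demo}
cohort <- simulate_cohort(seed = 7)
fit <- run_full_analysis(cohort)
fit
glance(fit)
```

```{r plot, fig.width = 7, fig.height = 3}
autoplot(fit)
```

## Known limitations

* The angle–length maps and the duct-length scale are calibrated stand-ins
  for planning-software internals; absolute AIDs and place frequencies are
  only as good as those calibrations, although all downstream statistics
  are rank-preserving in them.
* Whether "inserted length" means full-array or active-span length for
  partial insertions is ambiguous in clinical reports; we treat it as the
  arc position of the apical contact, which is the quantity the spiral
  model needs.
* The sentence ceiling makes large negative sentence-cell targets
  infeasible by design; recovery there is attenuated by a few hundredths
  of a correlation unit.
* Single-rater measurement error in A/B is not modelled; adding it would
  attenuate the geometry diagnostics but not the score-model targets.
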