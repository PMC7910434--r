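---
title: "Abnormal-point microperimetry outcomes: model, assumptions and design choices"
author: "mpoutcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abnormal-point microperimetry outcomes: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpoutcomes)
```

## The problem

Mesopic microperimetry measures differential light sensitivity (in dB) at
a set of retinal locations while tracking the fundus. In intermediate
age-related macular degeneration (iAMD), the mean sensitivity of a whole
test grid is only mildly depressed, because most points in a typical exam
are still normal. An endpoint built on the whole-grid mean therefore
dilutes any treatment effect on the diseased retinal foci. This package
implements the alternative: score every point against an age-corrected
normative expectation, keep only the points that are *abnormal*, and build
the endpoint (counts, mean thresholds, mean deviations), the trial
eligibility screen, and the test–retest repeatability statistics from that
restricted set.

## The normative model and calibration

The expected normal threshold is linear in age and independent of
location within the grid:

$$\hat t(\text{age}) = 32.3 - 0.06 \cdot \text{age} \quad [\mathrm{dB}],$$

with a single pointwise normative SD of 1.78 dB at every eccentricity and
age. These are the constants of the MAIA device's internal normative
database, and `normative_model()` carries them as overridable defaults.

Device populations can sit systematically off this line. The calibration
stage (`estimate_offset()`) measures the shift on a healthy cohort
recorded with the same device: each healthy eye contributes the
difference between its age-expected threshold and its grid-mean measured
threshold (averaged over its repeated exams), and the cohort mean of
those differences is the offset. For the reference healthy cohort
(mean age 62.2 years, mean sensitivity 25.9 dB) this gives

```{r}
round(expected_threshold(normative_model(), 62.2) - 25.9, 2)
```

The offset is a single global constant added to every measured threshold
before deviation scoring — not a per-eye correction. Because the model is
linear in age, per-eye aggregation and the cohort-mean-age shortcut agree
exactly for balanced designs; the per-eye form is the implementation and
the shortcut is used as an independent oracle in the tests.

## Deviations and abnormality

For point $i$ of an exam at age $a$ with calibration offset $c$,

$$d_i = (t_i + c) - \hat t(a),$$

and the point is abnormal under criterion $z$ when $d_i < -z \cdot 1.78$
(strictly). The two conventional criteria are $z = 1.65$ (the 5%
normative tail) and $z = 2$ (the 2.5% tail).

**Unrounded cutoffs are the default.** $1.65 \times 1.78 = 2.937$ dB and
$2 \times 1.78 = 3.56$ dB are conventionally quoted rounded to 2.9 and
3.6 dB. The package computes with the exact products because they
preserve the nominal tail probabilities: a 2.9 dB cutoff corresponds to a
5.2% tail, more liberal than "less than 5%". `rounded = TRUE` (or the
CLI's `--rounded-cutoffs`) reproduces the quoted one-decimal values. A
deviation exactly at the cutoff is *normal* ("lower than" is strict).

Per-eye summaries (`summarize_eye()`) report the abnormal count, the
whole-grid and abnormal-restricted mean adjusted threshold and mean
deviation, and the within-grid sample SD (n−1, as everywhere a spread is
reported). An eye with no abnormal point has *undefined* restricted
means: they are carried as `NA` and such eyes are excluded from
abnormal-restricted cohort aggregates (their exclusion count is
reported), while remaining in whole-grid aggregates and in eligibility
denominators.

Cohort summaries report the percentage of abnormal points under **both**
conventions — pooled ($\sum k_j / \sum n_j$) and mean of per-eye
fractions — because the two differ whenever counts vary across eyes and
published tables do not always say which was used.

## Eligibility

`check_eligibility()` implements the screen "at least `min_abnormal`
abnormal points" (default 5), either in every supplied exam (default,
the stricter reading appropriate for enrolment) or in any exam. The
cohort summary tallies eligible eyes per exam and under the both-exams
rule, with `pct_excluded = 100 (1 - k/n)`; for instance 18 eligible of
25 eyes means 28% of potential recruits are excluded.

## Repeatability and separation

`bland_altman()` computes the mean paired difference (first minus second
exam), its sample SD, and the 95% limits of agreement
$\bar d \pm 1.96\, s_d$. Published scalar "limits of agreement" values
are ambiguous between the *span* between the two limits
($2 \times 1.96\, s_d$) and the *half-width* ($1.96\, s_d$); the object
reports both, and the span is used where a single number is needed,
since the two dashed limits of a Bland–Altman plot are roughly symmetric
about a near-zero mean difference and a single figure most naturally
denotes their separation.

`cohens_d()` uses the equal-weight pooled SD
$\sqrt{(s_a^2 + s_b^2)/2}$ — the convention of the common online
calculators used in the clinical literature — with a df-weighted option.
The healthy comparator pools each healthy eye's repeated exams as
independent observations (so 22 eyes contribute 44 values); averaging
per eye first is available by simply summarising before the call.

## The synthetic cohort generator

No raw patient data accompany this problem, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
and the whole pipeline is exercised on them.

Per eye: an age is drawn (healthy 62.2 ± 4.4, iAMD 67.7 ± 7.1 years,
truncated to 40–95), a true sensitivity surface is laid down as
`expected(age) − device_offset` (default 2.67 dB, so the calibration
stage has a known truth to recover), and — for iAMD eyes — a focal
lesion lowers $k$ points by per-point depths drawn from
$\mathcal N(-5, 1.5^2)$ dB (capped at 0), with
$k \sim \mathrm{round}\,\mathcal N(12, 9^2)$ truncated to $[0, 33]$.
Lesion points form a contiguous angular sector by default (focal
drusen-like damage); random scatter is an option. Each exam then adds
independent Gaussian measurement noise per point, rounds to the device's
one-decimal output precision and truncates to 0–36 dB (the generator
warns if more than 1% of measurements hit the bounds, since floor
effects bias deviations).

Chosen once, with these rationales:

* **Noise SD 1.732 dB**: the device's staircase thresholding is out of
  scope, so the noise is a free parameter calibrated against the
  pointwise repeatability constraint — a pointwise limits-of-agreement
  span of 9.6 dB implies $2 \cdot 1.96 \cdot \sqrt2 \cdot \sigma = 9.6$,
  i.e. $\sigma \approx 1.73$ dB. This also yields healthy within-grid
  SDs near 1.8 dB, matching the normative pointwise SD as observed in
  healthy cohorts.
* **Lesion defaults** ($k \sim 12 \pm 9$, depth $-5 \pm 1.5$ dB): give
  on average about a third of points abnormal (≈ 11 of 33 at
  $z = 1.65$), abnormal-point mean deviations near −5 dB, whole-grid
  mean deviations near −2 dB and within-grid SDs around 2.4–2.8 dB —
  the magnitudes reported for real iAMD cohorts.
* **Reproducibility**: each eye's random stream is seeded
  deterministically from (master seed, eye index), so datasets are
  bit-identical across runs and independent of generation order.

What the generator does **not** emulate: staircase quantisation beyond
one-decimal rounding, fixation instability, learning/fatigue effects
across the two same-visit exams, spatially graded lesion borders,
between-eye variation in true healthy sensitivity beyond age (real
healthy cohorts show grid-mean SDs near 1.3 dB across eyes; simulated
healthy eyes differ only through age and noise, which makes
healthy-vs-iAMD effect sizes larger than clinical ones), and any
dependence of measurement noise on defect depth. The last point
matters when interpreting repeatability results: with exchangeable
per-point noise, the variance of a mean over $k$ abnormal points is
necessarily at least that of the mean over all 33 points, so the
simulated abnormal-only limits of agreement land *above* the all-points
limits, whereas a small clinical cohort can show the opposite ordering
(through sampling variability of SD estimates at n ≈ 20 eyes, or noise
structure the published data do not constrain). Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and
the averaging-based orderings (eye-level spans well below the pointwise
span), not every ordering a particular clinical sample may display.

## Numerical and interface choices

* Thresholds are validated against the 0–36 dB device range on ingest —
  never clipped; CSV stores thresholds at the device's one-decimal
  precision and round-trips them bit-identically; internal computation
  is full precision.
* Sample SDs (n−1) everywhere a "±" is reported.
* Problem sizes in the test-suite Monte-Carlo checks are set by the
  precision they need: the normative-tail check uses 20,000 simulated
  healthy eyes (660,000 points), putting the Monte-Carlo SE of the
  flagged percentage at ~0.027 points, small enough to resolve
  $\Phi(-1.65) = 4.95\%$ from the 5% bound; parameter recovery uses 200
  eyes per cohort, where the offset estimator's SE is ~0.015 dB against
  a ±0.1 dB tolerance.
* The grid's angular layout is a convention (8 points per ring at 45°
  starting on the horizontal meridian; 12 at 30° for the 61-point
  normative layout): only eccentricities are fixed by the published
  designs, and no statistic depends on angles. Custom layouts load from
  a YAML definition (`read_grid()`).
* Laterality carries no semantics: coordinates are abstract Cartesian
  degrees centred on fixation.
* The command-line surface (`inst/cli/mp.R`) is a thin wrapper over the
  exported functions: `simulate`, `score`, `summarize`, `agreement`,
  `run`, exiting non-zero on validation failure.

## A worked end-to-end run

```{r, message = FALSE}
res <- run_pipeline(list(seed = 1), out_dir = tempfile("mp_run_"))
res$offset
res$cohorts$iAMD$eligibility
res$agreement
```

The iAMD cohort's abnormal counts, restricted-mean deviations and
eligibility fractions can be compared against the magnitudes quoted
above; the agreement table shows the pointwise span far above the
eye-level spans.

## Known limitations

* The normative line is extrapolated to 7° eccentricity (the database
  was built within 5°); this mirrors standard practice but is an
  assumption, not a fit.
* The eligibility screen and abnormality cutoffs are fixed clinical
  conventions, not inferential tests; no multiple-testing machinery is
  attached, by design.
* Progression (inter-visit change) analysis and scotopic testing are out
  of scope.
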