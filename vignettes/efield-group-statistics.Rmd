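---
title: "Group-level E-field statistics: models, corridors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level E-field statistics: models, corridors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efieldstats)
```

This vignette is the package's own account of the statistics it
implements: what the models assume, which tunable parameters matter, what
the synthetic cohort generator does and does not emulate, and the choices
made where the underlying methodology is genuinely ambiguous.

## The setting

Transcranial magnetic stimulation (TMS) and transcranial electrical
stimulation (tES) dosimetry studies summarize each participant by an
ROI-average E-field magnitude (V/m): the mean Euclidean norm of the
simulated field over a 10 mm-radius sphere at the cortical projection of
the stimulation site (C3 motor: MNI −52.2, −16.4, 57.8; F3 prefrontal:
MNI −35.5, 49.4, 32.4), restricted to gray matter. Four protocols are
analyzed per person — TMS and tES, motor and prefrontal. TMS dose is
individualized: intensity is 120% of the resting motor threshold (rMT, in
% of maximal stimulator output), converted to a coil current rate
`dI/dt = min(1.2 * rMT, 100)/100 * 150e6 A/s` for a MagVenture-class
machine. tES is fixed-dose (2 mA), so between-subject tES variance is
purely anatomical.

The package starts *after* field modeling: its inputs are per-subject
ROI magnitudes (or discrete field samples for the ROI operator), plus
single E-field values for two template heads (MNI-152 and Ernie) that act
as one-observation comparison groups.

## ANOVA from sufficient statistics

`anova_from_summaries()` computes the one-way fixed-effects ANOVA from
per-group (n, mean, SD), which is exactly recoverable because the
between- and within-group sums of squares are functions of the sufficient
statistics only. Two design facts drive the implementation:

* **Singleton template groups.** A template head contributes one
  observation: zero within-group SS and zero within-group df. With 195
  individuals and two templates the omnibus design has df = (2, 194) on
  197 observations — the only reading consistent with the published
  degrees of freedom.
* **Summary/raw equivalence.** `anova_from_raw()` implements the
  classical decomposition independently, and the suite asserts agreement
  with the summary route to 12 significant digits on 1,000 random
  designs. This matters because the pipeline mixes both: published
  tables arrive as summaries, synthetic cohorts as raw values.

Effect size is partial eta squared,
`SS_between / (SS_between + SS_within)`, which for a one-way design
equals plain eta squared. Alpha is 0.05 two-tailed everywhere and no
multiplicity correction is applied across the twelve ANOVAs (four
omnibus, four diagnosis, four sex), mirroring standard practice in this
literature; the report footer says so.

`tukey_kramer()` runs studentized-range post hocs from the same
summaries, with the Tukey–Kramer unequal-n standard error. Singleton
groups are refused with advice to exclude templates: a one-observation
group has no within-group variance to compare against. With only two
groups the procedure degenerates cleanly (q = √2·|t|, p equals the pooled
two-sided t test), which keeps the pipeline total when a cohort is
restricted to two diagnoses.

## The corridor of stability and its ambiguity

`point_of_stability()` asks: how many subjects are needed before the
group-mean estimate stabilizes? For each subsample size s it draws
`reps_per_size` (default 10,000) random subsamples **without
replacement** — subsamples of a fixed cohort of real scans cannot repeat
a subject; with-replacement bootstrap sampling is retained as an option —
and the point of stability (POS) is the smallest s whose 5–95 percentile
band of subsample means lies inside the corridor of stability *for that
and every larger size*, enforced over all larger sizes up to `max_size`,
not merely the next one.

The corridor itself is the under-specified ingredient. Descriptions of
this family of analyses typically define the corridor by the 5th and
95th percentiles of the full sample, but that cannot be taken at face
value for a mean-stability question: a size-1 subsample mean already
falls inside a P5–P95 *value* corridor about 90% of the time, which
would force POS estimates near 1, not in the published several-tens
range. Rather than
silently guessing the intended construction, all three defensible
readings are implemented and explicit in configuration:

* `sample_percentile` — the literal text: (P5, P95) of the values.
* `mean_relative_width` — mean·(1 ∓ w), default w = 0.05; the reading
  whose POS magnitudes land in the published several-tens range, and the
  default used by the pipeline report and the acceptance script.
* `mean_ci` — mean ∓ z·SD/√N, a confidence-interval-style corridor.

Similarly, "10,000 repetitions" admits two procedures: independent
subsamples per size (`band_within_corridor`, the default, matching the
arithmetic of "1,950,000 subsamples") and accumulation trajectories
(`trajectory_quantile`: per permutation, running means define an
individual entry-without-exit time; the reported POS is the 95th
percentile of those times). Both are implemented; neither is asserted to
be the historical procedure, and published POS values (42–52) are treated
as qualitative context, not reproduction targets. The qualitative claim
the package does reproduce is that every protocol's POS falls well below
152, the number of scans in the MNI-152 composite.

Numerical choices, stated once: percentiles use linear interpolation
between closest ranks (`quantile type 7`) and the result records this;
at s = N without replacement the subsample is exhaustive and the band has
exactly zero width (computed without resampling noise); constant data
yields a zero-width corridor and POS = `min_size`; degenerate zero-width
corridors on non-constant data are an error. One RNG stream is derived
per (protocol, size) from the master seed, so results are invariant to
evaluation order. A closed-form Gaussian check — POS ≈ smallest s with
z₀.₉₅·SD·√((N−s)/(N·s)) ≤ w·mean — agrees with the simulated
band-criterion POS within ±6 in the suite, and doubling the default rep
count moves POS by at most ±3 across 20 seed replicates.

## The synthetic cohort generator

`cohort_params()`/`generate_cohort()` emulate the *statistical* structure
of a 195-subject transdiagnostic cohort: five diagnostic groups of
31/87/31/25/21 (healthy, alcohol use, tobacco use, anxiety, depression),
106 men / 89 women assigned independently of diagnosis (only marginal
counts are published), rMT ~ normal(50.46, 8.91) truncated to [31, 78]
%MSO, and per-(diagnosis × protocol) E-field moments taken from the
reference summary table, with normal-truncated-at-zero marginals —
means and SDs are the only published moments, so a truncated normal is
the minimal-assumption family. Within a subject the four protocol values
share a latent anatomical factor with loading 0.5 (configurable): the
same head drives all four models, so some positive correlation is the
realistic default, but its true value is unpublished. Truncation is
implemented by inverse-CDF sampling, so draw counts are fixed and every
subject consumes a private substream derived from the master seed by
counter offset — cohorts are bit-reproducible and invariant to
generation order.

Two generation modes:

* **direct** (default): each cell value is drawn from the truncated
  normal with the cell's target moments.
* **mechanistic**: TMS values are `gain_i × dI/dt_i` with a per-subject
  lognormal anatomical gain (lognormal for positivity), moment-matched so
  cell marginals still hit their targets given the dose distribution
  (dose moments computed by quadrature over the truncated rMT density,
  including the 100% MSO cap); tES values are `gain'_i × 2 mA`,
  independent of rMT by construction.

Mechanistic calibration has a hard feasibility floor: with gain
independent of dose, a cell's target SD cannot be below
`(target mean) × (dose CV)`. Under the reference parameterization the
120% rMT dose CV is ≈ 17%, and several TMS cells have target CVs at or
below that — those cells are *structurally impossible* for an
independent-gain model, and the generator raises a calibration error
naming the cell rather than silently missing its moments. This is itself
scientifically informative: dose individualization alone accounts for
essentially all of the published TMS E-field variance, consistent with
the observation that fixed-dose tES cells show no diagnosis effects while
individualized TMS cells do. Direct mode is therefore the default.

What passing tests on synthetic cohorts do **not** show: synthetic
subjects have no spatial field structure, no anatomically realistic
covariance beyond the single latent factor, and exactly normal (truncated)
marginals. Conclusions about distribution-shape-sensitive quantities —
the percentile corridor, tail-dependent outlier counts — transfer to real
cohorts only insofar as real ROI magnitudes are near-normal.

## Template values and a documented discrepancy

The reference summary table and the accompanying results text disagree
about which motor-TMS value belongs to which template (81.46 vs 78.16
V/m, attribution swapped). Omnibus F statistics are provably invariant to
the swap (the suite asserts this), but percent differences are not. The
default follows the results-text attribution (MNI-152 = 78.16), which is
the only assignment consistent with the published "8.3% lower"
percentage; `default_templates(assignment = "table")` selects the other
reading, and the report surfaces the ambiguity in a note rather than
deciding it silently. Percent differences are denominated by the
individual-group mean, `(group − template)/group × 100`, the only
denominator consistent with all verifiable published percentages; the
two motor-tES percentages (computed 15.6/17.6 from the printed table vs
16.3/17.7 as published) appear to have been derived from unrounded data
and are not asserted anywhere.

## ROI averaging

`roi_mean_magnitude()` abstracts a tetrahedral-mesh average as weighted
point samples (element centroid + volume): format-agnostic and exactly
testable against brute-force enumeration. The sphere is closed
(‖x − c‖ ≤ r), the magnitude is averaged (mean of norms, the standard
reading of an ROI-average magnitude outcome; not the norm of the mean,
which would cancel opposing vectors), and weighting by element volume is
the default with an unweighted option, since published descriptions
rarely state which was used. An empty ROI after tissue filtering is an
explicit error, distinguishable from a genuine zero field.

## Problem sizes and runtime

Defaults reproduce the full study scale: 4 protocols × sizes 1–195 ×
10,000 subsamples, which the compiled resampling kernel completes in
well under a minute per protocol on one CPU. The test suite uses reduced
but statistically meaningful scales chosen once: 2,000 reps for
monotonicity and approximation properties (20 seed replicates), 10⁶
draws for the Monte-Carlo studentized-range oracle, 50,000 subjects per
cell for moment-recovery checks, and one full-scale default run as a
runtime bound.

## Limitations

No mixed-effects, repeated-measures, covariate (age), or per-diagnosis
stability analyses; no percentile-based (e.g. E100) or normal-component
outcome measures; no claim that the synthetic generator captures real
anatomical covariance. The ANOVA machinery assumes homoscedastic normal
groups, as the original comparisons do; with singleton template groups
there is no way to check the templates' contribution to that assumption.
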