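---
title: "Models and methods behind cyclefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyclefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclefate)
library(data.table)
```

`cyclefate` analyses lineage-linked single-cell reporter trajectories to ask
how a mother cell's experience of glucose withdrawal shapes her daughters'
choice between proliferation and quiescence. This vignette documents the
models the package implements, the parameters that matter and their
defaults, the synthetic-data generator that stands in for imaging data, and
the numerical choices made where the design was genuinely open.

## The measurement model

Each tracked cell carries seven channels sampled on a common imaging grid
(default 15 min over 48 h):

* the four Fucci4 reporters — Cdt1 (peaks at the G1/S transition and is
  degraded through S), Geminin (induced at S entry, peaks at mitosis
  onset, collapses at division), SLBP (peaks at the S/G2 boundary) and a
  histone H1.0 fusion (constant chromatin signal with a transient
  excursion during mitosis);
* the DHB CDK2 sensor, reported as separate nuclear and cytoplasmic mean
  intensities; CDK2 activity is their ratio Cyt/Nuc, which sits near 0.6
  in quiescent cells and rises to a mitotic peak in cycling cells;
* a p21 reporter (nuclear mean intensity).

All intensities are in arbitrary units; times are hours.

## Phase calling

Phases are assigned from waveform landmarks, after smoothing each channel
with a centered moving average (default 5 frames) and normalizing to the
per-cell robust maximum (98th percentile, so a single aberrant frame cannot
define the scale):

* G1/S boundary — the Cdt1 peak, which coincides with Geminin onset;
* S/G2 boundary — the SLBP peak;
* G2/M boundary — the Geminin peak;
* division — the recorded lineage event when present (it is authoritative);
  an H1 mitotic signature time is reported alongside, never silently
  merged.

Peaks are located as the global maximum of the smoothed trace and then
refined to the raw-trace maximum within half a smoothing window. The
refinement matters: a moving average drags the maximum of an asymmetric
peak toward its gentler side, so cells with, say, a short G1 before a long
S would otherwise acquire a systematically shifted G1/S boundary. Ties
break to the earliest frame. Intervals are half-open — a boundary frame
belongs to the later phase — so every frame between birth and division
receives exactly one label.

A cell whose Geminin trace never leaves its baseline (dynamic range below
3x) is labelled G1/G0 throughout with all boundaries flagged truncated;
this is how quiescent daughters appear. If the detected SLBP peak falls
after the Geminin peak the ordering is unresolvable and the cell is
labelled undetermined with a diagnostic flag.

### Duration summaries and censoring

Durations are only reported when both boundaries of a phase were observed:
the first phase of a cell without a recorded birth is truncated (mothers
are captured mid-cycle), as is any phase cut by the observation window.
G1 durations use the recorded division time of the mother as the birth
time — not the first sampled frame — which removes a frame-snapping bias
of about half a sampling interval.

Truncation alone does not make the summary unbiased: a cell born late in
the movie can only contribute *short* completed phases, so late-born cells
bias means downward. `phase_duration_summary()` therefore keeps durations
from born cells only when the cell was observable for at least the longest
fully observed cell cycle in the data set (`followup = "complete-cycle"`),
so no included cell could have had any observed cycle length censored
away. Mothers, bounded by their own recorded division, are always kept.

## Fate calling

CDK2 activity is the elementwise cytoplasm/nucleus ratio (frames with a
nuclear mean below 1e-6 a.u. are masked, not divided). The binary rule:
a cell is **quiescent** when its smoothed ratio stays below
`ratio_threshold` (default 0.8) for a contiguous interval longer than
`min_window` (default 10 h), and **proliferating** otherwise. The interval
is measured from the first to the last frame of the sub-threshold run. Two
boundary conventions follow from the rule itself: an undivided track
observed for no more than 10 h can never satisfy it and is
*indeterminate*, while a track that ends in a recorded division is
classifiable however short it is (division rules out quiescence). Daughters
still unobserved at the horizon carry a `censored` flag.

The three-state scheme reports, in addition: *quiescent* when the smoothed
ratio never shows a sustained rise (rolling least-squares slope above
0.01 h^-1 maintained for 2 h or more), *G1-arrested* when it rises but the
Cdt1 trace never passes its peak, and *proliferative* otherwise. "Passing
the peak" is operationalized as the trace falling back below
`cdt1_peak_fraction` (default 0.9) of its per-cell maximum after the
maximum — a still-climbing Cdt1 has not peaked. The binary rule is
authoritative for all fractions; a cell the binary rule calls quiescent is
never reported as three-state proliferative (the low-CDK2,
Cdt1-peak-passed combination — an S-phase arrest — maps to G1 arrest).

The quiescent fraction rises monotonically in `ratio_threshold` and falls
monotonically in `min_window`; both monotonicities are asserted as property
tests.

## Lineage statistics

Trajectories are anchored to the founding mother's division (time 0);
mothers occupy negative anchored time, daughters positive. Inheritance is
quantified on 5-h windows: the mother side uses `[-5, 0)` h, the daughter
side `(0, 5]` h, and pairs with an empty window are dropped. The
mother–daughter statistic is the Pearson correlation between the mother's
pre-mitosis p21 window mean and each quiescent daughter's post-mitosis
window mean.

Sibling resemblance uses the discrepancy

$$D = \frac{2\sum_i (x_i-y_i)^2}{\sum_i (x_i-\bar x)^2 + \sum_i (y_i-\bar y)^2}$$

over the two siblings' post-mitosis p21 window series. D is 0 for
identical siblings, symmetric in the (non-ordered) pair, and invariant to
a common additive shift and to common rescaling; it is undefined (and
flagged) when both series are constant. Because the natural reading of a
*resemblance* is "closer to 1 is more alike", the package reports
`R2 = 1 - D` alongside raw D. Group-level values pool the pairs by
concatenating their series, so the denominator carries the between-pair
spread of p21 levels; per-pair values are returned as well. Within a pair,
siblings are ordered by cell identifier — D's symmetry makes the choice
inconsequential for the numerator, and the pooled denominator is
insensitive to it in practice.

Sibling fate concordance counts pairs in which both daughters made the
same call; pairs with an indeterminate member are excluded and reported.
When sibling fates are independent with quiescence probability $p$, the
expected discordant fraction is $2p(1-p)$ — the S-group test uses this
closed form as its oracle.

Daughter proliferation versus mother time-to-mitosis bins mothers into
right-open 1.3-h bins from 0, computes the percentage of proliferating
daughters per bin, and reports the Pearson correlation over bin centers;
bins with fewer than 2 mothers are dropped, and the signed r is returned
(the built-in coupling makes it negative — proliferation falls as the
mother's exposure lengthens).

## The synthetic-cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions, and all downstream acceptance checks are parameter-recovery
exercises against it.

**Cell cycle.** Phase durations are drawn from normal distributions
truncated below at 0.25 h. The location and scale are moment-matched
numerically so that the *truncated* distribution has exactly the
configured mean and SD — 4.92 ± 2.09, 5.59 ± 1.52, 2.19 ± 0.93 and
0.81 ± 0.13 h for G1/S/G2/M under control conditions, and 7.39 ± 4.38,
6.23 ± 2.05, 3.74 ± 1.42 and 0.84 ± 0.23 h under glucose depletion (the
G1 elongation is the depletion signature). Parameterizing the truncated
normal directly with these numbers would inflate the realized depletion G1
mean from 7.39 to about 7.88 h, which is why the moments are matched
instead.

**Capture.** Mothers are captured mid-cycle at treatment onset (t = 0):
each is assigned a stage (G1 or S) and a uniformly drawn remaining
fraction of that stage, so her birth lies before the observation window.
The stage composition defaults to 38.82% G1 / 61.18% S, the mixture for
which the stage-conditional quiescence probabilities (86.54% for the G1
group, 51.22% for the S group) reproduce an overall 64.93% daughter
quiescence. By default composition is assigned by a stratified quota
pattern — every cohort prefix of length m contains round(0.3882 m) G1
mothers — so a cohort's composition is a fixed property of the design, as
it is in an observed cohort, rather than a resampled random variable;
`stage_assignment = "bernoulli"` restores independent draws. The quota
pattern is also stable under cohort extension.

**Fate mechanism.** Fates are not drawn directly; they emerge from p21 at
birth crossing a quiescence threshold.

* G1-captured mothers accumulate p21 to a G2/M plateau
  $L = L_0\,\exp\{\lambda (t_{div} - \bar t) + \sigma_{bio} Z\}$, with a
  modest rise through G1, suppression in S, and the robust rise through
  G2/M. The exposure coupling $\lambda$ (default 0.06 h^-1) makes
  longer-exposed mothers accumulate more p21, which is what links daughter
  fate to the mother's time to mitosis.
* Each daughter inherits half the plateau times a pair-shared
  transmission factor (lognormal, sd(log) 0.09) times a per-sibling split
  asymmetry (lognormal, sd(log) 0.05). She is quiescent when the result
  exceeds a threshold set at the (1 − 0.8654) quantile of that composite
  distribution — computed once per configuration by a deterministic
  Monte-Carlo quadrature under a fixed internal seed. Because siblings
  share everything but the small split term, equal inheritance forces
  concordant decisions, and letting the split noise go to zero makes
  concordance exact.
* S-captured mothers stay low in p21 (plateau scaled by 0.2); their
  daughters accumulate p21 de novo, independently (lognormal, sd(log)
  0.5, with the same exposure coupling on the mother's division time),
  against the (1 − 0.5122) quantile threshold. Sibling fates are then
  independent coin flips at 51.22%, giving the $2p(1-p)$ discordance.
* Control cohorts and later depletion generations use the de-novo
  mechanism at the control rate (7.14%) or the S-group rate respectively.

The four p21 noise scales (biological sd(log) 0.245, transmission 0.09,
split 0.05, exposure coupling 0.06 h^-1) were calibrated once, jointly, so
that the *pipeline's* outputs on simulated cohorts reproduce the study's
reported lineage statistics — a mother–daughter window-mean correlation
near 0.79, a pooled concordant-sibling resemblance 1 − D near 0.90, and a
strong inverse binned proliferation-time relation — and then frozen. They
are deliberately not free dials: moving any of them changes all three
statistics at once.

**Traces.** Dividing cells follow piecewise-linear reporter waveforms with
the landmark structure described under phase calling; the Geminin and SLBP
waveforms fall from their peaks at the same slope they rose, so the peak
is locally symmetric and its sampled maximum is an unbiased boundary
estimator. The CDK2 ratio ramps linearly from the quiescent baseline 0.6
at birth to the mitotic peak 1.75 at division; quiescent daughters sit
flat at baseline while Cdt1 accumulates slowly and Geminin stays off.
Proliferating daughters degrade p21 from S entry with a 3-h half-life.
Measurement noise is multiplicative lognormal per frame and channel
(sigma 0.05 by default) — fluorescence intensities are positive and
heteroscedastic, so additive Gaussian noise would be the wrong model.

**Reproducibility.** Every cell owns an RNG substream derived by hashing
the cohort seed with the cell's lineage path, with a 10-draw burn-in after
seeding (the first outputs of freshly seeded Mersenne–Twister states are
measurably biased across many streams). Identical configurations therefore
produce byte-identical cohorts, and enlarging a cohort never reshuffles
existing cells. An optional induced-degradation scenario
(`condition = "p21_degradation"`) collapses p21 to undetectable within
about 2 h of the inducer time and lets CDK2 activity rise to a plateau
below the mitotic peak without division; it is qualitative and carries no
numeric target.

**What the generator does not emulate.** No cell death, no spatial
interactions, no mechanistic AMPK/p53 signalling dynamics, no
photobleaching or focus drift, and reporter waveforms are idealized
piecewise-linear shapes. Passing tests therefore demonstrate that the
pipeline recovers the statistical structure it is designed for — not that
it is robust to every artifact of real microscopy.

## Image rendering and quantification

The renderer draws each cell as a nuclear disk (radius 5 px at 0.55
µm/px) carrying the nuclear channel intensities, surrounded by a 2-px
cytoplasmic annulus carrying the cytoplasmic CDK2 signal, over a smooth
multiplicative illumination gradient plus an additive background, with
optional Gaussian read noise and Brownian cell drift. The "2-px ring" is
read as an annulus of width 2 px starting at the nuclear boundary — a ring
of 2 px *diameter* would be geometrically degenerate. Disk and ring pixel
sets are disjoint by construction, and the quantifier uses the same
geometry, so a noise-free rendered cell re-measures exactly.

Quantification proceeds per frame: the illumination surface is estimated
from the 20th percentile of 32-px tiles (robust to cell pixels), smoothed
with a symmetric-shrink 3x3 mean — which passes linear gradients through
unchanged, including at the borders — bilinearly interpolated with linear
extrapolation beyond the outer tile centers, and divided out; the global
background (median of sub-Otsu pixels) is then subtracted. Nuclei are
detected on the H1 channel with a Laplacian-of-Gaussian filter at
sigma = radius/sqrt(2) (scale-matched blob detection), keeping local
maxima above an Otsu-derived response threshold with a minimum separation
of twice the nuclear radius. Neither the LoG scale nor the threshold is
specified by the measurement conventions the package follows; both are
declared defaults. Frame-to-frame linking is greedy mutual-nearest-
neighbor under a displacement cap, with divisions recorded when a new
track starts next to an existing one — a deliberate simplification of
LAP-style tracking that is adequate at synthetic densities.

## Problem sizes and numerical choices

Acceptance-grade checks use cohorts of 500 mothers for phase-duration
recovery (several thousand completed phases), 500 mothers split evenly by
stage for the grouped fate fractions (about 500 daughters per group), a
140-mother unsynchronized depletion cohort trimmed to 265 classifiable
daughters, a 21-mother control cohort (42 daughters), and a 900-mother
G1-only cohort for the inheritance statistics (about 1,500
mother–daughter pairs and 700 concordant sibling pairs). These sizes keep
every analysis within seconds to half a minute on one CPU while holding
the seed-to-seed spread of each recovered statistic well inside its
tolerance band.

Numerical conventions: times serialize with 4 decimal places (0.36 s);
smoothing windows are odd and shrink symmetrically at trace ends; peak
ties break early; half-open phase intervals avoid double counting; the
moment-matching of truncated normals runs Nelder–Mead to a 1e-14 relative
tolerance; and the fate-threshold quadrature uses 2e5 draws under a fixed
internal seed, making thresholds deterministic functions of the
configuration.

## Known limitations

Sibling fates in the G1 group are strongly correlated by construction, so
a quiescent *fraction* over n daughters has roughly half the effective
sample size a binomial model assumes; tests that check convergence of
fate fractions use the sibling pair as the independent unit. The phase
caller assumes the four reporters are all present and roughly in their
canonical shapes; it does not attempt mitotic substaging, and its
behaviour on reporters with non-monotone artifacts (e.g. strong
photobleaching) is untested. The mutual-NN linker will mis-link at cell
densities or speeds where assignment becomes combinatorial; it is not a
replacement for LAP tracking on real data.
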