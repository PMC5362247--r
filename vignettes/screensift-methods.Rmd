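---
title: "Methods: scoring, filtering and kinetics in screensift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, filtering and kinetics in screensift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensift)
```

## The experimental design being modelled

screensift analyses *rescue screens*: an siRNA library (pools of four siRNAs
per gene) is transfected into cells carrying an inducible lethal transgene
(for example doxycycline-inducible DUX4), the lethal stimulus is switched on,
and viability is read out per well by an ATP-dependent luminescence assay.
Non-rescued wells collapse to a few percent of the uninduced signal; a pool
that protects cells stands out as a bright well. Three sources of
false-positive calls dominate such screens and each gets a dedicated filter:

1. **Off-target pools** — one siRNA in the pool rescues through an unintended
   target. Detected by *deconvolution*: retest the four siRNAs individually.
2. **Induction inhibitors** — the pool blocks the inducible expression system
   itself rather than the death pathway. Detected by a *counter-screen* in a
   matched cell line where the same promoter drives a neutral reporter
   (luciferase): pools that depress the reporter are removed.
3. **Non-expressed targets** — a "hit" against a gene the cell does not
   express cannot be on-target. Removed by an RNA-seq expression floor.

## Scoring model

**Plate normalization.** Each 384-well plate is normalized by the *median
method*: every sample-well signal is divided by the median of the sample-well
signals on its plate. Control wells are reported on the same scale but never
enter the median. The ratio is dimensionless and invariant to per-plate
multiplicative scale (reader gain, reagent lot, cell number), which is the
dominant plate artefact for luminescence. An additive mode (signal minus
plate median) exists behind a flag for sensitivity analysis; it is *not*
scale-invariant, and a property test pins down that directional difference.

**Robust Z.** For each replicate, all sample-well ratios across the
experiment are standardized as

$$Z_i = \frac{x_i - \mathrm{median}(x)}{1.4826 \cdot \mathrm{MAD}(x)},$$

with the raw median absolute deviation and the usual normal-consistency
constant 1.4826. Median/MAD rather than mean/SD because a screen's whole
point is its outliers. The location and scale are experiment-wide per
replicate (the library is randomized across plates, so the experiment-wide
null is the better-estimated one); per-plate scaling is available via
`scope = "plate"`. Zero MAD is a hard error — a degenerate plate should
never silently produce infinite scores.

**Replicate summary.** Pools are screened in triplicate; the reported score
is the arithmetic mean of the per-replicate Z (with min and max retained),
and the *fold rescue* is the mean normalized ratio. Pools measured in fewer
replicates are flagged `n=k` rather than dropped.

## The filter cascade

`run_cascade()` applies, in order, with bookkeeping at every stage:

| stage | rule | comparator |
|---|---|---|
| primary hits | mean Z at or above `z_enhancer` (default 3.0) | inclusive `>=` |
| counter-screen | counter Z at or below the cutoff is eliminated | inclusive `<=` |
| expression | gene passes if expressed above `min_fpkm` (default 0.5) | strict `>` |
| deconvolution | only on-target classes pass, when results are supplied | — |

The comparator directions follow the field's reporting conventions
("Z-score of 3.0 or greater", "cutoff of at most -0.5", "greater than an
FPKM of 0.5"); sensitizers are strict (`<` the negative threshold).

The counter-screen cutoff defaults to the **minimum Z of the scrambled
controls** run in the counter-screen (`counterscreen_threshold()`): a pool is
only suspicious if it depresses the reporter more than every non-silencing
control did. Candidates that were never counter-screened are retained and
flagged `untested` rather than dropped — typically only pools above a lower
Z bound are retested, and absence of evidence is not elimination.

The expression rule is **pass-if-either-condition exceeds the floor**
(`max(FPKM_uninduced, FPKM_induced) > min_fpkm`): genes strongly induced by
the stimulus itself can be silent at baseline yet be genuine mediators, so an
uninduced-only rule would discard exactly the most interesting class. An
`overall_mean` mode is available.

Filtering runs at pool level through the counter-screen and collapses to gene
level (best pool per gene by mean Z) before the expression filter, since a
gene may own several pools (e.g. isoform-specific pools) and is reported once.

`screen_correlation()` reports the Spearman rank correlation (average ranks
on ties) between primary and counter-screen Z on their shared pools — a
negative correlation diagnoses systematic coupling between "rescue" and
induction inhibition.

## Deconvolution rules

A pool is classified from its per-siRNA fold rescues (relative to the
non-silencing control under induction) at an inclusive 2-fold threshold:

* `on_target_multi` — at least two siRNAs rescue at `>= rescue_fold`;
* `single_dominant` — exactly one rescues: an off-target suspect, eligible
  for the synergy test;
* `no_rescue` — none rescue.

The **synergy test** pools the three individually non-rescuing siRNAs and
retests them once: if that triple pool reaches the rescue threshold
(inclusive), independent weak on-target activities are synergizing and the
pool is upgraded to `on_target_synergy`; otherwise it stays
`single_dominant`. The threshold for the triple pool is configurable because
published designs do not pin a separate number; we reuse `rescue_fold`.
Classification is permutation-invariant in the fold vector and monotone:
raising any single fold can only promote a pool in the order
`no_rescue < single_dominant < on_target_{synergy,multi}`.

## Decay kinetics

Transcription-shutoff time courses (e.g. after DRB, an RNA-polymerase-II
inhibitor) are quantified by standard relative qPCR:
$\mathrm{abundance}(t) = 2^{-\Delta\Delta C_t}$ against a reference RNA
(18S rRNA — a polymerase-I transcript, hence untouched by the shutoff), with
the $t=0$ point anchored at exactly 1. The decay fit is **ordinary least
squares of $\ln(\text{abundance})$ on time** — the classical semi-log plot —
giving $k = -\text{slope}$ and $t_{1/2} = \ln 2 / k$, with $R^2$ in log
space (clamped to $[0,1]$ with a flag). Slopes within $10^{-6}$/min of zero,
or rising series, are reported as *non-decaying* rather than errors:
stabilized transcripts are a result, not a failure. Protein decay from
densitometry after translation shutoff uses the same code path. A nonlinear
exponential fit (`method = "nls"`) exists for comparison; log-OLS is the
default because it is the method the semi-log convention implies and it is
exactly recoverable (a noiseless exponential yields $k$ to $10^{-10}$).

On a fixed 0–120 min sampling window the estimator's precision degrades for
long half-lives: $\mathrm{se}(k) = \sigma/\sqrt{S_{xx}}$ is constant in $k$,
so the relative error grows as $k$ shrinks. With 7 points and 5% CV the
median relative half-life error is a few percent up to $t_{1/2} \approx 60$
min but about 8% at 180 min and above 15% at 360 min; the property suite
asserts these derived bounds, and this is why long half-lives reported from
short shutoff windows should be read as order-of-magnitude.

## The synthetic world

`simulate_screen()` generates the stated screen, not a tunable toy:

* 384-well plates: 352 sample wells, 16 scrambled controls (column 23), 4
  positive-control wells, 12 empty; one plate set shared across 3 replicates
  (a replicate is the same plate re-measured with fresh noise).
* `kill_fraction = 0.047`: induced viability of non-rescued wells as a
  fraction of the uninduced baseline, anchored to the published scrambled
  control level (4.7% of the no-induction control).
* Planted classes: 2% `true_rescuer` (survival uniform on 0.30–0.75,
  matching the validated-hit range), 1% `offtarget_single`, 1%
  `dox_inhibitor` (reporter depressed to 10–50% in the counter-screen),
  remainder null. 10% of genes are low-expressed (FPKM < 0.5 in both
  conditions), drawn from the non-rescuer classes: a gene that is not
  expressed cannot mediate an on-target rescue, so planting unexpressed
  "true" rescuers would only measure a self-inflicted contradiction.
* Signal model: `baseline x plate_factor x viability x noise` with a
  lognormal per-plate factor (sdlog 0.10) and multiplicative lognormal well
  noise (CV 0.10 by default; luminescence is strictly positive and
  CV-stable, which is why the noise is multiplicative). The screen-wide CV
  is not published; 0.10 is this package's choice and the deconvolution
  suite exercises 0.10–0.15.
* Positive controls are set to survival 1.0 (normalized ratio ~21). The two
  published control anchors — scrambled viability 4.7% and a
  positive-control normalized ratio of 80 — are mutually inconsistent if
  the ratio is survival/kill, implying a plate-median well viability of
  ~1.25%, below the scrambled level; rather than model that second, unstated
  baseline, the simulator caps survival at the uninduced level.
* Expression is noiseless in the simulator, so elimination of planted
  low-expression genes is deterministic (rate 1.0).

Everything is seeded (`seed` is mandatory, Mersenne-Twister with inversion
normals), and identical seeds give byte-identical written bundles.

**What a green test does not establish.** The simulator has no spatial/edge
gradients, no transfection-efficiency variation, no correlation between the
primary and counter screens beyond the planted inhibitor class (so the
screen-wide Spearman rho is ~0 here, unlike a real screen pair), and its
class effects are well separated; recovery at sensitivity >= 0.9 / FDR <=
0.1 under these conditions validates the pipeline's logic and bookkeeping,
not the discriminative power of any particular real screen.

A structural property of the minimum-of-controls cutoff is worth knowing:
the minimum of 16 control Z-scores sits in the tail of the null
distribution, so a nontrivial fraction of genuinely null counter-screen
scores fall below it by chance — in the simulator this false elimination is
the main limiter of cascade sensitivity (and in a real screen it trades
sensitivity for protection against induction artefacts in exactly the same
way).

## Numerical choices and degenerate inputs

* Even-count medians (and the MAD's inner median) use the average of the two
  middle values.
* Zero MAD, plates without sample wells, non-positive plate medians,
  mismatched time grids, non-positive abundances and short series are hard
  errors with named context, never silent NA/Inf propagation.
* Well addresses tolerate leading zeros on input ("A01") and canonicalize
  without them; output is tab-separated UTF-8 with numbers formatted at 15
  significant digits, which makes write/read/write round trips byte-stable.
* FDR is defined as 0 when no positives are called.
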