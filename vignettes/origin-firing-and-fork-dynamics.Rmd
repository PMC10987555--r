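---
title: "Quantifying origin firing and fork dynamics from EdU-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying origin firing and fork dynamics from EdU-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliquant)
```

## The measurement

EdU-seq marks nascent DNA with the thymidine analog EdU and sequences it.
When cells are released from mitosis into S phase in the presence of
hydroxyurea (HU), dNTP pools collapse and replication forks stall within a few
tens of kilobases of the origins that fired, so EdU-seq signal piles up in
narrow peaks at fired origins: peak height is a proxy for the fraction of
cells in which that origin fired (its *firing efficiency*). Removing HU lets
forks resume; harvesting at increasing times after release, with an EdU pulse
before each harvest, converts the same assay into a fork-progression readout:
signal moves outward from origins at the fork speed.

`repliquant` implements the quantification stack for these designs on a
binned genome (10 kb bins by default), plus the companion single-molecule
(DNA combing) and cytological (MiDAS EdU foci, 53BP1 bodies) analyses.

## The sigma statistic

Raw per-bin EdU counts are first normalized against deep sequencing of
genomic DNA from the same cells: for bin $b$,

$$\mathrm{norm}_b = \frac{s_b}{c_b}\,\tilde c,$$

where $s_b$ and $c_b$ are sample and control counts and $\tilde c$ is the
median control count over reliable bins (the rescaling keeps values on the
count scale). This removes library bias and the per-bin fraction of masked
(unmappable) sequence. Bins whose control count falls below 25% of the median
control are masked outright — the quotient is unstable there — and masks
propagate through all downstream arithmetic.

The *sigma value* of a bin is its normalized count divided by the standard
deviation of the background:

$$\sigma_b = \mathrm{norm}_b / \sqrt{\lambda},$$

with $\lambda$ the central-50% trimmed mean of the unmasked normalized counts
(the trimming keeps origin peaks out of the background estimate) and
$\sqrt\lambda$ its Poisson standard deviation. Sigma is deliberately **not**
mean-centred: background bins fluctuate around $\sqrt\lambda$ with unit-scale
noise, and peak heights read in count-noise units. Published sigma tracks
produced by other implementations may differ by a monotone rescaling, since
the original scripts' exact estimator is not public; every comparison this
package makes (fold-changes, correlations, profile widths) is invariant to
such a rescaling.

The *adjusted sigma* of a release timepoint is the per-bin difference from
the matched 0-min (no-release) sample, $a\sigma_b = \sigma_{t,b} -
\sigma_{0,b}$, which cancels the background and the HU-arrest peaks and
isolates post-release synthesis. Subtraction (rather than a ratio) preserves
units and makes the 0-min track identically zero.

## Origin calling, efficiency and classes

Under HU arrest peaks are narrow, so origins are called as runs of at least
`min_run = 2` consecutive unmasked bins with $\sigma \ge \sqrt\lambda + 3$;
runs separated by a single sub-threshold bin are bridged, and each run
reports one summit at its maximal bin. The per-origin firing efficiency is
the maximum sigma within one bin of the summit (floored at 0) — a height, not
an area, because stalled forks travel little and published efficiency axes
are in sigma units.

Origins are classified by the fold-change of efficiency under Cyclin E
overexpression (OE) versus normal expression (NE), with a pseudocount to
stabilise near-zero denominators:

$$\rho = \frac{\mathrm{eff}_{OE} + 1}{\mathrm{eff}_{NE} + 1};\qquad
\rho \ge 4 \Rightarrow \text{Oi};\quad 2 \le \rho < 4 \Rightarrow
\text{intermediate};\quad \rho < 2 \Rightarrow \text{CN}.$$

Cross-sample agreement (e.g. parental versus mutant clones) is summarized per
class by Pearson correlation of paired efficiencies (Spearman is also
reported), excluding and counting origins masked in either sample.

## Fork progression from metagene profiles

For each release timepoint, the adjusted-sigma track is averaged over windows
of $\pm 300$ kb around origin summits. The profile's spatial extent is
summarized by its full width at half maximum: the distance between the
outermost points where the profile crosses half its maximum, by linear
interpolation. Two numerical details matter:

* **Baseline.** The half level is measured above a far-field baseline (the
  median of the outermost 20% of offsets, floored at 0). On profiles that
  decay to zero this is the ordinary FWHM; on real metagenes it prevents
  signal from *neighbouring* origins inside the window from masquerading as
  peak width.
* **Outermost crossings.** Release profiles develop a central trough (the
  0-min subtraction removes the origin-proximal signal), so the width is
  taken between the outermost crossings, not around the global maximum.

Each origin feeds two divergent forks, so the per-fork progression rate is

$$v = \frac{\Delta \mathrm{FWHM} / 2}{\Delta t},$$

estimated from two timepoints directly or as a least-squares slope with more,
with a bootstrap over origins (the window matrix is resampled jointly across
timepoints) for confidence intervals.

## Fiber and MiDAS statistics

DNA combing reports per-molecule CldU/IdU track lengths; IdU lengths after HU
release convert to rates as `length (um) x 2.0 kb/um / 40 min` (both factors
are parameters; 2.0 kb/um is the standard stretching constant for combed DNA,
which the source figures never state because they plot lengths). Groups are
compared by two-way fixed-effects ANOVA (genotype, condition, interaction)
with Fisher's LSD — classical unprotected pairwise $t$ tests on the pooled
residual mean square — and the usual significance tiers (`*` P<0.05 ...
`****` P<0.0001). Quantiles in summaries use the type-7 (linear
interpolation) definition, the common plotting default.

MiDAS positivity is the fraction of mitotic cells with at least 2 EdU foci;
53BP1-body fractions use a threshold of 1 body. Replicate fractions are
compared by two-way ANOVA with Tukey's HSD on genotype-by-treatment cells;
when the residual mean square is exactly zero (identical replicates) the
degenerate limit assigns p = 1 to zero differences. MiDAS-seq signal over a
region set is rescaled region-by-region to a common relative axis (linear
interpolation to 100 positions, flanks of 50% of the span — the flank size is
a free choice, not stated in the source design) and averaged; heatmap rows
order double-peak regions by genomic size (descending, ties by position) and
single-peak regions by their maximum sigma (switchable to the mean).

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground truth
from a single `sim_config()`. What it emulates:

* a 2-chromosome, 10 Mb genome of 10 kb bins (1,000 bins) with 50 origins —
  desk-scale in seconds;
* a genomic-DNA control with lognormal bin-to-bin mappability bias
  (sd 0.15) and 2% unmappable bins, sequenced deep (1,200 reads/bin)
  relative to the EdU background (400 reads/bin), as real gDNA controls are;
* per-origin NE efficiencies planted **on the raw sigma scale**
  (uniform 25–60, i.e. 5–40 sigma above the background level
  $\sqrt{400}=20$), with class fold-changes 1x / 3x / 6x applied on the same
  scale — matching how origins were classified in the source studies (by
  their sigma values) — and class fractions of one sixth Oi, one sixth
  intermediate;
* rectangular HU-arrest peaks of half-width 30 kb (fork travel under HU; a
  free parameter, chosen so peaks span a few bins and width tests are exact);
* mildly overdispersed negative-binomial counts (dispersion 0.002, i.e.
  variance $\mu(1 + 0.002\mu)$; set 0 for Poisson oracle tests) and a
  noise-free mode returning expected counts for exact end-to-end checks;
* release timecourses in which forks resume at the HU-arrest boundary and a
  30-min EdU pulse labels `hu_travel + v(t-30) .. hu_travel + v t` on each
  side of every fired origin; each sample carries a fixed total EdU signal
  mass split over fired origins (a fixed sequencing budget), so fewer fired
  origins concentrate more signal each;
* an optional dNTP-coupling regime, `v = v_base (n_fired/n_origins)^{-c}`,
  emulating dNTP-limited fork progression: with `c > 0` and fewer fired
  origins, forks run faster and per-origin release amplitude rises;
* truncated-normal fiber rates with measurement noise, Poisson EdU-foci
  counts, and MiDAS regions with edge-weighted (double-peak) or centred
  (single-peak) signal.

Everything is deterministic given the config seed: each generator derives its
own stream, and separate calls rebuild the same shared truth (bias field,
origin catalog, region set), so the control and every EdU track cancel
exactly under normalization in the noise-free mode.

### Problem sizes and layouts used in validation

Origin-calling, classification and correlation checks run on the default
layout (50 origins, minimum spacing 100 kb). Fork-progression checks use a
**sparse layout** (20 origins, minimum spacing 300 kb) on the same genome:
with 50 origins, release rings at 1.5 kb/min and 90 min cover nearly half the
genome, every 0.6 Mb window contains several origins' forks, and no width
functional of the mean profile identifies the speed — a genuine
identifiability limit of the dense desk-scale layout, not of the estimator.
At real-genome origin density a 0.6 Mb window is dominated by its own origin,
which the sparse layout reproduces. For the dNTP-regime comparison the
metagene is averaged over each genotype's *fired* origins (the locus set is a
parameter): under a fixed sequencing budget, averaging over all catalog
origins cancels the concentration effect exactly, whereas per-fired-origin
averaging isolates what the comparison is about — per-fork recovery.

The LSD calibration uses 1,000 replications of a 2x2 design with n = 10 per
cell; the power check uses two groups of 50 separated by 3 pooled standard
deviations.

### What passing tests do and do not show

The generator plants the *mechanisms* the pipeline must recover (shared
mappability bias, efficiency fold-changes, outward-moving label rings,
region-confined MiDAS signal) but idealizes much of real data: peaks are
rectangles, background is homogeneous, replication timing structure, GC bias,
copy-number variation and fragile-site clustering are absent, and origin
efficiencies are independent of position. Passing tests therefore validate
the estimators and their calibration, not robustness to every artifact of
real sequencing data. Two further caveats: sigma magnitudes are comparable
only within this package's estimator (see above), and with only ~8 origins in
the small classes the per-class correlation of a replicate pair is itself a
noisy statistic — its sampling spread is visible across simulation seeds.

## Degenerate inputs and tie-breaks

Masked bins propagate as the union of masks; an origin whose whole summit
neighbourhood is masked reports a missing efficiency and is excluded (and
counted) from correlations. Peak ties within a run resolve to the first
maximal bin (`which.max`). Windows at chromosome ends contribute only their
in-bounds offsets, with per-offset counts tracked. `compute_sigma` refuses
fewer than 50 unmasked bins; `estimate_progression` refuses fewer than two
timepoints; ANOVA helpers refuse groups below n = 3 (fibers) or 2 replicates
per cell (fractions), and a design with an empty cell falls back to one-way
ANOVA with a warning.
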