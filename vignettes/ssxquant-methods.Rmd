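---
title: "Quantification methods for spike-in calibrated chromatin profiling and imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for spike-in calibrated chromatin profiling and imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssxquant)
library(dplyr)
```

ssxquant implements the quantification procedures used to study how SSX
fusion oncoproteins (such as SS18-SSX in synovial sarcoma) read and reinforce
the Polycomb-deposited H2AK119ub1 chromatin mark: spike-in calibration of
CUT&RUN and native ChIP signal, peak-centered signal matrices and
log2-ratio clustering, per-nucleus immunofluorescence statistics keyed to an
eGFP reporter, foci co-localization scoring, NanoBRET proximity statistics,
and salt-fractionation distributions. Every assay has a seeded synthetic-data
generator with recorded ground truth, so each statistic can be validated by
recovery rather than by comparison to irreproducible wet-lab data.

## Spike-in calibration

Global changes in a chromatin mark are invisible to library-size
normalization: if a knockout halves the mark everywhere, per-million scaling
of each sample simply renormalizes both conditions to the same total and the
loss disappears. Spiking a fixed amount of exogenous chromatin (e.g.
*E. coli* or *Drosophila*) into every sample provides an internal scale that
survives sequencing-depth differences.

Two schemes are implemented, matching the two assays they serve.

**Fraction-based scaling (CUT&RUN).** For sample $x$, let $N_x$ be the
fraction of uniquely aligned reads that map to the spike-in genome
(`spikein_fraction()`). The per-sample factor is

$$\mathrm{factor}_x = N_{\min} / N_x,$$

where $N_{\min}$ is the smallest spike-in fraction in the group, so the
reference sample has factor exactly 1 and all factors lie in $(0, 1]$.
Because $N_x$ is a *fraction*, it carries no depth information: the factors
correct spike-in composition only. `ssxquant` therefore applies them to
depth-normalized coverage (`normalize_track()`, signal per million aligned
reads). With that convention the spike-in-attributed signal
($N_x \times$ scaled per-million depth) is equal across samples, and in the
generative model below the calibrated condition ratio at a peak equals the
true retention factor exactly in expectation. Applying fraction-based
factors to raw-count tracks of unequal depth would leave the depth confound
in place, which is why the pairing of factor and normalization is part of
the contract here.

**Alpha-normalized downsampling (calibrated native ChIP).** Each IP sample is
paired by (group, condition) with its input, and the raw factor is

$$\mathrm{raw}_x = \frac{1}{N(\mathrm{IP\ spike})} \times
  \frac{N(\mathrm{input\ spike})}{N(\mathrm{input\ primary})},$$

with all three quantities read *counts*. A per-group coefficient $\alpha$
(the reciprocal of the largest raw factor) rescales the factors so the
largest equals exactly 1. The $1/N(\mathrm{IP\ spike})$ term is an inverse
count, so these factors *do* correct depth and are applied directly to raw
counts — by multiplication (`apply_factor()`) for continuous tracks, or by
seeded binomial thinning (`downsample_counts()`), which mirrors read-level
downsampling at the count level (each read is kept independently with
probability equal to the factor). Replicates are combined by summing thinned
counts after per-replicate factors. Numerically, final factors are computed
as $\mathrm{raw}_x / \max_x(\mathrm{raw}_x)$ rather than
$\alpha \cdot \mathrm{raw}_x$, so the reference factor is exactly 1 in
floating point.

Ambiguities resolved here (and tested): $N_x$ is used as a fraction in
$[0,1]$ — the ratio $N_{\min}/N_x$ is identical whether percentages or
fractions are used; multi-mapping reads never enter any count; an IP with
zero spike-in reads or with zero or multiple matching inputs is an error,
never a silent choice; IgG controls, when listed, are treated as ordinary
samples.

## Peak-centered signal matrices and derived summaries

`signal_matrix()` builds the regions x bins matrix behind reference-point
heatmaps: a ±10 kb window around each peak midpoint
(`floor((start + end)/2)`, 0-based), split into 50-bp cells, each cell the
mean per-base track value over its span (both window and bin width are
arguments). Coordinates are BED-style 0-based half-open throughout; strand is
ignored (the peaks are unstranded). Windows that extend past a reference edge
are zero-padded and the affected rows flagged rather than dropped, keeping
the matrix rectangular. Rows are ranked by increasing mean over the full
window (`rank_rows()`, stable, ties broken by region id); whether published
heatmaps rank on the full window or a central one is not documented, so the
full-window mean is used and stated here.

Per-region scores (`region_scores()`) are the mean per-base signal over the
peak body. Condition contrasts use
`log2_ratio()` $= \log_2((a + c)/(b + c))$ with pseudocount $c$ (default 1 on
the binned-count scale; it bounds ratios at empty regions and is
configurable — recovery analyses on depth-normalized scores use a smaller
value, e.g. 0.01, matched to that scale). `kmeans_cluster()` splits per-region
ratios into populations (default $k = 2$, depleted vs retained — $k$ is a
parameter, as the published analysis does not state one) using Lloyd
iterations from k-means++ seeds, best of `restarts` runs by within-cluster
sum of squares, fully deterministic given its seed. `spearman_matrix()`
rank-correlates tracks over summary bins (default 10 kb, configurable; the
original summary bin is not documented) with average ranks for ties;
constant tracks have undefined rank correlation and are reported `NA` with a
warning.

Internally all window means come from one cumulative-sum integral of the
binned track, so matrix cells, region scores and re-binning share a single
length-weighted-averaging definition; tests compare each against independent
per-base loops.

## Per-nucleus immunofluorescence statistics

Nuclei are segmented from the DAPI channel by Li minimum cross-entropy
thresholding. `li_threshold()` minimizes

$$\eta(t) = -\big(A_b(t)\log\mu_b(t) + A_f(t)\log\mu_f(t)\big),$$

where $A$ and $\mu$ are the summed and mean intensities of background
($\le t$) and foreground ($> t$). The default solver scans every distinct
intensity with cumulative sums and returns the exact global minimizer; the
classical fixed-point iteration
$t \leftarrow (\mu_b - \mu_f)/(\log\mu_b - \log\mu_f)$ is available as
`method = "iterative"` and agrees on well-separated histograms, but can stop
in a local minimum on adversarial ones, so the exact scan is the contract.
The criterion is scale-equivariant: rescaling the image by $c$ rescales the
threshold by exactly $c$.

Segmentation takes 8-connected components above the threshold (4-connectivity
available), drops components below `min_area` (default 50 px) and renumbers
labels contiguously. Touching nuclei are not split (no watershed); the
synthetic generator places non-overlapping nuclei, so validation does not
exercise that failure mode — a stated limitation for crowded real images.

`measure_nuclei()` records each nucleus's mean intensity per channel, then
divides every channel mean by that nucleus's DAPI mean ("DAPI
normalization"), the assumption being that DAPI content is approximately
constant across nuclei. No background subtraction is applied before
normalization (none is part of the published procedure); an optional flag is
deliberately absent rather than silently defaulted. Nuclei are classed
eGFP-high when normalized eGFP exceeds 1, low otherwise; a value exactly 1
is assigned low (the published rule, "> 1 or < 1", leaves equality
unassigned, so the tie rule is declared here). The headline statistic
(`high_low_ratio()`) is the ratio of class means of the DAPI-normalized
marker intensity; it is invariant to uniform rescaling of the marker channel
and of all channels jointly, which the tests assert. The tissue-section
variant (`dapi_ratio_per_nucleus()`) reports marker/DAPI per nucleus plus
the group mean.

`dab_mean_od()` implements mean DAB nuclear optical density on a
single-channel brightfield proxy, $\mathrm{OD} = \log_{10}(I_0/\max(I, 1))$
with a user-supplied white point $I_0$ (default: image maximum); full color
deconvolution is out of scope and the proxy is stated as such.

## Foci co-localization

Published co-occurrence scoring of marker foci against tether (anchor) foci
is visual; `foci_overlap_pct()` operationalizes it: a query focus counts as
overlapping when its centroid lies within an anchor mask dilated by a match
radius (default: the mean anchor radius). The score is
$100 \times \mathrm{matched}/\mathrm{total}$ and is monotone nondecreasing in
the match radius. `detect_foci()` (threshold at an intensity quantile,
components within area bounds) is an automated stand-in for manual focus
selection.

The generator gives each anchor exactly one query-channel focus that either
co-occurs (probability `overlap_prob`, jittered within the anchor) or is
displaced beyond the dilated anchor radius; displaced foci are
rejection-sampled away from all anchors so the measured overlap fraction is
an unbiased binomial estimate of `overlap_prob`. If non-partnered anchors
produced no query focus at all, the query-set overlap would trivially be
100%; the displacement design is what makes the statistic informative.

## Plate assays

NanoBRET: per well, the raw ratio $BU$ is acceptor emission (620 nm filter)
over donor emission (450 nm filter); $\mathrm{mBU} = 1000 \times BU$; the
condition value is the mean of the +ligand wells minus the mean of the
no-acceptor (−ligand) control wells. Two technical replicates per arm is the
standard design; any number is accepted. The statistic is invariant to a
shared gain on both emissions and linear in acceptor gain.

Salt fractionation: per-fraction band intensities (maximum intensity per
band, accepted as given numbers) are expressed as percentages of their sum
across the five fractions (80/150/300/500 mM NaCl, then chromatin), so the
result is invariant to global blot exposure.

## The synthetic-data generators

All generators draw every random quantity from one seeded stream
(Mersenne-Twister via an internal `with_seed()`, which restores the caller's
RNG state), so identical seed and configuration give byte-identical outputs
— including written files, whose numeric formatting is fixed at 6
significant digits.

**Spike-in experiment.** A single toy reference (`chrT`) carries
non-overlapping peaks placed one per genome slot; per-base peak enrichment is
Gamma(3, 1) over a uniform background holding 10% of IP material
(`peak_mass_frac = 0.9`). Spike-in material is a constant 5% of condition-A
IP material — constant *per cell* across conditions, which is the physical
premise of spike-in calibration. Condition B scales depleted peaks by the
retention factor before resampling, and its sequencing depth carries a
confound (default 2x). Reads are then drawn hierarchically: spike-in reads
binomially from the sample depth, primary reads multinomially over bins.
The headline configuration (retention 0.3, all peaks depleted, 2x depth,
10,000 peaks) follows the validation scenario; the 50 Mb default reference
is sized so 10,000 peaks of 0.5–2 kb fit without overlap. Because peak
bodies also contain ambient background, the calibrated per-peak ratio sits
slightly above the pure retention factor (about +0.02 at the defaults) —
this is a property of the score definition, not of the calibration, and
stays well inside the 10% recovery tolerance. Read-level artifacts (PCR
duplication, mappability) are deliberately not modeled; alignment is out of
scope, so generators emit count summaries and binned coverage directly.

**Nuclei images.** Non-overlapping disk nuclei (rejection-sampled with a
2-px gap so 8-connected components never merge) on a uniform background;
16-bit intensities. Per-nucleus DAPI levels vary with 10% CV; normalized
eGFP is 3 for the high class and 0.2 for the low class (straddling the
cutoff of 1 with margin); the marker sits at 0.8 x DAPI, times `marker_fold`
in high nuclei. Per-pixel Gaussian noise has SD equal to 5% of local signal
by default. Noise models for any of these assays are not published;
these defaults are declared choices of plausible magnitude, not claims about
the original data. Consequences for interpretation: recovery tests validate
the estimators under this noise model — they do not certify performance on
images with uneven illumination, overlapping nuclei or autofluorescence.

**Foci fields, BRET plates, salt profiles.** As described above; the BRET
generator inverts the mBU formula exactly at zero noise (+ligand
$BU = \mathrm{baseline} + \mathrm{mBU}/1000$), and the default salt weights
(0.10, 0.15, 0.15, 0.10, 0.50) describe a chromatin-dominant protein, the
regime of interest for a chromatin-bound factor; published percentages for
the corresponding figure are not available in text form, so these weights
are a declared scenario.

## Numerical choices and degenerate inputs

* Tracks validate length = `ceil(seqlength / bin)`; re-binning is
  length-weighted averaging, exact at partial last bins.
* A constant image has no Li threshold (error), an empty supra-threshold
  mask is a valid zero-label map with a warning, a nucleus with nonpositive
  DAPI mean is dropped with a warning, and an empty eGFP class makes the
  high/low ratio an error rather than `NaN`.
* Overlapping bedGraph intervals, malformed BED lines (reported with line
  numbers) and role-less sample tables are errors at read time.
* k-means with $k = 1$ returns the global mean directly; $k$ greater than
  the number of regions is an error. Ties in ranking break on region id so
  orderings are reproducible.
* TIFF channel roles are always taken from an explicit channel map, never
  guessed from metadata.

## Validation scale

The shipped tests validate recovery at moderate problem sizes chosen to keep
the suite fast while leaving sampling error far below the tolerances being
checked: 10,000 peaks over 50 Mb for the headline calibration scenario
(2,000 peaks over 10 Mb for clustering), 200 nuclei per image with 10 seeds
for the eGFP ratio, 500 anchors for foci overlap, 100 random 64x64 images
for the Li threshold oracle, and 100 simulated plates for the BRET
Monte-Carlo mean. `scripts/acceptance.R` re-runs the same analyses from
scratch at these sizes and writes the resulting statistics as JSON.

## Known limitations

* The spike-in model draws reads per bin, not per fragment; fragment-length
  effects and duplicate structure are absent.
* No watershed splitting of touching nuclei; the segmentation is only as
  good as Li thresholding on well-separated DAPI signal.
* The DAB statistic uses a single-channel proxy with a user white point, not
  color deconvolution.
* Foci "co-occurrence" is a declared centroid-within-dilated-mask rule; the
  original scoring was visual and has no stated distance criterion.
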