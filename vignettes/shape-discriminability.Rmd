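---
title: "From pixels to behavior: methods behind the shape-discriminability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pixels to behavior: methods behind the shape-discriminability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Rats trained in a visual water maze can discriminate some pairs of simple
shapes almost perfectly while other pairs stay near chance. At the same time,
populations of neurons recorded along the lateral visual hierarchy — primary
visual cortex (V1) and the extrastriate areas LM, LI, LL and TO — carry
different amounts of information about the same shape pairs. `ratvision`
implements the full analysis chain that asks *where* along this hierarchy
neural discriminability stops looking like raw image similarity and starts
looking like the animals' behavioral difficulty:

1. render the six binary shape stimuli and measure their physical
   dissimilarity (pixel differences, PIX, and a simulated-V1 filter-bank
   measure, V1Sim);
2. decode shape identity from spike-count tables with a resampled linear
   readout, pair by pair;
3. score water-maze trial logs into per-pair accuracies;
4. quantify the correspondence between the neural, physical and behavioral
   six-pair profiles with chi-square and Pearson statistics under a
   derangement permutation null, and summarize the V1-to-TO shift in a single
   transformation index

$$H = [Z(\mathrm{TO},\mathrm{Beh}) - Z(\mathrm{TO},\mathrm{Pix})]
    - [Z(\mathrm{V1},\mathrm{Beh}) - Z(\mathrm{V1},\mathrm{Pix})],$$

where $Z$ is the Fisher-transformed sample Pearson correlation between two
six-pair profiles. Positive $H$ means discriminability is pixel-aligned at
the bottom of the hierarchy and behavior-aligned at the top.

Because the underlying recordings and trial logs are not public, the package
ships a synthetic-data generator whose representational geometry is under
experimental control; every statistic can therefore be exercised — and its
recovery properties verified — end to end.

## Stimulus model

The six glyphs (square, diamond-in-a-square, triangle, letter lambda, letter
H, plus) are drawn as outline strokes on a black 768 x 1280 canvas at
1280/102 ≈ 12.55 px/deg, the geometry of the recording display. Only three
facts constrain the renderings: the mean bounding-box width is 27.3 deg with
per-shape widths between 23 and 33 deg, white-pixel counts are equalized
across shapes, and the background is black. Everything else is package
design, chosen once:

* **Width assignment.** Glyphs that share skeleton strokes get equal widths
  (square = diamond-in-square = H = 24 deg; triangle 27, lambda 31.8, plus
  33; mean exactly 27.3). In the original line drawings the
  diamond-in-a-square *contains* the square and the plus shares its
  horizontal bar with the H crossbar; equal widths make those shared strokes
  coincide on the pixel grid. Without this, outline shapes at six different
  scales overlap almost nowhere and the pixel measure degenerates to a
  near-constant vector.
* **Stroke width.** The base stroke is 30 px (≈ 2.4 deg), comfortably above
  the rat acuity cutoff implied by the 20 px low-pass below, and is the free
  parameter for luminance equalization.
* **Luminance equalization.** White counts are equalized to the median count
  of the initially rendered set. Because axis-aligned stroke boundaries cross
  whole pixel rows at once, a plain bisection on stroke width cannot land
  within 1%; instead each shape's threshold on the distance-to-skeleton field
  is set to the target-count order statistic, with ties broken in stable scan
  order, so every shape has *exactly* the target count. The skeleton is
  rescaled as the stroke thickens so the bounding box is unaffected
  (rendered widths are within one pixel of target).

## Physical similarity

**PIX** counts pixels that differ between two binary rasters (a Hamming
distance; for binary images identical to the summed squared difference). The
15-pair vector is rescaled to $(0.5, 1]$ by dividing by its maximum, halving,
and adding 0.5 — an affine map that preserves rank order and correlations.

**V1Sim** passes each image through a Gaussian low-pass (FWHM 20 px ≈ 1.5
cpd, the approximate acuity of the animals), z-normalizes it, and convolves
it with 80 filters: five spatial frequencies (0.04, 0.08, 0.15, 0.30,
0.60 cpd) x 16 orientations spanning the full circle, each filter a
cosine-phase oriented sinusoid under an isotropic Gaussian envelope
(sigma = support/4), sized to hold two cycles and normalized to zero mean and
unit norm. Pair dissimilarity is $D = 1 - r$ where $r$ is the Pearson
correlation between the two concatenated response stacks, then rescaled as
for PIX. Responses are linear — no rectification or pooling — which is the
simplest reading of a "simplified" V1 front end; alternatives would be model
extensions, not parameter tweaks.

Numerically, convolution is exact zero-padded linear convolution via FFT.
Because every filter has exactly zero mean, every response plane sums to
zero, so stack correlations reduce to Parseval sums that can be accumulated
filter by filter in the frequency domain: peak memory is a single padded
spectrum, never the 80-plane stack, and the full-resolution computation takes
under a minute. A direct spatial engine (`engine = "direct"`) materializes
the planes and is tested to agree with the streaming engine to 1e-10.

On the default renderings the two measures correlate at r = 0.89 across the
15 pairs (`scripts/acceptance.R` recomputes this), matching the published
finding that the physical-similarity calculation is insensitive to method
details.

## Population decoding

Spike-count tables hold stimulus-window (4 s) and preceding baseline-window
(2 s) counts per unit, shape and trial. Net responses are stimulus rate minus
baseline rate in Hz; negative values are kept. Units enter the analysis when
their best shape evokes a trial-mean net response above 2 Hz and every shape
has at least 12 presentations.

The readout is a linear SVM (penalty C = 0.5) trained per shape pair on
pseudo-population vectors: units were recorded at different times, so each
unit's trials are independently permuted within condition before being glued
into population vectors. Per resampling iteration a fresh subset of cells is
drawn without replacement (size = the smallest area's unit count, to equalize
areas), trials are subsampled to the 12-trial minimum, and a stratified
random 10/2 train/test split per condition yields a held-out proportion
correct. Reported accuracies are means over 100 iterations (SEM over
iterations). Chance is estimated by repeating the whole procedure with
condition labels shuffled on each of 100 outer repeats and taking the 95th
percentile of the shuffled means. Degenerate training sets (identical
vectors) fall back to predicting the first class.

Two unstated details of the original procedure were fixed as follows: the
same cell subsample is reused across pairs within one iteration (a config
flag varies this), and the trial subsample size equals the global minimum
trial count per condition.

## Behavior

Per-pair performance is the proportion of correct trials pooled over the
last four sessions, with an exact Clopper-Pearson 95% interval (inverted
binomial tails, not a normal approximation — windows hold only ~40-50
trials). Pairs are compared by pooling correct/incorrect outcomes, reshuffling
group membership 10000 times, and declaring the observed difference
significant when it falls outside the central [2.5, 97.5] percentile interval
of the permuted differences. Between-batch consistency is the Pearson
correlation of the six per-pair accuracies across the two batches, with the
derangement permutation p-value below.

## Correspondence statistics and their null

The match between a neural six-pair profile $O$ and a reference $E$
(physical dissimilarity or behavioral accuracy, both in $(0.5, 1]$) is scored
two ways: $\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ (a descriptive distance —
lower is better — not a classical goodness-of-fit test) and the Pearson
correlation. Significance uses an exhaustive permutation null restricted to
*derangements*: the 265 of 720 shuffles of six elements that leave no element
in place. "More extreme" is directional — smaller for chi-square, larger for
correlation — and strict, with p the proportion of more-extreme null values.

The transformation index uses the same machinery: the null applies
independent derangements to the two neural vectors (the behavioral and pixel
references stay fixed), recomputes all four terms for each of the 265 x 265
combinations — the contrast factorizes into an outer difference, so this is
exact and instantaneous — and compares $H$ to the null's 95th percentile
(correlation mode, upper tail) or 5th percentile (chi-square mode, where a
transformation appears as a large *negative* index).

**A calibration caveat.** Excluding fixed-point shuffles from the null is not
innocuous: the excluded permutations are exactly those that partially
resemble the observed arrangement, so the surviving null is biased away from
the observed value and tail p-values are inflated roughly twofold (simulation
with independent $O$, $E$: ~10% rejection at nominal 5%, versus 4.8% for the
all-permutation null). The package implements the published procedure
faithfully and the test suite asserts the true calibration; treat p-values
near the threshold with corresponding caution.

## The synthetic study

The generator's job is to produce data with the statistical structure the
analysis assumes, with the representational geometry as the experimenter's
dial:

* Each area's target 15-pair geometry is $(1-w)\,d_{\mathrm{pix}} +
  w\,d_{\mathrm{beh}}$ with default weights $w = 0, 0.25, 0.5, 0.75, 1$ for
  V1, LM, LI, LL, TO — V1 carries pure pixel geometry, TO pure behavioral
  geometry.
* The six configured behavioral accuracies (defaults 0.98, 0.95, 0.85, 0.75,
  0.57, 0.52, spanning the near-perfect to near-chance range observed in the
  water maze) are assigned to the six behavioral pairs so that their
  correlation with pixel dissimilarity is minimized over all 720 assignments,
  mirroring the empirical finding that behavioral difficulty is not
  pixel-driven. The remaining nine pairs of the behavioral geometry are
  interpolated against pixel dissimilarity (only the six behavioral pairs
  enter any downstream statistic).
* Shapes are embedded by classical multidimensional scaling of the target
  distances (six points embed in at most five dimensions; an error is raised
  if more than half the eigenvalue mass is negative). Each unit projects the
  shape coordinates onto a random direction and passes the projection
  through a softplus — rates stay positive without hard-rectification
  artifacts. Rates are baseline (3 ± 2 Hz) plus a shape-independent visual
  drive (6 ± 2 Hz) plus the selective term (gain 1.6 Hz, projection scale 2);
  counts are Poisson over the 4 s stimulus and 2 s baseline windows. The
  shape-independent drive is what lets ~100% of units pass the 2 Hz
  inclusion rule while the selective term stays small enough that pairwise
  decoding with ~200 cells lands in the 70-95% range rather than at ceiling,
  the regime the recorded areas occupy.
* 40 trials are generated per shape (a realistic 2-3 h session). The decoder
  still subsamples 12 trials per condition each iteration; generating only
  the 12-trial minimum would make every iteration reuse the same trials, so
  trial-sampling noise would freeze into each pair's apparent geometry
  instead of averaging out, and the geometry-to-decoding correspondence
  collapses (r ≈ 0.1-0.5 instead of ≈ 0.9).
* Water-maze logs: one rat per pair per batch, 17 and 16 sessions for the
  two batches, sessions of 10 or 12 trials, platform side following the
  cyclic LRLLRLRR pseudo-random scheme from a random start, and per-trial
  correctness Bernoulli at the pair's asymptote scaled by a logistic
  learning ramp that reaches 95% of asymptote by session 8 (so the scored
  last-four-session window sits at asymptote).

What the generator deliberately omits: correlated noise across units,
adaptation and latency structure, stimulus motion (motion exists only as
trial structure), laminar circuitry (the upper/lower-layer comparison is
emulated as two populations with different $w$), and any coupling between
the recorded animals and the behaving animals beyond the shared geometry.
Passing tests therefore show that the *statistics* recover planted structure
under Poisson noise — not that real cortex is organized this way.

## Problem sizes and numerical choices

The test suite runs the full pipeline at the sizes a desk check affords: the
parameter-recovery suite uses the default study (200 units/area, 40
trials/shape) over 20 seeds with 40 resampling iterations per pair; the
chance-level check uses a reduced 10 x 10 shuffle-by-resample grid; null
calibration uses 1000 independent draws. The acceptance script renders the
stimulus set at full resolution (768 x 1280, stride 1, all 80 filters).
Reproducibility is by explicit seeds everywhere; reruns with the same seed
are bit-identical. Ties in the SVM (identical training vectors) predict the
first class; all-zero dissimilarity vectors, constant profiles, and perfect
correlations (|r| = 1, where Fisher-Z diverges) raise errors rather than
propagating NaN.

## Known limitations

* The glyph geometry (stroke routing, exact outline shapes) is reconstructed
  from a verbal description; the PIX-V1Sim correlation (0.89 here vs 0.899
  reported) is reproduced, but per-pair values are not guaranteed to match
  the originals.
* The derangement null's anti-conservativeness (above) is inherited from the
  published procedure.
* The behavioral permutation test treats trials as exchangeable, ignoring
  session structure and learning within the scored window.
* The V1Sim model is linear; energy-model or normalization variants would
  change D values, though the published comparison suggests the analysis is
  robust to this choice.
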