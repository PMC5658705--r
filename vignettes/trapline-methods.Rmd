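---
title: "trapline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trapline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapline)
```

## The problem

A mother-machine chip confines hundreds of clonal *E. coli* lineages in
dead-end channels ("traps"). Live cells are phenotyped by phase-contrast
time-lapse (growth, division, lineage structure) and single-molecule
fluorescence (copy numbers of a reporter such as a YFP fusion, down to
less than one molecule per generation). The cells are then fixed and
genotyped in place: sequential rounds of FISH probing light each trap up
in one of two dyes per round, reading out one bit of a strain-specific
barcode RNA. Since every cell in a trap is the progeny of the cell at the
back of the channel, the trap's barcode genotypes all of its cells. This
package implements that analysis chain end to end and ships a synthetic
generator that produces every input with known ground truth.

## The synthetic world

`sim_params()` states the simulated experiment. Defaults follow the
reference design: **233 traps**, phase contrast every **60 s**,
single-molecule fluorescence every **13 min**, total duration **272 min**,
doubling time 30 min (`growth_rate_per_min = log(2)/30`). Everything not
fixed by that design is a package choice, held constant:

* **Geometry.** Traps are vertical channels 100 px long, 9 px wide, on a
  20 px pitch, closed end up; cells are spherocylinders (rectangles with
  semicircular caps) of width equal to the trap width. At a typical 100x
  magnification this corresponds to roughly 0.1 µm/px — coarser than real
  data, chosen to keep test fixtures fast.
* **Growth and division.** Cells elongate exponentially; a cell splits
  into exactly two daughters on reaching `division_length_px` (26 px).
  Division is deterministic with an optional `division_asymmetry`;
  daughters occupy the parent's extent (`cell_gap_px = 0`), because a
  stacked visual gap would make synchronized divisions shift the whole
  column abruptly — septation conserves length. Cells pushed past the
  open end leave the trap.
* **Expression.** Per fluorescence frame and cell, the true molecule
  count is Poisson with a per-genotype mean; molecules sit uniformly in
  the cell and are rendered as 2-D Gaussians (`psf_sigma_px = 1.3`, peak
  amplitude 300 counts over a background of 100). The implied peak SNR
  (~15) is a free parameter of the fixtures, not an asserted property of
  any instrument.
* **Noise.** The standard sCMOS approximation:
  Poisson(signal × `noise_gain`) shot noise plus Gaussian read noise
  (`read_noise_sd = 2`). Setting `noise_gain = 0` and
  `read_noise_sd = 0` yields noiseless fixtures.
* **Cameras.** Phase and fluorescence cameras are related by a true
  affine transform (`camera_offset`, default a (2.5, −1.5) px
  translation); simulated landmark pairs let the pipeline estimate it the
  way a real calibration would.
* **FISH.** Each round, a trap emits `fish_signal_mean` in the dye
  dictated by its codeword bit (Cy3 ↔ 1, Cy5 ↔ 0) plus a crosstalk
  fraction (2%) in the other dye; DAPI marks every occupied trap. An
  optional injected *miscall* swaps one trap's dyes in one round,
  emulating a single barcode read error.

What a green test on this world establishes: that the algorithms are
implemented correctly with respect to their contracts (overlap scoring,
exact assignment, vote accumulation, interval arithmetic) and that the
pipeline composes end to end. What it does **not** establish: robustness
to real phase-contrast texture, focus drift, phototoxicity, asynchronous
growth-rate variation, or probe-chemistry failure modes — none of which
the generator emulates.

## Segmentation

An empty-trap reference image is subtracted after an integer-pixel
alignment search (±3 px, minimum mean squared difference), removing the
static channel structure. The corrected image is thresholded by Otsu's
method; touching cells are split by a watershed on the negated exact
Euclidean distance transform. Watershed seeds are the connected regions
where the distance reaches `seed_fraction` (0.6) of its maximum: rods
touching cap-to-cap have a distance dip at the junction, so each cell
body contributes one seed and elongated cells are not oversegmented (the
flat distance ridge of a rod defeats naive local-maxima seeding).
Components outside `[min_area_px, max_area_px]` = [20, 1000] px are
dropped and labels are renumbered top-to-bottom. A guard rejects frames
whose "foreground" does not stand at least 5 robust SDs above background,
so blank frames return zero cells rather than thresholded noise. The area
bounds and polarity are configuration, calibrated on fixtures; no claim
is made that they match any particular instrument.

## Tracking

`link_frames()` scores migrations by J(p, c) and divisions by
J(p, c₁∪c₂), requiring positive overlap with both daughters (binary
fission only; 1→3 events are excluded by construction). The optimum over
all consistent assignments is found exactly by dynamic programming over
parents and used-child subsets; ties resolve toward the topmost cells.
This replaces a global multi-frame (Viterbi-style) tracker with the exact
per-frame-pair optimum — on trap-scale instances the two agree wherever
we can enumerate, and the pairwise optimum is what the brute-force oracle
in the test suite verifies. Gap closing across missing frames is out of
scope.

The four lineage filters and their defaults (`filter_params()`):

| rule | drops | threshold (default) |
|---|---|---|
| i | single observations with transient area excursions | >30% from a 5-obs window median |
| ii | generations with persistent area shifts | >30% step that persists |
| iii | generations with large center-of-mass movements | >9 px (one cell width) |
| iv | very short-lived generations | <5 frames, kept if mother + 2 daughters |

The rules are qualitative in the field; the numbers are repository
defaults. Rule ii checks that a large step *persists* (median level
before vs. after), so a spike that rule i would drop never triggers rule
ii — this keeps rejection counts monotone when thresholds are loosened.

## Spot counting

The fast radial symmetry transform votes, for each radius n ∈ {2, 3} px,
at the pixel n steps up the intensity gradient (bright polarity only —
fluorescent spots are bright; the dark-spot branch is omitted). Vote
count and magnitude images are normalized (saturation k = 9.9), raised to
α = 2 and smoothed (Gaussian, σ = n/2); the response is averaged over
radii. Radii and α suit a PSF of σ ≈ 1.3 px.

Detection thresholds the *local-maxima population* of the response at
`k = 8` robust SDs in **log domain**: the response over noise is strongly
kurtotic, so a pixel-wise MAD reflects flat background rather than the
noise peaks that false positives actually come from, while noise peaks
are roughly log-normal and true spots sit orders of magnitude above them.
Non-maximum suppression keeps the stronger of any two maxima closer than
3 px, and positions are refined by a quadratic fit to the 3×3
neighborhood. Consequence: two molecules closer than ~3 px merge into one
detection, so counts are biased low at high density — quadratically in
the mean count, which matters little below ~1 molecule per cell.

The inter-camera transform is a full 6-parameter affine least-squares fit
to landmark pairs (a similarity transform is a special case; the affine
fit reduces to it when the data demand). Spots are assigned to the label
at their mapped pixel in the nearest-in-time phase mask — the 13-min
fluorescence cadence is coarse against the 1-min phase cadence, and no
mask interpolation is attempted; spots landing on background are rescued
to the nearest cell within 2 px, else left unassigned.

## Genotyping

Traps are located as peaks of the vertically summed DAPI profile
(intensity-weighted run centers, minimum spacing, 5 robust SDs above
background). FISH background is the per-frame median of inter-trap
columns, subtracted per pixel (floored at 0) before vertical summation
over each trap's column interval — vertical because the traps are
vertical channels. `call_bit()` applies the strict sign rule on
log(Cy3/Cy5) with sums floored at 1 count (the floor doubles as a
pseudocount; an `ambiguity_band > 0` turns near-ties into explicit
no-calls for QC, default 0). Codewords decode by exact lookup; with
`n_rounds` a multiple of the codeword length, each block of rounds is one
independent determination and `consensus_genotype()` takes a strict
majority, flagging `corrected` when it outvoted a disagreement. For
C > 2 colors the same machinery generalizes with argmax over per-dye
sums; the two-color log ratio is kept as the primary rule.

## Accuracy statistics

`confusion_counts()` tallies true/false positive/negative identifications
of a chosen genotype per *determination* (trap × redundancy), treating
redundant determinations as independent Bernoulli trials — that
independence is an assumption of the analysis, stated here once.
`clopper_pearson()` is the exact Beta-quantile interval; the test suite
checks it against independent binomial-tail root-finding to 1e-9.
`max_growth_rate()` slides a log-linear fit (default 7 points = 35 min at
the 5-min plate-reader cadence) over background-subtracted OD and
converts the maximal slope to the minimum doubling time ln 2 / λ*; the
`min_od` floor keeps sub-noise points out of the log fit, and on logistic
curves a wider window (~15 points) balances the noise-driven downward
bias of a sliding maximum against the curvature-driven upward bias.
`repression_ratio()` averages background-subtracted Fluo/OD over the last
12 well-measured time points (≈ the last hour at 5-min cadence) — the
"steady-state window" is a package definition.

## Known limitations

* Spot counts are biased low when molecules crowd within ~3 px
  (quadratic in the mean); absolute counting above a few molecules per
  cell per frame needs PSF fitting or deconvolution, which is out of
  scope.
* Deterministic symmetric division synchronizes a lineage's divisions;
  real lineages desynchronize. Set `division_asymmetry > 0` for
  desynchronized fixtures.
* The tracker is exact per frame pair but not globally over time, and
  does not close gaps across missing frames.
* The TIFF codec covers uncompressed grayscale 8/16-bit stacks only — the
  raw-acquisition case — not compressed or tiled variants.
* Redundancy bookkeeping is exact integer arithmetic: n traps at
  redundancy r yield n × r determinations, and one flipped determination
  gives n × r − 1 correct ones. Published tallies that do not satisfy
  this identity cannot be reproduced by counting, only quoted.
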