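---
title: "Quantifying structure and function in engineered neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying structure and function in engineered neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritescope)
```

# Scope

`neuritescope` quantifies three families of measurements made on
multi-nodal neural networks grown in microfluidic devices (MFDs) with
axon tunnels, a synaptic compartment, and a microelectrode-array (MEA)
interface:

1. **Mitochondrial distribution and transport.** TMRM-labelled
   mitochondria inside 145-µm axon-tunnel segments are detected in
   single frames, counted over timepoints, and tracked over time through
   kymographs to yield per-tunnel motile ratios, transport speeds and
   anterograde/retrograde direction.
2. **Neurite and synapse morphometry.** Neuritic boutons are counted as
   skeleton endpoints of the binarized neurite mask; neurite coverage is
   a particle-analysis area; synaptic contacts are the co-occurrence
   (mask intersection) of a presynaptic (Piccolo) and postsynaptic
   (PSD95) marker channel, with an upper size cut-off of 15 µm
   equivalent diameter. Structure height in the synaptic compartment is
   measured from z-stacks.
3. **Extracellular electrophysiology.** Raw MEA traces (10 kHz) are
   band-pass filtered (Butterworth, 2nd order, 300–3,000 Hz,
   zero-phase), spikes are detected at 5 standard deviations below the
   trace median, binned at 1 ms, and functional connectivity is the
   peak-lag Pearson correlation over ±100 ms with an activity filter
   (≥ 10 spikes per electrode) and a significance filter (p ≤ 0.001);
   the total network correlation is the mean peak *r* over included
   pairs.

Because the raw microscopy underlying such measurements is rarely
available, every stage is paired with a synthetic-data generator that
renders calibrated scenes with complete ground truth, so the pipelines
are validated by *parameter recovery*: simulate known speeds, counts,
heights, overlaps, spike times and couplings, run the full pipeline, and
compare.

# The synthetic scenes and what they do (not) emulate

All imaging scenes are built from isotropic Gaussian blobs (σ =
`psf_sigma`, default 1.5 px at 0.2 µm/px — a diffraction-limited punctum
convolved with a small object) or hard discs of stated physical area, on
a flat background plus a linear illumination ramp, with additive
Gaussian read noise. Defaults encode the acquisition the pipelines
assume: 145-µm tunnels at 0.2 µm/px, one frame per second for 60 s,
z-stacks with a known z-step, and 7-min MEA recordings at 10 kHz with a
fixed 1-ms biphasic negative-peak spike template.

Choices worth knowing:

* **Object brightness.** The default peak signal-to-noise ratio is 16
  with read noise 0.003 on a unit luminance scale, typical of
  confocal TMRM puncta. Pixel-exact counting through a plain
  top-hat → Otsu chain requires the threshold (which Otsu places near
  half the object amplitude) to clear the background's top-hat residue
  by ≥ 4–5 noise SD; that margin is roughly `(snr/2 − 2.4)·σ`, so exact
  counting is a realistic expectation from SNR ≈ 14 upward, and the
  count-recovery benchmarks run at the default SNR 16. The kymograph
  benchmarks run at SNR 5: averaging across the tunnel width and
  matched-filter smoothing recover the deficit there.
* **Separability.** Stationary objects are placed with a minimum
  separation (default 10 px along the tunnel axis) so that each forms
  its own kymograph stripe; dense static counting scenes instead use
  2-D separation across the tunnel strip. Counting merged puncta as one
  is a property of the assay, not a failure of the simulator.
* **Not emulated:** full 3-D point-spread functions, photobleaching,
  motion blur within a frame, autofluorescent background texture,
  bursting or oscillatory structure in the MEA traces, and
  electrode-to-neurite geometry. Passing the recovery benchmarks
  therefore shows the *algorithms* are faithful and well-calibrated on
  scenes satisfying their stated assumptions; it does not certify
  performance on real data with artefacts outside that envelope.

A single integer seed fixes all randomness; per-frame and per-channel
substreams are derived from it, so regenerating any single asset is
reproducible.

# Numerical and algorithmic choices

**Thresholding.** Otsu and Triangle thresholds use a 256-bin histogram
over the observed intensity range, and are invariant under affine
rescaling of the luminance. Otsu's between-class-variance criterion is
weight-sensitive: on a frame whose true foreground is a tiny fraction of
the pixels (or absent), it splits the *background*. The mitochondria
detector therefore takes the larger of the Otsu threshold and a robust
noise floor, `median + floor_k·MAD` of the top-hatted frame
(`floor_k = 6` by default, 0 restores the bare chain). On scenes with
real foreground the Otsu threshold dominates and the floor is inert.

**Component shape.** Eccentricity comes from the second central moments
of the pixel set with the 1/12 per-pixel (unit square) variance added,
so a one-pixel-wide line stays strictly below 1 and a disc measures 0.
The artefact filter removes components with area > 5 µm² or eccentricity
> 0.995, applied to every component (the device-edge artefacts it
targets are large and elongated; interior objects of that size are not
plausible single mitochondria either).

**Kymographs.** Row *t* is the mean luminance across the tunnel width at
each position along the axis in frame *t*. Stationary objects are
removed by subtracting the per-column temporal *median* (robust to a
moving object transiting the column) and counted as contiguous
above-threshold runs of the detrended column-median profile. Track
detection then binarizes the filtered kymograph: the threshold is the
larger of a robust noise floor (median + 6·MAD) and, in cluttered scenes
(> 5% of pixels above the floor), an Otsu split of the above-floor
values — on a mostly-empty clipped kymograph plain Otsu would split the
background, and in a bright dense one the noise floor alone would admit
every structure's smoothed skirt. The mask is despeckled and the dashed
per-frame footprints of fast objects (which need not overlap between
consecutive rows) are bridged by an anisotropic (3-row × 9-column)
closing. Candidate lines come from three sources: least-squares fits of
skeleton branches split at junctions (the primary detector),
whole-component pixel-cloud fits, and an exhaustive slope-scan
projection that recovers trajectories whose skeleton evidence is
fragmented by crossings. Every candidate is refit at subpixel precision
from per-row intensity centroids of the nearest contiguous mask run
inside a ±8 px corridor, iterated three times so a poor initial fit
converges, then validated by fit quality (R² ≥ 0.9), time extent
(≥ 10 rows), support fill and density, mask coverage along the line,
and temporal continuity (the line must ride above the noise level in
≥ 80% of its rows — a real object emits in every frame). Accepted
tracks are extracted strongest-support first and consume their per-row
mask runs; after each pass the residual kymograph is re-thresholded, so
dimmer traces are not lost behind the histogram mass of brighter ones.
Fragments of one trajectory and lines within the corridor's resolution
of an accepted track are merged rather than double-counted. Tracks
with |net displacement| < 3 µm are stationary (or *bidirectional* when
their path length exceeds 10 µm; these are reported separately and
excluded from the motile ratio, since back-and-forth "fluctuating"
movement is not reliably captured by a kymograph in the first place).
Two trajectories that run closer than the corridor width at nearly the
same slope are merged — they are genuinely ambiguous in a kymograph.

**Morphometry.** The bouton chain is top-hat (5 µm disc), tiled CLAHE
(8×8 tiles, contrast limit 2 — near the smallest value that still
equalizes structure without amplifying empty-tile noise), Otsu, 3×3
median filter, closing (2 px disc), hole filling, Zhang–Suen thinning,
spur pruning (≤ 6 px), and endpoint detection (skeleton pixels with one
8-neighbour). Endpoints within 12 px of the image border are ignored:
neurites anchored at the field edge end there, not at a bouton. Manual
additions from a visual review enter as a CSV of points and are added to
the automated count. The 15-µm co-occurrence cut-off is interpreted as
an equivalent diameter (a 15-µm *area* reading is available via
`cutoff_is_area = TRUE`); overlap particles are measured on binary
masks.

**Z-stack height.** A single global Otsu threshold from the
maximum-intensity projection is applied to every slice; a slice carries
signal if its foreground area exceeds `min_area_um2` (default 0.5 µm²),
and height is `(last − first + 1) · z_step`. Degenerate stacks warn and
return 0.

**Electrophysiology.** Filtering is forward–backward (zero-phase) so
spike timestamps carry no filter delay. The detection threshold uses the
plain standard deviation of the full filtered trace below its median —
as stated, not a robust noise estimate — with a MAD-based option.
Events are timestamped at the local minimum of each sub-threshold
excursion with a 1-ms dead time. Bins are half-open `[k, k+1)` ms and
hold counts, not occupancy. The lagged Pearson correlation is computed
exactly for all 201 lags via FFT cross-products with prefix-sum means
and variances (verified against the direct per-lag formula to machine
precision); the peak maximizes *signed* r, ties breaking toward smaller
|lag|, and the p-value is the two-sided t transform at the peak with
`n_overlap − 2` degrees of freedom.

**A documented caveat.** The p ≤ 0.001 filter is applied to the peak of
a 201-lag scan without multiple-testing correction, and Pearson's r on
sparse 1-ms binary trains is so far from its nominal t distribution
that a handful of chance coincidences can clear the filter. Under
independent trains at culture-typical rates (~1 spike/s over 7 min) the
majority of electrode pairs retain a nominally significant peak; the
package's permutation check (`test-ephys.R`) demonstrates this
anticonservatism directly. Total-network-correlation values built from
this filter should be read as a connectivity-weighted summary, not as a
set of individually significant connections.

# Group statistics and orchestration

`run_stage()` drives each stage from a YAML config and writes CSV
tables, a summary JSON and a log; runs are byte-reproducible for a given
config and seed (numeric fields are rounded to 6 significant digits at
write time). `compare_groups()` reproduces the reporting convention of
routing by a Shapiro–Wilk normality check to Welch/paired t-tests or
their rank-based alternatives — thin calls to the standard routines, for
report parity only. A thin command-line wrapper (`exec/neuritescope`)
exposes the stages as `neuritescope <stage> --config cfg.yaml`.

# Problem sizes in the test suite

The unit tests run on miniature scenes (tens of pixels, seconds of
recording) with brute-force oracles: flood-fill labelling, exhaustive
histogram threshold scans, direct per-lag correlations, permutation
nulls, and hand-computed morphology on 5×5 arrays. The recovery
benchmarks use the full study geometry — 60-frame series over 145-µm
tunnels, 20 tunnels per condition, 7-min × 12-channel recordings at
10 kHz, up to 20-termini neurite fields on a 1024² canvas — sized so the
whole suite completes in well under half an hour on one CPU.

# Known limitations

* Motile-count recovery degrades with crowding. At 7 motile
  trajectories among 43 stationary per tunnel the recovered group-mean
  motile ratio is biased: at SNR 5 roughly half of the fast (> 1 µm/s)
  trajectories leave too little above-floor mask support to be
  extracted (their dashed footprints sit near the binarization floor),
  biasing the ratio down by ~0.03–0.05; at high SNR the opposite
  happens — near-parallel trajectory pairs, which order statistics make
  common at that density, braid within the corridor resolution and
  fragment into extra detections, biasing the ratio up by ~0.02–0.04.
  The sparse condition (3 motile / 47 stationary) is recovered within
  ±0.01 at SNR 5. Speed estimates are unaffected (they are conditioned
  on detection).
* Exact count recovery through the top-hat → Otsu chain needs the
  brightness margin discussed above; at SNR 5 the chain admits
  pixel-noise false positives on sparse scenes, which is a property of
  the published procedure, not of the implementation.
* The kymograph analysis intentionally does not track particles across
  frames; curved or pausing trajectories are fit by a single line.
* No spike sorting, burst detection, stimulus-artefact handling or
  graph-theoretic network measures.
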