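# neuritescope

Quantification of mitochondrial transport, neurite/synapse morphometry
and MEA functional connectivity in engineered neural networks.

Multi-nodal neural networks grown in microfluidic devices — cell
chambers joined by narrow axon tunnels and synaptic compartments, often
interfaced with a microelectrode array (MEA) — make it possible to
watch early neurodegeneration-related phenotypes emerge: how fast
mitochondria move along axons, how neurites and synaptic contacts
remodel, and how functionally coupled the network is. `neuritescope`
implements the full quantification stack for such experiments as a
tested, reusable R package, together with a synthetic-data generator
with complete ground truth so that every stage can be validated by
parameter recovery.

## The measurements

**Mitochondrial transport (kymographs).** TMRM-labelled mitochondria in
145-µm tunnel segments are imaged once per second for a minute. Each
tunnel's kymograph *K(t, x)* holds the mean luminance across the tunnel
width at position *x* along the axis in frame *t*. Stationary
mitochondria form vertical stripes (removed and counted by per-column
temporal median subtraction); motile mitochondria form slanted lines
whose speed is the change in distance over the change in time,

```
v = |Δx| · (µm/px) / (Δt · s/row),
```

with the sign of the slope giving anterograde vs retrograde direction.
Per tunnel the package reports the motile ratio
`n_motile / (n_motile + n_stationary)`, mean speed and anterograde
fraction.

**Mitochondria counting.** Detection chain per frame: white top-hat →
Otsu threshold → 8-connected components → rejection of artefacts with
area > 5 µm² or eccentricity > 0.995; sizes are pixel counts times the
squared pixel size. Structure heights come from z-stacks
(`(last − first + 1) · z_step` over slices whose foreground exceeds an
area criterion), and two-channel coverage ratios from per-channel Otsu
areas.

**Boutons and synapses.** Neuritic boutons are endpoints of the
thinned neurite mask (top-hat → CLAHE → Otsu → median filter → closing
→ hole filling → thinning → endpoint detection), with a manual-review
sidecar for additions. Synaptic contacts are the intersection of the
presynaptic (Otsu) and postsynaptic (Triangle) marker masks, measured
by particle analysis under a 15-µm equivalent-diameter cut-off.

**Electrophysiology.** Raw MEA traces (10 kHz) are filtered with a
zero-phase 2nd-order Butterworth band-pass (300–3,000 Hz); spikes are
negative crossings of `median − 5·SD` of the filtered trace,
timestamped at the local minimum. Spike trains are binned at 1 ms and
the functional connectivity of each electrode pair is Pearson's *r*
maximised over signal lags in ±100 ms ("peak lag"), with electrodes
under 10 spikes excluded and pairs with p > 0.001 (t transform at the
peak) excluded; the total network correlation is the mean peak *r* over
included pairs.

## Worked example

Simulate one tunnel with eight stationary mitochondria and one moving
at 1.296 µm/s at peak SNR 5, then run the kymograph pipeline:

```r
library(neuritescope)

p <- sim_params(n_stationary = 8L, n_motile = 1L,
                speeds_um_s = 1.296, snr = 5, seed = 2L)
scene <- gen_mito_series(p)
scene$series
#> <image_series> 23 x 725 px, 60 frames @ 1 s, 0.2 um/px

kymo <- build_kymograph(scene$series, scene$rois[1, ])
kymo
#> <kymograph> tunnel 1: 60 rows (time) x 725 cols, 1 s/row, 0.2 um/px

sup <- suppress_stationary(kymo)
sup$n_stationary
#> [1] 8

tracks <- detect_tracks(sup$filtered)
tracks[, c("speed_um_s", "direction", "rows_spanned", "r2")]
#>   speed_um_s   direction rows_spanned        r2
#> 1   1.284201 anterograde           60 0.9991516

motility_summary(tracks, sup$n_stationary)[c("motile_ratio", "mean_speed_um_s")]
#> $motile_ratio
#> [1] 0.1111111
#> $mean_speed_um_s
#> [1] 1.284201
```

The eight stationary stripes are found exactly, the single motile
mitochondrion is recovered as one anterograde track spanning all 60
frames, and its speed (1.284 µm/s) is within 1% of the simulated
1.296 µm/s. The motile ratio 1/9 ≈ 0.111 matches the scene's truth.

The same pattern applies to the other stages: `detect_mitochondria()`,
`zstack_height()`, `area_ratio()`, `count_boutons()`,
`synapse_cooccurrence()`, `bandpass()` → `detect_spikes()` →
`network_correlation()`. `run_stage()` (or the thin
`exec/neuritescope` command-line wrapper) drives whole experiment
layouts from a YAML config, and `compare_groups()` applies the
normality-routed group statistics used for reporting.

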