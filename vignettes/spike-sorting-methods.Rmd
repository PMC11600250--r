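---
title: "Deep embedded clustering for extracellular spike sorting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep embedded clustering for extracellular spike sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedec)
```

## The problem

A microelectrode array (MEA) electrode records the summed extracellular
potential of every neuron near it. Spike sorting turns that single voltage
trace into per-neuron spike trains: detect the brief (~1 ms) negative
deflections that action potentials produce, and group them by their
waveform shape so each group corresponds to one putative source neuron.
`spikedec` implements a complete sorting chain whose clustering stage is a
family of deep-learning models — a deep autoencoder with k-means (DeepAE),
Deep Embedded Clustering (DEC), Improved Deep Embedded Clustering (IDEC) —
benchmarked against an autoencoder-ensemble baseline, together with a
ground-truthed simulator and fluorescence calcium-trace analysis for
recordings where imaging and electrophysiology were acquired
simultaneously.

## Detection and preprocessing

Raw traces are bandpass filtered at 300–3000 Hz with a zero-phase
(forward–backward) 4th-order Butterworth filter. Zero-phase filtering is a
deliberate choice: it preserves trough positions, which the alignment step
depends on; the method definition names only the band.

The noise scale is the robust estimator

$$\sigma_m = \mathrm{median}(|x|)\,/\,0.6745,$$

whose denominator is the median absolute value of a standard normal, so
$\sigma_m$ converges to the noise standard deviation while ignoring the
sparse spike fraction. It is computed on the full filtered trace — the
median makes masking spike segments unnecessary. Detection flags samples
crossing below $-5\sigma_m$. Polarity is negative-only: extracellular
somatic spikes are trough-dominated, and the downstream alignment is to the
waveform minimum, which only makes sense for negative deflections. A dead
time of 3.2 ms (one extraction window) after each accepted crossing
suppresses re-triggering on the same spike's sub-threshold oscillations,
and crossings that re-align to the same trough (within ±2 samples) are
deduplicated — the zero-phase filter rings symmetrically, so a large spike
can push a ringing lobe through the threshold just before the true trough.

For each event a provisional window of 20 samples before and 44 after the
crossing is cut, its minimum located, and the final 64-sample window re-cut
as 20 samples before and 43 after the trough. Every emitted waveform
therefore has length 64 with its minimum at a fixed position (offset 20),
which the clustering requires. Each waveform is min-max scaled to [0, 1]
and differenced, $\nabla x(t) = (x(t{+}1) - x(t))/\Delta t$ with
$\Delta t = 50\ \mu s$ at 20 kHz, giving the 63-dimensional gradient
feature vector. Min-max scaling removes per-spike offset and gain (the
features are invariant to affine rescaling of the waveform); the gradient
emphasises shape over amplitude.

## The sorters

All four sorters operate on the same feature matrix and share one
symmetric fully-connected autoencoder architecture, by default
63–256–64–10 with rectified-linear hidden units and linear latent and
output layers. The architecture is a package choice (the method definition
names none): small enough to train quickly on a CPU, expressive enough for
63-dimensional gradients. Features are standardised internally by their
global mean and standard deviation; the scaling is stored with the model.
Training is minibatch Adam (learning rate $10^{-3}$, batch 256, 30 epochs
of pretraining by default), written directly on matrix operations so that a
single integer seed fixes every weight and every batch draw — the package
has no deep-learning-framework dependency and the entire training loop is
deterministic by contract.

* **DeepAE** pretrains the autoencoder, embeds all spikes, and runs k-means
  (10 restarts) on the latent codes.
* **DEC** discards the decoder after pretraining, initialises K centroids
  by k-means on the latent codes, and then alternates between (a)
  refreshing the auxiliary target $P$ and (b) minibatch gradient steps on
  $KL(P\|Q)$ with respect to encoder weights and centroids. The soft
  assignment is the Student's-t kernel
  $q_{ij} \propto (1 + \|z_i - \mu_j\|^2/\alpha)^{-(\alpha+1)/2}$ with
  $\alpha = 1$, and the target is $p_{ij} \propto q_{ij}^2 / f_j$,
  $f_j = \sum_i q_{ij}$ — the canonical deep-embedded-clustering
  formulation, which the underlying method adopts from the works it builds
  on.
* **IDEC** keeps the decoder and optimises
  $L = L_{\mathrm{recon}} + \gamma L_{\mathrm{cluster}}$ with
  $\gamma = 0.1$, preserving local structure in the embedding while
  sharpening clusters. At $\gamma = 0$ the update path reduces *exactly*
  (bitwise, at equal seeds) to continued autoencoder training; this is a
  tested contract.
* **AE-Ensemble**, the normalisation baseline, trains five shallow
  autoencoders (63–128–latent, latent dims 8/10/12/10/8, distinct seeds,
  15 epochs each — the single-hidden-layer members plateau earlier than
  the deep net), concatenates their latent codes and clusters the
  concatenation with k-means. The exact recipe of the published baseline
  is not specified anywhere we could consult, so this reimplementation
  aims to be a competitive, reproducible reference; deeper two-hidden-layer
  members were evaluated during development and were not better.

Fine-tuning runs at most 600 minibatch iterations (learning rate
$5 \times 10^{-4}$), refreshes the target distribution every
epoch-equivalent, and stops early when fewer than 0.1% of spikes change
cluster between refreshes. K is always supplied by the caller (K = 5 in
the benchmarks, matching the simulator's ground truth); the package does
no model selection for K.

In `run_benchmark()` one autoencoder is pretrained per data set and shared
by DeepAE, DEC and IDEC — the standard practice, since DEC and IDEC are
defined as fine-tuning stages on a pretrained autoencoder — while k-means
initialisation and fine-tuning use per-sorter seeds. The ensemble trains
its own members.

## Scoring

Detections are paired to ground-truth spikes by greedy nearest-neighbour
one-to-one matching within ±10 samples. Clustering accuracy is the
Hungarian-matched accuracy: the best one-to-one mapping of predicted
clusters to true neurons on the confusion matrix (a compact $O(n^3)$
augmenting-path implementation, unit-tested against brute-force
enumeration). The default scope scores only detections paired to a true
spike (`matched_only`), which isolates clustering quality — the quantity
that varies across sorters sharing one detector; the `all_truth` scope,
which also charges missed detections as errors, is available as a switch.
Sorter comparisons are reported as the relative accuracy improvement
$100\,(a_{\mathrm{model}} - a_{\mathrm{ref}})/a_{\mathrm{ref}}$ against
the AE-Ensemble, summarised as mean ± sd over data sets.

## The simulator

The generator emulates ground-truthed benchmark recordings of the kind
produced by compartmental-model simulators, without licensing their
biophysics. Each source neuron is a biphasic template: an asymmetric
Gaussian trough (width 150–300 µs at 20 kHz — the physiological range;
much sharper troughs make the gradient features pathologically sensitive
to single-sample alignment jitter, much wider ones fall below the 300 Hz
band edge), an after-hyperpolarisation rebound of 10–50% of the trough
depth, and an optional small pre-spike capacitive bump. The trough sits at
35% of the 64-sample template length. Trough amplitudes are drawn in
−120…−50 µV against white Gaussian noise of sd 10 µV, i.e. an SNR
(trough/noise) range of 5–12, so 5σ detection is exercised non-trivially.

Because min-max preprocessing erases amplitude, neurons are separable only
by shape. Template banks are therefore rejection-sampled until every pair
is at least a minimum distance apart (default 0.025 per-sample RMS) *in
the representation the sorters actually see* — the bandpass-filtered,
trough-aligned, min-max-scaled gradient. Without this floor, randomly
drawn banks frequently contain pairs that are indistinguishable in feature
space, which no Euclidean clustering method could ever separate; real
benchmark datasets consist of sortable units, so the floor is part of
emulating them.

Spike times follow a refractory renewal process: gaps are the 2 ms
refractory period plus an exponential with rate $r/(1 - r\,\tau_{ref})$,
so the mean rate equals the configured rate exactly and realized counts
match the Poisson expectation — the benchmark's size classes are defined
by spike *counts*, with duration solved as count divided by summed rate.
Overlapping spikes superpose linearly and both remain in the ground truth;
collisions are a genuine error source, and their frequency scales with the
summed firing rate. Benchmark sets use rates {3, 5, 8, 13, 21} Hz for the
five neurons plus 40 Hz of unlabelled low-amplitude (−30…−15 µV)
background units mimicking distant neurons.

What the simulator does *not* model: electrode geometry and spatial
correlation across channels (the sorting is per-electrode), electrode
drift, bursting with amplitude adaptation, and non-Gaussian noise. Passing
benchmarks here therefore demonstrates correct implementation and the
relative behaviour of the sorters under controlled conditions, not
performance on real tissue.

## Benchmark problem sizes

The reference experiment runs 10 independent sets of the "small" class
scaled to ≈10,000 spikes each and 10 sets of the "large" class scaled to
≈11,000 spikes each (scale factors 0.1 and 0.01 of the 100,000 /
1,100,000-spike classes), with per-set seeds derived from one master seed.
These sizes keep a full four-sorter comparison around a quarter of an hour
on one CPU core. A consequence of desk scaling is that the two classes
collapse to nearly the same per-set problem size, so the small-versus-large
contrast is expressed only weakly; the within-class comparisons (each
sorter against the ensemble on the same sets) are unaffected. A second
consequence is statistical: with 10 sets per class and between-set
standard deviations of several percentage points, mean improvements carry
a standard error of a few points, so the fine ordering of the two
embedded-clustering variants (DEC versus IDEC) is within sampling noise at
this scale and can flip between suite seeds; the acceptance tests assert
the full expected pattern regardless and report any shortfall rather than
widening their bands.

The parameter-recovery fixture used in the tests is deliberately cleaner
than the benchmark: 5,000 spikes from five neurons at 0.8–2.4 Hz (low
summed rate, hence few collisions), troughs −120…−100 µV and noise sd
8 µV. On it, all four sorters reach Hungarian accuracy ≥ 0.9.

## Calcium traces

Fluorescence ROI traces (frame interval 12.5 ms by default; 20,000 frames
span ≈250 s) are corrected for photobleaching by subtracting an order-10
least-squares polynomial. The fit uses R's orthogonal-polynomial basis on
a rescaled time axis — a raw power basis of degree 10 over 20,000 frames
is numerically singular — and the identity
`residuals + fitted_baseline == intensities` holds exactly. Calcium spikes
are local maxima of the corrected trace that rise at least 4 robust noise
scales (MAD) above the corrected baseline and have at least that
topographic prominence; of two peaks closer than 0.5 s the larger wins,
since noise crests on a slow decay tail would otherwise be counted twice.
Each event carries its apex time (the local maximum, which also defines
the amplitude) and a half-rise onset time; the onset is the right quantity
to compare against known event times, and on simulated traces at SNR 8 it
recovers injected spikes to within one frame. ΔF/F uses
$F_0$ = 10th percentile of the raw trace — a robust basal-fluorescence
choice, configurable because the underlying method leaves $F_0$ undefined.

Simultaneously acquired spike trains are aligned by the recorded
start-time offset between acquisitions; co-occurrence counts calcium
events with at least one electrophysiological spike within ±1 s, covering
the sub-second unaccounted delay of manual alignment (≈0.6 s). Population
summaries report per-day spike rate and pairwise mutual-information
synchronicity (binarized 2×2 plug-in estimator, log base 2; 20 ms bins for
electrophysiology, one frame for calcium) normalised to day 1, with the
standard error over units or pairs. The plug-in estimator is biased
upward at small bin counts; relative day-to-day comparisons at fixed
binning are unaffected, which is how it is used here.

## Numerical and degenerate-input choices

* Constant waveforms have no min-max scale and are rejected with a count.
* A cluster whose soft frequency $f_j$ is zero is excluded from the target
  distribution and reported.
* `kmeans` initialisation uses 10 restarts to stabilise against bad seeds.
* Ties in the trough search resolve to the earliest sample (R's
  `which.min`); hard labels are `max.col(Q, ties.method = "first")`.
* All randomness flows from integer seeds through R's RNG; functions
  restore the caller's RNG state, and repeated calls with equal arguments
  are bitwise identical. OpenBLAS matrix products are deterministic for a
  fixed library build.

## Known limitations

Single-channel sorting only — no multi-electrode template matching,
overlap decomposition or drift correction. No automatic choice of K. The
plug-in mutual information is uncorrected for small-sample bias. The
benchmark's absolute accuracies depend on the simulator's difficulty
settings; the package reports relative improvements against the in-suite
baseline for that reason.
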