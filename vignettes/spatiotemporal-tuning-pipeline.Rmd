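---
title: "Methods: spatiotemporal tuning, decoding and clustering of visual cortical populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal tuning, decoding and clustering of visual cortical populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vistuning)
```

# Overview

`vistuning` implements a multi-stage analysis for characterizing visual
cortical neuron populations from calcium-imaging responses to
bandpass-filtered noise stimuli: stimulus synthesis, quality control,
two-dimensional spatiotemporal tuning fits with a speed-tuning index,
anisotropy and orientation selectivity indices, hierarchical-bootstrap
statistics, linear-SVM speed decoding, and functional clustering with
area-composition statistics. Because the raw imaging data such an
analysis is designed for are terabyte-scale, the package ships a
first-class synthetic-data generator that emulates the study design —
the stimulus batteries, the nested mouse/area/neuron structure, and
GCaMP6s-like calcium dynamics — so that every stage is verifiable by
parameter recovery against a known ground truth.

This vignette is the package's methods account: the models, their
assumptions, the tunable parameters with their defaults and rationale,
the numerical choices, and the limits of what synthetic validation can
show.

# Stimulus model

Three stimulus batteries are represented by condition grids
(`build_condition_grid`):

* **Dataset 1** (isotropic): 5 center spatial frequencies (0.02, 0.04,
  0.08, 0.16, 0.32 cpd) x 6 center temporal frequencies (0.5, 1, 2, 4,
  8, 16 Hz), infinite orientation bandwidth — 30 conditions.
* **Dataset 2** (anisotropic): the same 30 frequency combinations with
  a 15 deg FWHM orientation band whose center rotates clockwise at
  45 deg/s, so a 4-s epoch sweeps `[0, 180)` exactly once.
* **Dataset 3** (elongation): 4 spatial frequencies (0.04–0.32 cpd) x 4
  orientation bandwidths (infinite, 60, 30, 15 deg FWHM) at 2 Hz — 16
  conditions.

Stimuli are synthesized (`synthesize_noise_movie`) by shaping white
Gaussian noise with a spectral amplitude mask that is Gaussian in log2
radial spatial frequency and log2 temporal frequency (FWHM = 1 octave
each) and, for anisotropic conditions, Gaussian in orientation angle
(wrapped on the 180-periodic circle, FWHM = the condition's bandwidth),
applied per frame at the rotating center orientation. Movies are
normalized to 50% RMS contrast around a mean luminance of 1, an
idempotent operation.

Two stimulus-domain choices deserve explanation:

* **Filter roll-off.** The bandpass family is not dictated by the
  design beyond "narrow"; Gaussian profiles in log2 frequency were
  chosen because the downstream tuning model is itself log-Gaussian, so
  the stimulus and analysis share one parameterization of "1-octave
  bandwidth".
* **Spectral envelope vs 1/f base.** The filter mask is applied as the
  movie's *realized* spectral envelope. Composing the Gaussian envelope
  with an uncompensated 1/f amplitude base would displace the realized
  spectral peak by about `sigma^2 * ln 2` (~0.13 octave) below the
  nominal center — off the coordinates every later analysis assumes.
  Since a white Gaussian base supplies random phases with flat expected
  amplitude, specifying the envelope directly is the construction that
  keeps the stimulus on its stated (SF, TF) coordinates.

Movies default to 64 x 64 pixels over a 100-degree field (a single
pixel pitch on both axes so the FFT grid is isotropic) at 30 fps.
This preserves every tested frequency except the extreme corner of the
grid: at 0.32 cpd or 16 Hz the 1-octave upper band edge exceeds the
Nyquist limit, which raises a warning, and such conditions are
validated analytically on the filter profile (`measure_filter_fwhm`)
rather than on a rendered movie. A center frequency above Nyquist is an
error.

# Synthetic population and calcium model

`sample_population` draws a nested population: per-mouse random offsets
(SD 0.3 octave for log2 SF/TF preferences, 0.1 for the speed index) are
shared by all neurons of a mouse, then neurons draw tuning parameters
from per-area distributions. The per-area defaults encode the
qualitative organization the pipeline is meant to resolve — anterior
dorsal areas (AL, RL, AM) prefer low SF / high TF with high
speed-tuning indices and sharp-OS-rich cell-type mixtures; ventral
areas (LI, POR/P) prefer high SF / low TF with non-OS-rich mixtures;
V1 and LM sit in between. The default scale is 10 mice x 8 areas x 150
neurons per area per mouse.

Each neuron's response to a condition follows the tuning surface
(below) times an **elongation gain** at the condition's orientation
bandwidth. The gains are 4-vectors over {infinite, 60, 30, 15} deg by
cell type: decreasing for non-OS (suppressed by elongation), increasing
for sharp-OS (driven only by elongated patterns), flat for broad-OS
(elongation-invariant). Because anisotropic epochs sweep orientation
through the full `[0, 180)` range, the epoch-mean response is
independent of preferred orientation, so the gains directly encode
orientation-averaged drive; the neuron's orientation tuning instead
shapes the *within-epoch* time course, which is what the OSI estimator
reads out.

**Orientation tuning curve.** A wrapped Gaussian on the 180-periodic
orientation circle, peak-normalized, parameterized by FWHM. A
FWHM-matched von Mises was considered and rejected: its heavy tails
retain appreciable selectivity (OSI ~ 0.17) even at 170 deg FWHM,
whereas near-flat tuning at the widest widths is part of the validation
contract; the wrapped Gaussian is equally circular-correct and achieves
it.

**Calcium dynamics.** Spike-to-fluorescence conversion uses a
double-exponential kernel (rise 200 ms, decay 560 ms — GCaMP6s-typical),
normalized to unit integral so a sustained rate converges to its own
amplitude. The epoch-mean of a 4-s boxcar under this kernel is
attenuated by a closed-form factor (`kernel_epoch_mean_factor`, ~0.815
at 8 Hz), which scales all amplitudes uniformly and therefore biases
only the fitted peak amplitude, not preferred frequencies or slant.

**Trial noise.** Additive Gaussian noise of SD 0.05 dF/F per frame plus
a multiplicative epoch gain with CV 0.15. These defaults place the
reliability distribution astride the r > 0.3 selection threshold, so
quality control is exercised in both directions rather than trivially
passed. Traces are emitted directly as dF/F at 8 Hz (the raw-movie
processing pipeline — registration, ROI detection, neuropil
subtraction — is upstream of this package's scope).

# Quality control

Responses are de-randomized into canonical condition order
(`derandomize`); each condition's window carries the preceding gray
(baseline), the 4-s stimulus, and the following 4-s gray. A neuron is
**responsive** if the across-trial median time course of at least one
condition exceeds its pre-stimulus baseline by more than 3 SD
continuously for more than 1 s during the stimulus; the baseline is the
final 2 s of the preceding gray, which leaves room for the previous
epoch's calcium tail to decay. Neurons meeting the criterion only
within 2 s after stimulus offset are flagged offset-only and excluded
(the window is a package choice; the criterion names no width).

The **reliability index** r is the 75th percentile (linear
interpolation between order statistics) of the 6 pairwise Pearson
correlations between concatenated de-randomized trial time courses.
Correlations are computed on full epochs (stimulus plus following gray)
so offset transients count consistently; a per-condition mode exists
behind a flag. Zero-variance trials contribute correlation 0, keeping r
defined for silent neurons, which then fail the threshold. A shuffle
control (`reliability_null`) permutes epoch identity within trials and
reports the 97.5 and 99.75 null percentiles. Selection requires
responsive, not offset-only, and r > 0.3.

# Tuning model

The core model (`evaluate_model`) is an elliptical Gaussian in log2
frequency coordinates,

$$R(sf, tf) = A \exp\!\left(-\frac{(\log_2 sf - \log_2 sf_0)^2}{2\sigma_{sf}^2}\right)
             \exp\!\left(-\frac{(\log_2 tf - g(sf))^2}{2\sigma_{tf}^2}\right),
\qquad g(sf) = \xi\,(\log_2 sf - \log_2 sf_0) + \log_2 tf_0,$$

where the slant `xi` is the speed-tuning index: 0 for separable SF x TF
tuning, 1 for tuning invariant along lines of constant speed `tf/sf`.

**Fitting** (`fit_spatiotemporal`) is bounded multi-start least squares:
starts at the observed peak with slants {−1, 0, 1}, refined by
`L-BFGS-B` within bounds spanning the tested range plus or minus two
octaves (`sf0` in [0.005, 1.28] cpd, `tf0` in [0.125, 64] Hz, widths in
[0.3, 10] octaves, `xi` in [−3, 3]). Fit quality is the normalized RMS
error, RMS residual divided by the fitted peak amplitude (the fitted
peak is more noise-robust than the raw maximum; a flag switches).
Fits with nRMSE < 0.1 are accepted; parameters are reported but flagged
otherwise. Where both the isotropic and anisotropic batteries yield
accepted fits, the one with the larger fitted peak is selected
(`select_best_fit`; exact ties resolve to the isotropic fit).

**Derived quantities.** Half-maximum cutoffs of the slices
`R(sf, tf0)` and `R(sf0, tf)` have closed forms; along SF the slant
contributes a second exponential, shrinking the effective width via
`1/sigma_eff^2 = 1/sigma_sf^2 + xi^2/sigma_tf^2`. Shapes are lowpass /
bandpass / highpass against the tested bounds; when both cutoffs fall
outside the bounds the dimension is labeled broadband and excluded from
bandpass fractions (a case the taxonomy otherwise leaves undefined).
Peak speed is `tf0/sf0` in deg/s; speed-tuned means `xi > 0.5`,
strictly, from isotropic fits.

**Anisotropy preference.** `API = (R1 − R0)/(R1 + R0)` over the peak
anisotropic and isotropic amplitudes, in [−1, 1]; categories use the
closed outer ranges [−1, −1/3] (ISO-preferring) and [1/3, 1]
(ANISO-preferring), mixed in between.

**Orientation selectivity.** The time course at the neuron's peak
anisotropic condition approximates an orientation tuning curve through
the known trajectory `theta(t) = 45 t mod 180`. Because calcium decay
outlasts the stimulus, post-offset activity is wrapped around — added
onto the onset response at `t − 4 s` — before binning into 12 bins of
15 deg (the bin count is a package choice). OSI = 1 − circular variance
on the doubled angle; negative bin amplitudes are clipped to zero since
the formula treats them as nonnegative weights. Trial time courses are
averaged with the mean before binning.

The estimator is validated by simulation (`validate_osi`): Poisson
spike trains with zero spontaneous rate driven through wrapped-Gaussian
tuning curves of 10–170 deg FWHM, convolved with the calcium kernel.
Spike-binned OSI and the wrap-around calcium OSI are compared across
the sweep; the calcium estimate is attenuated but monotonically related
(rank correlation > 0.95), which is the property the downstream
analyses rely on. The default simulation rate (100 Hz peak) keeps the
small-sample positive bias of the circular-vector estimator below the
near-flat contract at the widest tuning.

# Hierarchical bootstrap statistics

Nested data (cells within animals) violate the independence assumptions
of plain two-sample tests. The package's machinery
(`hierarchical_resample`) draws M animals with replacement, then N
cells with replacement within each drawn animal, L times. For a
two-group comparison (`hb_ks_test`) the KS statistic D is computed on L
paired resamples; for each significance level alpha the interval
between the `alpha/2` and `1 − alpha/2` percentiles of D is compared to
the asymptotic critical value

$$D_\alpha = c(\alpha)\sqrt{\frac{n_1 + n_2}{n_1 n_2}},
\qquad c(\alpha) = 1.36,\ 1.63,\ 1.95 \text{ for } \alpha = 0.05,\ 0.01,\ 0.001,$$

with `n1 = n2 = N*M`, the resampled sizes (the consistent choice, since
D is computed on resamples). The most stringent level whose lower CI
bound exceeds its critical value is reported. The construction is
conservative by design; calibration on null two-level data (100
replicate runs) keeps the rejection rate at the 0.05 label below 10%.
The asymptotic critical-value formula's small-sample behavior is
inherited, not corrected, and no multiple-testing correction is applied
across area pairs. Effect sizes between bootstrap distributions use
Cohen's d with categories small (< 0.2), median (0.2–2, closed
interval), large (> 2). Density summaries use Gaussian KDEs with
bandwidth 0.05 or 0.1 depending on the parameter's scale.

# Speed decoding

Speed pairs are neighboring dataset-1 conditions lying orthogonally to
iso-speed lines — `((sf, tf), (2sf, tf/2))`, a 4-fold speed difference;
swapping the combination gives the matched iso-speed pair, identical
speeds. The full grid yields 20 pairs of each kind.

`decode_pair` trains a linear SVM (cost C = 1, features z-scored with
training-split statistics only; the protocol fixes neither, these are
package choices) on 2 of the 4 trials per condition and tests on the
other 2; accuracy is the fraction of the 4 test presentations
classified correctly, averaged over 100 random splits. `pool_curve`
repeats this for 50 random neuron pools (drawn with replacement, which
equalizes pool availability across areas) per pool size, reporting the
mean and 95% CI over pools. Differences between conditions or areas
(`delta_accuracy`) are evaluated at pool size 16 — small ensembles
discriminate best between populations — with a two-sample t-test over
the 50-resample accuracy sets.

A structural caveat worth stating: with 4 trials there are only 6
distinct half-half splits, so a given pool's iteration-averaged
accuracy converges to a data statistic with an SD near 13 percentage
points under pure noise; the 50-resample grand mean of a chance
calibration therefore carries an intrinsic SD of about 2 points. This
is a property of the protocol, not of the implementation.

# Clustering

**Elongation types.** Per area, 10 sub-datasets of 500 reliable cells
are drawn hierarchically (mice with replacement, then cells); all
sub-datasets are pooled and ward-linkage clustering (squared-Euclidean,
`ward.D2`) is cut at 3 clusters. Clusters are *named by their mean
curve's slope* over bandwidth levels — decreasing = non-OS, increasing
= sharp-OS, flat = broad-OS — so the naming is invariant to cluster
index permutations.

**Functional clusters.** Each eligible neuron contributes a 60-element
vector (30 ISO + 30 ANISO trial-averaged amplitudes), min-max
normalized per neuron to [0, 1] (constant rows cannot be normalized and
are dropped with a warning); 2000 rows per area are sampled with
replacement. The first 12 principal components are extracted (PCA after
concatenating areas, matching a single training dataset), and k-means
(20 seeded restarts, best inertia) is run for each candidate k, scored
by mean silhouette on squared-Euclidean distances — matching the
clustering metric — plus Davies-Bouldin and Calinski-Harabasz indices
as independent checks. The selected k is the silhouette argmax; on
planted 12-archetype data the argmax lands at 12 with high label
agreement, which is the recoverable form of the "about 12 clusters"
structure. The whole population is then assigned to nearest centroids
in PC space (ties to the lowest index).

**Composition statistics.** Per area, 1000 hierarchical bootstraps (5
mice, 150 neurons per mouse) give cluster-proportion distributions,
expressed as ratios to the 1/k chance level with 95% CIs;
over/under-representation means the CI excludes chance. Area similarity
is the Pearson correlation of composition vectors per bootstrap (mean
and s.e.m. over bootstraps), with Cohen's d contrasts between
similarity distributions. t-SNE (perplexity 120 for global structure,
learning rate n/10) provides the 2-D view; descriptive cluster tags
derive from centroid properties rather than any fixed ordering.

# Maps

`phase_map` recovers retinotopy from a widefield movie: cycle-averaged
per-pixel time courses, phase = argmax time over the 20-s cycle
(matching the "location evoking maximal response" definition; a
first-harmonic Fourier mode is available for noisy data), amplitude =
peak-to-trough, with low-amplitude pixels flagged unreliable. The
estimator is unbiased up to a constant kernel-lag offset shared by all
pixels, which `phase_rmse` removes before comparing to ground truth.
`parameter_map` renders cortical parameter maps as Gaussian-weighted
local averages (the 400-um "filter width" is interpreted as the kernel
sigma; an FWHM interpretation is available), masking empty cells, and
is linear in the value vector.

# Problem sizes and reproducibility

All randomness descends from a single root seed through
`stage_seed(root, stage_name)`; re-running any stage with the same
configuration is bit-reproducible, and the end-to-end pipeline
(`run_pipeline`) regenerates byte-identical CSV outputs.

Problem sizes are chosen per purpose. The population generator's
default (10 mice x 8 areas x 150 neurons) represents the full study
scale. The default *pipeline* configuration runs the complete analysis
at 6 mice x 8 areas x 30 neurons with a reduced protocol (KS bootstrap
N = 50, M = 5, L = 200; one decoded pair in two areas at pools 2–16
with 20 resamples x 50 iterations; clustering on 150 sampled rows per
area with 200 composition bootstraps) — a scale at which every stage,
including its validation against ground truth, completes in minutes on
one CPU. The test suite uses smaller fixtures still, and the KS
calibration runs 100 replicate null datasets at N = 50, M = 5, L = 200.

# What synthetic validation does and does not show

Passing recovery tests demonstrates that the estimators are correct and
well-calibrated *under the generative model*: log-Gaussian tuning
surfaces, wrapped-Gaussian orientation tuning, linear double-exponential
calcium dynamics, Gaussian additive plus multiplicative epoch noise,
and stationarity within a session. Real recordings violate all of these
to some degree — calcium indicators saturate and their kinetics vary
across cells, response nonstationarity and correlated (shared) noise
across neurons are the norm, tuning surfaces need not be Gaussian, and
neuropil contamination survives imperfect preprocessing. Consequently,
synthetic recovery bounds estimator error from below, not from above;
area contrasts on real data additionally depend on sampling biases the
generator only caricatures. The pipeline's value on real data is that
every stage's behavior is known exactly on data where the truth is
known.

Other known limitations: no direction selectivity is computed (the
stimuli are non-coherent noise); spherical display geometry is not
modeled (coordinates are flat-screen degrees); the decoding chance
level carries the protocol-intrinsic variance described above; and the
12-cluster structure of real populations is not asserted — only the
procedure and its planted-model behavior are.
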