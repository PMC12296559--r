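---
title: "Sensor-to-source analysis of event-file binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-to-source analysis of event-file binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`eegbind` implements a complete sensor-to-source analysis chain for
prime–probe (S1–S2) "event file" experiments: behavioral binding statistics,
Morlet time–frequency analysis with FDR control, DICS and LCMV beamforming on
an analytic spherical head model, DBSCAN clustering of source maps, and
time-resolved correlations between pre-trial and post-trial source power.
Because raw data of this kind are rarely shareable, the package also ships a
forward-modelling simulator that plants the effects the analysis is meant to
detect, so every stage can be validated end to end against a known ground
truth. This vignette records the models, the tunable parameters, and the
design decisions that were genuinely open.

## The behavioral model

In the S1–S2 task, four key cells cross the response relation (repeated RR /
alternated RA) with the feature relation (repeated FR / alternated FA).
Partial repetition — only the response or only the features repeating — is
costly because the event file bound at S1 must be reconfigured. The binding
score summarises this cost:

score = (RRFA − RRFR) + (RAFR − RAFA),

applied identically to mean reaction times (ms) and to error rates
(percentage points). The score is invariant to adding a constant to all four
cell means, so participant-level speed differences cancel.

Trial filtering follows the standard scheme: S1-incorrect trials are dropped;
S2 RTs below 200 ms are dropped; and each participant's remaining S2 RTs are
truncated at the Tukey upper fence Q3 + 1.5·IQR. Quartiles use linear
interpolation between order statistics (R's default type-7 rule); the choice
of quantile rule is not standardised in the field, so it is exposed as the
`qtype` argument. RT analyses use S2-correct trials only; error analyses keep
the errors. With fewer than four retained trials a fence is not estimable in
any meaningful sense; such participants are flagged and left untruncated.

Group statistics are the one-sample t (with the within-subject effect size
dz = M/SD), Welch's t with Satterthwaite degrees of freedom, the 2×2
chi-square with Yates continuity correction (the corrected form is the
default because it reproduces the published demographic comparisons exactly
at two decimals, which the uncorrected form does not), and a mixed 2×2×2
ANOVA. The ANOVA is computed by explicit per-subject contrast decomposition
with unweighted (Type III) marginal means — exact for the balanced 2×2
within-subject design and deliberately not a general mixed-model solver.
Generalized eta squared follows the Bakeman/Olejnik convention
SS_effect / (SS_effect + all subject-related error SS).

## The synthetic study

The behavioral generator draws, per participant, a speed intercept
(SD 25 ms) and an individual binding cost ~ N(δ, 30 ms); trial RTs are
shifted-lognormal (shift 150 ms, within-cell SD 150 ms) so that the
distribution has positive support and realistic right skew. Defaults are
24 trials per cell (384 trials over 16 conditions, of which the four
full-repetition/alternation cells are analysed), δ = 35 ms — giving the
expected score 2δ = 70 ms, in the range of the published group means — and
error probabilities 0.05 (baseline) + 0.10 (binding cost), giving an
expected error-rate score of 20 percentage points. Individual binding costs
may be negative, as real participants' are; the expectation of the score
stays exactly 2δ.

The EEG generator places oscillating dipoles at grid voxels. Each source has
a frequency, a dipole orientation (by default a deterministic tangential
unit vector, the orientation EEG sees best), and a mean amplitude (nA·m) per
condition × period. The three analysis periods are post-S1
[−2500, −1500) ms, pre-S2 [−1000, 0) ms and post-S2 [0, 1000) ms relative to
S2; all windows in the package are half-open so adjacent windows never share
samples, and the sample at t = 0 belongs to post-S2. Epochs span
[−7000, 2000) ms at 256 Hz — exactly 2304 samples. Per trial, the oscillation
phase is uniform and the amplitude is A·(1 + cv·z) with a standard-normal
latent z and cv = 0.3; a planted coupling ρ ties the latents of a designated
(source, period) pair through a shared factor with loading √ρ, which yields
an across-trial amplitude correlation of exactly ρ in expectation. In
multi-participant studies the same construction is applied a second time to
per-participant amplitude scale factors (cv = 0.3), because the correlation
analysis operates across participants. Sensor data are the lead-field
projection of all sources plus white noise (default SD 1 µV).

What the simulator does *not* emulate: ocular/muscle artifacts, 1/f
background spectra, volume-conduction inhomogeneities, or any mechanistic
model of event-file formation — only the measurable signatures (RT costs,
condition-dependent band power, pre/post amplitude coupling). Passing tests
therefore demonstrate that the analysis recovers planted effects under the
model's assumptions, not that it is robust to every property of real EEG.

## Forward model

The head is a single homogeneous conducting sphere (radius 0.09 m,
conductivity 0.33 S/m) with sensors on a deterministic Fibonacci covering of
the sphere (60 by default, configurable). The surface potential of an
interior current dipole has a closed form: with f the fractional source
depth, u the cosine of the source–electrode angle, s = √(1 − 2fu + f²), the
radial and tangential gains are

S1 = (2f(u − f)/s³ + 1/s − 1)/f,  S2 = 2/s³ + ((f − u)/s + u)/(f(1 − u²)),

and V = (A·S1 + B·S2)/(4πσR²) with A the radial moment and B the tangential
projection. Numerically, the S2 fraction is rationalised for |u| > 0.9 to
avoid cancellation at electrodes aligned with the source, and a short series
expansion is used for sources within 10⁻³ R of the centre. The tests check
the closed form against an independent spherical-harmonic series oracle to
eight digits. Gains are average-referenced, matching the re-referencing of
the recordings. A three-shell or BEM model would scale all gains and smear
topographies but leaves every recovery property in this package qualitatively
unchanged; individual anatomy is explicitly out of scope.

The source grid is a cubic lattice clipped to the strict sphere interior,
0.005 m spacing by default (the 0.5 cm resolution standard for this
analysis), ordered lexicographically so voxel and cluster identities are
reproducible. Region labels are an input — geometric octant labels by
default — standing in for an anatomical atlas; a label set to exclude
(e.g. cerebellar regions) is a configuration option.

## Preprocessing

Resampling uses the Fourier method (spectrum truncation with symmetric
Nyquist-bin splitting), which is exact for band-limited signals on finite
epochs; a 10 Hz test tone survives 500→256 Hz resampling with ~0.01%
amplitude error. Filtering is an order-8 Butterworth band-pass (0.5–40 Hz)
plus an order-2 band-stop notch (48–52 Hz), both applied forward–backward
for zero phase; the band-pass poles at these design frequencies have modulus
0.9954, comfortably stable. Epoch rejection slides three windows in steps of
one sample: peak-to-peak > 200 µV within 200 ms, |amplitude| > 200 µV, and
peak-to-peak < 0.5 µV within 100 ms (the "low activity" metric is
peak-to-peak; the convention is not standardised, so thresholds and windows
are all arguments). A trial is dropped if any channel violates any rule in
any window, which makes rejection order-independent and idempotent. The
running extrema use a doubling scheme (O(n log w)) so the exhaustive
single-sample stepping stays fast.

## Time–frequency analysis

Morlet wavelets with width 5 cycles (σ_t = width/2πf), normalised to unit
total energy so white noise has flat expected power across frequencies.
Power is the squared magnitude of the complex convolution; samples closer to
an epoch edge than half the wavelet support are flagged invalid. The sensor
contrast compares FR against FA within a response-relation condition by
paired t tests per channel and 50 ms time bin inside 0–1000 ms (bin width
configurable; the published analyses report significant sub-windows but not
their binning), with Benjamini–Hochberg adjustment across the channel × bin
family within one band and response condition. The BH family is a genuine
free choice; it is documented, configurable, and fixed before testing.

## Source analysis

CSD matrices come from Hanning-tapered per-trial FFTs, averaged over trials
and over the FFT bins inside the band. DICS uses the unit-gain scalar
beamformer: the CSD is regularised as C + λ·mean(diag C)·I with λ = 0.05 by
default (the regularisation level is never stated in the published method;
it is exposed in the configuration and logged in every run), the orientation
per voxel minimises the quadratic form u'·Re(L'C⁻¹L)·u, and
w = (l'C⁻¹l)⁻¹ l'C⁻¹. The common filter is computed from the CSD pooled over
all trials of all conditions in the window, then applied to
condition-specific CSDs, so condition differences cannot leak into the
filters. The FR/FA contrast map is the normalised ratio
(P_FR − P_FA)/(P_FR + P_FA) ∈ [−1, 1], defined as 0 where both powers
vanish. Pre-trial maps are reported as the neural activity index, power
divided by the projected regularisation-noise power of each filter — the
standard unit-noise-gain convention, stated explicitly because NAI
definitions vary.

Cluster candidates are the top 1% of eligible voxels. Power and NAI maps
rank by signed value; ratio maps rank by magnitude separately within the
positive and negative sides (condition contrasts are meaningful in both
directions), each side keeping ceiling(fraction × side size) voxels. Ties
break by voxel order. DBSCAN runs with minPts 2 and eps = 1.5 × grid
spacing, which connects face (1.0) and edge (√2 ≈ 1.41) lattice neighbours
but not corner (√3 ≈ 1.73) or two-step axial (2.0) ones; at minPts 2 the
partition provably equals the connected components of the eps graph, which
is what the test oracle computes.

LCMV repeats the beamformer algebra on the real TOI covariance (per-trial
channel means removed within the TOI), restricted to the member voxels of a
cluster; reconstructed raw series are averaged across the cluster *before*
wavelet power is taken (the alternative — averaging power across voxels —
discards within-cluster phase alignment; raw-series averaging is declared as
the package's reading of "filtered average data within each cluster"). The
post-trial binding signature is the element-wise FR − FA difference of
band-power courses.

## Correlation analysis

The observational unit is the participant: each participant contributes one
pre-trial and one post-trial band-power course (trials averaged), and
r[i, j] is the Pearson correlation across participants between pre power at
time i and post power at time j, with p from the t transform and BH
q-values over the cells of one cluster-pair matrix (one matrix = one FDR
family). Cells involving a zero-variance time point are excluded from the
family. Two thresholds are conventional, q < 0.01 and q < 0.05; both are
supported and reported, with 0.01 as the stricter default. The choice of
participants (not trials) as the unit, and of the matrix as the family, are
both declared decisions — neither is standardised.

## Problem sizes and validation design

The validation experiments are sized for a desk-scale reproduction and are
stated here as the package's own choices. The end-to-end study simulates 24
HC participants, 24 trials per cell, 24 channels, and a 1.25 cm grid inside
a 5 cm source sphere; it must recover (i) a positive group binding score
from δ = 35 ms, (ii) a significant theta FR-vs-FA sensor contrast, (iii) a
DBSCAN cluster containing the planted source voxel, and (iv) a q-masked
block in the pre/post correlation matrix from ρ = 0.6 participant-level
coupling. The correlation grid is decimated to every 8th sample because
theta-band power, smoothed by a wavelet with σ_t ≈ 200 ms, carries no
information at 4 ms resolution. DICS localisation runs 100 independent
single-dipole simulations at sensor-variance SNR 10 and requires ≥ 95 hits
within one grid step. Coupling recovery simulates 200 trials with ρ = 0.7,
reconstructs both sources with LCMV, evaluates band power (5–7 Hz wavelets,
matching the 6 Hz planted source within one wavelet bandwidth) averaged in
four 250 ms sub-windows per period, and requires the planted ρ to fall in
the Fisher 95% CI of the mean matrix correlation; sub-window averaging is
used because single-point power estimates carry beamformer output noise
that attenuates correlations. Null calibration uses 200 replicates of
independent power-like series at n = 30.

## Known limitations

The spherical model cannot reproduce anatomical cluster locations, only
geometric recovery. The ANOVA handles exactly the 2 (group) × 2 × 2 design.
DBSCAN is O(n²) in the selected voxel count — irrelevant at the top-1%
scale it is used for. The BrainVision reader covers the common
float32/int16 multiplexed layout, not vectorized or ASCII variants. The
epoch container is R serialization, chosen over a hierarchical binary format
because no HDF5 binding is available in the supported dependency set;
round-trips are bit-exact but the files are R-specific.
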