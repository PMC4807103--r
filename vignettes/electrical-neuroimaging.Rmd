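---
title: "Electrical neuroimaging of two-session ERP experiments with erpfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrical neuroimaging of two-session ERP experiments with erpfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`erpfield` implements the analysis chain of a two-session event-related
potential (ERP) study in the electrical-neuroimaging tradition: epoched EEG
is turned into subject and group ERPs; condition differences are assessed
first channel-by-channel (mass-univariate paired t-tests with temporal and
spatial persistence criteria), then at the level of the whole electric
field (Global Field Power and topographic dissimilarity with paired
randomization tests), and finally in source space (a distributed inverse on
an analytic spherical head model, with voxel-wise parametric mapping and a
cluster-extent threshold).  Because studies of this kind rarely deposit raw
EEG, the package ships a dipole-based synthetic experiment generator with
full ground truth, so every stage of the chain is verifiable by simulation.

The protocol constants the package defaults to are those of a typical
high-density cued Go/NoGo preparation study: 500 Hz sampling, 1–30 Hz
band-pass, epochs −200..1000 ms around the cue, average reference, a 65 μV
amplitude-rejection criterion, a floor of 80 accepted trials per
subject/session, 110 scalp channels, α = .05 with a 20 ms (10-sample)
temporal-persistence criterion, at least 5 contiguous electrodes within
nine scalp clusters for waveform effects, 1000 permutations per time point
for the randomization tests, and a 10-point cluster-extent threshold for
source contrasts (with 15 subjects, the two-tailed critical value is
t(14) = 2.14).

# The synthetic experiment generator

`sim_design()` + `simulate_experiment()` produce a complete two-session,
multi-subject experiment.  Scalp signals are built physically: each
`source_component()` is a current dipole inside the brain sphere with a
Gaussian-windowed time course (peak latency, FWHM, amplitude), projected
through the three-shell spherical forward model.  Condition effects enter
in the two ways electrical neuroimaging distinguishes:

* **strength effects** — per-condition gain multipliers on a component.
  They scale Global Field Power but leave the normalized topography
  untouched;
* **topography effects** — per-condition source locations.  By default the
  displaced condition's scalp map is rescaled to the Global Field Power of
  the reference condition (`equalize_gfp = TRUE`), making the manipulation
  a pure change of configuration.  Without this, a displaced generator also
  changes field strength (different depth/orientation project with
  different efficiency), and a source-space contrast is then dominated by a
  global energy difference rather than by the displacement itself.

The default component set emulates a preparatory ERP: a posterior visual
response common to both sessions; a central preparatory component 1.6×
stronger in session A, peaking at 350 ms (a pure strength effect around
300–400 ms); and a late component whose generator sits in left premotor
cortex in session A but in its right-hemisphere counterpart in session B,
active around 430–480 ms (a pure topography effect; a right-lateralized
inhibitory generator in a covert-action session is the kind of displacement
such studies report).  Component locations sit on solution points of the
default ~1000-point source grid so the simulated ground truth is exactly
representable in source space — the usual convention in source-recovery
simulations.

Noise is temporally white Gaussian at the sensors, `noise_sd = 15` μV per
channel and sample, with an exponential spatial covariance scaled so that
neighbouring electrodes correlate at `noise_spatial_corr = 0.6`.  After the
1–30 Hz filter this leaves a single-trial background of about 5 μV RMS,
a realistic figure for filtered high-density EEG.  Between-subject
variability is a log-normal global gain (`subject_gain_sd = 0.2`).
Artifacts are 50 ms half-sine bursts of ±120 μV on one random channel in a
random 5% of trials; small fractions of trials are pre-flagged as
EMG-contaminated or error trials (2% each), mimicking upstream exclusion
stages whose detection is out of scope.  With 100 trials per condition the
expected accepted count (~91) stays above the 80-trial floor.

Everything derives from one master seed through fixed substreams
(`substream_seed()`), so a design reproduces bit-for-bit, per-subject and
per-condition streams are mutually independent, and the ground-truth record
(component parameters, per-subject gains, artifact and exclusion indices)
accompanies every dataset.

**What the generator does not emulate**: ocular/muscular artifact
morphology (bursts are generic transients), overlapping epochs or
inter-trial dependence (epochs are independent), non-stationary or
1/f-structured background EEG, anatomical head geometry, and behavioural
responses.  Passing the recovery suites therefore demonstrates the
correctness and calibration of the *statistics and inverse machinery* under
a controlled, physically forward-modelled data-generating process — not
robustness to every pathology of real recordings.

# Preprocessing

The chain is fixed and logged in protocol order: band-pass filter → average
reference → amplitude rejection → trial floor → spherical-spline
interpolation of bad channels (followed by re-referencing, which
interpolation slightly perturbs) → trial averaging.  Choices worth
recording:

* **Filter realization.** The 1–30 Hz Butterworth band-pass (4th-order
  transfer function) is applied with zero phase by multiplying the data's
  spectrum with the filter's forward-backward magnitude-squared response,
  after odd-symmetric reflection padding of up to one second.  This is the
  same response a forward–backward IIR pass produces (the suite verifies
  agreement with `signal::filtfilt` to a fraction of a percent away from
  the edges) but runs vectorized over all channels and trials at once,
  which keeps multi-subject simulations tractable; it is also free of the
  IIR edge transients.
* **Rejection semantics.** The 65 μV criterion is applied to the absolute
  post-filter voltage of every channel and sample; a trial is rejected when
  any value strictly exceeds the threshold.  Peak-to-peak semantics exist
  in the wild; the threshold parameter is exposed so either can be
  emulated.
* **No baseline correction** is applied by default — the emulated protocol
  never mentions one; an opt-in flag exists.
* **Spline parameters.** Perrin-style spherical splines with stiffness
  m = 4, 50 Legendre terms and ridge λ = 1e−5, fitted on the good channels
  under a zero-sum constraint.  The spline reproduces constants exactly and
  reconstructs a deleted channel of a forward-modelled dipole map with a
  median error below 10% of the map's GFP at 110 channels (and improves
  with montage density) — the forward model acts as the oracle here.

# Waveform statistics

`waveform_analysis()` computes point-wise paired t-tests on subject ERP
amplitudes (two-tailed, df = n−1; zero-variance differences get p = 1 and
are counted).  Significance must persist ≥ 10 contiguous samples per
channel (20 ms at 500 Hz) and, at each sample, span ≥ 5
adjacency-contiguous electrodes within one of nine named scalp clusters
(anterior/central/posterior × left/midline/right).  The temporal filter is
applied first by default; the order and the within-cluster restriction are
configurable and logged.  Filters only ever remove significance; both are
cross-checked against brute-force connected-component oracles.  No
additional multiple-comparison correction is applied — by design the
persistence criteria are the only guard, which is a documented limitation
of this analysis tradition rather than an oversight.

# Global field statistics

GFP is the spatial standard deviation of the average-referenced map; DISS
between two GFP-normalized maps satisfies `DISS² = 2(1 − r)` with `r` the
spatial Pearson correlation — both identities are asserted to 1e−10 in the
suite.  The paired randomization tests exchange each subject's condition
assignment independently (sign-flip of the paired difference), recompute
the group statistic per permutation, and use inclusive p counting
`p = (1 + #[perm ≥ obs]) / (n_perm + 1)`, which keeps the test valid at
finite permutation counts; the observed-included convention is the
conservative default where the emulated protocol is silent.  The TANOVA
statistic is the DISS between the two group-average maps (each normalized
at the group level — the convention of the software family this protocol
descends from); a variant normalizing single-subject maps before averaging
is provided (`variant = "subject_normalized"`).  Under a null simulation
the per-sample type-I rate of both tests sits in the nominal band (the
calibration suite measures it at 500 replicates × 200 permutations).

Two behaviours deserve explicit mention.  First, after 1–30 Hz filtering
the noise is temporally correlated (~17 ms), so under the null an
occasional ≥ 20 ms spurious window survives the persistence criterion
(roughly every second null dataset at 600 samples).  Per-sample calibration
is exact; window-level family-wise error is *reduced*, not controlled, by
the persistence rule.  Second, with a strong strength effect the group-map
TANOVA is slightly liberal in the affected window (the weaker condition's
mean map is noisier after normalization); the noise-free limit behaves as
intended (a pure strength effect yields DISS ≡ 0 and no topographic
significance).

# Source model

The forward model is a three-shell concentric-spheres conductor (brain/
skull/scalp radii 0.87/0.92/1.0, conductivities 1 : 1/80 : 1).  Rather than
transcribing a published series, the per-order radial transfer factor is
obtained by solving the small linear system of potential/current continuity
conditions at the shell boundaries for each Legendre order (80 terms,
column-equilibrated); the solution is anchored in tests by three exact
oracles: the homogeneous-sphere harmonic response `(2n+1)/n·R^{-(n+1)}`,
the central-dipole closed form `V = 3 q·ê / 4πσR²`, and the free-medium
dipole potential recovered from the bare multipole expansion.

Solution points live on a cubic lattice strictly inside the brain sphere
(~1000 points by default, a desk-scale stand-in for clinical grids of ~3000
points, which remain one configuration change away), with 26-neighbourhood
adjacency.  Two inverse operators are provided:

* `build_laura_inverse()` — a weighted minimum norm with a local
  autoregressive prior: each point is penalized for deviating from the
  inverse-squared-distance-weighted mean of its grid neighbours (exponent
  configurable).  This is the operator for current-density waveforms and
  window averages; it is linear, strength-equivariant, and its estimate
  energy shrinks monotonically with λ.
* `build_sloreta_inverse()` — a minimum-norm operator whose per-point
  activity is standardized by the resolution-derived variance.  For
  noiseless data from a single dipole the standardized maximum provably
  sits at the true solution point, and the suite confirms exact recovery.

The second operator exists because implementation falsified a tempting
assumption: the smoothing prior's current-density magnitudes do **not**
localize point sources to within a grid spacing — noiseless point-source
peaks land 1–1.5 spacings away (and difference maps between two displaced
configurations peak further still), an intrinsic property of weighted
minimum norm, not a bug.  Localization-sensitive steps — notably the
voxel-wise condition contrast — therefore default to the standardized
operator (`pipeline_config(source_method = "sloreta")`), while LAURA
remains the current-density method.  λ is chosen by generalized
cross-validation on the analysed map by default and then held fixed across
subjects within a window, so every subject is inverted with the same
operator.

`estimate_window_activity()` averages the subject ERP over a window first
and inverts the single map (identical, by linearity, to averaging inverted
moments).  `voxelwise_contrast()` runs paired t-tests per solution point,
thresholds at the two-tailed critical value (2.14 at df = 14), forms
connected components over the grid adjacency separately for positive and
negative t, and discards components below 10 points.

# Pipeline and reproducibility

`run_pipeline()` executes synth → preprocess → waveform → GFP test → TANOVA
→ source contrasts, taking the source-analysis windows from the TANOVA
result (with manual override), and writes a JSON + text report that echoes
every effective parameter and is byte-identical across reruns with the same
seed (wall-clock timing and machine-local paths are excluded from the
JSON).  A thin command-line wrapper (`inst/cli/erpfield`) exposes
`simulate | preprocess | waveform | globalfield | sources | run` over
delimited-text datasets; the R functions are the primary interface.

# Problem sizes used by the verification suites

The test and acceptance runs use deliberately reduced problem sizes, stated
here as the package's own choices: null calibration uses 16 channels,
100-sample epochs, 15 subjects, 200 permutations and 500 replicates;
effect-recovery runs use the full 110-channel montage and 15 subjects with
40 trials per condition (a desk-scale reduction of the ~95 accepted trials
the emulated protocol yields — enough that sensor noise after averaging is
well below between-subject variability) and the ~1000-point grid.  At these
sizes the strength effect is detected by the GFP test in its 300–400 ms
window, the displacement by TANOVA in its 430–480 ms window, and the
displaced generator is recovered by a surviving cluster whose peak lies
within two grid spacings of the true location in ≥ 9 of 10 seeds.

# Known limitations

* The spherical head model and Fibonacci montage are analytic stand-ins;
  no anatomical labelling of solution points is provided or intended.
* The persistence criteria do not control family-wise error (see above).
* EEG cannot resolve sources under the electrode cap's lower edge; the
  recovery suites accordingly draw test sources from the covered region.
* TANOVA here handles exactly two paired conditions; factorial designs and
  microstate segmentation are out of scope.
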