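---
title: "Detecting near-falls from trunk angular kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting near-falls from trunk angular kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearfall)
```

## The problem

A near-fall is a sudden loss of balance — typically a trip or slip during
walking, or a loss of stability in quiet stance — that is caught by a
neuromuscular balance recovery response before the body hits the ground.
Near-falls are far more frequent than falls and are an early marker of
declining balance control, but outside the laboratory they are usually
assessed by questionnaires. This package implements an automated detector
that operates on two trunk kinematic signals about the transverse (pitch)
axis: the angular velocity $\omega_y$ and the angular acceleration
$\alpha_y$. The trunk is used because recovering from an antero-posterior
perturbation requires a rapid, high-magnitude trunk rotation that changes
the whole-body angular momentum; that rotation leaves a signature in both
signals simultaneously, while everyday activities (running, lifting
objects, stair walking) tend to produce large excursions in at most one of
them at a time.

## Measuring $\alpha_y$ without differentiation: the sensor cluster

Gyroscopes measure angular velocity; angular acceleration is usually
obtained by numerically differentiating it, which amplifies sensor noise by
a factor of order $1/\Delta t$. The alternative implemented here is a rigid
cluster of four accelerometer + gyroscope packages. Let $r_{i}$
($i = 1, 2, 3$) be the position of package $i$ relative to package 0 in the
cluster frame, $a_i$ the measured linear accelerations, and $\omega$ the
mean of the four gyroscope readings. Rigid-body kinematics give
$a_i - a_0 = \alpha \times r_i + \omega \times (\omega \times r_i)$,
and projecting each centripetal-corrected difference
$d_i = a_i - a_0 - \omega \times (\omega \times r_i)$ onto a second lever
arm turns the cross products into scalar triple products:

$$
\begin{pmatrix}
(r_1 \times r_2)^\top \\ (r_2 \times r_3)^\top \\ (r_3 \times r_1)^\top
\end{pmatrix}
\alpha =
\begin{pmatrix}
d_1^\top r_2 \\ d_2^\top r_3 \\ d_3^\top r_1
\end{pmatrix}.
$$

`cluster_angular_acceleration()` solves this 3-by-3 system per sample (a
direct solve, never an explicit inverse). The matrix is constant per
geometry, so its conditioning is checked once in `cluster_geometry()`
(condition number cap `1e8`); the default geometry uses near-orthogonal
lever arms of 0.08, 0.08 and 0.05 m. A note on conventions: the lever arms
must point *from package 0 towards package i* for the algebra above to
close — with the opposite convention the centripetal term changes the wrong
sign. The package fixes the convention operationally by the round-trip
property: `rigid_body_forward_model()` followed by the solve reproduces the
prescribed $\alpha$ to $10^{-9}$, and the test suite enforces this over
random rigid states with $|\omega| \le 20$ rad/s, $|\alpha| \le 500$
rad/s².

For comparison, `central_difference()` and `backward_difference()`
implement the single-sensor baselines. For white measurement noise of
variance $\sigma^2$, their output noise variances are
$\sigma^2/(2\Delta t^2)$ and $2\sigma^2/\Delta t^2$ — at 100 Hz and
$\sigma = 0.02$ rad/s that is a noise standard deviation of 1.4 and 2.8
rad/s² respectively, versus roughly 0.5 rad/s² for the cluster solve with
0.02 m/s² accelerometer noise. Boundary samples of the quotients are
dropped, not padded: padding manufactures spurious edge extrema, and every
downstream rule works on extrema.

## The subroutines

Four stand-alone primitives are reused throughout.

**Raw autocorrelation.** `autocorrelation()` computes
$c_k = \sum_{i=1}^{T-k} f(t_{i+k}) f(t_i)$, normalised by $c_0$. There is
deliberately no mean removal or per-lag renormalisation: the trunk signals
oscillate around zero and the detection rules were designed against this
raw form (a `demean` flag exists for exploration). The finite-sum taper
means $r_k$ decays roughly linearly in $k$ for periodic signals, which is
why the fundamental period carries the largest positive-lag peak.

**Zero-crossing extrema.** `local_extrema()` partitions the timeline into
maximal runs of constant sign (values $\ge 0$ count as positive) and takes
one extremum per run — the element of largest magnitude, earliest time on
ties. An "extremum" is therefore the peak of one excursion between two zero
crossings, not any turning point; small ripples riding on a large excursion
do not generate extra extrema. This is the right granularity for gait,
where one touchdown produces one excursion.

**Two outlier tests.** `outlier_quartile()` applies Tukey fences at
$c = 1.5$ interquartile ranges, with quartiles by linear interpolation of
order statistics at position $(n-1)p + 1$ (so `{1,2,3,4,100}` flags only
100). `outlier_max_vs_mean()` asks whether the absolutely largest element
of a set dominates the mean magnitude of the rest by the factor $c = 1.5$;
it is scale-invariant and is the test used to find the single anomalous
excursion of a recovery response among ordinary gait extrema.

**Extrema distribution monitor.** `distribution_monitor()` histograms
extrema magnitudes in bins of width $h$ anchored at zero and tests the
counts of the five lowest-magnitude bins against each other with the
quartile rule. A flagged bin marks a clutter population (noise-induced
extrema); the returned irrelevance bound is the highest flagged bin edge,
clamped to at least 2 rad/s² for $\alpha_y$ (0.1 rad/s for $\omega_y$) —
magnitudes in that range are attributable to noise or irrelevant trunk
motion regardless of the histogram. The anchor at zero and the reading of
"first five bins" as the five lowest-magnitude bins are implementation
choices of this package.

## Personalised thresholds

All detection rules are scaled by per-subject thresholds calibrated from
unperturbed baseline walking (the study design uses three trials at about
1.4 m/s). Per trial and per signal:

1. The step frequency is the reciprocal lag of the leading autocorrelation
   peak of $\alpha_y$ — each foot touchdown leaves a recurring local
   maximum. Peaks within 75% of the top coefficient count as co-dominant
   and the shortest such lag wins, which prevents locking onto twice the
   period. The estimate is also reported as steps/min; the generator's
   default cadence (116.8 steps/min) reproduces the cohort average.
2. Low-magnitude clutter is excluded: the distribution monitor (limits
   ±5 rad/s², ±0.25 rad/s; bin widths 1 rad/s², 0.05 rad/s) plus the
   unconditional clamp floor.
3. The exclusion cutoff for maxima is then raised by one bin width per
   iteration until the median spacing of the surviving maxima matches the
   step period within ±10% (at most 20 iterations, else a calibration
   error). Several stopping rules are defensible for the iterative routine; the
   median of successive spacings was chosen as the statistic because it tolerates a minority of spurious maxima — e.g.
   differencing artefacts that split one touchdown excursion into two —
   while the unconditional clamp floor keeps isolated sub-clamp clutter
   from ever entering the average. Minima get the same treatment with
   exactly two cutoff-raising iterations and no spacing criterion, since
   their timing is not tied to gait events.
4. The surviving extrema yield the four thresholds per signal: global
   maximum/minimum and averaged local maximum/minimum. Thresholds are
   averaged arithmetically across trials; the whole calibration is
   deterministic.

## Necessary condition: observation windows

`detect_windows()` implements the necessary condition for a near-fall call.
Extrema of $\omega_y$ beyond 1.15 times the personalised global extrema are
clustered (split at gaps longer than one step period; equality keeps the
cluster); each cluster, extended by half a step period on both sides, is
kept only if $\alpha_y$ also has an extremum beyond 1.15 times its global
thresholds inside the extended bounds. This joint requirement is the core
discriminator against single-signal events such as picking up a load,
which produces a large trunk angular velocity excursion with an
unremarkable angular acceleration. The 1.15 ratio is the detection
sensitivity knob; raising it can only remove windows (a property test
enforces monotonicity).

The onset is refined to the sample immediately after the last zero
crossing of $\alpha_y$ preceding the first triggering extremum; the offset
is the zero crossing after the last in-window extremum, accepted only if
for one further step period every extremum of *both* signals stays inside
the band `[1.15 x global_min, 1.15 x global_max]` — a violating extremum
re-extends the window and the search repeats. The band test is applied to
both signals (the conservative choice; a looser variant would test
$\alpha_y$ alone). Windows truncated by the record are kept and flagged;
overlapping refined windows are merged.

## Sufficient conditions: the three-step cascade

Each window passes through up to three short-circuiting steps
(`classify_trial()` records which step decided, and why):

**Step 1 — periodicity versus correlated outliers.** Touchdown-type maxima
of $\alpha_y$ (those reaching at least half the window's largest maximum
and clearing the noise clamp) recurring at a stable spacing identify
periodic locomotion: at least five such maxima with three or more
successive spacings within ±10% of their median classify the window as an
ADL. The repetition minimum matters: a decaying recovery transient is
briefly periodic at its own ring-down frequency but cannot supply five
comparable lobes. Periodicity is evaluated first, because within a
periodic train the largest (jittered) touchdown would otherwise
occasionally pass the max-vs-mean test and read as an outlier. If the
window is not periodic, a time-correlated outlier pair — a
`outlier_max_vs_mean()` outlier among the relevant extrema of each signal,
within ±0.15 s of each other — is the recovery signature. Outlier
reference sets are relevance-filtered by the calibrated irrelevance
bounds so noise extrema cannot dilute the reference mean; if fewer than
two relevant extrema remain (quiet-stance context) the unfiltered set is
used instead, where the clutter itself is the reference against which a
lone transient stands out.

**Step 2 — transient frequency content.** The window extended by 1.25 s is
autocorrelated per signal; coefficient peaks flagged by the quartile test
whose lag implies a frequency above the step frequency indicate either
faster-than-gait periodic content (lags recur as integer multiples of a
base lag, within 10% — ADL-consistent) or a transient (no repeat —
recovery).

**Step 3 — boundary context.** The window extended by four step periods on
each side exposes the surrounding motion; the same correlated-outlier test
as step 1, applied over this context, decides recovery versus ADL. This is
the step that catches stance perturbations whose window contains too few
extrema to be self-evident.

## Classifying the preceding task and the perturbation type

For recovery windows, the four step periods before the onset are
summarised by two features: the average relevant local maximum of
$\alpha_y$ (the same clamp-plus-iterative selection as calibration,
targeted at the interval's own dominant period) and the dominant period
itself. These are compared by mean absolute relative deviation to
reference features for standing, walking and running; the least deviation
wins, ties to walking. The walking reference is the calibration itself;
because only walking baselines are part of the protocol, the standing and
running defaults are scale factors on the walking reference (amplitude
ratio 181/44 from the cohort's running versus walking averaged global
maxima; cadence ratio 1.3; standing at half the noise clamp) and
`task_references()` accepts measured references instead. A pre-interval
whose relevant maxima never clear the clamp is quiet standing by the
amplitude floor rule — this short-circuit is what makes stance
perturbations robust even when the numerically differenced signal drowns
low-magnitude standing in noise.

The perturbation type reads the initial balance response: the dominant
$\omega_y$ extremum within the first half of the window, capped at 0.25 s
after onset. That interval is segmented on its own so that the in-interval
peak of an excursion continuing past the cap still counts. Under the
configured sign convention (+1: positive $\omega_y$ is forward pitch), a
positive response from walking is a trip, negative a slip; from standing,
an anterior or posterior loss of balance; from running only the direction
is reported. The convention is a configuration constant validated by an
antisymmetry test: negating both signals swaps trip with slip and anterior
with posterior while preserving every recovery verdict.

## Performance metrics

`evaluate_detection()` scores at trial level (a trial is positive when at
least one window is called a recovery; additional calls in a perturbed
trial are reported separately, not double-counted), producing sensitivity,
specificity, positive predictive value, F1 and prevalence. Prevalence is
reported as the perturbed share of all trials. `ppv_from_prevalence()`
extrapolates the PPV to other prevalences via Bayes' theorem — the measure
that separates detector configurations most sharply when near-falls are
rare, and the quantity `scripts/acceptance.R` recomputes.

## The synthetic generator: what it emulates, and what it does not

Because the human-subject recordings are not redistributed with the
package, every stage is tested against `gait_profile()` /
`generate_trial()` signals built to have the statistical structure the
framework assumes:

* $\omega_y$ is a band-limited harmonic series at the step frequency
  (0.35, 0.12, 0.05 rad/s at 1-3 times the fundamental) plus one Gaussian
  touchdown transient per step (sd 25 ms), and $\alpha_y$ is its *exact
  analytic derivative*. The derivative-of-Gaussian form makes the
  touchdown pulse biphasic with a 32 rad/s² default peak and a lognormal
  step-to-step jitter (sd 0.15), placing averaged local maxima and global
  maxima inside the cohort ranges (19-46 and 28-84 rad/s²). Generating the
  pair consistently — rather than drawing $\alpha_y$ independently — is
  essential: the single-sensor baselines differentiate the measured
  $\omega_y$, and they must recover the same touchdown content the cluster
  measures directly, or the IMC/IMU comparison would be meaningless.
* Perturbations are one-sided damped sinusoids (decay 0.2 s) injected
  consistently into both signals; the ring frequency is solved so that one
  transient exceeds the global thresholds of *both* signals by the same
  configurable scale (default 1.5), and the regular stepping is suppressed
  for three decay constants, as recovery stepping disrupts the gait
  rhythm. The sign of the first lobe encodes the direction.
* Measurement noise is white Gaussian per signal (0.02 rad/s, 0.3 rad/s²)
  plus sporadic impact artefacts in the measured angular velocity only: a
  two-sample (about 20 ms) common-mode transient at heel strike, 0.15
  rad/s for walking and scaled with event intensity (running 0.35 rad/s;
  a pick-and-drop floor impact 0.6 rad/s). The artefacts model
  impact-driven soft-tissue and mounting vibration, which the
  accelerometer-based cluster solve does not see but which differencing
  amplifies by $1/\Delta t$ into spurious angular-acceleration extrema.
  This is the mechanism behind the degraded specificity and the inflated
  calibrated thresholds of the differenced configurations, and it vanishes
  at zero noise. Bias drift and axis misalignment are not modelled.
* ADL templates: running raises cadence by a third and touchdown peaks to
  the 181/44 cohort ratio with sharper (8 ms) transients; stairs scale
  walking mildly; sit-to-stand adds a sub-threshold flexion-extension
  excursion before walking; pick-and-drop is a slow trunk bend reaching
  1.4 times the angular-velocity global threshold with a negligible
  angular-acceleration footprint — the canonical single-signal anomaly.

`generate_benchmark_set()` reproduces the study composition (627 trials:
74 trips, 16 slips, 62 anterior and 27 posterior stance losses, 84
sit-to-stand, 168 walking, 72 running, 82 stairs, 42 pick-and-drop) with
every trial carrying machine-readable ground truth.

What passing tests on this corpus demonstrate is internal validity: the
implemented rules detect and classify exactly the signal structure the
framework's assumptions describe, at realistic amplitudes, noise levels
and class balance, and degrade in the documented way when the directly
measured acceleration is replaced by a differenced one. They do not
demonstrate performance on real trunk recordings, where soft-tissue
artefact spectra, inter-subject gait variability and perturbation
responses are all richer than the templates here.

## Numerical and design choices

* Sample rate: 100 Hz default (typical for wearable units; a
  deliberate configuration constant); all time parameters are in seconds, never samples.
* Uniform grids are validated to a relative spacing tolerance of 1e-6;
  zero crossings use the same $\ge 0$ sign map as the segmentation.
* The optional zero-phase low-pass stage (`lowpass_smooth()`, 20 Hz
  default) is off everywhere by default and in all round-trip tests; the
  original device used a proprietary sensor-fusion stage that is not
  specified, and nothing in the acceptance behaviour depends on smoothing.
* Calibration problem sizes: three 30 s baselines per subject; the
  benchmark uses 12 s trials. These sizes give roughly 50 steps per
  baseline, enough for the distribution monitor's bins and a stable
  autocorrelation peak.
* Degenerate inputs fail loudly: identically zero signals (undefined
  autocorrelation normalisation), aperiodic baselines (no peak), too-short
  baselines (fewer than 10 step periods), singular cluster geometries,
  non-uniform grids, and empty extrema sets each raise a descriptive
  error rather than propagating NaN.
* The four-package mean is used for $\omega$ in the cluster solve; the
  centripetal correction uses that mean, so a common-mode gyro artefact
  perturbs the solve only through the (quadratically small) centripetal
  term.

## Limitations

Only antero-posterior (pitch-axis) mechanics are addressed; mediolateral
perturbations require a different decision geometry. Calibration is
global and static — a long-term deployment would re-run `calibrate_thresholds()`
when footwear, surface or health status change. The preceding-task
references for standing and running are derived, not measured, unless the
user supplies them. Ground-impact (fall) detection is out of scope: the
framework detects the recovery response between the personalised lower
bounds and a fall's upper bounds, not the fall itself.
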