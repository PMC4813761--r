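---
title: "Models and methods behind stopmeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopmeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopmeg)
```

# The task and the race model

`stopmeg` analyses (and simulates) the stop/change-signal paradigm. On every
trial a fixation cross (1.3-1.5 s, uniform) and a 0.2 s blank pause precede a
lateralised go arrow; on half the trials a stop/change signal follows at a
stimulus onset asynchrony (SOA) set by an adaptive staircase. Four task
variants arise from crossing the signal stimulus (vertical bar vs. opposite
arrow) with the required response (stop vs. change to the opposite button).
The *contextual complexity* of a variant is the minimal number of cue
elements that must be combined to act: a bar makes stopping simple (level 1)
but changing complex (level 2), an arrow the reverse, so complexity is the
stimulus-by-response interaction and all lower-level confounds cancel in
that contrast.

Behavior follows the horse-race model: an ex-Gaussian go process of finish
time $T_{go} = \mathcal{N}(\mu,\sigma^2) + \mathrm{Exp}(\tau)$ races a stop
process of fixed duration (the stop-signal reaction time, SSRT) started at
the SOA. The stop wins - and the response is withheld, or replaced in change
mode - exactly when $T_{go} > \mathrm{SOA} + \mathrm{SSRT}$. Two staircase
threads (starting at 0 and 0.3 s) are sampled at random on signal trials
and move by $\pm$50 ms after each outcome, asymptoting at zero; this
first-order up/down rule targets 50% stopping success regardless of the RT
distribution.

## Go-process defaults

The go-process defaults are $\mu = 0.455$, $\sigma = 0.05$, $\tau = 0.06$ s
(median go RT $\approx 0.51$ s). The exponential tail was set so that the
mean-median gap of the go distribution is $\approx 0.009$ s. That gap is
what separates the classic *average-difference* SSRT estimator (mean go RT
minus mean SOA, biased upward by exactly the mean-median gap when the
staircase sits at 50%) from the unbiased inhibition-function midpoint - and
0.009 s is precisely the mean SSRTav-SSRTmcmc difference reported for real
sessions in the behavioral table shipped with the package. A heavier tail
(e.g. $\tau = 0.15$) would make the average-difference estimator diverge
from the midpoint by $\approx 0.04$ s, contradicting that observation, and
would break the internal consistency requirement that all three estimators
agree within 0.02 s on clean simulations.

Trial-to-trial SSRT jitter is available (`ssrt_sd`) but defaults to zero so
that the inhibition-function midpoint equals the generating SSRT exactly.
RT drift - the slowing produced by subjects waiting for the signal - is
linear in trial index (`drift_slope`), matching the linear component the
analysis later removes. An inter-trial interval jittered uniformly on
0.1-0.9 s is appended after each 1 s response window; the jitter matters
for the convolution model (below), where quasi-periodic event trains would
otherwise make the design ill-conditioned.

# SSRT estimation

Three estimators are computed per session:

* **average difference**: mean go-only RT minus mean signal-trial SOA;
* **integration**: the $p$-th quantile of the go-only RT distribution
  (classic convention: sorted RT at 1-based index $\lceil p\,n \rceil$),
  with $p$ the fail fraction, minus the mean SOA;
* **MCMC inhibition-function midpoint** with RT-drift correction.

The drift model is a cubic smoothing spline of go-only RT on trial index
(smoothing by generalized cross validation; a straight line below 30
points). Its level is re-anchored so residuals have zero *median*: under
the race model the midpoint condition $P(\text{success}) = 0.5$ involves
the median of the go distribution at that point of the session, so a
median-tracking predictor makes the psychometric midpoint equal the true
SSRT; a mean-tracking predictor would inherit the mean-median gap as bias.

The inhibition function is modelled as
$P(\text{success}\mid z) = \lambda/2 + (1-\lambda)\,
\mathrm{logistic}\!\left(\beta (z - \alpha)\right)$, with
$z = \widehat{RT}(i) - \mathrm{SOA}_i$ the RT-corrected SOA. The logistic
family is a pragmatic choice (the sigmoid family is not otherwise
constrained); because staircase data concentrate near the midpoint, the
midpoint estimate is insensitive to the exact shape. Priors:
$\alpha \sim \mathcal{N}(\text{SSRTav}, 0.05\,\mathrm{s})$, $\log\beta$
uniform on $[\log 0.5, \log 2000]$, $\lambda \sim \mathrm{Beta}(1,19)$
truncated to $[0, 0.1]$. Sampling is random-walk Metropolis, by default 4
chains of 5,000 iterations with the first half discarded; convergence is
monitored by split-$\hat R$ (warning above 1.1). Goodness of fit is a
binned binomial deviance over quintiles of $z$ (sparse tails merged to
keep at least 5 trials per bin): twice the saturated minus model
log-likelihood, zero when binned predictions match binned observations.
Five bins against three fitted parameters leave roughly two residual
degrees of freedom, so honest sessions score near 2 - the scale on which
the published per-session deviances sit (mean 2.7, threshold 7.5) - where
a ten-bin convention would push even well-fitting sessions near the
rejection threshold.

A property worth stating explicitly, because the test suite measures it:
with a well-functioning tracking staircase, *linear* RT drift barely hurts
the average-difference estimator - the staircase follows the drifting
median with sub-millisecond steady-state lag, so the estimator's bias
stays at the mean-median gap regardless of drift. The drift-corrected
midpoint is the less biased estimator (its only systematic error is the
small logistic-vs-asymmetric-curve mismatch), but both biases are a few
milliseconds, so on single sessions the comparison is often decided by
sampling noise. This mirrors the close agreement between the two
estimators observed on real sessions.

Sessions are screened by three rules, in order: the median SOA of failed
signal trials must not be below that of successful ones; the fail fraction
must reach 0.28; and the deviance must not exceed 7.5. The third rule is
only evaluated when the first two pass - no psychometric function is
derived for sessions already discarded. The package ships the published
per-session behavioral table as a plain-text fixture; applying these rules
reproduces its retained/rejected partition except for one row (subject 7,
condition 1) whose printed deviance of 7.6 exceeds the stated 7.5 threshold
yet is retained in the original - an internal inconsistency of the printed
table that the tests document explicitly.

Post-signal slowing is measured drift-free by differencing: for every
go-only trial preceded by a run of signal trials of uniform outcome, the
preceding go-only RT is subtracted. The complexity effect on go RT is the
stimulus-by-response interaction on per-session medians (first/last 15
trials trimmed), tested by permuting cell labels within subjects.

# Source extraction (LCMV beamformer)

Sensor covariance is estimated over all samples of a block and regularized
with a ridge equal to $10^{-4}$ times the mean diagonal element. For a
source with lead field $L$ (channels x 3), the orientation of maximum
power is the minimum-eigenvalue eigenvector of $L^\top C^{-1} L$,
restricted first to the magnetically effective subspace of $L$: in a
spherical conductor the radial orientation is exactly silent and must not
be selected. With oriented gain $l = Lu$ the filter is
$w = C^{-1} l / (l^\top C^{-1} l)$, which passes the source with unit gain
($w^\top l = 1$) while minimizing output variance. Filters are computed per
block and never shared. The pairwise squared correlation of raw weight
vectors is reported as a leakage diagnostic (raw rather than normalized
weights; the choice is inconsequential for a correlation up to channel
scaling and is fixed here for reproducibility).

Extracted series are standardized robustly: medians of the raw and squared
signal over non-overlapping 10 s segments are averaged into first- and
second-moment estimates $m_1, m_2$ and the series is mapped to
$(x - m_1)/\sqrt{m_2 - m_1^2}$. Medians make the moments insensitive to
brief large artifacts; on Gaussian data the robust second moment is
smaller than the variance (the median of a squared Gaussian is
$\approx 0.455\sigma^2$), so the standardized series has variance slightly
above one - a fixed, harmless scale convention applied uniformly.

The forward model is an analytic single-sphere magnetic dipole model
(radial magnetometers; closed-form external field; tangential dipole
components only, the radial component being silent). It replaces
realistic single-shell head modelling, which is out of scope; the sphere
center defaults to the sensor centroid so that gains are invariant to
common translations. Simulated geometries are arbitrary: by default 28
sensors on a spherical cap and three sources at 120 degrees spacing and
0.6 of the sensor radius, which keeps the maximal inter-source filter
$r^2$ below 0.1 - comparable to the small leakage measured in real
recordings.

# Time-frequency decomposition

Multitaper spectral estimation runs over whole blocks in 0.4 s windows
stepped by 0.05 s, on frequencies 2.5-90 Hz in 2.5 Hz steps. The spectral
half-bandwidth is 2.5 Hz up to 25 Hz, $0.1 f$ between 25 and 50 Hz, and
5 Hz above. DPSS (Slepian) tapers are computed from the classic symmetric
tridiagonal eigenproblem with time-half-bandwidth $TW = \text{window}
\times W$ and taper count $K = \max(1, \lfloor 2TW \rfloor - 1)$ (1 taper
at 2.5 Hz bandwidth, 3 at 5 Hz); the taper-count rule is the standard
concentration heuristic, chosen here because only the bandwidths are
externally constrained. Power is averaged over tapers and square-rooted to
RMS amplitude, which is linear in signal amplitude and is the response
variable of the convolution model. Windows are computed only where they
lie entirely inside the block; nothing is zero-padded.

# The convolution GLM for induced responses

Trials overlap: a signal follows the go cue by a few hundred ms, the press
follows both. Event-locked averaging therefore mixes responses. The
convolution model instead regresses the continuous frequency-specific RMS
amplitude on event trains convolved with a Fourier basis spanning -0.5 to
+1.5 s around each event: a constant plus 11 sine/cosine pairs sampled on
the 0.05 s grid (23 columns per regressor; the order resolves envelope
structure to roughly 5 Hz and is not otherwise constrained). Harmonics are
periodic over the 41-point sampled window, making the columns exactly
orthogonal on the grid. Events snap to the nearest TF sample. Parametric
modulators (e.g. the predicted go RT from the drift spline) weight the
impulse train after mean-centering within event type, so the unmodulated
regressor keeps the mean response. Both the data and the design are
high-passed by projecting out a discrete-cosine subspace below 0.25 Hz -
identical treatment on both sides keeps the GLM consistent; the filter is
read as *removal* of sub-0.25 Hz components, the only reading that removes
time-on-task confounds. Coefficients are ordinary least squares per
frequency; rank deficiency falls back to a minimum-norm solution with a
warning. The induced response of an event type is the basis times its
coefficients; with isolated events this equals the triggered average
exactly, and with overlapping events it disambiguates them provided the
event types do not always co-occur.

One estimation detail matters for sustained, trial-spanning effects (the
complexity-scaled gamma): the fixation-to-go lag is nearly constant
(1.5-1.7 s), so fixation and go regressors are close to collinear and a
response lasting longer than the 2 s basis window splits between them
unstably. The pipeline therefore estimates the *trial-locked* response
with a dedicated single-regressor deconvolution on trial onsets. Because
inter-trial intervals are jittered and trials are at least 2.7 s apart,
trial windows are effectively isolated and this deconvolution coincides
with the stable triggered average - the model's own equivalence limit.
Phasic, signal-locked effects (theta/alpha, beta) remain estimated by the
full multi-regressor model.

# Group statistics

Condition contrasts are weighted sums of per-subject induced-response
images; the complexity contrast uses $(+1,-1,-1,+1)$ over the stimulus x
response cells, cancelling condition-independent structure exactly.
Familywise error over each time-frequency image is controlled by sign-flip
permutation of subject images with the maximum-|t| statistic, two-tailed:
exact under symmetric errors, assumption-free about smoothness, and fully
testable by simulation - which is why it replaces parametric random-field
thresholds with non-sphericity corrections here. At least 5 subjects are
required (below that the $2^n$ flip patterns cannot resolve $\alpha =
0.05$) and fewer than 100 permutations are refused.

The theta/alpha (2-12 Hz) band course of the signal-locked response,
averaged over successful and unsuccessful trials, yields a *peak rate of
rise* (maximum centered difference within -0.2 to +0.5 s). Rates are
compared across sources between short- and long-SSRT sessions (median
split) by a two-factor permutation ANOVA: group labels permute across
sessions, source labels within sessions; per-source post hoc permutation
tests run when the interaction is significant at 0.05.

# The synthetic study

The generator provides ground truth for every stage. Each source is unit
RMS 1/f background plus band-limited, Hanning-enveloped components:

* theta/alpha (2-12 Hz) bursts, 0-0.4 s after each stop/change signal,
  amplitude 2.6 (in background-RMS units), at `pre_sma` and `r_ifg`;
* sustained gamma (55-90 Hz) across each trial, amplitude 0.8 per
  complexity level, at `pre_sma` only;
* post-signal beta (15-25 Hz, 0.2-1.0 s) with success-by-response
  amplitudes (0.7 successful stop, 0.15 failed stop, 0.35/0.3 change), at
  `pre_sma` and `r_ifg`;
* a sustained beta rhythm at `m1` gated down by 70% around presses.

Injection is linear in amplitude by construction (the band-limited carrier
and envelopes are independent of the amplitude), so scaling a configured
amplitude scales the injected component exactly. Sources are mixed to
sensors through the spherical lead field with white sensor noise; the
default study uses an amplitude signal-to-noise ratio of 2. Ten subjects
perform all four variants (24 trials per block at the demonstration
scale); subjects differ in go-process mean (SD 0.03 s), SSRT (SD 0.02 s),
and a common lognormal effect-amplitude gain (sigma 0.2). Amplitudes were
chosen once, while designing the study, to produce effects as prominent
relative to background as those visible in real stop-signal MEG
time-frequency images and to give the ten-subject design adequate power;
they are deliberately clear-cut, which is what a ground-truth validation
study requires.

What the generator does *not* emulate: realistic head geometry and field
spread, physiological artifacts (blinks, cardiac), non-stationary
background spectra, phase-locked evoked components, or any coupling
between behavior and source amplitudes beyond the configured modulators.
Passing tests therefore demonstrate that the pipeline recovers known
effects under its own model assumptions - not that those assumptions hold
for any particular real recording.

# Numerical choices and degenerate inputs

* Sub-stream seeds are derived deterministically from one integer seed and
  a stage label; identical seeds reproduce sessions, recordings and
  statistics bit for bit.
* The covariance ridge ($10^{-4}$ of the mean diagonal) guarantees an
  invertible matrix even for rank-deficient data; all-constant data is
  flagged singular.
* Staircases never go below the SOA floor; step and floor are validated.
* The integration estimator refuses fail fractions of exactly 0 or 1;
  the drift spline requires 10 go trials; the psychometric fit requires 20
  signal trials spanning 3 distinct corrected SOAs.
* Eigen-orientation sign is fixed (largest component positive) so filters
  are reproducible; extracted-series sign is arbitrary up to that
  convention, which RMS analyses do not see.
* TF windows must fit entirely inside a block; events outside the TF span
  are dropped with a warning; blocks shorter than one cutoff period skip
  the high-pass with a warning.

# Problem sizes used in the shipped checks

The test-suite simulations are sized for a desk run: staircase calibration
uses 10,000 trials; estimator-recovery checks use sessions with 2,000
signal trials and 50 drift replicates; the familywise-error calibration
uses 500 replicates of 8 subjects and 20 x 20 images at 200 permutations;
the end-to-end study uses 20 replicates of the default 10-subject design.
These sizes are the package's validation design; all of them scale up by
changing the corresponding arguments.

# Known limitations

* The psychometric family is fixed to the logistic; midpoints are robust
  to this, slopes less so.
* Ordinary least squares ignores the autocorrelation of TF amplitude
  series; coefficient estimates are unbiased but their nominal variances
  are not used anywhere (inference happens at the group level by
  permutation).
* The beamformer assumes the forward model is exact; co-registration
  error, a dominant issue on real data, is not modelled.
* Change-mode behavior is modelled as the stop race plus a fixed extra
  latency for the second press; no second race is simulated.
* The mixed hierarchical models used for the original group behavioral
  statistics are replaced by within-subject permutation contrasts; exact
  F statistics from the original analyses are not reproduction targets.
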