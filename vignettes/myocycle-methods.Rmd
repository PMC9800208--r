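---
title: "Models and methods behind myocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myocycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myocycle)
```

# Scope

`myocycle` implements the full in vitro assay battery used to characterize a
myosin motor's chemomechanical cycle — steady-state actin-activated ATPase,
stopped-flow transient kinetics, mant-ATP single-turnover SRX/DRX
decomposition, three-bead optical-trap mechanics, in vitro motility filament
tracking, and Markov state model estimation — together with a simulator that
generates synthetic raw data for every assay from a known ground truth. This
vignette records the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data do and do not establish about
real recordings.

# The chemomechanical cycle and its observables

One crossbridge cycle is treated as a serial loop of first-order steps:
ATP-induced dissociation from actin, hydrolysis, re-attachment, phosphate
release and ADP release. For a serial loop the mean period is the sum of mean
state dwells, so the steady-state cycling rate is

$$k_\mathrm{cat} = \Big(\sum_i 1/k_i\Big)^{-1} = 1/t_\mathrm{cycle}.$$

`simulate_cycle_dwells()` realizes the loop as a continuous-time Markov
chain; `analytic_kcat()` gives the closed form the realization must converge
to, which is the backbone of the simulator's self-tests.

ATP binding to actomyosin is a rapid equilibrium ($K_1$, in 1/uM) followed by
a rate-limiting isomerization ($k_{+2}$) that dissociates myosin from actin.
The observed dissociation rate at a given [ATP] is the hyperbola

$$k_\mathrm{obs} = \frac{K_1 k_{+2}\,[\mathrm{ATP}]}{1 + K_1 [\mathrm{ATP}]},$$

with the second-order binding rate $K_1 k_{+2}$ as its initial slope and
$k_{+2}$ as its asymptote. ADP competes for the nucleotide pocket; at fixed
ATP the observed rate falls as

$$k_\mathrm{obs}([\mathrm{ADP}]) = \frac{k_0}{1 + [\mathrm{ADP}]/K_\mathrm{ADP}}.$$

The competition law is often written in normalized form without the rate
prefactor $k_0$; dimensional consistency requires one, so the package fits
$k_0$ (or accepts it as known) and defines $K_\mathrm{ADP}$ operationally as
the ADP concentration at which the observed rate halves. When microscopic
ADP rates are supplied to `rate_scheme()` they must satisfy
$K_\mathrm{ADP} = k_{-\mathrm{ADP}}/k_{+\mathrm{ADP}}$.

# Steady-state ATPase

The NADH-coupled assay reports ATP consumption as a linear decrease in A340.
The pipeline is: standards regression (nmol NADH against absorbance; the
slope is the plate's conversion factor), linear-range slope extraction per
well, conversion to a per-head rate, basal subtraction, and a
Michaelis-Menten fit.

**Linear-range policy.** The published description of such protocols says
only "the linear range". The rule implemented: the longest contiguous window
of at least 10 samples whose rolling 5-point local slopes all lie within 5%
of the window's global slope and whose $R^2 \ge 0.995$, ties broken toward
the earliest window (initial velocity, before substrate depletion). Both
criteria are floored by a robust noise estimate taken from first differences
of the trace: the local-slope band becomes
$\max(0.05\,|s|,\ 3\,\mathrm{SE}_\mathrm{local})$ and a window whose residual
scatter does not exceed 1.2 times the noise is accepted even when $R^2$
falls short. Without the floor, wells whose true slope sits at the noise
floor — the basal well above all — would be rejected wholesale, because both
raw criteria scale with signal-to-noise rather than curvature. Curvature
from NADH depletion still rejects late windows, because depletion residuals
exceed the noise.

**Ambiguity policy.** A fit is flagged rather than reported when the 95%
CI half-width exceeds 100% of the estimate for either parameter, or when
$K_M$ exceeds 10 times the largest tested actin concentration. CIs use the
$t$ quantile at the fit's residual degrees of freedom; with 7 actin
concentrations the normal quantile under-covers noticeably.

**Efficiency.** Catalytic efficiency $k_\mathrm{cat}/K_M$ computed from
ratio-of-means differs from a mean of per-replicate ratios; the package
reports the ratio of the fitted values, and `derive_cycle_metrics()` applies
it per construct.

# Stopped-flow transients

Each transient is fit as a single exponential
$A(1 - e^{-k_\mathrm{obs}t}) + c$ (pyrene fluorescence rises on
dissociation), initialized from log-linearized residuals; a transient whose
span covers less than $3/k_\mathrm{obs}$ is flagged truncated. The ATP
dependence is fit twice: a linear regression through the origin over the
low-ATP subset (points with $[\mathrm{ATP}] \le 0.2/K_1$ from a pilot
hyperbolic fit, minimum 3) for $K_1k_{+2}$, and the full two-parameter
hyperbola for $k_{+2}$ and $1/K_1$.

The two estimates are cross-checked: $K_1k_{+2} \approx k_{+2} K_1$ within
twice the combined uncertainty. The through-origin estimator carries a known
downward curvature bias bounded by $K_1k_{+2}(1 - \bar f)$ with
$\bar f$ the weight-averaged $1/(1 + K_1 a)$ over the low subset (about 4%
at the 0.2/$K_1$ cut); that bound enters the combined uncertainty as a
systematic term. Omitting it makes the check fail on perfectly good fits
whenever the statistical errors are small.

Transient-level standard errors propagate into the concentration-response
fits as $1/\mathrm{SE}^2$ weights when available.

# Single-turnover SRX/DRX decomposition

Myosin heads free of actin hydrolyze ATP either at the basal
disordered-relaxed (DRX) rate or roughly an order of magnitude slower in the
super-relaxed (SRX) state. After a chase with excess unlabeled ATP, the
mant-ATP fluorescence decays as the two-population mixture

$$y(t) = A_\mathrm{fast} e^{-k_\mathrm{fast}t} +
  (1 - A_\mathrm{fast}) e^{-k_\mathrm{slow}t},$$

constrained to start at 1 and decay to 0. The signal is normalized to the
mean of the five samples preceding the chase; the chase time comes from
metadata when present and otherwise from the largest drop of the smoothed
derivative. Phases are labeled by rate ordering (SRX is the slow phase), and
fits whose two rates fall within a factor of 3 are rejected as
phase-collapsed rather than reported with arbitrary labels. SRX/DRX are
treated as a static mixture over the chase; interconversion rates exist in
`rate_scheme()` but default to zero, since the assay itself cannot separate
slow interconversion from amplitude.

Defaults reflect the protocol: 1 Hz sampling, chase at 60 s, 940 s of
monitoring, noise of 0.01 normalized units, DRX at 0.03/s and SRX at
0.003/s. At these conditions the recovered SRX percentage is unbiased to
within 2 points across the whole mixture range, which is what the recovery
tests assert.

# Optical trap

**Simulation.** The bead-position baseline is an Ornstein-Uhlenbeck process
with equipartition variance $k_BT/\kappa$ and a corner frequency of 2.5 kHz
by default — representative of a two-trap dumbbell with ~0.5 um beads at
~0.1 pN/nm combined stiffness — sampled exactly at 20 kHz. Binding reduces
the variance fourfold and shifts the mean by $d_1$ at attachment and by
$d_2$ after an exponential delay; attachment starts are Poisson and
durations exponential.

**Stiffness.** The periodogram of a sampled OU process is not a continuous
Lorentzian but its AR(1) counterpart
$S(f) = C/(1 - 2a\cos(2\pi f/f_s) + a^2)$; fitting the continuous form
biases the corner by >10% when $f_c/f_s \approx 0.1$. The package fits the
discrete form to log-binned periodogram means, in log space, weighted by bin
occupancy, and derives variance $Cf_s/(2(1-a^2))$ and stiffness
$k_BT/\mathrm{var}$.

**Detection.** Running variance in a 5 ms window with hysteresis (enter
below 0.5, exit above 0.75 of the free-baseline variance, estimated as the
median windowed variance); events shorter than one window are discarded
(the dead time). Each edge is then refined by a two-segment Gaussian
changepoint over mean and variance within one window of the crossing — the
variance drop is unique to the binding transition, so the second substep
(a mean-only change) cannot capture the edge. At the defaults the detector
produces no false events in hundreds of seconds of pure baseline and ≥90%
recall for events at least twice the dead time.

**Detachment rate.** For durations left-truncated at $t_0$ the exponential
MLE is $\hat k = 1/(\overline{t} - t_0)$, implemented in closed form with a
nonparametric bootstrap CI. Detection recall is soft between one and two
windows, so `fit_detachment_from_events()` censors at three times the dead
time, where truncation is sharp; this removes a ~5% downward bias and makes
the estimate insensitive (<1%) to halving the analysis sampling rate.

**Steps and substeps.** The per-event total step is the terminal bound level
(the completed working stroke) minus the flanking baseline; the bound-mean
shift is reported alongside. Ensemble averages align events at attachment
(time-forward) and detachment (time-reversed), extending events shorter
than the span (the median duration) by holding the bound level adjacent to
the far edge. The level at each alignment instant comes from a
single-exponential fit excluding a guard band next to the alignment point —
1 ms on the forward edge, where changepoint selection bias inflates the
first samples, and one dead time on the reversed edge, where detection
jitter lets free samples leak in — extrapolated back to the instant itself.
$d_2$ is the difference between the reversed level at detachment and the
forward level at attachment; $d_1 = d_\mathrm{total} - d_2$ by
construction, within numerical tolerance. The quoted noise floor on $d_2$
is a 10-block jackknife over events; the ensemble-fit covariance alone
understates it several-fold. Residual edge jitter leaves a systematic of
roughly 0.1-0.2 nm on $d_2$ at realistic substep delay rates; recovery
tests therefore use max(3 noise floors, 0.2 nm) as their band, and
sub-0.2 nm substep accuracy should not be expected from this detector.

# In vitro motility

**Rendering.** Filaments are straight segments with Gaussian cross-section
($\sigma$ = width/2.355) rendered analytically per pixel (perpendicular
Gaussian times an erf end-cap term), translated along their own axis, with
Poisson photon noise. Ground-truth midpoints are sub-pixel. Real movies
additionally contain photobleaching, filament flexing and out-of-focus
filaments, none of which are modeled — passing recovery tests demonstrates
tracker correctness, not robustness to those effects.

**Detection.** Multiscale bright-ridge Hessian response at
$\sigma \in \{w/2.355 : w = 2\ldots6\}$ px, max-pooled; Otsu threshold on
the response, floored at median + 6 MAD of the response so an empty frame
yields an empty mask (Otsu alone always splits the histogram); connected
components; Zhang-Suen thinning; branch pruning by the longest geodesic path
(double BFS); arc-length midpoint with linear interpolation. Components are
filtered by skeleton length (≥8 px) and by mean width (component area over
skeleton length) against the 2-6 px band with a 1.5x slack for mask
broadening. Midpoint RMSE on noiseless renders is below 1 px.

**Linking.** Frame-to-frame linear assignment on squared midpoint
displacement, gated at 15 px per elapsed frame, with birth/death costs at
1.05 gate$^2$ in the standard square augmented matrix; the solver is a
shortest-augmenting-path (Jonker-Volgenant) implementation verified against
exhaustive enumeration. Gap closing up to 1 frame is used in the video
pipelines, because crossings drop detections for a frame.

**Velocity.** Per-track velocity is the median frame-to-frame step scaled to
um/s. The median, rather than the mean, is deliberate: crossings corrupt
single steps and pulled 20-filament per-video means ~3% low; the mean
remains available (`estimator = "mean"`). Video-level analyses require
tracks of at least 10 of 30 frames, which excludes the short-lived
near-stationary ghost tracks that crossings create; the function default
remains 5 frames for short recordings. At the protocol frame rate (1/s,
30 s) and 0.108 um/px these choices recover programmed speeds from 0.5 to
1.0 um/s within ~1% per video.

# Markov state models

Transition counts are sliding-window pairs $(s_t, s_{t+\tau})$ per
trajectory, never across trajectories. The estimator adds a pseudocount of
$1/n$ — $n$ the number of microstates, the only count defined at estimation
time — to every element and row-normalizes; the prior guarantees strict
positivity, hence ergodicity and a unique equilibrium $\pi$ (leading left
eigenvector, normalized). No detailed-balance constraint is imposed, so
eigenvalues may be complex; they are sorted by magnitude with index
tie-breaks and a warning marks the non-reversible case. Implied timescales
are $-\tau/\ln|\lambda_i|$; eigenvalues within $10^{-12}$ of 1 report as
infinite.

# Problem sizes and reproducibility

Every generator takes an integer seed and is bit-reproducible; ground truth
travels with the dataset but is never consumed by the analysis modules
except in tests. The recovery studies use 100 plates per ATPase
parameterization, 200 stopped-flow datasets per construct, single-turnover
traces at protocol sampling, trap recordings of 300-480 s (roughly 500
events), and 20-filament videos of 30 frames at 512 x 512 px — sizes at
which the medians and coverage rates quoted above are stable from seed to
seed.

```{r example}
rep <- construct_report(myh7b_reference_params())
rep$metrics
```

# Known limitations

Load-dependent (strain-sensitive) kinetics, thick-filament regulation and
the structural interacting-heads motif are out of scope; the trap module
analyzes unloaded events only. The stopped-flow module fits transients
phenomenologically rather than integrating the full kinetic scheme. The
single-turnover module does not correct for free-nucleotide background or
rebinding. The motility module does not model filament length changes,
curvature statistics or photometry.
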