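---
title: "Methods: the speed-curvature power law in repetitive tongue movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the speed-curvature power law in repetitive tongue movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artikin)
```

## The problem and the model

When an effector traces a curved path, its speed and the local curvature of
the path are empirically coupled: speed falls where curvature rises, as a
power function

$$ v = k\,\kappa^{-\beta}, \qquad \log v = \log k - \beta \log \kappa, $$

with exponent $\beta$ (close to $1/3$ for ellipse-like planar drawing, the
"one-third power law") and a velocity gain factor $k$ that sets the overall
speed scale. `artikin` implements a complete, testable pipeline for
assessing this law in repetitive tongue movements of the kind recorded by
3D electromagnetic articulography (EMA) during metronome-paced syllable
repetition ([ta]/[ka] at 30-570 bpm, i.e. 0.5-9.5 syllables per second):
conditioning of raw 1250 Hz trajectories, an analytic spline
representation, segmentation into closing and opening movements, kinematic
triples and the critically damped gesture model, rate-stratified log-log
regression of speed on 3D curvature, a mid-sagittal 2D comparison, and
phase-portrait density portraits. A synthetic-data module emulates the
whole paradigm with exact ground truth so each stage is verifiable without
any recordings.

Speed is the tangential velocity $v = \lVert \dot r \rVert$ and curvature
the 3D cross-product form
$\kappa = \lVert \dot r \times \ddot r \rVert / \lVert \dot r \rVert^3$,
both evaluated on one analytic spline object per trial so that $r$,
$\dot r$ and $\ddot r$ are mutually consistent.

## Synthetic sessions and what they emulate

`generate_session()` emits one recording per (sequence, rate, trial):

* the tongue sensor traces a closed figural template once per metronome
  beat, timed so that $v = k\kappa^{-\beta}$ holds *exactly* along the 3D
  path (arc-length reparameterization, $dt = ds/(k\kappa^{-\beta})$);
* the default template is a smooth "bent loop" (an ellipse whose superior
  coordinate carries a second-harmonic bend). Two circular arcs cannot
  close into a C1 curve with unequal radii, and piecewise-constant
  curvature would collapse the log-log regression onto two abscissa
  values; the bent loop keeps curvature continuously varying and strictly
  positive, which the generator verifies;
* the excursion shrinks linearly from 15 mm at the slowest to 10 mm at the
  fastest configured rate, and the true exponent interpolates from 0.50
  down to 0.33, so recovered $\beta$ must fall and $k$ (implied by the
  fixed cycle period) must rise with rate;
* a lateral component is built into the 3D figure with RMS 7.5% of the
  in-plane RMS (study range 5-10%), so the law holds in 3D and the
  mid-sagittal projection is genuinely lossy;
* a slow multiplicative envelope (default $\pm 5\%$) emulates
  token-to-token size variability, giving the peak-velocity-amplitude
  regressions within-stratum spread;
* three reference sensors ride on slow rigid head motion (default 2 mm /
  1.5 deg) that also displaces the tongue channel, as in raw data; and
  i.i.d. Gaussian sensor noise (default 0.05 mm per axis at 1250 Hz) is
  added last.

Features of real data the generator does not emulate: quasi-stationary
dwells between slow-rate syllables (real slow speech is target-to-target
with much higher transit speeds than a law-exact slow cycle), anatomical
constraints (palate contact), sensor dropouts, and non-white sensor noise.
Passing tests therefore demonstrate correctness of the estimators under
the stated conditions, not robustness to every property of real EMA
recordings.

## Conditioning chain

1. **Two-stage decimation** 1250 to 83.33 Hz (factors 5 then 3), each stage
   a 30th-order equiripple FIR lowpass with the group delay of order/2
   samples compensated by an index shift. Both stages place the passband
   edge at $0.8 \times 41.67$ Hz; stage 1's stopband starts at the first
   alias boundary of its output rate (208.33 Hz) and stage 2's at
   $1.2 \times 41.67 = 50$ Hz with 5:1 passband weighting. At order 30
   this keeps the passband flat to well under 1%; a symmetric narrow
   transition at both stages would cost several percent of ripple, which
   would leak directly into every amplitude-dependent quantity downstream.
   Taps are normalized to exact unit DC gain.
2. **Head-motion correction**: per frame, the closed-form unit-quaternion
   (Horn) absolute-orientation solution maps the three reference sensors
   onto a fixed template and the same rigid transform is applied to all
   channels; an optional constant occlusal transform then fixes the
   anatomical frame (identity for synthetic data, which is generated in
   the occlusal frame).
3. **Zero-delay Butterworth lowpass**, 4th order, 25 Hz, forward-backward,
   with odd-reflection padding of 3x the filter order and edge-value
   offsetting so the zero-state step transient vanishes and DC passes
   exactly. Note that at 83.33 Hz sampling the *digital* (bilinear)
   response differs strongly from the analog formula near Nyquist; tests
   assert the digital closed form.

## Spline representation and differentiation

Each axis is represented by a least-squares quintic B-spline with one knot
per sample (order 6). These splines are C4-continuous, hence satisfy the
required C3 continuity; with a knot per sample the least-squares problem
is rank-deficient by a handful of basis functions, so a small roughness
penalty on $\int (f^{(4)})^2$ (relative weight $10^{-8}$, scaled by the
trace ratio of the Gram and penalty matrices) pins the solution without
measurable bias on band-limited signals: a 2 Hz sinusoid at 83.33 Hz is
reproduced to $10^{-6}$ relative in position and $10^{-3}$ relative in
acceleration. The penalty integral is computed exactly (the 4th derivative
of a quintic spline is piecewise linear, so two-point Gauss quadrature per
inter-knot interval is exact), and the sparse banded normal equations are
solved with a sparse Cholesky factorization.

Raw-series differentiation uses nine-point finite-difference stencils of
eighth-order accuracy (weights from Fornberg's algorithm; shifted
nine-point stencils at the boundaries). A consistency invariant ties the
two routes together: for band-limited signals the spline velocity and the
stencil derivative of the positions agree to better than 1% RMS.

## Segmentation

The movement axis of a trial is the leading principal component of the
position covariance; its sign is fixed so that closing movements (toward
the palate, superior) have positive score velocity. Zero crossings of the
score velocity are the primary delimiters; within each inter-zero span the
onset (offset) is the earliest (latest) crossing of 20% of the span's peak
velocity, so multi-peak profiles yield one movement. Spans with peak score
speed below 1 mm/s (a floor the data do not pin down; it guards against
noise micro-spans) are skipped. The study's manual exclusion of
non-targeted movements is operationalized as an amplitude floor: segments
whose excursion falls below 20% of the trial median are dropped; when
generator ground truth is available, segments are instead matched to
consecutive true delimiters.

## Kinematic triples and the c factor

Per movement: duration $T$ between the 20% delimiters (as the study
defines it), amplitude $A$ as the 3D path length — by default over the
zero-velocity delimiters, so $A$ equals the figural excursion; a config
switch uses the threshold delimiters instead — and peak velocity $v^*$ as
the maximum tangential speed. The relation $v^*/A = c\,\pi/T$ is fitted
per stratum without an intercept (the model has none; a with-intercept
variant exists for diagnostics), and $c$ is reported in units of $\pi$.
For harmonic movements delimited at zero velocity $c = 1/2$ exactly; for
critically damped gestures (the standard mass-spring gesture model
$\ddot x = -k x - b\dot x$, $\zeta = 1$, solved in closed form by
`simulate_gesture()`) the 20%-threshold duration gives $c \approx 0.458$,
just below the analytic bound of one half. The reported $r^2$ is the
squared Pearson correlation of $v^*/A$ with $1/T$, which is comparable
across strata, unlike the no-intercept coefficient of determination.

## Power-law estimation

Each movement contributes five speed-curvature samples at equal time
fractions $i/6$ strictly inside the zero-velocity delimiters: endpoint
samples would have zero principal-axis velocity and undefined $\log v$,
while the zero-delimited window deliberately retains the high-curvature
transitions that threshold delimiters would cut away. Equal *time*
fractions are used (an arc-length option would oversample fast straight
sections; time fractions follow the occupancy of the movement itself).
Ordinary least squares of $\log_{10} v$ on $\log_{10} \kappa$ gives
$\beta$ (negated slope), $k$ ($10^{\text{intercept}}$; base 10 so gain
magnitudes land on the customary printed scale — $\beta$ and $r^2$ are
base-invariant), $r^2$, and the two-sided Pearson-correlation p-value.
Samples with speed below $10^{-3}$ mm/s are flagged degenerate and
excluded from regressions but never dropped from the sample table. No
curvature-range exclusions are applied anywhere: rate stratification in
3D makes them unnecessary. The same subsampling times are reused for the
mid-sagittal comparison, where curvature and speed are recomputed from
the x-y projection only.

## Phase portraits and the regime score

The occupancy histogram of the (score, score velocity) plane — 100x100
cells over the 1-99th percentile box, smoothed with a one-cell Gaussian
kernel, normalized to unit mass — approximates the phase-space density:
uniform-in-time sampling weights each cell by sojourn time, so a point
attractor (dwell at a target) appears as a localized blob and a limit
cycle as a ring. The quantitative score is this package's own extension
of that visual classification: cells at or above half the maximum density
form the high-density region; the connected component containing the mode
is the mode blob; the concentration $C$ is its mean density relative to
the mean density of all occupied cells; and the score is
$C/(C + c_0)$ with $c_0 = 10$, the geometric midpoint between measured
point-like ($C \sim 10^2$) and ring-like ($C \sim 10^{0.5\text{-}1}$)
concentrations. Scores above 0.5 indicate fixed-point structure, below
0.5 ring-like structure; densities with no salient structure are flagged
indeterminate. On the synthetic regimes at the paradigm extremes the
scores separate by a wide margin (about 0.9 vs 0.28).

## Numerical choices and degenerate inputs

* Reparameterization uses an 8192-point trapezoidal integral per cycle and
  monotone (Hyman) spline inversion; the circle test recovers constant
  speed to a relative sd below $10^{-4}$.
* Delimiter root-finding uses `uniroot` at $10^{-10}$ tolerance on the
  spline velocity; subsample times are exact fractions of the refined
  zeros.
* Paths with vanishing curvature are rejected when $\beta > 0$ (infinite
  speed); collinear reference-sensor configurations are rejected in the
  Horn solver (rank deficiency); cutoffs at or above Nyquist, series
  shorter than the stencil, and trials without motion raise informative
  errors.
* Evaluation outside a spline's domain is an error; boundary values are
  clamped only within a $10^{-9}$ relative tolerance.

## Known limitations

* With the 25 Hz analysis bandwidth, white sensor noise of $\sigma$ mm
  after conditioning contributes roughly $10^4 \sigma$ mm/s$^2$ of
  acceleration noise. Law-exact slow cycles (30 bpm) have accelerations of
  only $\sim 70$ mm/s$^2$, so curvature at the slowest rates is
  noise-limited for conditioned noise above a few $\mu$m — an estimator
  property worth knowing when interpreting slow-rate exponents; real slow
  speech moves much faster between targets. End-to-end recovery checks
  therefore run noise-free (head motion and token variability on), which
  is also how the generator's round-trip invariants are stated.
* The regime score is a heuristic summary of density topology, not a
  dynamical-systems fit; no bifurcation detection is attempted.
* Problem sizes in the tests and the acceptance script (4-8 rates, one
  trial per rate, 8-10 syllables per trial; 83.33 Hz generation where the
  1250 Hz front end is not itself under test) are chosen to keep the full
  suite fast while leaving every stage exercised; the defaults of
  `session_config()` describe the full paradigm.
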