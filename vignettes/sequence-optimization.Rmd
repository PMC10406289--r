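---
title: "Simulation-driven MRI sequence optimization: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-driven MRI sequence optimization: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrseqopt)
```

This vignette explains the science implemented by `mrseqopt`: the two
domain-specific languages, the phantom and signal model behind the simulator,
the twelve image-quality metrics, the surrogate-learning protocol, and the
constrained evolutionary search — together with the numerical choices and
assumptions that a user should know before trusting results on their own
problems.

## The pipeline at a glance

A clinical demand ("maximize grey/white contrast, keep SNR above 30, avoid
ghosting") is parsed from the requirements DSL and translated into a numeric
optimization problem.  Sequence space is the Cartesian parameter grid of four
Cartesian sequence families — EPI, spin-echo EPI, bSSFP, and RARE — over
matrix size, TE/TR, echo train length, EPI factor, readout duration and
measurement count.  Each grid sequence is simulated four times (square
phantom; circular phantom plain, with off-resonance, and with motion), scored
with twelve metrics, and the resulting table trains one regression surrogate
per metric.  An evolutionary algorithm then searches sequence space against
the surrogates under a penalty fitness, and the winning candidate is emitted
as sequence-DSL text.

## The sequence DSL and its defaults

A sequence is described by one mandatory sentence (echo type + readout type)
plus optional `Specify` and `Add` sentences.  The four echo/readout
combinations map onto the four families, and every unset field takes that
family's default — the values of the shipped default sequences under
`inst/extdata/`.  Defaults make upper-level descriptions executable:

```{r}
spec <- expand_defaults(parse_sequence(
  'define MRI sequence "R" using a "SpinEcho" with "LineReadout".'))
c(te = spec$te, tr = spec$tr, etl = spec$etl)
```

Concrete-syntax choices: sentences end with a period, quoted names are
case-sensitive while keywords are not, and `is higher than` is accepted as a
synonym of `is greater than` in the requirements DSL.  Readout durations are
written in microseconds in DSL text (the field convention for ADC durations),
while the learning table stores them in milliseconds.

Gradient-echo sequences internally carry a refocussing angle of 0, so the
ten-dimensional numeric input vector of the learning problem is fully defined
for every family and the two categorical inputs (echo type, readout type) are
recoverable by rounding — the mechanism the repair step uses.

## Translating vague wording: the ordinal dictionary

Strict constraints are numeric already.  Vague constraints (`avoid
"ghosting"`, `have high "CGC"`) are mapped through an ordinal dictionary:
avoidance of an artifact metric becomes an upper bound of 0.05 (allowance:
0.20), and quantifier aims become banded bounds per metric family — for
contrasts `very_low/low/decent/high/very_high` map to lower bounds
1/2/5/10/20, for SNR 5/10/20/30/50, for the correlation metrics
0.5/0.65/0.75/0.85/0.95, and for acquisition time to upper bounds.  Only
three anchors of this table are externally fixed (ghost < 0.05, "high"
contrast > 10, sharpness > 0.85, the values appearing in the worked
requirement translations); the remaining bands interpolate monotonically and
the whole dictionary is a config object the user can override.

## Phantoms

The square training phantom (100 x 100 mm, 4 spins/mm^2 on a regular 0.5 mm
grid) carries three 20 x 20 mm tissue squares — CSF (T1 4000 ms, T2
2000 ms, PD 1.0), grey matter (1350/110/0.8) and white matter (850/80/0.65),
typical 3 T literature values — plus a striped CSF structure section (the
sharpness target) and a filled CSF block (the homogeneity target).  The exact
sub-region geometry is a package choice (only anchored graphically in the
phantom design it emulates): the object is confined to a 48 mm
phase-encoding extent so that its N/2-ghost replica, the object support
shifted by half the PE field of view, never intersects the object — a
precondition for a well-defined ghost metric.

The circular phantom (2 spins/mm^2 on a 0.5 x 1.0 mm grid, so the spin count
is exactly `fov_x * fov_y * density`) is a 15 mm-radius disc with grey-matter
parameters.  It optionally carries a uniform 50 Hz off-resonance (the
distortion probe; only "non-zero" is externally prescribed, 50 Hz is a
representative shim error at 3 T) or a sawtooth translational motion along
the phase-encoding axis (amplitude 5 mm, period = the duration of one
measurement; a slow-drift model, sampled at each excitation).  Spins sit on
regular deterministic sub-grids for reproducibility.

## The simulator and its assumptions

The simulator is a tissue-level isochromat model: one magnetization vector
per tissue is evolved through the full event schedule — instantaneous
(hard-pulse) RF rotations with a nominal 1 ms reserved in the timing checks,
exponential T1/T2 relaxation and off-resonance precession between events —
across all prescans and measurements, so transient and steady-state effects
are captured.  Spatial encoding is applied analytically: because all spins of
a tissue share one magnetization history, each ADC sample is the tissue
magnetization times a precomputed Fourier sum over the tissue's spin
positions, a separable matrix product on the regular spin grid.  Rigid
translational motion enters as a per-shot linear phase on the PE k
coordinate.  Only the final measurement's k-space is scored; earlier
measurements exist to establish the steady state.

What this model deliberately omits: slice profiles, gradient waveforms and
hardware limits, intra-voxel dephasing (T2'), diffusion, flow, chemical
shift, and coil sensitivities (a homogeneous unit coil is assumed).
Spoiling is ideal: "after echotrain"/"after segment" zero the transverse
magnetization at the end of a shot; balanced spoiling around an exact 180°
refocussing pulse or a balanced readout has no effect in this model and is a
no-op.

The simulator is validated against closed forms rather than against another
simulator: free decay after a 90° pulse (`|s| = PD e^{-t/T2}`, exact), the
spin-echo amplitude's immunity to uniform off-resonance (exact), the
alternating-phase short-TR steady state against an independently iterated
two-pulse recursion (within 0.01%), Parseval's identity for the
reconstruction, and the EPI off-resonance image shift against the Fourier
shift theorem (`shift = delta_f x echo spacing x FOV`, exact at integer
pixels).

Timing conventions: interleaved ascending PE ordering (echo `e` of shot `s`
acquires line `e * shots + s`; the centre line `n/2` is acquired at TE); EPI
alternates readout polarity within a shot; RARE uses a CPMG train with echo
spacing `TE / k_centre`; bSSFP acquires one line per TR with 0°/180°
alternating excitation (and receiver) phase and linearly ramped prescan
flips `angle * (p+1) / (count+1)`.  The dwell time is
`readout_duration / n_columns` and the EPI echo spacing allows a 0.1 ms ramp.

A consequence worth knowing: in a first measurement at short TR, shot-to-shot
T1 saturation transients modulate adjacent k-space lines and produce strong
coherent ghosting.  This is physical, and it is why the measurement count
matters in the training grid — sequences scored on a later measurement are in
steady state and nearly ghost-free, and the optimizer discovers exactly this.

## Noise and the twelve metrics

Complex Gaussian noise (independent real/imaginary channels) is added in
k-space.  The default level is relative: the k-space sigma is chosen so that
the image-domain per-channel noise std equals 2% of the maximum of the
noiseless reconstruction.  Since the SNR metric divides the tissue mean by
that same per-channel std, the maximum attainable SNR is `1/0.02 = 50`, and
the worked SNR > 30 constraints are attainable but selective.  Noise is added for the SNR metrics (single-image
background method with the Rayleigh correction 0.655); the remaining
square-phantom metrics are computed from the noiseless reconstruction of the
same k-space, and the circular-phantom simulations are noiseless so that the
PCC shift scans measure motion and off-resonance effects, not noise.

The ghost level is reported as ghost-region mean over object-region mean
(small is good), the orientation that makes an `avoid ghosting -> ghost <
0.05` constraint satisfiable; the inverse orientation is available by
argument.  Sharpness and homogeneity are Pearson correlations against the
phantom's ground-truth proton-density image over the structure mask and the
filled-CSF window (the window includes the region boundary so the reference
is never constant).  Motion sensitivity is `1 - max PCC` over all integer
circular PE shifts of the motion image against the motion-free
reconstruction — zero for a pure shift by construction, positive for
intra-scan motion.  Distortion sensitivity is the argmax location of that
scan divided by the interpolated PE matrix size, with ties broken toward the
smaller circular distance.  The motion/distortion reference is the plain
circular reconstruction (not the phantom itself), isolating motion and
off-resonance effects from sequence-intrinsic blurring.

## Surrogates: the three-way holdout protocol

Rows are split 60/20/20 into train/test/validation.  For each metric, three
model types are tuned by uniform random search (200 draws each by default)
under 10-fold cross-validation on the training partition: support vector
regression (tolerance in [0.001, 0.9], epsilon in [0.1, 0.9], kernel in
{radial, linear, polynomial}; inputs z-scored, target standardized), a
k-nearest-neighbour regressor with Minkowski distance exponent in [0.1, 20]
and a rectangular/triangular/gaussian weighting kernel (k fixed at 7, the
conventional default; this learner is implemented in-package since no
installed package provides weighted-Minkowski kNN regression), and a random
forest with 1-20 trees and depth 0-20 (0 = unlimited).  The tuned candidates
are compared by RMSE on the test partition; only the winner is evaluated on
validation.  The tests assert this isolation directly: corrupting the
validation targets changes neither the tuned hyperparameters nor the model
choice.  Errors are reported as RMSE, RRSE (RMSE relative to the
constant-mean predictor, which scores exactly 1) and RMSLE.  Constant input
columns (e.g. the fixed 90° excitation angle) are dropped before scaling and
before the PCA, which therefore operates on the ten-column numeric view.

## The constrained evolutionary search

Candidates are genomes in `[0,1]^10`, affinely mapped to the grid parameter
ranges.  Before evaluation each candidate is *repaired*: the refocussing
angle is rounded to {0, 180} and the EPI factor to the nearest admissible
value (recovering the categorical family), then the whole vector is snapped
to the nearest point of that family's validity-filtered grid under
per-coordinate range-normalized distance.  This makes repair idempotent,
guarantees validity, and clamps out-of-range timings to the family extremes —
an infeasible bSSFP-family TE/TR of 130/4300 ms repairs to the largest grid
pair, 17/36 ms.

The fitness is the predicted goal metric (negated for minimization;
acquisition-time goals are range-normalized so the penalty constants dominate
every goal scale) minus a constant 1000 per violated strict constraint, minus
0.1 x |goal| per violated vague constraint — except violated avoid-bounds on
ghosting, motion and distortion, which contribute `exp(50 (p_m - c_m))`:
negligible for slight violations, overwhelming for gross ones.  The penalty
constants are package defaults (only their qualitative structure is
externally prescribed) and are config-overridable.  A fitness trace that
turns positive certifies that no strict constraint is active at the
incumbent, since the strict penalty exceeds every attainable goal magnitude.

The EA itself: population 50, 100 generations, line crossover with
probability 0.1 (interpolation on the parent segment extended by 10% on
either side — the interpolation interval is otherwise unspecified, so
inside-segment-with-extension is the package's choice), Gaussian mutation
with probability 0.9 and step 0.1 of the gene range, two elites, tournament
size 3.  The mutation step anneals geometrically to 5% of its initial value
across the generations; a constant step was the alternative, but annealing
lets the search both traverse the grid early and settle into a single grid
cell late, and it is what makes the analytic benchmark (recovering the
optimum of `-sum((x-0.5)^2)` to within 0.05 per coordinate on every seed)
reliable.  Elitism makes the best-so-far trace non-decreasing, which the
tests assert.

## Problem sizes used in the checks

The shipped test and reproduction runs use the reduced grid: 16 x 16
matrices on 50 x 50 mm phantoms, 182 valid sequences across the four
families, four simulations each (about ten seconds in total), surrogate
budgets of 20-60 random draws, and the full 50 x 100 EA.  These sizes are the
package's choice of a desk-scale experiment; the full grid (32/64 matrices,
up to 10 measurements, 200-draw budgets) runs the identical code paths and is
what `sequence_grid_config(reduced = FALSE)` and the CLI default to.  At the
reduced scale two metric floors move visibly: truncation sidelobes put the
ghost floor near 0.07 (so the 0.05 avoid-bound stays slightly violated and
contributes a small exponential penalty everywhere), and the 1-px shift
quantum makes distortion sensitivity multiples of 0.02.

## What passing tests do and do not show

The synthetic campaign exercises contrast, saturation, steady-state,
ghosting, blurring, shift and timing behaviour with known ground truth, so
the test suite can pin the simulator to closed forms and the metrics to
constructed oracles.  It does not emulate everything real acquisitions show:
no receive-coil shading, no T2' decay or susceptibility gradients (distortion
appears only as bulk shift, not local warping), no through-plane effects, no
physiological noise, and motion is a slow rigid drift.  Conclusions about
*which* sequence wins a clinical requirement therefore transfer to real
scanners only as far as these effects are secondary; the framework —
DSL, simulator contract, metric definitions, holdout protocol, penalty
search — is what the package warrants.

## Known limitations

* Cartesian trajectories only; radial/spiral sampling and their streak
  metrics are out of scope.
* Preparation modules (inversion recovery, fat saturation) are not modelled.
* The repair step projects onto the simulated grid, so the optimizer cannot
  propose parameters outside the training ranges by design.
* Surrogate quality is bounded by the campaign size; on the reduced grid the
  SNR surrogates are the weakest (validation RRSE near 1 for CSF SNR), and
  thin feasible regions can be smoothed away if the tuning budget is cut
  drastically below the default.
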