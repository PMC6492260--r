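---
title: "Designing multi-delay PCASL experiments with asldesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-delay PCASL experiments with asldesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asldesign)
```

## The design problem

Arterial spin labeling (ASL) measures perfusion by magnetically labeling
arterial blood and imaging it after a post-labeling delay (PLD). The
label-control difference signal is small, so within a fixed scan time the
choice of PLDs largely determines how precisely cerebral blood flow (CBF)
and arterial transit time (ATT) can be estimated: sampling too early
misses slow-arriving blood, sampling too late wastes signal to T1 decay,
and every extra delay costs averages. `asldesign` treats this as a formal
optimal-design problem: predict the estimation error of any candidate PLD
schedule from its Fisher information, and search for the schedule that
minimizes the predicted error averaged over the transit times one expects
to encounter.

## Signal model

The pseudo-continuous ASL difference signal follows the general kinetic
model: zero before the label arrives (`t < ATT`), an inflow phase while
the bolus of duration `tau` accumulates, and apparent-T1 decay after the
full bolus has arrived. Time `t` is measured from the start of labeling,
so a delay maps to `t = tau + PLD` (plus the slice offset in 2D readouts).
The apparent relaxation time couples to perfusion through venous outflow,
`1/T1' = 1/T1t + f/lambda`. User-facing CBF is in mL/100g/min; the kinetic
rate is `f = CBF/6000` s^-1 so that `f/lambda`, with `lambda` in mL/g, is
a rate. The defaults in `asl_acq()` are representative 3T gray-matter
values: `tau` 1.4 s, labeling efficiency 0.85, `lambda` 0.9 mL/g, T1 of
blood 1.65 s, T1 of tissue 1.445 s.

```{r}
acq <- asl_acq()
gkm_signal(1.9, cbf = 50, att = 0.5, acq)  # signal at the bolus peak
```

The model is continuous at both phase boundaries and peaks exactly at
`t = tau + ATT`. Breakpoint ownership (arrival starts the inflow branch,
the peak starts the decay branch) is a bookkeeping convention that
continuity makes inconsequential.

## Sensitivity functions and the frozen-T1' approximation

The Fisher information needs the derivatives of the signal with respect
to CBF and ATT. Design calculations use a simplified CBF sensitivity in
which T1' is frozen at a reference perfusion of 50 mL/100g/min
(`acq$fixed_outflow_cbf`), which makes the model exactly linear in
perfusion: the sensitivity no longer depends on the unknown CBF, and with
it the whole design problem loses its CBF dependence (the CBF-only
criterion exactly, the joint criterion up to a uniform scale). Only an
ATT prior is then needed.

The package also provides the complete derivative, including the
dependence of T1' on perfusion through the outflow term
(`dT1'/df = -T1'^2/lambda`), and verifies both against central finite
differences of the signal in the test suite.
`sensitivity_approx_error()` quantifies the cost of freezing T1': the
maximum relative deviation between the two sensitivities over true CBF
from 0 to 100 mL/100g/min, evaluated on a dense time grid across the
bolus window (arrival to peak).

```{r}
100 * as.numeric(sensitivity_approx_error(acq, t_step = 0.005))
```

About 1.7% at worst - small enough to ignore for design purposes. The
comparison window matters: past the peak the frozen and self-consistent
models decay at slightly different rates, so the *pointwise* relative
deviation grows without bound as the signal itself decays to nothing. We
confine the comparison to the bolus window, where the inflowing label
carries the CBF information that the design tries to capture; published
figures for this quantity that include part of the decay are slightly
larger (for reference, extending the window 50 ms past the peak gives
1.78%).

## Fisher information, CRLB, and design criteria

For sample times `t_i`, `A` label-control pair averages, and difference
noise variance `sigma^2`, the 2x2 information matrix is
`F = (A/sigma^2) * sum_i s_i s_i'` with `s_i` the (CBF, ATT) sensitivity
vector. Its inverse bounds the covariance of any unbiased estimator
(Cramer-Rao); the package inverts it in closed form and treats condition
numbers above 1e8 as singular - an ill-conditioned information matrix
here always means a lack of ATT information (every sample past the bolus
peak, where the two sensitivities are collinear), and the design
machinery avoids such matrices by prior truncation rather than
regularizing them.

Two criteria are built in, plus a generalization:

* `d_optimal`: minimize `1/det(F)`, the volume of the joint confidence
  ellipsoid - balanced CBF and ATT accuracy;
* `l_optimal`: minimize `[F^-1]_11`, the CBF variance alone, which still
  accounts for ATT as a nuisance parameter;
* `weighted_trace`: minimize `trace(W F^-1)` for any PSD weight matrix,
  for explicit CBF/ATT trade-offs (the weights must be chosen by the
  user; we do not attempt to calibrate them).

`sigma^2` is a pure scale factor for all three, so no noise estimate is
needed to *rank* designs; a calibrated value converts bounds to
physiological units.

## The transit-time prior

A design tuned to a single ATT is poor at other ATTs, so the criterion is
averaged over a discretized prior (`att_prior()`): uniform over a core
range - the default 0.5-1.8 s covers gray matter in healthy adults -
extended on each side by a 0.3 s linear taper to zero, which avoids hard
edge effects. The default grid step of 1 ms keeps the averaged criterion
stable well below 0.1% compared with finer steps. Any discrete prior can
be supplied through `att_prior_weights()`.

In 2D multi-slice readouts, slice `k` is read `k * slice_duration` after
the first, so each slice sees its own effective delays. For each slice
the prior is truncated at the slice's shortest effective delay
(`truncate_below()`): a transit time at or below it means that slice
samples no inflow at all and its information matrix is singular. The
truncation is strict at the boundary (where the sensitivities are exactly
collinear) and keeps the retained masses unnormalized, so that transit
times visible to more slices carry proportionally more weight when the
per-(slice, ATT) criterion values are combined:
`cost = sum(phi * p) / sum(p)` over retained pairs.

## Scan-time accounting

One acquisition of a delay costs `tau + PLD + readout` seconds for the
label image and the same for the control (variable TR: short delays are
acquired with short repetition times). The number of averages is
`A = floor(budget / (2 * sum(tau + PLD_i + readout)))` - the factor 2 for
the label+control pair is essential to reproduce standard protocol
timings:

```{r}
compute_averages(c(0.25, 0.5, 0.75, 1, 1.25, 1.5), 1.4, 1.275, 300)  # 7
compute_averages(1.8, 1.4, 1.275, 300)                               # 33
```

## The exchange search

`optimize_plds()` implements a coordinate exchange: delays live on a
25 ms grid in [0.2, 3] s (the lower bound leaves room for background
suppression pulses; the upper bound only trims the search space, since
the optimal longest delay never exceeds the longest prior transit time).
The search visits each delay cyclically and replaces it with the best
grid value between its neighbours - which keeps the list sorted -
recomputing `A` for every candidate set, until a full pass changes
nothing. Ties keep the incumbent and candidates are scanned in ascending
order, so results are fully deterministic. Initialization spreads the
delays over 0.25-1.5 s by default; it should cover most of the prior
range, or early exchanges can be dominated by ill-conditioned
information.

The integer jump in `A` between neighbouring designs creates basins that
a one-delay-at-a-time move cannot always cross, so final costs can differ
by around a percent between initializations. `optimize_plds_multi()`
runs a fixed set of five initialization ranges spanning the prior support
and keeps the lowest-cost design; we use it for production designs and
for the delay-count comparisons below. `sweep_num_plds()` repeats the
search over a range of delay counts.

Two structural properties are worth knowing (both are asserted in the
test suite): the optimized design is exactly invariant to the CBF point
at which the ATT sensitivity is evaluated, and for a point prior at a
single ATT the chosen sample times cluster at `t = ATT` (arrival, where
ATT information peaks) and `t = ATT + tau` (bolus peak, where CBF
information peaks) - in delay terms, `PLD = max(ATT - tau, 0.2)` and
`PLD = ATT`.

Restricting the delay count costs little: re-optimizing the joint
criterion with 10 delays (4 averages) instead of 40 (1 average) changes
the prior-averaged predicted CBF and ATT errors by well under one percent
in our runs, which makes shorter, easier-to-implement schedules
practical.

## Noise conventions and calibration

Eq-style information formulas and the simulator must agree on what
`sigma` means. The package convention: `noise_model(sigma)` takes the SD
of a single label or control image; a single difference then has
variance `2 sigma^2` (`diff_variance()`), and that is the
`noise_variance` the information functions expect. Averaging `A` pairs
leaves `2 sigma^2 / A` per data point. Keeping the factor 2 explicit is
what puts Cramer-Rao predictions and Monte Carlo RMSEs on the same scale.

Absolute noise is scanner- and sequence-specific, so the default is a
calibration rule rather than a number: `calibrate_sigma()` returns the
sigma at which the evenly spaced reference protocol has a predicted CBF
error of 5 mL/100g/min (10% of typical gray-matter perfusion) at
ATT 1.15 s - a realistic operating point for background-suppressed PCASL
at 3T. All design rankings are sigma-invariant; only absolute error
curves and the single-delay trade-off below depend on it.

## Single-delay protocols

With one delay, CBF is fitted with an assumed transit time; the
theoretical error combines the one-parameter Cramer-Rao variance with
the systematic mismatch bias, `RMSE = sqrt(var + bias^2)` (we read the
usual RMSE decomposition this way; `single_pld_rmse()`). Sweeping the
assumed ATT and averaging over a uniform true-ATT range finds the best
single operating point:

```{r, eval = FALSE}
sigma <- calibrate_sigma(acq)
optimal_assumed_att(pld = 1.8, cbf = 50, acq = acq, n_averages = 33,
                    noise_variance = 2 * sigma^2)
```

At the calibrated noise level this returns 1.20 s. The mean-RMSE curve
is flat to about 0.1% across assumed ATTs of 1.15-1.35 s, and its argmin
moves with the noise level (about 1.4x more noise moves it to 1.25 s, a
commonly quoted operating point), so the choice among neighbouring 50 ms
grid values is essentially free in practice.

## Monte Carlo validation

`simulate_dataset()` draws noisy difference data at every (delay, slice)
sample time - directly in the difference domain by default, or as
explicit label/control pairs, which is also how the optional per-delay
variable-noise feature (`per_pld_scale`) is simulated. `fit_nlls()`
recovers both parameters by bounded Levenberg-Marquardt least squares
(CBF in [0, 200], ATT in [0, 2.5]; function tolerance 1e-10, at most 200
iterations; analytic Jacobian from the sensitivity functions),
initialized by an exhaustive coarse grid search (CBF step 10, ATT step
0.1). `run_monte_carlo()` fits each slice's series separately - the
analogue of voxelwise fitting, where a voxel sees only its own slice's
delays - and pools the per-slice estimates into per-ATT RMSE, bias and
SD; `predict_errors()` mirrors this by averaging per-slice bound SDs
across contributing slices, and uses the per-slice single-delay RMSE for
single-delay protocols. Reported SDs in the Monte Carlo tables are
population SDs so that `RMSE^2 = bias^2 + SD^2` holds exactly per cell.

Non-convergent fits are counted (`n_failed`) and their bounded estimates
retained, never silently dropped; at the default operating point
failures are of order 1 in 10^4.

What the simulator emulates - and what it does not: Gaussian noise,
identical across delays unless scaled, independent at every acquired
sample; ideal label timing; a single-compartment kinetic model. Real
data add Rician magnitude noise (benign above SNR ~3), variable
background-suppression effectiveness across delays, dispersion of the
bolus, macrovascular contamination and motion. Passing Monte Carlo
checks therefore validates the statistical machinery, not the
acquisition physics.

## Numerical choices, in one place

* condition-number limit 1e8 for declaring an information matrix
  singular; such (slice, ATT) pairs make a design infeasible rather than
  being skipped;
* strict per-slice prior truncation at the shortest effective delay
  (the boundary itself is exactly singular; one prior step above it the
  condition number is already ~1e3);
* exchange tie-break keeps the incumbent delay; candidate scan order is
  ascending; convergence is a full pass with no change, capped at 50
  passes;
* delay grid 25 ms; prior step 1 ms; grid-search initialization lattice
  CBF x ATT = 10 x 0.1;
* the single-delay one-parameter variance uses the complete CBF
  sensitivity evaluated at the mismatch solution.

## Problem sizes used by the tests

The full study-scale Monte Carlo (131 transit times x 2000 repeats) is
what `run_monte_carlo()` defaults reproduce. The test suite exercises
the identical code paths at desk scale - a 0.05 s transit-time grid with
200 repeats for the four bundled protocols, and coarser priors for the
optimizer property checks - which keeps the whole suite within a few
minutes while still testing estimator efficiency (within 20% of the
bound at mid-range ATT) and predicted-versus-simulated protocol
rankings for clearly separated protocols. Near-tied protocols (predicted
errors within a few percent) are not ranked reliably by either route and
are not asserted.

## Limitations

The framework optimizes delays for a fixed label duration; optimizing
the label duration itself, per-delay durations, or time-encoded schemes
is out of scope. The kinetic model is single-compartment PCASL without
dispersion; PASL needs different sensitivity functions. Error
predictions are lower bounds: estimator nonlinearity inflates simulated
RMSEs by up to ~10% over the bound even at moderate SNR, and more at
transit times poorly covered by a protocol.
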