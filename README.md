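# asldesign

Optimal experimental design for multi-delay arterial spin labeling
(ASL) perfusion MRI.

ASL quantifies cerebral blood flow (CBF) by magnetically labeling
arterial blood and imaging the label-control difference after a
post-labeling delay (PLD). The technique is SNR-starved, and within a
fixed scan time the choice of PLDs largely decides how accurately CBF
and arterial transit time (ATT) can be estimated. `asldesign` is for
ASL methodologists and physicists who want to design PLD schedules with
predictable accuracy instead of evenly spaced guesses: it predicts
estimation errors from first principles and searches for the schedule
that minimizes them.

## What it computes

The pseudo-continuous ASL difference signal follows the general kinetic
model ΔM(t; f, Δt): zero for t < Δt, inflow for Δt ≤ t < τ + Δt, and
apparent-T1 decay afterwards, with 1/T1′ = 1/T1t + f/λ, label duration
τ, perfusion f and transit time Δt. For sample times t
(per-slice-adjusted in 2D readouts), A label-control pair averages and
difference-noise variance σ², the Fisher information of θ = (CBF, ATT)
is

    F(t; θ) = (A/σ²) Σᵢ (∂ΔM(tᵢ)/∂θ) (∂ΔM(tᵢ)/∂θ)′ ,

and F⁻¹ is the Cramér-Rao lower bound on the estimator covariance. A
design is scored by D-optimality (1/det F, joint CBF+ATT accuracy) or
L-optimality ([F⁻¹]₁₁, CBF accuracy alone), averaged over a
tapered-uniform ATT prior, with a per-slice prior truncation that keeps
the information matrices well conditioned. A coordinate-exchange search
over a 25 ms PLD grid minimizes this cost under the scan-time budget
A = ⌊T / (2 Σᵢ (τ + PLDᵢ + readout))⌋. Monte Carlo simulation plus
bounded nonlinear least-squares fitting validates every design against
its predicted errors.

## Worked example

Design a 10-delay protocol for joint CBF and ATT accuracy in a 5-minute
scan, then check it:

```r
library(asldesign)
acq <- asl_acq()        # tau 1.4 s, 3T gray-matter constants
prior <- att_prior()    # ATT 0.5-1.8 s core, 0.3 s taper
design <- optimize_plds(10, prior, criterion_spec("d_optimal"), acq,
                        scan_time_budget = 300)
design
#> ASL protocol 'd_optimal optimized (N=10)'
#>   10 PLDs (s): 0.250, 0.475, 0.600, 0.650, 0.700, 1.350, 1.450, 1.500, 1.825, 1.950
#>   tau 1.4 s, readout 1.275 s, 5 slices x 53.12 ms, 4 average(s)
#>   scan time 300 s (budget 300 s)
```

The search concentrates delays in two groups — short delays sampling the
inflow (ATT information) and long delays around the bolus peak and decay
(CBF information) — and finds that 4 averages of these 10 delays fit the
300 s budget. Predicted errors at a calibrated noise level (reference
protocol pinned at a 10% CBF error):

```r
sigma <- calibrate_sigma(acq)
predict_errors(design, att_values = c(0.7, 1.0, 1.3, 1.6), acq = acq,
               noise_variance = diff_variance(noise_model(sigma)))
#>   att cbf_sd att_sd n_slices_contributing
#> 1 0.7   3.56  0.102                     5
#> 2 1.0   5.61  0.111                     5
#> 3 1.3   5.54  0.105                     5
#> 4 1.6   7.22  0.113                     5
```

i.e. CBF errors of 3.6-7.2 mL/100g/min (7-14% of a gray-matter CBF of
50) and ATT errors near 0.1 s across the prior range. Monte Carlo
recovery (200 noisy datasets per ATT, per-slice fits) lands on the
predictions:

```r
run_monte_carlo(design, att_grid = c(1.0, 1.3), cbf_true = 50,
                noise = noise_model(sigma), n_repeats = 200, seed = 1)
#>   att_true cbf_rmse cbf_bias att_rmse
#> 1      1.0     5.50   -0.148    0.132
#> 2      1.3     5.81   -0.113    0.117
```

Four ready-made 5-slice protocols (single-delay, evenly spaced
reference, and two optimized designs) ship with the package via
`example_protocols()`; `compare_protocols()` reports predicted and
simulated errors side by side. A command-line front end with
`optimize`, `crlb`, `simulate`, `fit` and `compare` subcommands is
installed from `exec/asldesign`. See the vignette
(`vignettes/design-methodology.Rmd`) for the model, conventions and
numerical choices.

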