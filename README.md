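# photoclamp

Rod and cone photoreceptors adapt: their gain and kinetics change with mean
light level, fast enough to shape every cycle of a modulated stimulus.
Because every downstream visual signal is built from photoreceptor
currents, separating *receptor* nonlinearities from *circuit*
nonlinearities is hard — retinal models usually just assume the front end
is linear. `photoclamp` implements the tool that breaks this deadlock for
physiologists: a biochemical model of the phototransduction cascade that is
accurate enough to be trusted and simple enough to be **exactly inverted**,
so that one can compute the light stimulus that will force a photoreceptor
to produce any chosen, physically realizable response — including the
response it *would* produce if it did not adapt ("light-adaptation clamp").

## The model

The cascade is the standard kinetic loop: photons isomerize opsin (rate
`gamma`, decay `sigma`), active opsin drives phosphodiesterase (decay
`phi`, spontaneous activation `eta`), PDE hydrolyzes cGMP, cGMP gates the
channels carrying the current `I = k G^n`, and calcium entering through
those channels (extrusion rate `beta`) feeds back on the cyclase that
resynthesizes cGMP (affinity `K_GC`, cooperativity `m`):

    dR/dt = gamma * Stim - sigma * R
    dP/dt = R - phi * P + eta
    dG/dt = S - P * G,   S = S_max / (1 + (C/K_GC)^m)
    I     = k * G^n
    dC/dt = q * I - beta * C

`q` and `S_max` are fixed by requiring the measured dark current to be a
fixed point. Consensus parameter sets for primate and mouse rods and cones
are built in (`consensus_params()`), and the cascade's static
nonlinearities, linear filters, and single time-dependent nonlinearity can
each be inverted in closed form — `invert_current()` maps a photocurrent
back to the unique stimulus that produces it, exactly on noise-free model
output, and with band-limiting plus power-spectrum matching for measured
responses.

On top of the forward/inverse pair the package provides: small-signal
linear-filter fitting (`fit_linear_model()`), the clamp designers
(`design_clamp()`, `design_step_flash_clamp()`, `design_kinetics_clamp()`),
Nelder-Mead single-cell and shared-parameter consensus fitting
(`fit_cell()`, `fit_consensus()`), MSE-doubling sensitivity ranges and
sloppy-model Hessian analysis (`sensitivity_range()`, `sloppy_hessian()`),
response metrics (best-fit-sinusoid error, step+flash gain ratio,
time-to-peak, stimulus-response loop area, residual power spectra), photon
calibration from optical power to isomerization rates
(`power_to_isomerizations()`), and generators for the standard stimulus
protocols (`make_variable_mean_noise()` and friends). A thin command-line
wrapper over these functions ships at `inst/cli/photoclamp.R`.

## Worked example

```r
library(photoclamp)

## 1. A consensus mouse rod with a 24 pA dark current
params <- consensus_params("mouse_rod")
dark   <- dark_operating_point(params, dark_current = 24)
dark
#> <dark_point> I_D = 24 pA, G_D = 13.3887 uM, P_D = 0.211488 s^-1
#>   q = 1.04167 uM/s/pA, S_max = 113.439 uM/s

## 2. Simulate its response to a variable-mean noise stimulus, then invert
##    the current back into the stimulus
stim  <- make_variable_mean_noise(cell_type = "mouse_rod", segment_dur = 2,
                                  seed = 1)
state <- simulate_cascade(params, dark, stim,
                          initial = steady_state(params, dark, stim$values[1]))
est   <- invert_current(state$I, params, dark)
fraction_variance(stim, est)
#> [1] 0.9999669

## 3. Design a stimulus that makes the rod's response to a 0.5 Hz, 80%
##    contrast sinusoid itself sinusoidal (a light-adaptation clamp)
lf    <- fit_linear_model(params, dark, mean_level = 25, seed = 1)
lf
#> <linear_filter> alpha = 1.198, tau_r = 78.21 ms, tau_d = 188.8 ms
#>   fit at mean = 25 R*/s (mouse_rod)
sine  <- make_sinusoid_stimulus(25, contrast = 0.8, freq = 0.5,
                                duration = 6, dt = 1e-3)
clamp <- design_clamp(sine, params, dark, lf)
clamp
#> <clamp_result> 6000 samples, dt = 0.001 s
#>   feasible = TRUE, clipped fraction = 0, achieved-vs-target variance ratio = 1.4e-30

orig <- simulate_cascade(params, dark, sine,
                         initial = steady_state(params, dark, sine$values[1]))
c(original = best_fit_sinusoid(orig$I, 0.5)$mse,
  modified = best_fit_sinusoid(clamp$achieved_response, 0.5)$mse)
#>   original   modified
#> 0.06345392 0.01560742
```

Reading the output: inversion of the noise-free simulated current recovers
the stimulus essentially exactly (variance explained ~1). The fitted
small-signal filter for this rod at 25 R*/s rises in ~78 ms and decays in
~189 ms. The clamp design is feasible — the required stimulus never goes
negative — and the forward simulation of the modified stimulus reproduces
the linear target to numerical precision, cutting the response's deviation
from a pure sinusoid (variance-normalized MSE against the best-fitting
sinusoid) by about fourfold; the residual is dominated by the filter's
settling transient in the first cycle.

The methods vignette (`vignettes/adaptation-clamp.Rmd`) documents the
model's assumptions, the numerical schemes, the regularized inversion for
noisy responses, the clamp feasibility rules, and the limits of the linear
reference model for adapted cones.

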