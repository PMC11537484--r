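---
title: "Phototransduction models, exact inversion, and the light-adaptation clamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phototransduction models, exact inversion, and the light-adaptation clamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoclamp)
```

## The model

Rod and cone photocurrents are generated by a G-protein cascade: photons
isomerize opsin, active opsin drives phosphodiesterase (PDE) through
transducin, PDE hydrolyzes cGMP, and falling cGMP closes the outer-segment
channels that carry the current. Calcium entering through those channels
feeds back on guanylate cyclase, the enzyme that resynthesizes cGMP; this
feedback is the main engine of rapid light adaptation. `photoclamp`
implements the standard kinetic description of this loop:

\[
\begin{aligned}
dR/dt &= \gamma\,\mathrm{Stim}(t) - \sigma R \\
dP/dt &= R - \phi P + \eta \\
dG/dt &= S - P\,G, \qquad S = S_{max} / \bigl(1 + (C/K_{GC})^m\bigr) \\
I &= k\,G^n \\
dC/dt &= q\,I - \beta C
\end{aligned}
\]

with `Stim` in isomerizations per second (R*/s) and `I` the outer-segment
current. We treat `I` as a positive magnitude; recordings list dark
currents as negative, and the I/O layer accepts either sign. The transducin
step is folded into the opsin stage: it adds a delay short relative to the
rates above, and removing it keeps the cascade exactly invertible.

Two parameters are eliminated by steady-state conditions so that the dark
state is a fixed point: with a measured dark current \(I_D\),

\[
G_D = (I_D/k)^{1/n}, \qquad
q = \beta C_D / I_D, \qquad
S_{max} = G_D\,(\eta/\phi)\,\bigl(1 + (C_D/K_{GC})^m\bigr),
\]

computed by `dark_operating_point()`. The channel constants `k = 0.01`,
`n = 3`, the cyclase cooperativity `m = 4`, and the dark calcium
`c_dark = 1` uM are fixed from prior measurements for all cell types, as is
`beta` for rods; `consensus_params()` returns the per-type consensus values
for the remaining parameters (opsin decay `sigma`, PDE decay `phi`, dark
PDE activation `eta`, cyclase affinity `k_gc`, gain `gamma`). The opsin and
PDE decay rates are tied (`sigma == phi`): the light-driven signal passes
both first-order stages in series, so their rates enter symmetrically, and
because the derived \(S_{max}\) scales with \(1/\phi\), raising `phi` above
`sigma` leaves every fixed point of the system unchanged — the output
depends only on the slower of the two rates. (The converse is not true:
raising `sigma` changes the light-collection gain \(\gamma/\sigma\), which
is why the tie is resolved in favor of a single shared value during
fitting.)

The model is intended for the input range that constrained it: cone models
should not be pushed above roughly 50,000 R*/s, where pigment bleaching —
deliberately omitted — becomes relevant. Photoreceptor synaptic output,
electrical coupling, and horizontal-cell feedback are outside the model's
scope; it describes transduction currents only.

## Numerical scheme

`simulate_cascade()` integrates the system with forward Euler at a fixed
reference step of 0.1 ms for cones and 1 ms for rods, treating the stimulus
as constant over each step. Classical RK4 (with the stimulus linearly
interpolated) is available via `method = "rk4"` and is used in the test
suite, together with `deSolve::lsoda`, as a convergence cross-check;
halving the Euler step changes simulated currents by well under 0.5% RMS
on the variable-mean noise stimulus. Euler at 1 ms is stable while
\(P\,dt < 2\); rod PDE activity stays orders of magnitude below that bound
for physiological stimuli (rod saturation is complete by ~1000 R*/s), and
the integrator raises an error naming the failure time if a state ever
becomes non-finite.

Simulations at a nonzero background start from the root-found fixed point
(`steady_state()`, a bracketed one-dimensional root in \(G\) — the
synthesis and hydrolysis sides are monotone in \(G\), so the fixed point is
unique) rather than from a burn-in run; this removes onset transients
deterministically.

## Exact inversion

Given a current trace, the cascade can be run backwards
(`invert_current()`):

1. \(G = (I/k)^{1/n}\) pointwise, and \(C\) from the linear calcium ODE
   (`current_to_cgmp()`, `current_to_calcium()`);
2. \(P = (S(C) - dG/dt)/G\) (`pde_from_cgmp()`);
3. \(R = dP/dt + \phi P - \eta\), then
   \(\mathrm{Stim} = (dR/dt + \sigma R)/\gamma\) (`stimulus_from_pde()`).

The default derivative scheme, `"matched"`, mirrors the forward Euler
discretization sample by sample — forward differences and the same calcium
recursion — so inverting a simulated current reproduces the stimulus to
rounding error (the final three samples fall outside the differentiation
support and are held at the last determined value). Central-difference and
spectral schemes are provided for traces that did not come from the
reference integrator; they are accurate on smooth currents but cannot be
exact for broadband stimuli, which is why the discretization-consistent
scheme is the default.

For measured responses, noise is the limiting factor: the two
differentiation stages amplify it as \((2\pi f)^3\). `inversion_settings()`
therefore supports the regularization used in practice: a hard band limit
(defaults 60 Hz for primate cones, 30 Hz for mouse cones, 15 Hz for rods)
and a power-spectrum-matching constraint. The band limit is applied to the
*current* before differentiation — removing out-of-band noise after it has
been amplified and nonlinearly mixed would be too late — using a brick-wall
filter on an even (mirrored) extension of the trace, so the hard cutoff
does not ring off the record boundaries of non-periodic traces. Spectrum
matching then rescales the Fourier amplitude of the estimate, bin by bin
within the band, to a reference amplitude spectrum while preserving phases;
the matched estimate's power spectrum equals the reference exactly, by
construction. Negative recovered intensities are never silently removed:
the mathematical estimate is returned intact with its negative fraction as
an attribute, and clipping happens only in the clamp-design layer, where it
is reported.

## The linear reference model

The clamp needs a description of how a photoreceptor *would* respond if it
had no nonlinearities. Following standard practice, that reference is a
parameterized filter

\[
L(t) = \alpha\,\frac{(t/\tau_R)^3}{1 + (t/\tau_R)^3}\,e^{-t/\tau_D},
\]

a cubed saturating rise (time constant `tau_r`) times an exponential decay
(`tau_d`), fit by `fit_linear_model()` to the full model's response to
low-contrast Gaussian noise at a chosen mean. Defaults: 5% RMS contrast
(deep in the linear regime but well conditioned), 30 s of noise for cones
and 60 s for rods, noise refreshed at the integration step, and a fixed
seed. The simplex search runs over the log time constants with the scale
\(\alpha\) profiled out in closed form; stimulus and response are
block-averaged to 1 ms before fitting, which removes only frequencies far
above the filter's support. Fits are reproducible under a fixed seed and
insensitive to the noise refresh interval and, for the time constants, to
the assumed dark current (which scales only \(\alpha\)).

One honest limitation matters when interpreting clamp designs. For rods at
25 R*/s the fitted filter is an accurate small-signal model (residual ~3-5%
RMS, impulse peak time within ~5% of the model's dim-flash peak). For cones
at 22,000 R*/s the true small-signal transfer is strongly high-pass —
adaptation attenuates slow fluctuations — and a monophasic filter cannot
express that: the fit leaves a ~19% broadband residual, concentrated at low
frequencies, and its impulse response peaks ~30% earlier than the model's
flash response. This is a property of the filter family, not of the fit;
linear models genuinely overpredict slow components of adapted cone
responses. Consequences: clamp targets for cones embody "the response of a
linear cone", which is exactly what the clamp is for, but the modified
stimulus for a low-contrast cone input does not collapse back to the input
(for rods it does, to within ~3%).

## The light-adaptation clamp

`design_clamp()` chains the pieces: pass the original stimulus through the
linear filter to get a target current free of adaptive distortion, invert
the full model on that target, clip any negative stimulus samples to zero
(reporting the clipped fraction), and verify by forward simulation. When
nothing is clipped the achieved response equals the target to inversion
tolerance, so the interesting quantities are the feasibility diagnostics.
A target current that touches zero is declared infeasible outright — no
light waveform can produce it, because zero current requires unbounded PDE
activity.

The three applications mirror the standard experiments:

* **Sinusoids** (`design_clamp()` on `make_sinusoid_stimulus()`): a
  high-contrast sinusoid drives strongly asymmetric, non-sinusoidal
  responses; the modified stimulus makes the simulated response sinusoidal,
  shrinking the best-fit-sinusoid error many-fold. Defaults of 2 Hz for
  cones and 0.5 Hz for rods keep the modulation inside the per-type
  recoverable bands.
* **Step plus flash** (`design_step_flash_clamp()`): identical test flashes
  before and during a step in mean level. The forward model's flash gain
  drops roughly twofold during the step; the modified stimulus restores a
  simulated gain ratio of 1. The filter fit at the pre-step mean defines
  the target, matching the convention of using a single filter per design.
  The published experiments do not state their background and flash
  intensities, so the package's worked examples and tests fix them once as
  fixture choices: 5,000 to 10,000 R*/s with 50 R* flashes for cones, and
  5 to 15 R*/s with 0.5 R* flashes for rods — large enough steps for a
  clear (~2x) gain change in the forward model, small enough that the
  linear target current stays positive and the test flashes stay in the
  locally linear range (stronger flashes need briefly negative light after
  the flash tail, which clips and perturbs the achieved gain by a few
  percent).
* **Kinetics scaling** (`design_kinetics_clamp()`): the target is the
  linear flash response with both time constants multiplied by a factor.
  Slowing (factors above 1) is cleanly feasible; speeding pushes the
  required stimulus negative — a brief increment must be followed by a
  decrement below zero light — so the clipped modulation energy is always
  reported, and designs losing more than 20% of it are flagged infeasible
  with the largest cleanly achievable scale attached. Speeding by ~20% is
  typically the practical limit, consistent with the contrast ceiling of
  real stimulators.

## Fitting, sensitivity, and sloppiness

`fit_cell()` and `fit_consensus()` estimate the free parameters —
(`gamma`, `sigma`, `eta`, `k_gc`) for rods, plus `beta` for cones — by
Nelder-Mead simplex on the per-sample mean squared error, with `sigma` and
`phi` tied, positivity enforced by searching in log-parameters, three
perturbed restarts, and a relative objective tolerance of 1e-8. Each
cell's dark cGMP is pinned by its measured dark current; consensus fits
share the kinetic parameters across cells and give each cell its own
`gamma`, absorbing sensitivity differences. Recordings are assumed to
begin near steady state: the fitter equilibrates at the mean of the first
half second of stimulus and drops that initial half second from the error,
so small equilibration mismatches cannot bias the kinetic parameters.
Goodness of fit is reported as the fraction of variance explained,
\(1 - SSE/SST\).

`sensitivity_range()` reproduces the MSE-doubling analysis: one parameter
is varied on each side of the optimum (bisection on the log axis) until
the fit error doubles. When the tie is active, varying `sigma` varies
`phi` with it — since the output depends only on the smaller rate, varying
`sigma` alone upward would never change the error and the upper bound
would not exist. Unreachable bounds within the search span are returned
as open, flagged, rather than extrapolated. `sloppy_hessian()` builds the
finite-difference Hessian of any scalar cost (central second differences
over parameter pairs, default relative step 1%, symmetrized) and
eigendecomposes it into stiff and sloppy parameter combinations; a
gradient outer-product variant is included for comparison with the
first-derivative form of the same analysis.

## What the synthetic data do and do not show

`make_variable_mean_noise()`, `make_flash_family()`,
`make_step_flash_stimulus()`, and `make_sinusoid_stimulus()` generate the
stimulus protocols that constrain the models: Gaussian noise with periodic
mean steps spanning up to 30-fold (defaults: five levels, 2 s segments and
1,500-45,000 R*/s for cones, 5 s and 1-30 R*/s for rods, 50% contrast —
segment durations and contrasts are fixture choices, recorded in the trace
metadata, since the originals are not printed), flash families doubling
from ~3 R*, and step-plus-flash protocols. `make_synthetic_recording()`
adds white Gaussian current noise to a forward simulation and keeps the
ground-truth parameters, enabling parameter-recovery experiments. All
generators are deterministic under a fixed seed.

These fixtures emulate the stimulus statistics, not the recordings: real
suction-electrode and patch noise is neither white nor stationary, real
cells differ from one another (and from any consensus model), and the
fixtures include no bleaching, no instrument drift, and no cell-to-cell
kinetic variability. Passing parameter-recovery tests therefore shows the
estimation machinery is consistent — data generated by the model class are
mapped back to their generating parameters at realistic noise — not that
recordings from a new preparation will be fit equally well. Test problem
sizes are chosen for determinism and speed: recovery experiments use three
synthetic rods with 12 s of variable-mean noise each at the 1 ms rod step;
filter fits use the full 30 s/60 s durations of the standard procedure;
inversion round trips use three-level, 6 s variable-mean fixtures per cell
type.

## Known numerical edge cases

* Inversion requires strictly positive current: fully closed channels carry
  no information about cGMP, and near-zero cGMP makes the PDE division
  ill-conditioned (signalled with sample locations).
* The exact-inversion guarantee is discretization-bound: traces must come
  from (or be treated as) the reference Euler grid; resampled or measured
  traces should use the band-limited path.
* The calcium frequency-domain solver assumes an effectively periodic
  trace; the time-domain exponential-trapezoid solver is the default
  inside the inversion because measured traces are not periodic.
* Time-to-peak uses local quadratic interpolation around the extremum and
  refuses monotone traces; gain ratios refuse windows that overlap or run
  off the trace.
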