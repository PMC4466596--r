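---
title: "Modelling cognitive stability and flexibility with ruleflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive stability and flexibility with ruleflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ruleflex models a combined task-switching / distractor-inhibition
paradigm: on every 2-s trial a digit (1-9, never 5) is judged either by
parity (baseline rule) or, when a brighter digit appears below fixation,
by magnitude (switch rule); a darker second digit must be ignored
(distractor). The package implements a two-module stochastic dynamical
model of this task — a working-memory module holding the active rule as
an attractor state, and a four-choice decision module reduced to a
nonlinear drift–diffusion process — together with the machinery to fit
it to trial-level behaviour, to reconstruct the rule module's potential
landscape, to quantify attractor stability as a minimal path action, and
to predict BOLD regressors from simulated activity.

## The rule module

The rule module is a mean-field reduction of a spiking winner-take-all
network: two selective excitatory populations (one per task rule)
embedded in shared non-selective and inhibitory pools. Its state is the
pair of NMDA synaptic gating variables $(S_1, S_2)$ with

$$\dot S_i = -\frac{S_i}{\tau_\mathrm{NMDA}} + (1 - S_i)\,\gamma\, r_i/1000,$$

time in ms, rates $r_i$ in Hz, $\gamma = 0.641$,
$\tau_\mathrm{NMDA} = 100$ ms. Rates follow the effective transfer
function `rate_transfer()`, whose gain, threshold and curvature depend
on the AMPA-mediated self-coupling and which receives the effective
currents $x_1 = J_{N,11} S_1 - J_{N,12} S_2 + I_0 + I_1$ (and
symmetrically for $x_2$). `effective_couplings()` assembles
$J_{N,\cdot}$, $J_{A,\cdot}$ and $I_0$ from the physiological constants
of `physio_constants()`: conductances, mean voltages, population
fractions, synaptic time constants, and the structural weights
$w_+ = 1.68$, $w_- = 1 - f(w_+ - 1)/(1 - f) = 0.88$ at coding level
$f = 0.15$.

Two constants of this reduction deserve comment, because the
parameter set as published does not pin them down unambiguously and the
package fixes them by calibration:

* **`mg_gate`** (0.91) weights the voltage-dependent magnesium-block
  attenuation of the NMDA conductances,
  $g_\mathrm{eff} = g / (1 + \mathtt{mg\_gate}\,e^{-0.062 V}/3.57)$.
* **`eta_gain`** (0.076) is the dimensionless closed-loop gain of the
  shared inhibitory population: its open-loop f-I gain $c_I/g_{I2}$ is
  attenuated by its own GABAergic self-inhibition. The value is close
  to the closed-loop factor
  $1/(1 + \tfrac{c_I}{g_{I2}} g_{\mathrm{GABA},I} (\bar V_I - V_\mathrm{rev})
  \tfrac{\tau_\mathrm{GABA}}{1000} C_I) \approx 0.071$ computed from the
  printed constants, which supports this reading.

The pair was fixed once, jointly, by requiring the module's documented
behaviour: exactly three stable states (a symmetric spontaneous state
near 3 Hz and two selective high-activity states at 20–40 Hz), all of
which survive $\pm 0.005$ perturbations of the conductance scalings
`s_nmda` and `s_gaba`. At the frozen values the spontaneous state fires
at 2.44 Hz and the high states at 21 Hz. This calibration is not a free
dial of the simulator: every analysis in the package uses these two
numbers unchanged.

### Noise

Finite-size fluctuations enter as an Ornstein–Uhlenbeck process per
population (correlation time $\tau_\mathrm{AMPA} = 2$ ms, stationary
variance $\sigma_\mathrm{rule}^2/2$), added to the gating *rate*
equations. Because $\dot S$ is a rate, the noise process carries units
of 1/s; the integrator therefore adds `S_noise/1000` per ms. This
convention was chosen deliberately: adding the same process on the
per-ms scale makes $\sigma_\mathrm{rule} = 0.1$ (the standard landscape
value) so strong that trajectories pin to the clamped corners of the
unit square and the three-basin structure of the published landscapes
cannot exist. The decision module's noise, by contrast, is a *current*
that stands next to the stimulus inputs inside the
$\tau\,\dot X = \ldots$ equations and needs no unit conversion.

Gating variables are clamped to $[0, 1]$ after every Euler–Maruyama
step (they are channel-open fractions); the OU update uses the exact
discretisation $n \leftarrow n e^{-\Delta t/\tau} +
\sigma/\sqrt2\,\sqrt{1 - e^{-2\Delta t/\tau}}\, z$. The default step is
$\Delta t = 0.5$ ms and `simulate_rule()` refuses steps above
$\tau_\mathrm{AMPA}/2$. The Heaviside gate in the cross-population AMPA
term uses $\theta(0) = 0$; the choice only matters on a measure-zero
set and is fixed for reproducibility.

## The decision module

The four-choice winner-take-all network is reduced, at the bifurcation
of its spontaneous state, to three amplitude equations

$$\tau \dot X = \tfrac{\alpha}{2}(\delta I_1 - \delta I_2) + \beta X Z + I^X_\mathrm{noise},$$
$$\tau \dot Y = \tfrac{\alpha}{2}(\delta I_3 - \delta I_4) - \beta Y Z + I^Y_\mathrm{noise},$$
$$\tau \dot Z = \tfrac{\alpha}{4}(\delta I_1 + \delta I_2 - \delta I_3 - \delta I_4) + \tfrac{\beta}{4}(X^2 - Y^2) + I^Z_\mathrm{noise},$$

with $\tau = 100$ ms and the slow time identified with trial time in
ms, so that first-passage times are reaction times directly. The four
population directions are the corners of a symmetric tetrahedron;
`project_populations()` recovers the per-pool activities
$p_1 = (X+Z)/2$, $p_2 = (-X+Z)/2$, $p_3 = (Y-Z)/2$, $p_4 = (-Y-Z)/2$.
A trial starts at the origin; the first projection to cross 10 decides,
and the crossing time is the RT. The quadratic terms produce divergence
in finite time, which makes RTs insensitive to the exact threshold.
Simultaneous crossings within one step go to the larger projection,
exact ties to the lower pool index (both measure-zero). Trials without
a crossing by 2000 ms are non-responses; downstream statistics
renormalise over responded trials. There is no separate non-decision
time.

During the 900-ms stimulus the pools receive
$\delta I_1 = D_{11} + c_+ r_1$, $\delta I_2 = c_+ r_1$,
$\delta I_3 = D_{12} + c_+ r_2$, $\delta I_4 = c_+ r_2$ (the
incorrect-feature drives are fixed at zero, and baseline trials have
$D_{12} = 0$ as only one digit is shown). After stimulus offset all
$\delta I$ are zero while noise and the nonlinearity keep acting — the
top-down feed is read literally as a stimulus-interval input, even
though the rule rates stay elevated; this is a documented
interpretation choice.

## Task protocol and the synthetic generator

`generate_session()` reproduces the scanner protocol: 300 trials of
2 s (240 baseline, 20 distractor, 20 switch, 20 ambiguous), every
critical trial separated from the next by 3–6 baseline trials, digits
from $\{1..9\}\setminus\{5\}$, cue brightness sampled from the printed
intervals (brighter digit in $[169,195]$, its partner at
$255 - \mathrm{gray}$, ambiguous lower digit in $[117,137]$, i.e. 8.2 %
of the 8-bit range). The gap vector is built constructively (a
constant split plus randomised bounded exchanges that preserve the
total), which is deterministic under the seed and always satisfies the
constraints. Ambiguous trials are generated for realistic logs and
BOLD timelines but never simulated or fitted; the synthetic logs record
them as non-responses.

Rule-module inputs per condition follow the condition table:
baseline drives only rule 1 with $I_{1,\mathrm{base}}$; distractor adds
$\bar I_\mathrm{dist} \pm \Delta I_\mathrm{dist}/2$ favouring rule 1;
switch mirrors the differential towards rule 2. Every trial starts from
the rule-1 attractor, obtained by noise-free relaxation from
$(0.8, 0.1)$.

`reference_params()` is the package's representative synthetic
subject. The paper-level constraints it satisfies — baseline accuracy
above 0.9 with some distractor/switch errors, mean RTs ordered baseline
< distractor < switch, reliable rule switching, trial-energy ordering
switch > distractor > baseline, $\sigma_\mathrm{rule} = 0.1$ — leave a
family of acceptable vectors; one member was chosen and frozen
(accuracies ≈ .98/.98/.91, mean RTs ≈ 646/678/710 ms). Subject-level
fitted values for the original cohort are not published, so these are
the package's own calibration, not a reproduction.

What the generator does *not* emulate: non-decision (sensory/motor)
time, learning and sequential dependencies across trials, lapses,
hand-mapping effects, and any strategy in the ambiguous condition.
Passing tests therefore certify the internal consistency of the model
and its estimators on data that share the model's structure — not the
model's adequacy for any real subject.

## Likelihood, priors and sampling

For a parameter vector $\theta$ the likelihood of a subject's summary
statistics multiplies, per condition, a multinomial factor for the four
decision counts (category rates = simulated decision probabilities from
fresh model runs, floored at $1/(2 n_\mathrm{sim})$ and renormalised)
and, per (condition, decision) cell, the asymptotic two-sample
Kolmogorov–Smirnov probability that the subject's and simulated RT
samples share a distribution. KS factors are only included for cells
with at least 3 RTs on both sides (the statistic is degenerate below
that), and the product runs over all decisions, not only correct ones.
Gaussian shrinkage priors ($\mu = 1$ for the conductance scalings, 0
otherwise, $\sigma_p = 0.07$) complete the posterior. Only $|\sigma|$
enters the dynamics, so negative noise proposals are canonicalised by
absolute value and the posterior over the noise amplitudes is
sign-symmetric; fits fold the sign before density estimation.

`metropolis_hastings()` uses an isotropic Gaussian proposal
($\sigma_{MH} = 0.01$) on all 13 parameters and re-simulates the
likelihood with fresh noise at every evaluation (a pseudo-marginal
scheme). Two practical facts shape the desk-scale defaults:

* Around the all-zero prior mean no simulated projection ever reaches
  threshold, the simulated counts are all-none, and the likelihood is
  flat — a plateau a $\sigma_{MH} = 0.01$ random walk escapes only
  slowly. `fit_behavior()` therefore initialises chains from a pilot
  search (best of ~100 posterior evaluations at candidates drawn from
  a 3-fold-widened prior), which is part of the fitting procedure and
  uses the same posterior.
* With short chains the pseudo-marginal noise (several log-units at
  $n_\mathrm{sim} = 128$) collapses the acceptance rate (the chain
  sticks on lucky likelihood draws). The
  `common_random_numbers = TRUE` mode holds one simulation seed fixed,
  turning the target into a deterministic approximation and restoring
  mixing; it conditions the fit on one noise realisation and is the
  recommended desk-scale setting. Published-scale settings (2 chains of
  $10^6$ steps, 50,000 burn-in, $n_\mathrm{sim} = 1024$, fresh noise)
  are available via `paper_scale()`.

MAP estimates are per-parameter argmaxima of Gaussian-kernel densities
(Silverman bandwidth, 512 grid points over the sampled range extended
by 10 %) of the pooled post-burn-in marginals, with spread summarised
by the full width at half maximum. This follows the marginal (not
joint-mode) convention; a locally adaptive kernel would sharpen skewed
marginals but the downstream checks are insensitive to the kernel
choice at their stated tolerances.

`goodness_of_fit()` reports, per condition, an exact multinomial test —
$P = \sum_{x : P(x) \le P(x_0)} P(x)$ by full enumeration of the
compositions of $N$ into four categories in log space, with ties
included at relative tolerance $10^{-12}$ — plus a KS probability per
eligible cell; at the standard design this is at least six tests per
subject. The KS survival function uses the theta-series form of the
Kolmogorov distribution for small statistics and the equivalent
alternating series for large ones, truncated at $10^{-12}$.

## Potential landscape

The input-free rule module defines a Fokker–Planck equation for the
density over $(S_1, S_2)$ with drift $F$ and diffusion
$D = (\sigma_\mathrm{rule}/2)^2$ on the seconds scale.
`fp_steady_state()` propagates an initially uniform density with an
implicit (backward-in-time, centred-in-space) step until
$\max|\Delta P|/\Delta t < 10^{-9}$, and the generalized potential is
the Boltzmann-type $U = -\ln P_{ss}$ (floored at $10^{-300}$,
min-shifted to zero). Numerical choices:

* **Conservative finite volumes with no-flux walls.** The gating
  variables are confined to $[0,1]$ (the simulator clamps), so the
  physically matching boundary condition is zero flux. An absorbing
  wall ($P = 0$) was tried and rejected: the rule attractors sit about
  two local widths from the $S = 0$ walls, and absorption selectively
  drains exactly those basins, inverting the basin weights relative to
  direct simulation. The interior stencil is the standard second-order
  BTCS discretisation either way, and the scheme conserves mass to
  machine precision by construction.
* **Step-size growth.** The implicit step is unconditionally stable,
  so after every 50 unconverged iterations the step grows tenfold
  (from 10 ms, capped at $10^7$ ms); this is inverse-power iteration
  toward the stationary eigenvector and does not change the fixed
  point of the iteration.
* **Default grid.** $128 \times 128$ cells; the package's own checks
  run at $64 \times 64$, where basin depths differ from the refined
  grid by well under 5 %.

`simulate_landscape_histogram()` is the independent cross-check: an
Euler–Maruyama ensemble of walkers integrating the same white-noise
SDE from uniform random starts (the sampling picture behind the steady
state), accumulated into an occupancy histogram after per-walker
burn-in. An ensemble is essential: at $\sigma_\mathrm{rule} = 0.1$ the
rule basins are ~20 natural log-units deep, so a single trajectory
cannot mix between them in any feasible run, while a symmetric ensemble
reproduces the 50/50 basin weights. Note that the OU-driven trial
simulator and this white-noise landscape SDE are two different
stochastic models of the same drift: an OU process of stationary
variance $\sigma^2/2$ and correlation time $\tau$ has white-noise
intensity $\sigma^2 \tau / 2$, which no time unit reconciles exactly
with $D = (\sigma/2)^2$; the landscape definition takes the latter, and
an OU simulation at $\sigma' = \sigma\sqrt{\tau_s/(2 D)}\,$... — in
practice, at amplitude $\sigma' \approx 11 \sigma$ — has the matching
low-frequency intensity.

## Minimal transition action

Transition probabilities between attractors are dominated by the path
minimising the Hamilton–Jacobi action

$$S(x) = \int \Big(\sqrt{\tfrac{E_\mathrm{eff} + V(S)}{D}} - \tfrac{F_l}{2D}\Big)\, dl,
\qquad V = \frac{|F|^2}{4D} + \frac{\nabla\!\cdot\!F}{2},$$

with $F_l$ the drift component along the path. (The printed source
form of the integrand is typographically corrupted; this reading
follows the underlying path-integral framework, with
$E_\mathrm{eff} + V \ge 0$ guaranteed by the choice of
$E_\mathrm{eff}$.) `minimize_path_action()` fixes the endpoints at the
two rule minima of the landscape's $U$, sets
$E_\mathrm{eff} = -\min V$ over the whole grid (the longest kinetic
time, $t = \int dl / (2\sqrt{D(E_\mathrm{eff}+V)})$), and minimises the
discretised integral (midpoint rule, 50 line elements) over the
interior nodes with BFGS (finite-difference gradients, up to 5000
iterations), adding a penalty of $10^5$ on the variance of the segment
lengths to keep the discretisation uniform; the penalty is excluded
from the reported action, and doubling it moves the action by well
under 1 %. Each direction starts from both the straight line and a
polyline through the spontaneous minimum, keeping the better solution;
the optimal paths run through the spontaneous basin and are mirror
images across the diagonal at symmetric parameters. Divergence terms
use central differences with step $10^{-5}$; residual negative
$E_\mathrm{eff} + V$ from discretisation is clipped at zero with a
warning and a count.

## BOLD regressor prediction

`trial_energy_table()` simulates trials per condition, integrates the
summed selective rates $\int (r_1 + r_2)\,dt$ over each full trial, and
averages per (condition, decision) cell, normalised to the
correct-baseline cell; empty cells inherit their condition mean. A
session's energy timecourse holds each trial's cell value over the
trial (trials are contiguous, so this is a step function; the spec's
impulse and a stimulus-window boxcar are available as options), is
z-scored — a constant course, as in an all-correct-baseline session,
maps to zeros by convention — convolved with the unit-sum canonical
double-gamma HRF (peak delay 6 s, undershoot delay 16 s, dispersions 1,
peak:undershoot 6:1, 32-s kernel) on a 0.1-s grid, and sampled at the
2-s repetition time. No GLM, motion modelling or image handling is in
scope; ambiguous trials contribute nothing (they are modelled as
separate nuisance regressors downstream, outside this package).

## Problem sizes used by the package's own checks

The test-suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is stable:
landscapes at $64^2$ (refinement checks against $128^2$), walker
ensembles of 256 × 80,000 steps, action paths with 50 elements (30 in
module-level sweeps), behavioural batches of 256–5000 trials per
condition, goodness-of-fit batteries at $n_\mathrm{sim} = 512$ over 20
synthetic subjects, and recovery fits of 2 × 1200 MCMC steps at
$n_\mathrm{sim} = 128$ with common random numbers, on a
near-prior truth with strong identifiable drifts. The published
protocol (two chains of $10^6$ steps, $n_\mathrm{sim} = 1024$) is
available through `paper_scale()` and `run_pipeline(scale = "paper")`.

## Known limitations

* The two reduction constants (`mg_gate`, `eta_gain`) are calibrated,
  not derived; other pairs reproducing all anchors would shift coupling
  values within a narrow band.
* The spontaneous rate of the calibrated module is 2.44 Hz against the
  nominal "approximately 3 Hz".
* The likelihood is simulation-based; short chains require common
  random numbers, which conditions the posterior on one noise
  realisation.
* Landscape and action analyses describe the input-free module; inputs
  deform the landscape during stimuli, which the stability metric
  deliberately ignores.
* The BOLD stage predicts a regressor timecourse only; validating it
  against measured fMRI data requires a GLM pipeline outside this
  package.
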