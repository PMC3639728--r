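---
title: "A mean-field route to EEG burst suppression: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mean-field route to EEG burst suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoburst)
```

## The scientific problem

Burst suppression is an EEG pattern of alternating high-amplitude
oscillatory bursts and near-isoelectric (suppressed) stretches, seen in
deep anesthesia, anoxia, hypothermia and coma.  Single neurons burst when
a fast spiking subsystem is modulated by a much slower variable; this
package applies the same *fast--slow* logic at the population scale.  The
fast subsystem is a mesoscopic mean-field model of the EEG -- coupled
excitatory (`e`) and inhibitory (`i`) neuronal populations whose mean soma
membrane potentials `h_e`, `h_i` evolve under conductance-weighted
synaptic input, with `h_e` taken as the EEG proxy.  The slow subsystem is
an activity-dependent depression of synaptic peak amplitudes, motivated by
short-term synaptic resource depletion (recovery timescales of order
1 s, an order of magnitude slower than resting EEG dynamics).

## The fast system

For each population `k`, the membrane equation is

    tau_k dh_k/dt = h_rest_k - h_k + sum_l  psi_lk(h_k) I_lk,

where `I_lk` is the synaptic response of connection class `lk`
(source `l`, target `k`) and the ionic weight

    psi_lk(h) = (h_eq_lk - h) / |h_eq_lk - h_rest_k|

is `+1` (excitatory) or `-1` (inhibitory) at rest, vanishing at the
reversal potential.  The absolute value in the denominator is essential:
the inhibitory reversal potentials lie below rest, so a signed denominator
would flip the sign of every inhibitory current and the model would have
no physiological equilibrium (we verified this numerically -- with a
signed denominator the reduced equilibrium system of the reference
parameter set has no root anywhere in the physiological range).

Each unitary PSP is, in the basic model, an alpha function
`Gamma * gamma0 * t * exp(1 - gamma0 * t)` -- the impulse response of a
critically damped second-order filter with peak amplitude `Gamma` at
`t = 1/gamma0`.  Anesthetic agents prolong the *decay* of the inhibitory
PSP without changing its rise, which a critically damped kernel cannot
express.  The extended kinetics factor the operator into two first-order
stages with rates

    gamma       = eps * gamma0 / (e^eps - 1),
    gamma_tilde = gamma * e^eps,

and drive normalization `gamma_tilde * exp(gamma/gamma0) * Gamma * A`.
For every decay-shape factor `eps >= 0` the impulse response peaks at
`t = 1/gamma0` with amplitude `Gamma`; increasing `eps` lengthens the
tail.  As `eps -> 0` both rates converge to `gamma0` and the alpha
function is recovered; the implementation uses the analytic limit at
`eps = 0` and an `expm1` formulation so the near-critically-damped regime
does not suffer cancellation.  `eps_ii` is the model's principal
anesthetic axis (GABA-ergic agents prolong the inhibitory decay roughly in
proportion to concentration).

Firing rates are instantaneous sigmoids of the membrane potential,

    S_k(h) = S_max_k / (1 + exp(-sqrt(2) (h - mu_bar_k) / sigma_k)).

The increasing form with slope constant `sqrt(2)` follows the original
model formulation; the slope constant is exposed as a parameter
(`sigmoid_slope`).  With the alternative slope constant 2 the reference
set equilibrates at implausibly low firing rates (~3e-3 per s), so the
`sqrt(2)` convention is also the empirically coherent one here.

Long-range excitatory cortico-cortical input obeys a telegraph
(damped-wave) equation; this package studies the spatially homogeneous
case, where it reduces to the second-order ODE
`(d/dt + v Lambda)^2 phi_ek = (v Lambda)^2 N_alpha_ek S_e(h_e)`.  The
full dynamic operator is kept (no adiabatic elimination of `phi`), since
elimination would distort transient spectra.  State dimension is fixed at
14: two potentials, four `(I, J)` synaptic pairs, two `(phi, psi)` flux
pairs.

Internal units are mV, ms and cm throughout.  The reference parameter set
(`preset_model("table3")`, also shipped as
`inst/extdata/table3.yaml`) is a normative resting-EEG configuration: a
single stable fixed point, population firing rates well below 20 per s,
and a linearized fluctuation spectrum with low-frequency decay plus an
alpha-band resonance.

```{r fixed-point}
P <- preset_model("table3")
fp <- find_fixed_point(P)
fp
1000 * c(e = firing_rate(fp$h[["e"]], "e", P),
         i = firing_rate(fp$h[["i"]], "i", P))  # rates per second
```

## The slow systems

Both slow laws evolve selected synaptic peak amplitudes `Gamma_lk` on a
timescale `1/mu_l = 1000 ms`:

* **SS1** `dGamma/dt = mu_l (theta_l - k_l S_l(h_l))` -- linear
  recovery/depletion with separately specifiable recovery rate
  `mu * theta` and depletion gain `mu * k`.  Amplitudes are unbounded in
  principle (an optional floor at 0 mV exists and is off by default,
  staying faithful to the law as stated).
* **SS2** `dGamma/dt = mu_l (Gamma0 / (1 + exp(kappa_l (h_l - xi_l))) - Gamma)`
  -- bounded sigmoidal depression, keeping each amplitude in
  `(0, Gamma0]` and decreasing with source depolarization past the
  threshold `xi_l`.

**Units of the SS1 depletion gain.** The canonical bursting configuration
is quoted with `k_i = 10` in mV·s.  Read literally against rates in s⁻¹
that implies a slow-equilibrium source rate `theta_i / k_i =
0.1818/10 ≈ 0.018` per s -- far *below* the fixed-point rate, which would
drive `Gamma_ii` to minus infinity and preclude bursting entirely.  We
therefore store `k` internally in mV·ms (i.e. mV per unit per-ms rate),
making the slow equilibrium rate `0.1818 mV / 10 mV·ms = 18.18` per s,
just under the 20 per s normative ceiling and consistent with the
recovery/depletion cycle that bursting requires: during suppression the
inhibitory rate is below 18.18 per s and `Gamma_ii` recovers; during a
burst it exceeds it and the amplitude depletes.

**SS2 threshold anchoring.** `xi_l` is not given a value anywhere we can
anchor to, so the default centers the depression sigmoid on the operating
point: `xi_l` is set to the fixed-point membrane potential of the
unmodulated fast system at configuration time (`resolve_slow()`).  When a
model parameter is swept, resolve the slow configuration *once* against
the baseline model first, so the thresholds do not drift with the swept
fixed point.  For the bounded-depression preset (`preset_slow("fig7")`
paired with `preset_model("fig7")`, i.e. `eps_ii = 1.8`,
`eps_ie = 1.5`), the unmodulated fast system has exactly one fixed point
-- an unstable ~16.5 Hz focus near (-47.5, -47.7) mV -- and the threshold
anchors there.

## Numerical integration

The reference scheme is classical fixed-step RK4 at `dt = 0.1` ms,
implemented in compiled code (the R-level `fast_rhs()` / `coupled_rhs()`
are the readable reference implementation; the test suite asserts exact
agreement between the two on random states).  A stiff adaptive fallback
(`solver = "stiff_adaptive"`, lsoda) integrates the same compiled
right-hand side; on the canonical bursting configuration the two agree to
~5e-6 mV RMS in `h_e` over 10 s, against a tolerance requirement of
1e-3 mV.  Solutions that leave a sanity envelope (|h| > 500 mV or
non-finite) raise an error naming the first offending time.  Optional
stochastic drive (for spectrum validation only -- the bursting runs are
noise-free) adds a seeded white Euler--Maruyama perturbation to one
extra-cortical rate, held constant within each step; runs are bitwise
reproducible given the seed.

Output is decimated to `record_dt` (default 1 ms) as instantaneous
samples.  Default initial conditions are the fast system's fixed point
with slow amplitudes at their resting values; when no fixed point can be
located the resting-potential state is used with a warning.

## Dynamical analysis

*Fixed points* are found by damped Newton iteration on the equilibrium
system reduced to `(h_e, h_i)` -- every other component is slaved at
equilibrium -- from a grid of starting points.  All distinct roots are
collected; when several equilibria coexist the most hyperpolarized stable
one (the physiological resting state) is preferred.  Stability comes from
the eigenvalues of the central finite-difference Jacobian of the full
14-dimensional right-hand side (eigenvalues are step-size invariant to
1e-4 between steps of 1e-5 and 1e-6).

*Linearized fluctuation spectra* are `|H(2 pi i f)|^2`, with `H` the
transfer function from a chosen extra-cortical drive to `h_e`, evaluated
by solving `(2 pi i f I - J) x = b` on the frequency grid, and reported
per unit drive spectral density.  **Peak-frequency definition:** any
spectrum satisfying the "1/f decay at low frequencies" criterion has its
global argmax at the lowest grid frequency, so a literal argmax can never
certify an alpha peak.  The reported peak is therefore the highest
*interior local maximum* -- the resonance riding on the low-frequency
background -- falling back to the global argmax only for spectra with no
interior local maximum.  For the reference set this gives 11.5 Hz, and a
60 s noise-driven simulation's Welch estimate matches the linearized
prediction at the peak to within a few percent.

*Continuation* is natural-parameter continuation of the fixed-point locus
with secant warm starts and adaptive sub-stepping; when the branch is
lost (e.g. at a fold) the furthest reachable point is recorded so that a
stability change remains bracketed, and each bracketed change is refined
by bisection on the leading eigenvalue's real part (tolerance 1e-4 of the
range; crossings with nonzero imaginary part are reported as Hopf
points, with a warning if the implied period leaves 1--1000 ms).
Limit-cycle continuation, fold-of-cycles and torus detection are out of
scope; the bistability they imply is demonstrated directly by
`hysteresis_probe()`, which sweeps a parameter in both directions with
warm-started simulations and classifies each end state by peak-to-peak
amplitude (default threshold 1 mV, 3 s settle, last 1 s analyzed).
Supercritical versus subcritical character is judged empirically from
the continuous growth of the emerging oscillation, not from normal-form
coefficients.

```{r continuation}
br <- continue_fixed_points(P, "Gamma_ii", c(1.3, 1.55), steps = 11)
br
```

The reference set sits just below a supercritical Hopf in the
inhibitory-inhibitory amplitude: the fixed point loses stability near
`Gamma_ii ≈ 1.454` through a ~15 Hz pair, and a bistable window (stable
fixed point coexisting with a ~30 mV oscillation) extends down to
`Gamma_ii ≈ 1.26`.  SS1 bursting is exactly this hysteresis loop traversed
by the slow variable: suppression while `Gamma_ii` recovers upward,
burst onset at the Hopf (~15 Hz), intra-burst chirp down to ~12 Hz, and
burst termination when depletion drags the system off the oscillatory
branch.

## Burst metrics

Segmentation (`segment_bursts()`) removes a slowly varying local baseline
(moving average, default 100 ms) so that the tonic depolarization shift
between burst and suppression states does not register as signal, then
thresholds the moving-RMS envelope (default window 50 ms) of the
residual.  The default threshold is 10% of the 95th percentile of the
absolute baseline-removed signal, with an absolute floor of 0.1 mV so
numerically flat records are never segmented on rounding ripple;
sub-threshold gaps shorter than 200 ms are closed and bursts shorter than
200 ms dropped.  All settings are recorded in the returned object.  The
suppression ratio is the suppressed fraction of the analyzed span (so
suppression ratio + burst fraction = 1 exactly); duration statistics
exclude intervals truncated by the record boundaries.

Dominant frequencies come from a Hann-windowed spectrogram (default
500 ms windows, 75% overlap, 4x zero-padding), with each segment
constant-detrended so baseline offsets do not leak into the lowest bins;
the per-frame ridge is the argmax restricted to 1--40 Hz (above that the
harmonics of the burst oscillation would capture the argmax).  Onset and
offset frequencies average the ridge over frames lying wholly within the
first and last quarter of each burst -- frames straddling a burst edge
would see the burst/suppression baseline step as spurious low-frequency
power -- with a periodogram fallback for bursts too short to contain a
full frame.

## What the canonical runs show

With the reference fast system and SS1 depression of `Gamma_ii`
(`mu_i = 0.001` per ms, `theta_i = 0.1818` mV, `k_i = 10` mV·ms),
60 s of simulation yields ~12 bursts of ~3.0 s separated by ~2.1 s of
near-isoelectric suppression, with the intra-burst dominant frequency
descending from ~14.6 Hz at onset to ~12.8 Hz at offset.  Weakening the
recovery level `theta_i` shortens bursts and lengthens suppressions
monotonically until the EEG is fully isoelectric.  With bounded (SS2)
depression of all four amplitudes, bursting switches on as the inhibitory
PSP decay is prolonged -- isoelectric through `eps_ii = 1.8`, recurrent
bursting from 1.9 on a 0.1 grid -- and lowering the excitatory
extra-cortical rate `p_ee` lengthens the suppressions until bursting is
extinguished.

## Problem sizes and study conditions

The packaged analyses use 60 s of analyzed signal after a 10 s transient,
RK4 at `dt = 0.1` ms with 1 ms output sampling; sweeps use one such run
per grid point.  The hysteresis probe uses 3 s per parameter value per
direction.  Spectrum validation uses a 60 s noise-driven run with 2 s
Welch windows at 50% overlap.

## Known limitations

* The spatially extended (nonzero Laplacian) model is not implemented;
  all results concern the homogeneous reduction.
* Limit-cycle branches are not continued; burst termination via a fold of
  cycles is inferred from simulation and hysteresis, not computed.
* Under the default threshold anchoring, the bounded-depression runs show
  excitatory efficacy *falling* during bursts and recovering between
  them.  The reported phase relationship in which excitatory efficacy
  rises during the burst evidently depends on the unstated depression
  thresholds and initial amplitudes; with our anchoring (thresholds at
  the unmodulated fixed point, which for the prolonged-IPSP fast system
  is a depolarized unstable focus) the time-averaged depression during
  the oscillation exceeds that of the quiescent state.  The thresholds
  are exposed (`xi`) for users who wish to explore other anchorings.
* SS1 amplitudes are unbounded by design; pathological parameterizations
  can drive them negative (an optional floor exists).
* The deterministic model produces strictly periodic bursting; the
  quasi-periodic burst timing of clinical records requires stochastic
  forcing, which the simulator supports but the packaged analyses do not
  use.

## Reproducing the packaged numbers

`scripts/acceptance.R` recomputes, from a fresh install: the fixed-point
firing-rate ceiling and spectral peak of the reference set, the
onset/offset chirp frequencies of the SS1 bursting configuration, and the
`eps_ii` bursting threshold of the SS2 configuration.  See the README for
invocation.
```{r session, echo = FALSE}
sessionInfo()$R.version$version.string
```
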