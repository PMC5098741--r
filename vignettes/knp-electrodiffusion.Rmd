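---
title: "Electrodiffusion in extracellular space: the KNP scheme in knpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrodiffusion in extracellular space: the KNP scheme in knpsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knpsim)
```

## The model and its assumptions

`knpsim` simulates ion concentrations and the electrical potential in the
extracellular space (ECS) of a 1D tissue column, driven by per-depth time
series of transmembrane ionic fluxes and capacitive currents. The scheme
rests on four assumptions:

1. **Lateral homogeneity.** All state varies only with depth; the column is
   a stack of N well-mixed subvolumes of height $l_c$ and tissue
   cross-section $A_c$.
2. **Porous medium.** Only the volume fraction $\alpha$ of tissue is ECS,
   and tortuosity $\lambda$ hinders transport: every flux and the
   conductivity use effective diffusion constants
   $\tilde D^k = D^k/\lambda^2$ and the ECS cross-section $\alpha A_c$.
3. **Bulk electroneutrality.** On scales above micrometers/microseconds the
   ECS carries no net free charge; any charge that ionic currents deposit
   in a subvolume sits on neural membranes and equals the (known)
   capacitive current. This converts charge continuity into Kirchhoff's
   current law per subvolume and turns the potential into the solution of
   an N-by-N tridiagonal linear system at each instant — no charge
   relaxation (Poisson) dynamics is integrated.
4. **One-way coupling.** The neuron-side sources are prescribed inputs; the
   ECS state does not feed back on them.

Per time step the solver (i) evaluates interface conductivities
$\sigma_{n,n+1} = (F/\psi)\sum_k \tilde D^k (z^k)^2 \bar c^k$ and diffusive
currents $I^d = F\sum_k z^k J^{kd}$ from the current concentrations,
(ii) assembles and solves the Kirchhoff system for $V$ (reference row
$V_1 = 0$; top row imposes $I^d + I^f = 0$ toward the deep reservoir),
(iii) evaluates Nernst-Planck diffusive and drift fluxes, and (iv) advances
interior concentrations by forward Euler. The edge subvolumes are
constant-concentration reservoirs. This operation order is fixed: the
potential always corresponds to the concentrations used to build the
system, which is what makes the per-step Kirchhoff residual a sharp
correctness check (it is tracked for every run and is ~1e-16 relative in
practice).

A note on the top-boundary row: writing the zero-net-current condition
$I^d_{N-1,N} + I^f_{N-1,N} = 0$ in terms of $V$ gives
$\sigma_{N-1,N}(V_{N-1} - V_N) = -(l_c/\alpha A_c)\, I^d_{N-1,N}$ — the
sign matters, and the implementation is fixed by requiring that the
recorded interface currents satisfy the boundary condition exactly, which
the test suite asserts at every recorded instant.

## Parameters, units, defaults

Strict SI is used internally (m, s, V, A, mol/m³, S/m); concentrations in
mol/m³ are numerically mM, so user-facing tables may be read in mM.

| Parameter | Default | Why |
|---|---|---|
| N | 15 | 1.5 mm column at 100 μm resolution; two reservoir edges |
| $l_c$ | 100 μm | subvolume height |
| $A_c$ | 3000 μm² | tissue cross-section for a ~10-neuron population |
| $\alpha$ | 0.2 | typical cortical ECS volume fraction |
| $\lambda$ | 1.6 | typical cortical tortuosity |
| T | 300 K | gives $\sigma = 0.766$ S/m at baseline and a $-0.175$ mV GHK junction for the standard shift set, both within a unit of the last printed digit of the reference values this configuration reproduces |
| ions | K⁺, Na⁺, Ca²⁺, X⁻ | $D^k$ = 1.96, 1.33, 0.71, 2.03 ×10⁻⁹ m²/s; baselines 3, 150, 1.4, 155.8 mM |

Two conventions deserve explicit statement because the literature is
ambiguous about both:

- **Cross-sections.** $A_c$ is stored as the *tissue* cross-section
  (3000 μm²); the ECS cross-section is $\alpha A_c = 600$ μm². Every
  transport formula uses the product, so either reading of "cross-section"
  is consistent as long as $\alpha$ appears exactly once.
- **Diffusion constants.** The $D^k$ above are free-solution values, and
  $1/\lambda^2$ is applied in every flux/conductivity formula. Treating
  them as already tortuosity-corrected would inflate the baseline
  conductivity by $\lambda^2 = 2.56$, contradicting the 0.76 S/m that this
  configuration is built to reproduce.

The anion X⁻ carries all otherwise unattributed charge; its baseline is
computed by `electroneutral_anion_concentration()` so the resting state is
exactly charge-neutral (it comes out at the Cl⁻-like 155.8 mM).

## Time stepping and numerical choices

- **Explicit forward Euler, default dt = 0.1 ms.** The diffusion stability
  limit $\tilde D\,\mathrm{d}t/l_c^2 < 0.5$ has a margin of ~10⁵ at
  $l_c$ = 100 μm, so accuracy, not stability, sets the step; the scheme is
  first-order and the suite verifies O(dt) convergence by step halving.
- **Direct tridiagonal elimination** for the potential each step (N = 15
  makes cost negligible); a numerically singular pivot (e.g. all
  conductivities zero) is a hard error.
- **Zero-order hold** between source samples when the solver step is finer
  than the source sampling.
- **Negative concentrations are a hard error** naming the ion, subvolume
  and time — clipping would silently distort diffusion potentials, which
  are exactly the quantity of interest.
- **No-diffusion mode** zeroes $J^{kd}$ in the continuity equation and
  $I^d$ in the potential system, and nothing else; $\sigma$ keeps its
  concentration dependence in both modes. A separate `freeze_conductivity`
  option pegs $\sigma$ at its initial value, which makes the per-interface
  *total* current of diffusion-on and diffusion-off runs with identical
  sources agree to solver precision — a useful invariant, because the total
  current is fixed by current conservation alone.

## The synthetic source generator

The generator stands in for a compartmental-simulator export when none is
available. It emulates the statistical structure of a small cortical
population's output — not any particular cell model:

- Each of 10 neurons fires as an independent Poisson process at 5 AP/s.
- Each AP deposits a biphasic pulse pair into the soma subvolume (n = 3):
  an alpha-shaped Na⁺ influx (population peak −30 nA, τ = 0.5 ms) followed
  1 ms later by a K⁺ efflux (+30 nA, τ = 1 ms). Amplitudes scale as
  population value / n_neurons.
- Slow Ca²⁺ (−0.5 nA) and X⁻ (1 nA) population currents are spread
  uniformly over the dendritic span (subvolumes 3–14). These magnitudes
  are chosen as plausible orders relative to the AP currents; the spatial
  profile is a free parameter, not a fidelity claim.
- At every sample a capacitive return current distributed over the
  dendritic span closes each neuron's current loop *exactly*, so the
  depth-summed total transmembrane current is zero to rounding error —
  the conservation property the Kirchhoff solve requires of its input. A
  real neuron achieves this through cable dynamics; the generator imposes
  it by construction.

What passing tests on generated sources do **not** show: realistic
dendritic return-current profiles, synaptic synchrony, channel kinetics,
or ion-pump/glial clearance (absent here as in the modelled system). They
do show that the solver conserves charge and reproduces junction physics
under realistically-sized, realistically-timed drive.

## Diagnostics

- **PSD:** one-sided FFT periodogram of the mean-subtracted signal
  (optional Hann window, off by default since the reference procedure is
  plain FFT), then averaged into 0.1-decade geometric frequency bins. The
  raw periodogram satisfies Parseval to <1%, which the suite checks.
- **Power-law fit:** least squares on log10-power vs log10-frequency; the
  default band for 21 s decay segments is 0.05–2 Hz — low enough to sit
  above the slowest decay mode's corner frequency, high enough for 13
  bins; the band is always a parameter.
- **Junction potentials:** `ghk_potential()` implements the standard
  (monovalent) GHK voltage equation with $\tilde D^k$ as permeabilities;
  Ca²⁺ is excluded, which at 1.4 mM baseline and −0.1 mM shifts changes
  the result negligibly compared to keeping a divalent term the equation
  cannot represent. `henderson_potential()` handles arbitrary valences via
  the linear-mixing profile,
  $V = -\psi W \ln(S_B/S_A)/(S_B - S_A)$ with $W = \sum z D \Delta c$,
  $S = \sum z^2 D c$. The two agree to first order *over monovalent
  compositions*; a divalent contribution enters Henderson's $W$ but is
  invisible to GHK, so comparisons between them in the tests use
  monovalent shift sets.
- **CSD:** centered second differences of $\sigma \Delta V$ per $l_c^2$,
  per unit ECS volume, edges undefined. The corrected variant subtracts
  the divergence of the diffusive current density first. On simulation
  snapshots the corrected estimator recovers the imposed sources exactly
  (a discrete identity, verified as a round trip), and reports ~0 on
  source-free decay states where the standard estimator misreads
  diffusive currents as neuronal sources.

## Scenario scale

The standard decay experiment integrates 21 s at dt = 0.1 ms (210,000
steps), recording V every 1 ms — ample for a 0.05–2 Hz fit band with a
500 Hz Nyquist margin — and runs in well under a minute. The exponent of
the fitted $1/f^\beta$ law comes out at $\beta \approx 1.98$ with
$R^2 > 0.999$: the Brownian-noise signature of exponentially relaxing
concentration profiles. The initial profile (all shifts confined to the
soma subvolume) is a sharper-than-realistic stand-in for a profile built
up by minutes of activity, so the exponent is expected near, not exactly
at, 2.

## Known limitations

- One spatial dimension; no lateral structure, single population.
- Explicit Euler only; stiff source series with sub-0.1 ms structure need
  a smaller dt, paid linearly in runtime.
- No ion pumps, glial buffering, or ECS-to-neuron feedback; long driven
  runs accumulate ion shifts that real tissue would clear.
- The potential is a subvolume average; comparison with point-electrode
  recordings is only qualitative.
- GHK calculator is monovalent by design; use Henderson for divalent
  compositions.
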