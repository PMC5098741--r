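# knpsim

A 1D electrodiffusion simulator for the extracellular space (ECS) of neural
tissue, built on the Kirchhoff–Nernst–Planck (KNP) scheme.

## The problem

Most forward models of extracellular potentials (local field potentials,
current-source density analysis) treat the ECS as a volume conductor: the
potential is set entirely by neuronal current sources through a fixed
conductivity, and ionic diffusion is ignored. But neural activity moves ions
— K⁺ accumulates where neurons fire, Na⁺ is depleted — and because ion
species have different mobilities, the resulting concentration gradients
drive *diffusive currents* that carry net charge and generate their own
(liquid-junction-like) potentials. `knpsim` is for computational
neuroscientists who want to quantify that effect: it evolves ECS ion
concentrations and the ECS potential jointly, with diffusion switchable on
and off, for any supplied set of transmembrane current sources.

## The model

A tissue column is discretized into N subvolumes of height l_c and tissue
cross-section A_c, of which a fraction α is ECS, with tortuosity λ reducing
the effective diffusion constants to D̃ᵏ = Dᵏ/λ². For each ion k with
valence zᵏ, the continuity equation per interior subvolume n is

    αA_c l_c ∂cₙᵏ/∂t = Jₙᵏᴹ + Jᵏᵈ(n-1,n) − Jᵏᵈ(n,n+1) + Jᵏᶠ(n-1,n) − Jᵏᶠ(n,n+1)

with Nernst–Planck interface fluxes (ψ = RT/F)

    Jᵏᵈ = −(αA_c/l_c) D̃ᵏ Δc          (diffusion)
    Jᵏᶠ = −(αA_c/(ψ l_c)) zᵏ D̃ᵏ c̄ ΔV  (drift)

The potential is not propagated dynamically: bulk electroneutrality implies
that the net current into every subvolume — ionic transmembrane Iᴹ,
capacitive I^cap, diffusive Iᵈ = FΣzᵏJᵏᵈ and field Iᶠ = −(αA_c/l_c)σΔV —
sums to zero (Kirchhoff's current law), which yields a tridiagonal linear
system for V at every time step, with V₁ = 0 as reference and zero net
electrical current through the top boundary. The conductivity

    σ = (F/ψ) Σₖ D̃ᵏ (zᵏ)² (c̄ₙᵏ + c̄ₙ₊₁ᵏ)/2

is concentration-dependent. The edge subvolumes are constant-concentration
reservoirs. Disabling diffusion (Jᵏᵈ ≡ 0, Iᵈ ≡ 0) recovers classical
volume-conductor behaviour.

Also included: a seeded synthetic population-source generator (Poissonian
AP firing, soma-dominated biphasic Na⁺/K⁺ pulses, exact depth-balanced
return currents), Goldman–Hodgkin–Katz and Henderson junction-potential
calculators, log-binned power spectra with power-law fitting, and CSD
estimation with and without the diffusion correction
(∇(σ∇V) − ∇iᵈ = −CSD).

## Worked example

The default configuration is a 15-subvolume, 1.5 mm cortical column
(l_c = 100 μm, tissue cross-section 3000 μm², α = 0.2, λ = 1.6, T = 300 K)
with K⁺, Na⁺, Ca²⁺ and an unspecified anion X⁻ at charge-neutral baseline
concentrations (3, 150, 1.4, 155.8 mM).

```r
library(knpsim)
cfg <- default_configuration()

# baseline ECS conductivity and its tissue-referenced (apparent) value
c0 <- cfg$ions$baseline_concentration
sigma <- interface_conductivity(c0, c0, cfg$ions, cfg$constants, cfg$geometry)
round(c(sigma = sigma, apparent = apparent_conductivity(sigma, cfg$geometry)), 3)
#>    sigma apparent
#>    0.766    0.153

# an electroneutral concentration perturbation in the soma subvolume ...
shifts <- c(Na = -5.1, K = 6.0, Ca = -0.1, X = 0.7)  # mM
st <- perturbed_state(cfg, 3, shifts)

# ... generates a diffusion potential even with zero neuronal sources:
V <- solve_potential(assemble_potential_system(st, cfg$ions, cfg$geometry,
                                               cfg$constants))
round(V[3] * 1e3, 4)   # mV, soma subvolume
#> -0.1669

# the closed-form GHK junction potential for the same composition change
base <- setNames(c0, cfg$ions$name)
round(ghk_potential(base, base + shifts[cfg$ions$name],
                    cfg$ions, cfg$constants) * 1e3, 4)
#> -0.1751

# let the perturbation decay by electrodiffusion for 21 s and fit the PSD
opts <- solver_options(dt = 1e-4, duration = 21, record_stride = 10)
traj <- run_simulation(cfg, sources = NULL, options = opts, initial_state = st)
fit <- fit_power_law(power_spectrum(traj$potential[3, ], 1e-3), c(0.05, 2))
fit
#> power-law fit: 1/f^1.976 over [0.05, 2] Hz (R^2 = 0.9999, 13 bins)
```

The decaying diffusion potential is Brownian-like: its spectrum follows
1/f² because local concentrations (and hence V) relax approximately
exponentially. With `include_diffusion = FALSE` the same initial state
gives V ≡ 0 at every step — a volume conductor carries no potential without
sources.

Driven simulations use a source series, either synthetic,

```r
src <- generate_population_sources(population_params(seed = 1),
                                   duration = 5, ions = cfg$ions,
                                   geometry = cfg$geometry)
traj <- run_simulation(cfg, src, solver_options(dt = 1e-4, duration = 5))
```

or imported from a compartmental-simulator export via
`read_source_series()` / `map_segment_currents()`. A command-line
front-end (`inst/cli/knpsim.R`) wraps the `simulate`, `decay` and
`analyze` workflows.

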