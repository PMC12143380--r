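# excimash

Surface-hopping exciton dynamics with variational polaron renormalization.

## What this is for

Excitation energy transfer in photosynthetic pigment-protein complexes
(LH2, FMO, LHCII and their relatives) is usually modelled with a
Frenkel-exciton Hamiltonian,

    H_s = sum_n eps_n |n><n| + sum_{n!=m} J_nm |n><m|,

coupled linearly to harmonic vibrational baths with Huang-Rhys factors
g_k^2.  Treating the vibrations classically is cheap but subtle: a naive
classical treatment without back-action drives the exciton system to
infinite temperature, and even a consistent one treats high-frequency
intramolecular modes (hbar omega >> k_B T) as thermally fluctuating when
they are really frozen in their quantum ground states.

`excimash` implements the full computational chain needed to quantify
this nuclear quantum effect:

- **multi-state MASH** (mapping approach to surface hopping) trajectory
  dynamics with a compiled kernel: focused initial conditions, the
  population estimator `Phi_n = 1/N + alpha_N (|c_n|^2 - 1/N)`,
  energy-conserving momentum rescaling at hops, frustrated-hop
  reflection, five-batch error bars, and a no-back-action baseline;
- a **variational polaron transformation (VPT)** that quantizes selected
  high-frequency modes by renormalizing the exciton Hamiltonian:
  `eps'_n = eps_n - sum_k hbar omega_k (2 f_nk g_k - f_nk^2)`,
  `J'_nm = J_nm <B_nm>` with band-narrowing factors
  `<B_nm> = exp(-1/2 sum_k (f_nk^2+f_mk^2) coth(beta hbar omega_k/2))`,
  solved self-consistently from the Bogoliubov free-energy bound;
- **spectral-density tooling**: reorganization-energy densities
  Lambda(omega), the low / high / nonresonant partition at k_B T and
  hbar omega_max (the maximum exciton gap), and equal-reorganization
  discretization of smooth solvent components;
- **equilibrium oracles**: the mixed quantum-classical Boltzmann average
  by Monte-Carlo phase-space integration, and exact truncated-boson
  diagonalization for tiny systems;
- **kinetics**: group populations with batch errors, mono- and
  biexponential rise fits, rate-constant ratios;
- **synthetic model generators** for LH2-like ring funnels, FMO-like
  funnels and LHCII-like two-group models, so the whole pipeline runs
  without any external data.

## Worked example

Generate a small two-ring funnel (8 inner "B850-like" sites, 4 outer
"B800-like" sites), excite an outer site, and compare classical MASH
against the VPT-renormalized dynamics:

```r
library(excimash)

m   <- make_ring_funnel(n_inner = 8, n_outer = 4, seed = 5)
cfg <- pipeline_config(t_max = 1500, n_traj = 4000, dt = 0.5, seed = 1,
                       initial_site = 9, fit_group = "B850like",
                       n_per_component = 12)
rep <- run_pipeline(m, cfg)
rep
#> <pipeline_report>
#>   kT = 208.5 cm^-1, omega_max = 1402.7 cm^-1
#>   high-frequency reorg fraction: 54%
#>   narrowing J'/J: mean 0.913, min 0.867
#>   classical: tau = 0.596 ps, p_inf = 0.654
#>   vpt: tau = 0.896 ps, p_inf = 0.625
#>   lowfreq: tau = 0.585 ps, p_inf = 0.565
#>   classical/VPT rate ratio(s): 1.5
```

Reading the output: `kT` and `omega_max` delimit the high-frequency
window; 54% of the bath reorganization energy below the exciton gap sits
above k_B T, so a quantum treatment of those modes matters.  The VPT
narrows the intersite couplings by ~9% on average, and the inter-ring
transfer time `tau` fitted from the B850-like rise is correspondingly
1.5x longer when the high-frequency modes are treated quantum
mechanically (`vpt`, 0.90 ps) than when they are treated classically
(`classical`, 0.60 ps) -- the nuclear quantum effect slows the transfer,
while leaving the direction of the funnel unchanged.  The
low-frequency-only run (`lowfreq`, high-frequency modes removed) is
statistically indistinguishable from the classical run at this ensemble
size; at 1e4 trajectories it resolves as slightly slower than
`classical`, i.e. classically treated high-frequency modes actively
promote the transfer.  (Numbers above are from this exact script; your
machine will reproduce them bit-for-bit at the same seed.)

Equilibrium self-consistency of the dynamics can be checked
independently:

```r
sdens <- spectral_density(
  discrete   = data.frame(omega_cm1 = 180, huang_rhys = 0.3),
  continuous = continuous_component("debye", 35, 50))
dm   <- make_dimer(417, 50, sdens)       # site gap ~ 2 kT at 300 K
bath <- dynamical_bath(sdens, n_per_component = 16)
ts   <- run_ensemble(dm$system, bath,
                     mash_config(t_max = 3000, n_traj = 2000, seed = 3))
longtime_populations(ts, 0.3)$populations
#> [1] 0.8784 0.1216
qc_equilibrium(dm$system, bath, 300, n_samples = 2e4, seed = 11)$populations
#> [1] 0.8769 0.1231
```

Model files are plain JSON (`write_model()` / `load_model()`); thin
command-line wrappers live in `inst/cli/` (`generate.R`, `simulate.R`,
`equilibrium.R`, `fit.R`, `pipeline.R`).

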