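---
title: "Surface-hopping exciton dynamics with variational polaron renormalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-hopping exciton dynamics with variational polaron renormalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excimash)
```

## The model

Excitation energy transfer in pigment-protein complexes is described here
by a Frenkel-exciton Hamiltonian `H = H_s + H_b + H_sb`.  In the basis of
locally excited chromophores ("sites"),

- `H_s = sum_n eps_n |n><n| + sum_{n != m} J_nm |n><m|`, with site energies
  `eps_n` and intersite couplings `J_nm` in cm^-1;
- `H_b` is a set of harmonic vibrational modes with frequencies `omega_k`,
  replicated identically and independently on every site;
- `H_sb = sum_nk hbar omega_k g_k (b_nk^+ + b_nk) |n><n|` couples each
  site's energy linearly to its own modes with dimensionless strengths
  `g_k` (Huang-Rhys factors `g_k^2`).

All of the bath information is carried by a spectral density, stored as a
table of discrete modes `(omega_k, g_k^2)` plus smooth low-frequency
"solvent" components.  We work with the density of reorganization
energies `Lambda(omega)`, whose integral is the total reorganization
energy `Lambda = sum_k hbar omega_k g_k^2 + sum_j lambda_j`.  The package
normalizes all energies to cm^-1 and all times to fs; the conversion
constants are `omega[rad/fs] = 2 pi c nu[cm^-1]` with
`c = 2.99792458e-5 cm/fs`, and `k_B = 0.69503476 cm^-1/K`, so
`k_B T = 208.5 cm^-1` at 300 K.

## Classical-limit dynamics: multi-state MASH

The classical limit replaces each mode's ladder operators by mass-scaled
phase-space variables, giving a multi-state potential matrix
`V_nn(q) = eps_n + sum_k kappa_k q_nk` (with
`kappa_k = g_k omega_k sqrt(2 omega_k)` in hbar = 1 units) and
`V_nm = J_nm` off the diagonal.  Trajectories propagate nuclear variables
alongside a complex coefficient vector `c` using the multi-state mapping
approach to surface hopping (MASH):

- the nuclei feel the Hellmann-Feynman force of the *most populated*
  instantaneous adiabatic state ("active state"), plus the harmonic bath
  force;
- whenever another adiabat overtakes the active one, the momentum is
  rescaled along a hop direction to conserve total energy exactly; if the
  kinetic energy along that direction is insufficient, the momentum
  component is reversed instead (a frustrated hop) and the active state is
  retained;
- populations are measured with the estimator
  `Phi_n = 1/N + alpha_N (|c_n|^2 - 1/N)`, `alpha_N = (N-1)/(H_N-1)`,
  which sums to one identically and is consistent with the mixed
  quantum-classical equilibrium average, unlike the raw `|c_n|^2`.

Initial conditions are "focused": `c_n = r_n exp(i phi_n)` with uniform
random phases and magnitudes chosen so that `Phi` is exactly the unit
vector on the initially excited site.  Nuclei start from the classical
Boltzmann distribution centered at `q = 0` (a vertical excitation);
a thermal Wigner distribution is available as an alternative initial
condition only, since its zero-point energy corresponds to an elevated
classical temperature at long times.

The defining property of this classical limit --- and the package's
central invariant --- is detailed balance: long-time ensemble averages of
`Phi` agree with the mixed quantum-classical equilibrium, i.e. the
phase-space average of the excitonic Boltzmann distribution.  The
`qc_equilibrium()` Monte-Carlo estimator provides that reference
independently of the dynamics.  A no-back-action baseline
(`run_no_backaction()`), in which the nuclear force ignores the excitonic
state, instead drives all site populations to `1/N` --- infinite
temperature --- which is why back-action-free classical simulations
cannot be used to diagnose nuclear quantum effects.

### Numerical scheme

Velocity Verlet advances the nuclei.  The coefficients are advanced by a
symmetric Strang splitting
`exp(-i V(q_new) dt/2) exp(-i V(q_old) dt/2)`,
each factor evaluated exactly in the instantaneous eigenbasis.  This has
the same formal accuracy as a midpoint-Hamiltonian exponential (local
error `O(dt^3)`), is exactly unitary (coefficient norm is conserved to
~1e-10 over thousands of steps), and reuses the eigendecomposition that
the forces and the hop test already need at each end point, so each step
costs a single diagonalization.  That diagonalization is warm-started: the
potential matrix is rotated into the previous step's eigenbasis, where it
is nearly diagonal, and polished with one or two Jacobi sweeps.  This
keeps eigenvector columns continuous along the trajectory and is several
times faster than a cold dense eigensolve for the 10-30-site systems the
package targets.

The hop direction is taken along the projected nonadiabatic coupling
between the two states involved, `d_nk = kappa_k U_n,old U_n,new`
(normalized; the `1/(V_new - V_old)` prefactor drops out on
normalization).  The momentum-rescaling equation
`|p + gamma d|^2/2 + V_new = |p|^2/2 + V_old` is solved for the root of
smaller magnitude; accepted hops conserve total energy to machine
precision by construction.  This direction choice is isolated in a single
code block of the kernel and is validated by the detailed-balance tests:
asymmetric dimers with structured baths relax to the independent
Monte-Carlo equilibrium within two combined standard errors.

Default timestep: `min(0.25 fs, T_fastest/40)`, where `T_fastest` is the
period of the fastest retained bath mode.  Ties in the maximum-population
test retain the incumbent active state (chattering guard; measure-zero
event).  Trajectories that produce non-finite values are discarded and
counted; a discard rate above 0.1% flags the run.  Every trajectory draws
its random stream from a counter-based hash of (seed, trajectory index),
so ensembles are reproducible and independent of execution order.

## Quantizing high-frequency modes: the variational polaron transformation

Modes with `hbar omega_k` well above `k_B T` are poorly described by
classical mechanics: a classical thermal ensemble gives their site-energy
fluctuations the full variance `2 k_B T lambda_k`, whereas the quantum
modes are frozen near their ground states.  The package treats them with
a variational polaron transformation (VPT): a canonical dressing
`H' = e^G H e^-G` with generator
`G = sum_nk f_nk (b_nk^+ - b_nk) |n><n|`.  The transformed Hamiltonian is
again of system-bath form with

- renormalized site energies
  `eps'_n = eps_n - sum_k hbar omega_k (2 f_nk g_k - f_nk^2)`;
- renormalized couplings `J'_nm = J_nm <B_nm>` with the band-narrowing
  factor
  `<B_nm> = exp(-1/2 sum_k (f_nk^2 + f_mk^2) coth(beta hbar omega_k / 2))`;
- a residual interaction with reduced diagonal couplings `(g_k - f_nk)`
  and exponential off-diagonal fluctuations with zero mean.

The displacements `f_nk` minimize the Bogoliubov upper bound `F_0` on the
free energy.  The stationarity condition is solved by fixed-point
iteration of

```
f_nk = omega_k g_k / (omega_k - coth(beta omega_k/2) * sum_{m != n} J'_nm Gamma_nm)
```

where `Gamma_nm = sum_M P_M U_nM U_mM / sum_M P_M U_nM^2` is built from
the Boltzmann-weighted eigenstates of the current `H'_s`.  Iteration
starts at the full-polaron point `f = g`, converges in under ten sweeps
on every shipped fixture, and is insensitive to the initial guess; a
mixing factor of 0.5 engages only if the update oscillates for three
consecutive sweeps.  The implementation was validated against brute-force
minimization of `F_0` on dense displacement grids for symmetric and
asymmetric dimers: the fixed point coincides with the grid minimum to
grid resolution, and the reported residual is the finite-difference
gradient of `F_0` at the solution.  Two limits are exact: `g = 0` gives
`f = 0` (identity), and `J = 0` gives `f = g` (full polaron).

For *dynamics*, the renormalized exciton Hamiltonian `(eps', J')` is
propagated with MASH over the low-frequency bath only; the residual
fluctuations of the transformed high-frequency modes are neglected, which
is the standard practice this transformation is designed for (they are
small precisely when the narrowing factors are close to one, as they are
for the light-harvesting regimes here).  For *equilibrium* comparisons,
the phase-space average of the transformed Hamiltonian retains the
reduced diagonal couplings `omega_k (g_k - f_nk)^2`
(`vpt_equilibrium()`); dropping them entirely turns out to push the
populations *away* from the exact truncated-boson reference, because the
bare-frame and transformed-frame classical averages err in opposite
directions while the elastic-channel narrowing over-localizes.  This
choice is what makes the transformed-frame classical average demonstrably
closer to the quantum populations in the strong-vibronic regime (see
`test-equilibrium.R`).

## Partitioning the spectral density

Following the physical reasoning above, the bath is split at two
energies: `k_B T`, separating classically valid from quantum-suspect
modes, and `hbar omega_max`, the spread of the exciton eigenvalues, above
which modes are non-resonant with the exciton dynamics and affect
neither treatment.  Discrete modes with `hbar omega < k_B T` (strictly;
the boundary itself routes to "high") and all smooth solvent components
form the low-frequency bath; discrete modes in `[k_B T, hbar omega_max]`
enter the VPT; modes above `hbar omega_max` are dropped by default (a
flag retains them).  The diagnostic `reorg_fraction()` --- the share of
reorganization energy in `[k_B T, hbar omega_max]` relative to
`[0, hbar omega_max]` --- is the single number that best predicts how
strongly a quantum treatment of the vibrations matters.

Smooth components are discretized for the trajectory methods by
equal-reorganization quadrature: the cumulative profile of
`Lambda(omega)`, up to a cutoff capturing 99.9% of `lambda`, is cut into
slices of equal reorganization energy, each replaced by one mode at its
median frequency.  Two hundred modes reproduce the classical Debye bath
correlation function `lambda exp(-omega_c t)` to 1% over a picosecond;
the dynamics default of 16-24 modes per component is well converged for
the observables here because the trajectory ensemble averages over the
microscopic mode structure.

## Synthetic study systems

No literature Hamiltonians or measured spectral densities ship with the
package; the generators in `R/synthetic.R` produce models with the
*statistical* structure of three light-harvesting archetypes, clearly
flagged as synthetic in their metadata:

- `ring_funnel_LH2like`: two concentric rings (default 16 + 8 sites;
  desk-scale analyses here use 8 + 4) with strong inner-ring
  nearest-neighbour couplings (250 cm^-1), weak outer-ring couplings
  (-25 cm^-1), and weak inter-ring couplings (35 cm^-1); the inner ring
  is red-shifted by 850 cm^-1, forming the inward funnel.  The bath
  combines a moderate Debye solvent (lambda = 100 cm^-1, omega_c =
  60 cm^-1) with tens of discrete modes on a log-spaced comb up to
  1700 cm^-1, rescaled so that 54% of the reorganization energy below
  the exciton gap lies above `k_B T`.  The offset is chosen so that the
  donor (outer-ring) level falls into a *gap* of the acceptor exciton
  spectrum rather than into its dense band edge: this detuning is what
  makes high-frequency modes mechanistically relevant to the inter-ring
  step --- low-frequency fluctuations alone cannot bridge the donor to
  the acceptor levels, classically fluctuating high-frequency modes can,
  and quantum-frozen (VPT-renormalized) ones again cannot.  With the
  donor resonant with the band edge instead, low-frequency modes suffice
  and additional classical high-frequency noise merely adds friction,
  inverting the qualitative effect.
- `eightsite_FMOlike`: eight weakly coupled sites on an energy ladder;
  small exciton gaps and only 11% high-frequency reorganization weight.
  In this regime every narrowing factor stays above 0.94 and the
  classical and VPT dynamics coincide.
- `funnel_LHCIIlike`: fourteen sites in two groups ("Chla" low,
  "Chlb" high) with 44% high-frequency weight; downhill transfer is
  biexponential.

The generators are deterministic at fixed seed, regenerate byte-identical
model files, and re-tune the bath scaling to the *realized* exciton gap
of the generated Hamiltonian.

What the synthetic models do **not** emulate: static site-energy
disorder, correlated or site-dependent baths, the specific mode
frequencies of bacteriochlorophyll/chlorophyll, or any quantitative
literature parameter set.  Passing the package's acceptance checks on
these models therefore demonstrates the *mechanisms* --- detailed
balance, band narrowing, the sign of the nuclear quantum effect on the
transfer rate --- not agreement with any published number for LH2, FMO or
LHCII.  To reproduce published rates, supply the corresponding literature
model as a JSON file to `run_pipeline()`.

## Equilibrium oracles

Two independent references close the loop on the dynamics:

- `qc_equilibrium()` evaluates the mixed quantum-classical average by
  Monte Carlo.  Because the site-energy shift
  `d_n = sum_k kappa_k q_nk` is the only bath-dependent quantity in the
  excitonic trace, its exact Gaussian marginal `N(0, 2 k_B T lambda)` is
  sampled directly --- a marginalization, not an approximation --- and the
  per-sample weight `Tr_ex exp(-beta V)` is accumulated in log space.
  Momenta and the state-independent bath potential cancel analytically.
  The estimator is verified against two-dimensional Gauss-Hermite
  quadrature on dimer fixtures.
- `quantum_equilibrium_small()` diagonalizes the full vibronic
  Hamiltonian on a site (x) Fock product basis for systems up to 3 sites
  and 2 total oscillators, doubling the truncation until populations move
  by less than 1e-6.

## Kinetics

Group populations (with standard errors recomputed from batch means of
the summed series) are reduced to time constants by nonlinear least
squares: `P(t) = P_inf (1 - exp(-t/tau))` for single-step transfer, or
`P(t) = P_inf - A_1 exp(-t/tau_1) - A_2 exp(-t/tau_2)` with non-negative
amplitudes and `tau_1 <= tau_2` for funnels with fast and slow channels
(five tau-ratio multi-starts; best residual kept; near-equal timescales
are flagged degenerate).  Fits start at `t = 0` with uniform weights.
Rate-constant ratios between two fits propagate the parameter
covariances.  Recovery tests: noiseless curves are reproduced to 1e-6;
with Gaussian noise of sigma = 0.01 the mean recovered tau is within 2%
of truth and 2-sigma intervals cover at >= 90%.

## Problem sizes and tolerances used in the shipped analyses

The package's own validation runs (tests and the acceptance script) use
desk-scale protocols chosen to make the statistical checks sharp:

- dimer detailed-balance runs: 1e4 trajectories, dt = 0.25 fs, five
  batches, with the equilibration time and bath density scaled with the
  site-energy bias (3 ps / 16 modes per component for the symmetric
  dimer up to 8 ps / 32 modes at a 2 k_B T bias, whose uphill hops are
  activated and slow).  These runs start from the relaxed bath
  distribution of the initial site rather than a vertical excitation:
  trajectories conserve energy individually, so a vertical start
  deposits the reorganization energy into the finite bath and heats it
  by Delta T/T ~ lambda/(n_modes k_B T) above the canonical reference,
  a real microcanonical effect that would otherwise contaminate the
  detailed-balance comparison at the few-0.001 population level.
  Agreement with the Monte-Carlo equilibrium is required within twice
  the combined standard error.
- ring-funnel comparisons: 8 + 4 sites, 1e4 trajectories, dt = 0.5 fs,
  ~1.25 ps.  dt = 0.5 fs was adopted for these after verifying that the
  populations from dt = 0.25 fs agree within combined ensemble errors
  across the entire series; energy drift per trajectory remains a small
  fraction of k_B T per ps.
- equilibrium oracle cross-checks: 4e4-1e5 Monte-Carlo samples;
  Gauss-Hermite quadrature with 80-100 nodes; Fock truncations verified
  by doubling.

## Known limitations

- The hop direction is a documented stand-in for the reference
  prescription it emulates; it satisfies the detailed-balance invariant
  on all shipped fixtures, which is the property that matters for the
  long-time physics, but other choices could differ at short times.
- The no-back-action baseline reports raw `|c_n|^2`; the Phi estimator's
  justification presumes MASH dynamics.
- `quantum_equilibrium_small()` scales exponentially and is a tiny-system
  oracle only.
- Biexponential fits are only as identifiable as the data allow; the
  degenerate flag should be honored downstream.
- VPT residual off-diagonal fluctuations are neglected in dynamics; for
  systems with narrowing factors far below ~0.7 (deep polaron regime) a
  perturbative treatment of the residual coupling would be more
  appropriate than either limit implemented here.
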