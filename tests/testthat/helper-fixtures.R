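# Shared fixtures for the test suite.  Everything is built in code; no data
# files are read.

# canonical dimer bath: Debye solvent + one sub-thermal discrete mode
fixture_dimer_sd <- function() {
  spectral_density(
    discrete = data.frame(omega_cm1 = 180, huang_rhys = 0.3),
    continuous = continuous_component("debye", lambda_cm1 = 35, omega_c_cm1 = 50)
  )
}

# a single high-frequency mode as a discretized bath
fixture_high_mode <- function(omega_cm1 = 1200, huang_rhys = 0.3) {
  discretized_bath(omega_cm1, huang_rhys)
}

# exact quantum site populations |<n| exp(-i H t) |i>|^2 of a bare exciton
# Hamiltonian (cm^-1), on a time grid in fs -- the zero-coupling oracle
exact_quantum_pops <- function(system, times_fs, initial_site) {
  H <- system$couplings
  diag(H) <- system$site_energies
  ee <- eigen(cm1_to_radfs(H), symmetric = TRUE)
  sapply(times_fs, function(t) {
    amp <- ee$vectors %*% (exp(-1i * ee$values * t) * ee$vectors[initial_site, ])
    Mod(amp)^2
  })
}

# deterministic Gauss-Hermite evaluation of the mixed quantum-classical
# equilibrium for a dimer with one mode per site (2 coupled coordinates)
gh_dimer_equilibrium <- function(system, lambda_cm1, temperature, n_nodes = 80) {
  gh <- pracma::gaussHermite(n_nodes)
  kT <- thermal_energy_cm1(temperature)
  sig <- sqrt(2 * kT * lambda_cm1)
  H0 <- system$couplings
  diag(H0) <- system$site_energies
  num <- c(0, 0); den <- 0
  for (i in seq_along(gh$x)) for (j in seq_along(gh$x)) {
    V <- H0
    diag(V) <- diag(H0) + sqrt(2) * sig * c(gh$x[i], gh$x[j])
    ee <- eigen(V, symmetric = TRUE)
    b <- ee$values / kT
    w <- exp(-(b - min(b)))
    wt <- gh$w[i] * gh$w[j] * exp(-min(b))
    num <- num + wt * drop(ee$vectors^2 %*% w)
    den <- den + wt * sum(w)
  }
  num / den
}
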