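# R interface to the MASH trajectory kernel: configuration, the population
# estimator, initial conditions, ensemble drivers, and time-series container.

#' MASH simulation configuration
#'
#' @param t_max Simulation length (fs).
#' @param n_traj Ensemble size; must be divisible by `n_batches`.
#' @param dt Timestep (fs).  Default: `min(0.25, T_fastest/40)` where
#'   T_fastest is the period of the fastest retained bath mode.
#' @param dt_out Output sampling interval (fs); rounded to a multiple of `dt`.
#' @param n_batches Number of batches for standard errors (default 5).
#' @param seed RNG seed; per-trajectory streams are derived from
#'   (seed, trajectory index) so ensembles are order-independent.
#' @param temperature Temperature (K).
#' @param initial_site Initially excited site (1-based).
#' @param nuclear_sampling `"classical_boltzmann"` (vertical excitation from
#'   the classical ground-state equilibrium), `"wigner"` (thermal Wigner
#'   distribution, carrying zero-point energy), or
#'   `"classical_boltzmann_relaxed"` (thermal distribution centered at the
#'   initially excited site's displaced minimum; used for equilibrium
#'   checks so the finite microcanonical bath is not heated by the
#'   reorganization energy of a vertical start).
#' @param backaction `"mash"` for full MASH, `"none"` for the no-back-action
#'   baseline in which nuclei ignore the excitonic state.
#' @return A list of class `mash_config`.
#' @export
mash_config <- function(t_max, n_traj, dt = NULL, dt_out = 10, n_batches = 5,
                        seed = 1, temperature = 300, initial_site = 1,
                        nuclear_sampling = c("classical_boltzmann", "wigner",
                                             "classical_boltzmann_relaxed"),
                        backaction = c("mash", "none")) {
  nuclear_sampling <- match.arg(nuclear_sampling)
  backaction <- match.arg(backaction)
  stopifnot(t_max > 0, n_traj >= 1, n_batches >= 1)
  if (n_traj %% n_batches != 0) stop("n_traj must be divisible by n_batches")
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  structure(
    list(t_max = t_max, n_traj = as.integer(n_traj), dt = dt, dt_out = dt_out,
         n_batches = as.integer(n_batches), seed = seed,
         temperature = temperature, initial_site = as.integer(initial_site),
         nuclear_sampling = nuclear_sampling, backaction = backaction),
    class = "mash_config"
  )
}

default_dt <- function(bath) {
  if (!length(bath$omega_cm1)) return(0.25)
  t_fastest <- 1 / (.c_cm_fs * max(bath$omega_cm1))  # period in fs
  min(0.25, t_fastest / 40)
}

#' MASH population estimator
#'
#' Phi_n = 1/N + alpha_N (|c_n|^2 - 1/N) with alpha_N = (N - 1)/(H_N - 1)
#' and H_N the N-th harmonic number.  The estimator sums to one exactly for
#' any normalized coefficient vector and is consistent with the mixed
#' quantum-classical equilibrium; individual entries may lie outside \[0, 1\].
#'
#' @param c Complex coefficient vector with unit norm (or a vector of
#'   populations |c_n|^2 summing to one).
#' @return Numeric vector Phi.
#' @export
population_estimator <- function(c) {
  if (is.complex(c)) pop <- Mod(c)^2 else pop <- as.numeric(c)
  if (abs(sum(pop) - 1) > 1e-8) stop("coefficients are not normalized")
  N <- length(pop)
  1 / N + alpha_mash(N) * (pop - 1 / N)
}

#' @rdname population_estimator
#' @param N Number of excitonic states.
#' @export
alpha_mash <- function(N) (N - 1) / (sum(1 / seq_len(N)) - 1)

#' Focused initial coefficients
#'
#' Draws c_n = r_n exp(i phi_n) with independent uniform phases and
#' magnitudes chosen so that the population estimator is exactly one on the
#' initial site and zero elsewhere:
#' r_i^2 = (N - 1 + alpha_N)/(N alpha_N), r_other^2 = (alpha_N - 1)/(N alpha_N).
#'
#' @param initial_site 1-based index of the initially excited site.
#' @param n_sites Number of sites (>= 2).
#' @return Complex vector of length `n_sites` with unit norm.
#' @export
focused_init <- function(initial_site, n_sites) {
  if (n_sites < 2) stop("focused initial condition needs at least 2 sites")
  a <- alpha_mash(n_sites)
  r <- rep(sqrt((a - 1) / (n_sites * a)), n_sites)
  r[initial_site] <- sqrt((n_sites - 1 + a) / (n_sites * a))
  phi <- stats::runif(n_sites, 0, 2 * pi)
  complex(modulus = r, argument = phi)
}

#' Potential matrix in the site basis
#'
#' V_nn(q) = eps_n + sum_k kappa_k q_nk (converted back to cm^-1),
#' V_nm = J_nm.  `q` uses the package's mass-scaled internal units; the
#' state-independent harmonic bath potential is not included.
#'
#' @param q Site x mode matrix of nuclear positions (internal units).
#' @param system An `exciton_system`.
#' @param bath A `discretized_bath`.
#' @return Site-basis potential matrix in cm^-1.
#' @export
potential_matrix <- function(q, system, bath) {
  q <- as.matrix(q)
  kappa <- bath_kappa_radfs(bath)
  if (!all(dim(q) == c(n_sites(system), length(kappa)))) {
    stop("q must be n_sites x n_modes")
  }
  V <- system$couplings
  diag(V) <- system$site_energies + radfs_to_cm1(drop(q %*% kappa))
  V
}

#' Sample nuclear initial conditions
#'
#' Classical Boltzmann: q ~ N(0, kT/omega^2), p ~ N(0, kT).  Wigner:
#' q ~ N(0, coth(beta omega/2)/(2 omega)), p ~ N(0, (omega/2) coth(...)).
#' Internal angular units (hbar = 1).
#'
#' @param bath A `discretized_bath`.
#' @param temperature Temperature (K).
#' @param mode `"classical_boltzmann"` or `"wigner"`.
#' @param n_sites Number of independent site baths to sample.
#' @return List with matrices `q` and `p` (n_sites x n_modes).
#' @export
sample_nuclei <- function(bath, temperature,
                          mode = c("classical_boltzmann", "wigner"),
                          n_sites = 1) {
  mode <- match.arg(mode)
  if (temperature <= 0) stop("temperature must be > 0")
  w <- cm1_to_radfs(bath$omega_cm1)
  kT <- cm1_to_radfs(thermal_energy_cm1(temperature))
  if (mode == "classical_boltzmann") {
    sq <- sqrt(kT) / w
    sp <- rep(sqrt(kT), length(w))
  } else {
    cth <- 1 / tanh(w / (2 * kT))
    sq <- sqrt(cth / (2 * w))
    sp <- sqrt(w * cth / 2)
  }
  M <- length(w)
  list(q = matrix(stats::rnorm(n_sites * M), n_sites, M, byrow = TRUE) *
         rep(sq, each = n_sites),
       p = matrix(stats::rnorm(n_sites * M), n_sites, M, byrow = TRUE) *
         rep(sp, each = n_sites))
}

# shared setup for the kernel calls
kernel_args <- function(system, bath, config, vpt = NULL) {
  if (!is.null(vpt)) {
    eps <- vpt$eps_prime
    J <- vpt$J_prime
  } else {
    eps <- system$site_energies
    J <- system$couplings
  }
  dt <- if (is.null(config$dt)) default_dt(bath) else config$dt
  nsteps <- ceiling(config$t_max / dt)
  stride <- max(1L, round(config$dt_out / dt))
  nsteps <- as.integer(ceiling(nsteps / stride) * stride)
  list(
    eps = cm1_to_radfs(eps), J = cm1_to_radfs(J),
    omega = cm1_to_radfs(bath$omega_cm1), kappa = bath_kappa_radfs(bath),
    kT = cm1_to_radfs(thermal_energy_cm1(config$temperature)),
    dt = dt, nsteps = nsteps, stride = as.integer(stride)
  )
}

#' Run an ensemble of MASH trajectories
#'
#' Propagates `config$n_traj` trajectories and returns ensemble-averaged
#' populations with per-batch standard errors.  With `backaction = "mash"`
#' the populations are the Phi estimator of [population_estimator()]; the
#' no-back-action baseline reports raw |c_n|^2 (see [run_no_backaction()]).
#'
#' @param system An `exciton_system`.
#' @param bath A `discretized_bath` (for VPT runs: the low-frequency bath
#'   only; the high-frequency modes live inside the renormalized
#'   Hamiltonian).
#' @param config A [mash_config()].
#' @param vpt Optional `vpt_solution`; if supplied, dynamics uses the
#'   renormalized site energies and couplings.
#' @return A `population_ts` object: `times` (fs), `phi` (site x time),
#'   `sem`, `batch` (site x time x batch array of batch means), plus
#'   bookkeeping fields.
#' @export
run_ensemble <- function(system, bath, config, vpt = NULL) {
  stopifnot(inherits(system, "exciton_system"),
            inherits(bath, "discretized_bath"),
            inherits(config, "mash_config"))
  N <- n_sites(system)
  if (config$initial_site > N) stop("initial_site exceeds n_sites")
  ka <- kernel_args(system, bath, config, vpt)
  backaction <- config$backaction == "mash"
  res <- mash_ensemble_cpp(
    ka$eps, ka$J, ka$omega, ka$kappa, ka$kT, ka$dt, ka$nsteps, ka$stride,
    config$n_traj, config$n_batches, config$seed, config$initial_site - 1L,
    switch(config$nuclear_sampling, classical_boltzmann = 0L, wigner = 1L,
           classical_boltzmann_relaxed = 2L),
    backaction
  )
  counts <- as.numeric(res$counts)
  discards <- sum(res$discards)
  if (any(counts == 0)) stop("an entire batch was discarded; inspect the model")
  nout <- ka$nsteps / ka$stride + 1
  batch <- array(res$csum, dim = c(N, nout, config$n_batches))
  for (b in seq_len(config$n_batches)) {
    m <- batch[, , b, drop = FALSE] / counts[b]   # mean |c_n|^2 per batch
    if (backaction) m <- 1 / N + alpha_mash(N) * (m - 1 / N)
    batch[, , b] <- m
  }
  phi <- apply(batch, c(1, 2), mean)
  sem <- apply(batch, c(1, 2), stats::sd) / sqrt(config$n_batches)
  flagged <- discards > 0.001 * config$n_traj
  if (flagged) {
    warning("discard rate above 0.1%: ", discards, " of ", config$n_traj,
            " trajectories")
  }
  structure(
    list(times = seq(0, by = ka$dt * ka$stride, length.out = nout),
         phi = phi, sem = sem, batch = batch,
         estimator = if (backaction) "phi" else "c2",
         site_labels = system$site_labels, groups = system$groups,
         dt = ka$dt, n_traj = config$n_traj, n_batches = config$n_batches,
         discards = discards, flagged = flagged),
    class = "population_ts"
  )
}

#' No-back-action baseline dynamics
#'
#' Nuclei evolve under the bare bath Hamiltonian (the force is independent
#' of the excitonic state) while the coefficients follow V(q(t)).  This
#' baseline drives the exciton system towards equal populations of all
#' sites, i.e. infinite temperature; populations are reported as raw
#' |c_n|^2, since the Phi estimator's equilibrium rationale presumes MASH.
#'
#' @inheritParams run_ensemble
#' @export
run_no_backaction <- function(system, bath, config) {
  config$backaction <- "none"
  run_ensemble(system, bath, config)
}

#' Single-trajectory diagnostics
#'
#' Propagates one trajectory and returns conserved-energy and norm traces
#' plus a hop log, for integrator verification.
#'
#' @inheritParams run_ensemble
#' @param traj_index Which trajectory stream to run (determines the RNG
#'   stream together with `config$seed`).
#' @return List with `times`, `pops` (site x time |c_n|^2), `energy_cm1`,
#'   `norm`, `hops` (data frame: step, from, to, accepted, dE_cm1).
#' @export
mash_trajectory <- function(system, bath, config, traj_index = 0, vpt = NULL) {
  ka <- kernel_args(system, bath, config, vpt)
  res <- mash_trajectory_cpp(
    ka$eps, ka$J, ka$omega, ka$kappa, ka$kT, ka$dt, ka$nsteps, ka$stride,
    config$seed, as.integer(traj_index), config$initial_site - 1L,
    switch(config$nuclear_sampling, classical_boltzmann = 0L, wigner = 1L,
           classical_boltzmann_relaxed = 2L),
    config$backaction == "mash"
  )
  hops <- as.data.frame(res$hops)
  if (nrow(hops)) {
    names(hops) <- c("step", "from", "to", "accepted")
    hops$dE_cm1 <- radfs_to_cm1(res$hop_dE)
  } else {
    hops <- data.frame(step = integer(0), from = integer(0), to = integer(0),
                       accepted = integer(0), dE_cm1 = numeric(0))
  }
  list(times = seq(0, by = ka$dt * ka$stride, length.out = ncol(res$pops)),
       pops = res$pops, energy_cm1 = radfs_to_cm1(res$energy),
       norm = res$norm, hops = hops, ok = res$ok, dt = ka$dt)
}

#' @export
print.population_ts <- function(x, ...) {
  cat("<population_ts> ", nrow(x$phi), " sites x ", ncol(x$phi),
      " times (0..", max(x$times), " fs), estimator ", x$estimator,
      ", ", x$n_traj, " trajectories in ", x$n_batches, " batches\n", sep = "")
  invisible(x)
}

#' Export a population time series as CSV
#'
#' Columns: `time_fs`, one `phi_<label>` and one `sem_<label>` per site.
#'
#' @param ts A `population_ts`.
#' @param path Output path.
#' @export
write_series_csv <- function(ts, path) {
  df <- data.frame(time_fs = ts$times)
  for (i in seq_len(nrow(ts$phi))) df[[paste0("phi_", ts$site_labels[i])]] <- ts$phi[i, ]
  for (i in seq_len(nrow(ts$phi))) df[[paste0("sem_", ts$site_labels[i])]] <- ts$sem[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
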