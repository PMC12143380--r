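# Equilibrium references: mixed quantum-classical populations by Monte-Carlo
# phase-space integration, and fully quantum populations by truncated-boson
# brute force on tiny instances.

new_equilibrium_estimate <- function(populations, stderr, n_samples, method) {
  structure(
    list(populations = populations / sum(populations), stderr = stderr,
         n_samples = n_samples, method = method),
    class = "equilibrium_estimate"
  )
}

#' @export
print.equilibrium_estimate <- function(x, ...) {
  cat("<equilibrium_estimate> method ", x$method, ", n = ", x$n_samples, "\n",
      sep = "")
  print(round(rbind(population = x$populations, stderr = x$stderr), 5))
  invisible(x)
}

#' Mixed quantum-classical equilibrium populations
#'
#' Estimates the phase-space average of the excitonic Boltzmann
#' distribution,
#' <|n><n|>_cl = int dp dq Tr_ex\[e^{-beta H(p,q)} |n><n|\] / int dp dq
#' Tr_ex\[e^{-beta H(p,q)}\],
#' by importance sampling with the uncoupled-bath Gaussian as proposal.
#' Momenta and the state-independent bath potential integrate out
#' analytically; the only bath-dependent quantity is the Gaussian
#' site-energy shift d_n = sum_k kappa_k q_nk, whose exact marginal
#' N(0, 2 kT lambda) is sampled directly.  The per-sample weight is the
#' excitonic trace Tr_ex\[e^{-beta V(q)}\], accumulated in log space.
#'
#' @param system An `exciton_system`.
#' @param bath A `discretized_bath` (its total reorganization energy sets
#'   the shift variance).
#' @param temperature Temperature (K).
#' @param n_samples Number of Monte-Carlo samples (>= 1000).
#' @param seed RNG seed.
#' @param site_reorg Optional per-site reorganization energies (cm^-1)
#'   overriding the bath total, for models whose diagonal coupling differs
#'   between sites (e.g. the residual coupling of a polaron-transformed
#'   Hamiltonian).
#' @return An `equilibrium_estimate` with fields `populations`, `stderr`,
#'   `ess` (effective sample size).
#' @export
qc_equilibrium <- function(system, bath, temperature, n_samples = 1e4, seed = 1,
                           site_reorg = NULL) {
  stopifnot(inherits(system, "exciton_system"))
  if (n_samples < 1e3) stop("n_samples must be at least 1000")
  N <- n_sites(system)
  kT <- thermal_energy_cm1(temperature)
  if (is.null(site_reorg)) {
    lam <- if (inherits(bath, "discretized_bath")) bath_reorganization(bath) else 0
    site_reorg <- rep(lam, N)
  }
  stopifnot(length(site_reorg) == N, all(site_reorg >= 0))
  sig <- sqrt(2 * kT * site_reorg)  # sd of the per-site energy shift, cm^-1
  H0 <- hamiltonian_matrix(system)
  .with_seed(seed, {
    d <- matrix(stats::rnorm(n_samples * N), n_samples, N) %*% diag(sig, N)
    logw <- numeric(n_samples)
    popm <- matrix(0, n_samples, N)
    for (s in seq_len(n_samples)) {
      V <- H0
      diag(V) <- diag(H0) + d[s, ]
      ee <- eigen(V, symmetric = TRUE)
      b <- ee$values / kT
      wts <- exp(-(b - min(b)))
      tr <- sum(wts)
      popm[s, ] <- drop(ee$vectors^2 %*% wts) / tr
      logw[s] <- -min(b) + log(tr)
    }
    wt <- exp(logw - max(logw))
    wt <- wt / sum(wt)
    est <- drop(wt %*% popm)
    se <- sqrt(colSums(wt^2 * sweep(popm, 2, est)^2))
    ess <- 1 / sum(wt^2)
    if (ess < 0.01 * n_samples) {
      warning("effective sample size below 1% of n_samples; poor proposal overlap")
    }
    out <- new_equilibrium_estimate(est, se, n_samples, "qc_montecarlo")
    out$ess <- ess
    out
  })
}

#' Mixed quantum-classical equilibrium of a polaron-transformed model
#'
#' Applies the phase-space average of [qc_equilibrium()] to the
#' VPT-renormalized Hamiltonian.  Because the polaron transformation is an
#' exact canonical transformation, the classical average in the transformed
#' frame is a different -- and for high-frequency modes a better --
#' approximation to the fully quantum populations than the same average in
#' the bare frame: the transformed modes couple only through the reduced
#' residual coefficients (g_k - f_nk), so their spurious classical thermal
#' broadening is largely removed.  Any untransformed (low-frequency) bath
#' content contributes its full reorganization energy.
#'
#' @param system The original `exciton_system`.
#' @param vpt A `vpt_solution` for its high-frequency modes.
#' @param temperature Temperature (K).
#' @param low_bath Optional `discretized_bath` of untransformed modes.
#' @param n_samples,seed Passed to [qc_equilibrium()].
#' @return An `equilibrium_estimate`.
#' @export
vpt_equilibrium <- function(system, vpt, temperature, low_bath = NULL,
                            n_samples = 1e4, seed = 1) {
  stopifnot(inherits(vpt, "vpt_solution"))
  N <- n_sites(system)
  lam_low <- if (is.null(low_bath)) 0 else bath_reorganization(low_bath)
  resid <- if (length(vpt$omega_cm1)) {
    drop(sweep(-vpt$f, 2, vpt$g, `+`)^2 %*% vpt$omega_cm1)
  } else rep(0, N)
  sys_p <- exciton_system(vpt$eps_prime, vpt$J_prime,
                          system$site_labels, system$groups)
  est <- qc_equilibrium(sys_p, low_bath, temperature, n_samples, seed,
                        site_reorg = resid + lam_low)
  est$method <- "vpt_qc_montecarlo"
  est
}

#' Excitonic Boltzmann populations (no residual bath)
#'
#' Site populations of the bare (or renormalized) exciton Hamiltonian at
#' thermal equilibrium: P_n = sum_M P_M U_nM^2.  This is the limit of the
#' mixed quantum-classical average for a system with no remaining bath
#' coupling, e.g. a polaron-renormalized Hamiltonian whose high-frequency
#' modes have been absorbed.
#'
#' @param eps Site energies (cm^-1) or an `exciton_system`.
#' @param J Coupling matrix (ignored when `eps` is a system).
#' @param temperature Temperature (K).
#' @return An `equilibrium_estimate` with method `"system_boltzmann"`.
#' @export
system_boltzmann <- function(eps, J = NULL, temperature = 300) {
  if (inherits(eps, "exciton_system")) {
    H <- hamiltonian_matrix(eps)
  } else {
    H <- as.matrix(J)
    diag(H) <- eps
  }
  kT <- thermal_energy_cm1(temperature)
  ee <- eigen(H, symmetric = TRUE)
  b <- ee$values / kT
  P <- exp(-(b - min(b)))
  P <- P / sum(P)
  pops <- drop(ee$vectors^2 %*% P)
  new_equilibrium_estimate(pops, rep(0, length(pops)), 0L, "system_boltzmann")
}

#' Fully quantum equilibrium populations by truncated-boson diagonalization
#'
#' Exact diagonalization of the vibronic Hamiltonian on the site (x) Fock
#' product basis.  Only feasible at brute-force scale: at most 3 sites and
#' 2 oscillators in total (the per-site baths contribute n_sites x n_modes
#' oscillators).  Convergence is verified by doubling the Fock truncation
#' until the maximum population change is below `conv_tol`.
#'
#' @param system An `exciton_system` (<= 3 sites).
#' @param bath A `discretized_bath` replicated on every site; total
#'   oscillator count n_sites * n_modes must be <= 2.
#' @param temperature Temperature (K).
#' @param n_fock Initial Fock-space truncation per oscillator (<= 30).
#' @param conv_tol Convergence threshold on populations when doubling.
#' @return An `equilibrium_estimate` with method `"quantum_truncated"`.
#' @export
quantum_equilibrium_small <- function(system, bath, temperature, n_fock = 8,
                                      conv_tol = 1e-6) {
  stopifnot(inherits(system, "exciton_system"))
  N <- n_sites(system)
  M <- length(bath$omega_cm1)
  if (N > 3) stop("brute-force oracle limited to 3 sites")
  if (N * M > 2) stop("brute-force oracle limited to 2 oscillators in total")
  if (n_fock > 30) stop("n_fock must be <= 30")
  pops <- quantum_pops_fock(system, bath, temperature, n_fock)
  repeat {
    n2 <- 2 * n_fock
    if (n2 > 64) stop("truncated-boson populations did not converge by n_fock = 64")
    pops2 <- quantum_pops_fock(system, bath, temperature, n2)
    if (max(abs(pops2 - pops)) < conv_tol) {
      return(new_equilibrium_estimate(pops2, rep(0, N), 0L, "quantum_truncated"))
    }
    pops <- pops2
    n_fock <- n2
  }
}

# populations at a fixed Fock truncation
quantum_pops_fock <- function(system, bath, temperature, n_fock) {
  N <- n_sites(system)
  M <- length(bath$omega_cm1)
  kT <- thermal_energy_cm1(temperature)
  Hs <- hamiltonian_matrix(system)
  nf <- n_fock
  IN <- diag(N)
  If <- diag(nf)
  bop <- matrix(0, nf, nf)
  if (nf > 1) bop[cbind(seq_len(nf - 1), seq_len(nf - 1) + 1)] <- sqrt(seq_len(nf - 1))
  xop <- bop + t(bop)           # b + b^dagger
  nop <- diag(seq_len(nf) - 1)  # number operator
  # oscillator ordering: (site 1, mode 1), (site 1, mode 2), ..., (site N, mode M)
  osc <- expand.grid(k = seq_len(M), n = seq_len(N))[, c("n", "k")]
  nosc <- nrow(osc)
  dim_tot <- N * nf^nosc
  kron_chain <- function(site_part, which_osc, op) {
    out <- site_part
    for (j in seq_len(nosc)) {
      out <- kronecker(out, if (!is.na(which_osc) && j == which_osc) op else If)
    }
    out
  }
  H <- kron_chain(Hs, NA, NULL)
  for (j in seq_len(nosc)) {
    w <- bath$omega_cm1[osc$k[j]]
    g <- bath$g[osc$k[j]]
    proj <- matrix(0, N, N)
    proj[osc$n[j], osc$n[j]] <- 1
    H <- H + kron_chain(IN, j, w * (nop + 0.5 * If)) +
      kron_chain(proj, j, w * g * xop)
  }
  ee <- eigen(H, symmetric = TRUE)
  b <- ee$values / kT
  wts <- exp(-(b - min(b)))
  wts <- wts / sum(wts)
  # site index varies slowest in the kronecker ordering
  site_of <- rep(seq_len(N), each = nf^nosc)
  amp2 <- ee$vectors^2
  pops <- numeric(N)
  for (n in seq_len(N)) {
    pops[n] <- sum(wts * colSums(amp2[site_of == n, , drop = FALSE]))
  }
  stopifnot(abs(sum(pops) - 1) < 1e-10, dim_tot == nrow(H))
  pops
}

#' Long-time population average of a time series
#'
#' Mean of the ensemble populations over the final `window` of the
#' trajectory, with a standard error combined across batches (treating the
#' time average within each batch as one draw).
#'
#' @param ts A `population_ts`.
#' @param window Fraction of the trajectory (from the end) to average over.
#' @return List with `populations` and `sem`.
#' @export
longtime_populations <- function(ts, window = 0.25) {
  stopifnot(inherits(ts, "population_ts"))
  nt <- ncol(ts$phi)
  sel <- seq.int(max(1L, floor((1 - window) * nt) + 1L), nt)
  bm <- apply(ts$batch[, sel, , drop = FALSE], c(1, 3), mean)
  list(populations = rowMeans(bm),
       sem = apply(bm, 1, stats::sd) / sqrt(dim(bm)[2]))
}
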