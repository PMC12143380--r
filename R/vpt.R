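# Variational polaron transformation (VPT).
#
# The transformation dresses each site with displacements f_nk of its
# high-frequency modes.  Minimizing the Bogoliubov bound F0 on the free
# energy with respect to f_nk yields the self-consistency condition
#
#   f_nk = omega_k g_k / (omega_k - coth(beta omega_k / 2) sum_{m != n} J'_nm Gamma_nm)
#
# where J'_nm = J_nm <B_nm> are couplings renormalized by the band-narrowing
# factor and Gamma is a Boltzmann-weighted overlap ratio of the eigenstates
# of the renormalized exciton Hamiltonian.  All energies in cm^-1.

#' Band-narrowing factors
#'
#' <B_nm> = exp(-1/2 sum_k (f_nk^2 + f_mk^2) coth(beta hbar omega_k / 2)).
#' The coth factor equals 2 n_k + 1 with n_k the Bose-Einstein occupation, so
#' narrowing strengthens with temperature and with vibronic coupling.
#'
#' @param f Site x mode matrix of variational displacements.
#' @param omegas Mode frequencies (cm^-1), length = ncol(f).
#' @param temperature Temperature in kelvin.
#' @return Symmetric site x site matrix with entries in (0, 1].
#' @export
band_narrowing <- function(f, omegas, temperature) {
  f <- as.matrix(f)
  if (ncol(f) != length(omegas)) stop("ncol(f) must equal length(omegas)")
  if (temperature <= 0) stop("temperature must be > 0")
  if (!ncol(f)) return(matrix(1, nrow(f), nrow(f)))
  cth <- .coth_half_beta(omegas, temperature)
  s <- drop(f^2 %*% cth)           # per-site sum_k f_nk^2 coth_k
  exp(-outer(s, s, `+`) / 2)
}

#' Renormalized site energies and couplings
#'
#' eps'_n = eps_n - sum_k hbar omega_k (2 f_nk g_k - f_nk^2);
#' J'_nm = J_nm <B_nm>.
#'
#' @param system An `exciton_system`.
#' @param high_modes A `discretized_bath` holding the modes included in the
#'   transformation.
#' @param f Site x mode matrix of displacements.
#' @param temperature Temperature in kelvin (for the narrowing factors).
#' @return List with `eps_prime` (vector), `J_prime` (matrix), `narrowing`.
#' @export
renormalize <- function(system, high_modes, f, temperature) {
  f <- as.matrix(f)
  w <- high_modes$omega_cm1
  g <- high_modes$g
  if (!all(dim(f) == c(n_sites(system), length(w)))) {
    stop("f must be n_sites x n_modes")
  }
  shift <- if (length(w)) {
    drop(sweep(f, 2, g, function(fk, gk) 2 * fk * gk) %*% w - f^2 %*% w)
  } else rep(0, n_sites(system))
  B <- band_narrowing(f, w, temperature)
  Jp <- system$couplings * B
  diag(Jp) <- 0
  list(eps_prime = system$site_energies - shift, J_prime = Jp, narrowing = B)
}

#' Boltzmann eigenstate workspace and Gamma matrix
#'
#' Diagonalizes the renormalized exciton Hamiltonian, forms Boltzmann
#' weights P_M over its eigenstates, and computes
#' Gamma_nm = sum_M P_M U_nM U_mM / sum_M P_M U_nM^2 with U_nM = <n|M>.
#'
#' @param eps_prime Renormalized site energies (cm^-1).
#' @param J_prime Renormalized coupling matrix (cm^-1, symmetric).
#' @param temperature Temperature in kelvin.
#' @return List with `eigvals`, `eigvecs`, `boltzmann`, `gamma`.
#' @export
gamma_matrix <- function(eps_prime, J_prime, temperature) {
  H <- as.matrix(J_prime)
  diag(H) <- eps_prime
  ee <- eigen(H, symmetric = TRUE)
  beta_e <- ee$values / thermal_energy_cm1(temperature)
  P <- exp(-(beta_e - min(beta_e)))
  P <- P / sum(P)
  U <- ee$vectors
  W <- U %*% (P * t(U))           # W_nm = sum_M P_M U_nM U_mM
  d <- diag(W)
  if (any(d < 1e-300)) {
    stop("gamma_matrix: Boltzmann-weighted site norm underflowed (degenerate spectrum?)")
  }
  list(eigvals = ee$values, eigvecs = U, boltzmann = P, gamma = W / d)
}

# Bogoliubov upper bound F0 (system part only; the bath free energy does not
# depend on f).  Returns cm^-1.
vpt_free_energy <- function(system, high_modes, f, temperature) {
  rn <- renormalize(system, high_modes, f, temperature)
  H <- rn$J_prime
  diag(H) <- rn$eps_prime
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  kT <- thermal_energy_cm1(temperature)
  b <- ev / kT
  -kT * (log(sum(exp(-(b - min(b))))) - min(b))
}

#' Solve the variational polaron transformation self-consistently
#'
#' Fixed-point iteration of the stationarity condition for f_nk starting
#' from the full-polaron guess f = g, recomputing the renormalized
#' Hamiltonian and Gamma matrix each sweep.  If the update oscillates
#' (sign-alternating changes for three sweeps) a mixing factor of 0.5 is
#' applied.  The returned residual is the maximum finite-difference
#' stationarity defect dF0/df_nk.
#'
#' @inheritParams renormalize
#' @param temperature Temperature in kelvin.
#' @param tol Convergence threshold on the maximum relative change of f.
#' @param max_iter Maximum number of sweeps.
#' @param f_init Optional initial guess (defaults to f = g on every site).
#' @return An object of class `vpt_solution`: `f`, `eps_prime`, `J_prime`,
#'   `narrowing`, `iterations`, `converged`, `residual`, plus the mode set
#'   and temperature used.
#' @export
solve_vpt <- function(system, high_modes, temperature, tol = 1e-10,
                      max_iter = 100, f_init = NULL) {
  stopifnot(inherits(system, "exciton_system"))
  N <- n_sites(system)
  w <- high_modes$omega_cm1
  g <- high_modes$g
  M <- length(w)
  if (M == 0) {
    return(structure(
      list(f = matrix(0, N, 0), eps_prime = system$site_energies,
           J_prime = system$couplings, narrowing = matrix(1, N, N),
           iterations = 0L, converged = TRUE, residual = 0,
           omega_cm1 = numeric(0), g = numeric(0), temperature = temperature),
      class = "vpt_solution"
    ))
  }
  cth <- .coth_half_beta(w, temperature)
  f <- if (is.null(f_init)) matrix(g, N, M, byrow = TRUE) else as.matrix(f_init)
  stopifnot(all(dim(f) == c(N, M)))
  mix <- 1
  osc_count <- 0
  prev_delta <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rn <- renormalize(system, high_modes, f, temperature)
    gm <- gamma_matrix(rn$eps_prime, rn$J_prime, temperature)
    JG <- rn$J_prime * gm$gamma
    diag(JG) <- 0
    s <- rowSums(JG)                       # sum_{m != n} J'_nm Gamma_nm
    denom <- outer(rep(1, N), w) - outer(s, cth, function(sn, ck) ck * sn)
    # denom_{nk} = omega_k - coth_k * s_n
    if (any(abs(denom) < 1e-8 * outer(rep(1, N), w))) {
      stop("solve_vpt: self-consistency denominator crossed zero; ",
           "max |s_n| = ", signif(max(abs(s)), 4), " cm^-1")
    }
    f_new <- outer(rep(1, N), w * g) / denom
    delta <- f_new - f
    if (!is.null(prev_delta) && sum(abs(delta)) > 0 && sum(abs(prev_delta)) > 0) {
      if (sum(delta * prev_delta) < 0) osc_count <- osc_count + 1 else osc_count <- 0
      if (osc_count >= 3) mix <- 0.5
    }
    prev_delta <- delta
    f <- f + mix * delta
    rel <- max(abs(delta) / pmax(abs(f), 1e-12))
    if (max(abs(delta)) == 0 || rel < tol) { converged <- TRUE; break }
  }
  rn <- renormalize(system, high_modes, f, temperature)
  # Hellmann-Feynman stationarity defect by central finite differences of F0
  h <- 1e-6
  resid <- 0
  for (n in seq_len(N)) for (k in seq_len(M)) {
    fp <- f; fp[n, k] <- f[n, k] + h
    fm <- f; fm[n, k] <- f[n, k] - h
    gdx <- (vpt_free_energy(system, high_modes, fp, temperature) -
              vpt_free_energy(system, high_modes, fm, temperature)) / (2 * h)
    resid <- max(resid, abs(gdx))
  }
  structure(
    list(f = f, eps_prime = rn$eps_prime, J_prime = rn$J_prime,
         narrowing = rn$narrowing, iterations = iter, converged = converged,
         residual = resid, omega_cm1 = w, g = g, temperature = temperature),
    class = "vpt_solution"
  )
}

#' @export
print.vpt_solution <- function(x, ...) {
  cat("<vpt_solution> ", length(x$omega_cm1), " modes, ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      ", residual ", signif(x$residual, 3), " cm^-1 per unit f\n", sep = "")
  if (length(x$omega_cm1)) {
    offd <- x$narrowing[upper.tri(x$narrowing)]
    cat("  narrowing <B_nm>: min ", signif(min(offd), 4), ", mean ",
        signif(mean(offd), 4), "\n", sep = "")
  }
  invisible(x)
}

#' Summary statistics of coupling renormalization
#'
#' Mean and minimum of J'_nm / J_nm over distinct pairs with |J_nm| above a
#' cutoff (pairs with negligible coupling carry no information about the
#' band narrowing).
#'
#' @param system The original `exciton_system`.
#' @param vpt A `vpt_solution`.
#' @param j_cutoff Minimum |J_nm| (cm^-1) for a pair to enter the average.
#' @return List with `mean`, `min`, `n_pairs`.
#' @export
narrowing_stats <- function(system, vpt, j_cutoff = 1) {
  J <- system$couplings
  sel <- upper.tri(J) & abs(J) > j_cutoff
  if (!any(sel)) return(list(mean = NA_real_, min = NA_real_, n_pairs = 0L))
  r <- vpt$narrowing[sel]
  list(mean = mean(r), min = min(r), n_pairs = sum(sel))
}

#' Serialize / load a VPT solution as JSON
#'
#' @param vpt A `vpt_solution`.
#' @param path File path.
#' @export
write_vpt <- function(vpt, path) {
  obj <- unclass(vpt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vpt
#' @export
load_vpt <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$f <- as.matrix(obj$f)
  obj$J_prime <- as.matrix(obj$J_prime)
  obj$narrowing <- as.matrix(obj$narrowing)
  structure(obj, class = "vpt_solution")
}
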