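# Core data model: Frenkel-exciton system, spectral density, bath partition
# and discretization.

#' Construct a Frenkel-exciton system
#'
#' Defines the excitonic Hamiltonian H_s = sum_n eps_n |n><n| +
#' sum_{n != m} J_nm |n><m| in the basis of locally excited sites.
#'
#' @param site_energies Numeric vector of site energies eps_n (cm^-1).
#' @param couplings Symmetric numeric matrix of intersite couplings J_nm
#'   (cm^-1) with zero diagonal.  A scalar is accepted for a dimer.
#' @param site_labels Optional character vector of site names.
#' @param groups Optional named list mapping group names (e.g. `"B850"`) to
#'   integer site indices.
#' @return An object of class `exciton_system`.
#' @examples
#' sys <- exciton_system(c(0, 100), matrix(c(0, 50, 50, 0), 2))
#' n_sites(sys)
#' @export
exciton_system <- function(site_energies, couplings, site_labels = NULL,
                           groups = list()) {
  site_energies <- as.numeric(site_energies)
  n <- length(site_energies)
  if (n < 1) stop("site_energies must be non-empty")
  if (is.numeric(couplings) && length(couplings) == 1 && n == 2) {
    couplings <- matrix(c(0, couplings, couplings, 0), 2, 2)
  }
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(n, n))) {
    stop("couplings must be a ", n, " x ", n, " matrix")
  }
  if (max(abs(couplings - t(couplings))) > 1e-10) {
    stop("couplings matrix is asymmetric beyond 1e-10 cm^-1")
  }
  if (any(diag(couplings) != 0)) {
    stop("couplings must have an exactly zero diagonal; put site energies in site_energies")
  }
  couplings <- (couplings + t(couplings)) / 2
  if (is.null(site_labels)) site_labels <- paste0("site", seq_len(n))
  if (length(site_labels) != n) stop("site_labels length must equal n_sites")
  if (length(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      stop("groups must be a named list")
    }
    for (g in names(groups)) {
      idx <- groups[[g]]
      if (any(idx < 1 | idx > n | idx != round(idx))) {
        stop("group '", g, "' contains invalid site indices")
      }
      groups[[g]] <- as.integer(idx)
    }
  }
  structure(
    list(site_energies = site_energies, couplings = couplings,
         site_labels = site_labels, groups = groups),
    class = "exciton_system"
  )
}

#' @rdname exciton_system
#' @param system An `exciton_system`.
#' @export
n_sites <- function(system) length(system$site_energies)

#' @export
print.exciton_system <- function(x, ...) {
  cat("<exciton_system> ", n_sites(x), " sites\n", sep = "")
  cat("  energies [cm^-1]: ", paste(signif(x$site_energies, 5), collapse = ", "), "\n", sep = "")
  if (length(x$groups)) {
    for (g in names(x$groups)) {
      cat("  group ", g, ": ", length(x$groups[[g]]), " sites\n", sep = "")
    }
  }
  invisible(x)
}

# site-basis Hamiltonian matrix in cm^-1
hamiltonian_matrix <- function(system) {
  H <- system$couplings
  diag(H) <- system$site_energies
  H
}

#' Construct a continuous spectral-density component
#'
#' Smooth low-frequency ("solvent") contributions to the bath, parameterized
#' so that the reorganization-energy density Lambda(omega) integrates to
#' `lambda_cm1`.  Supported forms: `"debye"` (Lorentzian cut-off,
#' Lambda(omega) = (2/pi) lambda omega_c / (omega^2 + omega_c^2)),
#' `"overdamped_brownian"` (same functional form, conventional alias) and
#' `"lognormal"` (Lambda(omega) = lambda * dlnorm(omega; log omega_c, sigma)).
#'
#' @param form One of `"debye"`, `"overdamped_brownian"`, `"lognormal"`.
#' @param lambda_cm1 Reorganization energy of the component (cm^-1, >= 0).
#' @param omega_c_cm1 Characteristic frequency (cm^-1, > 0).
#' @param sigma Log-width for the lognormal form.
#' @return An object of class `continuous_component`.
#' @export
continuous_component <- function(form = c("debye", "overdamped_brownian", "lognormal"),
                                 lambda_cm1, omega_c_cm1, sigma = 0.7) {
  form <- match.arg(form)
  if (!is.numeric(lambda_cm1) || lambda_cm1 < 0) stop("lambda_cm1 must be >= 0")
  if (!is.numeric(omega_c_cm1) || omega_c_cm1 <= 0) stop("omega_c_cm1 must be > 0")
  if (form == "lognormal" && (!is.numeric(sigma) || sigma <= 0)) {
    stop("sigma must be > 0 for the lognormal form")
  }
  structure(
    list(form = form, lambda_cm1 = lambda_cm1, omega_c_cm1 = omega_c_cm1,
         sigma = if (form == "lognormal") sigma else NULL),
    class = "continuous_component"
  )
}

# Lambda(omega) of a continuous component (dimensionless; integrates to lambda)
component_density <- function(comp, omega) {
  out <- numeric(length(omega))
  pos <- omega > 0
  w <- omega[pos]
  out[pos] <- switch(comp$form,
    debye = ,
    overdamped_brownian =
      (2 / pi) * comp$lambda_cm1 * comp$omega_c_cm1 / (w^2 + comp$omega_c_cm1^2),
    lognormal =
      comp$lambda_cm1 * stats::dlnorm(w, meanlog = log(comp$omega_c_cm1),
                                      sdlog = comp$sigma)
  )
  out
}

# cumulative reorganization profile of a component, int_0^omega Lambda
component_cumulative <- function(comp, omega) {
  switch(comp$form,
    debye = ,
    overdamped_brownian =
      (2 / pi) * comp$lambda_cm1 * atan(pmax(omega, 0) / comp$omega_c_cm1),
    lognormal =
      comp$lambda_cm1 * stats::plnorm(pmax(omega, 0),
                                      meanlog = log(comp$omega_c_cm1),
                                      sdlog = comp$sigma)
  )
}

# inverse of the cumulative profile (quantile of the lambda-distribution)
component_quantile <- function(comp, frac) {
  switch(comp$form,
    debye = ,
    overdamped_brownian =
      comp$omega_c_cm1 * tan(frac * pi / 2),
    lognormal =
      stats::qlnorm(frac, meanlog = log(comp$omega_c_cm1), sdlog = comp$sigma)
  )
}

#' Construct a spectral density
#'
#' The full bath description: a table of discrete vibrational modes
#' (frequency omega_k and Huang-Rhys factor g_k^2) plus a list of continuous
#' components.  The same bath is replicated identically and independently on
#' every site.
#'
#' @param discrete A data frame with columns `omega_cm1` (> 0) and
#'   `huang_rhys` (>= 0), one row per mode.  May be empty.
#' @param continuous A list of [continuous_component()] objects (or a single
#'   one).
#' @return An object of class `spectral_density`.
#' @examples
#' sd <- spectral_density(
#'   discrete = data.frame(omega_cm1 = c(750, 1200), huang_rhys = c(0.05, 0.03)),
#'   continuous = continuous_component("debye", lambda_cm1 = 35, omega_c_cm1 = 50)
#' )
#' total_reorganization(sd)
#' @export
spectral_density <- function(discrete = NULL, continuous = list()) {
  if (is.null(discrete)) {
    discrete <- data.frame(omega_cm1 = numeric(0), huang_rhys = numeric(0))
  }
  discrete <- as.data.frame(discrete)
  if (!all(c("omega_cm1", "huang_rhys") %in% names(discrete))) {
    stop("discrete must have columns omega_cm1 and huang_rhys")
  }
  if (nrow(discrete) && any(discrete$omega_cm1 <= 0)) {
    stop("discrete mode frequencies must be > 0 (field: bath.discrete.omega_cm1)")
  }
  if (nrow(discrete) && any(discrete$huang_rhys < 0)) {
    stop("Huang-Rhys factors must be >= 0 (field: bath.discrete.huang_rhys)")
  }
  if (inherits(continuous, "continuous_component")) continuous <- list(continuous)
  if (!all(vapply(continuous, inherits, logical(1), "continuous_component"))) {
    stop("continuous must be a list of continuous_component objects")
  }
  structure(
    list(discrete = discrete[c("omega_cm1", "huang_rhys")], continuous = continuous),
    class = "spectral_density"
  )
}

#' @export
print.spectral_density <- function(x, ...) {
  cat("<spectral_density> ", nrow(x$discrete), " discrete modes, ",
      length(x$continuous), " continuous component(s)\n", sep = "")
  cat("  total reorganization energy: ",
      signif(total_reorganization(x), 6), " cm^-1\n", sep = "")
  invisible(x)
}

#' Per-mode reorganization energies of the discrete part
#'
#' lambda_k = hbar omega_k g_k^2, in cm^-1.
#'
#' @param sd A `spectral_density` (or its `discrete` data frame).
#' @return Numeric vector, one entry per discrete mode.
#' @export
mode_reorganization <- function(sd) {
  d <- if (inherits(sd, "spectral_density")) sd$discrete else sd
  d$omega_cm1 * d$huang_rhys
}

#' Total bath reorganization energy
#'
#' Lambda = sum_k hbar omega_k g_k^2 + sum_j lambda_j over continuous
#' components; exact (no quadrature) in both terms.
#'
#' @param sd A `spectral_density`.
#' @return Total reorganization energy in cm^-1.
#' @export
total_reorganization <- function(sd) {
  stopifnot(inherits(sd, "spectral_density"))
  sum(mode_reorganization(sd)) +
    sum(vapply(sd$continuous, function(cc) cc$lambda_cm1, numeric(1)))
}

#' Broadened density of bath reorganization energies
#'
#' Evaluates Lambda(omega) on a frequency grid.  Each discrete mode
#' contributes a Brownian-oscillator lineshape proportional to
#' g_k^2 omega_k^2 gamma omega / ((omega_k^2 - omega^2)^2 + omega^2 gamma^2),
#' normalized so that its integral over the full frequency axis recovers the
#' mode's reorganization energy hbar omega_k g_k^2.  Continuous components
#' contribute their analytic density.
#'
#' @param sd A `spectral_density`.
#' @param grid Strictly increasing vector of positive frequencies (cm^-1).
#' @param broadening Lorentzian-like width gamma (cm^-1, > 0) applied to each
#'   discrete mode (purely for visualization/integration on a grid).
#' @return Numeric vector Lambda(grid), dimensionless.
#' @export
reorganization_density <- function(sd, grid, broadening = 10) {
  stopifnot(inherits(sd, "spectral_density"))
  if (!length(grid)) stop("grid must be non-empty")
  if (any(diff(grid) <= 0) || any(grid < 0)) {
    stop("grid must be strictly increasing and non-negative")
  }
  if (!is.numeric(broadening) || broadening <= 0) stop("broadening must be > 0")
  out <- numeric(length(grid))
  if (nrow(sd$discrete)) {
    for (k in seq_len(nrow(sd$discrete))) {
      wk <- sd$discrete$omega_cm1[k]
      g2 <- sd$discrete$huang_rhys[k]
      if (g2 == 0) next
      shape <- function(w) {
        wk^2 * broadening * w / ((wk^2 - w^2)^2 + w^2 * broadening^2)
      }
      # normalize numerically so the mode integrates to lambda_k = wk * g2
      nrm <- stats::integrate(shape, 0, wk, rel.tol = 1e-10)$value +
        stats::integrate(shape, wk, Inf, rel.tol = 1e-10)$value
      out <- out + (wk * g2 / nrm) * shape(grid)
    }
  }
  for (cc in sd$continuous) out <- out + component_density(cc, grid)
  out
}

#' Maximum gap between exciton eigenenergies
#'
#' hbar omega_max, the spread of the eigenvalues of the excitonic
#' Hamiltonian.  Bath frequencies above this gap are out of resonance with
#' the exciton dynamics.
#'
#' @param system An `exciton_system` with at least two sites.
#' @return hbar omega_max in cm^-1.
#' @examples
#' max_exciton_gap(exciton_system(c(0, 100), 50))  # sqrt(100^2 + 4*50^2)
#' @export
max_exciton_gap <- function(system) {
  stopifnot(inherits(system, "exciton_system"))
  if (n_sites(system) < 2) stop("max_exciton_gap needs at least 2 sites")
  ev <- eigen(hamiltonian_matrix(system), symmetric = TRUE, only.values = TRUE)$values
  max(ev) - min(ev)
}

#' Partition the bath into low, high and nonresonant parts
#'
#' Discrete modes with hbar omega_k < k_B T are "low" (treated classically
#' together with all continuous solvent components); modes with
#' k_B T <= hbar omega_k <= hbar omega_max are "high" (candidates for polaron
#' quantization); modes above hbar omega_max are "nonresonant".
#'
#' @param sd A `spectral_density`.
#' @param temperature Temperature in kelvin.
#' @param omega_max Maximum exciton gap hbar omega_max (cm^-1), typically
#'   [max_exciton_gap()] of the system.
#' @return A `bath_partition` with integer mode indices `low`, `high`,
#'   `nonresonant` into `sd$discrete`, plus `kT` and `omega_max`.
#' @export
partition_bath <- function(sd, temperature, omega_max) {
  stopifnot(inherits(sd, "spectral_density"))
  if (temperature <= 0) stop("temperature must be > 0")
  if (omega_max <= 0) stop("omega_max must be > 0")
  kT <- thermal_energy_cm1(temperature)
  w <- sd$discrete$omega_cm1
  structure(
    list(kT = kT, omega_max = omega_max,
         low = which(w < kT),
         high = which(w >= kT & w <= omega_max),
         nonresonant = which(w > omega_max)),
    class = "bath_partition"
  )
}

#' @export
print.bath_partition <- function(x, ...) {
  cat("<bath_partition> kT = ", signif(x$kT, 5), " cm^-1, omega_max = ",
      signif(x$omega_max, 5), " cm^-1\n  low: ", length(x$low),
      " modes (+ all continuous), high: ", length(x$high),
      ", nonresonant: ", length(x$nonresonant), "\n", sep = "")
  invisible(x)
}

#' Fraction of reorganization energy in the thermal-to-resonant window
#'
#' Ratio of the reorganization energy in \[k_B T, hbar omega_max\] to that in
#' [0, hbar omega_max].  Continuous components are integrated over each
#' interval; discrete modes contribute by their frequency.
#'
#' @inheritParams partition_bath
#' @return A fraction in \[0, 1\].
#' @export
reorg_fraction <- function(sd, temperature, omega_max) {
  stopifnot(inherits(sd, "spectral_density"))
  if (temperature <= 0) stop("temperature must be > 0")
  kT <- thermal_energy_cm1(temperature)
  w <- sd$discrete$omega_cm1
  lam <- mode_reorganization(sd)
  num <- sum(lam[w >= kT & w <= omega_max])
  den <- sum(lam[w <= omega_max])
  for (cc in sd$continuous) {
    num <- num + max(component_cumulative(cc, omega_max) -
                       component_cumulative(cc, kT), 0)
    den <- den + component_cumulative(cc, omega_max)
  }
  if (den <= 0) stop("reorg_fraction undefined: no reorganization energy below omega_max")
  num / den
}

#' Discretize a continuous component into effective modes
#'
#' Equal-reorganization quadrature: the cumulative reorganization profile of
#' the component (up to a cutoff capturing 99.9% of lambda) is cut into
#' `n_modes` slices of equal reorganization energy; each slice is replaced
#' by one mode at its median frequency with g_j^2 = (slice lambda)/omega_j.
#'
#' @param component A [continuous_component()].
#' @param n_modes Number of effective modes (>= 1).
#' @return A data frame with columns `omega_cm1`, `huang_rhys`.
#' @export
discretize_continuous <- function(component, n_modes) {
  stopifnot(inherits(component, "continuous_component"))
  if (n_modes < 1 || n_modes != round(n_modes)) stop("n_modes must be a positive integer")
  capture <- 0.999
  slice <- capture * component$lambda_cm1 / n_modes
  fr <- capture * (seq_len(n_modes) - 0.5) / n_modes
  omega <- vapply(fr, function(f) component_quantile(component, f), numeric(1))
  if (any(!is.finite(omega)) || any(omega <= 0)) {
    stop("component could not be discretized (non-integrable profile)")
  }
  data.frame(omega_cm1 = omega, huang_rhys = slice / omega)
}

#' Build the discretized bath used by trajectory dynamics
#'
#' Collects the requested part of a spectral density into a flat list of
#' modes: discrete modes are passed through, continuous components are
#' discretized with [discretize_continuous()].  When `part` is `"low"` only
#' sub-k_B T discrete modes plus all continuous components are retained;
#' `"all"` keeps every mode (nonresonant modes can be dropped when the
#' exciton gap is supplied).
#'
#' @param sd A `spectral_density`.
#' @param n_per_component Modes per continuous component.
#' @param part `"all"` or `"low"`.
#' @param temperature Required for `part = "low"` (kelvin).
#' @param omega_max If given, discrete modes above it are dropped as
#'   nonresonant (set `keep_nonresonant = TRUE` to retain them).
#' @param keep_nonresonant Keep modes above `omega_max`.
#' @return An object of class `discretized_bath` with fields `omega_cm1`,
#'   `g` (dimensionless couplings, g_k = sqrt of Huang-Rhys), `origin`.
#' @export
dynamical_bath <- function(sd, n_per_component = 24, part = c("all", "low"),
                           temperature = NULL, omega_max = NULL,
                           keep_nonresonant = FALSE) {
  stopifnot(inherits(sd, "spectral_density"))
  part <- match.arg(part)
  d <- sd$discrete
  origin <- rep("discrete", nrow(d))
  if (part == "low") {
    if (is.null(temperature)) stop("temperature needed for part = 'low'")
    kT <- thermal_energy_cm1(temperature)
    keep <- d$omega_cm1 < kT
    d <- d[keep, , drop = FALSE]
    origin <- origin[keep]
  } else if (!is.null(omega_max) && !keep_nonresonant) {
    keep <- d$omega_cm1 <= omega_max
    d <- d[keep, , drop = FALSE]
    origin <- origin[keep]
  }
  for (cc in sd$continuous) {
    dd <- discretize_continuous(cc, n_per_component)
    d <- rbind(d, dd)
    origin <- c(origin, rep("from-continuous", nrow(dd)))
  }
  structure(
    list(omega_cm1 = d$omega_cm1, g = sqrt(d$huang_rhys), origin = origin),
    class = "discretized_bath"
  )
}

#' @rdname dynamical_bath
#' @param omega_cm1 Mode frequencies (cm^-1, > 0).
#' @param huang_rhys Huang-Rhys factors g_k^2 (>= 0).
#' @param origin Per-mode origin tags.
#' @export
discretized_bath <- function(omega_cm1, huang_rhys,
                             origin = rep("discrete", length(omega_cm1))) {
  omega_cm1 <- as.numeric(omega_cm1)
  huang_rhys <- as.numeric(huang_rhys)
  stopifnot(length(omega_cm1) == length(huang_rhys),
            all(omega_cm1 > 0), all(huang_rhys >= 0))
  structure(list(omega_cm1 = omega_cm1, g = sqrt(huang_rhys), origin = origin),
            class = "discretized_bath")
}

#' @rdname dynamical_bath
#' @param bath A `discretized_bath`.
#' @export
bath_reorganization <- function(bath) sum(bath$omega_cm1 * bath$g^2)

# per-mode linear coupling coefficient kappa_k (rad/fs units, hbar = 1):
# V_nn picks up kappa_k q_nk with kappa_k = g_k omega_k sqrt(2 omega_k),
# the classical image of hbar omega_k g_k (b + b^dagger).
bath_kappa_radfs <- function(bath) {
  w <- cm1_to_radfs(bath$omega_cm1)
  bath$g * w * sqrt(2 * w)
}

#' @export
print.discretized_bath <- function(x, ...) {
  cat("<discretized_bath> ", length(x$omega_cm1), " modes, reorganization ",
      signif(bath_reorganization(x), 6), " cm^-1\n", sep = "")
  invisible(x)
}

# ---- model file IO ----------------------------------------------------------

#' Read or write an exciton + bath model file
#'
#' Model files are JSON with top-level keys `system`
#' (`energies_cm1`, `couplings_cm1`, `labels`, `groups`), `bath`
#' (`discrete`: array of `{omega_cm1, huang_rhys}`, `continuous`: array of
#' `{form, lambda_cm1, omega_c_cm1, sigma}`) and `meta`
#' (`units`, `temperature_K`).  Couplings are stored as the full symmetric
#' matrix.
#'
#' @param path File path.
#' @return `load_model()`: a list with elements `system`, `sd` and `meta`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("system", "bath")) {
    if (is.null(obj[[key]])) stop("model file missing required key: ", key)
  }
  s <- obj$system
  if (is.null(s$energies_cm1)) stop("missing field: system.energies_cm1")
  if (is.null(s$couplings_cm1)) stop("missing field: system.couplings_cm1")
  groups <- if (is.null(s$groups)) list() else lapply(s$groups, as.integer)
  system <- exciton_system(
    site_energies = as.numeric(s$energies_cm1),
    couplings = as.matrix(s$couplings_cm1),
    site_labels = if (is.null(s$labels)) NULL else as.character(s$labels),
    groups = groups
  )
  b <- obj$bath
  disc <- b$discrete
  if (is.null(disc) || (is.data.frame(disc) && !nrow(disc))) {
    disc <- data.frame(omega_cm1 = numeric(0), huang_rhys = numeric(0))
  }
  cont <- list()
  if (!is.null(b$continuous)) {
    cdf <- b$continuous
    if (is.data.frame(cdf)) {
      cont <- lapply(seq_len(nrow(cdf)), function(i) {
        continuous_component(
          form = cdf$form[i], lambda_cm1 = cdf$lambda_cm1[i],
          omega_c_cm1 = cdf$omega_c_cm1[i],
          sigma = if ("sigma" %in% names(cdf) && !is.na(cdf$sigma[i])) cdf$sigma[i] else 0.7
        )
      })
    } else if (length(cdf)) {
      cont <- lapply(cdf, function(cc) {
        do.call(continuous_component, cc[!vapply(cc, is.null, logical(1))])
      })
    }
  }
  sdens <- spectral_density(discrete = disc, continuous = cont)
  list(system = system, sd = sdens, meta = obj$meta)
}

#' @rdname load_model
#' @param system An `exciton_system`.
#' @param sd A `spectral_density`.
#' @param temperature_K Temperature recorded in the file metadata.
#' @param meta Optional extra metadata fields (named list).
#' @export
write_model <- function(system, sd, path, temperature_K = 300, meta = list()) {
  stopifnot(inherits(system, "exciton_system"), inherits(sd, "spectral_density"))
  cont <- lapply(sd$continuous, function(cc) {
    out <- list(form = cc$form, lambda_cm1 = cc$lambda_cm1,
                omega_c_cm1 = cc$omega_c_cm1)
    if (!is.null(cc$sigma)) out$sigma <- cc$sigma
    out
  })
  obj <- list(
    system = list(
      energies_cm1 = system$site_energies,
      couplings_cm1 = system$couplings,
      labels = system$site_labels,
      groups = system$groups
    ),
    bath = list(discrete = sd$discrete, continuous = cont),
    meta = c(list(units = "cm-1", temperature_K = temperature_K), meta)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a broadened Lambda(omega) curve as CSV
#'
#' @inheritParams reorganization_density
#' @param path Output CSV path (columns `omega_cm1`, `lambda_density`).
#' @export
write_density_csv <- function(sd, grid, path, broadening = 10) {
  lam <- reorganization_density(sd, grid, broadening)
  utils::write.csv(data.frame(omega_cm1 = grid, lambda_density = lam),
                   path, row.names = FALSE)
  invisible(path)
}
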