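# End-to-end workflow: partition -> VPT -> MASH variants -> kinetic fits ->
# comparison report, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param temperature Temperature (K).
#' @param t_max Simulation length (fs).
#' @param n_traj Ensemble size per variant.
#' @param n_batches Batches for standard errors.
#' @param seed Base RNG seed (variants derive distinct streams).
#' @param dt Timestep (fs); `NULL` for the bath-resolved default.
#' @param dt_out Output interval (fs).
#' @param n_per_component Discretization modes per continuous component.
#' @param initial_site Initially excited site.
#' @param fit_group Group name whose rise is fitted.
#' @param fit_model `"mono"` or `"biexp"`.
#' @param variants Subset of `c("classical", "vpt", "lowfreq")`.
#' @param no_backaction Also run the no-back-action baseline.
#' @param wigner Also run classical dynamics with Wigner initial sampling.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(temperature = 300, t_max = 1000, n_traj = 5000,
                            n_batches = 5, seed = 1, dt = NULL, dt_out = 10,
                            n_per_component = 16, initial_site = 1,
                            fit_group = NULL, fit_model = c("mono", "biexp"),
                            variants = c("classical", "vpt", "lowfreq"),
                            no_backaction = FALSE, wigner = FALSE) {
  fit_model <- match.arg(fit_model)
  variants <- match.arg(variants, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline on a model
#'
#' Stages: (i) bath partition summary (k_B T, hbar omega_max, reorganization
#' fractions); (ii) VPT solution on the resonant high-frequency modes with
#' narrowing statistics; (iii) MASH population dynamics for the requested
#' variants -- all modes classical, VPT-renormalized (low-frequency bath
#' only), and low-frequency-only without renormalization -- plus optional
#' no-back-action and Wigner runs; (iv) kinetic fits of the target group and
#' classical/VPT rate ratios; (v) a manifest sufficient to reproduce the run.
#'
#' @param model A list with `system` and `sd` (as from [load_model()] or the
#'   generators), or a path to a model JSON file.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A list of class `pipeline_report` with elements `partition`,
#'   `vpt`, `series`, `fits`, `ratios`, `manifest`.
#' @export
run_pipeline <- function(model, config = pipeline_config(), out_dir = NULL) {
  t_start <- Sys.time()
  model_path <- NULL
  if (is.character(model)) {
    model_path <- model
    model <- load_model(model)
  }
  system <- model$system
  sdens <- model$sd
  stages <- list()
  timings <- c()
  failed_at <- NULL
  tick <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      failed_at <<- c(name, conditionMessage(e))
      NULL
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  # (i) partition summary
  kT <- thermal_energy_cm1(config$temperature)
  wmax <- max_exciton_gap(system)
  part <- partition_bath(sdens, config$temperature, wmax)
  partition <- list(
    kT_cm1 = kT, omega_max_cm1 = wmax,
    n_low = length(part$low), n_high = length(part$high),
    n_nonresonant = length(part$nonresonant),
    total_reorganization_cm1 = total_reorganization(sdens),
    high_fraction = reorg_fraction(sdens, config$temperature, wmax)
  )

  # (ii) VPT on resonant high-frequency modes
  high_bath <- structure(
    list(omega_cm1 = sdens$discrete$omega_cm1[part$high],
         g = sqrt(sdens$discrete$huang_rhys[part$high]),
         origin = rep("discrete", length(part$high))),
    class = "discretized_bath"
  )
  vpt <- tick("vpt", solve_vpt(system, high_bath, config$temperature))
  vstats <- if (!is.null(vpt)) narrowing_stats(system, vpt) else NULL

  # (iii) dynamics variants
  bath_all <- dynamical_bath(sdens, config$n_per_component, "all",
                             omega_max = wmax)
  bath_low <- dynamical_bath(sdens, config$n_per_component, "low",
                             temperature = config$temperature)
  base_cfg <- function(seed_offset, ...) {
    mash_config(t_max = config$t_max, n_traj = config$n_traj, dt = config$dt,
                dt_out = config$dt_out, n_batches = config$n_batches,
                seed = config$seed + seed_offset,
                temperature = config$temperature,
                initial_site = config$initial_site, ...)
  }
  series <- list()
  if ("classical" %in% config$variants) {
    series$classical <- tick("classical",
                             run_ensemble(system, bath_all, base_cfg(0)))
  }
  if ("vpt" %in% config$variants && !is.null(vpt)) {
    series$vpt <- tick("vpt_run",
                       run_ensemble(system, bath_low, base_cfg(1), vpt = vpt))
  }
  if ("lowfreq" %in% config$variants) {
    series$lowfreq <- tick("lowfreq",
                           run_ensemble(system, bath_low, base_cfg(2)))
  }
  if (isTRUE(config$no_backaction)) {
    series$no_backaction <- tick("no_backaction",
                                 run_no_backaction(system, bath_all, base_cfg(3)))
  }
  if (isTRUE(config$wigner)) {
    series$wigner <- tick("wigner",
                          run_ensemble(system, bath_all,
                                       base_cfg(4, nuclear_sampling = "wigner")))
  }

  # (iv) kinetic fits
  fits <- list()
  ratios <- NULL
  if (!is.null(config$fit_group)) {
    fitter <- if (config$fit_model == "biexp") fit_biexp else fit_mono
    for (v in names(series)) {
      if (is.null(series[[v]]) || v == "no_backaction") next
      fits[[v]] <- tick(paste0("fit_", v),
                        fitter(group_population(series[[v]], config$fit_group)))
    }
    if (!is.null(fits$classical) && !is.null(fits$vpt)) {
      # k_classical / k_vpt = tau_vpt / tau_classical
      ratios <- rate_ratio(fits$classical, fits$vpt)
    }
  }

  # (v) manifest
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("excimash")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    model_md5 = if (!is.null(model_path)) unname(tools::md5sum(model_path)) else NA,
    seed = config$seed,
    timings_s = timings,
    failed_at = failed_at,
    wall_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  unlink(tmp)

  report <- structure(
    list(partition = partition,
         vpt = list(solution = vpt, narrowing = vstats),
         series = series, fits = fits, ratios = ratios, manifest = manifest),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (v in names(series)) {
      if (!is.null(series[[v]])) {
        write_series_csv(series[[v]], file.path(out_dir, paste0("series_", v, ".csv")))
      }
    }
    summary_obj <- report
    summary_obj$series <- lapply(series, function(s) if (is.null(s)) NULL else {
      list(times = s$times, n_traj = s$n_traj, estimator = s$estimator)
    })
    jsonlite::write_json(
      lapply(unclass(summary_obj), function(x) x), # drop classes for output
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, null = "null"
    )
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  kT = ", signif(x$partition$kT_cm1, 4), " cm^-1, omega_max = ",
      signif(x$partition$omega_max_cm1, 5), " cm^-1\n", sep = "")
  cat("  high-frequency reorg fraction: ",
      round(100 * x$partition$high_fraction, 1), "%\n", sep = "")
  if (!is.null(x$vpt$narrowing) && !is.na(x$vpt$narrowing$mean)) {
    cat("  narrowing J'/J: mean ", signif(x$vpt$narrowing$mean, 3), ", min ",
        signif(x$vpt$narrowing$min, 3), "\n", sep = "")
  }
  for (v in names(x$fits)) {
    f <- x$fits[[v]]
    if (is.null(f)) next
    if (f$model == "mono") {
      cat("  ", v, ": tau = ", signif(f$tau_ps, 3), " ps, p_inf = ",
          signif(f$p_inf, 3), "\n", sep = "")
    } else {
      cat("  ", v, ": tau1 = ", signif(f$tau1_ps, 3), " ps, tau2 = ",
          signif(f$tau2_ps, 3), " ps\n", sep = "")
    }
  }
  if (!is.null(x$ratios)) {
    cat("  classical/VPT rate ratio(s): ",
        paste(signif(x$ratios$ratio, 3), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
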