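# Reduction of population time series to kinetic observables: group
# populations, mono/biexponential rise fits, and rate ratios.

#' Summed population of a site group
#'
#' Sums the member populations at every time; the standard error is
#' recomputed from the batch means of the summed quantity (not from
#' per-site standard errors).
#'
#' @param ts A `population_ts`.
#' @param group A group name present in the model's `groups`, or an integer
#'   vector of site indices.
#' @return A `group_ts`: `times` (fs), `p`, `sem`, `batch` (time x batch).
#' @export
group_population <- function(ts, group) {
  stopifnot(inherits(ts, "population_ts"))
  if (is.character(group)) {
    if (!group %in% names(ts$groups)) stop("unknown group name: ", group)
    idx <- ts$groups[[group]]
    label <- group
  } else {
    idx <- as.integer(group)
    label <- paste(idx, collapse = "+")
  }
  if (!length(idx)) stop("group is empty")
  if (any(idx < 1 | idx > nrow(ts$phi))) stop("group indices out of range")
  bsum <- apply(ts$batch[idx, , , drop = FALSE], c(2, 3), sum)
  structure(
    list(times = ts$times, p = rowMeans(bsum),
         sem = apply(bsum, 1, stats::sd) / sqrt(ncol(bsum)),
         batch = bsum, label = label),
    class = "group_ts"
  )
}

#' @export
print.group_ts <- function(x, ...) {
  cat("<group_ts> group ", x$label, ", ", length(x$times), " times, final p = ",
      signif(tail(x$p, 1), 4), "\n", sep = "")
  invisible(x)
}

new_kinetics_fit <- function(model, pars, cov, residual_rms, degenerate = FALSE) {
  structure(
    c(list(model = model), pars,
      list(covariance = cov, residual_rms = residual_rms,
           degenerate = degenerate)),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (x$model == "mono") {
    cat("<kinetics_fit> mono: p_inf = ", signif(x$p_inf, 4), ", tau = ",
        signif(x$tau_ps, 4), " ps\n", sep = "")
  } else {
    cat("<kinetics_fit> biexp: p_inf = ", signif(x$p_inf, 4), ", tau1 = ",
        signif(x$tau1_ps, 4), " ps (A1 = ", signif(x$A1, 3), "), tau2 = ",
        signif(x$tau2_ps, 4), " ps (A2 = ", signif(x$A2, 3), ")",
        if (x$degenerate) " [degenerate: tau1 ~ tau2]", "\n", sep = "")
  }
  invisible(x)
}

# accepts a group_ts or (times, values); returns list(t_ps, p)
as_fit_data <- function(ts, values = NULL) {
  if (inherits(ts, "group_ts")) {
    list(t_ps = ts$times / 1000, p = ts$p)
  } else {
    stopifnot(!is.null(values), length(ts) == length(values))
    list(t_ps = as.numeric(ts) / 1000, p = as.numeric(values))
  }
}

#' Monoexponential rise fit
#'
#' Nonlinear least squares of P(t) = P_inf (1 - exp(-t/tau)) for a
#' population rising from ~0.  Deterministic initial guesses: P_inf from
#' the final value, tau from the first crossing of P_inf (1 - 1/e).
#'
#' @param ts A `group_ts`, or a numeric vector of times in fs.
#' @param values Population values when `ts` is a plain time vector.
#' @return A `kinetics_fit` with `p_inf`, `tau_ps`, parameter covariance and
#'   RMS residual.
#' @export
fit_mono <- function(ts, values = NULL) {
  d <- as_fit_data(ts, values)
  pinf0 <- mean(tail(d$p, max(3, length(d$p) %/% 10)))
  if (!is.finite(pinf0) || pinf0 < 0.01) {
    stop("fit_mono: series shows no rise (final value ~ 0)")
  }
  thresh <- pinf0 * (1 - exp(-1))
  ix <- which(d$p >= thresh)[1]
  tau0 <- if (is.na(ix) || d$t_ps[ix] <= 0) max(d$t_ps) / 3 else d$t_ps[ix]
  df <- data.frame(t = d$t_ps, p = d$p)
  fit <- minpack.lm::nlsLM(
    p ~ pinf * (1 - exp(-t / tau)), data = df,
    start = list(pinf = pinf0, tau = tau0),
    lower = c(0, 1e-6), upper = c(1.5, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  new_kinetics_fit("mono",
                   list(p_inf = unname(cf["pinf"]), tau_ps = unname(cf["tau"])),
                   vcov(fit), sqrt(mean(residuals(fit)^2)))
}

#' Biexponential rise fit
#'
#' P(t) = P_inf - A1 exp(-t/tau1) - A2 exp(-t/tau2) with non-negative
#' amplitudes and tau1 <= tau2 by convention.  Multi-start over five
#' tau-ratio seeds around the monoexponential timescale; the best residual
#' is kept.  Fits with tau2/tau1 < 1.05 are flagged degenerate.
#'
#' @inheritParams fit_mono
#' @return A `kinetics_fit` with `p_inf`, `tau1_ps`, `tau2_ps`, `A1`, `A2`.
#' @export
fit_biexp <- function(ts, values = NULL) {
  d <- as_fit_data(ts, values)
  mono <- tryCatch(fit_mono(ts, values), error = function(e) NULL)
  tau0 <- if (is.null(mono)) max(d$t_ps) / 3 else mono$tau_ps
  pinf0 <- if (is.null(mono)) mean(tail(d$p, 3)) else mono$p_inf
  p0 <- d$p[1]
  df <- data.frame(t = d$t_ps, p = d$p)
  best <- NULL
  for (ratio in c(2, 5, 10, 25, 50)) {
    st <- list(pinf = pinf0,
               A1 = (pinf0 - p0) / 2, A2 = (pinf0 - p0) / 2,
               tau1 = tau0 / sqrt(ratio), tau2 = tau0 * sqrt(ratio))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        p ~ pinf - A1 * exp(-t / tau1) - A2 * exp(-t / tau2), data = df,
        start = st, lower = c(0, 0, 0, 1e-6, 1e-6), upper = c(1.5, 1, 1, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("fit_biexp: no start converged")
  cf <- coef(best$fit)
  cv <- vcov(best$fit)
  if (cf["tau1"] > cf["tau2"]) {  # enforce ordering convention
    cf[c("tau1", "tau2")] <- cf[c("tau2", "tau1")]
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
    perm <- c("pinf", "A2", "A1", "tau2", "tau1")
    cv <- cv[perm, perm]
    dimnames(cv) <- list(c("pinf", "A1", "A2", "tau1", "tau2"),
                         c("pinf", "A1", "A2", "tau1", "tau2"))
  }
  degen <- cf["tau2"] / cf["tau1"] < 1.05
  new_kinetics_fit("biexp",
                   list(p_inf = unname(cf["pinf"]),
                        tau1_ps = unname(cf["tau1"]), tau2_ps = unname(cf["tau2"]),
                        A1 = unname(cf["A1"]), A2 = unname(cf["A2"])),
                   cv, sqrt(mean(residuals(best$fit)^2)), degen)
}

#' Ratio of rate constants between two fits
#'
#' Rates are inverse time constants, so the ratio k_a/k_b equals tau_b/tau_a
#' (per component for biexponential fits).  Uncertainties are propagated
#' from the fit covariances.
#'
#' @param fit_a,fit_b Two `kinetics_fit` objects of the same model type.
#' @return Data frame with columns `component`, `ratio`, `stderr`.
#' @export
rate_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "kinetics_fit"), inherits(fit_b, "kinetics_fit"))
  if (fit_a$model != fit_b$model) stop("fits have different model types")
  one <- function(comp, ta, tb, va, vb) {
    r <- tb / ta
    data.frame(component = comp, ratio = r,
               stderr = r * sqrt(va / ta^2 + vb / tb^2))
  }
  if (fit_a$model == "mono") {
    one("tau", fit_a$tau_ps, fit_b$tau_ps,
        fit_a$covariance["tau", "tau"], fit_b$covariance["tau", "tau"])
  } else {
    rbind(
      one("tau1", fit_a$tau1_ps, fit_b$tau1_ps,
          fit_a$covariance["tau1", "tau1"], fit_b$covariance["tau1", "tau1"]),
      one("tau2", fit_a$tau2_ps, fit_b$tau2_ps,
          fit_a$covariance["tau2", "tau2"], fit_b$covariance["tau2", "tau2"])
    )
  }
}
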