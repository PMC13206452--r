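# Non-compartmental exposure metrics: AUC by the linear-up/log-down
# trapezoid, terminal slope by log-linear regression with automatic window
# selection, Cmax/tmax from the sampling grid, and the urinary excretion
# fraction from the urine sink.

# linear-up/log-down trapezoid over the full sampled range
auc_linlog <- function(time, conc) {
  stopifnot(length(time) == length(conc), !is.unsorted(time))
  if (length(time) < 2) return(0)
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- (c1 + c2) / 2 * dt
  down <- c2 < c1 & c2 > 0 & c1 > 0
  seg[down] <- (c1[down] - c2[down]) / log(c1[down] / c2[down]) * dt[down]
  sum(seg)
}

# interpolate a concentration at one time (linear; exact grid hits returned
# as-is)
interp_conc <- function(time, conc, at) {
  approx(time, conc, xout = at, rule = 2)$y
}

#' Terminal slope by log-linear regression
#'
#' Fits `log(C) ~ t` over candidate terminal windows (the last 3 up to the
#' last `max_points` samples after the post-dose peak) and keeps the window
#' with the highest adjusted R-squared.
#'
#' @param time_h sampling times, hours
#' @param conc concentrations (positive within the fitted window)
#' @param max_points largest terminal window considered
#' @return a list with `lambda_z` (1/h), `n_points`, `adj_r2`, and
#'   `estimable`; `lambda_z` is `NA` when no valid window exists
#' @export
lambda_z <- function(time_h, conc, max_points = 10) {
  keep <- is.finite(conc) & conc > 0
  time_h <- time_h[keep]; conc <- conc[keep]
  n <- length(time_h)
  if (n < 3)
    return(list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_,
                estimable = FALSE))
  i_max <- which.max(conc)
  best <- list(lambda_z = NA_real_, n_points = 0L, adj_r2 = -Inf,
               estimable = FALSE)
  for (np in 3:min(max_points, n)) {
    ix <- (n - np + 1L):n
    if (min(ix) <= i_max) next
    fit <- lm(log(conc[ix]) ~ time_h[ix])
    slope <- -coef(fit)[2]
    if (!is.finite(slope) || slope <= 0) next
    # noise-free profiles fit exactly; the perfect-fit warning is expected
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.finite(r2) && r2 > best$adj_r2)
      best <- list(lambda_z = unname(slope), n_points = np, adj_r2 = r2,
                   estimable = TRUE)
  }
  if (!best$estimable) best$adj_r2 <- NA_real_
  best
}

#' Non-compartmental PK metrics from a concentration-time profile
#'
#' For single-dose profiles (`tau = NULL`), AUC_last runs from the last
#' dose to the last positive sample and AUC_inf adds `C_last / lambda_z`.
#' For multiple-dose profiles with a dosing interval `tau`, AUC_tau covers
#' the final interval `[t_last_dose, t_last_dose + tau]` and AUC_inf is the
#' interval AUC plus the terminal extrapolation `C(tau) / lambda_z` from
#' samples beyond the interval (a superposition-consistent steady-state
#' AUC_inf); the plain interval AUC is always reported alongside.
#'
#' @param time_h sampling times, hours
#' @param conc_ug_mL concentrations, ug/mL; non-negative
#' @param dose_times_h administration times, hours
#' @param tau_h dosing interval for multiple-dose metrics, hours, or `NULL`
#' @param ae_fraction optional fraction of the dose recovered unchanged in
#'   urine (from the simulation urine sink), carried through to the result
#' @return an object of class `pk_metrics`: `auc_tau`, `auc_inf` (ug h/mL),
#'   `cmax` (ug/mL), `tmax` (h), `lambda_z` (1/h), `ae_fraction`, and the
#'   `lambda_z` fit diagnostics
#' @export
pk_metrics <- function(time_h, conc_ug_mL, dose_times_h = 0, tau_h = NULL,
                       ae_fraction = NA_real_) {
  if (length(time_h) < 3)
    stop("at least 3 samples are required", call. = FALSE)
  if (any(conc_ug_mL < 0)) stop("negative concentrations", call. = FALSE)
  ord <- order(time_h)
  time_h <- time_h[ord]; conc_ug_mL <- conc_ug_mL[ord]
  last_dose <- max(dose_times_h[dose_times_h <= max(time_h)])

  post <- time_h >= last_dose
  tp <- time_h[post]; cp <- conc_ug_mL[post]
  cmax <- max(cp)
  tmax <- tp[which.max(cp)] - last_dose

  if (is.null(tau_h)) {
    auc_tau <- auc_linlog(tp, cp)
    lz <- lambda_z(tp, cp)
    c_last <- rev(cp[cp > 0])[1]
    auc_inf <- if (lz$estimable) auc_tau + c_last / lz$lambda_z else
      NA_real_
  } else {
    t_end <- last_dose + tau_h
    if (max(time_h) < t_end)
      stop("profile does not cover the final dosing interval", call. = FALSE)
    within <- tp <= t_end
    tt <- c(tp[within], t_end)
    cc <- c(cp[within], interp_conc(tp, cp, t_end))
    dup <- duplicated(tt)
    auc_tau <- auc_linlog(tt[!dup], cc[!dup])
    cmax <- max(cc)
    tmax <- tt[which.max(cc)] - last_dose
    lz <- lambda_z(tp, cp)
    c_tau <- interp_conc(tp, cp, t_end)
    auc_inf <- if (lz$estimable) auc_tau + c_tau / lz$lambda_z else
      NA_real_
  }
  structure(
    list(auc_tau = auc_tau, auc_inf = auc_inf, cmax = cmax, tmax = tmax,
         lambda_z = lz$lambda_z, lambda_z_n = lz$n_points,
         lambda_z_adj_r2 = lz$adj_r2, ae_fraction = ae_fraction),
    class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf(
    "<pk_metrics> AUC_tau %.4g ug.h/mL | AUC_inf %.4g ug.h/mL | Cmax %.4g ug/mL | tmax %.3g h\n",
    x$auc_tau, x$auc_inf, x$cmax, x$tmax))
  if (is.finite(x$ae_fraction))
    cat(sprintf("  urinary fraction of unchanged drug %.3f\n",
                x$ae_fraction))
  invisible(x)
}

#' PK metrics of the victim drug from a simulation
#'
#' Convenience wrapper: extracts the venous plasma profile and urine sink
#' and computes [pk_metrics()] over the final dosing interval (multi-dose)
#' or from the single dose.
#'
#' @param sim a `pbpk_simulation`
#' @param drug drug name within the simulation
#' @return a `pk_metrics` object
#' @export
sim_pk_metrics <- function(sim, drug = "victim") {
  stopifnot(inherits(sim, "pbpk_simulation"))
  pr <- plasma_conc(sim, drug)
  i <- match(drug, sim$model$drug_names)
  d <- sim$doses[sim$doses$drug == i, , drop = FALSE]
  dose_times_h <- minutes_to_hours(d$time)
  tau_h <- if (nrow(d) > 1) {
    iv <- diff(sort(dose_times_h))
    iv[length(iv)]
  } else NULL
  ae <- compartment_amount(sim, "urine", drug)
  ae_frac <- ae[length(ae)] / sim$dosed[i]
  pk_metrics(pr$time_h, pr$conc_ug_mL, dose_times_h, tau_h,
             ae_fraction = ae_frac)
}
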