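# Synthetic "observed" PK studies: subject-level profiles simulated from
# the PBPK model with lognormal between-subject variability (BSV) on the
# parameters the model calibration touches (hepatic clearance, lumped
# rest-of-body partitioning, absorption rate), allometric weight scaling
# of the physiology, and proportional-lognormal residual error.  The
# generator exists so the evaluation metrics and parameter-recovery
# workflow run with no external data; it emulates the statistical
# structure of sparse/rich clinical PK datasets, not any particular study.

#' Synthetic study specification
#'
#' @param n_subjects number of virtual subjects
#' @param weight_range_kg min/max body weight (uniform draw); volumes scale
#'   linearly, flows and GFR with weight^0.75
#' @param bsv_cv lognormal coefficient of variation per parameter; named
#'   entries `hepatic_cl`, `rest_of_body_kp`, `absorption_rate` (mean-1
#'   multipliers)
#' @param residual_sd proportional residual error: sd of the lognormal
#'   multiplicative error on the log scale
#' @param sampling_times_h observation times, hours after first dose
#' @param seed integer seed; a fixed seed makes the output bit-reproducible
#' @return a list of class `synthetic_study_spec`
#' @export
synthetic_study_spec <- function(n_subjects = 12,
                                 weight_range_kg = c(55, 90),
                                 bsv_cv = c(hepatic_cl = 0.25,
                                            rest_of_body_kp = 0.25,
                                            absorption_rate = 0.25),
                                 residual_sd = 0.2,
                                 sampling_times_h = c(0.5, 1, 1.5, 2, 3, 4,
                                                      6, 8, 12, 16, 24),
                                 seed = 1L) {
  stopifnot(n_subjects >= 1, length(weight_range_kg) == 2,
            all(weight_range_kg > 0),
            weight_range_kg[2] >= weight_range_kg[1],
            all(bsv_cv >= 0), residual_sd >= 0,
            length(sampling_times_h) >= 3)
  structure(
    list(n_subjects = as.integer(n_subjects),
         weight_range_kg = weight_range_kg, bsv_cv = bsv_cv,
         residual_sd = residual_sd, sampling_times_h = sampling_times_h,
         seed = as.integer(seed)),
    class = "synthetic_study_spec")
}

# mean-1 lognormal multipliers for a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

apply_subject_parameters <- function(compound, physiology, weight,
                                     cl_mult, kp_mult, ka_mult) {
  phys <- scale_physiology(physiology, weight)
  cmp <- compound
  cmp$clearance$hepatic_plasma_cl <-
    cmp$clearance$hepatic_plasma_cl * cl_mult
  cmp$clearance$hepatic_cl_multiple_dose <-
    cmp$clearance$hepatic_cl_multiple_dose * cl_mult
  cmp$intestinal_permeability <- cmp$intestinal_permeability * ka_mult
  base_kp <- compound_partitions(cmp, phys)
  kp <- as.numeric(base_kp)
  names(kp) <- names(base_kp)
  kp["rest"] <- kp["rest"] * kp_mult
  cmp$partition_overrides <- kp
  cmp$kp_scale <- 1
  list(compound = cmp, physiology = phys)
}

#' Generate a synthetic observed PK study
#'
#' Per subject: draw weight and lognormal parameter multipliers, simulate
#' the individual, sample at the specified times, and apply proportional
#' lognormal residual error.  Identical parameter draws (e.g. all-zero
#' BSV) share one simulation.  The arm-level mean profile and the
#' noise-free model prediction of the reference individual are returned
#' alongside the observations.
#'
#' @param spec a [synthetic_study_spec()]
#' @param compound victim [compound_model()]
#' @param reg a [regimen()]
#' @param physiology reference `pbpk_physiology`
#' @param arm_id arm label carried into the output table
#' @param options solver options
#' @return a list of class `synthetic_study`: `observations` (tidy
#'   data.frame `subject_id`, `time_h`, `conc_ug_per_mL`, `dose_mg`,
#'   `arm_id`), `subjects` (drawn parameters), `mean_profile`, and
#'   `reference_prediction`
#' @export
generate_study <- function(spec, compound = builtin_linezolid(),
                           reg = regimen("oral", dose_mg = 600),
                           physiology = default_physiology(),
                           arm_id = "arm1", options = sim_options()) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  n <- spec$n_subjects
  t_end <- max(spec$sampling_times_h) + 1
  cv <- function(p) if (is.na(spec$bsv_cv[p])) 0 else spec$bsv_cv[[p]]
  subjects <- with_local_seed(spec$seed, {
    df <- data.frame(
      subject_id = seq_len(n),
      weight = runif(n, spec$weight_range_kg[1], spec$weight_range_kg[2]),
      cl_mult = rlnorm_cv(n, cv("hepatic_cl")),
      kp_mult = rlnorm_cv(n, cv("rest_of_body_kp")),
      ka_mult = rlnorm_cv(n, cv("absorption_rate")))
    df$residual <- replicate(n, exp(rnorm(length(spec$sampling_times_h),
                                          0, spec$residual_sd)),
                             simplify = FALSE)
    df
  })
  dose_mg <- if (is.null(reg$dose_mg))
    reg$dose_mg_per_kg * physiology$body_weight else reg$dose_mg

  key <- sprintf("%.12g|%.12g|%.12g|%.12g", subjects$weight,
                 subjects$cl_mult, subjects$kp_mult, subjects$ka_mult)
  sims <- new.env()
  predict_subject <- function(i) {
    k <- key[i]
    if (is.null(sims[[k]])) {
      sp <- apply_subject_parameters(compound, physiology,
                                     subjects$weight[i],
                                     subjects$cl_mult[i],
                                     subjects$kp_mult[i],
                                     subjects$ka_mult[i])
      sim <- run_simulation(sp$compound, reg, sp$physiology,
                            t_end_h = t_end, options = options)
      pr <- plasma_conc(sim)
      sims[[k]] <- approx(pr$time_h, pr$conc_ug_mL,
                          xout = spec$sampling_times_h, rule = 2)$y
    }
    sims[[k]]
  }
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    pred <- predict_subject(i)
    data.frame(subject_id = i, time_h = spec$sampling_times_h,
               conc_ug_per_mL = pred * subjects$residual[[i]],
               predicted_ug_per_mL = pred,
               dose_mg = dose_mg, arm_id = arm_id)
  }))

  ref_sim <- run_simulation(compound, reg, physiology, t_end_h = t_end,
                            options = options)
  ref_pr <- plasma_conc(ref_sim)
  reference <- data.frame(
    time_h = spec$sampling_times_h,
    conc_ug_per_mL = approx(ref_pr$time_h, ref_pr$conc_ug_mL,
                            xout = spec$sampling_times_h, rule = 2)$y)
  mean_profile <- aggregate(conc_ug_per_mL ~ time_h, data = obs, FUN = mean)

  structure(
    list(observations = obs, subjects = subjects,
         mean_profile = mean_profile, reference_prediction = reference,
         spec = spec, regimen = reg, arm_id = arm_id),
    class = "synthetic_study")
}

#' Recover model parameters from a synthetic study
#'
#' Least-squares fit of log observed concentrations against the model
#' prediction, re-simulating the reference individual with a scaled
#' parameter.  Currently the free parameter the calibration workflow
#' optimizes is the hepatic plasma clearance.
#'
#' @param study a [generate_study()] result (or a compatible tidy table
#'   with `time_h` and `conc_ug_per_mL`)
#' @param free_params character vector of parameters to fit; must be
#'   non-empty and a subset of `"hepatic_cl"`
#' @param compound victim model holding the starting values
#' @param physiology reference physiology
#' @param bounds multiplier search interval around the starting value
#' @param options solver options
#' @param tol optimizer tolerance on the multiplier
#' @return a list: `estimates` (named, mL/min/kg), `multiplier`,
#'   `objective` (residual sum of squares in log space), `converged`
#' @export
recover_parameters <- function(study, free_params = c("hepatic_cl"),
                               compound = builtin_linezolid(),
                               physiology = default_physiology(),
                               bounds = c(0.25, 4), options = sim_options(),
                               tol = 1e-4) {
  if (length(free_params) == 0)
    stop("nothing to fit: free_params is empty", call. = FALSE)
  if (!all(free_params %in% "hepatic_cl"))
    stop("unsupported free parameter(s): ",
         paste(setdiff(free_params, "hepatic_cl"), collapse = ", "),
         call. = FALSE)
  obs <- if (inherits(study, "synthetic_study")) study$observations
         else study
  reg <- if (inherits(study, "synthetic_study")) study$regimen
         else attr(study, "regimen")
  if (is.null(reg))
    stop("study carries no regimen information", call. = FALSE)
  keep <- obs$conc_ug_per_mL > 0
  obs <- obs[keep, , drop = FALSE]
  t_end <- max(obs$time_h) + 1

  objective <- function(mult) {
    cmp <- compound
    cmp$clearance$hepatic_plasma_cl <-
      cmp$clearance$hepatic_plasma_cl * mult
    cmp$clearance$hepatic_cl_multiple_dose <-
      cmp$clearance$hepatic_cl_multiple_dose * mult
    sim <- run_simulation(cmp, reg, physiology, t_end_h = t_end,
                          options = options)
    pr <- plasma_conc(sim)
    pred <- approx(pr$time_h, pr$conc_ug_mL, xout = obs$time_h,
                   rule = 2)$y
    if (any(pred <= 0)) return(1e10)
    sum((log(obs$conc_ug_per_mL) - log(pred))^2)
  }
  fit <- optimize(objective, interval = bounds, tol = tol)
  mult <- fit$minimum
  if (min(abs(mult - bounds)) < 1e-3)
    stop("parameter recovery did not converge (estimate at search bound)",
         call. = FALSE)
  list(
    estimates = c(hepatic_cl =
                    compound$clearance$hepatic_plasma_cl * mult),
    multiplier = mult, objective = fit$objective, converged = TRUE)
}
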