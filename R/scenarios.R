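# Pre-registered experiment runner: monotherapy, standard-dose DDI under
# the ABCB1-only and combined ABCB1+ABCG2 mechanism hypotheses, the
# high-dose perpetrator sweep, and the published alternative interaction
# parameter sets for sensitivity analysis.
#
# Design template shared by all arms: the perpetrator (rifampin) is given
# once daily for 7 pre-treatment days, the victim (linezolid, 600 mg BID)
# starts on day 8 alongside continued perpetrator dosing, and the victim
# profile is read out on day 14 (final 12-h interval, with a 48-h
# follow-up for the terminal slope).

#' Scenario specification
#'
#' @param id scenario identifier
#' @param victim_regimen a [regimen()] for the victim
#' @param perpetrator_regimen a [regimen()] for the perpetrator, or `NULL`
#'   for monotherapy
#' @param mechanism_flags see [build_pbpk_model()]
#' @param parameter_set `"base"`, `"nilles"` or `"asaumi"` interaction
#'   parameter set (see [sensitivity_sets()])
#' @param description free-text description
#' @return an object of class `ddi_scenario`
#' @export
scenario_spec <- function(id, victim_regimen, perpetrator_regimen = NULL,
                          mechanism_flags = default_mechanism_flags(),
                          parameter_set = "base", description = "") {
  parameter_set <- match.arg(parameter_set, c("base", "nilles", "asaumi"))
  stopifnot(inherits(victim_regimen, "pbpk_regimen"))
  if (!is.null(perpetrator_regimen))
    stopifnot(inherits(perpetrator_regimen, "pbpk_regimen"))
  structure(
    list(id = id, victim_regimen = victim_regimen,
         perpetrator_regimen = perpetrator_regimen,
         mechanism_flags = mechanism_flags, parameter_set = parameter_set,
         description = description),
    class = "ddi_scenario")
}

std_victim_regimen <- function() {
  regimen("oral", dose_mg = 600, n_doses = 14, interval_h = 12,
          start_time_h = 168)
}

std_perp_regimen <- function(dose_mg = 600, dose_mg_per_kg = NULL) {
  regimen("oral", dose_mg = dose_mg, dose_mg_per_kg = dose_mg_per_kg,
          n_doses = 14, interval_h = 24, start_time_h = 0)
}

#' Shipped scenario table
#'
#' Monotherapy, the two standard-dose DDI mechanism hypotheses (perpetrator
#' 600 mg QD), the sensitivity parameter sets, and the dose sweep at
#' 10-40 mg/kg/day.
#'
#' @return a named list of [scenario_spec()] objects
#' @export
builtin_scenarios <- function() {
  abcb1_only <- list(abcb1_induction = TRUE, abcb1_inhibition = TRUE,
                     abcg2_inhibition = FALSE, abcg2_static_fold = FALSE)
  sc <- list(
    scenario_spec("linezolid_monotherapy", std_victim_regimen(),
                  description = "victim 600 mg BID days 8-14, no perpetrator"),
    scenario_spec("ddi_standard_abcb1", std_victim_regimen(),
                  std_perp_regimen(600), mechanism_flags = abcb1_only,
                  description = "ABCB1-mediated interaction only"),
    scenario_spec("ddi_standard_combined", std_victim_regimen(),
                  std_perp_regimen(600),
                  description = "combined ABCB1 + ABCG2 interaction"),
    scenario_spec("ddi_standard_combined_nilles", std_victim_regimen(),
                  std_perp_regimen(600), parameter_set = "nilles",
                  description = "combined interaction, alternative in-vitro set"),
    scenario_spec("ddi_standard_combined_asaumi", std_victim_regimen(),
                  std_perp_regimen(600), parameter_set = "asaumi",
                  description = "combined interaction, alternative in-vitro set"))
  for (d in c(10, 20, 25, 30, 35, 40))
    sc[[length(sc) + 1L]] <- scenario_spec(
      sprintf("highdose_%d", d), std_victim_regimen(),
      std_perp_regimen(dose_mg = NULL, dose_mg_per_kg = d),
      description = sprintf("combined interaction, perpetrator %d mg/kg QD", d))
  names(sc) <- vapply(sc, `[[`, character(1), "id")
  sc
}

#' Published alternative interaction parameter sets
#'
#' Two published in-vitro characterizations of the perpetrator's ABCB1
#' induction/inhibition used for sensitivity analysis: the Nilles set
#' (Emax 5.1 after 96 h exposure — the default — or 7 after 120 h; EC50
#' 1 uM; Ki 12.9 uM) and the Asaumi set (Emax 4, EC50 0.0639 uM, Ki
#' 0.488 uM).
#'
#' @param nilles_variant `"96h"` (Emax 5.1, default) or `"120h"` (Emax 7)
#' @return a named list of override lists with `emax`, `ec50`, `ki`
#' @export
sensitivity_sets <- function(nilles_variant = c("96h", "120h")) {
  nilles_variant <- match.arg(nilles_variant)
  list(
    nilles = list(emax = if (nilles_variant == "96h") 5.1 else 7,
                  ec50 = 1, ki = 12.9),
    asaumi = list(emax = 4, ec50 = 0.0639, ki = 0.488))
}

#' Apply an interaction parameter override set to a perpetrator model
#'
#' Replaces the ABCB1 induction Emax/EC50 and the ABCB1 inhibition Ki;
#' all other entries (ABCG2, auto-induction) are untouched.  The input
#' model is not modified (`"base"` returns it unchanged).
#'
#' @param perpetrator a perpetrator [compound_model()]
#' @param set `"base"`, `"nilles"`, `"asaumi"`, or an override list with
#'   `emax`, `ec50`, `ki`
#' @param ... passed to [sensitivity_sets()]
#' @return the (possibly modified) compound model
#' @export
apply_interaction_overrides <- function(perpetrator, set = "base", ...) {
  if (is.character(set)) {
    if (set == "base") return(perpetrator)
    set <- sensitivity_sets(...)[[match.arg(set, c("nilles", "asaumi"))]]
  }
  perpetrator$interactions <- lapply(perpetrator$interactions, function(e) {
    if (e$applies_to == "victim" && e$target == "ABCB1") {
      if (e$mechanism == "induction") {
        e$emax <- set$emax; e$ec50 <- set$ec50
      } else if (e$mechanism == "competitive_inhibition") {
        e$ki <- set$ki
      }
    }
    e
  })
  perpetrator
}

#' Run a DDI scenario
#'
#' Runs matched simulations with and without the perpetrator at identical
#' solver settings and returns exposure metrics and DDI ratios.  With all
#' interaction mechanisms disabled (or no perpetrator regimen) the
#' co-administration arm reduces to the victim-only system, so the DDI
#' ratios are exactly 1.
#'
#' @param spec a [scenario_spec()]
#' @param victim victim [compound_model()] (default built-in linezolid)
#' @param perpetrator perpetrator [compound_model()] (default built-in
#'   rifampin); the scenario's parameter set is applied on top
#' @param physiology a `pbpk_physiology`
#' @param options a [sim_options()] list
#' @param keep_profiles keep the full simulations in the result
#' @return a list of class `scenario_result`: `metrics_with`,
#'   `metrics_without` (both [pk_metrics()]), `ddi_auc_ratio`,
#'   `ddi_cmax_ratio` (on the interval AUC), `ddi_auc_inf_ratio`, and the
#'   simulations if requested
#' @export
run_scenario <- function(spec, victim = builtin_linezolid(),
                         perpetrator = builtin_rifampin(),
                         physiology = default_physiology(),
                         options = sim_options(followup_h = 36),
                         keep_profiles = FALSE) {
  stopifnot(inherits(spec, "ddi_scenario"))
  on_fail <- function(e)
    stop(sprintf("scenario '%s': %s", spec$id, conditionMessage(e)),
         call. = FALSE)
  any_mech <- any(unlist(spec$mechanism_flags))
  sim_without <- tryCatch(
    run_simulation(victim, spec$victim_regimen, physiology,
                   options = options),
    error = on_fail)
  if (is.null(spec$perpetrator_regimen) || !any_mech) {
    sim_with <- sim_without
  } else {
    perp <- apply_interaction_overrides(perpetrator, spec$parameter_set)
    sim_with <- tryCatch(
      run_simulation(victim, spec$victim_regimen, physiology,
                     perpetrator = perp,
                     perpetrator_regimen = spec$perpetrator_regimen,
                     mechanism_flags = spec$mechanism_flags,
                     options = options),
      error = on_fail)
  }
  m1 <- sim_pk_metrics(sim_with)
  m0 <- sim_pk_metrics(sim_without)
  ratios <- ddi_ratio(m1, m0, auc = "auc_tau")
  res <- list(spec = spec, metrics_with = m1, metrics_without = m0,
              ddi_auc_ratio = ratios$ddi_auc_ratio,
              ddi_cmax_ratio = ratios$ddi_cmax_ratio,
              ddi_auc_inf_ratio = m1$auc_inf / m0$auc_inf)
  if (keep_profiles) res[c("sim_with", "sim_without")] <-
    list(sim_with, sim_without)
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$spec$id, "\n")
  cat(sprintf("  without perpetrator: AUC_tau %.4g, AUC_inf %.4g, Cmax %.4g\n",
              x$metrics_without$auc_tau, x$metrics_without$auc_inf,
              x$metrics_without$cmax))
  cat(sprintf("  with perpetrator:    AUC_tau %.4g, AUC_inf %.4g, Cmax %.4g\n",
              x$metrics_with$auc_tau, x$metrics_with$auc_inf,
              x$metrics_with$cmax))
  cat(sprintf("  DDI ratios: AUC %.3f (interval) / %.3f (inf), Cmax %.3f\n",
              x$ddi_auc_ratio, x$ddi_auc_inf_ratio, x$ddi_cmax_ratio))
  invisible(x)
}

#' One-at-a-time Kcat sensitivity of victim exposure
#'
#' Perturbs each transporter's Kcat by +100% (doubling) in turn and
#' reports the relative change in single-dose victim AUC and Cmax, plus
#' the ratio of the ABCB1 to the ABCG2 effect magnitude (the dominance of
#' ABCB1 in victim disposition).
#'
#' @param victim victim [compound_model()]
#' @param physiology a `pbpk_physiology`
#' @param dose_mg single oral dose for the probe simulation
#' @param options solver options
#' @return data.frame with one row per transporter: `d_auc_rel`,
#'   `d_cmax_rel`; attribute `abcb1_over_abcg2` carries the AUC effect
#'   magnitude ratio
#' @export
kcat_sensitivity <- function(victim = builtin_linezolid(),
                             physiology = default_physiology(),
                             dose_mg = 600,
                             options = sim_options(rtol = 1e-7,
                                                   atol = 1e-9)) {
  reg <- regimen("oral", dose_mg = dose_mg, n_doses = 1)
  base <- sim_pk_metrics(run_simulation(victim, reg, physiology,
                                        t_end_h = 48, options = options))
  rows <- lapply(names(victim$transporters), function(id) {
    mod <- victim
    mod$transporters[[id]]$kcat <- 2 * mod$transporters[[id]]$kcat
    m <- sim_pk_metrics(run_simulation(mod, reg, physiology, t_end_h = 48,
                                       options = options))
    data.frame(transporter = id,
               d_auc_rel = (m$auc_inf - base$auc_inf) / base$auc_inf,
               d_cmax_rel = (m$cmax - base$cmax) / base$cmax)
  })
  out <- do.call(rbind, rows)
  b1 <- abs(out$d_auc_rel[out$transporter == "ABCB1"])
  g2 <- abs(out$d_auc_rel[out$transporter == "ABCG2"])
  attr(out, "abcb1_over_abcg2") <- if (length(b1) && length(g2)) b1 / g2
  else NA_real_
  out
}

#' Percent AUC reduction of a DDI arm relative to monotherapy
#'
#' @param auc_mono monotherapy exposure
#' @param auc_ddi co-administration exposure
#' @return percent reduction, `100 x (1 - ddi/mono)`
#' @export
percent_auc_reduction <- function(auc_mono, auc_ddi) {
  if (auc_mono <= 0) stop("monotherapy AUC must be > 0", call. = FALSE)
  100 * (auc_mono - auc_ddi) / auc_mono
}
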