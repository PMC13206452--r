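# Perpetrator effects on victim transporters: induction turnover dynamics,
# competitive inhibition via apparent-Km scaling, and static expression
# fold-changes.  The turnover state is expressed as a fraction of baseline,
# so the pre-induction steady state is 1 and the baseline synthesis rate
# equals the degradation constant.

#' Apparent transporter synthesis rate under induction
#'
#' `Rsyn_app = Rsyn x (1 + Emax x I / (EC50 + I))`: monotone increasing in
#' the free inducer concentration and bounded by `Rsyn x (1 + Emax)`.
#'
#' @param rsyn baseline synthesis rate (normalized units)
#' @param emax maximum induction effect, unitless >= 0
#' @param ec50 inducer concentration at half-maximal effect, umol/L > 0
#' @param inducer_free_conc free inducer concentration, umol/L >= 0
#' @return the apparent synthesis rate
#' @export
synthesis_rate <- function(rsyn, emax, ec50, inducer_free_conc) {
  if (any(ec50 <= 0)) stop("ec50 must be > 0", call. = FALSE)
  if (any(inducer_free_conc < 0))
    stop("inducer concentration must be >= 0", call. = FALSE)
  rsyn * (1 + emax * inducer_free_conc / (ec50 + inducer_free_conc))
}

#' Steady-state expression under constant induction pressure
#'
#' The linear turnover ODE `dE/dt = Rsyn_app - Kdeg x E` with `Rsyn = Kdeg`
#' (normalized baseline) settles at `E = 1 + Emax x I / (EC50 + I)`.
#'
#' @inheritParams synthesis_rate
#' @return steady-state expression as a fraction of baseline
#' @export
expression_steady_state <- function(emax, ec50, inducer_free_conc) {
  synthesis_rate(1, emax, ec50, inducer_free_conc)
}

#' Induction turnover state
#'
#' Expression state for one (organ, transporter) pair as a fraction of
#' baseline.  The default degradation half-life of 36 h is a typical
#' intestinal ABC-transporter turnover; with a 7-day perpetrator
#' pre-treatment (> 4 half-lives) induction is essentially at steady state.
#'
#' @param kdeg first-order degradation rate constant, 1/min
#' @param emax,ec50 induction parameters (see [synthesis_rate()])
#' @param expression_state initial expression (fraction of baseline)
#' @return an object of class `induction_state`
#' @export
induction_state <- function(kdeg = log(2) / 2160, emax = 0, ec50 = 1,
                            expression_state = 1) {
  stopifnot(kdeg > 0, expression_state > 0)
  structure(list(expression_state = expression_state, kdeg = kdeg,
                 rsyn_baseline = kdeg, emax = emax, ec50 = ec50),
            class = "induction_state")
}

#' Advance an induction state over a time step
#'
#' Integrates the turnover ODE exactly for a constant free inducer
#' concentration over the step:
#' `E(t+dt) = Ess + (E(t) - Ess) exp(-Kdeg dt)` with
#' `Ess = 1 + Emax I/(EC50 + I)`.  In whole-body simulations the same ODE
#' is co-integrated with the mass balance; this stepper serves unit-level
#' use and stiff-limit checks.
#'
#' @param state an [induction_state()]
#' @param inducer_free_conc free inducer concentration over the step, umol/L
#' @param dt step length, min, > 0
#' @return the updated `induction_state`
#' @export
step_expression <- function(state, inducer_free_conc, dt) {
  stopifnot(inherits(state, "induction_state"), dt > 0)
  ess <- expression_steady_state(state$emax, state$ec50, inducer_free_conc)
  state$expression_state <- ess +
    (state$expression_state - ess) * exp(-state$kdeg * dt)
  state
}

#' Apparent Michaelis constant under competitive inhibition
#'
#' `Km_app = Km x (1 + I/Ki)`: linear in the free inhibitor concentration
#' and never below Km.
#'
#' @param km Michaelis constant without inhibitor, umol/L > 0
#' @param inhibitor_free_conc free inhibitor concentration, umol/L >= 0
#' @param ki inhibition constant, umol/L > 0
#' @return the apparent Km, umol/L
#' @export
apparent_km <- function(km, inhibitor_free_conc, ki) {
  if (any(km <= 0)) stop("km must be > 0", call. = FALSE)
  if (any(ki <= 0)) stop("ki must be > 0", call. = FALSE)
  if (any(inhibitor_free_conc < 0))
    stop("inhibitor concentration must be >= 0", call. = FALSE)
  km * (1 + inhibitor_free_conc / ki)
}

#' Apply a static expression fold-change
#'
#' Multiplies the baseline expression of the named transporter by a fixed
#' fold.  In whole-body simulations the fold is active for the duration of
#' perpetrator dosing (the averaged expression change developing over the
#' pre-treatment period).
#'
#' @param state an [induction_state()]
#' @param transporter transporter id the state belongs to
#' @param fold expression fold-change, > 0
#' @param target transporter id the fold applies to; states of other
#'   transporters are returned unchanged
#' @return the (possibly scaled) `induction_state`
#' @export
apply_static_fold <- function(state, transporter, fold, target = transporter) {
  stopifnot(inherits(state, "induction_state"))
  if (!is.finite(fold) || fold <= 0) stop("fold must be > 0", call. = FALSE)
  if (!target %in% INTERACTION_TARGETS)
    stop("unknown transporter: ", target, call. = FALSE)
  if (identical(transporter, target))
    state$expression_state <- state$expression_state * fold
  state
}
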