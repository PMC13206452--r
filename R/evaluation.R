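# Model-qualification statistics: mean relative deviation (MRD) for
# concentrations, geometric mean fold error (GMFE) for PK parameters,
# predicted/observed and DDI exposure ratios, average fold error (AFE),
# root mean square error (RMSE), and the 1.5-/2-fold classification.

check_positive_pairs <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  keep <- is.finite(predicted) & is.finite(observed) &
    predicted > 0 & observed > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 1)
    stop("no positive predicted/observed pairs", call. = FALSE)
  if (n_dropped > 0)
    message(n_dropped, " non-positive pair(s) excluded from log-domain metric")
  list(predicted = predicted[keep], observed = observed[keep],
       n_dropped = n_dropped)
}

#' Mean relative deviation of predicted concentrations
#'
#' `MRD = 10^sqrt(mean((log10 Cpred - log10 Cobs)^2))`: the root-mean-square
#' deviation on the log10 scale, exponentiated back to a fold scale (>= 1).
#' Values <= 2 indicate adequate predictive performance.
#'
#' @param predicted predicted concentrations, > 0
#' @param observed observed concentrations, > 0
#' @return the MRD (unitless fold scale)
#' @export
mrd <- function(predicted, observed) {
  p <- check_positive_pairs(predicted, observed)
  10^sqrt(mean((log10(p$predicted) - log10(p$observed))^2))
}

#' Geometric mean fold error of PK parameters
#'
#' `GMFE = 10^mean(|log10 PKpred - log10 PKobs|)`: symmetric in over- and
#' under-prediction, >= 1.
#'
#' @inheritParams mrd
#' @return the GMFE (unitless fold scale)
#' @export
gmfe <- function(predicted, observed) {
  p <- check_positive_pairs(predicted, observed)
  10^mean(abs(log10(p$predicted) - log10(p$observed)))
}

#' DDI exposure ratios
#'
#' Exposure with the perpetrator divided by exposure without; a ratio < 1
#' indicates net induction.
#'
#' @param with_perp `pk_metrics` (or list with `auc_tau`/`auc_inf`, `cmax`)
#'   for the co-administration arm
#' @param without_perp matching metrics for the monotherapy arm
#' @param auc which AUC to ratio (`"auc_tau"` or `"auc_inf"`)
#' @return list with `ddi_auc_ratio` and `ddi_cmax_ratio`
#' @export
ddi_ratio <- function(with_perp, without_perp, auc = "auc_tau") {
  a1 <- with_perp[[auc]]; a0 <- without_perp[[auc]]
  c1 <- with_perp$cmax; c0 <- without_perp$cmax
  if (any(c(a1, a0, c1, c0) <= 0))
    stop("exposures must be positive", call. = FALSE)
  list(ddi_auc_ratio = a1 / a0, ddi_cmax_ratio = c1 / c0)
}

#' Average fold error of predicted vs observed DDI ratios
#'
#' `AFE = 10^|mean(log10(pred/obs))|`: the bias of the DDI prediction on a
#' fold scale, >= 1.
#'
#' @param pred_ratios predicted DDI ratios, > 0
#' @param obs_ratios observed DDI ratios, > 0
#' @return the AFE
#' @export
afe <- function(pred_ratios, obs_ratios) {
  p <- check_positive_pairs(pred_ratios, obs_ratios)
  10^abs(mean(log10(p$predicted) - log10(p$observed)))
}

#' Root mean square error of predicted vs observed DDI ratios
#'
#' `RMSE = sqrt(mean((pred - obs)^2))` on the ratio scale (precision of the
#' DDI prediction).
#'
#' @inheritParams afe
#' @return the RMSE
#' @export
rmse <- function(pred_ratios, obs_ratios) {
  if (length(pred_ratios) != length(obs_ratios))
    stop("predicted and observed must have equal length", call. = FALSE)
  sqrt(mean((pred_ratios - obs_ratios)^2))
}

#' Fold-error classification of predictions
#'
#' A prediction within two-fold of the observation is conventionally
#' acceptable; within 1.5-fold is good.  The fold error per pair is
#' `max(pred/obs, obs/pred)`.
#'
#' @inheritParams mrd
#' @return list with the per-pair logicals `within_1_5` and `within_2`
#'   and the aggregated `fraction_within_1_5`, `fraction_within_2`
#' @export
fold_classification <- function(predicted, observed) {
  p <- check_positive_pairs(predicted, observed)
  fe <- pmax(p$predicted / p$observed, p$observed / p$predicted)
  list(within_1_5 = fe <= 1.5, within_2 = fe <= 2,
       fraction_within_1_5 = mean(fe <= 1.5),
       fraction_within_2 = mean(fe <= 2))
}

#' Evaluation report over a paired predicted/observed table
#'
#' Computes MRD over concentration pairs and, per PK quantity, GMFE, AFE
#' (for ratio quantities), RMSE and fold-error fractions.
#'
#' @param pairs data.frame with columns `arm_id`, `quantity` (one of
#'   `conc`, `auc`, `cmax`, `ae`, `ddi_auc_ratio`, `ddi_cmax_ratio`),
#'   `predicted`, `observed`, and optionally `time_h`
#' @return a list of class `eval_report`
#' @export
evaluate_pairs <- function(pairs) {
  need <- c("arm_id", "quantity", "predicted", "observed")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  rep <- list(mrd = NA_real_, by_quantity = list())
  conc <- pairs[pairs$quantity == "conc", , drop = FALSE]
  if (nrow(conc)) rep$mrd <- mrd(conc$predicted, conc$observed)
  for (qt in setdiff(unique(pairs$quantity), "conc")) {
    sub <- pairs[pairs$quantity == qt, , drop = FALSE]
    fc <- fold_classification(sub$predicted, sub$observed)
    rep$by_quantity[[qt]] <- list(
      n = nrow(sub),
      gmfe = gmfe(sub$predicted, sub$observed),
      afe = if (grepl("ratio", qt)) afe(sub$predicted, sub$observed)
            else NA_real_,
      rmse = rmse(sub$predicted, sub$observed),
      fraction_within_1_5 = fc$fraction_within_1_5,
      fraction_within_2 = fc$fraction_within_2)
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  if (is.finite(x$mrd)) cat(sprintf("  MRD (concentrations): %.3f\n", x$mrd))
  for (qt in names(x$by_quantity)) {
    q <- x$by_quantity[[qt]]
    cat(sprintf(
      "  %s (n=%d): GMFE %.3f%s, RMSE %.3g, within 1.5x %.0f%%, within 2x %.0f%%\n",
      qt, q$n, q$gmfe,
      if (is.finite(q$afe)) sprintf(", AFE %.3f", q$afe) else "",
      q$rmse, 100 * q$fraction_within_1_5, 100 * q$fraction_within_2))
  }
  invisible(x)
}

#' Reference clinical DDI evaluation exposures
#'
#' The published steady-state exposures of linezolid (600 mg BID) with and
#' without standard-dose rifampin used to qualify the DDI model: the
#' observed clinical arm and the model predictions under the
#' ABCB1-mediated-only and the combined ABCB1+ABCG2 interaction
#' hypotheses.  AUC is the steady-state AUC over a 12-h dosing interval
#' (ug h/mL), Cmax in ug/mL.  DDI ratios are recomputed from these
#' exposures at full precision.
#'
#' @return a data.frame with columns `model`, `quantity`, `without_rif`,
#'   `with_rif`
#' @export
ddi_reference_exposures <- function() {
  data.frame(
    model = rep(c("observed", "abcb1_only", "combined"), each = 2),
    quantity = rep(c("auc", "cmax"), 3),
    without_rif = c(181.2, 23.0, 128.7, 18.4, 128.7, 18.4),
    with_rif = c(120.9, 17.9, 102.3, 16.1, 96.6, 15.7),
    stringsAsFactors = FALSE)
}

#' Reference high-dose exposure table
#'
#' Published model-predicted steady-state linezolid exposures (600 mg BID)
#' alone and with once-daily rifampin at 10-40 mg/kg: AUC_inf in ug h/mL
#' and Cmax in ug/mL per arm.
#'
#' @return a data.frame with columns `rifampin_mg_kg` (NA for monotherapy),
#'   `auc_inf`, `cmax`
#' @export
highdose_reference_exposures <- function() {
  data.frame(
    rifampin_mg_kg = c(NA, 10, 20, 25, 30, 35, 40),
    auc_inf = c(161.5, 113.6, 110.0, 109.2, 108.9, 108.8, 108.8),
    cmax = c(17.0, 14.9, 14.7, 14.6, 14.6, 14.5, 14.5))
}

#' Qualification statistics recomputed from the reference DDI exposures
#'
#' Recomputes, at full precision, the DDI AUC/Cmax ratios per interaction
#' hypothesis and the AFE and RMSE of each predicted ratio against the
#' observed ratio.  Ratios are formed from the printed exposures before any
#' rounding.
#'
#' @return a data.frame with one row per (model, quantity): `ratio`, `afe`,
#'   `rmse` (AFE/RMSE are NA for the observed arm)
#' @export
ddi_reference_statistics <- function() {
  ref <- ddi_reference_exposures()
  ref$ratio <- ref$with_rif / ref$without_rif
  obs <- ref[ref$model == "observed", ]
  ref$afe <- NA_real_; ref$rmse <- NA_real_
  for (r in which(ref$model != "observed")) {
    o <- obs$ratio[obs$quantity == ref$quantity[r]]
    ref$afe[r] <- afe(ref$ratio[r], o)
    ref$rmse[r] <- rmse(ref$ratio[r], o)
  }
  ref
}
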