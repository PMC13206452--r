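# Physiology: organ volumes, regional plasma flows, GFR, transporter
# expression per organ, and the absorption geometry constant.  The default
# is a 73-kg adult with textbook organ volumes and plasma flows; every value
# is user-overridable through the physiology config file.

PBPK_ORGANS <- c("gut", "portal", "liver", "kidney", "rest")
PBPK_TISSUES <- c("gut", "liver", "kidney", "rest")  # organs with a Kp

#' Default adult physiology
#'
#' A 73-kg adult.  Plasma volumes: arterial 0.9 L, venous 2.1 L, portal
#' 0.25 L.  Tissue volumes (L): gut 1.2, liver 1.8, kidney 0.31, lumped
#' rest-of-body 60.  Regional plasma flows (L/min): gut (portal inflow)
#' 0.9, hepatic artery 0.35, kidney 0.66, rest 1.35; venous return equals
#' cardiac plasma output 3.26 L/min.  GFR 0.12 L/min.  The gut lumen is a
#' 1-L virtual volume with a first-order transit to feces (default mean
#' small-intestinal residence 180 min).  `absorption_s2v` is the effective
#' (villi-amplified) absorptive surface-to-volume constant (1/cm) that
#' converts an intestinal permeability (cm/min) into a lumen absorption
#' rate constant (1/min); it was calibrated once so that an oral dose of
#' the reference victim model reaches tmax within 1-2 h with near-complete
#' absorption, and then frozen.
#'
#' Relative transporter expression factors scale each transporter's
#' reference concentration organ by organ.  Hepatic ABCB1/ABCG2 expression
#' is zero by default (no biliary efflux of the reference victim); the
#' intestinal and renal factors were calibrated once against the victim
#' model's stated disposition (urinary fraction of unchanged drug 0.30-0.40
#' after a single oral dose, steady-state exposure) and frozen, with ABCB1
#' carrying the dominant share of transporter flux.
#'
#' @param body_weight_kg body weight; volumes scale linearly and flows and
#'   GFR allometrically (power 0.75) from the 73-kg reference
#' @return an object of class `pbpk_physiology`
#' @export
default_physiology <- function(body_weight_kg = 73) {
  phys <- structure(
    list(
      body_weight = 73,
      volumes = c(lumen = 1.0, gut = 1.2, portal = 0.25, liver = 1.8,
                  kidney = 0.31, art = 0.9, ven = 2.1, rest = 60),
      flows = c(gut = 0.9, hepatic_artery = 0.35, kidney = 0.66,
                rest = 1.35),
      cardiac_output_plasma = 3.26,
      gfr = 0.12,
      absorption_s2v = 2800,
      gut_transit_time = 180,
      blood_plasma_ratio = 1,
      relative_expression = list(
        gut    = c(ABCB1 = 0.15, ABCG2 = 0.008),
        kidney = c(ABCB1 = 0.95, ABCG2 = 0.046),
        liver  = c(ABCB1 = 0, ABCG2 = 0))),
    class = "pbpk_physiology")
  phys <- scale_physiology(phys, body_weight_kg)
  validate_physiology(phys)
  phys
}

#' Validate a physiology specification
#'
#' Checks positivity of volumes, flows and GFR, the venous-return flow
#' balance (cardiac plasma output equals the sum of regional plasma flows),
#' and non-negativity of relative expression factors.
#'
#' @param phys a `pbpk_physiology`
#' @return the physiology, invisibly, or an error
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  need_v <- c("lumen", "gut", "portal", "liver", "kidney", "art", "ven",
              "rest")
  if (!all(need_v %in% names(phys$volumes)))
    stop("physiology volumes must name: ",
         paste(need_v, collapse = ", "), call. = FALSE)
  if (any(phys$volumes <= 0)) stop("all volumes must be > 0", call. = FALSE)
  need_q <- c("gut", "hepatic_artery", "kidney", "rest")
  if (!all(need_q %in% names(phys$flows)))
    stop("physiology flows must name: ",
         paste(need_q, collapse = ", "), call. = FALSE)
  if (any(phys$flows <= 0)) stop("all flows must be > 0", call. = FALSE)
  if (phys$gfr <= 0) stop("gfr must be > 0", call. = FALSE)
  if (phys$gut_transit_time <= 0)
    stop("gut_transit_time must be > 0", call. = FALSE)
  q_sum <- sum(phys$flows[need_q])
  if (abs(q_sum - phys$cardiac_output_plasma) > 1e-9 * q_sum)
    stop(sprintf(
      "flow balance violated: regional flows sum to %.6g L/min but cardiac plasma output is %.6g L/min",
      q_sum, phys$cardiac_output_plasma), call. = FALSE)
  for (org in names(phys$relative_expression)) {
    re <- phys$relative_expression[[org]]
    if (any(re < 0))
      stop("relative expression must be >= 0", call. = FALSE)
  }
  invisible(phys)
}

#' Scale a physiology to a different body weight
#'
#' Volumes scale linearly with weight; plasma flows and GFR scale
#' allometrically with weight^0.75 (a stand-in for a full anthropometric
#' model).  Expression factors, transit time and the absorption constant
#' are unchanged.
#'
#' @param phys a `pbpk_physiology`
#' @param body_weight_kg target body weight
#' @return a rescaled `pbpk_physiology`
#' @export
scale_physiology <- function(phys, body_weight_kg) {
  stopifnot(inherits(phys, "pbpk_physiology"), body_weight_kg > 0)
  r <- body_weight_kg / phys$body_weight
  phys$volumes <- phys$volumes * r
  phys$flows <- phys$flows * r^0.75
  phys$cardiac_output_plasma <- phys$cardiac_output_plasma * r^0.75
  phys$gfr <- phys$gfr * r^0.75
  phys$body_weight <- body_weight_kg
  phys
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat("<pbpk_physiology>", sprintf("%.1f kg adult", x$body_weight), "\n")
  cat("  volumes (L):",
      paste(sprintf("%s %.3g", names(x$volumes), x$volumes),
            collapse = ", "), "\n")
  cat("  plasma flows (L/min):",
      paste(sprintf("%s %.3g", names(x$flows), x$flows), collapse = ", "),
      sprintf("; GFR %.3g\n", x$gfr))
  invisible(x)
}

# expression factor lookup with 0 default
relative_expression <- function(phys, organ, transporter) {
  re <- phys$relative_expression[[organ]]
  if (is.null(re) || is.na(re[transporter])) 0 else unname(re[transporter])
}

# lumen absorption rate constant (1/min) from permeability (cm/min):
# ka = permeability x effective surface-to-volume (1/cm)
absorption_rate_constant <- function(compound, phys) {
  perm <- compound$intestinal_permeability
  if (!is.finite(perm) || perm <= 0)
    stop("compound has no positive intestinal permeability", call. = FALSE)
  perm * phys$absorption_s2v
}
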