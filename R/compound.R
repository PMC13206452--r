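# Compound models: drug-specific physicochemistry, clearances, transporter
# kinetics and perpetrator interaction entries, plus the in-vitro-to-in-vivo
# derivations linking assay intrinsic clearance to a catalytic rate constant.

TRANSPORTER_IDS <- c("ABCB1", "ABCG2")
INTERACTION_TARGETS <- c("ABCB1", "ABCG2", "OATP1B1", "AADAC")
INTERACTION_MECHANISMS <- c("induction", "competitive_inhibition", "static_fold")

#' Physicochemical properties of a compound
#'
#' @param molecular_weight g/mol, > 0
#' @param logP octanol-water log partition coefficient (unitless)
#' @param compound_type one of `"monoprotic_base"`, `"acid"`, `"neutral"`
#' @param pKa acid dissociation constant (unitless); ignored for neutral
#'   compounds
#' @param fu_plasma fraction unbound in plasma, in (0, 1]
#' @param solubility_water aqueous solubility in g/L, > 0
#' @return an object of class `pbpk_physchem`
#' @export
physchem <- function(molecular_weight, logP, compound_type = "neutral",
                     pKa = NA_real_, fu_plasma = 1, solubility_water = 1) {
  compound_type <- match.arg(compound_type,
                             c("neutral", "monoprotic_base", "acid"))
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be > 0", call. = FALSE)
  if (!(fu_plasma > 0 && fu_plasma <= 1))
    stop("fu_plasma must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(solubility_water) || solubility_water <= 0)
    stop("solubility_water must be > 0", call. = FALSE)
  if (compound_type != "neutral" && !is.finite(pKa))
    stop("pKa is required for ionizable compounds", call. = FALSE)
  structure(
    list(molecular_weight = molecular_weight, logP = logP,
         compound_type = compound_type, pKa = pKa,
         fu_plasma = fu_plasma, solubility_water = solubility_water),
    class = "pbpk_physchem")
}

#' Transporter kinetic parameters for one ABC transporter
#'
#' `kcat` is the catalytic rate constant per pmol transporter (1/min, the
#' nmol/min/pmol scale used in compound tables); `reference_concentration`
#' is the transporter concentration (umol/L tissue) in the reference organ,
#' scaled to other organs by the physiology's relative-expression factors.
#' The assay-provenance fields (`clint_assay`, `abundance_assay`) are
#' optional and record the in-vitro values a `kcat` was derived from.
#'
#' @param transporter_id `"ABCB1"` or `"ABCG2"`
#' @param kcat 1/min per pmol transporter, >= 0
#' @param km Michaelis constant, umol/L, > 0
#' @param reference_concentration umol/L, > 0
#' @param clint_assay optional assay intrinsic clearance, uL/min/mg protein
#' @param abundance_assay optional assay transporter abundance, pmol/mg protein
#' @return an object of class `pbpk_transporter`
#' @export
transporter_kinetics <- function(transporter_id, kcat, km,
                                 reference_concentration,
                                 clint_assay = NA_real_,
                                 abundance_assay = NA_real_) {
  transporter_id <- match.arg(transporter_id, TRANSPORTER_IDS)
  if (!is.numeric(kcat) || kcat < 0) stop("kcat must be >= 0", call. = FALSE)
  if (!is.numeric(km) || km <= 0) stop("km must be > 0", call. = FALSE)
  if (!is.numeric(reference_concentration) || reference_concentration <= 0)
    stop("reference_concentration must be > 0", call. = FALSE)
  structure(
    list(transporter_id = transporter_id, kcat = kcat, km = km,
         reference_concentration = reference_concentration,
         clint_assay = clint_assay, abundance_assay = abundance_assay),
    class = "pbpk_transporter")
}

#' Clearance specification
#'
#' Hepatic plasma clearance is entered per kg body weight; the multiple-dose
#' value applies to any regimen with more than one administration (steady
#' state).  `gfr_fraction` scales the glomerular filtration of unbound drug
#' and lumps net tubular reabsorption.
#'
#' @param hepatic_plasma_cl mL/min/kg, >= 0
#' @param hepatic_cl_multiple_dose mL/min/kg, >= 0 and <= single-dose value
#' @param gfr_fraction fraction of GFR available for filtration of unbound
#'   drug (default 1)
#' @return an object of class `pbpk_clearance`
#' @export
clearance_spec <- function(hepatic_plasma_cl,
                           hepatic_cl_multiple_dose = hepatic_plasma_cl,
                           gfr_fraction = 1) {
  if (hepatic_plasma_cl < 0 || hepatic_cl_multiple_dose < 0)
    stop("clearances must be >= 0", call. = FALSE)
  if (hepatic_cl_multiple_dose > hepatic_plasma_cl)
    stop("multiple-dose CL must not exceed single-dose CL", call. = FALSE)
  if (gfr_fraction < 0) stop("gfr_fraction must be >= 0", call. = FALSE)
  structure(
    list(hepatic_plasma_cl = hepatic_plasma_cl,
         hepatic_cl_multiple_dose = hepatic_cl_multiple_dose,
         gfr_fraction = gfr_fraction),
    class = "pbpk_clearance")
}

#' One perpetrator interaction entry
#'
#' @param target target transporter/enzyme id (`"ABCB1"`, `"ABCG2"`,
#'   `"OATP1B1"`, `"AADAC"`)
#' @param mechanism `"induction"`, `"competitive_inhibition"` or
#'   `"static_fold"`
#' @param emax maximum induction effect (unitless, >= 0; induction only)
#' @param ec50 inducer concentration at half-maximal effect, umol/L
#'   (induction only)
#' @param ki inhibition constant, umol/L (competitive inhibition only)
#' @param fold static expression fold-change (> 0; static_fold only)
#' @param applies_to `"victim"` for effects on a co-administered substrate's
#'   transporters, `"self_clearance"` for auto-induction of the perpetrator's
#'   own clearance pathways
#' @param clearance_fraction fraction of the perpetrator's hepatic clearance
#'   carried by this pathway (self_clearance entries only)
#' @return an object of class `pbpk_interaction`
#' @export
interaction_entry <- function(target, mechanism, emax = NA_real_,
                              ec50 = NA_real_, ki = NA_real_,
                              fold = NA_real_, applies_to = "victim",
                              clearance_fraction = NA_real_) {
  target <- match.arg(target, INTERACTION_TARGETS)
  mechanism <- match.arg(mechanism, INTERACTION_MECHANISMS)
  applies_to <- match.arg(applies_to, c("victim", "self_clearance"))
  if (mechanism == "induction") {
    if (!is.finite(emax) || emax < 0)
      stop("induction requires emax >= 0", call. = FALSE)
    if (!is.finite(ec50) || ec50 <= 0)
      stop("induction requires ec50 > 0", call. = FALSE)
  }
  if (mechanism == "competitive_inhibition" && (!is.finite(ki) || ki <= 0))
    stop("competitive inhibition requires ki > 0", call. = FALSE)
  if (mechanism == "static_fold" && (!is.finite(fold) || fold <= 0))
    stop("static_fold requires fold > 0", call. = FALSE)
  if (applies_to == "self_clearance" &&
      (!is.finite(clearance_fraction) || clearance_fraction <= 0 ||
       clearance_fraction > 1))
    stop("self_clearance entries require clearance_fraction in (0, 1]",
         call. = FALSE)
  structure(
    list(target = target, mechanism = mechanism, emax = emax, ec50 = ec50,
         ki = ki, fold = fold, applies_to = applies_to,
         clearance_fraction = clearance_fraction),
    class = "pbpk_interaction")
}

#' Assemble a compound model
#'
#' @param name compound name
#' @param physchem a [physchem()] object
#' @param clearance a [clearance_spec()] object
#' @param transporters list of [transporter_kinetics()] objects (at most one
#'   per transporter id)
#' @param interactions list of [interaction_entry()] objects (perpetrators)
#' @param intestinal_permeability cm/min; converted to a gut absorption rate
#'   constant via the physiology's effective surface-to-volume constant
#' @param organ_permeability cm/min; recorded for provenance (the reduced
#'   model is flow-limited, so this value does not enter the mass balance)
#' @param kp_scale unitless calibration factor applied to computed partition
#'   coefficients (distribution optimization knob; default 1)
#' @param partition_overrides optional named numeric vector of user-supplied
#'   tissue:plasma Kp values, overriding the computed set organ by organ
#' @return an object of class `compound_model`
#' @export
compound_model <- function(name, physchem, clearance, transporters = list(),
                           interactions = list(),
                           intestinal_permeability = NA_real_,
                           organ_permeability = NA_real_,
                           kp_scale = 1, partition_overrides = NULL) {
  stopifnot(inherits(physchem, "pbpk_physchem"),
            inherits(clearance, "pbpk_clearance"))
  ids <- vapply(transporters, function(x) x$transporter_id, character(1))
  if (anyDuplicated(ids))
    stop("at most one kinetics entry per transporter", call. = FALSE)
  names(transporters) <- ids
  for (e in interactions) stopifnot(inherits(e, "pbpk_interaction"))
  if (!is.null(partition_overrides)) {
    if (is.null(names(partition_overrides)) || any(partition_overrides <= 0))
      stop("partition_overrides must be a named vector of positive Kp",
           call. = FALSE)
  }
  if (kp_scale <= 0) stop("kp_scale must be > 0", call. = FALSE)
  structure(
    list(name = name, physchem = physchem, clearance = clearance,
         transporters = transporters, interactions = interactions,
         intestinal_permeability = intestinal_permeability,
         organ_permeability = organ_permeability,
         kp_scale = kp_scale, partition_overrides = partition_overrides),
    class = "compound_model")
}

#' @export
print.compound_model <- function(x, ...) {
  cat("<compound_model>", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol, logP %.2f, %s, fu %.2f\n",
              x$physchem$molecular_weight, x$physchem$logP,
              x$physchem$compound_type, x$physchem$fu_plasma))
  cat(sprintf("  hepatic CL %.3g (single) / %.3g (multiple) mL/min/kg, GFR fraction %.3g\n",
              x$clearance$hepatic_plasma_cl,
              x$clearance$hepatic_cl_multiple_dose,
              x$clearance$gfr_fraction))
  for (tr in x$transporters)
    cat(sprintf("  %s: Kcat %.4g /min, Km %.4g uM, ref conc %.4g uM\n",
                tr$transporter_id, tr$kcat, tr$km,
                tr$reference_concentration))
  for (e in x$interactions)
    cat(sprintf("  %s on %s (%s)%s\n", e$mechanism, e$target, e$applies_to,
                if (e$mechanism == "induction")
                  sprintf(": Emax %.4g, EC50 %.4g uM", e$emax, e$ec50)
                else if (e$mechanism == "competitive_inhibition")
                  sprintf(": Ki %.4g uM", e$ki)
                else sprintf(": fold %.4g", e$fold)))
  invisible(x)
}

#' Derive Vmax from assay intrinsic clearance
#'
#' `Vmax = CLint x Km`, with the unit reconciliation uL/min/mg x umol/L =
#' pmol/min/mg (1e-6 L x umol = pmol).
#'
#' @param clint_assay intrinsic clearance from the transport assay,
#'   uL/min/mg protein, >= 0
#' @param km Michaelis constant, umol/L, > 0
#' @return Vmax in pmol/min/mg protein
#' @examples
#' derive_vmax(16, 100)  # 1600 pmol/min/mg
#' @export
derive_vmax <- function(clint_assay, km) {
  if (any(!is.finite(clint_assay)) || any(clint_assay < 0))
    stop("clint_assay must be >= 0", call. = FALSE)
  if (any(!is.finite(km)) || any(km <= 0))
    stop("km must be > 0", call. = FALSE)
  clint_assay * km
}

#' Derive the catalytic rate constant from Vmax and transporter abundance
#'
#' `Kcat = Vmax / abundance`; full precision is returned and any rounding
#' (e.g. to two significant figures for reporting) is the caller's concern.
#'
#' @param vmax pmol/min/mg protein, >= 0
#' @param abundance transporter abundance, pmol/mg protein, > 0
#' @return Kcat in 1/min
#' @examples
#' derive_kcat(derive_vmax(16, 100), 13.18)  # 121.4 -> 120 at 2 s.f.
#' @export
derive_kcat <- function(vmax, abundance) {
  if (any(!is.finite(vmax)) || any(vmax < 0))
    stop("vmax must be >= 0", call. = FALSE)
  if (any(!is.finite(abundance)) || any(abundance <= 0))
    stop("abundance must be > 0", call. = FALSE)
  vmax / abundance
}

#' Built-in linezolid victim model
#'
#' Final calibrated parameter set for the oxazolidinone antibiotic linezolid:
#' a monoprotic weak base (pKa 1.7, essentially un-ionized at physiological
#' pH) with low protein binding (fu 0.69), linear hepatic plasma clearance
#' (0.65 mL/min/kg single dose, 0.5 mL/min/kg at steady state), glomerular
#' filtration with net tubular reabsorption (GFR fraction 0.2), and active
#' renal/intestinal efflux by ABCB1 (Kcat 72 /min, Km 51 uM, reference
#' concentration 0.077 uM) and ABCG2 (Kcat 720 /min, Km 53 uM, reference
#' concentration 0.025 uM).  Hepatic transporter expression is zero in the
#' default physiology because linezolid is not excreted unchanged in bile.
#' The distribution scale factor (`kp_scale`) was calibrated during model
#' development against steady-state exposure and terminal half-life.
#'
#' @return a [compound_model()]
#' @export
builtin_linezolid <- function() {
  compound_model(
    name = "linezolid",
    physchem = physchem(molecular_weight = 337.35, logP = 0.55,
                        compound_type = "monoprotic_base", pKa = 1.7,
                        fu_plasma = 0.69, solubility_water = 3),
    clearance = clearance_spec(hepatic_plasma_cl = 0.65,
                               hepatic_cl_multiple_dose = 0.5,
                               gfr_fraction = 0.15),
    transporters = list(
      transporter_kinetics("ABCB1", kcat = 72, km = 51,
                           reference_concentration = 0.077,
                           clint_assay = 2.1, abundance_assay = 10.3),
      transporter_kinetics("ABCG2", kcat = 720, km = 53,
                           reference_concentration = 0.025,
                           clint_assay = 16, abundance_assay = 13.18)),
    interactions = list(),
    intestinal_permeability = 9e-6,
    organ_permeability = 9e-4,
    kp_scale = 0.62)
}

#' Built-in rifampin perpetrator model
#'
#' The rifamycin antibiotic rifampin as a DDI perpetrator: induction of
#' ABCB1 expression (Emax 2.5, EC50 0.34 uM) via the turnover model,
#' competitive inhibition of ABCB1 (Ki 9.1 uM) and ABCG2 (Ki 14 uM), a
#' static 1.5-fold ABCG2 expression increase during co-administration, and
#' auto-induction of its own hepatic clearance pathways (AADAC: Emax 0.985;
#' OATP1B1-mediated uptake: Emax 0.383; EC50 0.34 uM for all).  Rifampin's
#' own PK parameters are not transporter-mediated in this reduced model:
#' disposition is hepatic clearance (with auto-induction) plus glomerular
#' filtration, with a uniform user-supplied tissue partition coefficient.
#' These literature-typical disposition values are fully user-overridable
#' through the compound config file.
#'
#' @return a [compound_model()]
#' @export
builtin_rifampin <- function() {
  compound_model(
    name = "rifampin",
    physchem = physchem(molecular_weight = 822.94, logP = 2.7,
                        compound_type = "neutral", pKa = NA_real_,
                        fu_plasma = 0.17, solubility_water = 1.4),
    clearance = clearance_spec(hepatic_plasma_cl = 1.3,
                               hepatic_cl_multiple_dose = 1.3,
                               gfr_fraction = 1),
    transporters = list(),
    interactions = list(
      interaction_entry("ABCB1", "induction", emax = 2.5, ec50 = 0.34),
      interaction_entry("ABCB1", "competitive_inhibition", ki = 9.1),
      interaction_entry("ABCG2", "competitive_inhibition", ki = 14),
      interaction_entry("ABCG2", "static_fold", fold = 1.5),
      interaction_entry("OATP1B1", "induction", emax = 0.383, ec50 = 0.34,
                        applies_to = "self_clearance",
                        clearance_fraction = 0.45),
      interaction_entry("AADAC", "induction", emax = 0.985, ec50 = 0.34,
                        applies_to = "self_clearance",
                        clearance_fraction = 0.55)),
    intestinal_permeability = 1e-5,
    organ_permeability = NA_real_,
    kp_scale = 1,
    partition_overrides = c(gut = 0.7, liver = 0.7, kidney = 0.7,
                            rest = 0.7))
}

# Internal helpers -----------------------------------------------------------

# absolute hepatic plasma clearance (L/min) for a given body weight and
# regimen multiplicity
hepatic_cl_Lmin <- function(compound, body_weight_kg, multiple_dose = FALSE) {
  per_kg <- if (multiple_dose) compound$clearance$hepatic_cl_multiple_dose
            else compound$clearance$hepatic_plasma_cl
  per_kg * body_weight_kg / 1000
}

interaction_entries <- function(compound, applies_to = "victim",
                                mechanism = NULL, target = NULL) {
  keep <- vapply(compound$interactions, function(e) {
    e$applies_to == applies_to &&
      (is.null(mechanism) || e$mechanism == mechanism) &&
      (is.null(target) || e$target == target)
  }, logical(1))
  compound$interactions[keep]
}
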