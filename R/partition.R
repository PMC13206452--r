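# Tissue-to-plasma partition coefficients by the Rodgers-Rowland
# mechanistic equations for neutrals, acids and weak monoprotic bases
# (pKa < 7; un-ionized or predominantly un-ionized at physiological pH).
# Strong bases would require the acidic-phospholipid variant and are out
# of scope for the shipped compounds.

# Fractional tissue composition: extracellular water, intracellular water,
# neutral lipids, neutral phospholipids, and the tissue-to-plasma albumin
# ratio.  Compact standard set; the "rest" row is a mass-weighted average
# over muscle, skin, adipose and bone for the lumped compartment.
default_tissue_composition <- function() {
  data.frame(
    organ = c("gut", "liver", "kidney", "rest"),
    f_ew  = c(0.282, 0.161, 0.273, 0.100),
    f_iw  = c(0.475, 0.573, 0.483, 0.550),
    f_nl  = c(0.0487, 0.0348, 0.0207, 0.0800),
    f_np  = c(0.0163, 0.0252, 0.0162, 0.0100),
    alb_ratio = c(0.158, 0.086, 0.130, 0.080),
    stringsAsFactors = FALSE)
}

# plasma neutral lipid / phospholipid fractions
PLASMA_F_NL <- 0.0023
PLASMA_F_NP <- 0.0013
PH_PLASMA <- 7.4
PH_INTRACELL <- 7.0

#' Compute tissue:plasma partition coefficients (Rodgers-Rowland)
#'
#' Mechanistic prediction of the tissue:plasma partition coefficient Kp for
#' each perfused tissue from the compound's lipophilicity, ionization state
#' and plasma protein binding, using fractional tissue composition (water,
#' neutral lipid, neutral phospholipid) and tissue:plasma albumin ratios.
#' User-supplied values override the computed ones organ by organ and are
#' flagged in the provenance attribute.
#'
#' @param physchem a [physchem()] object (monoprotic bases must have
#'   pKa < 7; strong bases are not supported by this variant)
#' @param physiology a `pbpk_physiology` (defines the organ set)
#' @param composition tissue composition table; defaults to the built-in set
#' @param overrides optional named numeric vector of user-supplied Kp values
#' @param kp_scale unitless scale factor applied to the computed (not the
#'   user-supplied) Kp values
#' @return a named numeric vector of Kp per tissue with attribute
#'   `provenance` (`"computed"` or `"user_supplied"` per organ), class
#'   `pbpk_partition`
#' @export
compute_partition_coefficients <- function(physchem, physiology,
                                           composition = default_tissue_composition(),
                                           overrides = NULL, kp_scale = 1) {
  stopifnot(inherits(physchem, "pbpk_physchem"))
  organs <- PBPK_TISSUES
  missing_org <- setdiff(organs, composition$organ)
  if (length(missing_org))
    stop("missing tissue-composition entry for: ",
         paste(missing_org, collapse = ", "), call. = FALSE)

  P <- 10^physchem$logP
  fu <- physchem$fu_plasma
  xy <- ionization_xy(physchem)

  # plasma lipid partitioning and the residual albumin association term
  plasma_lipid <- (P * PLASMA_F_NL + (0.3 * P + 0.7) * PLASMA_F_NP) /
    (1 + xy$Y)
  ka_alb <- max(1 / fu - 1 - plasma_lipid, 0)

  kp <- vapply(organs, function(org) {
    row <- composition[composition$organ == org, ]
    kpu <- row$f_ew +
      (1 + xy$X) / (1 + xy$Y) * row$f_iw +
      (P * row$f_nl + (0.3 * P + 0.7) * row$f_np) / (1 + xy$Y) +
      ka_alb * row$alb_ratio
    kpu * fu
  }, numeric(1))
  kp <- kp * kp_scale
  provenance <- setNames(rep("computed", length(organs)), organs)

  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), organs)
    if (length(bad))
      stop("unknown organs in Kp overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    kp[names(overrides)] <- overrides
    provenance[names(overrides)] <- "user_supplied"
  }
  if (any(kp <= 0)) stop("Kp must be > 0", call. = FALSE)
  structure(kp, provenance = provenance, class = "pbpk_partition")
}

# intracellular/plasma ionization factors X and Y
ionization_xy <- function(physchem) {
  switch(physchem$compound_type,
    neutral = list(X = 0, Y = 0),
    monoprotic_base = {
      if (physchem$pKa >= 7)
        stop("strong bases (pKa >= 7) require the acidic-phospholipid ",
             "variant, which is not implemented", call. = FALSE)
      list(X = 10^(physchem$pKa - PH_INTRACELL),
           Y = 10^(physchem$pKa - PH_PLASMA))
    },
    acid = list(X = 10^(PH_INTRACELL - physchem$pKa),
                Y = 10^(PH_PLASMA - physchem$pKa)))
}

# partition set for a compound within a physiology, honouring per-compound
# overrides and the calibrated distribution scale
compound_partitions <- function(compound, physiology) {
  compute_partition_coefficients(compound$physchem, physiology,
                                 overrides = compound$partition_overrides,
                                 kp_scale = compound$kp_scale)
}

#' Steady-state volume of distribution implied by a partition set
#'
#' `Vss = V_plasma + sum(V_tissue x Kp)` over the perfused tissues.
#'
#' @param partitions a `pbpk_partition` vector
#' @param physiology a `pbpk_physiology`
#' @return Vss in litres
#' @export
vss_from_partitions <- function(partitions, physiology) {
  v <- physiology$volumes
  plasma <- v[["art"]] + v[["ven"]] + v[["portal"]]
  plasma + sum(v[PBPK_TISSUES] * as.numeric(partitions[PBPK_TISSUES]))
}
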