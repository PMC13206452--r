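# Structured-text (YAML) configuration files for compounds, physiologies
# and regimens, with schema validation through the package constructors.
# Serialization round-trips are lossless at 15 significant digits.

yaml_write <- function(x, path) {
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

compound_to_list <- function(compound) {
  list(
    name = compound$name,
    physchem = unclass(compound$physchem),
    clearance = unclass(compound$clearance),
    transporters = lapply(unname(compound$transporters), unclass),
    interactions = lapply(compound$interactions, function(e)
      Filter(function(v) !(is.numeric(v) && all(is.na(v))), unclass(e))),
    intestinal_permeability = compound$intestinal_permeability,
    organ_permeability = compound$organ_permeability,
    kp_scale = compound$kp_scale,
    partition_overrides = if (is.null(compound$partition_overrides)) NULL
      else as.list(compound$partition_overrides))
}

compound_from_list <- function(x) {
  pc <- x$physchem
  cl <- x$clearance
  compound_model(
    name = x$name,
    physchem = physchem(pc$molecular_weight, pc$logP, pc$compound_type,
                        num_or_na(pc$pKa), pc$fu_plasma,
                        pc$solubility_water),
    clearance = clearance_spec(cl$hepatic_plasma_cl,
                               cl$hepatic_cl_multiple_dose,
                               cl$gfr_fraction),
    transporters = lapply(x$transporters, function(tr)
      transporter_kinetics(tr$transporter_id, tr$kcat, tr$km,
                           tr$reference_concentration,
                           num_or_na(tr$clint_assay),
                           num_or_na(tr$abundance_assay))),
    interactions = lapply(x$interactions, function(e)
      interaction_entry(e$target, e$mechanism, num_or_na(e$emax),
                        num_or_na(e$ec50), num_or_na(e$ki),
                        num_or_na(e$fold),
                        if (is.null(e$applies_to)) "victim" else e$applies_to,
                        num_or_na(e$clearance_fraction))),
    intestinal_permeability = num_or_na(x$intestinal_permeability),
    organ_permeability = num_or_na(x$organ_permeability),
    kp_scale = if (is.null(x$kp_scale)) 1 else x$kp_scale,
    partition_overrides = if (is.null(x$partition_overrides)) NULL
      else unlist(x$partition_overrides))
}

#' Write a compound model to a config file
#'
#' @param compound a [compound_model()]
#' @param path output file (YAML)
#' @return the path, invisibly
#' @export
write_compound_config <- function(compound, path) {
  stopifnot(inherits(compound, "compound_model"))
  yaml_write(compound_to_list(compound), path)
}

#' Read and validate a compound config file
#'
#' Field values pass through the package constructors, so schema
#' violations (missing fields, out-of-range values) error with the
#' offending field named.
#'
#' @param path config file path
#' @return a [compound_model()]
#' @export
read_compound_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  compound_from_list(yaml::read_yaml(path))
}

#' Write a physiology to a config file
#'
#' @param phys a `pbpk_physiology`
#' @param path output file (YAML)
#' @return the path, invisibly
#' @export
write_physiology_config <- function(phys, path) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  x <- unclass(phys)
  x$volumes <- as.list(x$volumes)
  x$flows <- as.list(x$flows)
  x$relative_expression <- lapply(x$relative_expression, as.list)
  yaml_write(x, path)
}

#' Read and validate a physiology config file
#'
#' @param path config file path
#' @return a `pbpk_physiology`
#' @export
read_physiology_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  x <- yaml::read_yaml(path)
  phys <- structure(
    list(body_weight = x$body_weight,
         volumes = unlist(x$volumes),
         flows = unlist(x$flows),
         cardiac_output_plasma = x$cardiac_output_plasma,
         gfr = x$gfr, absorption_s2v = x$absorption_s2v,
         gut_transit_time = x$gut_transit_time,
         blood_plasma_ratio = x$blood_plasma_ratio,
         relative_expression = lapply(x$relative_expression, unlist)),
    class = "pbpk_physiology")
  validate_physiology(phys)
  phys
}

#' Write a regimen to a config file
#'
#' @param reg a [regimen()]
#' @param path output file (YAML)
#' @return the path, invisibly
#' @export
write_regimen_config <- function(reg, path) {
  stopifnot(inherits(reg, "pbpk_regimen"))
  yaml_write(Filter(Negate(is.null), unclass(reg)), path)
}

#' Read and validate a regimen config file
#'
#' @param path config file path
#' @return a [regimen()]
#' @export
read_regimen_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  x <- yaml::read_yaml(path)
  regimen(route = x$route, dose_mg = x$dose_mg,
          dose_mg_per_kg = x$dose_mg_per_kg,
          n_doses = if (is.null(x$n_doses)) 1 else x$n_doses,
          interval_h = if (is.null(x$interval_h)) 24 else x$interval_h,
          start_time_h = if (is.null(x$start_time_h)) 0 else x$start_time_h,
          infusion_duration_min = if (is.null(x$infusion_duration_min)) 30
            else x$infusion_duration_min)
}
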