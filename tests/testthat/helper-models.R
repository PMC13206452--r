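# Shared fixtures: a degenerate one-compartment configuration (all organs
# collapsed into one well-mixed pool by tiny volumes and large flows) and
# fast solver settings for property loops.

onecpt_physiology <- function(V = 5, Q = 400) {
  phys <- default_physiology()
  phys$volumes <- c(lumen = 1, gut = 1e-3, portal = 1e-3, liver = 1e-3,
                    kidney = 1e-3, art = 1e-3, ven = V, rest = 1e-3)
  phys$flows <- c(gut = Q, hepatic_artery = Q, kidney = Q, rest = Q)
  phys$cardiac_output_plasma <- 4 * Q
  phys$gfr <- 1e-9
  phys$relative_expression <- list(
    gut = c(ABCB1 = 0, ABCG2 = 0), kidney = c(ABCB1 = 0, ABCG2 = 0),
    liver = c(ABCB1 = 0, ABCG2 = 0))
  phys
}

# neutral probe compound with unit binding and a prescribed total clearance
onecpt_compound <- function(cl_L_min = 0.1, bw = 73, ka_perm = 1e-5) {
  compound_model(
    "probe",
    physchem(100, 0, "neutral", fu_plasma = 1, solubility_water = 10),
    clearance_spec(cl_L_min * 1000 / bw, gfr_fraction = 0),
    intestinal_permeability = ka_perm,
    partition_overrides = c(gut = 1, liver = 1, kidney = 1, rest = 1))
}

# physiology with all transporter expression removed
no_transporter_physiology <- function() {
  phys <- default_physiology()
  phys$relative_expression <- lapply(phys$relative_expression,
                                     function(x) x * 0)
  phys
}

fast_options <- function(...) sim_options(rtol = 1e-7, atol = 1e-9, ...)

# the standard study template: 7 pre-treatment days of once-daily
# perpetrator, then 7 days of twice-daily victim alongside it
std_victim_regimen_test <- function() {
  regimen("oral", dose_mg = 600, n_doses = 14, interval_h = 12,
          start_time_h = 168)
}
std_perp_regimen_test <- function() {
  regimen("oral", dose_mg = 600, n_doses = 14, interval_h = 24)
}
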