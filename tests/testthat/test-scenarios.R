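# Scenario-level behaviour.  These tests run whole multi-week simulations
# and dominate the suite's runtime; they use the shipped compound models.

test_that("with every mechanism disabled, co-administration equals monotherapy", {
  spec <- scenario_spec(
    "null_ddi", std_victim_regimen_test(), std_perp_regimen_test(),
    mechanism_flags = list(abcb1_induction = FALSE,
                           abcb1_inhibition = FALSE,
                           abcg2_inhibition = FALSE,
                           abcg2_static_fold = FALSE))
  res <- run_scenario(spec, keep_profiles = TRUE)
  expect_identical(res$sim_with$state, res$sim_without$state)
  expect_identical(res$ddi_auc_ratio, 1)
  expect_identical(res$ddi_cmax_ratio, 1)
})

test_that("published sensitivity parameter sets are exposed verbatim", {
  ss <- sensitivity_sets()
  expect_equal(ss$nilles, list(emax = 5.1, ec50 = 1, ki = 12.9))
  expect_equal(sensitivity_sets("120h")$nilles$emax, 7)
  expect_equal(ss$asaumi, list(emax = 4, ec50 = 0.0639, ki = 0.488))

  rif <- builtin_rifampin()
  over <- apply_interaction_overrides(rif, "nilles")
  ind <- Filter(function(e) e$mechanism == "induction" &&
                  e$target == "ABCB1", over$interactions)[[1]]
  expect_equal(ind$emax, 5.1)
  expect_equal(ind$ec50, 1)
  # the base model is untouched by the override (isolation)
  base_ind <- Filter(function(e) e$mechanism == "induction" &&
                       e$target == "ABCB1", rif$interactions)[[1]]
  expect_equal(base_ind$emax, 2.5)
  expect_equal(base_ind$ec50, 0.34)
  # ABCG2 and auto-induction entries are untouched
  expect_equal(Filter(function(e) e$target == "ABCG2" &&
                        e$mechanism == "competitive_inhibition",
                      over$interactions)[[1]]$ki, 14)
  expect_identical(apply_interaction_overrides(rif, "base"), rif)
})

test_that("the shipped scenario table covers the dose sweep", {
  sc <- builtin_scenarios()
  expect_true(all(c("linezolid_monotherapy", "ddi_standard_abcb1",
                    "ddi_standard_combined", "highdose_10", "highdose_20",
                    "highdose_25", "highdose_30", "highdose_35",
                    "highdose_40") %in% names(sc)))
  expect_equal(sc$highdose_40$perpetrator_regimen$dose_mg_per_kg, 40)
  expect_null(sc$linezolid_monotherapy$perpetrator_regimen)
})

test_that("the two mechanism hypotheses differ only through ABCG2 terms", {
  victim <- builtin_linezolid()
  victim$transporters$ABCG2 <- NULL
  sc <- builtin_scenarios()
  r1 <- run_scenario(sc$ddi_standard_abcb1, victim = victim,
                     keep_profiles = TRUE)
  r2 <- run_scenario(sc$ddi_standard_combined, victim = victim,
                     keep_profiles = TRUE)
  i <- 1:11  # victim mass states
  rel <- abs(r1$sim_with$state[, i] - r2$sim_with$state[, i]) /
    pmax(abs(r1$sim_with$state[, i]), 1e-8)
  expect_lt(max(rel), 1e-9)
  expect_equal(r1$ddi_auc_ratio, r2$ddi_auc_ratio, tolerance = 1e-9)
})

test_that("DDI strength is monotone in induction Emax and inhibitor potency", {
  sc <- builtin_scenarios()$ddi_standard_combined
  ratio_for <- function(emax = 2.5, ec50 = 0.34, ki = 9.1) {
    rif <- apply_interaction_overrides(builtin_rifampin(),
                                       list(emax = emax, ec50 = ec50,
                                            ki = ki))
    run_scenario(sc, perpetrator = rif)$ddi_auc_ratio
  }
  # AUC ratio is non-increasing in Emax
  r_emax <- c(ratio_for(emax = 0), ratio_for(emax = 1.25),
              ratio_for(emax = 2.5))
  expect_true(all(diff(r_emax) < 0))
  # and non-decreasing in inhibitor potency 1/Ki (inhibition spares the
  # victim from efflux)
  r_ki <- c(ratio_for(ki = 1e9), ratio_for(ki = 9.1), ratio_for(ki = 1))
  expect_true(all(diff(r_ki) >= 0))
  # Ki -> Inf reproduces the induction-only arm; Emax -> 0 the
  # inhibition-only arm
  flags_no_inh <- list(abcb1_induction = TRUE, abcb1_inhibition = FALSE,
                       abcg2_inhibition = TRUE, abcg2_static_fold = TRUE)
  sc_no_inh <- scenario_spec("ind_only", sc$victim_regimen,
                             sc$perpetrator_regimen,
                             mechanism_flags = flags_no_inh)
  expect_equal(ratio_for(ki = 1e9),
               run_scenario(sc_no_inh)$ddi_auc_ratio, tolerance = 1e-4)
})

test_that("doubling ABCB1 Kcat moves exposure more than doubling ABCG2 Kcat", {
  ks <- kcat_sensitivity()
  expect_true(all(ks$d_auc_rel < 0))  # more efflux, less exposure
  expect_gt(attr(ks, "abcb1_over_abcg2"), 1)
})
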