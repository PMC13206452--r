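test_that("Vmax and Kcat derivations follow the assay arithmetic", {
  # uL/min/mg x umol/L reconciles to pmol/min/mg
  expect_equal(derive_vmax(16, 100), 1600)
  expect_equal(derive_vmax(0, 100), 0)
  expect_equal(derive_vmax(2.1, 100), 210)
  expect_error(derive_vmax(16, 0), "km")
  expect_error(derive_vmax(-1, 100), "clint")

  kcat <- derive_kcat(derive_vmax(16, 100), 13.18)
  expect_equal(kcat, 1600 / 13.18, tolerance = 1e-12)
  expect_equal(signif(kcat, 2), 120)
  expect_equal(derive_kcat(0, 10), 0)
  expect_equal(derive_kcat(210, 10.3), 20.4, tolerance = 1e-3)
  expect_error(derive_kcat(100, 0), "abundance")
})

test_that("derivation pipeline round-trips to machine precision", {
  set.seed(42)
  for (i in 1:25) {
    clint <- runif(1, 0.1, 100)
    km <- runif(1, 1, 500)
    ab <- runif(1, 0.5, 50)
    expect_equal(derive_kcat(derive_vmax(clint, km), ab), clint * km / ab,
                 tolerance = 1e-14)
  }
})

test_that("built-in linezolid model carries the published parameter set", {
  lzd <- builtin_linezolid()
  expect_equal(lzd$physchem$molecular_weight, 337.35)
  expect_equal(lzd$physchem$logP, 0.55)
  expect_equal(lzd$physchem$compound_type, "monoprotic_base")
  expect_equal(lzd$physchem$pKa, 1.7)
  expect_equal(lzd$physchem$fu_plasma, 0.69)
  expect_equal(lzd$physchem$solubility_water, 3)
  expect_equal(lzd$clearance$hepatic_plasma_cl, 0.65)
  expect_equal(lzd$clearance$hepatic_cl_multiple_dose, 0.5)
  expect_equal(lzd$transporters$ABCB1$kcat, 72)
  expect_equal(lzd$transporters$ABCB1$km, 51)
  expect_equal(lzd$transporters$ABCB1$reference_concentration, 0.077)
  expect_equal(lzd$transporters$ABCG2$kcat, 720)
  expect_equal(lzd$transporters$ABCG2$km, 53)
  expect_equal(lzd$transporters$ABCG2$reference_concentration, 0.025)
  expect_equal(lzd$intestinal_permeability, 9e-6)
  expect_equal(lzd$organ_permeability, 9e-4)
  expect_length(lzd$interactions, 0)
})

test_that("built-in rifampin model carries the published interaction constants", {
  rif <- builtin_rifampin()
  ind <- Filter(function(e) e$mechanism == "induction" &&
                  e$target == "ABCB1", rif$interactions)[[1]]
  expect_equal(ind$emax, 2.5)
  expect_equal(ind$ec50, 0.34)
  ki_b1 <- Filter(function(e) e$mechanism == "competitive_inhibition" &&
                    e$target == "ABCB1", rif$interactions)[[1]]
  expect_equal(ki_b1$ki, 9.1)
  ki_g2 <- Filter(function(e) e$mechanism == "competitive_inhibition" &&
                    e$target == "ABCG2", rif$interactions)[[1]]
  expect_equal(ki_g2$ki, 14)
  fold <- Filter(function(e) e$mechanism == "static_fold",
                 rif$interactions)[[1]]
  expect_equal(fold$target, "ABCG2")
  expect_equal(fold$fold, 1.5)
  auto <- Filter(function(e) e$applies_to == "self_clearance",
                 rif$interactions)
  auto_emax <- sort(vapply(auto, `[[`, numeric(1), "emax"))
  expect_equal(auto_emax, c(0.383, 0.985))
  expect_true(all(vapply(auto, `[[`, numeric(1), "ec50") == 0.34))
})

test_that("compound constructors validate their invariants", {
  expect_error(physchem(337, 0.5, fu_plasma = 0), "fu_plasma")
  expect_error(physchem(337, 0.5, fu_plasma = 1.2), "fu_plasma")
  expect_error(physchem(-1, 0.5), "molecular_weight")
  expect_error(physchem(337, 0.5, "monoprotic_base"), "pKa")
  expect_error(transporter_kinetics("ABCB1", -1, 51, 0.077), "kcat")
  expect_error(transporter_kinetics("ABCB1", 72, 0, 0.077), "km")
  expect_error(clearance_spec(0.5, 0.65), "multiple-dose")
  expect_error(interaction_entry("ABCB1", "induction", emax = 2.5,
                                 ec50 = 0), "ec50")
  expect_error(interaction_entry("ABCB1", "competitive_inhibition"), "ki")
  expect_error(interaction_entry("ABCG2", "static_fold", fold = 0), "fold")
  pc <- physchem(100, 0)
  cl <- clearance_spec(1)
  tr <- transporter_kinetics("ABCB1", 72, 51, 0.077)
  expect_error(compound_model("x", pc, cl, transporters = list(tr, tr)),
               "one kinetics entry")
})

test_that("compound configs round-trip losslessly", {
  for (cmp in list(builtin_linezolid(), builtin_rifampin())) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_compound_config(cmp, path)
    expect_equal(read_compound_config(path), cmp)
  }
  expect_error(read_compound_config("no/such/file.yaml"), "not found")
})

test_that("shipped config files validate and match the built-ins", {
  d <- system.file("extdata", package = "pbpkddi")
  expect_equal(read_compound_config(file.path(d, "linezolid.yaml")),
               builtin_linezolid())
  expect_equal(read_compound_config(file.path(d, "rifampin.yaml")),
               builtin_rifampin())
  expect_equal(read_physiology_config(file.path(d,
                                                "physiology_adult73.yaml")),
               default_physiology())
  reg <- read_regimen_config(file.path(d, "regimen_linezolid_600bid.yaml"))
  expect_equal(reg$dose_mg, 600)
  expect_equal(reg$n_doses, 14L)
  expect_equal(reg$interval_h, 12)
})
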