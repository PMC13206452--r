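test_that("the right-hand side is zero at rest and conserves mass", {
  model <- build_pbpk_model(builtin_linezolid(), default_physiology())
  dy <- model$rhs(0, model$y0, numeric(2))[[1]]
  expect_equal(dy, rep(0, model$n_states))

  # with drug on board, total mass derivative equals the infusion rate
  y <- model$y0
  set.seed(1)
  y[1:11] <- runif(11, 0, 50)
  for (rate in c(0, 2.5)) {
    dy <- model$rhs(100, y, c(rate, 0))[[1]]
    expect_equal(sum(dy[1:11]), rate, tolerance = 1e-12)
  }
  expect_error(model$rhs(0, model$y0 - 1, numeric(2)),
               "negative compartment")
})

test_that("a degenerate one-compartment model matches the closed form", {
  phys <- onecpt_physiology(V = 5, Q = 400)
  cmp <- onecpt_compound(cl_L_min = 0.1)
  sim <- run_simulation(cmp, regimen("iv_bolus", dose_mg = 100), phys,
                        t_end_h = 6, options = sim_options(grid_min = 15))
  pr <- plasma_conc(sim)
  v_tot <- sum(phys$volumes) - phys$volumes[["lumen"]]
  dose_umol <- mg_to_umol(100, 100)
  pred_ugmL <- umolL_to_ugmL(dose_umol / v_tot *
                               exp(-0.1 * pr$time_min / v_tot), 100)
  sel <- pr$time_min > 0
  expect_lt(max(abs(pr$conc_ug_mL[sel] - pred_ugmL[sel]) / pred_ugmL[sel]),
            0.001)
})

test_that("mass balance holds to 1e-6 across routes and regimens", {
  lzd <- builtin_linezolid()
  phys <- default_physiology()
  sims <- list(
    run_simulation(lzd, regimen("oral", dose_mg = 600, n_doses = 3,
                                interval_h = 12), phys, t_end_h = 48),
    run_simulation(lzd, regimen("iv_bolus", dose_mg = 600), phys,
                   t_end_h = 24),
    run_simulation(lzd, regimen("iv_infusion", dose_mg = 600,
                                infusion_duration_min = 30), phys,
                   t_end_h = 24))
  for (sim in sims) {
    expect_lt(mass_balance_error(sim)[["victim"]], 1e-6)
    expect_gt(min(sim$state[, 1:11]), -1e-9)
  }
})

test_that("exposure is dose-linear once transporters are removed", {
  lzd <- builtin_linezolid()
  phys <- no_transporter_physiology()
  a1 <- sim_pk_metrics(run_simulation(lzd, regimen("oral", dose_mg = 600),
                                      phys, t_end_h = 48))$auc_inf
  a2 <- sim_pk_metrics(run_simulation(lzd, regimen("oral", dose_mg = 1200),
                                      phys, t_end_h = 48))$auc_inf
  expect_equal(a2 / a1, 2, tolerance = 0.001)
})

test_that("single-dose urinary excretion of unchanged drug is 30-40%", {
  sim <- run_simulation(builtin_linezolid(),
                        regimen("oral", dose_mg = 600),
                        default_physiology(), t_end_h = 72)
  ae <- compartment_amount(sim, "urine")
  fe <- ae[length(ae)] / sim$dosed[["victim"]]
  expect_gte(fe, 0.30)
  expect_lte(fe, 0.40)
})

test_that("physiology validation enforces the flow balance", {
  phys <- default_physiology()
  expect_silent(validate_physiology(phys))
  bad <- phys
  bad$flows[["kidney"]] <- bad$flows[["kidney"]] * 2
  expect_error(validate_physiology(bad), "flow balance")
  bad2 <- phys
  bad2$volumes[["liver"]] <- 0
  expect_error(validate_physiology(bad2), "volumes")
  bad3 <- phys
  bad3$relative_expression$gut[["ABCB1"]] <- -1
  expect_error(validate_physiology(bad3), "relative expression")
})

test_that("allometric weight scaling preserves the flow balance", {
  for (w in c(50, 73, 100)) {
    phys <- default_physiology(w)
    expect_silent(validate_physiology(phys))
    expect_equal(phys$body_weight, w)
    expect_equal(phys$volumes[["rest"]], 60 * w / 73, tolerance = 1e-12)
    expect_equal(phys$gfr, 0.12 * (w / 73)^0.75, tolerance = 1e-12)
  }
})
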