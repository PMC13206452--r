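test_that("apparent synthesis rate follows the Emax occupancy model", {
  expect_equal(synthesis_rate(1, 2.5, 0.34, 0), 1)
  expect_equal(synthesis_rate(1, 2.5, 0.34, 0.34), 2.25)
  expect_equal(synthesis_rate(2, 2.5, 0.34, 0.34), 4.5)
  # saturates at 1 + Emax
  expect_equal(synthesis_rate(1, 2.5, 0.34, 1e9), 3.5, tolerance = 1e-6)
  # monotone increasing in the inducer concentration
  conc <- seq(0, 10, by = 0.25)
  expect_true(all(diff(synthesis_rate(1, 2.5, 0.34, conc)) > 0))
  expect_error(synthesis_rate(1, 2.5, 0, 1), "ec50")
  expect_error(synthesis_rate(1, 2.5, 0.34, -1), "inducer")
})

test_that("turnover expression settles at the analytic steady state", {
  st <- induction_state(kdeg = log(2) / 2160, emax = 2.5, ec50 = 0.34)
  # no inducer: stays at baseline indefinitely
  st0 <- st
  for (i in 1:20) st0 <- step_expression(st0, 0, 2160)
  expect_equal(st0$expression_state, 1, tolerance = 1e-12)
  # constant half-maximal occupancy, >= 10 degradation half-lives
  st1 <- step_expression(st, 0.34, 10 * 2160 / log(2))
  expect_equal(st1$expression_state,
               expression_steady_state(2.5, 0.34, 0.34),
               tolerance = 1e-3)
  expect_equal(expression_steady_state(2.5, 0.34, 0.34), 2.25)
})

test_that("fast turnover tracks the instantaneous steady state", {
  st <- induction_state(kdeg = 10, emax = 2.5, ec50 = 0.34)
  for (conc in c(0.1, 0.5, 2)) {
    st <- step_expression(st, conc, 5)   # 50 half-lives worth of kdeg
    expect_equal(st$expression_state,
                 expression_steady_state(2.5, 0.34, conc),
                 tolerance = 1e-10)
  }
})

test_that("competitive inhibition scales the apparent Km linearly", {
  expect_equal(apparent_km(51, 0, 9.1), 51)
  expect_equal(apparent_km(51, 9.1, 9.1), 102)
  expect_equal(apparent_km(53, 14, 14), 106)
  conc <- seq(0, 50, by = 1)
  km_app <- apparent_km(51, conc, 9.1)
  expect_true(all(diff(km_app) > 0))
  expect_true(all(km_app >= 51))
  slopes <- diff(km_app) / diff(conc)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
  expect_error(apparent_km(0, 1, 9.1), "km")
  expect_error(apparent_km(51, 1, 0), "ki")
})

test_that("static fold-changes scale only the targeted transporter", {
  st <- induction_state()
  expect_equal(apply_static_fold(st, "ABCG2", 1)$expression_state, 1)
  expect_equal(apply_static_fold(st, "ABCG2", 1.5)$expression_state, 1.5)
  expect_equal(
    apply_static_fold(st, "ABCB1", 1.5, target = "ABCG2")$expression_state,
    1)
  expect_error(apply_static_fold(st, "ABCG2", 0), "fold")
  expect_error(apply_static_fold(st, "ABCG2", 1.5, target = "XYZ"),
               "unknown transporter")
})

test_that("transporter flux saturates and vanishes correctly", {
  kin <- transporter_kinetics("ABCB1", 72, 51, 0.077)
  amount <- organ_transporter_amount(kin, default_physiology(), "kidney")
  expect_gt(amount, 0)
  expect_equal(transporter_flux(0, kin, 1, amount), 0)
  # half-saturation at S = Km
  expect_equal(transporter_flux(51, kin, 1, amount),
               0.5 * 72 * amount, tolerance = 1e-12)
  # saturation limit
  expect_equal(transporter_flux(1e6 * 51, kin, 1, amount), 72 * amount,
               tolerance = 1e-4)
  # linear regime
  s <- 1e-4
  expect_equal(transporter_flux(s, kin, 1, amount),
               72 * amount * s / 51, tolerance = 1e-5)
  # zero expression yields zero flux
  expect_equal(transporter_flux(51, kin, 0, amount), 0)
  expect_error(transporter_flux(1, kin, 1, amount, km_app = 0), "km_app")
})
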