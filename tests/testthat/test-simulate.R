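test_that("zero dose yields identically zero concentrations", {
  sim <- run_simulation(builtin_linezolid(),
                        regimen("oral", dose_mg = 0), default_physiology(),
                        t_end_h = 12)
  expect_equal(max(abs(sim$state)), 0)
})

test_that("a standard oral dose peaks at 1-2 h with Cmax of order 10 ug/mL", {
  sim <- run_simulation(builtin_linezolid(),
                        regimen("oral", dose_mg = 600),
                        default_physiology(), t_end_h = 48)
  m <- sim_pk_metrics(sim)
  expect_gte(m$tmax, 1)
  expect_lte(m$tmax, 2)
  expect_gt(m$cmax, 5)
  expect_lt(m$cmax, 30)
  expect_false(sim$lumen_supersaturated[["victim"]])
})

test_that("NCA reproduces closed forms on synthetic profiles", {
  # constant concentration: AUC = c x T
  tt <- seq(0, 12, by = 0.25)
  m <- pk_metrics(tt, rep(4, length(tt)), dose_times_h = 0, tau_h = 12)
  expect_equal(m$auc_tau, 48, tolerance = 1e-12)

  # dense mono-exponential: AUC_inf = C0/k, lambda_z = k
  k <- 0.2; c0 <- 10
  tt <- seq(0, 36, by = 0.25)
  m <- pk_metrics(tt, c0 * exp(-k * tt))
  expect_equal(m$auc_inf, c0 / k, tolerance = 0.005)
  expect_equal(m$lambda_z, k, tolerance = 1e-6)

  # too few samples for any terminal fit
  expect_error(pk_metrics(c(0, 1), c(1, 0.5)), "3 samples")
  lz <- lambda_z(c(0, 1), c(10, 5))
  expect_false(lz$estimable)
  expect_true(is.na(lz$lambda_z))
})

test_that("interval AUC is insensitive to the output grid", {
  lzd <- builtin_linezolid()
  reg <- regimen("oral", dose_mg = 600, n_doses = 3, interval_h = 12)
  m5 <- sim_pk_metrics(run_simulation(lzd, reg, t_end_h = 48))
  m2 <- sim_pk_metrics(run_simulation(lzd, reg, t_end_h = 48,
                                      options = sim_options(grid_min = 2.5)))
  expect_lt(abs(m5$auc_tau - m2$auc_tau) / m2$auc_tau, 0.002)
})

test_that("piecewise restarts match a single events-driven solve", {
  lzd <- builtin_linezolid()
  reg <- regimen("oral", dose_mg = 600, n_doses = 3, interval_h = 12)
  s1 <- run_simulation(lzd, reg, t_end_h = 48)
  s2 <- run_simulation(lzd, reg, t_end_h = 48,
                       options = sim_options(engine = "events"))
  expect_identical(s1$time, s2$time)
  # dose instants differ only by the pre-/post-bolus reporting convention
  keep <- !(s1$time %in% unique(s1$doses$time))
  rel <- abs(s1$state[keep, ] - s2$state[keep, ]) /
    pmax(abs(s1$state[keep, ]), 1e-8)
  expect_lt(max(rel), 1e-8)
})

test_that("twice-daily dosing reaches steady state within a week", {
  sim <- run_simulation(builtin_linezolid(),
                        regimen("oral", dose_mg = 600, n_doses = 14,
                                interval_h = 12),
                        default_physiology(), t_end_h = 168)
  pr <- plasma_conc(sim)
  auc_win <- function(a, b) {
    sel <- pr$time_h >= a & pr$time_h <= b
    pbpkddi:::auc_linlog(pr$time_h[sel], pr$conc_ug_mL[sel])
  }
  day6 <- auc_win(132, 144)
  day7 <- auc_win(144, 156)
  expect_lt(abs(day7 - day6) / day6, 0.01)
})

test_that("mg/kg doses resolve against the physiology body weight", {
  phys <- default_physiology()
  d1 <- pbpkddi:::expand_doses(regimen("oral", dose_mg_per_kg = 10),
                               builtin_rifampin(), phys, 2L)
  d2 <- pbpkddi:::expand_doses(regimen("oral", dose_mg = 730),
                               builtin_rifampin(), phys, 2L)
  expect_equal(d1$amount, d2$amount, tolerance = 1e-12)
})

test_that("profile CSV export is tidy and complete", {
  sim <- run_simulation(builtin_linezolid(),
                        regimen("oral", dose_mg = 600),
                        default_physiology(), t_end_h = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(sim, path)
  df <- read.csv(path)
  expect_setequal(
    names(df),
    c("time_min", "drug", "compartment", "amount_umol", "conc_ug_per_mL",
      "expression_state"))
  expect_setequal(unique(df$compartment),
                  c("lumen", "gut", "portal", "liver", "kidney", "art",
                    "ven", "rest", "urine", "feces", "metabolized"))
  ven <- df[df$compartment == "ven", ]
  pr <- plasma_conc(sim)
  expect_equal(ven$conc_ug_per_mL, pr$conc_ug_mL, tolerance = 1e-9)
})
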