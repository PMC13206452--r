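no_bsv_spec <- function(n = 3, residual = 0, seed = 7, ...) {
  synthetic_study_spec(
    n_subjects = n, weight_range_kg = c(73, 73),
    bsv_cv = c(hepatic_cl = 0, rest_of_body_kp = 0, absorption_rate = 0),
    residual_sd = residual, seed = seed, ...)
}

test_that("without variability every subject equals the reference prediction", {
  st <- generate_study(no_bsv_spec())
  for (s in unique(st$observations$subject_id)) {
    sub <- st$observations[st$observations$subject_id == s, ]
    expect_equal(sub$conc_ug_per_mL,
                 st$reference_prediction$conc_ug_per_mL,
                 tolerance = 1e-10)
  }
})

test_that("a fixed seed reproduces the study bit for bit", {
  spec <- synthetic_study_spec(n_subjects = 4, residual_sd = 0.2, seed = 3)
  s1 <- generate_study(spec)
  s2 <- generate_study(spec)
  expect_identical(s1$observations, s2$observations)
  s3 <- generate_study(synthetic_study_spec(n_subjects = 4,
                                            residual_sd = 0.2, seed = 4))
  expect_false(identical(s1$observations$conc_ug_per_mL,
                         s3$observations$conc_ug_per_mL))
})

test_that("the residual error model has the specified log-scale sd", {
  st <- generate_study(no_bsv_spec(n = 300, residual = 0.2, seed = 5))
  r <- log(st$observations$conc_ug_per_mL /
             st$observations$predicted_ug_per_mL)
  expect_gt(sd(r), 0.18)
  expect_lt(sd(r), 0.22)
})

test_that("hepatic clearance is recovered exactly from noise-free data", {
  st <- generate_study(no_bsv_spec(n = 2))
  fit <- recover_parameters(st)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["hepatic_cl"]), 0.65,
               tolerance = 0.01)
})

test_that("hepatic clearance is recovered within 10% under residual noise", {
  st <- generate_study(no_bsv_spec(n = 24, residual = 0.2, seed = 11))
  fit <- recover_parameters(st)
  expect_lt(abs(fit$estimates[["hepatic_cl"]] - 0.65) / 0.65, 0.10)
})

test_that("recovery is unbiased over seeded replicates", {
  ests <- vapply(1:8, function(seed) {
    st <- generate_study(no_bsv_spec(n = 8, residual = 0.2, seed = seed),
                         options = fast_options())
    recover_parameters(st, options = fast_options())$estimates[["hepatic_cl"]]
  }, numeric(1))
  # Monte-Carlo error of the replicate mean at this n
  expect_lt(abs(mean(ests) - 0.65) / 0.65, 0.05)
})

test_that("exposure GMFE against the generating model shrinks with noise", {
  subject_aucs <- function(st) {
    vapply(split(st$observations, st$observations$subject_id),
           function(sub) pbpkddi:::auc_linlog(sub$time_h,
                                              sub$conc_ug_per_mL),
           numeric(1))
  }
  ref_auc <- function(st)
    pbpkddi:::auc_linlog(st$reference_prediction$time_h,
                         st$reference_prediction$conc_ug_per_mL)
  st0 <- generate_study(no_bsv_spec(n = 6, residual = 0))
  g0 <- gmfe(subject_aucs(st0), rep(ref_auc(st0), 6))
  st1 <- generate_study(no_bsv_spec(n = 6, residual = 0.3, seed = 9))
  g1 <- gmfe(subject_aucs(st1), rep(ref_auc(st1), 6))
  expect_equal(g0, 1, tolerance = 1e-6)
  expect_gt(g1, g0)
})

test_that("recovery rejects an empty or unknown parameter list", {
  st <- generate_study(no_bsv_spec(n = 2))
  expect_error(recover_parameters(st, free_params = character(0)),
               "nothing to fit")
  expect_error(recover_parameters(st, free_params = "lipophilicity"),
               "unsupported")
})
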