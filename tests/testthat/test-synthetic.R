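test_that("noiseless generation equals the model output and is seeded", {
  d0 <- generate_tracer_data(P6, times = c(0.5, 7), noise_cv = 0,
                             qss = QSS6)
  tr <- simulate_tracer_experiment(P6, times = c(0.5, 7), qss = QSS6)
  fr <- tracer_fractions(tr)
  for (i in seq_len(nrow(d0))) {
    expect_equal(d0$fraction_of_dose[i],
                 fr[fr$time_days == d0$time_days[i], d0$pool[i]])
  }
  expect_true(all(is.na(d0$sd)))
  d1 <- generate_tracer_data(P6, noise_cv = 0.05, seed = 123, qss = QSS6)
  d2 <- generate_tracer_data(P6, noise_cv = 0.05, seed = 123, qss = QSS6)
  expect_identical(d1, d2)
  d3 <- generate_tracer_data(P6, noise_cv = 0.05, seed = 124, qss = QSS6)
  expect_false(identical(d1$fraction_of_dose, d3$fraction_of_dose))
})

test_that("the proportional noise model has the requested CV", {
  # pool many replicates of one experiment's relative errors
  reps <- lapply(1:12, function(s)
    generate_tracer_data(P6, times = c(1, 4, 14), noise_cv = 0.05,
                         seed = s, qss = QSS6))
  base <- generate_tracer_data(P6, times = c(1, 4, 14), noise_cv = 0,
                               qss = QSS6)
  rel <- unlist(lapply(reps, function(d)
    (d$fraction_of_dose - base$fraction_of_dose) / base$fraction_of_dose))
  rel <- rel[is.finite(rel)]
  expect_equal(sd(rel), 0.05, tolerance = 0.25)  # ~288 draws
  expect_equal(mean(rel), 0, tolerance = 0.01)
  # recorded sd column is cv * mean
  expect_equal(reps[[1]]$sd, 0.05 * base$fraction_of_dose)
})

test_that("noise truncation never produces negative fractions", {
  d <- generate_tracer_data(P6, times = c(0.01, 28), noise_cv = 2,
                            seed = 9, qss = QSS6)
  expect_true(all(d$fraction_of_dose >= 0))
})

test_that("published parameter fixtures are transcribed faithfully", {
  p6 <- published_params(6)
  expect_equal(p6[["kInDuo"]], 0.0690)
  expect_equal(p6[["kInBM"]], 15.8)
  expect_equal(p6[["vRBCSpleen"]], 0.0235)
  expect_equal(p6[["Km"]], 0.0159)
  expect_equal(p6[["vDiet"]], 0.00377)
  expect_equal(p6[["kNTBI_Fe1Tf"]], 1.08e9)
  expect_equal(published_params(1)[["vRBCSpleen"]], 0.0833)
  expect_equal(published_params(7)[["vRBCSpleen"]], 0.0283)
  expect_error(published_params(0))
  expect_error(published_params("six"))
  # ensemble matrix covers all ten independent estimates
  expect_equal(dim(published_ensemble()), c(17, 10))
})

test_that("diet scenarios scale only the two diet knobs", {
  defi <- diet_scenario(P6, "deficient")
  expect_equal(defi[["vDiet"]], P6[["vDiet"]] * 0.25)
  expect_equal(defi[["kHepSyn"]], P6[["kHepSyn"]] * 0.5)
  rich <- diet_scenario(P6, "rich")
  expect_equal(rich[["kHepSyn"]] / P6[["kHepSyn"]], 1.35)
  same <- setdiff(names(P6), c("vDiet", "kHepSyn"))
  expect_equal(unclass(rich)[same], unclass(P6)[same])
})

test_that("a noiseless dataset refit at truth closes the round trip", {
  d <- generate_tracer_data(P6, times = default_obs_times(), noise_cv = 0,
                            qss = QSS6)
  expect_lt(objective(P6, d, qss = QSS6), 1e-10)
})
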