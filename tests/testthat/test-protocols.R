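test_that("zero-length time span echoes the initial state", {
  s <- default_state(MODEL6)
  tr <- run(MODEL6, s, times = 0)
  expect_equal(unname(tr$states[1, ]), unname(s[MODEL6$species$name]))
})

test_that("integration matches the analytic solution of first-order decay", {
  # an isolated labeled RBC pool decays as exp(-vRBCSpleen * t) once the
  # recycling route back into the pool (spleen -> plasma -> bone marrow ->
  # RBC) is switched off via a negligible erythroid maturation constant
  m <- build_model(iron_params(kInRBC = 1e-12, base = P6))
  s <- default_state(m)
  s[["FeRBC*"]] <- 1e-5
  tr <- run(m, s, times = c(0, 1, 5, 10))
  k <- P6[["vRBCSpleen"]]
  expect_equal(tr$states[, "FeRBC*"], 1e-5 * exp(-k * c(0, 1, 5, 10)),
               tolerance = 1e-7)
})

test_that("quasi steady state is a fixed point of the lead-in", {
  q2 <- quasi_steady_state(MODEL6_PLAIN, leadin_days = 35, init = QSS6)
  expect_equal(unname(q2[names(QSS6)]), unname(QSS6), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_lt(attr(QSS6, "residual"), 1e-2)
})

test_that("tracer injection perturbs only plasma NTBI*", {
  s <- as_tracer_state(QSS6, MODEL6)
  expect_identical(inject_tracer(s, 0, MODEL6)[["NTBI*"]], s[["NTBI*"]])
  dose <- 1e-9
  s1 <- inject_tracer(s, dose, MODEL6)
  expect_equal(s1[["NTBI*"]] - s[["NTBI*"]], dose / 1.3e-3)
  others <- setdiff(names(s), "NTBI*")
  expect_equal(unname(s1[others]), unname(s[others]))
  # immediately post injection all label is in plasma
  tr <- run(MODEL6, s1, times = 0, dose = dose)
  fr <- tracer_fractions(tr)
  expect_equal(fr$plasma[1], 1)
  expect_equal(sum(fr[1, -1]), 1)
})

test_that("transition time bookkeeping matches the first-order closed form", {
  expect_equal(transition_time(P6, qss = QSS6),
               1 / P6[["vRBCSpleen"]], tolerance = 1e-6)
  # a one-per-day exit constant gives a one-day residence time
  p1 <- iron_params(vRBCSpleen = 1)
  expect_equal(transition_time(p1), 1, tolerance = 1e-6)
})

test_that("tracer fractions sum to one and the dose cancels", {
  fr <- tracer_fractions(TRACER0)
  expect_true(all(abs(rowSums(fr[, -1]) - 1) < 1e-6))
  expect_true(all(as.matrix(fr[, -1]) >= 0 & as.matrix(fr[, -1]) <= 1 + 1e-9))
  # linearity of the labeled subsystem: halving the dose leaves fractions
  # unchanged
  s0 <- as_tracer_state(QSS6, MODEL6)
  d1 <- 1e-6 * plasma_iron_mol(s0, MODEL6)
  t1 <- run(MODEL6, inject_tracer(s0, d1, MODEL6), c(0, 1, 7, 28),
            dose = d1, atol = tracer_atol(MODEL6, d1))
  t2 <- run(MODEL6, inject_tracer(s0, d1 / 2, MODEL6), c(0, 1, 7, 28),
            dose = d1 / 2, atol = tracer_atol(MODEL6, d1 / 2))
  f1 <- as.matrix(tracer_fractions(t1)[, -1])
  f2 <- as.matrix(tracer_fractions(t2)[, -1])
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("plasma tracer clears monotonically over the first hour", {
  s0 <- inject_tracer(as_tracer_state(QSS6, MODEL6), 1e-9, MODEL6)
  tr <- run(MODEL6, s0, seq(0, 1 / 24, length.out = 25), dose = 1e-9)
  pl <- tracer_fractions(tr)$plasma
  expect_true(all(diff(pl) < 0))
})

test_that("the diet switch can only turn two knobs", {
  m2 <- apply_diet(MODEL6_PLAIN, vDiet = P6[["vDiet"]],
                   kHepSyn = P6[["kHepSyn"]])
  expect_equal(m2$params, MODEL6_PLAIN$params)
  expect_error(apply_diet(MODEL6_PLAIN, Km = 1), "refused")
  expect_error(apply_diet(MODEL6_PLAIN, kInLiver = 5), "refused")
  # starvation: with no dietary influx total body iron only decreases
  m0 <- apply_diet(MODEL6_PLAIN, vDiet = 0)
  tr <- run(m0, QSS6, seq(0, 200, by = 20))
  tot <- apply(tr$states, 1, total_iron, model = m0)
  expect_true(all(diff(tot) < 0))
})

test_that("hepcidin elevation reproduces the chronic-disease pattern", {
  a1 <- anemia_protocol(MODEL6_PLAIN, hepcidin_fold = 1, horizon_days = 50,
                        qss = QSS6, n_grid = 60)
  expect_true(all(abs(a1$fold_change - 1) < 1e-3))
  a5 <- anemia_protocol(MODEL6_PLAIN, hepcidin_fold = 5, horizon_days = 365,
                        qss = QSS6, n_grid = 400)
  f <- a5$fold_change
  expect_gt(f[["duodenum"]], 1)
  expect_lt(f[["plasma"]], 1)
  expect_gt(f[["liver"]], 1)
  expect_gt(f[["spleen"]], 1)
  # spleen overshoots early then relaxes
  spl <- a5$trajectory$states[, "FeSpleen"]
  expect_lt(a5$peaks$peak_time_days[a5$peaks$pool == "spleen"], 50)
  expect_gt(max(spl) / spl[1], f[["spleen"]])  # transient above endpoint
})
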