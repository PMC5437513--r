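test_that("objective is zero at the generating truth and order-invariant", {
  d <- generate_tracer_data(P6, times = c(0.5, 2, 7), noise_cv = 0,
                            qss = QSS6)
  expect_lt(objective(P6, d, qss = QSS6), 1e-10)
  set.seed(3)
  d2 <- d[sample(nrow(d)), ]
  p_off <- iron_params(kInRBC = 2, base = P6)
  expect_equal(objective(p_off, d, qss = QSS6),
               objective(p_off, d2, qss = QSS6))
})

test_that("weighted objective uses measurement uncertainties", {
  d <- generate_tracer_data(P6, times = c(1, 7), noise_cv = 0.05, seed = 2,
                            qss = QSS6)
  p_off <- iron_params(kInRBC = 1.3, base = P6)
  unw <- objective(p_off, d, qss = QSS6)
  w <- objective(p_off, d, weighted = TRUE, qss = QSS6)
  expect_gt(w, unw)  # sd ~ 5% of fractions < 1 inflates residuals
})

test_that("SRES solves smooth benchmarks and honours constraints", {
  r <- sres_optimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
                     lambda = 60, mu = 10, generations = 60, seed = 3)
  expect_lt(r$value, 1e-3)
  # constrained optimum on the boundary x1 = 0.5
  rc <- sres_optimize(function(x) list(f = sum(x^2),
                                       phi = max(0, 0.5 - x[1])),
                      rep(-5, 3), rep(5, 3), lambda = 60, mu = 10,
                      generations = 80, seed = 3)
  expect_true(rc$feasible)
  expect_equal(rc$par[1], 0.5, tolerance = 5e-3)
  expect_equal(rc$value, 0.25, tolerance = 2e-2)
})

test_that("SRES is deterministic under a fixed seed", {
  f <- function(x) list(f = sum((x - 1)^2), phi = max(0, x[2] - 2))
  r1 <- sres_optimize(f, c(-4, -4), c(4, 4), lambda = 30, mu = 5,
                      generations = 30, seed = 99)
  r2 <- sres_optimize(f, c(-4, -4), c(4, 4), lambda = 30, mu = 5,
                      generations = 30, seed = 99)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$value, r2$value)
})

test_that("stochastic ranking degenerates gracefully without a constraint", {
  # identical problem posed constrained-with-zero-violation and bare
  f1 <- function(x) sum((x - 2)^2)
  f2 <- function(x) list(f = sum((x - 2)^2), phi = 0)
  r1 <- sres_optimize(f1, c(-5, -5), c(5, 5), lambda = 40, mu = 6,
                      generations = 40, seed = 7)
  r2 <- sres_optimize(f2, c(-5, -5), c(5, 5), lambda = 40, mu = 6,
                      generations = 40, seed = 7)
  expect_identical(r1$par, r2$par)
})

test_that("local refinement descends and never worsens the objective", {
  f <- function(x) sum((x - c(1, -1))^2)
  r <- local_refine(f, c(3, 3), c(-5, -5), c(5, 5))
  expect_equal(r$par, c(1, -1), tolerance = 1e-5)
  # starting at the optimum stays there
  r0 <- local_refine(f, c(1, -1), c(-5, -5), c(5, 5))
  expect_equal(r0$value, 0, tolerance = 1e-10)
  # monotonicity on a rugged function
  g <- function(x) sum(x^2) + 0.3 * sum(sin(15 * x))
  start <- c(2, -2)
  rg <- local_refine(g, start, c(-5, -5), c(5, 5), maxfeval = 300)
  expect_lte(rg$value, g(start))
})

test_that("joint fits may only free vDiet and kHepSyn per diet", {
  d <- generate_tracer_data(P6, times = c(1, 7), noise_cv = 0, qss = QSS6)
  expect_error(fit_problem(list(d, d), diet_free = c("vDiet", "Km")),
               "Km")
  pr <- fit_problem(list(d, d), free = c("kInRBC"),
                    diet_free = c("vDiet", "kHepSyn"), base = P6)
  expect_equal(pr$theta_names,
               c("kInRBC", "vDiet@1", "kHepSyn@1", "vDiet@2", "kHepSyn@2"))
})

test_that("ensembles with identical seeds have zero parameter CV", {
  d <- generate_tracer_data(P6, times = c(1, 7, 28), noise_cv = 0,
                            qss = QSS6)
  prob <- fit_problem(d, free = c("kInRBC", "kRestOut"), base = P6)
  ens <- fit_ensemble(prob, n_runs = 2, seeds = c(5, 5), lambda = 12,
                      mu = 3, generations = 4, refine = FALSE)
  expect_equal(unname(ens$cv), c(0, 0))
  expect_identical(ens$fits[[1]]$theta, ens$fits[[2]]$theta)
})

test_that("model selection follows the transition-time rule", {
  mk <- function(tau, ssq, feas = TRUE) {
    structure(list(rbc_transition_days = tau, value = ssq,
                   feasible = feas), class = "iron_fit")
  }
  picked <- select_model(list(mk(12.0, 0.1), mk(42.5, 0.3), mk(75.9, 0.2)))
  expect_equal(picked$rbc_transition_days, 42.5)
  expect_equal(select_model(list(mk(50, 1)))$rbc_transition_days, 50)
  # tie at equal distance from 40 days: lower sum of squares wins
  tied <- select_model(list(mk(35, 0.5), mk(45, 0.2)))
  expect_equal(tied$value, 0.2)
  # infeasible fits are never selected
  expect_equal(select_model(list(mk(42, 0.1, FALSE), mk(20, 9)))$value, 9)
  expect_error(select_model(list(mk(42, 0.1, FALSE))),
               "constraint-satisfying")
})

test_that("parameter comparison flags shifted parameters", {
  A <- matrix(10^c(1, 1.05, 0.95, 2, 2.1, 1.9), nrow = 2, byrow = TRUE,
              dimnames = list(c("kInRBC", "kRestOut"), NULL))
  B <- A; B["kInRBC", ] <- B["kInRBC", ] * 100
  tab <- compare_params(A, B)
  expect_equal(tab$parameter[1], "kInRBC")
  expect_lt(tab$p_value[1], 0.01)
  # identical ensembles: statistic 0, p = 1 by convention
  same <- compare_params(A, A)
  expect_true(all(same$t == 0 | same$p_value == 1))
})
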