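# Constrained least-squares calibration against tracer datasets.
#
# The observable is the fraction of injected dose per pool; the objective
# is the unweighted sum of squared residuals over datasets x times x pools
# (optionally 1/sd^2-weighted when the dataset carries uncertainties), and
# the nonlinear constraint keeps total body iron at the injection state
# within [1.8, 2.2] mg.  Rate constants are searched on the log10 scale:
# they span ~10 orders of magnitude.

.default_free <- c("kInDuo", "kInLiver", "kInRBC", "kInRest", "kInBM",
                   "kDuoLoss", "kRestOut", "kBMSpleen", "vRBCSpleen",
                   "VDuoNTBI", "VLiverNTBI", "VSpleenNTBI", "VRestNTBI",
                   "Km", "kNTBI_Fe1Tf", "kFe1Tf_Fe2Tf")

#' Define a calibration problem
#'
#' Bundles datasets, the free parameters with their (log10) bounds, the
#' total-iron constraint and the simulation protocol into a `fit_problem`.
#' In joint (multi-diet) mode all parameters are shared across diets
#' except those named in `diet_free`, which must be a subset of
#' `c("vDiet", "kHepSyn")` -- the two knobs a diet is allowed to turn;
#' freeing any other parameter per diet is rejected.
#'
#' @param datasets a `tracer_data` (or list of them, one per diet).
#' @param free names of parameters estimated (shared across diets).
#' @param base baseline [iron_params()]; non-free parameters are fixed at
#'   these values (`vDiet` is fixed by default, mirroring the calibration
#'   choice of pinning dietary influx to its physiological value).
#' @param bounds 2 x n matrix of log10 bounds, columns named by parameter;
#'   default spans 2 decades either side of `base` (4 decades total).
#' @param diet_free per-diet free parameters (joint mode only).
#' @param constraint total-iron window in mg at the injection state.
#' @param weighted use 1/sd^2 weighting when the data carry sd.
#' @param leadin_days de-novo lead-in; `diet_leadin_days` applies to any
#'   dataset whose diet differs from the first (adequate-first layout).
#' @param diet_leadin_days re-equilibration after a diet switch.
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(datasets, free = .default_free,
                        base = iron_params(), bounds = NULL,
                        diet_free = NULL,
                        constraint = c(1.8, 2.2), weighted = FALSE,
                        leadin_days = 5000, diet_leadin_days = 35) {
  if (inherits(datasets, "tracer_data")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  lapply(datasets, validate_tracer_data)
  if (!is.null(diet_free)) {
    bad <- setdiff(diet_free, c("vDiet", "kHepSyn"))
    if (length(bad))
      stop("only vDiet and kHepSyn may vary per diet; refused: ",
           paste(bad, collapse = ", "))
    free <- setdiff(free, diet_free)
  }
  bad <- setdiff(free, .param_names)
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(bounds)) {
    ctr <- log10(unclass(base)[free])
    bounds <- rbind(lower = ctr - 2, upper = ctr + 2)
    colnames(bounds) <- free
  }
  stopifnot(all(free %in% colnames(bounds)))
  n_diet <- length(datasets)
  theta_names <- c(free,
                   if (!is.null(diet_free))
                     unlist(lapply(seq_len(n_diet), function(i)
                       paste0(diet_free, "@", i))))
  structure(list(datasets = datasets, free = free, base = base,
                 bounds = bounds, diet_free = diet_free,
                 theta_names = theta_names,
                 constraint = constraint, weighted = weighted,
                 leadin_days = leadin_days,
                 diet_leadin_days = diet_leadin_days),
            class = "fit_problem")
}

# full bounds in theta order (diet-free params get the base +/- 2 decades)
.theta_bounds <- function(problem) {
  lo <- problem$bounds["lower", problem$free]
  hi <- problem$bounds["upper", problem$free]
  if (!is.null(problem$diet_free)) {
    ctr <- log10(unclass(problem$base)[problem$diet_free])
    for (i in seq_along(problem$datasets)) {
      lo <- c(lo, ctr - 2); hi <- c(hi, ctr + 2)
    }
  }
  names(lo) <- names(hi) <- problem$theta_names
  list(lower = lo, upper = hi)
}

# per-diet full parameter sets from a theta vector (log10 scale)
.theta_to_params <- function(problem, theta) {
  p <- problem$base
  nf <- length(problem$free)
  if (nf) p[problem$free] <- 10^theta[seq_len(nf)]
  lapply(seq_along(problem$datasets), function(i) {
    pi <- p
    if (!is.null(problem$diet_free)) {
      off <- nf + (i - 1) * length(problem$diet_free)
      pi[problem$diet_free] <- 10^theta[off + seq_along(problem$diet_free)]
    }
    pi
  })
}

#' Sum-of-squares objective for a parameter set
#'
#' Simulates the tracer experiment implied by each dataset and returns
#' the sum over datasets, times and pools of squared residuals between
#' simulated and observed fraction of dose (1/sd^2-weighted when
#' requested and available).  An integration failure yields a large
#' penalty value rather than an error, so the optimizer can route around
#' pathological parameter regions.
#'
#' @param params an [iron_params()] candidate.
#' @param datasets a `tracer_data` or list of them.
#' @param weighted use 1/sd^2 weights.
#' @param leadin_days lead-in length.
#' @param qss optional pre-computed quasi-steady state for `params`.
#' @return the sum of squares (scalar).
#' @export
objective <- function(params, datasets, weighted = FALSE,
                      leadin_days = 5000, qss = NULL) {
  if (inherits(datasets, "tracer_data")) datasets <- list(datasets)
  tot <- 0
  for (d in datasets) {
    sim <- try(suppressWarnings(simulate_tracer_experiment(
      params, times = sort(unique(d$time_days)),
      leadin_days = leadin_days, qss = qss)), silent = TRUE)
    if (inherits(sim, "try-error")) return(1e6)
    tot <- tot + .dataset_ssq(sim, d, weighted)
  }
  tot
}

.dataset_ssq <- function(traj, d, weighted = FALSE) {
  fr <- tracer_fractions(traj)
  pm <- as.matrix(fr[, .pool_names])
  pred <- pm[cbind(match(d$time_days, fr$time_days),
                   match(d$pool, colnames(pm)))]
  res2 <- (pred - d$fraction_of_dose)^2
  if (weighted && "sd" %in% names(d) && all(is.finite(d$sd)) &&
      all(d$sd > 0))
    res2 <- res2 / d$sd^2
  sum(res2)
}

# One full candidate evaluation: per-diet lead-in, injection, SSQ and the
# total-iron constraint violation at the injection state.  The first
# dataset's diet defines the de-novo background; later datasets (joint
# mode) re-equilibrate for diet_leadin_days from that background.
.evaluate_theta <- function(problem, theta) {
  plist <- .theta_to_params(problem, theta)
  ssq <- 0; viol <- 0; totfe <- numeric(length(plist))
  qss1 <- NULL
  for (i in seq_along(plist)) {
    p <- plist[[i]]
    plain <- try(build_model(p, include_tracer = FALSE), silent = TRUE)
    if (inherits(plain, "try-error"))
      return(list(f = 1e6, phi = 1e6, totalfe = totfe))
    qss <- try(suppressWarnings({
      if (i == 1) {
        qss1 <- quasi_steady_state(plain, problem$leadin_days)
        qss1
      } else {
        final_state(run(plain, qss1, c(0, problem$diet_leadin_days)))
      }
    }), silent = TRUE)
    if (inherits(qss, "try-error"))
      return(list(f = 1e6, phi = 1e6, totalfe = totfe))
    totfe[i] <- total_iron(qss, plain)
    viol <- viol + max(0, problem$constraint[1] - totfe[i]) +
      max(0, totfe[i] - problem$constraint[2])
    d <- problem$datasets[[i]]
    sim <- try(suppressWarnings(simulate_tracer_experiment(
      p, times = sort(unique(d$time_days)), qss = qss)), silent = TRUE)
    if (inherits(sim, "try-error"))
      return(list(f = 1e6, phi = viol, totalfe = totfe))
    ssq <- ssq + .dataset_ssq(sim, d, problem$weighted)
  }
  list(f = ssq, phi = viol, totalfe = totfe)
}

.fit_result <- function(problem, theta, ev, optimizer, seed, evals = NA) {
  plist <- .theta_to_params(problem, theta)
  p <- plist[[1]]
  # derived quantities are recomputed from the returned parameters
  plain <- build_model(p, include_tracer = FALSE)
  qss <- quasi_steady_state(plain, problem$leadin_days)
  structure(list(
    params = p, params_per_diet = plist, theta = theta,
    free = problem$theta_names, value = ev$f,
    feasible = ev$phi == 0, violation = ev$phi,
    total_iron_mg = total_iron(qss, plain),
    tf_saturation_pct = tf_saturation(qss, plain),
    rbc_transition_days = transition_time(p, qss = qss),
    optimizer = optimizer, seed = seed, evals = evals,
    problem = problem
  ), class = "iron_fit")
}

#' Calibrate the iron model against tracer data
#'
#' The front-door fitting function: global search by the
#' stochastic-ranking evolution strategy ([sres_optimize()]) under the
#' total-iron constraint, optionally polished by Hooke-Jeeves pattern
#' search ([local_refine()]), on the log10 parameter scale.
#'
#' @param datasets a `tracer_data` or list of them (one per diet).
#' @param ... passed to [fit_problem()] (`free`, `base`, `bounds`,
#'   `diet_free`, `constraint`, `weighted`, ...).
#' @param problem alternatively, a ready-made [fit_problem()].
#' @param seed integer seed making the whole fit reproducible.
#' @param lambda,mu,generations,pf SRES settings (population, parents,
#'   generations, ranking-swap probability).
#' @param refine run the local polish after the global phase.
#' @param refine_feval evaluation budget of the polish.
#' @return an `iron_fit`: estimated parameters, objective value,
#'   constraint status, and derived quantities (total iron, transferrin
#'   saturation, RBC transition time) recomputed from the returned
#'   parameter values.
#' @seealso [fit_ensemble()], [select_model()], [compare_params()]
#' @export
fit_tracer <- function(datasets = NULL, ..., problem = NULL, seed = 1,
                       lambda = 200, mu = 30, generations = 250,
                       pf = 0.45, refine = TRUE, refine_feval = 1500) {
  if (is.null(problem)) problem <- fit_problem(datasets, ...)
  b <- .theta_bounds(problem)
  fn <- function(theta) .evaluate_theta(problem, theta)
  res <- sres_optimize(fn, b$lower, b$upper, lambda = lambda, mu = mu,
                       generations = generations, pf = pf, seed = seed)
  theta <- res$par; evals <- res$evals
  if (refine && !is.null(theta)) {
    pol <- local_refine(fn, theta, b$lower, b$upper,
                        maxfeval = refine_feval)
    theta <- pol$par; evals <- evals + (pol$evals %||% 0)
  }
  ev <- .evaluate_theta(problem, theta)
  .fit_result(problem, theta, ev,
              optimizer = if (refine) "SRES+HJ" else "SRES",
              seed = seed, evals = evals)
}

#' @export
print.iron_fit <- function(x, ...) {
  cat("<iron_fit> ", x$optimizer, " (seed ", x$seed, ", ",
      x$evals, " evaluations)\n", sep = "")
  cat("  sum of squares: ", format(x$value, digits = 5),
      if (x$feasible) "  [constraint satisfied]" else
        paste0("  [INFEASIBLE, violation ", format(x$violation, digits = 3), "]"),
      "\n", sep = "")
  cat("  total iron: ", format(x$total_iron_mg, digits = 4),
      " mg   Tf saturation: ", format(x$tf_saturation_pct, digits = 3),
      " %   RBC transition time: ",
      format(x$rbc_transition_days, digits = 4), " d\n", sep = "")
  invisible(x)
}

#' @export
coef.iron_fit <- function(object, free_only = FALSE, ...) {
  if (free_only) 10^object$theta else unclass(object$params)
}

#' @export
summary.iron_fit <- function(object, ...) {
  b <- .theta_bounds(object$problem)
  est <- 10^object$theta
  tab <- data.frame(parameter = object$free, estimate = est,
                    log10_lower = b$lower, log10_upper = b$upper,
                    at_bound = object$theta <= b$lower + 1e-9 |
                      object$theta >= b$upper - 1e-9)
  rownames(tab) <- NULL
  out <- list(coefficients = tab, value = object$value,
              feasible = object$feasible,
              derived = c(total_iron_mg = object$total_iron_mg,
                          tf_saturation_pct = object$tf_saturation_pct,
                          rbc_transition_days = object$rbc_transition_days))
  class(out) <- "summary.iron_fit"
  out
}

#' @export
print.summary.iron_fit <- function(x, ...) {
  cat("Calibrated iron model\n  sum of squares:", format(x$value, digits = 5),
      if (x$feasible) "(feasible)" else "(infeasible)", "\n")
  print(x$coefficients, digits = 4)
  cat("Derived:\n"); print(round(x$derived, 3))
  invisible(x)
}

#' @export
predict.iron_fit <- function(object, times = default_obs_times(),
                             diet = 1, ...) {
  p <- object$params_per_diet[[min(diet, length(object$params_per_diet))]]
  sim <- simulate_tracer_experiment(p, times = times,
                                    leadin_days = object$problem$leadin_days)
  fr <- tracer_fractions(sim)
  fr[match(times, fr$time_days), , drop = FALSE]
}

#' @export
residuals.iron_fit <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$problem$datasets)) {
    d <- object$problem$datasets[[i]]
    p <- object$params_per_diet[[i]]
    sim <- simulate_tracer_experiment(
      p, times = sort(unique(d$time_days)),
      leadin_days = object$problem$leadin_days)
    fr <- tracer_fractions(sim)
    pm <- as.matrix(fr[, .pool_names])
    pred <- pm[cbind(match(d$time_days, fr$time_days),
                     match(d$pool, colnames(pm)))]
    out[[i]] <- data.frame(dataset = i, time_days = d$time_days,
                           pool = d$pool, observed = d$fraction_of_dose,
                           fitted = pred,
                           residual = d$fraction_of_dose - pred)
  }
  do.call(rbind, out)
}

#' @export
plot.iron_fit <- function(x, diet = 1, ...) {
  d <- x$problem$datasets[[diet]]
  times <- sort(unique(d$time_days))
  dense <- sort(unique(c(times, 10^seq(log10(max(min(times), 1e-2)),
                                       log10(max(times)), length.out = 80))))
  fr <- predict(x, times = dense, diet = diet)
  old <- graphics::par(mfrow = c(2, 4), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in .pool_names) {
    obs <- d[d$pool == p, ]
    graphics::plot(fr$time_days, fr[[p]], type = "l", xlab = "days",
                   ylab = "fraction of dose", main = p,
                   ylim = range(0, fr[[p]], obs$fraction_of_dose), ...)
    graphics::points(obs$time_days, obs$fraction_of_dose, pch = 16)
  }
  invisible(x)
}

#' @export
simulate.iron_fit <- function(object, nsim = 1, seed = NULL,
                              noise_cv = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(1e6, nsim)
  out <- lapply(seeds, function(s)
    generate_tracer_data(object$params,
                         times = sort(unique(object$problem$datasets[[1]]$time_days)),
                         noise_cv = noise_cv, seed = s))
  if (nsim == 1) out[[1]] else out
}

#' Ensemble of independent calibrations
#'
#' Runs `n_runs` independent fits (different seeds) and summarizes
#' per-parameter variability across runs as a coefficient of variation
#' (sd/mean), the identifiability diagnostic: well-determined parameters
#' show small CVs across independent estimates, poorly identifiable ones
#' vary by orders of magnitude.
#'
#' @param problem a [fit_problem()].
#' @param n_runs number of independent runs (>= 2 for a CV).
#' @param seeds integer seeds, one per run.
#' @param ... passed to [fit_tracer()] (SRES budget etc.).
#' @return list with `fits` (list of `iron_fit`), `cv` (named vector,
#'   percent), and `summary` (parameters x runs table).
#' @export
fit_ensemble <- function(problem, n_runs = 3,
                         seeds = seq_len(n_runs), ...) {
  stopifnot(length(seeds) == n_runs)
  fits <- lapply(seeds, function(s)
    fit_tracer(problem = problem, seed = s, ...))
  est <- sapply(fits, function(f) 10^f$theta)
  rownames(est) <- problem$theta_names
  colnames(est) <- paste0("run", seq_len(n_runs))
  cv <- apply(est, 1, function(v) 100 * sd(v) / mean(v))
  list(fits = fits, cv = cv, summary = est)
}

#' Select a model from an ensemble by RBC transition time
#'
#' Among constraint-satisfying fits, returns the one whose RBC transition
#' time is closest to the target mean erythrocyte lifetime (40 days in
#' the mouse); ties are broken by the lower sum of squares.
#'
#' @param results list of `iron_fit` objects (or a [fit_ensemble()]
#'   result).
#' @param target_transition target RBC residence time (days).
#' @return the selected `iron_fit`.
#' @export
select_model <- function(results, target_transition = 40) {
  if (is.list(results) && !is.null(results$fits)) results <- results$fits
  stopifnot(length(results) >= 1)
  feas <- Filter(function(f) isTRUE(f$feasible), results)
  if (!length(feas)) stop("no constraint-satisfying fit in the ensemble")
  dist <- vapply(feas, function(f)
    abs(f$rbc_transition_days - target_transition), numeric(1))
  ssq <- vapply(feas, function(f) f$value, numeric(1))
  feas[[order(dist, ssq)[1]]]
}

#' Per-parameter comparison of two fit ensembles
#'
#' Welch two-sample t-test on log10 parameter values, one test per shared
#' parameter, sorted by p-value: the parameters most significantly
#' different between two calibration conditions (e.g. adequate vs rich
#' diet) are the processes whose regulation the shared model structure
#' fails to capture.
#'
#' @param ensembleA,ensembleB [fit_ensemble()] results, lists of
#'   `iron_fit`s, or parameters-by-runs matrices.
#' @return data.frame: parameter, group means (log10), t statistic,
#'   p value, BH-adjusted p value; sorted by p.
#' @export
compare_params <- function(ensembleA, ensembleB) {
  as_mat <- function(e) {
    if (is.matrix(e)) return(log10(e))
    if (is.list(e) && !is.null(e$summary)) return(log10(e$summary))
    if (is.list(e)) {
      m <- sapply(e, function(f) f$theta)
      rownames(m) <- e[[1]]$free
      return(m)
    }
    stop("cannot interpret ensemble")
  }
  A <- as_mat(ensembleA); B <- as_mat(ensembleB)
  shared <- intersect(rownames(A), rownames(B))
  if (!length(shared)) stop("no shared parameters between ensembles")
  rows <- lapply(shared, function(p) {
    a <- A[p, ]; b <- B[p, ]
    if (sd(a) == 0 && sd(b) == 0) {
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- t.test(a, b)
    }
    data.frame(parameter = p, mean_log10_A = mean(a), mean_log10_B = mean(b),
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, "BH")
  out[order(out$p_value, -abs(out$t)), ]
}
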