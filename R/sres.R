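#' Evolution strategy with stochastic ranking (SRES)
#'
#' (mu, lambda) evolution strategy with self-adaptive step sizes and
#' stochastic ranking of objective versus constraint violation, the
#' constrained global optimizer used for model calibration (the total-iron
#' window makes the estimation problem nonlinearly constrained, which is
#' what this algorithm handles well).
#'
#' Stochastic ranking sorts the population by a bubble pass in which two
#' adjacent individuals are compared on the objective with probability
#' `pf` (or when both are feasible) and on the constraint violation
#' otherwise, balancing feasibility pressure against objective descent.
#' With no constraint (violation identically zero) the ranking degenerates
#' to plain objective sorting and the algorithm reduces to an
#' unconstrained evolution strategy.
#'
#' @param fn function of a parameter vector returning `list(f = objective,
#'   phi = constraint violation >= 0)`; a bare numeric return is treated
#'   as an unconstrained objective.
#' @param lower,upper finite bounds (search space; offspring are clipped).
#' @param lambda offspring population size.
#' @param mu parent number (default `lambda/7`, rounded, >= 2).
#' @param generations number of generations.
#' @param pf probability of comparing on the objective when at least one
#'   of a pair is infeasible.
#' @param seed integer seed; same seed, same result.
#' @param init optional matrix of initial candidates (rows) to seed the
#'   population.
#' @return list: `par` (best feasible, or best by ranking if none
#'   feasible), `value`, `violation`, `feasible`, `evals`, `trace`
#'   (best feasible objective per generation).
#' @references Runarsson & Yao (2000) IEEE Trans. Evol. Comput. 4:284-294.
#' @export
sres_optimize <- function(fn, lower, upper, lambda = 200, mu = 30,
                          generations = 250, pf = 0.45, seed = NULL,
                          init = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower), lambda >= 4)
  n <- length(lower)
  if (is.null(mu)) mu <- max(2L, round(lambda / 7))
  mu <- min(mu, lambda - 1L)
  if (!is.null(seed)) set.seed(seed)

  eval1 <- function(x) {
    r <- fn(x)
    if (!is.list(r)) r <- list(f = r, phi = 0)
    if (!is.finite(r$f)) r$f <- 1e12
    if (!is.finite(r$phi)) r$phi <- 1e12
    r
  }

  tau  <- 1 / sqrt(2 * sqrt(n))
  taup <- 1 / sqrt(2 * n)
  sigma0 <- (upper - lower) / sqrt(n)

  X <- matrix(runif(lambda * n, rep(lower, each = lambda),
                    rep(upper, each = lambda)), nrow = lambda)
  if (!is.null(init)) {
    init <- as.matrix(init)
    k <- min(nrow(init), lambda)
    X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 rep(lower, each = k)),
                            rep(upper, each = k))
  }
  S <- matrix(rep(sigma0, each = lambda), nrow = lambda)

  evals <- 0L
  best <- list(par = NULL, value = Inf, violation = Inf, feasible = FALSE)
  trace <- numeric(generations)

  rank_sr <- function(f, phi) {
    idx <- seq_along(f)
    N <- length(f)
    for (sweep_i in seq_len(N)) {
      swapped <- FALSE
      for (j in seq_len(N - 1)) {
        a <- idx[j]; b <- idx[j + 1]
        use_f <- (phi[a] == 0 && phi[b] == 0) || (runif(1) < pf)
        do_swap <- if (use_f) f[a] > f[b] else phi[a] > phi[b]
        if (do_swap) { idx[j] <- b; idx[j + 1] <- a; swapped <- TRUE }
      }
      if (!swapped) break
    }
    idx
  }

  for (g in seq_len(generations)) {
    res <- lapply(seq_len(lambda), function(i) eval1(X[i, ]))
    evals <- evals + lambda
    f <- vapply(res, `[[`, numeric(1), "f")
    phi <- vapply(res, `[[`, numeric(1), "phi")

    feas <- phi == 0
    cand <- if (any(feas)) which(feas)[which.min(f[feas])] else NULL
    if (!is.null(cand) &&
        (!best$feasible || f[cand] < best$value)) {
      best <- list(par = X[cand, ], value = f[cand], violation = 0,
                   feasible = TRUE)
    } else if (!best$feasible) {
      alt <- which.min(phi + f * 1e-12)
      if (phi[alt] < best$violation)
        best <- list(par = X[alt, ], value = f[alt], violation = phi[alt],
                     feasible = FALSE)
    }
    trace[g] <- if (best$feasible) best$value else NA_real_

    ord <- rank_sr(f, phi)
    parents <- ord[seq_len(mu)]
    Xp <- X[parents, , drop = FALSE]
    Sp <- S[parents, , drop = FALSE]

    pick <- ((seq_len(lambda) - 1L) %% mu) + 1L
    g_noise <- rnorm(lambda)
    Xn <- matrix(0, lambda, n); Sn <- matrix(0, lambda, n)
    for (i in seq_len(lambda)) {
      si <- Sp[pick[i], ] * exp(taup * g_noise[i] + tau * rnorm(n))
      si <- pmin(si, upper - lower)
      xi <- Xp[pick[i], ] + si * rnorm(n)
      Xn[i, ] <- pmin(pmax(xi, lower), upper)
      Sn[i, ] <- si
    }
    X <- Xn; S <- Sn
  }
  best$evals <- evals
  best$trace <- trace
  best
}

#' Derivative-free local refinement (Hooke-Jeeves pattern search)
#'
#' Polishes a candidate by Hooke-Jeeves pattern search on a penalized
#' objective (`f + 1e6 * phi^2`), within bounds.  The search is monotone:
#' the returned value never exceeds the starting one.
#'
#' @param fn as in [sres_optimize()].
#' @param start starting point (must lie within the bounds).
#' @param lower,upper bounds.
#' @param maxfeval evaluation budget.
#' @param tol step-size convergence tolerance.
#' @return list(`par`, `value`, `violation`, `feasible`, `evals`).
#' @export
local_refine <- function(fn, start, lower, upper, maxfeval = 2000,
                         tol = 1e-8) {
  stopifnot(all(start >= lower - 1e-12), all(start <= upper + 1e-12))
  start <- pmin(pmax(start, lower), upper)
  pen <- function(x) {
    r <- fn(x)
    if (!is.list(r)) r <- list(f = r, phi = 0)
    f <- if (is.finite(r$f)) r$f else 1e12
    phi <- if (is.finite(r$phi)) r$phi else 1e12
    f + 1e6 * phi^2
  }
  if (length(start) == 1) {
    op <- optimize(function(x) pen(x), lower = lower, upper = upper,
                   tol = max(tol, 1e-10))
    hj <- list(xmin = op$minimum, count = NA_integer_)
    if (pen(start) < op$objective) hj$xmin <- start
  } else {
    hj <- suppressWarnings(
      pracma::hooke_jeeves(start, pen, lb = lower, ub = upper,
                           tol = tol, maxfeval = maxfeval))
  }
  r <- fn(hj$xmin)
  if (!is.list(r)) r <- list(f = r, phi = 0)
  # monotonicity guard against any pathological penalized/raw mismatch
  r0 <- fn(start)
  if (!is.list(r0)) r0 <- list(f = r0, phi = 0)
  if (r$f + 1e6 * r$phi^2 > r0$f + 1e6 * r0$phi^2) {
    hj$xmin <- start; r <- r0
  }
  list(par = hj$xmin, value = r$f, violation = r$phi,
       feasible = r$phi == 0, evals = hj$count %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
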