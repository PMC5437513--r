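# Simulation protocols: quasi-steady-state lead-in, tracer injection,
# diet switching and the chronic-disease (raised hepcidin) experiment.

#' Quasi-steady-state lead-in
#'
#' Integrates the model for a long lead-in (default 5000 days for de-novo
#' equilibration; diet experiments re-equilibrate for 35 days from a stored
#' state) so that the unlabeled species reach a quasi steady state before a
#' tracer pulse.  The only secular drift left is the slow diet/loss iron
#' balance.
#'
#' @param model an `iron_model`.
#' @param leadin_days duration (days).
#' @param init starting state; defaults to empty iron pools.
#' @return final state, with attribute `residual` = max relative
#'   derivative (per day) over the concentration species.
#' @export
quasi_steady_state <- function(model, leadin_days = 5000,
                               init = default_state(model)) {
  stopifnot(leadin_days > 0)
  traj <- run(model, init, times = c(0, leadin_days))
  s <- final_state(traj)
  d <- model_rhs(model, s)
  scale <- pmax(abs(s), 1e-12)
  attr(s, "residual") <- max(abs(d) / scale)
  s
}

#' Inject a radioactive tracer dose into plasma NTBI
#'
#' Adds `dose_mol / V_plasma` to the NTBI* concentration, leaving all
#' other species untouched, and records the dose (the denominator of all
#' fraction-of-dose observables).  The dose is chosen small relative to
#' total body iron so the perturbation of the unlabeled system is
#' negligible; tracer fractions are invariant to its exact value because
#' the labeled subsystem is linear at a fixed unlabeled background.
#'
#' @param state tracer-model state (see [as_tracer_state()]).
#' @param dose_mol injected amount of labeled iron (mol).
#' @param model the tracer `iron_model`.
#' @return state with incremented NTBI* and attribute `dose`.
#' @export
inject_tracer <- function(state, dose_mol, model) {
  stopifnot(dose_mol >= 0)
  vp <- .volumes_of(model)[["plasma"]]
  state[["NTBI*"]] <- state[["NTBI*"]] + dose_mol / vp
  attr(state, "dose") <- dose_mol
  state
}

#' Lift a tracer-free state into the tracer model
#'
#' @param state state of the tracer-free model.
#' @param model the tracer `iron_model` to lift into.
#' @return full tracer-model state with all labeled pools at zero.
#' @export
as_tracer_state <- function(state, model) {
  s <- setNames(numeric(nrow(model$species)), model$species$name)
  common <- intersect(names(state), names(s))
  s[common] <- state[common]
  s
}

#' Plasma iron amount of a state (mol)
#'
#' Sums NTBI and transferrin-bound iron (mono- and di-ferric, labeled and
#' unlabeled) over the plasma volume.  Used to size the default injection
#' dose.
#'
#' @param state model state.
#' @param model the `iron_model`.
#' @return mol of iron in plasma.
#' @export
plasma_iron_mol <- function(state, model) {
  vp <- .volumes_of(model)[["plasma"]]
  g <- function(nm) if (nm %in% names(state)) state[[nm]] else 0
  (g("NTBI") + g("NTBI*") + g("Fe1Tf") + g("Fe1Tf*") +
      2 * (g("Fe2Tf") + g("Fe2Tf*") + g("Fe2Tf**"))) * vp
}

#' Simulate a complete tracer experiment
#'
#' Lead-in to quasi steady state (on the tracer-free system for speed),
#' optional diet-switch re-equilibration, tracer pulse into plasma, then
#' integration over the observation grid.
#'
#' @param params an [iron_params()] set (ground truth or candidate).
#' @param times observation days post-injection.  The default grid spans
#'   the fast plasma clearance and the slow erythroid phase.
#' @param leadin_days de-novo equilibration length.
#' @param dose_mol injected dose; default 1e-6 of the quasi-steady-state
#'   plasma iron amount, small enough that the labeled NTBI pulse is
#'   negligible against circulating NTBI and the tracer subsystem is
#'   linear (fractions of dose independent of the dose).
#' @param qss optional pre-computed tracer-free quasi-steady state
#'   (skips the lead-in; used by diet protocols and the fitting loop).
#' @param volumes optional compartment-volume overrides.
#' @return `iron_traj` over `c(0, times)` with the dose recorded.
#' @export
simulate_tracer_experiment <- function(params,
                                       times = default_obs_times(),
                                       leadin_days = 5000,
                                       dose_mol = NULL, qss = NULL,
                                       volumes = NULL) {
  plain <- build_model(params, include_tracer = FALSE, volumes = volumes)
  if (is.null(qss)) qss <- quasi_steady_state(plain, leadin_days)
  tracer <- build_model(params, include_tracer = TRUE, volumes = volumes)
  s0 <- as_tracer_state(qss, tracer)
  if (is.null(dose_mol)) dose_mol <- 1e-6 * plasma_iron_mol(s0, tracer)
  s0 <- inject_tracer(s0, dose_mol, tracer)
  grid <- if (times[1] > 0) c(0, times) else times
  run(tracer, s0, grid, dose = dose_mol, atol = tracer_atol(tracer, dose_mol))
}

#' Default observation grid for tracer experiments (days)
#' @export
default_obs_times <- function()
  c(0.01, 0.04, 0.17, 0.5, 1, 2, 4, 7, 10, 14, 21, 28)

#' Per-species absolute tolerance for tracer simulations
#'
#' The labeled pools live at concentrations proportional to the (small)
#' injected dose; a fixed absolute tolerance tuned to the unlabeled
#' system would swamp them.  Labeled species get an absolute tolerance of
#' 1e-10 of the dose expressed in their own compartment's concentration
#' units (or in mol for the amount pools), unlabeled species keep 1e-12.
#'
#' @param model tracer `iron_model`.
#' @param dose_mol injected dose (mol).
#' @return numeric vector of per-species absolute tolerances.
#' @export
tracer_atol <- function(model, dose_mol) {
  sp <- model$species
  vol <- .volumes_of(model)
  atol <- rep(1e-12, nrow(sp))
  lab <- sp$fe_l > 0
  conc <- sp$unit == "conc"
  atol[lab & conc] <- 1e-10 * dose_mol / vol[sp$compartment[lab & conc]]
  atol[lab & !conc] <- 1e-10 * dose_mol
  pmin(atol, 1e-12)
}

#' Steady-state transition time of a pool
#'
#' Pool iron content divided by total outflow flux at the quasi steady
#' state -- the mean residence time of an iron atom in the pool.  For the
#' RBC pool, whose only exit is first-order transfer to the spleen, this
#' equals `1/vRBCSpleen` exactly; the function computes it by flux
#' bookkeeping over the reaction network so the identity is a check, not
#' an assumption.
#'
#' @param params an [iron_params()] set.
#' @param pool one of `"rbc"`, `"bone_marrow"`, `"duodenum"`, `"liver"`,
#'   `"spleen"`, `"rest"`, `"plasma"`.
#' @param leadin_days lead-in used to reach the steady state.
#' @param qss optional pre-computed tracer-free quasi-steady state.
#' @return transition time in days (NA with a warning if the pool has no
#'   steady-state throughput).
#' @examples
#' transition_time(published_params(6))  # ~42.5 days
#' @export
transition_time <- function(params, pool = "rbc", leadin_days = 5000,
                            qss = NULL) {
  model <- build_model(params, include_tracer = FALSE)
  if (is.null(qss)) qss <- quasi_steady_state(model, leadin_days)
  sp <- model$species
  vol <- .volumes_of(model)
  pool <- match.arg(pool, setdiff(.pool_names, "excreted"))
  in_pool <- sp$compartment == pool & (sp$fe_u + sp$fe_l) > 0
  species <- sp$name[in_pool]
  fe <- (sp$fe_u + sp$fe_l)[in_pool]
  content <- sum(fe * qss[species] * vol[[pool]])
  fl <- reaction_fluxes(model, qss)
  outflow <- 0
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    consumed <- intersect(names(r$reactants), species)
    if (length(consumed)) {
      idx <- match(consumed, species)
      outflow <- outflow +
        sum(fe[idx] * unlist(r$reactants[consumed])) * fl[[i]]
    }
  }
  if (outflow <= 0) {
    warning("pool '", pool, "' has no steady-state throughput; transition time undefined")
    return(NA_real_)
  }
  content / outflow
}

#' Switch the dietary regime
#'
#' Returns a model in which exactly two parameters are replaced: the
#' dietary iron influx `vDiet` and the hepcidin synthesis rate `kHepSyn`.
#' These are the only two knobs the diet/disease protocols may turn; any
#' other parameter passed is rejected.
#'
#' @param model an `iron_model`.
#' @param vDiet new dietary influx (M/day), or NULL to keep.
#' @param kHepSyn new hepcidin synthesis rate (M/day), or NULL to keep.
#' @param ... guard: anything else is an error.
#' @return the modified model.
#' @export
apply_diet <- function(model, vDiet = NULL, kHepSyn = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("apply_diet may only change vDiet and kHepSyn; refused: ",
         paste(names(extra), collapse = ", "))
  p <- model$params
  if (!is.null(vDiet)) { stopifnot(vDiet >= 0); p[["vDiet"]] <- vDiet }
  if (!is.null(kHepSyn)) { stopifnot(kHepSyn >= 0); p[["kHepSyn"]] <- kHepSyn }
  build_model(p, include_tracer = model$include_tracer,
              volumes = NULL)
}

#' Simulate the anemia of chronic disease
#'
#' From the adequate-diet quasi steady state, scales the hepcidin
#' synthesis rate so the steady hepcidin level is `hepcidin_fold` times
#' baseline, integrates for `horizon_days`, and reports per-pool
#' concentration fold changes (final/initial) together with the peak value
#' and peak time of the transiently overshooting spleen and liver pools.
#'
#' @param model tracer-free `iron_model` at the adequate diet.
#' @param hepcidin_fold multiplier on the steady hepcidin level.
#' @param horizon_days simulated duration.
#' @param qss optional pre-computed baseline quasi-steady state.
#' @param n_grid output resolution.
#' @return list: `trajectory` (`iron_traj`), `fold_change` (named vector
#'   over pools + `total_iron`), `peaks` (data.frame for spleen and liver).
#' @export
anemia_protocol <- function(model, hepcidin_fold = 5, horizon_days = 365,
                            qss = NULL, n_grid = 600) {
  stopifnot(hepcidin_fold > 0, horizon_days > 0)
  if (model$include_tracer)
    model <- build_model(model$params, include_tracer = FALSE)
  if (is.null(qss)) qss <- quasi_steady_state(model)
  sick <- apply_diet(model, kHepSyn = model$params[["kHepSyn"]] * hepcidin_fold)
  times <- seq(0, horizon_days, length.out = n_grid)
  traj <- run(sick, qss, times)
  s0 <- traj$states[1, ]; s1 <- final_state(traj)
  vp <- .volumes_of(model)[["plasma"]]
  plasma_fe <- function(s) s[["NTBI"]] + s[["Fe1Tf"]] + 2 * s[["Fe2Tf"]]
  pools <- c(plasma = NA, duodenum = "FeDuo", bone_marrow = "FeBM",
             rbc = "FeRBC", liver = "FeLiver", spleen = "FeSpleen",
             rest = "FeRest")
  fold <- c(plasma = plasma_fe(s1) / plasma_fe(s0),
            vapply(pools[-1], function(nm) s1[[nm]] / s0[[nm]], numeric(1)),
            total_iron = total_iron(s1, model) / total_iron(s0, model))
  peaks <- do.call(rbind, lapply(c(spleen = "FeSpleen", liver = "FeLiver"),
    function(nm) {
      v <- traj$states[, nm]
      i <- which.max(v)
      data.frame(peak_time_days = times[i], peak_over_initial = v[i] / v[1])
    }))
  peaks$pool <- c("spleen", "liver")
  list(trajectory = traj, fold_change = fold, peaks = peaks,
       hepcidin_fold = hepcidin_fold)
}
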