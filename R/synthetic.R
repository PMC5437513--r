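# Synthetic tracer datasets with the structure of the radioiron
# distribution experiment: per-compartment fraction of a small injected
# dose over ~0-28 days, for the 8 reported pools, with optional
# proportional noise.  Stands in for the external mouse dataset during
# calibration testing and parameter recovery.

#' Generate a synthetic tracer time-course dataset
#'
#' Simulates the full experiment (lead-in to quasi steady state, optional
#' 35-day diet-switch re-equilibration, tracer pulse, sampling at
#' `times`), then applies multiplicative Gaussian noise with coefficient
#' of variation `noise_cv`, truncated at zero, and records `sd = noise_cv
#' * mean`.  Proportional noise is the simplest structure consistent with
#' per-point error bars growing with the signal; it is a stand-in, not a
#' reconstruction of the original measurement error.
#'
#' @param true_params ground-truth [iron_params()].
#' @param times observation days post-injection.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = exact model output).
#' @param seed integer; the dataset is reproducible given the seed.
#' @param diet label stored in the metadata ("adequate", "deficient",
#'   "rich", ...).
#' @param base_params if the experiment switches diet: the pre-switch
#'   (adequate) parameter set used for the de-novo lead-in, after which
#'   `true_params` is applied for `diet_leadin_days` before injection.
#' @param leadin_days de-novo equilibration (days).
#' @param diet_leadin_days diet re-equilibration before the pulse (days).
#' @param dose_mol injected dose; default 1e-4 of plasma iron.
#' @param qss optional pre-computed tracer-free quasi steady state of
#'   `true_params` (or of `base_params` when switching diet).
#' @return data.frame of class `tracer_data` with columns
#'   `time_days, pool, fraction_of_dose, sd` and metadata attributes
#'   (`params`, `diet`, `seed`, `noise_cv`).
#' @examples
#' d <- generate_tracer_data(published_params(6), times = c(1, 7, 28),
#'                           noise_cv = 0.05, seed = 1)
#' head(d)
#' @export
generate_tracer_data <- function(true_params, times = default_obs_times(),
                                 noise_cv = 0, seed = NULL,
                                 diet = "adequate", base_params = NULL,
                                 leadin_days = 5000, diet_leadin_days = 35,
                                 dose_mol = NULL, qss = NULL) {
  stopifnot(noise_cv >= 0, all(times >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(base_params)) {
    plain_base <- build_model(base_params, include_tracer = FALSE)
    if (is.null(qss)) qss <- quasi_steady_state(plain_base, leadin_days)
    plain <- build_model(true_params, include_tracer = FALSE)
    qss <- final_state(run(plain, qss, c(0, diet_leadin_days)))
  }
  traj <- simulate_tracer_experiment(true_params, times = times,
                                     leadin_days = leadin_days,
                                     dose_mol = dose_mol, qss = qss)
  fr <- tracer_fractions(traj)
  fr <- fr[match(times, fr$time_days), , drop = FALSE]
  long <- do.call(rbind, lapply(.pool_names, function(p)
    data.frame(time_days = fr$time_days, pool = p, mean = fr[[p]],
               stringsAsFactors = FALSE)))
  z <- if (noise_cv > 0) rnorm(nrow(long)) else numeric(nrow(long))
  long$fraction_of_dose <- pmax(0, long$mean * (1 + noise_cv * z))
  long$sd <- if (noise_cv > 0) noise_cv * long$mean else NA_real_
  out <- long[order(long$time_days, long$pool),
              c("time_days", "pool", "fraction_of_dose", "sd")]
  rownames(out) <- NULL
  structure(out, class = c("tracer_data", "data.frame"),
            params = true_params, diet = diet, seed = seed,
            noise_cv = noise_cv)
}

#' Diet scenario parameter sets for synthetic experiments
#'
#' Illustrative ground truths for deficient and rich synthetic scenarios:
#' deficient scales (vDiet, kHepSyn) by (0.25, 0.5), rich by (4, 1.35).
#' These factors are plausible defaults for generating test data (the
#' rich hepcidin factor yields the ~35% rise in circulating hepcidin seen
#' when refitting rich-diet data); they are not fitted values.
#'
#' @param base adequate-diet [iron_params()].
#' @param which one of "adequate", "deficient", "rich".
#' @return `iron_params` for the scenario.
#' @export
diet_scenario <- function(base = published_params(6),
                          which = c("adequate", "deficient", "rich")) {
  which <- match.arg(which)
  fac <- switch(which, adequate = c(1, 1), deficient = c(0.25, 0.5),
                rich = c(4, 1.35))
  iron_params(vDiet = base[["vDiet"]] * fac[1],
              kHepSyn = base[["kHepSyn"]] * fac[2], base = base)
}

#' Validate a tracer dataset's invariants
#' @keywords internal
validate_tracer_data <- function(d, where = "tracer dataset") {
  req <- c("time_days", "pool", "fraction_of_dose")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(where, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(d$pool %in% .pool_names))
  if (length(bad))
    stop(where, ": unknown pool name '", d$pool[bad[1]], "' at row ", bad[1])
  bad <- which(d$time_days < 0)
  if (length(bad))
    stop(where, ": negative time at row ", bad[1])
  bad <- which(d$fraction_of_dose < 0 | d$fraction_of_dose > 1)
  if (length(bad))
    stop(where, ": fraction_of_dose outside [0, 1] at row ", bad[1])
  invisible(d)
}
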