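# Shared fixtures: the canonical parameter set, its models and quasi
# steady state, computed once per test run.

P6 <- published_params(6)
MODEL6 <- build_model(P6, include_tracer = TRUE)
MODEL6_PLAIN <- build_model(P6, include_tracer = FALSE)
QSS6 <- quasi_steady_state(MODEL6_PLAIN)

# a short post-injection tracer trajectory used by several conservation
# and observable tests
TRACER0 <- local({
  s0 <- inject_tracer(as_tracer_state(QSS6, MODEL6),
                      1e-6 * plasma_iron_mol(as_tracer_state(QSS6, MODEL6),
                                             MODEL6),
                      MODEL6)
  run(MODEL6, s0, c(0, 0.01, 0.1, 0.5, 1, 3, 7, 14, 28),
      dose = attr(s0, "dose"),
      atol = tracer_atol(MODEL6, attr(s0, "dose")))
})

# random nonnegative tracer-model states for property tests
random_state <- function(model, scale = 1e-4) {
  s <- setNames(abs(rnorm(nrow(model$species))) * scale,
                model$species$name)
  s[["Hepcidin"]] <- abs(rnorm(1)) * 1e-8
  s
}
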