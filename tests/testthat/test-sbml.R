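test_that("SBML export/read-back preserves the species inventory", {
  f <- tempfile(fileext = ".xml")
  export_sbml(MODEL6, f)
  sb <- read_sbml(f)
  expect_equal(nrow(sb$species), nrow(MODEL6$species))
  expect_setequal(sb$species$name, MODEL6$species$name)
  expect_equal(unname(sb$compartments["plasma"]), 1.3e-3)
  expect_equal(unname(sb$parameters["vRBCSpleen"]), 0.0235)
  # tracer-free export carries no starred species
  f2 <- tempfile(fileext = ".xml")
  export_sbml(MODEL6_PLAIN, f2)
  sb2 <- read_sbml(f2)
  expect_equal(nrow(sb2$species), nrow(MODEL6_PLAIN$species))
  expect_false(any(grepl("\\*", sb2$species$name)))
})

test_that("exported ferroportin kinetic law evaluates like the rate law", {
  f <- tempfile(fileext = ".xml")
  export_sbml(MODEL6, f)
  sb <- read_sbml(f)
  set.seed(8)
  for (i in 1:3) {
    S <- runif(1, 0, 1e-3); Ic <- runif(1, 0, 1e-3)
    Hep <- runif(1, 0, 1e-7)
    env <- list(FeSpleen = S, FeSpleen_t = Ic, Hepcidin = Hep)
    got <- sb$kinetic_law("fpn_Spleen", env)
    want <- ferroportin_rate(S, Ic, Hep, P6[["VSpleenNTBI"]], P6[["Km"]],
                             P6[["Ki"]], 6.7e-5)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # mass-action and binding laws round-trip numerically too
  env <- list(FeRBC = 2e-3, FeRBC_t = 0)
  expect_equal(sb$kinetic_law("rbc_to_spleen", env),
               mass_action_flux(P6[["vRBCSpleen"]], 2e-3, 7.9e-4))
  env <- list(NTBI = 3e-8, Tf = 1.6e-5)
  expect_equal(sb$kinetic_law("bind_NTBI_Tf", env),
               tf_binding_flux(P6[["kNTBI_Fe1Tf"]], 3e-8, 1.6e-5, 1.3e-3))
})
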