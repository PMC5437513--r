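test_that("ferroportin export law evaluates correctly and symmetrically", {
  # direct hand evaluation: 1 * 1e-3 * 0.01 / ((0.01 + 0.01) * 1) = 5e-4
  expect_equal(ferroportin_rate(S = 0.01, Ic = 0, Hep = 0, V = 1,
                                Km = 0.01, Ki = 23e-9, volume = 1e-3),
               5e-4)
  expect_equal(ferroportin_rate(0, 0.01, 1e-8, 2, 0.01, 1e-9, 1e-3), 0)
  # hepcidin at Ki exactly halves the flux
  v0 <- ferroportin_rate(0.003, 0.001, 0, 1.34, 0.0159, 1e-9, 6.7e-5)
  v1 <- ferroportin_rate(0.003, 0.001, 1e-9, 1.34, 0.0159, 1e-9, 6.7e-5)
  expect_equal(v1, v0 / 2)
  # the labeled twin's law is the same expression with (S, Ic) swapped,
  # so both reactions share one saturating denominator: flux ratio equals
  # the substrate ratio
  a <- ferroportin_rate(0.004, 0.001, 5e-9, 0.2, 0.0159, 1e-9, 3.9e-5)
  b <- ferroportin_rate(0.001, 0.004, 5e-9, 0.2, 0.0159, 1e-9, 3.9e-5)
  expect_equal(a / b, 0.004 / 0.001)
  expect_error(ferroportin_rate(-1, 0, 0, 1, 0.01, 1e-9, 1e-3))
})

test_that("first-order and bimolecular fluxes are extensive (mol/day)", {
  expect_equal(mass_action_flux(1, 1, 1), 1)
  expect_equal(mass_action_flux(0.0235, 0.01, 7.9e-4), 1.8565e-7)
  expect_equal(mass_action_flux(0.5, 0, 1e-3), 0)
  expect_equal(tf_binding_flux(1.08e9, 3.3e-8, 1e-6, 1.3e-3),
               4.63e-8, tolerance = 1e-3)
  expect_equal(tf_binding_flux(1.08e9, 0, 1e-6, 1.3e-3), 0)
})

test_that("transferrin saturation and total iron observables", {
  m <- MODEL6
  s <- default_state(m)
  expect_equal(tf_saturation(s, m), 0)          # all apo
  s2 <- s; s2[["Tf"]] <- 0; s2[["Fe2Tf"]] <- m$params[["TfTotal"]]
  expect_equal(tf_saturation(s2, m), 100)       # fully di-ferric
  s3 <- s; s3[["Fe1Tf"]] <- 1e-5; s3[["Fe2Tf"]] <- 1e-5
  expect_equal(tf_saturation(s3, m), 100 * 3e-5 / 7.74e-5)  # 38.76%
  expect_equal(total_iron(s, m), 0)             # no iron anywhere
  s4 <- s; s4[["FeRBC"]] <- 0.01
  expect_equal(total_iron(s4, m), 0.01 * 7.9e-4 * 55.845 * 1000)  # 0.441 mg
  # di-ferric transferrin carries two iron ions
  s5 <- s; s5[["Fe2Tf"]] <- 1e-5
  expect_equal(total_iron(s5, m), 2 * 1e-5 * 1.3e-3 * 55.845 * 1000)
  # excreted iron is excluded unless asked for
  s6 <- s4; s6[["FeOutside"]] <- 1e-6
  expect_equal(total_iron(s6, m), total_iron(s4, m))
  expect_gt(total_iron(s6, m, include_outside = TRUE), total_iron(s4, m))
})
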