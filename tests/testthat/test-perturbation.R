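test_that("the identity perturbation leaves the parameter set unchanged", {
  p <- ref_params_cached()
  p2 <- apply_perturbation(p, perturbation(), ref_model())
  expect_identical(p2, p)
})

test_that("enzyme knockouts propagate to the kinase complex", {
  mod <- ref_model()
  p <- ref_params_cached()

  ko <- apply_perturbation(p, knockout_preset("pip5ki_ko"), mod)
  expect_equal(unname(ko$enzyme_activity["PIP5KI"]), 0)
  expect_equal(unname(ko$enzyme_activity["PI4K_PIP5KI_DVL"]), 0)
  expect_gt(ko$enzyme_activity["PI4K"], 0)

  ko2 <- apply_perturbation(p, knockout_preset("pi4k_ko"), mod)
  expect_equal(unname(ko2$enzyme_activity[c("PI4K", "PI4K_PIP5KI_DVL")]), c(0, 0))
  expect_gt(ko2$enzyme_activity["PIP5KI"], 0)

  # complex-only knockout leaves the single enzymes intact
  ko3 <- apply_perturbation(p, knockout_preset("complex_ko"), mod)
  expect_equal(unname(ko3$enzyme_activity["PI4K_PIP5KI_DVL"]), 0)
  expect_equal(unname(ko3$enzyme_activity[c("PI4K", "PIP5KI")]),
               unname(p$enzyme_activity[c("PI4K", "PIP5KI")]))

  # partial knockdown propagates multiplicatively
  half <- apply_perturbation(p, knockout_preset("pip5ki_half"), mod)
  expect_equal(unname(half$enzyme_activity["PI4K_PIP5KI_DVL"] /
                        p$enzyme_activity["PI4K_PIP5KI_DVL"]), 0.5)
})

test_that("apply is pure and rejects unknown identifiers", {
  mod <- ref_model()
  p <- ref_params_cached()
  snapshot <- p
  invisible(apply_perturbation(p, knockout_preset("pi4k_ko"), mod))
  expect_identical(p, snapshot)
  expect_error(apply_perturbation(p, perturbation(enzyme_scales = c(XYZ = 0)), mod),
               "unknown enzyme")
  expect_error(apply_perturbation(p, perturbation(gamma_scales = c(`v9->9` = 2)), mod),
               "unknown flux")
  expect_error(perturbation(enzyme_scales = c(PTEN = -1)), ">= 0")
})

test_that("composition multiplies scales and is associative", {
  a <- perturbation(enzyme_scales = c(PTEN = 0.5), influx_scales = c(`v->0` = 0.5))
  b <- perturbation(enzyme_scales = c(PTEN = 0.4, SHIP = 2))
  cc <- perturbation(gamma_scales = c(`v0->4` = 0.2))
  ab <- compose_perturbations(a, b)
  expect_equal(unname(ab$enzyme_scales["PTEN"]), 0.2)
  expect_equal(unname(ab$enzyme_scales["SHIP"]), 2)
  lhs <- compose_perturbations(compose_perturbations(a, b), cc)
  rhs_ <- compose_perturbations(a, compose_perturbations(b, cc))
  for (fld in c("enzyme_scales", "gamma_scales", "influx_scales")) {
    expect_equal(lhs[[fld]][order(names(lhs[[fld]]))],
                 rhs_[[fld]][order(names(rhs_[[fld]]))])
  }
})

test_that("scaling an enzyme scales its fluxes proportionally at fixed state", {
  mod <- ref_model()
  p <- ref_params_cached()
  x <- ref_basal()$abundances
  v0 <- pathway_fluxes(x, mod, p)
  s <- 1.37
  p2 <- apply_perturbation(p, perturbation(enzyme_scales = c(SIOSS = s)), mod)
  v1 <- pathway_fluxes(x, mod, p2)
  expect_equal(unname(v1["v45->4"] / v0["v45->4"]), s, tolerance = 1e-12)
  others <- setdiff(names(v0), "v45->4")
  expect_equal(v1[others], v0[others], tolerance = 1e-12)
})

test_that("presets encode the documented experimental conventions", {
  ap <- knockout_preset("apical")
  expect_equal(unname(ap$enzyme_values["PTEN"]), 2.3e-15)
  expect_equal(unname(ap$enzyme_values["PI3KI"]), 6.1e-16)
  bl <- knockout_preset("basolateral")
  expect_equal(unname(bl$enzyme_values["PTEN"]), 3.9e-17)
  expect_equal(unname(bl$enzyme_values["PI3KI"]), 1.5e-14)

  blk <- knockout_preset("block_pip2_inputs")
  expect_equal(unname(blk$gamma_scales["v0->4"]), 0.2)
  expect_setequal(names(blk$gamma_scales)[blk$gamma_scales == 0],
                  c("v0->45", "v5->45", "v345->45", "v34->4"))
  expect_equal(unname(blk$influx_scales["v->4"]), 0)

  up <- knockout_preset("sioss_up", upregulation = 3)
  expect_equal(unname(up$enzyme_scales["SIOSS"]), 3)

  fast <- knockout_preset("v345_34_fast")
  expect_equal(unname(fast$gamma_values["v345->34"]), 6e13)
  expect_equal(unname(fast$f_values["v345->34"]), 0.9998)

  expect_error(knockout_preset("no_such_preset"), "unknown preset")
})
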