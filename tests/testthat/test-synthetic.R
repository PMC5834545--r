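test_that("scenarios regenerate identically from the same seed", {
  a <- generate_scenario(seed = 21, noise_sigma = 0.1, n_free_parameters = 3,
                         model = ref_model(), base_params = ref_params_cached())
  b <- generate_scenario(seed = 21, noise_sigma = 0.1, n_free_parameters = 3,
                         model = ref_model(), base_params = ref_params_cached())
  expect_identical(a$free, b$free)
  expect_identical(a$truth$gamma, b$truth$gamma)
  expect_identical(a$targets, b$targets)
  c_ <- generate_scenario(seed = 22, noise_sigma = 0.1, n_free_parameters = 3,
                          model = ref_model(), base_params = ref_params_cached())
  expect_false(identical(a$truth$gamma, c_$truth$gamma))
})

test_that("zero observation noise collapses intervals onto the truth", {
  sc <- generate_scenario(seed = 4, noise_sigma = 0, n_free_parameters = 2,
                          model = ref_model(), base_params = ref_params_cached())
  rel_width <- (sc$targets$high - sc$targets$low) / sc$targets$high
  expect_lt(max(rel_width), 1e-6)
  expect_equal(sc$targets$low, unname(sc$truth_ss[sc$targets$species]),
               tolerance = 1e-6)
})

test_that("the truth satisfies its own derived targets", {
  sc <- generate_scenario(seed = 9, noise_sigma = 0.1, n_free_parameters = 3,
                          model = ref_model(), base_params = ref_params_cached())
  expect_equal(scenario_score(ref_model(), sc$truth, sc), 0)
  # and a clearly different set does not
  off <- param_update(sc$truth, sc$free, param_values(sc$truth, sc$free) * 8)
  expect_gt(scenario_score(ref_model(), off, sc), 0)
})

test_that("scenario JSON bundles round-trip", {
  sc <- generate_scenario(seed = 13, noise_sigma = 0.05, n_free_parameters = 2,
                          model = ref_model(), base_params = ref_params_cached())
  tmp <- tempfile(fileext = ".json")
  write_scenario(sc, tmp)
  back <- read_scenario(tmp)
  expect_equal(back$truth$gamma, sc$truth$gamma, tolerance = 1e-12)
  expect_equal(back$free, sc$free)
  expect_equal(back$targets$low, sc$targets$low, tolerance = 1e-12)
  expect_equal(back$seed, sc$seed)
})

test_that("the reference fixture honours the transport constraints", {
  p <- ref_params_cached()
  ss <- ref_basal()
  # whole-membrane recycling: total influx over total pool per minute
  recycling <- sum(p$influx) / sum(ss$abundances)
  expect_equal(recycling, 0.045, tolerance = 1e-6)
  # influxes below 25% of the receiving pools, effluxes below 7%
  expect_lt(p$influx["v->0"], 0.25 * ss$abundances["0"])
  expect_lt(p$influx["v->4"], 0.25 * ss$abundances["4"])
  expect_lt(p$influx["v->3"], 0.25 * ss$abundances["3"])
  expect_lt(p$efflux_k, 0.07)
  # PI(4,5)P2 sits in its literature interval (~10,000 molecules/um^2)
  expect_gt(ss$abundances["45"], 5000)
  expect_lt(ss$abundances["45"], 20000)
})
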