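test_that("the power-law rate law evaluates correctly", {
  expect_equal(gma_flux(10, 1, 1, 1), 10)
  expect_equal(gma_flux(1, 2.5, 0.4, 0.77), 1.0)
  # fast PI(3,4,5)P3 hydrolysis constants at a basolateral-like abundance
  expect_equal(gma_flux(760, 6e13, 1e-15, 0.9998), 45.54, tolerance = 1e-3)
  expect_equal(gma_flux(123, 5, 0, 0.8), 0)       # no enzyme, no flux
  expect_error(gma_flux(-1, 1, 1, 1), "negative")
  expect_error(gma_flux(0, 1, 1, -0.5), "kinetic order")
})

test_that("the RHS vanishes at a verified steady state and balances fluxes", {
  mod <- ref_model()
  p <- ref_params_cached()
  ss <- ref_basal()
  d <- rhs(ss$abundances, mod, p)
  expect_lt(max(abs(d) / pmax(ss$abundances, 1)), 1e-8)
  bal <- flux_balance(ss, mod)
  expect_lt(max(bal$relative_imbalance), 1e-8)
})

test_that("interconversions conserve total molecule count", {
  mod <- ref_model()
  p <- ref_params_cached()
  p$influx[] <- 0
  p$efflux_k <- 0
  x <- ref_basal()$abundances * runif(8, 0.5, 2)
  expect_equal(sum(rhs(x, mod, p)), 0, tolerance = 1e-9 * sum(abs(x)))
  traj <- simulate(mod, p, x0 = x, t_end = 200, n_out = 41)
  totals <- rowSums(traj$states)
  expect_equal(max(abs(totals - totals[1])) / totals[1], 0, tolerance = 1e-7)
})

test_that("the closed two-species cycle settles on the analytic balance", {
  toy <- toy_cycle()
  # analytic oracle: A* = total * k_rev / (k_fwd + k_rev) = 30 * 1/3 = 10
  ss <- find_steady_state(toy$model, toy$params, x0 = c(A = 30, B = 0))
  expect_equal(unname(ss$abundances), c(10, 20), tolerance = 1e-6)
  traj <- simulate(toy$model, toy$params, x0 = c(A = 30, B = 0), t_end = 50)
  expect_equal(unname(traj$states[nrow(traj$states), ]), c(10, 20),
               tolerance = 1e-6)
})

test_that("the basal steady state is flat and attracting", {
  mod <- ref_model()
  p <- ref_params_cached()
  ss <- ref_basal()
  traj <- simulate(mod, p, x0 = ss$abundances, t_end = 1000, n_out = 11)
  drift <- abs(traj$states[11, ] - unname(ss$abundances)) / unname(ss$abundances)
  expect_lt(max(drift), 1e-6)
  # perturb PI(4,5)P2 to half and return (stable node)
  x0 <- ss$abundances; x0["45"] <- x0["45"] / 2
  back <- find_steady_state(mod, p, x0 = x0)
  expect_equal(unname(back$abundances / ss$abundances), rep(1, 8),
               tolerance = 1e-6)
})

test_that("the steady state is independent of the start within tolerance", {
  mod <- ref_model()
  p <- ref_params_cached()
  ss <- ref_basal()
  set.seed(11)
  for (k in 1:5) {
    x0 <- ss$abundances * runif(8, 0.2, 5)
    ssk <- find_steady_state(mod, p, x0 = x0)
    expect_equal(unname(ssk$abundances / ss$abundances), rep(1, 8),
                 tolerance = 1e-6)
  }
})

test_that("an all-first-order parameterization matches the linear solve", {
  mod <- ref_model()
  p <- ref_params_cached()
  # linearize each rate law around the curated abundances: gamma' = gamma *
  # X*^(f-1) keeps the flux at X* unchanged while making every f = 1
  xstar <- stats::setNames(mod$species$basal_abundance, mod$species$id)
  subs <- mod$fluxes$substrate[match(names(p$gamma), mod$fluxes$id)]
  p$gamma <- p$gamma * xstar[subs]^(p$f - 1)
  p$f[] <- 1
  oracle <- linear_ss_oracle(mod, p)
  ss <- find_steady_state(mod, p, x0 = oracle * 1.7)
  expect_equal(unname(ss$abundances[names(oracle)]), unname(oracle),
               tolerance = 1e-6)
})

test_that("closed-transport steady states conserve the initial total", {
  mod <- ref_model()
  p <- ref_params_cached()
  p$influx[] <- 0
  p$efflux_k <- 0
  x0 <- ref_basal()$abundances
  ss <- find_steady_state(mod, p, x0 = x0, tol = 1e-10)
  expect_equal(sum(ss$abundances), sum(x0), tolerance = 1e-6)
})

test_that("negative initial states are rejected", {
  toy <- toy_cycle()
  expect_error(simulate(toy$model, toy$params, x0 = c(A = -1, B = 31)),
               "negative")
})
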