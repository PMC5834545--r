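test_that("parameter addresses read and write every component", {
  p <- ref_params_cached()
  free <- c("gamma:v0->45", "f:v5->45", "E:PTEN", "influx:v->0", "efflux_k")
  v <- param_values(p, free)
  expect_equal(unname(v[1]), unname(p$gamma["v0->45"]))
  expect_equal(unname(v[5]), p$efflux_k)
  p2 <- param_update(p, free, v * 2)
  expect_equal(unname(p2$gamma["v0->45"]), unname(v[1]) * 2)
  expect_equal(p2$efflux_k, p$efflux_k * 2)
  expect_error(param_values(p, "nonsense:xy"), "bad parameter address")
})

test_that("a perfect starting point is returned unchanged by the GA", {
  mod <- ref_model()
  p <- ref_params_cached()
  free <- c("gamma:v4->45", "gamma:v45->4")
  fit <- fit_ga(mod, p, phenomena = NULL, free = free,
                config = ga_config(pop_size = 10, generations = 3, seed = 7),
                refine = FALSE)
  expect_equal(fit$initial_score, 0)
  expect_equal(fit$score, 0)
  # pools-only score is 0 on an open set around the reference, so the
  # returned set still meets every interval
  expect_equal(adjustment_score(mod, fit$params, phenomena = NULL)$total, 0)
})

test_that("the GA trace is monotone and reproducible from the seed", {
  mod <- ref_model()
  p <- ref_params_cached()
  # degrade one parameter; the GA must improve on the degraded score
  p_bad <- param_update(p, "gamma:v4->45", param_values(p, "gamma:v4->45") / 30)
  cfg <- ga_config(pop_size = 12, generations = 6, seed = 3)
  fit1 <- fit_ga(mod, p_bad, phenomena = NULL, free = "gamma:v4->45",
                 config = cfg, refine = FALSE)
  fit2 <- fit_ga(mod, p_bad, phenomena = NULL, free = "gamma:v4->45",
                 config = cfg, refine = FALSE)
  expect_true(all(diff(fit1$trace) <= 0))
  expect_lte(fit1$score, fit1$initial_score)
  expect_identical(fit1$trace, fit2$trace)
  expect_equal(param_values(fit1$params, "gamma:v4->45"),
               param_values(fit2$params, "gamma:v4->45"))
})

test_that("the reference set is admissible under its own rules", {
  ok <- is_admissible(ref_model(), ref_params_cached())
  expect_true(isTRUE(ok))
  ok_fast <- is_admissible(ref_model(), ref_params_cached(), effort = "fast")
  expect_true(isTRUE(ok_fast))
})

test_that("a vanishing influx cap rejects any set with positive influx", {
  rules <- admissibility_rules(influx_cap = 1e-9)
  ok <- is_admissible(ref_model(), ref_params_cached(), rules)
  expect_false(isTRUE(ok))
  expect_match(attr(ok, "reason"), "influx")
})

test_that("rule constructors reject caps outside (0, 1]", {
  expect_error(admissibility_rules(influx_cap = 0))
  expect_error(admissibility_rules(efflux_cap = 1.5))
})

test_that("Monte-Carlo sampling is deterministic under a fixed seed", {
  mod <- ref_model()
  p <- ref_params_cached()
  r1 <- monte_carlo_search(mod, p, n = 40, seed = 7)
  r2 <- monte_carlo_search(mod, p, n = 40, seed = 7)
  expect_identical(r1$n_admissible, r2$n_admissible)
  expect_identical(r1$scores, r2$scores)
  expect_lte(r1$n_admissible, r1$n_tested)
  expect_true(r1$conf_int[1] >= 0 && r1$conf_int[2] <= 1)
})

test_that("admissible sets re-validate and score worse than the reference", {
  mod <- ref_model()
  p <- ref_params_cached()
  # narrow sampling around the reference (kinetic orders held) produces
  # admissible sets
  r <- monte_carlo_search(mod, p, n = 40, seed = 5, range_decades = 0.02,
                          f_range = NULL)
  expect_gte(r$n_admissible, 1)
  for (cand in r$admissible) {
    expect_true(isTRUE(is_admissible(mod, cand, effort = "fast")))
  }
  expect_true(all(r$scores >= 0))
})
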