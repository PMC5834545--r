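# -- parameter estimation: genetic algorithm + Monte-Carlo exploration ------

#' Address-based access to free parameters
#'
#' Fitting and sampling operate on a flat vector of "addresses" into a
#' parameter set: `"gamma:<flux>"`, `"f:<flux>"`, `"E:<enzyme>"`,
#' `"influx:<id>"` or `"efflux_k"`. Magnitude-like quantities (gamma, E,
#' influx, efflux) are handled in log10 space; kinetic orders linearly.
#'
#' @param params A `pip_params`.
#' @param free Character vector of addresses.
#' @return `param_values` returns the named numeric vector of current
#'   values; `param_update` returns a new `pip_params` with the addressed
#'   entries replaced by `values`.
#' @export
param_values <- function(params, free) {
  vapply(free, function(ad) {
    part <- strsplit(ad, ":", fixed = TRUE)[[1]]
    switch(part[1],
      gamma = params$gamma[[part[2]]],
      f = params$f[[part[2]]],
      E = params$enzyme_activity[[part[2]]],
      influx = params$influx[[part[2]]],
      efflux_k = params$efflux_k,
      stop("bad parameter address '", ad, "'", call. = FALSE))
  }, numeric(1))
}

#' @rdname param_values
#' @param values Numeric vector aligned with `free`.
#' @export
param_update <- function(params, free, values) {
  p <- params
  values <- unname(values)
  for (i in seq_along(free)) {
    part <- strsplit(free[i], ":", fixed = TRUE)[[1]]
    switch(part[1],
      gamma = p$gamma[[part[2]]] <- values[i],
      f = p$f[[part[2]]] <- values[i],
      E = p$enzyme_activity[[part[2]]] <- values[i],
      influx = p$influx[[part[2]]] <- values[i],
      efflux_k = p$efflux_k <- values[i])
  }
  p
}

is_log_address <- function(free) !startsWith(free, "f:")

#' Genetic-algorithm configuration
#'
#' Defaults: population 100, 300 generations, tournament selection (k = 3),
#' uniform crossover at rate 0.7, Gaussian mutation in log space (sigma =
#' 0.1 decade for magnitude parameters, 0.05 for kinetic orders) at rate
#' 0.15, elitism 2. Bounds are +/- `bound_decades` around the initial value
#' for magnitudes and `f_bounds` for kinetic orders.
#'
#' @param pop_size,generations,tournament_k,crossover_rate,mutation_rate,
#'   mutation_sigma,elitism,bound_decades,f_bounds,seed Tuning knobs.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, generations = 300, tournament_k = 3,
                      crossover_rate = 0.7, mutation_rate = 0.15,
                      mutation_sigma = 0.1, elitism = 2, bound_decades = 1.5,
                      f_bounds = c(0.1, 1.2), seed = 1) {
  structure(list(pop_size = pop_size, generations = generations,
                 tournament_k = tournament_k, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sigma = mutation_sigma,
                 elitism = elitism, bound_decades = bound_decades,
                 f_bounds = f_bounds, seed = seed),
            class = "ga_config")
}

#' Fit free parameters with a genetic algorithm
#'
#' Minimizes the adjustment score over the addressed free parameters,
#' starting from `initial_params` (which is always a member of the initial
#' population, so the final score can never exceed the initial one). Fully
#' reproducible from `config$seed`. An optional Nelder-Mead refinement
#' polishes the best individual.
#'
#' @param model A `pip_model`.
#' @param initial_params Starting `pip_params`.
#' @param targets Pool intervals (see [steady_state_targets()]).
#' @param phenomena Phenomena registry list, or `NULL`.
#' @param free Character vector of parameter addresses to fit.
#' @param config A [ga_config()].
#' @param refine Run a local polish on the best individual.
#' @param score_fn Score function `(model, params) -> number`; defaults to
#'   the total adjustment score. Supplying a custom function allows fitting
#'   synthetic scenarios.
#' @return List of class `ga_fit`: `params` (best), `score`, `trace`
#'   (best-so-far per generation, non-increasing), `initial_score`, `seed`.
#' @export
fit_ga <- function(model, initial_params, targets = steady_state_targets(),
                   phenomena = phenomena_registry(), free,
                   config = ga_config(), refine = TRUE, score_fn = NULL) {
  if (is.null(score_fn)) {
    score_fn <- function(model, params)
      adjustment_score(model, params, targets, phenomena)$total
  }
  set.seed(config$seed)
  n <- length(free)
  logp <- is_log_address(free)
  x0 <- param_values(initial_params, free)
  t0 <- ifelse(logp, log10(x0), x0)
  lower <- ifelse(logp, t0 - config$bound_decades, config$f_bounds[1])
  upper <- ifelse(logp, t0 + config$bound_decades, config$f_bounds[2])
  sigma <- ifelse(logp, config$mutation_sigma, config$mutation_sigma / 2)

  decode <- function(t) ifelse(logp, 10^t, t)
  evaluate <- function(t) {
    p <- param_update(initial_params, free, decode(t))
    s <- tryCatch(score_fn(model, p), error = function(e) Inf)
    if (!is.finite(s)) Inf else s
  }

  pop <- lapply(seq_len(config$pop_size), function(i) {
    if (i == 1) t0 else
      pmin(pmax(t0 + stats::rnorm(n, 0, sigma * 3), lower), upper)
  })
  fit <- vapply(pop, evaluate, numeric(1))
  if (all(!is.finite(fit))) {
    stop("no candidate reaches a steady state; fitting cannot start", call. = FALSE)
  }
  trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(config$elitism)]]
    while (length(newpop) < config$pop_size) {
      pick <- function() {
        cand <- sample.int(config$pop_size, config$tournament_k)
        pop[[cand[which.min(fit[cand])]]]
      }
      a <- pick(); b <- pick()
      child <- if (stats::runif(1) < config$crossover_rate) {
        mask <- stats::runif(n) < 0.5
        ifelse(mask, a, b)
      } else a
      mut <- stats::runif(n) < config$mutation_rate
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sigma[mut])
      newpop[[length(newpop) + 1L]] <- pmin(pmax(child, lower), upper)
    }
    keep <- seq_len(config$elitism)
    newfit <- c(fit[ord[keep]],
                vapply(newpop[-keep], evaluate, numeric(1)))
    pop <- newpop; fit <- newfit
    trace[g] <- min(fit)
  }
  best_t <- pop[[which.min(fit)]]
  best_s <- min(fit)
  if (refine) {
    opt <- stats::optim(best_t, evaluate, method = "Nelder-Mead",
                        control = list(maxit = 400))
    if (opt$value < best_s) { best_t <- opt$par; best_s <- opt$value }
  }
  best_t <- pmin(pmax(best_t, lower), upper)
  best_s <- evaluate(best_t)
  structure(list(params = param_update(initial_params, free, decode(best_t)),
                 score = best_s, trace = cummin(trace),
                 initial_score = evaluate(t0), free = free,
                 seed = config$seed),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("GA fit over", length(x$free), "free parameter(s); seed", x$seed, "\n")
  cat("  initial score:", format(x$initial_score, digits = 6), "\n")
  cat("  final score:  ", format(x$score, digits = 6), "\n")
  invisible(x)
}

#' Admissibility rules for Monte-Carlo exploration
#'
#' A sampled parameter set is admissible when (1) its steady state lies
#' inside every pool interval, (2) the coarse pool ordering holds (every
#' pool of rank group g exceeds every pool of group g+1), (3) each influx is
#' below `influx_cap` times the receiving pool, and (4) each efflux is below
#' `efflux_cap` times its pool.
#'
#' @param influx_cap,efflux_cap Fractions in (0, 1].
#' @param targets Pool intervals with rank groups.
#' @return List of class `admissibility_rules`.
#' @export
admissibility_rules <- function(influx_cap = 0.25, efflux_cap = 0.07,
                                targets = steady_state_targets()) {
  stopifnot(influx_cap > 0, influx_cap <= 1, efflux_cap > 0, efflux_cap <= 1)
  structure(list(influx_cap = influx_cap, efflux_cap = efflux_cap,
                 targets = targets),
            class = "admissibility_rules")
}

#' Check one parameter set against the admissibility rules
#'
#' @param model A `pip_model`.
#' @param params A `pip_params`.
#' @param rules An [admissibility_rules()] object.
#' @param x0 Steady-state search start.
#' @param effort `"full"` uses [find_steady_state()]; `"fast"` uses a
#'   bounded-budget Newton/short-integration search suited to screening
#'   thousands of candidates (candidates whose steady state is not located
#'   within the budget are rejected).
#' @return Logical scalar with attribute `"reason"` when inadmissible.
#' @export
is_admissible <- function(model, params, rules = admissibility_rules(),
                          x0 = model$species$basal_abundance,
                          effort = c("full", "fast")) {
  effort <- match.arg(effort)
  fail <- function(reason) structure(FALSE, reason = reason)
  ss <- if (effort == "fast") {
    fast_steady_state(model, params, x0 = x0)
  } else {
    tryCatch(find_steady_state(model, params, x0 = x0, max_time = 2e4),
             error = function(e) NULL)
  }
  if (is.null(ss)) return(fail("no steady state"))
  tg <- rules$targets
  ab <- ss$abundances[tg$species]
  if (any(ab < tg$low | ab > tg$high)) return(fail("pool outside interval"))
  groups <- split(ab, tg$rank_group)
  if (length(groups) > 1) {
    for (g in seq_len(length(groups) - 1)) {
      if (min(groups[[g]]) <= max(groups[[g + 1]])) return(fail("pool order violated"))
    }
  }
  influx_to <- c(`v->0` = "0", `v->4` = "4", `v->3` = "3")
  for (id in names(params$influx)) {
    if (params$influx[id] >= rules$influx_cap * ss$abundances[influx_to[id]]) {
      return(fail("influx exceeds cap"))
    }
  }
  if (params$efflux_k >= rules$efflux_cap) return(fail("efflux exceeds cap"))
  TRUE
}

#' Monte-Carlo search of parameter space
#'
#' Samples `n` parameter sets (magnitudes log-uniform within
#' `+/- range_decades` around the reference values, kinetic orders uniform
#' within `f_range`), checks each against the admissibility rules, and
#' scores the admissible ones. Deterministic for a fixed seed: each
#' candidate's random draws come from a seed derived from the master seed
#' and the candidate index, so results do not depend on evaluation order.
#'
#' @param model A `pip_model`.
#' @param params Reference `pip_params` the ranges are centred on.
#' @param n Number of candidate sets.
#' @param rules [admissibility_rules()].
#' @param seed Master seed.
#' @param range_decades Half-width of the log-uniform sampling window.
#' @param f_range Kinetic-order sampling interval; `NULL` keeps the
#'   reference kinetic orders fixed.
#' @param score_phenomena Include phenomena in the scores of admissible sets
#'   (slower); pool intervals are always scored.
#' @return List of class `mc_result`: `n_tested`, `n_admissible`,
#'   `fraction`, `conf_int` (95% binomial), `admissible` (list of parameter
#'   sets), `scores`, `seed`, `range_decades`.
#' @export
monte_carlo_search <- function(model, params, n, rules = admissibility_rules(),
                               seed = 1, range_decades = 1.5,
                               f_range = c(0.5, 1.2),
                               score_phenomena = FALSE) {
  stopifnot(n >= 1)
  inter <- names(params$gamma)
  free <- c(paste0("gamma:", inter),
            paste0("E:", names(params$enzyme_activity)),
            paste0("influx:", names(params$influx)), "efflux_k")
  if (!is.null(f_range)) free <- c(free, paste0("f:", inter))
  logp <- is_log_address(free)
  ref <- param_values(params, free)
  admissible <- list(); scores <- numeric(0)
  for (i in seq_len(n)) {
    set.seed((seed * 48271 + i) %% 2147483647)
    u <- stats::runif(length(free))
    vals <- ifelse(logp,
                   10^(log10(ref) + (2 * u - 1) * range_decades),
                   f_range[1] + u * (f_range[2] - f_range[1]))
    cand <- param_update(params, free, vals)
    ok <- is_admissible(model, cand, rules, effort = "fast")
    if (isTRUE(ok)) {
      sc <- adjustment_score(model, cand, rules$targets,
                             if (score_phenomena) phenomena_registry() else NULL)
      admissible[[length(admissible) + 1L]] <- cand
      scores <- c(scores, sc$total)
    }
  }
  k <- length(admissible)
  ci <- as.numeric(stats::binom.test(k, n)$conf.int)
  structure(list(n_tested = n, n_admissible = k, fraction = k / n,
                 conf_int = ci, admissible = admissible, scores = scores,
                 seed = seed, range_decades = range_decades),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte-Carlo parameter search\n")
  cat(sprintf("  admissible: %d / %d (%.3f%%), 95%% CI [%.3f%%, %.3f%%]\n",
              x$n_admissible, x$n_tested, 100 * x$fraction,
              100 * x$conf_int[1], 100 * x$conf_int[2]))
  if (x$n_admissible) {
    cat("  admissible scores: min", format(min(x$scores), digits = 4),
        "median", format(stats::median(x$scores), digits = 4), "\n")
  }
  invisible(x)
}
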