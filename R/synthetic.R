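# -- synthetic scenarios: ground truth + pseudo-observations ----------------

#' Generate a synthetic calibration scenario
#'
#' Builds a ground-truth parameter set by jittering selected free parameters
#' of the reference set, simulates its steady state, and derives from it (i)
#' noisy pool-interval targets (multiplicative lognormal noise - abundances
#' are positive and span orders of magnitude) and (ii) phenomenon outcomes
#' recorded by actually simulating the truth under a small panel of
#' perturbations. The truth always satisfies its own derived targets, so
#' estimation can be benchmarked against a known answer without any
#' external data.
#'
#' @param seed Integer seed; the same seed reproduces the scenario exactly.
#' @param noise_sigma Lognormal sigma of the observation noise (0 collapses
#'   the pool intervals to points at the truth).
#' @param n_free_parameters How many rate constants are jittered (and later
#'   fitted).
#' @param model A `pip_model`.
#' @param base_params Parameter set the truth is drawn around.
#' @param jitter_decades Half-width of the log-uniform truth jitter.
#' @return Object of class `pip_scenario`: list with `truth` (pip_params),
#'   `free` (addresses), `targets` (pool intervals data.frame),
#'   `phenomena` (list of recorded outcomes), `noise_sigma`, `seed`.
#' @export
generate_scenario <- function(seed, noise_sigma = 0.1, n_free_parameters = 3,
                              model = load_network(),
                              base_params = reference_params(),
                              jitter_decades = 0.25) {
  stopifnot(noise_sigma >= 0, n_free_parameters >= 1)
  set.seed(seed)
  pool <- paste0("gamma:", names(base_params$gamma))
  free <- sample(pool, n_free_parameters)
  vals <- param_values(base_params, free)
  truth <- param_update(base_params, free,
                        10^(log10(vals) +
                              stats::runif(n_free_parameters,
                                           -jitter_decades, jitter_decades)))
  ss <- tryCatch(find_steady_state(model, truth), error = function(e) NULL)
  tries <- 0
  while (is.null(ss) && tries < 5) {
    tries <- tries + 1
    truth <- param_update(base_params, free,
                          10^(log10(vals) +
                                stats::runif(n_free_parameters,
                                             -jitter_decades, jitter_decades)))
    ss <- tryCatch(find_steady_state(model, truth), error = function(e) NULL)
  }
  if (is.null(ss)) {
    stop("could not draw a ground truth with a steady state (", tries,
         " resamples)", call. = FALSE)
  }

  centre <- ss$abundances * exp(stats::rnorm(length(ss$abundances), 0, noise_sigma))
  half <- pmax(2 * noise_sigma, 1e-9)
  targets <- data.frame(
    species = names(ss$abundances),
    low = pmin(centre * exp(-half), ss$abundances),
    high = pmax(centre * exp(half), ss$abundances),
    rank_group = steady_state_targets()$rank_group[
      match(names(ss$abundances), steady_state_targets()$species)],
    stringsAsFactors = FALSE)

  probe <- c("pip5ki_half", "sioss_up", "pip5kii_ko")
  phen <- lapply(probe, function(nm) {
    spec <- knockout_preset(nm)
    pss <- find_steady_state(model, apply_perturbation(truth, spec, model),
                             x0 = ss$abundances)
    list(id = nm, readout = "45",
         outcome = unname(pss$abundances["45"] / ss$abundances["45"]),
         tol = 0.1)
  })
  structure(list(truth = truth, free = free, truth_ss = ss$abundances,
                 targets = targets, phenomena = phen,
                 noise_sigma = noise_sigma, seed = seed),
            class = "pip_scenario")
}

#' Score a parameter set against a synthetic scenario
#'
#' Same convention as [adjustment_score()]: squared relative distance to the
#' pool intervals plus squared distance beyond each recorded phenomenon
#' tolerance; 0 iff everything is met. By construction the scenario's own
#' truth scores 0.
#'
#' @param model A `pip_model`.
#' @param params Candidate `pip_params`.
#' @param scenario A `pip_scenario`.
#' @return Numeric score (Inf when no steady state is found).
#' @export
scenario_score <- function(model, params, scenario) {
  ss <- tryCatch(find_steady_state(model, params), error = function(e) NULL)
  if (is.null(ss)) return(Inf)
  tg <- scenario$targets
  ab <- ss$abundances[tg$species]
  d <- ifelse(ab < tg$low, (tg$low - ab) / tg$low,
              ifelse(ab > tg$high, (ab - tg$high) / tg$high, 0))
  total <- sum(d^2)
  for (ph in scenario$phenomena) {
    spec <- knockout_preset(ph$id)
    pss <- tryCatch(
      find_steady_state(model, apply_perturbation(params, spec, model),
                        x0 = ss$abundances),
      error = function(e) NULL)
    if (is.null(pss)) return(Inf)
    r <- unname(pss$abundances[ph$readout] / ss$abundances[ph$readout])
    total <- total + max(0, abs(r - ph$outcome) - ph$tol)^2
  }
  total
}

#' Serialize / load a synthetic scenario
#'
#' JSON bundles (truth, free addresses, targets, recorded phenomena, seed)
#' for regression testing; a written scenario reloads identically.
#'
#' @param scenario A `pip_scenario`.
#' @param path JSON file path.
#' @return `path` invisibly / the reloaded `pip_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(list(
    truth = list(gamma = as.list(scenario$truth$gamma),
                 f = as.list(scenario$truth$f),
                 enzyme_activity = as.list(scenario$truth$enzyme_activity),
                 influx = as.list(scenario$truth$influx),
                 efflux_k = scenario$truth$efflux_k),
    free = scenario$free,
    truth_ss = as.list(scenario$truth_ss),
    targets = scenario$targets,
    phenomena = scenario$phenomena,
    noise_sigma = scenario$noise_sigma,
    seed = scenario$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- raw$truth
  truth <- parameter_set(gamma = unlist(tr$gamma), f = unlist(tr$f),
                         enzyme_activity = unlist(tr$enzyme_activity),
                         influx = unlist(tr$influx), efflux_k = tr$efflux_k)
  structure(list(truth = truth, free = raw$free,
                 truth_ss = unlist(raw$truth_ss),
                 targets = raw$targets,
                 phenomena = lapply(seq_len(nrow(raw$phenomena)), function(i)
                   as.list(raw$phenomena[i, ])),
                 noise_sigma = raw$noise_sigma, seed = raw$seed),
            class = "pip_scenario")
}

#' @export
print.pip_scenario <- function(x, ...) {
  cat("Synthetic calibration scenario (seed", x$seed, ")\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  cat("  observation noise sigma:", x$noise_sigma, "\n")
  invisible(x)
}
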