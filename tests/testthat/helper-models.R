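# Shared fixtures: the curated model/parameters (loaded once) and small toy
# systems with analytically known behaviour, built in code.

ref_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_network()
    cache
  }
})

ref_params_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reference_params()
    cache
  }
})

ref_basal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- find_steady_state(ref_model(), ref_params_cached())
    cache
  }
})

sens_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sensitivity_matrix(ref_model(), ref_params_cached())
    }
    cache
  }
})

# Two-species closed cycle A <-> B with first-order kinetics:
# forward rate 2/min, backward 1/min, no transport. Total mass conserved;
# the unique steady state on the A+B = 30 manifold is A = 10, B = 20.
toy_cycle <- function() {
  model <- structure(list(
    species = data.frame(id = c("A", "B"), name = c("A", "B"),
                         basal_abundance = c(10, 20), stringsAsFactors = FALSE),
    fluxes = data.frame(
      id = c("vA->B", "vB->A"),
      kind = c("phosphorylation", "hydrolysis"),
      substrate = c("A", "B"), product = c("B", "A"),
      enzyme = c("fwd", "rev"), stringsAsFactors = FALSE),
    enzymes = list(fwd = "vA->B", rev = "vB->A"),
    complexes = list(), time_unit = "minutes"), class = "pip_model")
  params <- parameter_set(
    gamma = c(`vA->B` = 2, `vB->A` = 1),
    f = c(`vA->B` = 1, `vB->A` = 1),
    enzyme_activity = c(fwd = 1, rev = 1),
    influx = stats::setNames(numeric(0), character(0)),
    efflux_k = 0)
  list(model = model, params = params)
}

# One-species supply/decay system dX/dt = a - b X with closed form X* = a/b;
# relative steady-state sensitivities are +1 to a and -1 to b.
toy_supply_decay <- function(a = 50, b = 0.1) {
  model <- structure(list(
    species = data.frame(id = "0", name = "X", basal_abundance = a / b,
                         stringsAsFactors = FALSE),
    fluxes = data.frame(
      id = c("v->0", "v0->"), kind = c("influx", "efflux"),
      substrate = c(NA, "0"), product = c("0", NA),
      enzyme = c(NA, NA), stringsAsFactors = FALSE),
    enzymes = list(), complexes = list(), time_unit = "minutes"),
    class = "pip_model")
  params <- parameter_set(
    gamma = stats::setNames(numeric(0), character(0)),
    f = stats::setNames(numeric(0), character(0)),
    enzyme_activity = stats::setNames(numeric(0), character(0)),
    influx = c(`v->0` = a), efflux_k = b)
  list(model = model, params = params)
}

# Direct linear-solve oracle for any all-first-order parameterization:
# builds the rate matrix T (T[i,j] = per-molecule rate j -> i) and returns
# the steady state as the solution of -T x = influx.
linear_ss_oracle <- function(model, params) {
  sp <- model$species$id
  n <- length(sp)
  stopifnot(all(params$f == 1))
  Tm <- matrix(0, n, n, dimnames = list(sp, sp))
  inter <- model$fluxes[model$fluxes$kind %in% c("phosphorylation", "hydrolysis"), ]
  for (i in seq_len(nrow(inter))) {
    rate <- params$gamma[inter$id[i]] * params$enzyme_activity[inter$enzyme[i]]
    s <- inter$substrate[i]; p <- inter$product[i]
    Tm[s, s] <- Tm[s, s] - rate
    Tm[p, s] <- Tm[p, s] + rate
  }
  diag(Tm) <- diag(Tm) - params$efflux_k
  b <- stats::setNames(rep(0, n), sp)
  influx_to <- c(`v->0` = "0", `v->4` = "4", `v->3` = "3")
  for (id in names(params$influx)) b[influx_to[id]] <- params$influx[id]
  solve(-Tm, b)
}
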