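# -- GMA dynamics: flux evaluation, RHS, simulation, steady states ----------

#' Evaluate one power-law (GMA) flux
#'
#' The rate law of every interconversion is
#' `v = gamma * E * x^f`: rate constant times enzyme activity times the
#' substrate abundance raised to its kinetic order. Linear (first-order)
#' kinetics is the special case `f = 1`.
#'
#' @param x_substrate Substrate abundance (molecules/um^2), non-negative.
#' @param gamma Positive rate constant.
#' @param activity Non-negative enzyme activity (mg/um^2).
#' @param f Kinetic order of the substrate.
#' @return The flux value (molecules um^-2 min^-1); 0 when `activity` is 0.
#' @examples
#' gma_flux(10, 1, 1, 1)            # first-order: 10
#' gma_flux(760, 6e13, 1e-15, 0.9998)
#' @export
gma_flux <- function(x_substrate, gamma, activity, f) {
  if (any(x_substrate < 0)) stop("negative substrate abundance", call. = FALSE)
  if (any(x_substrate == 0 & f <= 0 & activity > 0)) {
    stop("zero substrate with non-positive kinetic order is outside the GMA domain",
         call. = FALSE)
  }
  gamma * activity * x_substrate^f
}

# Internal compiled view of model + params: everything rhs needs as plain
# vectors with integer indices, so the ODE right-hand side stays cheap.
compile_system <- function(model, params) {
  sp <- model$species$id
  inter <- model$fluxes[model$fluxes$kind %in% c("phosphorylation", "hydrolysis"), ]
  influx <- model$fluxes[model$fluxes$kind == "influx", ]
  coef <- params$gamma[inter$id] * params$enzyme_activity[inter$enzyme]
  if (anyNA(coef)) {
    bad <- inter$id[is.na(coef)]
    stop("parameter set incomplete for flux(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  in_rate <- stats::setNames(rep(0, length(sp)), sp)
  in_rate[influx$product] <- params$influx[influx$id]
  list(
    sp = sp, n = length(sp),
    flux_id = inter$id,
    sub = match(inter$substrate, sp),
    prod = match(inter$product, sp),
    coef = unname(coef),
    f = unname(params$f[inter$id]),
    influx = unname(in_rate),
    efflux_k = params$efflux_k
  )
}

sys_fluxes <- function(sys, x) {
  xs <- pmax(x[sys$sub], 0)
  sys$coef * xs^sys$f
}

sys_rhs <- function(sys, x) {
  v <- sys_fluxes(sys, x)
  dx <- sys$influx - sys$efflux_k * pmax(x, 0)
  dx <- dx - tabulate_add(sys$sub, v, sys$n) + tabulate_add(sys$prod, v, sys$n)
  dx
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  for (k in seq_along(idx)) out[idx[k]] <- out[idx[k]] + val[k]
  out
}

#' ODE right-hand side of the pathway
#'
#' Time derivative of each lipid pool: sum of fluxes producing the species
#' minus the sum consuming it, with influxes and first-order effluxes
#' included. Interconversions are 1:1 in stoichiometry, so with all transport
#' switched off the components of the returned vector sum to exactly zero
#' (total molecule conservation).
#'
#' @param state Named or ordered 8-vector of abundances (molecules/um^2).
#' @param model A `pip_model`.
#' @param params A `pip_params`.
#' @return Numeric 8-vector of derivatives (molecules um^-2 min^-1), named by
#'   species id.
#' @export
rhs <- function(state, model, params) {
  sys <- compile_system(model, params)
  x <- as_state(state, sys$sp)
  stats::setNames(sys_rhs(sys, x), sys$sp)
}

#' Evaluate all fluxes at a given state
#'
#' @inheritParams rhs
#' @return Named numeric vector over all flux ids (interconversions,
#'   influxes, effluxes).
#' @export
pathway_fluxes <- function(state, model, params) {
  sys <- compile_system(model, params)
  x <- as_state(state, sys$sp)
  v <- stats::setNames(sys_fluxes(sys, x), sys$flux_id)
  influx <- params$influx
  efflux <- stats::setNames(sys$efflux_k * x, paste0("v", sys$sp, "->"))
  c(v, influx, efflux)
}

as_state <- function(state, sp) {
  if (!is.null(names(state))) state <- state[sp]
  if (length(state) != length(sp) || anyNA(state)) {
    stop("state must be a complete 8-vector over species ",
         paste(sp, collapse = ", "), call. = FALSE)
  }
  unname(as.numeric(state))
}

#' Simulate pathway trajectories
#'
#' Integrates the stiff GMA system with `deSolve`'s LSODA method (automatic
#' stiff/non-stiff switching). States are floored at zero for flux
#' evaluation; a negative excursion beyond `10 * atol` is treated as an
#' integration failure.
#'
#' @param model A `pip_model`.
#' @param params A `pip_params`.
#' @param x0 Initial state (named or species-ordered 8-vector), non-negative.
#' @param t_end Final time (minutes).
#' @param n_out Number of output time points.
#' @param rtol,atol Integration tolerances (relative; absolute in
#'   molecules/um^2).
#' @param fluxes If `TRUE`, attach the per-time flux values.
#' @return A `pip_trajectory`: list with `times`, `states` (matrix, one
#'   column per species), optional `fluxes`, and the tolerances used.
#' @export
simulate <- function(model, params, x0 = model$species$basal_abundance,
                     t_end = 1000, n_out = 201, rtol = 1e-8, atol = 1e-10,
                     fluxes = FALSE) {
  stopifnot(t_end > 0)
  sys <- compile_system(model, params)
  x0 <- as_state(x0, sys$sp)
  if (any(x0 < 0)) stop("negative initial state", call. = FALSE)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::lsoda(
    y = stats::setNames(x0, sys$sp), times = times,
    func = function(t, y, p) list(sys_rhs(sys, y)),
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < n_out) {
    last <- sol[nrow(sol), -1]
    stop("integrator failure at t = ", sol[nrow(sol), 1],
         "; last valid state: ", paste(signif(last, 6), collapse = ", "),
         call. = FALSE)
  }
  states <- sol[, -1, drop = FALSE]
  if (min(states) < -10 * atol) {
    stop("state became negative beyond tolerance during integration", call. = FALSE)
  }
  states[states < 0] <- 0
  out <- list(times = times, states = states, species = sys$sp,
              rtol = rtol, atol = atol)
  if (fluxes) {
    out$fluxes <- t(apply(states, 1, function(x)
      pathway_fluxes(stats::setNames(x, sys$sp), model, params)))
  }
  structure(out, class = "pip_trajectory")
}

#' @export
print.pip_trajectory <- function(x, ...) {
  cat("Pathway trajectory:", length(x$times), "time points over",
      max(x$times), "min\n")
  cat("final state:\n")
  print(signif(x$states[nrow(x$states), ], 6))
  invisible(x)
}

#' Convert a trajectory to tidy long format
#'
#' @param x A `pip_trajectory`.
#' @param ... Unused.
#' @return A data.frame with columns `time`, `species`, `value`.
#' @export
as.data.frame.pip_trajectory <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = length(x$species)),
    species = rep(x$species, each = length(x$times)),
    value = as.vector(x$states),
    stringsAsFactors = FALSE
  )
}

# Damped Newton refinement of the RHS root, with numerical Jacobian.
# Returns NULL when it fails to converge to a non-negative root.
newton_refine <- function(sys, x, tol = 1e-9, max_iter = 60) {
  n <- sys$n
  for (it in seq_len(max_iter)) {
    fx <- sys_rhs(sys, x)
    if (ss_residual(fx, x) < tol * 1e-3) return(x)
    J <- matrix(0, n, n)
    h <- pmax(abs(x), 1) * 1e-7
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      xm <- x; xm[j] <- pmax(xm[j] - h[j], 0)
      J[, j] <- (sys_rhs(sys, xp) - sys_rhs(sys, xm)) / (xp[j] - xm[j])
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      if (all(xn > -1e-12) &&
          sum(sys_rhs(sys, pmax(xn, 0))^2) < sum(fx^2) * (1 - 1e-4 * lambda) ||
          lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6) return(NULL)
    x <- pmax(x + lambda * step, 0)
  }
  if (ss_residual(sys_rhs(sys, x), x) < tol) x else NULL
}

ss_residual <- function(dx, x) max(abs(dx) / pmax(x, 1))

#' Locate the steady state of the pathway
#'
#' The steady state is found by long integration (robust for this stiff
#' power-law system) followed by a damped Newton refinement pass on the
#' right-hand side. Convergence criterion:
#' `max_i |dX_i/dt| * (1 min) / max(X_i, 1) < tol`. For well-behaved
#' parameter sets a Newton solve from `x0` is attempted first as a shortcut;
#' the refinement criterion is identical on both routes.
#'
#' @param model A `pip_model`.
#' @param params A `pip_params`.
#' @param x0 Starting state; defaults to the curated basal abundances.
#' @param tol Relative residual tolerance.
#' @param max_time Maximum simulated horizon (minutes) before giving up.
#' @return A `pip_steady_state`: list with `abundances` (named 8-vector),
#'   `fluxes` (named vector over all flux ids) and `residual`.
#' @export
find_steady_state <- function(model, params, x0 = model$species$basal_abundance,
                              tol = 1e-9, max_time = 2e5) {
  sys <- compile_system(model, params)
  x <- as_state(x0, sys$sp)
  if (any(x < 0)) stop("negative initial state", call. = FALSE)

  ans <- newton_refine(sys, x, tol = tol)
  if (is.null(ans) || !ss_is_stable(sys, ans)) {
    # integrate in expanding chunks until the relative drift criterion holds
    t_chunk <- 500
    total <- 0
    repeat {
      sol <- tryCatch(
        suppressWarnings(
          deSolve::lsoda(y = x, times = c(0, t_chunk),
                         func = function(t, y, p) list(sys_rhs(sys, y)),
                         rtol = 1e-10, atol = 1e-12)),
        error = function(e) NULL)
      if (is.null(sol) || nrow(sol) < 2 || attr(sol, "istate")[1] < 0) {
        stop("steady-state search: integrator failed; residual ",
             signif(ss_residual(sys_rhs(sys, x), x), 4), " at t = ", total,
             call. = FALSE)
      }
      x <- pmax(as.numeric(sol[2, -1]), 0)
      total <- total + t_chunk
      if (ss_residual(sys_rhs(sys, x), x) < tol) break
      if (total >= max_time) {
        stop("no steady state within ", max_time, " min; residual trajectory ended at ",
             signif(ss_residual(sys_rhs(sys, x), x), 4), call. = FALSE)
      }
      t_chunk <- min(t_chunk * 2, 5e4)
    }
    refined <- newton_refine(sys, x, tol = tol)
    # accept only a local polish: on conservation manifolds (closed
    # transport) a near-singular Jacobian can otherwise slide the root far
    # from the integrated point
    if (!is.null(refined) && max(abs(refined - x) / pmax(x, 1)) < 1e-3) {
      x <- refined
    }
  } else {
    x <- ans
  }

  ab <- stats::setNames(x, sys$sp)
  structure(
    list(abundances = ab,
         fluxes = pathway_fluxes(ab, model, params),
         residual = ss_residual(sys_rhs(sys, x), x)),
    class = "pip_steady_state"
  )
}

# Bounded-effort steady-state search used inside Monte-Carlo screening:
# Newton from a few starts, then a single fixed-horizon integration followed
# by one refinement. Returns NULL instead of iterating further; candidates
# whose steady state cannot be located within this budget are rejected.
fast_steady_state <- function(model, params, x0, tol = 1e-9) {
  sys <- compile_system(model, params)
  x0 <- as_state(x0, sys$sp)
  starts <- list(x0, x0 * 0.1, x0 * 10)
  for (s in starts) {
    ans <- newton_refine(sys, s, tol = tol)
    if (!is.null(ans) && ss_is_stable(sys, ans)) {
      ab <- stats::setNames(ans, sys$sp)
      return(structure(list(abundances = ab,
                            fluxes = pathway_fluxes(ab, model, params),
                            residual = ss_residual(sys_rhs(sys, ans), ans)),
                       class = "pip_steady_state"))
    }
  }
  sol <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y = x0, times = c(0, 3000),
                     func = function(t, y, p) list(sys_rhs(sys, y)),
                     rtol = 1e-6, atol = 1e-8, maxsteps = 20000)),
    error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < 2 || attr(sol, "istate")[1] < 0) return(NULL)
  x <- pmax(as.numeric(sol[2, -1]), 0)
  ans <- newton_refine(sys, x, tol = tol)
  if (is.null(ans)) return(NULL)
  ab <- stats::setNames(ans, sys$sp)
  structure(list(abundances = ab,
                 fluxes = pathway_fluxes(ab, model, params),
                 residual = ss_residual(sys_rhs(sys, ans), ans)),
            class = "pip_steady_state")
}

# A Newton root is only accepted when it is locally attracting (all Jacobian
# eigenvalues with negative real part); otherwise fall back to integration,
# which can only settle on a stable attractor.
ss_is_stable <- function(sys, x) {
  n <- sys$n
  J <- matrix(0, n, n)
  h <- pmax(abs(x), 1) * 1e-7
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + h[j]
    xm <- x; xm[j] <- pmax(xm[j] - h[j], 0)
    J[, j] <- (sys_rhs(sys, xp) - sys_rhs(sys, xm)) / (xp[j] - xm[j])
  }
  ev <- eigen(J, only.values = TRUE)$values
  # strictly negative real parts AND a well-conditioned Jacobian: the
  # conserved mode of a closed-transport system shows up as a (numerically
  # tiny) eigenvalue and must fall through to integration, which respects
  # the conservation manifold
  all(Re(ev) < -1e-12) && min(abs(ev)) / max(abs(ev)) > 1e-10
}

#' @export
print.pip_steady_state <- function(x, ...) {
  cat("Pathway steady state (residual", format(x$residual, digits = 3), ")\n")
  print(signif(x$abundances, 6))
  invisible(x)
}

#' Per-species flux balance at a steady state
#'
#' For each species, the production (influx plus interconversions in) and
#' consumption (efflux plus interconversions out), and their relative
#' imbalance. At a valid steady state every imbalance is within the solver
#' tolerance.
#'
#' @param ss A `pip_steady_state`.
#' @param model The `pip_model` it was computed from.
#' @return Data.frame with columns `species`, `production`, `consumption`,
#'   `relative_imbalance`.
#' @export
flux_balance <- function(ss, model) {
  fx <- model$fluxes
  v <- ss$fluxes
  out <- lapply(model$species$id, function(s) {
    prod_ids <- fx$id[!is.na(fx$product) & fx$product == s]
    cons_ids <- fx$id[!is.na(fx$substrate) & fx$substrate == s]
    p <- sum(v[prod_ids]); cns <- sum(v[cons_ids])
    data.frame(species = s, production = p, consumption = cns,
               relative_imbalance = abs(p - cns) / max(ss$abundances[s], 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
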