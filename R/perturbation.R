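# -- declarative perturbations: knockouts, knockdowns, overexpression -------

#' Construct a perturbation specification
#'
#' A perturbation is a declarative, composable modification of a parameter
#' set. Scale maps multiply the referenced quantity (a scale of 0 is a
#' knockout, 0 < s < 1 a knockdown, s > 1 an upregulation); value maps
#' override it absolutely (used e.g. to impose measured enzyme activities or
#' an alternative rate law parameterization). Scaling an enzyme group scales
#' every flux it catalyses, and propagates multiplicatively to any ternary
#' complex the enzyme is a component of: knocking out PI4K or PIP5KI also
#' removes the PI4K+PIP5KI+DVL complex, while perturbing only the complex
#' leaves the single-enzyme fluxes intact.
#'
#' @param enzyme_scales Named numeric, enzyme id -> non-negative scale.
#' @param gamma_scales Named numeric, flux id -> non-negative scale.
#' @param influx_scales Named numeric, influx id -> non-negative scale.
#' @param enzyme_values Named numeric, enzyme id -> absolute activity.
#' @param gamma_values Named numeric, flux id -> absolute rate constant.
#' @param f_values Named numeric, flux id -> absolute kinetic order.
#' @param influx_values Named numeric, influx id -> absolute rate.
#' @param label Free-text description.
#' @return An object of class `pip_perturbation`.
#' @export
perturbation <- function(enzyme_scales = NULL, gamma_scales = NULL,
                         influx_scales = NULL, enzyme_values = NULL,
                         gamma_values = NULL, f_values = NULL,
                         influx_values = NULL, label = "") {
  num <- function(x) if (is.null(x)) numeric(0) else unlist(x)
  spec <- list(enzyme_scales = num(enzyme_scales),
               gamma_scales = num(gamma_scales),
               influx_scales = num(influx_scales),
               enzyme_values = num(enzyme_values),
               gamma_values = num(gamma_values),
               f_values = num(f_values),
               influx_values = num(influx_values),
               label = label)
  scales <- c(spec$enzyme_scales, spec$gamma_scales, spec$influx_scales)
  if (any(scales < 0)) stop("perturbation scales must be >= 0", call. = FALSE)
  structure(spec, class = "pip_perturbation")
}

#' Apply a perturbation to a parameter set
#'
#' Pure: returns a new `pip_params`, the input is unmodified. Absolute value
#' overrides are applied first, then scales; enzyme scales propagate to
#' complexes containing the enzyme.
#'
#' @param params A `pip_params`.
#' @param spec A `pip_perturbation`.
#' @param model The `pip_model` (needed for complex membership).
#' @return A new `pip_params`.
#' @export
apply_perturbation <- function(params, spec, model = load_network()) {
  p <- params
  known_enzymes <- names(p$enzyme_activity)
  check_ids <- function(ids, known, what) {
    bad <- setdiff(ids, known)
    if (length(bad)) stop("unknown ", what, ": ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  check_ids(names(spec$enzyme_values), known_enzymes, "enzyme id(s)")
  check_ids(names(spec$enzyme_scales), known_enzymes, "enzyme id(s)")
  check_ids(names(spec$gamma_values), names(p$gamma), "flux id(s)")
  check_ids(names(spec$gamma_scales), names(p$gamma), "flux id(s)")
  check_ids(names(spec$f_values), names(p$f), "flux id(s)")
  check_ids(names(spec$influx_values), names(p$influx), "influx id(s)")
  check_ids(names(spec$influx_scales), names(p$influx), "influx id(s)")

  for (e in names(spec$enzyme_values)) p$enzyme_activity[e] <- spec$enzyme_values[e]
  for (id in names(spec$gamma_values)) p$gamma[id] <- spec$gamma_values[id]
  for (id in names(spec$f_values)) p$f[id] <- spec$f_values[id]
  for (id in names(spec$influx_values)) p$influx[id] <- spec$influx_values[id]

  for (e in names(spec$enzyme_scales)) {
    s <- spec$enzyme_scales[e]
    p$enzyme_activity[e] <- p$enzyme_activity[e] * s
    for (cx in names(model$complexes)) {
      if (e %in% model$complexes[[cx]]) {
        p$enzyme_activity[cx] <- p$enzyme_activity[cx] * s
      }
    }
  }
  for (id in names(spec$gamma_scales)) p$gamma[id] <- p$gamma[id] * spec$gamma_scales[id]
  for (id in names(spec$influx_scales)) p$influx[id] <- p$influx[id] * spec$influx_scales[id]
  p
}

#' Compose two perturbations
#'
#' Scales multiply; absolute overrides of the second specification win over
#' the first. Composition is associative, and composing with the identity
#' perturbation is a no-op.
#'
#' @param a,b `pip_perturbation` objects.
#' @return A `pip_perturbation`.
#' @export
compose_perturbations <- function(a, b) {
  mul <- function(x, y) {
    ids <- union(names(x), names(y))
    out <- stats::setNames(rep(1, length(ids)), ids)
    out[names(x)] <- x
    out[names(y)] <- out[names(y)] * y
    out
  }
  override <- function(x, y) { x[names(y)] <- y; x }
  perturbation(
    enzyme_scales = mul(a$enzyme_scales, b$enzyme_scales),
    gamma_scales = mul(a$gamma_scales, b$gamma_scales),
    influx_scales = mul(a$influx_scales, b$influx_scales),
    enzyme_values = override(a$enzyme_values, b$enzyme_values),
    gamma_values = override(a$gamma_values, b$gamma_values),
    f_values = override(a$f_values, b$f_values),
    influx_values = override(a$influx_values, b$influx_values),
    label = trimws(paste(a$label, b$label))
  )
}

#' Named perturbation presets
#'
#' The registry (shipped as YAML) holds one preset per reference in-silico
#' experiment: single-enzyme knockouts with complex propagation, phosphatase
#' upregulations (exposed `upregulation` factor, default 2), the
#' blocked-input configuration used by the PI(4,5)P2 source decomposition
#' (all external inputs into the PI(4)P / PI(4,5)P2 pair stopped, with
#' `v0->4` kept at 20% of its rate constant to avoid numerically degenerate
#' PI(4)P levels), the apical / basolateral membrane configurations (absolute
#' PTEN and PI3KI activities), the slow / fast `v345->34` rate laws, and the
#' PI-influx reduction series.
#'
#' @param name Preset identifier; see `names(knockout_presets())`.
#' @param upregulation Scale used by `*_up` presets.
#' @return A `pip_perturbation`.
#' @export
knockout_preset <- function(name, upregulation = 2) {
  reg <- knockout_presets()
  if (!name %in% names(reg)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  raw <- reg[[name]]
  sc <- raw$enzyme_scales
  if (isTRUE(raw$upregulated) && length(sc)) {
    sc[sc < 0] <- upregulation      # -1 marks "the exposed factor"
  }
  perturbation(enzyme_scales = sc, gamma_scales = raw$gamma_scales,
               influx_scales = raw$influx_scales,
               enzyme_values = raw$enzyme_values,
               gamma_values = raw$gamma_values, f_values = raw$f_values,
               label = raw$label %||% name)
}

#' @rdname knockout_preset
#' @export
knockout_presets <- function() {
  yaml::read_yaml(system.file("extdata", "presets.yaml", package = "pipkin",
                              mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pip_perturbation <- function(x, ...) {
  cat("Perturbation:", if (nzchar(x$label)) x$label else "(unlabelled)", "\n")
  show <- function(nm, v, suffix = "") {
    if (length(v)) cat("  ", nm, ": ",
                       paste(sprintf("%s=%.4g%s", names(v), v, suffix), collapse = ", "),
                       "\n", sep = "")
  }
  show("enzyme scales", x$enzyme_scales, "x")
  show("gamma scales", x$gamma_scales, "x")
  show("influx scales", x$influx_scales, "x")
  show("enzyme activities", x$enzyme_values)
  show("rate constants", x$gamma_values)
  show("kinetic orders", x$f_values)
  show("influx rates", x$influx_values)
  invisible(x)
}
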