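# -- parameter sets: gamma, kinetic orders, enzyme activities, transport ----

#' Construct a parameter set
#'
#' A parameter set is the unit being fitted, perturbed and sampled. Each
#' interconversion flux `v[i->j]` follows the power law
#' `v = gamma * E * X^f` (rate constant, enzyme activity in mg/um^2, substrate
#' abundance in molecules/um^2 raised to its kinetic order). Transport is
#' described by three constant influx rates (molecules um^-2 min^-1) and one
#' shared first-order efflux rate constant (min^-1).
#'
#' @param gamma Named numeric vector of positive rate constants, one per
#'   interconversion flux id.
#' @param f Named numeric vector of kinetic orders, one per interconversion.
#' @param enzyme_activity Named numeric vector of non-negative enzyme group
#'   activities (mg/um^2).
#' @param influx Named numeric vector of non-negative influx rates with names
#'   `"v->0"`, `"v->4"`, `"v->3"`.
#' @param efflux_k Shared non-negative efflux rate constant (min^-1).
#' @return An object of class `pip_params`.
#' @export
parameter_set <- function(gamma, f, enzyme_activity, influx, efflux_k) {
  structure(
    list(gamma = gamma, f = f, enzyme_activity = enzyme_activity,
         influx = influx, efflux_k = as.numeric(efflux_k)),
    class = "pip_params"
  )
}

#' Reference parameter set
#'
#' Returns the committed reference parameterization of the pathway: rate
#' constants, kinetic orders, enzyme activities and transport rates whose
#' steady state satisfies the literature-derived pool intervals (PI(4,5)P2
#' around 10,000 molecules/um^2), whose whole-membrane recycling rate is
#' 4.5% per minute, and which reproduces the calibration phenomena. All
#' "percent of basal" computations in the experiments module use the steady
#' state of this set as denominator.
#'
#' @return A `pip_params` object.
#' @export
reference_params <- function() {
  read_parameters(system.file("extdata", "reference_parameters.csv",
                              package = "pipkin", mustWork = TRUE))
}

#' Read / write parameter tables
#'
#' Parameter tables are CSV files with columns
#' `flux_id, gamma, f, enzyme_id, enzyme_activity`: one row per
#' interconversion (gamma, kinetic order, enzyme group and its activity), one
#' row per influx (rate in the `gamma` column), and one row per efflux (the
#' shared rate constant in the `gamma` column, kinetic order 1). Numbers are
#' serialized with 12 significant digits so that write/read round-trips
#' reproduce steady states to better than 1e-10 relative.
#'
#' @param path CSV file path.
#' @return `read_parameters` returns a `pip_params`; `write_parameters`
#'   returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(flux_id = "character", gamma = "numeric",
                                        f = "numeric", enzyme_id = "character",
                                        enzyme_activity = "numeric"))
  is_in  <- grepl("^v->", tab$flux_id)
  is_out <- grepl("->$", tab$flux_id)
  inter  <- tab[!is_in & !is_out, ]
  influx <- tab$gamma[is_in]
  names(influx) <- tab$flux_id[is_in]
  k_rows <- unique(tab$gamma[is_out])
  if (length(k_rows) != 1L) {
    stop("parameter table '", path, "' does not have one shared efflux rate constant",
         call. = FALSE)
  }
  act <- tapply(inter$enzyme_activity, inter$enzyme_id, function(v) v[[1]])
  gamma <- inter$gamma; names(gamma) <- inter$flux_id
  f <- inter$f; names(f) <- inter$flux_id
  parameter_set(gamma = gamma, f = f,
                enzyme_activity = stats::setNames(as.numeric(act), names(act)),
                influx = influx, efflux_k = k_rows)
}

#' @rdname read_parameters
#' @param params A `pip_params` object.
#' @param model A `pip_model` used to recover the flux -> enzyme mapping.
#' @export
write_parameters <- function(params, path, model = load_network()) {
  inter <- model$fluxes[model$fluxes$kind %in% c("phosphorylation", "hydrolysis"), ]
  fmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))
  rows <- data.frame(
    flux_id = inter$id,
    gamma = fmt(params$gamma[inter$id]),
    f = fmt(params$f[inter$id]),
    enzyme_id = inter$enzyme,
    enzyme_activity = fmt(params$enzyme_activity[inter$enzyme]),
    stringsAsFactors = FALSE
  )
  rows <- rbind(rows, data.frame(
    flux_id = names(params$influx), gamma = fmt(params$influx),
    f = "", enzyme_id = "", enzyme_activity = ""))
  eff <- model$fluxes$id[model$fluxes$kind == "efflux"]
  rows <- rbind(rows, data.frame(
    flux_id = eff, gamma = fmt(rep(params$efflux_k, length(eff))),
    f = fmt(rep(1, length(eff))), enzyme_id = "", enzyme_activity = ""))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a parameter set against a model
#'
#' Produces a report listing problems rather than raising errors: missing
#' entries are errors, non-positive rate constants or negative activities in
#' an unperturbed context are warnings (a zero is legitimate inside a
#' knockout). An empty report means the set is usable.
#'
#' @param model A `pip_model`.
#' @param params A `pip_params`.
#' @return A data.frame with columns `level` ("error"/"warning"), `entry`,
#'   `message`; zero rows when the set is fully valid.
#' @export
validate_parameter_set <- function(model, params) {
  report <- list()
  note <- function(level, entry, message) {
    report[[length(report) + 1L]] <<- data.frame(
      level = level, entry = entry, message = message, stringsAsFactors = FALSE)
  }
  inter <- model$fluxes[model$fluxes$kind %in% c("phosphorylation", "hydrolysis"), ]
  for (id in inter$id) {
    g <- params$gamma[id]
    if (is.na(g)) note("error", id, "missing rate constant") else
      if (g <= 0) note("warning", id, "non-positive rate constant outside a knockout")
    if (is.na(params$f[id])) note("error", id, "missing kinetic order")
  }
  for (e in unique(inter$enzyme)) {
    a <- params$enzyme_activity[e]
    if (is.na(a)) note("error", e, "missing enzyme activity") else
      if (a < 0) note("error", e, "negative enzyme activity")
  }
  for (id in model$fluxes$id[model$fluxes$kind == "influx"]) {
    r <- params$influx[id]
    if (is.na(r)) note("error", id, "missing influx rate") else
      if (r < 0) note("error", id, "negative influx rate")
  }
  if (is.null(params$efflux_k) || length(params$efflux_k) != 1L || is.na(params$efflux_k)) {
    note("error", "efflux", "missing shared efflux rate constant")
  } else if (params$efflux_k < 0) {
    note("error", "efflux", "negative efflux rate constant")
  }
  if (length(report)) do.call(rbind, report) else
    data.frame(level = character(), entry = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' @export
print.pip_params <- function(x, ...) {
  cat("Phosphoinositide pathway parameter set\n")
  cat("  interconversions:", length(x$gamma), "(gamma, f)\n")
  cat("  enzyme groups:   ", length(x$enzyme_activity), "\n")
  cat("  influx rates:    ",
      paste(sprintf("%s=%.4g", names(x$influx), x$influx), collapse = ", "), "\n")
  cat("  efflux constant: ", format(x$efflux_k), "per min (shared)\n")
  invisible(x)
}
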