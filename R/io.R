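# -- serialization, provenance, round-trips ---------------------------------

# Polynomial rolling hash over a canonical 12-significant-digit rendering of
# the parameter set; used only for provenance records.
params_hash <- function(params) {
  txt <- paste(
    paste(names(params$gamma), formatC(params$gamma, digits = 12, format = "g")),
    paste(names(params$f), formatC(params$f, digits = 12, format = "g")),
    paste(names(params$enzyme_activity),
          formatC(params$enzyme_activity, digits = 12, format = "g")),
    paste(names(params$influx), formatC(params$influx, digits = 12, format = "g")),
    formatC(params$efflux_k, digits = 12, format = "g"),
    collapse = "|")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a steady state to JSON
#'
#' @param ss A `pip_steady_state`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(ss, path) {
  jsonlite::write_json(
    list(abundances = as.list(ss$abundances),
         fluxes = as.list(ss$fluxes),
         residual = ss$residual),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' Long format: `time`, `species`, `value`.
#'
#' @param traj A `pip_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Provenance record for a computation
#'
#' @param params The `pip_params` used.
#' @param seed Seed, if any randomness was involved.
#' @param tolerances Named list of numerical tolerances.
#' @return A list suitable for JSON serialization.
#' @export
provenance <- function(params, seed = NA, tolerances = list(rtol = 1e-8,
                                                            atol = 1e-10,
                                                            ss_tol = 1e-9)) {
  list(package = "pipkin",
       version = as.character(utils::packageVersion("pipkin")),
       r_version = R.version.string,
       params_hash = params_hash(params),
       seed = seed,
       tolerances = tolerances)
}
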