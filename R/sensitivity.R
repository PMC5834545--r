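# -- local steady-state sensitivity analysis --------------------------------

#' Steady-state relative sensitivity matrix
#'
#' For every pool X_i and every parameter p (rate constants, kinetic orders,
#' enzyme activities, influx rates and the efflux constant), the
#' dimensionless relative (logarithmic) sensitivity
#' `S[i, p] = (dX_i*/X_i*) / (dp/p)` is estimated by central finite
#' differences at the reference steady state, perturbing each parameter by
#' `+/- delta` of its value. Entries whose perturbed steady state cannot be
#' located are set to `NA` and flagged, never silently zeroed. A
#' consistency check recomputes the matrix at `delta/2` and flags entries
#' whose value changes by more than 20%.
#'
#' @param model A `pip_model`.
#' @param params A `pip_params`.
#' @param delta Relative perturbation size (default 1%).
#' @param check_consistency Recompute at `delta/2` and flag unstable
#'   entries.
#' @return Object of class `pip_sensitivity`: list with `S` (species x
#'   parameters matrix), `flagged` (logical matrix), `delta`, and the
#'   reference steady state.
#' @export
sensitivity_matrix <- function(model, params, delta = 0.01,
                               check_consistency = TRUE) {
  basal <- find_steady_state(model, params)
  addr <- function(prefix, v) {
    if (length(v)) paste0(prefix, ":", names(v)) else character(0)
  }
  addresses <- c(addr("gamma", params$gamma), addr("f", params$f),
                 addr("E", params$enzyme_activity),
                 addr("influx", params$influx), "efflux_k")
  compute <- function(d) {
    S <- matrix(NA_real_, nrow = nrow(model$species), ncol = length(addresses),
                dimnames = list(model$species$id, addresses))
    for (j in seq_along(addresses)) {
      ad <- addresses[j]
      p0 <- param_values(params, ad)
      if (p0 == 0) next   # a zeroed parameter has no relative sensitivity
      ss <- lapply(c(1 - d, 1 + d), function(fac) {
        tryCatch(find_steady_state(model, param_update(params, ad, p0 * fac),
                                   x0 = basal$abundances, max_time = 5e4),
                 error = function(e) NULL)
      })
      if (any(vapply(ss, is.null, logical(1)))) next
      S[, j] <- (ss[[2]]$abundances - ss[[1]]$abundances) /
        pmax(basal$abundances, .Machine$double.eps) / (2 * d)
    }
    S
  }
  S <- compute(delta)
  flagged <- is.na(S)
  if (check_consistency) {
    S2 <- compute(delta / 2)
    denom <- pmax(abs(S), abs(S2))
    rel <- abs(S - S2) / ifelse(denom > 1e-6, denom, Inf)
    flagged <- flagged | (!is.na(rel) & rel > 0.2)
  }
  structure(list(S = S, flagged = flagged, delta = delta, basal = basal),
            class = "pip_sensitivity")
}

#' @export
print.pip_sensitivity <- function(x, ...) {
  cat("Steady-state sensitivity matrix:", nrow(x$S), "species x",
      ncol(x$S), "parameters (delta =", x$delta, ")\n")
  cat("  |S| > 1 entries:", sum(abs(x$S) > 1, na.rm = TRUE),
      "; flagged:", sum(x$flagged), "\n")
  invisible(x)
}

#' Extract the high-sensitivity network
#'
#' Edges are exactly the matrix entries with `|S| > threshold`, directed
#' parameter -> species, keeping the sign and using `|S|` as weight.
#'
#' @param sens A `pip_sensitivity`.
#' @param threshold Absolute-magnitude cutoff (default 1, the amplifying
#'   regime).
#' @return Object of class `pip_sens_network`: list with `edges`
#'   (data.frame: parameter, species, sensitivity, weight) and
#'   `species_clusters` (list of species groups connected through shared
#'   high-sensitivity parameters).
#' @export
high_sensitivity_network <- function(sens, threshold = 1) {
  S <- sens$S
  idx <- which(!is.na(S) & abs(S) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    parameter = colnames(S)[idx[, 2]],
    species = rownames(S)[idx[, 1]],
    sensitivity = S[idx],
    weight = abs(S[idx]),
    stringsAsFactors = FALSE
  )
  clusters <- list()
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("parameter", "species")], directed = FALSE)
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == k]
      spp <- intersect(members, rownames(S))
      if (length(spp)) clusters[[length(clusters) + 1L]] <- sort(spp)
    }
  }
  structure(list(edges = edges, species_clusters = clusters,
                 threshold = threshold),
            class = "pip_sens_network")
}

#' @export
print.pip_sens_network <- function(x, ...) {
  cat("High-sensitivity network (|S| >", x$threshold, "):",
      nrow(x$edges), "edges\n")
  for (cl in x$species_clusters) {
    cat("  cluster:", paste(cl, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a sensitivity network to GraphML / edge-list CSV
#'
#' @param net A `pip_sens_network`.
#' @param path Output path; format chosen by extension (`.graphml` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_sensitivity_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.csv(net$edges, path, row.names = FALSE)
  }
  invisible(path)
}
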