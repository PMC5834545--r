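# -- pathway network: species, fluxes, enzyme groups ------------------------

#' Load a pathway network definition
#'
#' Reads a structured YAML network file describing the phosphoinositide
#' interconversion network: the 8 lipid species (ids are digit strings
#' encoding phosphorylated inositol positions, `"0"` for PI through `"345"`
#' for PI(3,4,5)P3), the 21 enzyme-catalysed interconversions, 3 influxes and
#' 8 first-order effluxes, and the enzyme groups catalysing them. The file is
#' validated structurally before a model object is returned.
#'
#' @param path Path to a network YAML file. Defaults to the curated network
#'   shipped with the package.
#' @return An object of class `pip_model`: a list with elements `species`
#'   (data.frame: id, name, basal_abundance), `fluxes` (data.frame: id, kind,
#'   substrate, product, enzyme), `enzymes` (named list of character vectors,
#'   enzyme id -> catalysed flux ids), `complexes` (named list, complex id ->
#'   component enzyme ids), and `time_unit`.
#' @examples
#' mod <- load_network()
#' nrow(mod$species)                    # 8 lipid species
#' sum(mod$fluxes$kind %in% c("phosphorylation", "hydrolysis"))  # 21
#' @export
load_network <- function(path = default_network_file()) {
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("failed to parse network file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (fld in c("species", "fluxes", "time_unit")) {
    if (is.null(raw[[fld]])) {
      stop("network file '", path, "' is missing required field '", fld, "'",
           call. = FALSE)
    }
  }

  species <- do.call(rbind, lapply(raw$species, function(s) {
    data.frame(id = as.character(s$id), name = s$name,
               basal_abundance = as.numeric(s$basal_abundance),
               stringsAsFactors = FALSE)
  }))
  fluxes <- do.call(rbind, lapply(raw$fluxes, function(fx) {
    data.frame(id = fx$id, kind = fx$kind,
               substrate = if (is.null(fx$substrate)) NA_character_ else as.character(fx$substrate),
               product   = if (is.null(fx$product))   NA_character_ else as.character(fx$product),
               enzyme    = if (is.null(fx$enzyme))    NA_character_ else fx$enzyme,
               stringsAsFactors = FALSE)
  }))

  inter <- fluxes[fluxes$kind %in% c("phosphorylation", "hydrolysis"), ]
  enzymes <- split(inter$id, inter$enzyme)

  model <- structure(
    list(species = species, fluxes = fluxes, enzymes = enzymes,
         complexes = lapply(raw$complexes, unlist),
         time_unit = raw$time_unit),
    class = "pip_model"
  )
  validate_network(model)
  model
}

#' @rdname load_network
#' @export
default_network_file <- function() {
  system.file("extdata", "network.yaml", package = "pipkin", mustWork = TRUE)
}

#' Validate network structural integrity
#'
#' Checks the invariants of the pathway definition: exactly 8 species with
#' unique ids, exactly 21 interconversions, 3 influxes and 8 effluxes (one
#' per species), every flux referencing declared species, every
#' interconversion carrying exactly one enzyme group, 1:1 stoichiometry
#' implied by single substrate/product, and connectivity of the
#' interconversion graph over the species.
#'
#' @param model A `pip_model`.
#' @return The model, invisibly; errors describe any violation.
#' @export
validate_network <- function(model) {
  sp <- model$species
  fx <- model$fluxes
  if (nrow(sp) != 8L) {
    stop("structural error: expected 8 species, found ", nrow(sp), call. = FALSE)
  }
  if (anyDuplicated(sp$id)) stop("structural error: duplicated species ids", call. = FALSE)
  if (any(sp$basal_abundance < 0)) {
    stop("structural error: negative basal abundance", call. = FALSE)
  }

  n_inter  <- sum(fx$kind %in% c("phosphorylation", "hydrolysis"))
  n_in     <- sum(fx$kind == "influx")
  n_out    <- sum(fx$kind == "efflux")
  if (n_inter != 21L) {
    inter <- fx[fx$kind %in% c("phosphorylation", "hydrolysis"), ]
    stop("structural error: expected 21 interconversion fluxes, found ",
         n_inter, " (", paste(inter$id, collapse = ", "), ")", call. = FALSE)
  }
  if (n_in != 3L) stop("structural error: expected 3 influxes, found ", n_in, call. = FALSE)
  if (n_out != 8L) stop("structural error: expected 8 effluxes, found ", n_out, call. = FALSE)
  if (!setequal(fx$substrate[fx$kind == "efflux"], sp$id)) {
    stop("structural error: effluxes must cover every species exactly once", call. = FALSE)
  }

  refd <- c(fx$substrate, fx$product)
  refd <- refd[!is.na(refd)]
  if (!all(refd %in% sp$id)) {
    stop("structural error: dangling species reference(s): ",
         paste(setdiff(refd, sp$id), collapse = ", "), call. = FALSE)
  }
  inter <- fx[fx$kind %in% c("phosphorylation", "hydrolysis"), ]
  if (any(is.na(inter$enzyme))) {
    stop("structural error: interconversion without an enzyme group", call. = FALSE)
  }
  if (any(is.na(inter$substrate)) || any(is.na(inter$product))) {
    stop("structural error: interconversion must have one substrate and one product",
         call. = FALSE)
  }
  for (cx in names(model$complexes)) {
    comp <- model$complexes[[cx]]
    if (!cx %in% names(model$enzymes)) {
      stop("structural error: complex '", cx, "' catalyses no flux", call. = FALSE)
    }
    missing <- setdiff(comp, names(model$enzymes))
    if (length(missing)) {
      stop("structural error: complex '", cx, "' references unknown enzyme(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  # connectivity of the interconversion graph over the 8 species
  g <- igraph::graph_from_data_frame(inter[, c("substrate", "product")],
                                     directed = FALSE,
                                     vertices = sp$id)
  if (igraph::components(g)$no != 1L) {
    stop("structural error: interconversion graph is not connected", call. = FALSE)
  }
  invisible(model)
}

#' Serialize a pathway model back to YAML
#'
#' Inverse of [load_network()]: writing a model and re-loading it yields an
#' identical model (round-trip property).
#'
#' @param model A `pip_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  row_to_list <- function(row) {
    out <- as.list(row)
    out[!vapply(out, function(x) is.na(x) || is.null(x), logical(1))]
  }
  obj <- list(
    time_unit = model$time_unit,
    species = lapply(seq_len(nrow(model$species)), function(i) {
      s <- model$species[i, ]
      list(id = s$id, name = s$name, basal_abundance = s$basal_abundance)
    }),
    fluxes = lapply(seq_len(nrow(model$fluxes)), function(i) {
      row_to_list(model$fluxes[i, c("id", "kind", "substrate", "product", "enzyme")])
    }),
    complexes = lapply(model$complexes, as.list)
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Fluxes catalysed by an enzyme group
#'
#' Returns the interconversion fluxes an enzyme group drives. With
#' `include_complexes = TRUE` (default) the fluxes of any ternary complex the
#' enzyme is a component of are included, reflecting that removing the enzyme
#' also removes the complex: PI4K participates in both `v0->4` and `v0->45`,
#' PIP5KI in both `v4->45` and `v0->45`.
#'
#' @param model A `pip_model`.
#' @param enzyme Enzyme group id.
#' @param include_complexes Include fluxes catalysed by complexes containing
#'   this enzyme as a component.
#' @return Character vector of flux ids.
#' @export
enzyme_fluxes <- function(model, enzyme, include_complexes = TRUE) {
  if (!enzyme %in% c(names(model$enzymes), names(model$complexes))) {
    stop("unknown enzyme group '", enzyme, "'", call. = FALSE)
  }
  out <- model$enzymes[[enzyme]]
  if (include_complexes) {
    for (cx in names(model$complexes)) {
      if (enzyme %in% model$complexes[[cx]]) {
        out <- union(out, model$enzymes[[cx]])
      }
    }
  }
  out
}

#' @export
print.pip_model <- function(x, ...) {
  inter <- x$fluxes[x$fluxes$kind %in% c("phosphorylation", "hydrolysis"), ]
  cat("Phosphoinositide pathway model (1 um^2 membrane patch)\n")
  cat("  species:          ", nrow(x$species), "\n")
  cat("  interconversions: ", nrow(inter),
      sprintf(" (%d phosphorylations, %d hydrolyses)\n",
              sum(inter$kind == "phosphorylation"), sum(inter$kind == "hydrolysis")))
  cat("  influxes:         ", sum(x$fluxes$kind == "influx"), "\n")
  cat("  effluxes:         ", sum(x$fluxes$kind == "efflux"),
      " (first order, shared rate constant)\n")
  cat("  enzyme groups:    ", length(x$enzymes), "\n")
  cat("  time unit:        ", x$time_unit, "\n")
  invisible(x)
}
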