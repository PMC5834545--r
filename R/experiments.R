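# -- scripted reproductions of the reference in-silico experiments ----------

# All experiments compare NEW steady states against the basal steady state
# of the supplied parameter set ("% of basal"); transients are not used.

experiment_result <- function(id, rows, basal, params) {
  structure(list(id = id, readouts = rows,
                 provenance = list(params_hash = params_hash(params),
                                   basal_residual = basal$residual,
                                   time = "steady state")),
            class = "pip_experiment")
}

#' @export
print.pip_experiment <- function(x, ...) {
  cat("Experiment:", x$id, "\n")
  print(x$readouts, row.names = FALSE, digits = 4)
  invisible(x)
}

readout_rows <- function(label, ss, basal, species) {
  data.frame(
    perturbation = label,
    species = species,
    abundance = unname(ss$abundances[species]),
    pct_of_basal = 100 * unname(ss$abundances[species] / basal$abundances[species]),
    stringsAsFactors = FALSE
  )
}

perturbed_ss <- function(model, params, spec, basal) {
  find_steady_state(model, apply_perturbation(params, spec, model),
                    x0 = basal$abundances)
}

#' PI(4,5)P2 source decomposition
#'
#' Starting from the configuration in which every external input into the
#' PI(4)P / PI(4,5)P2 pair is stopped (PI(4)P influx off, `v0->4` at 20% of
#' its rate constant, `v34->4`, `v0->45`, `v5->45` and `v345->45` off, the
#' mutual `v4->45` / `v45->4` exchange left intact), each input is
#' re-activated one at a time and the new steady state recorded. The
#' unperturbed control and the fully blocked baseline are included, so the
#' PI(4)P-influx case can be read against either baseline.
#'
#' @param model A `pip_model`.
#' @param params Reference `pip_params`.
#' @return A `pip_experiment` with PI(4)P and PI(4,5)P2 readouts (% of
#'   basal) per reactivated input.
#' @export
run_source_decomposition <- function(model = load_network(),
                                     params = reference_params()) {
  basal <- find_steady_state(model, params)
  block <- knockout_preset("block_pip2_inputs")
  reactivate <- function(drop_gamma = NULL, drop_influx = NULL, label) {
    spec <- block
    spec$gamma_scales <- spec$gamma_scales[setdiff(names(spec$gamma_scales), drop_gamma)]
    # v0->4 stays at 20% in every reactivation except its own
    spec$influx_scales <- spec$influx_scales[setdiff(names(spec$influx_scales), drop_influx)]
    spec$label <- label
    spec
  }
  cases <- list(
    reactivate(label = "all inputs blocked"),
    reactivate(drop_gamma = "v0->45", label = "only v0->45"),
    reactivate(drop_gamma = "v5->45", label = "only v5->45"),
    reactivate(drop_gamma = "v345->45", label = "only v345->45"),
    reactivate(drop_influx = "v->4", label = "only v->4")
  )
  rows <- do.call(rbind, lapply(cases, function(spec) {
    ss <- perturbed_ss(model, params, spec, basal)
    readout_rows(spec$label, ss, basal, c("4", "45"))
  }))
  rows <- rbind(readout_rows("unperturbed control", basal, basal, c("4", "45")),
                rows)
  blocked <- rows[rows$perturbation == "all inputs blocked", ]
  blocked_ab <- stats::setNames(blocked$abundance, blocked$species)
  rows$pct_of_blocked <- 100 * rows$abundance / blocked_ab[rows$species]
  experiment_result("source_decomposition", rows, basal, params)
}

#' PI(5)P channelling towards PI(4,5)P2
#'
#' In the blocked-input configuration with only `v5->45` re-activated, the
#' PI(3)P influx is scaled up; material then reaches PI(4,5)P2 through the
#' chain PI(3)P -> PI(3,5)P2 -> PI(5)P -> PI(4,5)P2. The PI(4,5)P2 level is
#' non-decreasing in the influx scale.
#'
#' @param model A `pip_model`.
#' @param params Reference `pip_params`.
#' @param scale_v3 Vector of PI(3)P-influx scale factors.
#' @return A `pip_experiment` with PI(4,5)P2 (% of basal) per scale.
#' @export
run_pi5p_channeling <- function(model = load_network(),
                                params = reference_params(),
                                scale_v3 = c(1, 25, 50)) {
  stopifnot(all(scale_v3 > 0))
  basal <- find_steady_state(model, params)
  block <- knockout_preset("block_pip2_inputs")
  block$gamma_scales <- block$gamma_scales[names(block$gamma_scales) != "v5->45"]
  rows <- do.call(rbind, lapply(scale_v3, function(s) {
    spec <- compose_perturbations(
      block, perturbation(influx_scales = c(`v->3` = s),
                          label = sprintf("v->3 x%g", s)))
    ss <- perturbed_ss(model, params, spec, basal)
    cbind(readout_rows(sprintf("only v5->45, v->3 x%g", s), ss, basal,
                       c("45", "5", "3")),
          scale_v3 = s)
  }))
  experiment_result("pi5p_channeling", rows, basal, params)
}

#' Apical / basolateral membrane configurations
#'
#' Imposes the measured PTEN and PI3KI activities of the apical (high PTEN,
#' low PI3KI) or basolateral (low PTEN, high PI3KI) plasma-membrane domain,
#' under the slow or fast `v345->34` rate law, optionally with an
#' additional PTEN knockdown, and reports the PI(3,4,5)P3, PI(4,5)P2 and
#' PI(3,4)P2 steady states.
#'
#' @param model A `pip_model`.
#' @param params Reference `pip_params`.
#' @param config `"apical"` or `"basolateral"`.
#' @param v345_34_mode `"slow"` or `"fast"`.
#' @param pten_knockdown Optional knockdown fraction (e.g. 0.9833 removes
#'   98.33% of PTEN activity) applied on top of the configuration.
#' @return A `pip_experiment`.
#' @export
run_membrane_polarity <- function(model = load_network(),
                                  params = reference_params(),
                                  config = c("apical", "basolateral"),
                                  v345_34_mode = c("slow", "fast"),
                                  pten_knockdown = NULL) {
  config <- match.arg(config)
  v345_34_mode <- match.arg(v345_34_mode)
  basal <- find_steady_state(model, params)
  spec <- compose_perturbations(knockout_preset(config),
                                knockout_preset(paste0("v345_34_", v345_34_mode)))
  label <- paste(config, v345_34_mode, sep = ", ")
  if (!is.null(pten_knockdown)) {
    spec <- compose_perturbations(
      spec, perturbation(enzyme_scales = c(PTEN = 1 - pten_knockdown)))
    label <- sprintf("%s, PTEN -%.2f%%", label, 100 * pten_knockdown)
  }
  ss <- perturbed_ss(model, params, spec, basal)
  experiment_result(paste0("membrane_polarity_", config, "_", v345_34_mode),
                    readout_rows(label, ss, basal, c("345", "45", "34")),
                    basal, params)
}

#' siRNA knockout / upregulation panel
#'
#' One perturbation per screened enzyme: kinases are knocked out one at a
#' time (knocking out PI4K or PIP5KI also removes the PI4K+PIP5KI+DVL
#' complex; the complex can also be removed alone), phosphatases are
#' upregulated by `upregulation`. Reports PI(4,5)P2 and PI(3,4)P2 as % of
#' basal plus the predicted direction of ENaC activity (down when
#' PI(4,5)P2 falls beyond `tolerance`, up when it rises beyond it).
#'
#' @param model A `pip_model`.
#' @param params Reference `pip_params`.
#' @param upregulation Factor applied to phosphatase presets.
#' @param tolerance Relative PI(4,5)P2 change regarded as "unchanged".
#' @return A `pip_experiment`; readouts carry an `enac_prediction` column
#'   on the PI(4,5)P2 rows.
#' @export
run_sirna_panel <- function(model = load_network(), params = reference_params(),
                            upregulation = 2, tolerance = 0.05) {
  basal <- find_steady_state(model, params)
  panel <- c("pip5ki_ko", "pi4k_ko", "complex_ko", "sioss_up", "pip5kii_ko",
             "synj_tmem55_up", "pi3ki_ko", "pi3kii_ko")
  rows <- do.call(rbind, lapply(panel, function(name) {
    spec <- knockout_preset(name, upregulation = upregulation)
    ss <- perturbed_ss(model, params, spec, basal)
    readout_rows(spec$label, ss, basal, c("45", "34"))
  }))
  r45 <- rows$pct_of_basal / 100
  rows$enac_prediction <- ifelse(rows$species != "45", NA_character_,
    ifelse(r45 < 1 - tolerance, "down",
           ifelse(r45 > 1 + tolerance, "up", "unchanged")))
  experiment_result("sirna_panel", rows, basal, params)
}

#' PI-drop propagation series
#'
#' Reproduces the graded shutdown of lipid supply: halving the PI influx
#' rate constant alone (`gamma0_only`), additionally closing the PI(4)P and
#' PI(3)P influxes (`plus_closed_transports`), and the configuration that
#' finally halves PI(4,5)P2 - both transports closed with PI influx at 2%
#' (`full_50pct`).
#'
#' @param model A `pip_model`.
#' @param params Reference `pip_params`.
#' @param mode One of `"gamma0_only"`, `"plus_closed_transports"`,
#'   `"full_50pct"`.
#' @return A `pip_experiment` with PI, PI(4)P and PI(4,5)P2 readouts.
#' @export
run_pi_drop <- function(model = load_network(), params = reference_params(),
                        mode = c("gamma0_only", "plus_closed_transports",
                                 "full_50pct")) {
  mode <- match.arg(mode)
  preset <- switch(mode, gamma0_only = "gamma0_half",
                   plus_closed_transports = "gamma0_half_closed",
                   full_50pct = "pi_drop_full")
  basal <- find_steady_state(model, params)
  spec <- knockout_preset(preset)
  ss <- perturbed_ss(model, params, spec, basal)
  experiment_result(paste0("pi_drop_", mode),
                    readout_rows(spec$label, ss, basal, c("0", "4", "45")),
                    basal, params)
}

#' Reproduce a full experiment panel and write a tidy CSV
#'
#' Convenience driver bundling the figure-sized experiment suites:
#' `"pi_supply"` (the PI-drop series plus the 50% kinase knockdowns),
#' `"sources"` (the PI(4,5)P2 source decomposition), `"small_pools"` (MTMR,
#' SYNJ/TMEM55 and PIKfyve perturbations), `"golgi_pi4p"` (a PI(4)P-influx
#' scan), `"polarity"` (the apical/basolateral grid), and `"sirna"` (the
#' knockout panel).
#'
#' @param panel Panel name.
#' @param model,params Model and reference parameters.
#' @param dir Optional output directory; when given, a
#'   `reproduce_<panel>.csv` is written there.
#' @return The combined tidy data.frame, invisibly when `dir` is given.
#' @export
reproduce_panel <- function(panel = c("pi_supply", "sources", "small_pools",
                                      "golgi_pi4p", "polarity", "sirna"),
                            model = load_network(), params = reference_params(),
                            dir = NULL) {
  panel <- match.arg(panel)
  basal <- find_steady_state(model, params)
  grab <- function(ex) cbind(experiment = ex$id, ex$readouts)
  out <- switch(panel,
    pi_supply = {
      drops <- do.call(rbind, lapply(
        c("gamma0_only", "plus_closed_transports", "full_50pct"),
        function(m) grab(run_pi_drop(model, params, m))))
      halves <- do.call(rbind, lapply(c("pip5ki_half", "pi4k_half"), function(nm) {
        spec <- knockout_preset(nm)
        ss <- perturbed_ss(model, params, spec, basal)
        cbind(experiment = nm, readout_rows(spec$label, ss, basal, c("4", "45")))
      }))
      merge_rows(drops, halves)
    },
    sources = grab(run_source_decomposition(model, params)),
    small_pools = do.call(rbind, lapply(
      c("mtmr_65", "synj_tmem55_up", "pikfyve_ko"), function(nm) {
        spec <- knockout_preset(nm)
        ss <- perturbed_ss(model, params, spec, basal)
        cbind(experiment = nm,
              readout_rows(spec$label, ss, basal, c("3", "5", "35")))
      })),
    golgi_pi4p = do.call(rbind, lapply(c(0, 0.5, 1, 2, 5), function(s) {
      spec <- perturbation(influx_scales = c(`v->4` = s),
                           label = sprintf("v->4 x%g", s))
      ss <- perturbed_ss(model, params, spec, basal)
      cbind(experiment = "golgi_pi4p",
            readout_rows(spec$label, ss, basal, c("4", "45")))
    })),
    polarity = do.call(rbind, lapply(c("apical", "basolateral"), function(cfg) {
      do.call(rbind, lapply(c("slow", "fast"), function(md) {
        grab(run_membrane_polarity(model, params, cfg, md))
      }))
    })),
    sirna = grab(run_sirna_panel(model, params))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(out, file.path(dir, paste0("reproduce_", panel, ".csv")),
                     row.names = FALSE)
    return(invisible(out))
  }
  out
}

merge_rows <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cl in setdiff(cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(cols, names(b))) b[[cl]] <- NA
  rbind(a[cols], b[cols])
}

#' Bar chart of an experiment result
#'
#' Simple ggplot2 rendering of the %-of-basal readouts; requires ggplot2.
#'
#' @param ex A `pip_experiment`.
#' @return A ggplot object.
#' @export
plot_experiment <- function(ex) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- ex$readouts
  ggplot2::ggplot(df, ggplot2::aes(x = perturbation, y = pct_of_basal,
                                   fill = species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::labs(x = NULL, y = "% of basal steady state", title = ex$id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
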