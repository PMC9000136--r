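# File round-tripping: trace tables, adjacency lists, run configurations.

#' Write / read a delimited trace table
#'
#' Tab-separated text with a header row; cell ids are 0-based and times are
#' in minutes.
#'
#' @param table a data.frame trace table.
#' @param path file path.
#' @return `read_trace_table` returns the data.frame.
#' @export
write_trace_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read an adjacency edge list
#'
#' One `i j` pair per line (whitespace separated, 0-based cell ids).
#'
#' @param graph a `monolayer_graph` (for writing).
#' @param path file path.
#' @return `read_edge_list` returns a two-column 1-based integer matrix.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges - 1L, path, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  e <- as.matrix(utils::read.table(path, header = FALSE,
                                   col.names = c("i", "j")))
  storage.mode(e) <- "integer"
  unname(e) + 1L
}

#' Build a monolayer from an explicit edge list
#'
#' Accepts an externally specified adjacency (e.g. a digitised experimental
#' layout) in place of the lattice construction.
#'
#' @param edges two-column matrix of 1-based cell indices (use
#'   [read_edge_list()] for 0-based files).
#' @param roles character vector, `"emitter"` / `"receiver"` per cell.
#' @param bpac expression per cell (default 1 for emitters, 0 otherwise).
#' @param scenario label stored with the graph.
#' @return a `monolayer_graph`.
#' @export
graph_from_edges <- function(edges, roles, bpac = NULL,
                             scenario = "custom") {
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  n <- length(roles)
  stopifnot(all(edges >= 1), all(edges <= n),
            all(roles %in% c("emitter", "receiver")))
  if (is.null(bpac)) bpac <- as.numeric(roles == "emitter")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n || !igraph::is_connected(g))
    stop("scenario graph is disconnected")
  structure(list(
    cells = data.frame(id = seq_len(n) - 1L, role = roles, bpac = bpac,
                       q = NA_real_, r = NA_real_),
    edges = edges,
    degree = tabulate(c(edges[, 1], edges[, 2]), nbins = n),
    scenario = scenario, seed = NA_integer_
  ), class = "monolayer_graph")
}

#' Run configuration: build, validate, round-trip
#'
#' A serialisable description of one simulation run: scenario, variant,
#' protocol, pharmacology, heterogeneity/noise settings and seed. Written
#' and read as YAML; round-trips losslessly. Unknown keys raise a schema
#' error naming the offending key.
#'
#' @param scenario scenario name for [build_scenario()].
#' @param variant model variant for [run_model_variant()].
#' @param n_cells,n_receivers,n_emitters scenario sizes.
#' @param kappa_erk,kappa_gj,far_frac variant knobs.
#' @param drug pharmacology drug name (`"none"` for wild type).
#' @param onset_time drug onset (min).
#' @param amplitudes pulse amplitudes of the two-pulse protocol.
#' @param bpac_cv expression heterogeneity.
#' @param seed integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(scenario = "single_emitter_cluster",
                       variant = "delayed_regulation",
                       n_cells = 46, n_receivers = 45, n_emitters = 5,
                       kappa_erk = 1, kappa_gj = 1, far_frac = 1,
                       drug = "none", onset_time = 0,
                       amplitudes = c(1, 1), bpac_cv = 0, seed = 1) {
  cfg <- list(scenario = scenario, variant = variant, n_cells = n_cells,
              n_receivers = n_receivers, n_emitters = n_emitters,
              kappa_erk = kappa_erk, kappa_gj = kappa_gj,
              far_frac = far_frac, drug = drug, onset_time = onset_time,
              amplitudes = amplitudes, bpac_cv = bpac_cv, seed = seed)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed <- c("scenario", "variant", "n_cells", "n_receivers", "n_emitters",
               "kappa_erk", "kappa_gj", "far_frac", "drug", "onset_time",
               "amplitudes", "bpac_cv", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(allowed, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  structure(cfg[allowed], class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Execute a run configuration
#'
#' Builds the scenario, runs the configured model variant, and (optionally)
#' writes the cell-level trace table, the interface table and a JSON
#' manifest recording the seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return the `trace_set`, invisibly when writing.
#' @export
run_from_config <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  graph <- build_scenario(cfg$scenario, n_cells = cfg$n_cells,
                          n_receivers = cfg$n_receivers,
                          n_emitters = cfg$n_emitters,
                          expression_cv = cfg$bpac_cv, seed = cfg$seed)
  protocol <- two_pulse_protocol(amplitudes = cfg$amplitudes)
  pharm <- pharmacology(drug = cfg$drug, onset_time = cfg$onset_time)
  ts <- run_model_variant(cfg$variant, graph, protocol,
                          kappa_erk = cfg$kappa_erk,
                          kappa_gj = cfg$kappa_gj,
                          far_frac = cfg$far_frac, pharm = pharm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trace_table(as.data.frame(ts), file.path(out_dir, "cells.tsv"))
    if (!is.null(ts$rho)) {
      iface <- data.frame(
        i = rep(graph$edges[, 1] - 1L, each = length(ts$time)),
        j = rep(graph$edges[, 2] - 1L, each = length(ts$time)),
        time_min = rep(ts$time, nrow(graph$edges)),
        rho = as.vector(ts$rho), flux = as.vector(ts$flux))
      write_trace_table(iface, file.path(out_dir, "interfaces.tsv"))
    }
    jsonlite::write_json(c(unclass(cfg), list(n_time = length(ts$time))),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(ts))
  }
  ts
}
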