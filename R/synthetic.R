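#' Sample per-cell bPAC expression levels
#'
#' Log-normal draws with mean `bpac_ref` and coefficient of variation `cv`
#' (so `sdlog^2 = log(1 + cv^2)` and `meanlog = log(bpac_ref) - sdlog^2/2`).
#' `cv = 0` returns `bpac_ref` exactly for every cell.
#'
#' @param n number of cells.
#' @param cv coefficient of variation, >= 0.
#' @param seed integer seed (reproducible draws).
#' @param bpac_ref reference expression level.
#' @return numeric vector of length `n`.
#' @export
sample_expression_levels <- function(n, cv = 0.3, seed = 1, bpac_ref = 1) {
  stopifnot(n >= 1)
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep(bpac_ref, n))
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(seed)
  stats::rlnorm(n, meanlog = log(bpac_ref) - sdlog^2 / 2, sdlog = sdlog)
}

#' Measurement noise model for synthetic traces
#'
#' Defaults emulate microscopy-extracted ERK-KTR N/C series: 3-minute
#' sampling, additive white measurement noise of 2% of the cohort's dynamic
#' range, static per-cell baseline offsets of 5% of the range, and no
#' non-responders. The fractional sds are resolved against the ground-truth
#' dynamic range at generation time unless absolute sds are given.
#'
#' @param meas_sd absolute additive Gaussian sd on `ktr_nc`, or `NULL` to
#'   use `meas_frac`.
#' @param baseline_sd absolute per-cell constant offset sd, or `NULL` to use
#'   `baseline_frac`.
#' @param meas_frac,baseline_frac fractional sds relative to the cohort
#'   dynamic range.
#' @param sampling_period observation cadence in minutes.
#' @param nonresponder_fraction probability that a cell is flat at baseline.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(meas_sd = NULL, baseline_sd = NULL,
                        meas_frac = 0.02, baseline_frac = 0.05,
                        sampling_period = 3, nonresponder_fraction = 0) {
  stopifnot(sampling_period > 0,
            nonresponder_fraction >= 0, nonresponder_fraction <= 1,
            is.null(meas_sd) || meas_sd >= 0,
            is.null(baseline_sd) || baseline_sd >= 0,
            meas_frac >= 0, baseline_frac >= 0)
  structure(list(meas_sd = meas_sd, baseline_sd = baseline_sd,
                 meas_frac = meas_frac, baseline_frac = baseline_frac,
                 sampling_period = sampling_period,
                 nonresponder_fraction = nonresponder_fraction),
            class = "noise_model")
}

#' Cell-to-cell heterogeneity specification
#'
#' @param bpac_cv coefficient of variation of log-normal bPAC expression.
#' @param pool_splits optional per-pulse near/far pool splits: a matrix with
#'   one row per pulse and columns `near`, `far` (rows must sum to 1), or
#'   `NULL` for no per-pulse resetting.
#' @param seed integer seed.
#' @return an object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(bpac_cv = 0.3, pool_splits = NULL, seed = 1) {
  stopifnot(bpac_cv >= 0)
  if (!is.null(pool_splits)) {
    pool_splits <- as.matrix(pool_splits)
    if (any(abs(rowSums(pool_splits) - 1) > 1e-9))
      stop("pool split fractions must sum to 1 per pulse")
  }
  structure(list(bpac_cv = bpac_cv, pool_splits = pool_splits, seed = seed),
            class = "heterogeneity_spec")
}

#' Generate a synthetic single-cell trace table
#'
#' Runs the multicellular model on a scenario with sampled bPAC expression,
#' resamples the ERK-KTR N/C signal to the observation cadence, and applies
#' the measurement model: static per-cell baseline offsets, i.i.d. Gaussian
#' measurement noise, and optional flat non-responders. The noiseless
#' ground-truth signal is retained alongside the observed one.
#'
#' @param graph a [build_scenario()] monolayer (its emitter expression is
#'   resampled using `het`).
#' @param params an [intracellular_params()] set.
#' @param protocol a [light_protocol()].
#' @param noise a [noise_model()].
#' @param het a [heterogeneity_spec()].
#' @param seed integer seed for the noise draws (expression uses
#'   `het$seed`).
#' @param chains,coupling,pharm,... passed to [simulate_tissue()].
#' @return list with `table` (data.frame: `cell_id`, `role`, `time_min`,
#'   `ktr_nc`, `ktr_nc_true`, `camp_true`, `responder`), `trace_set` (the
#'   underlying simulation), and `manifest` (seeds, scenario, noise
#'   resolution).
#' @export
generate_trace_table <- function(graph, params, protocol,
                                 noise = noise_model(),
                                 het = heterogeneity_spec(),
                                 seed = 1,
                                 chains = list(delay_chain_params()),
                                 coupling = coupling_params(),
                                 pharm = pharmacology(), ...) {
  stopifnot(inherits(noise, "noise_model"),
            inherits(het, "heterogeneity_spec"))
  em <- graph$cells$role == "emitter"
  graph$cells$bpac[em] <- sample_expression_levels(sum(em), het$bpac_cv,
                                                   seed = het$seed)
  reset <- if (!is.null(het$pool_splits)) {
    stopifnot(nrow(het$pool_splits) == nrow(protocol$pulses))
    het$pool_splits[, c("near", "far")[seq_along(chains)], drop = FALSE]
  } else FALSE
  sim <- simulate_tissue(graph, params, protocol, pharm, chains = chains,
                         coupling = coupling, dt = 1,
                         reset_pools_each_pulse = reset, ...)

  t_obs <- seq(0, protocol$t_end, by = noise$sampling_period)
  idx <- match(t_obs, sim$time)
  stopifnot(!anyNA(idx))
  truth_nc <- sim$ktr_nc[idx, , drop = FALSE]
  truth_camp <- sim$camp[idx, , drop = FALSE]
  n <- ncol(truth_nc)

  rng <- diff(range(truth_nc))
  meas_sd <- noise$meas_sd %||% (noise$meas_frac * rng)
  baseline_sd <- noise$baseline_sd %||% (noise$baseline_frac * rng)

  set.seed(seed)
  offsets <- stats::rnorm(n, 0, baseline_sd)
  nonresp <- stats::runif(n) < noise$nonresponder_fraction
  obs <- truth_nc
  obs[, nonresp] <- matrix(truth_nc[1, nonresp], nrow = length(t_obs),
                           ncol = sum(nonresp), byrow = TRUE)
  obs <- sweep(obs, 2, offsets, "+") +
    matrix(stats::rnorm(length(obs), 0, meas_sd), nrow = nrow(obs))
  if (any(obs <= 0)) {
    warning(sum(obs <= 0), " non-positive observed N/C value(s) clipped")
    obs[obs <= 0] <- 1e-6
  }

  table <- data.frame(
    cell_id = rep(graph$cells$id, each = length(t_obs)),
    role = rep(graph$cells$role, each = length(t_obs)),
    time_min = rep(t_obs, n),
    ktr_nc = as.vector(obs),
    ktr_nc_true = as.vector(truth_nc),
    camp_true = as.vector(truth_camp),
    responder = rep(!nonresp, each = length(t_obs))
  )
  list(table = table, trace_set = sim,
       manifest = list(scenario = graph$scenario, n_cells = n,
                       seed = seed, expression_seed = het$seed,
                       bpac_cv = het$bpac_cv,
                       meas_sd = meas_sd, baseline_sd = baseline_sd,
                       sampling_period = noise$sampling_period,
                       nonresponder_fraction = noise$nonresponder_fraction))
}

#' Write the canonical synthetic fixture suite
#'
#' Generates the named fixture set used throughout the analyses — all-emitter
#' two-pulse cohorts (equal and increasing amplitudes), the
#' single-emitter-cluster model variants (constant permeability, PKA-PDE
#' feedback, delayed regulation at both `kappa_erk` presets), the near/far
#' heterogeneity cases, the undershoot factorial corners, the pharmacology
#' variants, and the reduced-receiver layout — each as a delimited trace
#' table with a JSON manifest sidecar.
#'
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @param cohort_receivers receiver count of the cluster scenarios.
#' @return invisibly, a data.frame manifest (`name`, `file`, `n_cells`,
#'   `checksum`).
#' @export
make_fixture_suite <- function(seed = 1, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proto <- two_pulse_protocol()
  cluster <- build_scenario("single_emitter_cluster", seed = seed)
  small <- build_scenario("single_emitter_cluster", n_receivers = 10,
                          seed = seed)
  allem <- build_scenario("all_emitter", n_cells = 46, seed = seed)
  noise <- noise_model()
  runs <- list(
    fig2E_equal_amplitude = function()
      generate_trace_table(allem, intracellular_params(), proto,
                           noise, heterogeneity_spec(bpac_cv = 0.3,
                                                     seed = seed),
                           seed = seed),
    fig2F_increasing_amplitude = function()
      generate_trace_table(allem, intracellular_params(),
                           two_pulse_protocol(amplitudes = c(0.5, 1)),
                           noise, heterogeneity_spec(bpac_cv = 0.3,
                                                     seed = seed),
                           seed = seed)
  )
  variant_runs <- list(
    fig5G_constant_perm = function()
      run_model_variant("constant_permeability", cluster, proto),
    fig5H_pka_pde_feedback = function()
      run_model_variant("pka_pde_feedback", cluster, proto),
    fig5I_delayed = function()
      run_model_variant("delayed_regulation", cluster, proto),
    fig5I_delayed_slow_erk = function()
      run_model_variant("delayed_regulation", cluster, proto,
                        kappa_erk = 0.5),
    fig6C_case1_far = function()
      run_model_variant("near_far", cluster, proto, far_frac = 1),
    fig6C_case2_nearfar = function()
      run_model_variant("near_far", cluster, proto, far_frac = 0.8),
    fig6C_case3_near = function()
      run_model_variant("near_far", cluster, proto, far_frac = 0),
    fig6D_undershoot_gj = function()
      run_model_variant("undershoot", cluster, one_pulse_protocol(lead = 90)),
    fig6D_undershoot_gj_ac = function()
      run_model_variant("undershoot", cluster, one_pulse_protocol(lead = 90),
                        ac_feedback = TRUE),
    s8_ibmx = function()
      run_model_variant("delayed_regulation", cluster, proto,
                        pharm = pharmacology("IBMX")),
    s8_cx43_ngfp = function()
      run_model_variant("delayed_regulation", cluster, proto,
                        pharm = pharmacology("CX43-NGFP")),
    s8_brefeldin = function()
      run_model_variant("delayed_regulation", cluster, proto,
                        pharm = pharmacology("Brefeldin-A")),
    s7C_receivers10 = function()
      run_model_variant("delayed_regulation", small, proto)
  )
  manifest <- list()
  emit <- function(name, table, meta) {
    file <- file.path(dir, paste0(name, ".tsv"))
    write_trace_table(table, file)
    meta$name <- name
    meta$seed <- seed
    jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
    manifest[[length(manifest) + 1]] <<- data.frame(
      name = name, file = basename(file),
      n_cells = length(unique(table$cell_id)),
      checksum = sum(round(table$ktr_nc, 9)))
  }
  for (name in names(runs)) {
    g <- runs[[name]]()
    emit(name, g$table, g$manifest)
  }
  for (name in names(variant_runs)) {
    ts <- variant_runs[[name]]()
    emit(name, as.data.frame(ts),
         list(scenario = ts$meta$scenario, variant = name))
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
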