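# Monolayer scenarios and the coupled multicellular integrator.

# Axial hex-lattice spiral: centre cell then concentric rings. Gives a
# compact planar monolayer with interior degree 6 and boundary degree 3-5
# (mean near 5 for the sizes used), and well-defined distance shells.
hex_spiral <- function(n) {
  dirs <- rbind(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))
  coords <- matrix(0, nrow = 1, ncol = 2)
  ring <- 1
  while (nrow(coords) < n) {
    cur <- ring * dirs[5, ]
    for (i in 1:6) {
      for (s in seq_len(ring)) {
        coords <- rbind(coords, cur)
        cur <- cur + dirs[i, ]
      }
    }
    ring <- ring + 1
  }
  coords[seq_len(n), , drop = FALSE]
}

hex_edges <- function(coords) {
  dirs <- rbind(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))
  key <- paste(coords[, 1], coords[, 2])
  idx <- seq_len(nrow(coords))
  names(idx) <- key
  out <- NULL
  for (d in 1:6) {
    nb <- cbind(coords[, 1] + dirs[d, 1], coords[, 2] + dirs[d, 2])
    j <- idx[paste(nb[, 1], nb[, 2])]
    keep <- !is.na(j) & idx < j
    if (any(keep)) out <- rbind(out, cbind(idx[keep], j[keep]))
  }
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Build a monolayer scenario
#'
#' Constructs the cell graph of one of the three experimental layouts on a
#' hexagonal-disc lattice: `all_emitter` (every cell produces cAMP — the
#' spatially uniform perturbation), `single_emitter_cluster` (one central
#' emitter surrounded by receivers; 45 receivers by default, 10 for the
#' reduced variant), and `small_emitter_cluster` (a concentrated cluster of
#' `<= 15` emitters surrounded by receivers). Emitter bPAC expression levels
#' are log-normal with mean `bpac_ref = 1` and coefficient of variation
#' `expression_cv`; receivers have none. The lattice itself is deterministic;
#' the seed only affects expression sampling.
#'
#' @param name scenario name.
#' @param n_cells total cell count for `all_emitter` (default 46).
#' @param n_receivers receiver count for the cluster scenarios (default 45).
#' @param n_emitters emitter count for `small_emitter_cluster` (a cluster of
#'   more than 15 emitters no longer qualifies as "small" and warns).
#' @param expression_cv coefficient of variation of emitter bPAC levels.
#' @param seed integer seed for expression sampling.
#' @return an object of class `monolayer_graph` with fields `cells`
#'   (data.frame: `id`, `role`, `bpac`, axial coords `q`, `r`), `edges`
#'   (two-column matrix of 1-based cell indices), `degree`, `scenario`,
#'   `seed`.
#' @export
build_scenario <- function(name = c("all_emitter", "single_emitter_cluster",
                                    "small_emitter_cluster"),
                           n_cells = 46, n_receivers = 45, n_emitters = 5,
                           expression_cv = 0, seed = 1) {
  name <- match.arg(name)
  n_em <- switch(name,
    all_emitter = n_cells,
    single_emitter_cluster = 1,
    small_emitter_cluster = n_emitters
  )
  n <- switch(name,
    all_emitter = n_cells,
    single_emitter_cluster = 1 + n_receivers,
    small_emitter_cluster = n_emitters + n_receivers
  )
  if (name == "small_emitter_cluster" && n_emitters > 15)
    warning("a small emitter cluster is defined as <= 15 emitters; got ",
            n_emitters)
  stopifnot(n >= 1, n_em >= 1, n_em <= n)
  coords <- hex_spiral(n)
  edges <- if (n > 1) hex_edges(coords) else
    matrix(integer(0), ncol = 2)
  role <- rep("receiver", n)
  role[seq_len(n_em)] <- "emitter"  # spiral order: emitters form the core
  bpac <- numeric(n)
  bpac[role == "emitter"] <-
    sample_expression_levels(n_em, cv = expression_cv, seed = seed)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (n > 1 && (igraph::vcount(g) < n || !igraph::is_connected(g)))
    stop("scenario graph is disconnected")
  structure(list(
    cells = data.frame(id = seq_len(n) - 1L, role = role, bpac = bpac,
                       q = coords[, 1], r = coords[, 2]),
    edges = edges, degree = deg, scenario = name, seed = seed
  ), class = "monolayer_graph")
}

#' Graph distance from the nearest emitter
#'
#' @param graph a [build_scenario()] monolayer.
#' @return integer vector of shortest-path distances (0 for emitters).
#' @export
emitter_distance <- function(graph) {
  stopifnot(inherits(graph, "monolayer_graph"))
  n <- nrow(graph$cells)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  em <- which(graph$cells$role == "emitter")
  d <- igraph::distances(g, v = em)
  as.integer(apply(d, 2, min))
}

#' @export
print.monolayer_graph <- function(x, ...) {
  cat("<monolayer_graph> ", x$scenario, ": ", nrow(x$cells), " cells (",
      sum(x$cells$role == "emitter"), " emitters), ", nrow(x$edges),
      " interfaces, mean degree ", round(mean(x$degree), 2), "\n", sep = "")
  invisible(x)
}

# ---- state layout -------------------------------------------------------

# Per-cell state: camp, pka, erk, ktr_nuc, ktr_cyt, then for each chain
# population gj_na, gj_d1..gj_dN, gj_ca. Flattened column-major over cells.
state_layout <- function(chains) {
  blocks <- c("camp", "pka", "erk", "ktr_nuc", "ktr_cyt", "pde_act")
  chain_cols <- list()
  off <- length(blocks)
  for (c_i in seq_along(chains)) {
    N <- chains[[c_i]]$n_steps
    chain_cols[[c_i]] <- list(na = off + 1L,
                              d = off + 1L + seq_len(N),
                              ca = off + N + 2L)
    off <- off + N + 2L
  }
  list(n_base = 6L, n_vars = off, chain_cols = chain_cols)
}

# Vectorised RHS over all cells for one constant-light segment.
tissue_rhs <- function(t, y, env) {
  if (any(!is.finite(y))) {
    worst <- which(!is.finite(y))[1]
    stop("non-finite state at t = ", signif(t, 6),
         " (cell ", ((worst - 1L) %% env$n) + 1L, ")")
  }
  n <- env$n
  Y <- matrix(y, nrow = n)
  p <- env$p
  camp <- pmax(Y[, 1], 0)
  pka <- Y[, 2]; erk <- Y[, 3]; nuc <- Y[, 4]; cyt <- Y[, 5]
  pde_act <- Y[, 6]
  hill <- camp^p$n_pka / (p$k_pka^p$n_pka + camp^p$n_pka)

  gj_ca_tot <- numeric(n)
  for (cc in env$layout$chain_cols) gj_ca_tot <- gj_ca_tot + Y[, cc$ca]

  flux <- numeric(n)
  if (env$n_edges > 0 && env$coupling_scale > 0) {
    cp <- env$coupling
    reg <- cp$k_gj_gjf / (cp$p_bar * cp$x_f^3) *
      (gj_ca_tot[env$ei] / env$P[env$ei] + gj_ca_tot[env$ej] / env$P[env$ej])
    rho <- env$coupling_scale * cp$kappa_gj * (cp$k_gj + reg)
    flux <- as.vector(env$inc %*% (rho * (Y[env$ej, 1] - Y[env$ei, 1])))
  }

  dY <- matrix(0, nrow = n, ncol = env$layout$n_vars)
  dY[, 1] <- p$beta_b * (env$b / p$bpac_ref) * env$u +
    env$beta_0 * (1 - p$ac_pka_inhibition_gain * pka) -
    p$gamma_pde * (1 + p$pde_pka_feedback_gain * pde_act) * camp + flux
  dY[, 2] <- (hill - pka) / p$tau_pka
  psi <- pka + env$epac_enabled * p$epac_gain * hill
  dY[, 3] <- -p$kappa_erk * p$gamma_erk * psi * erk +
    p$k_erk_react * (p$erk_tot - erk)
  dY[, 4] <- p$k_ktr_in * cyt - p$k_ktr_out * erk * nuc
  dY[, 5] <- -dY[, 4]
  dY[, 6] <- (pka - pde_act) / p$tau_pde_fb

  for (c_i in seq_along(env$chains)) {
    ch <- env$chains[[c_i]]
    cc <- env$layout$chain_cols[[c_i]]
    r <- ch$n_steps / ch$tau_gj
    entry <- ch$k_act * pka * Y[, cc$na]
    D <- Y[, cc$d, drop = FALSE]
    ca <- Y[, cc$ca]
    dY[, cc$na] <- ch$gamma_gj * ca - entry
    dD <- r * cbind(0, D[, -ch$n_steps, drop = FALSE]) - r * D
    dD[, 1] <- dD[, 1] + entry
    dY[, cc$d] <- dD
    dY[, cc$ca] <- r * D[, ch$n_steps] - ch$gamma_gj * ca
  }
  list(as.vector(dY))
}

chain_reset_state <- function(Y, layout, chains, pool_total, fracs = NULL) {
  for (c_i in seq_along(chains)) {
    cc <- layout$chain_cols[[c_i]]
    f <- if (is.null(fracs)) chains[[c_i]]$pool_frac else fracs[c_i]
    Y[, cc$na] <- pool_total * f
    Y[, cc$d] <- 0
    Y[, cc$ca] <- 0
  }
  Y
}

make_rhs_env <- function(graph, eff, layout, u) {
  n <- nrow(graph$cells)
  edges <- graph$edges
  n_edges <- nrow(edges)
  inc <- if (n_edges > 0)
    Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                         j = c(seq_len(n_edges), seq_len(n_edges)),
                         x = c(rep(1, n_edges), rep(-1, n_edges)),
                         dims = c(n, n_edges))
  else NULL
  list2env(list(
    n = n, p = eff$params, b = graph$cells$bpac,
    beta_0 = eff$beta_0_vec,
    chains = eff$chains, coupling = eff$coupling,
    coupling_scale = eff$coupling_scale,
    epac_enabled = as.numeric(eff$epac_enabled),
    layout = layout, ei = edges[, 1], ej = edges[, 2],
    n_edges = n_edges, inc = inc, P = graph$degree, u = u
  ), parent = emptyenv())
}

# ---- main integrator ----------------------------------------------------

#' Simulate a coupled monolayer
#'
#' Integrates the full multicellular system: every cell's intracellular
#' circuit plus its gap-junction delay chains, coupled through the regulated
#' permeability flux at every interface. The system is first relaxed to its
#' dark steady state (drug-free) for `equilibrate` minutes, then driven by
#' the light protocol; integration restarts at every pulse edge and at the
#' pharmacology onset, so the piecewise-constant input is handled exactly.
#'
#' @param graph a [build_scenario()] monolayer.
#' @param params an [intracellular_params()] set (shared by all cells except
#'   where `per_cell` overrides apply).
#' @param protocol a [light_protocol()].
#' @param pharm a [pharmacology()] spec; acts from its `onset_time`.
#' @param chains list of [delay_chain_params()] (may be empty for a model
#'   without regulated permeability pools).
#' @param coupling a [coupling_params()] set.
#' @param dt output cadence in minutes (1 for model studies, 3 when
#'   emulating microscopy).
#' @param per_cell optional named list of per-cell parameter overrides;
#'   supported: `beta_0` (numeric vector, one per cell), `pool_total`
#'   (total inactive gap-junction pool per cell, default 1), and `camp0`
#'   (initial cAMP imposed after dark equilibration — used for closed-system
#'   studies of the coupling terms alone).
#' @param reset_pools_each_pulse if `TRUE`, chain pools are reset to their
#'   initial near/far split at every pulse onset (the per-pulse trafficking
#'   heterogeneity mechanism); alternatively a numeric matrix with one row
#'   per pulse and one column per chain giving the pool fractions to apply
#'   at each pulse onset.
#' @param equilibrate dark pre-equilibration time in minutes.
#' @param rtol,atol solver tolerances (stiff-capable `lsoda`).
#' @return an object of class `trace_set`: `time`, per-cell signal matrices
#'   (`camp`, `pka_on`, `erk_active`, `ktr_nc`, `ktr_nuc`, `ktr_cyt`,
#'   `gj_ca`), per-interface matrices (`rho`, `flux` — flux into the first
#'   endpoint), the `graph`, and `meta`.
#' @export
simulate_tissue <- function(graph, params, protocol,
                            pharm = pharmacology(),
                            chains = list(delay_chain_params()),
                            coupling = coupling_params(),
                            dt = 1, per_cell = list(),
                            reset_pools_each_pulse = FALSE,
                            equilibrate = 500,
                            rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(graph, "monolayer_graph"),
            inherits(params, "intracellular_params"),
            inherits(protocol, "light_protocol"),
            inherits(pharm, "pharmacology"))
  n <- nrow(graph$cells)
  layout <- state_layout(chains)
  pool_total <- per_cell$pool_total %||% rep(1, n)
  if (length(pool_total) == 1) pool_total <- rep(pool_total, n)
  beta_0_vec <- per_cell$beta_0 %||% rep(params$beta_0, n)
  if (length(beta_0_vec) == 1) beta_0_vec <- rep(beta_0_vec, n)
  stopifnot(length(beta_0_vec) == n, length(pool_total) == n)

  base_eff <- list(params = params, chains = chains, coupling = coupling,
                   coupling_scale = 1, epac_enabled = TRUE,
                   beta_0_vec = beta_0_vec)
  drug <- apply_pharmacology(params, chains, coupling, pharm)
  drug$beta_0_vec <- beta_0_vec
  eff_at <- function(t) if (t >= pharm$onset_time) drug else base_eff

  # dark steady state, drug-free
  Y0 <- matrix(0, nrow = n, ncol = layout$n_vars)
  Y0[, 3] <- params$erk_tot
  Y0[, 4] <- params$ktr_tot / 2
  Y0[, 5] <- params$ktr_tot / 2
  Y0 <- chain_reset_state(Y0, layout, chains, pool_total)
  if (equilibrate > 0) {
    env <- make_rhs_env(graph, base_eff, layout, u = 0)
    eq <- deSolve::lsoda(as.vector(Y0), c(0, equilibrate), tissue_rhs,
                         parms = env, rtol = rtol, atol = atol)
    Y0 <- matrix(eq[nrow(eq), -1], nrow = n)
  }

  if (!is.null(per_cell$camp0)) Y0[, 1] <- per_cell$camp0

  breaks <- protocol_breaks(protocol, extra = pharm$onset_time)
  grid <- sort(unique(c(seq(0, protocol$t_end, by = dt), breaks)))
  onsets <- protocol$pulses$t_on

  times_out <- numeric(0)
  states_out <- NULL
  y <- as.vector(Y0)
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    k_pulse <- which(abs(onsets - t0) < 1e-9)
    if (!isFALSE(reset_pools_each_pulse) && length(k_pulse) == 1) {
      fr <- if (is.matrix(reset_pools_each_pulse))
        reset_pools_each_pulse[k_pulse, ] else NULL
      Ys <- matrix(y, nrow = n)
      Ys <- chain_reset_state(Ys, layout, chains, pool_total, fracs = fr)
      y <- as.vector(Ys)
    }
    eff <- eff_at(t0)
    u <- light_input(protocol, t0)
    env <- make_rhs_env(graph, eff, layout, u = u)
    seg_t <- sort(unique(c(t0, grid[grid > t0 & grid <= t1])))
    sol <- deSolve::lsoda(y, seg_t, tissue_rhs, parms = env,
                          rtol = rtol, atol = atol)
    if (nrow(sol) < length(seg_t))
      stop("solver failed at t = ", signif(sol[nrow(sol), 1], 6), " min")
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- if (s == 1) seq_len(nrow(sol)) else seq_len(nrow(sol))[-1]
    times_out <- c(times_out, sol[keep, 1])
    states_out <- rbind(states_out, sol[keep, -1, drop = FALSE])
  }

  signal <- function(col) states_out[, (col - 1) * n + seq_len(n),
                                     drop = FALSE]
  camp <- signal(1); pka <- signal(2); erk <- signal(3)
  nuc <- signal(4); cyt <- signal(5)
  gj_ca <- matrix(0, nrow = nrow(states_out), ncol = n)
  gj_ca_pop <- list()
  for (c_i in seq_along(chains)) {
    pop <- signal(layout$chain_cols[[c_i]]$ca)
    gj_ca <- gj_ca + pop
    gj_ca_pop[[chains[[c_i]]$label]] <- pop
  }

  edges <- graph$edges
  rho <- flux <- NULL
  if (nrow(edges) > 0) {
    ei <- edges[, 1]; ej <- edges[, 2]
    cs <- ifelse(times_out >= pharm$onset_time, pharm$coupling_scale, 1)
    base <- coupling$k_gj_gjf / (coupling$p_bar * coupling$x_f^3)
    rho <- cs * coupling$kappa_gj *
      (coupling$k_gj + base * (sweep(gj_ca[, ei, drop = FALSE], 2,
                                     graph$degree[ei], "/") +
                               sweep(gj_ca[, ej, drop = FALSE], 2,
                                     graph$degree[ej], "/")))
    flux <- rho * (camp[, ej, drop = FALSE] - camp[, ei, drop = FALSE])
  }

  structure(list(
    time = times_out, graph = graph,
    camp = camp, pka_on = pka, erk_active = erk,
    ktr_nuc = nuc, ktr_cyt = cyt, ktr_nc = nuc / cyt,
    gj_ca = gj_ca, gj_ca_pop = gj_ca_pop,
    rho = rho, flux = flux,
    meta = list(scenario = graph$scenario, seed = graph$seed,
                params = params, chains = chains, coupling = coupling,
                pharm = pharm, protocol = protocol, dt = dt,
                reset_pools_each_pulse = reset_pools_each_pulse)
  ), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", ncol(x$camp), " cells x ", length(x$time),
      " time points (", min(x$time), "-", max(x$time), " min), scenario ",
      x$meta$scenario, "\n", sep = "")
  invisible(x)
}

#' Long-format trace table from a simulation
#'
#' @param x a `trace_set`.
#' @param ... unused.
#' @return data.frame with `cell_id` (0-based), `role`, `time_min`, `camp`,
#'   `pka_on`, `erk_active`, `ktr_nc`.
#' @export
as.data.frame.trace_set <- function(x, ...) {
  n <- ncol(x$camp); nt <- length(x$time)
  data.frame(
    cell_id = rep(x$graph$cells$id, each = nt),
    role = rep(x$graph$cells$role, each = nt),
    time_min = rep(x$time, n),
    camp = as.vector(x$camp),
    pka_on = as.vector(x$pka_on),
    erk_active = as.vector(x$erk_active),
    ktr_nc = as.vector(x$ktr_nc)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
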