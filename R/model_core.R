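#' PKA activity as a function of cAMP (Hill equilibrium)
#'
#' The fraction of PKA freed by cAMP binding, modelled as a Hill function
#' `camp^n / (K^n + camp^n)`. This is the equilibrium toward which the
#' dynamic PKA state relaxes (time constant `tau_pka`).
#'
#' @param camp cAMP concentration(s), >= 0 (a.u.). Vectorised.
#' @param params an [intracellular_params()] set.
#' @return PKA activity in \[0, 1\], monotone non-decreasing in `camp`.
#' @export
pka_activity <- function(camp, params) {
  stopifnot(inherits(params, "intracellular_params"))
  if (any(camp < 0)) stop("camp must be >= 0")
  camp^params$n_pka / (params$k_pka^params$n_pka + camp^params$n_pka)
}

#' Intracellular derivatives for one cell
#'
#' Right-hand side of the single-cell circuit at time `t`:
#' \itemize{
#'   \item cAMP: bPAC production `beta_b (b_i / bpac_ref) u(t)`, basal
#'     production `beta_0 (1 - g_ac pka)`, first-order PDE decay
#'     `gamma_pde * pde_scale * (1 + g_pde pka) * camp`, plus any
#'     gap-junction influx;
#'   \item PKA: relaxation to the Hill equilibrium;
#'   \item ERK: deactivated at rate `kappa_erk * gamma_erk * psi(camp)` with
#'     `psi = pka + epac_gain * hill(camp)` (Epac term removable), and
#'     reactivated at `k_erk_react * (erk_tot - erk)`;
#'   \item ERK-KTR: nuclear import `k_ktr_in * ktr_cyt` minus ERK-driven
#'     export `k_ktr_out * erk * ktr_nuc` (total pool conserved).
#' }
#'
#' @param state named list or vector with `camp`, `pka`, `erk`, `ktr_nuc`,
#'   `ktr_cyt`, `pde_act`, all non-negative.
#' @param t time in minutes.
#' @param params an [intracellular_params()] set.
#' @param protocol a [light_protocol()].
#' @param pharm a [pharmacology()] spec (its `pde_scale` / `epac_enabled`
#'   apply; onset handling is the caller's concern).
#' @param bpac_level the cell's bPAC expression `b_i`.
#' @param camp_influx net gap-junction cAMP influx (a.u./min).
#' @return named numeric vector of derivatives.
#' @export
intracellular_derivatives <- function(state, t, params, protocol,
                                      pharm = pharmacology(),
                                      bpac_level = 1, camp_influx = 0) {
  s <- as.list(state)
  if (any(unlist(s[c("camp", "erk", "ktr_nuc", "ktr_cyt")]) < 0) ||
      any(!is.finite(unlist(s))))
    stop("invalid state at t = ", t)
  p <- params
  u <- light_input(protocol, t)
  hill <- pka_activity(s$camp, p)
  d_camp <- p$beta_b * (bpac_level / p$bpac_ref) * u +
    p$beta_0 * (1 - p$ac_pka_inhibition_gain * s$pka) -
    p$gamma_pde * pharm$pde_scale *
      (1 + p$pde_pka_feedback_gain * s$pde_act) * s$camp +
    camp_influx
  d_pka <- (hill - s$pka) / p$tau_pka
  psi <- s$pka + as.numeric(pharm$epac_enabled) * p$epac_gain * hill
  d_erk <- -p$kappa_erk * p$gamma_erk * psi * s$erk +
    p$k_erk_react * (p$erk_tot - s$erk)
  d_nuc <- p$k_ktr_in * s$ktr_cyt - p$k_ktr_out * s$erk * s$ktr_nuc
  c(camp = d_camp, pka = d_pka, erk = d_erk,
    ktr_nuc = d_nuc, ktr_cyt = -d_nuc,
    pde_act = (s$pka - s$pde_act) / p$tau_pde_fb)
}

#' Simulate an isolated single cell
#'
#' Integrates the intracellular circuit of one uncoupled cell (no
#' gap-junction flux) under a light protocol, starting from its dark steady
#' state.
#'
#' @param params an [intracellular_params()] set.
#' @param protocol a [light_protocol()].
#' @param pharm a [pharmacology()] spec.
#' @param t_grid output times (min); default a 1-min grid over the protocol.
#' @param bpac_level bPAC expression of the cell.
#' @param ... further arguments to [simulate_tissue()] (e.g. tolerances).
#' @return a data.frame cell trace: `time`, `camp`, `pka_on`, `erk_active`,
#'   `ktr_nuc`, `ktr_cyt`, `ktr_nc`.
#' @export
simulate_single_cell <- function(params, protocol, pharm = pharmacology(),
                                 t_grid = NULL, bpac_level = 1, ...) {
  dt <- if (is.null(t_grid)) 1 else diff(t_grid)[1]
  g <- build_scenario("all_emitter", n_cells = 1, seed = 1)
  g$cells$bpac <- bpac_level
  ts <- simulate_tissue(g, params, protocol, pharm, chains = list(),
                        dt = dt, ...)
  tr <- data.frame(time = ts$time, camp = ts$camp[, 1],
                   pka_on = ts$pka_on[, 1], erk_active = ts$erk_active[, 1],
                   ktr_nuc = ts$ktr_nuc[, 1], ktr_cyt = ts$ktr_cyt[, 1],
                   ktr_nc = ts$ktr_nc[, 1])
  if (!is.null(t_grid)) tr <- tr[tr$time %in% t_grid, , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Fit intracellular rate constants to ERK-KTR traces
#'
#' Least-squares estimation of a subset of the intracellular parameters from
#' one or more observed `ktr_nc` time series sharing a protocol. Residuals
#' are computed on baseline-shifted signals (each trace minus its own
#' pre-stimulus mean), which cancels additive per-cell baseline offsets.
#' Optimisation is seeded multi-start Levenberg-Marquardt.
#'
#' @param traces a data.frame with columns `time` and `ktr_nc`, or a list of
#'   such data.frames on a common time grid.
#' @param protocol the [light_protocol()] that drove the traces.
#' @param free character vector of parameter names to estimate (subset of
#'   [intracellular_params()] fields).
#' @param params fixed parameter values (and starting point centre).
#' @param lower,upper named bounds for the free parameters (defaults:
#'   1e-3 and 10 on every rate).
#' @param n_starts number of random multi-start points (log-uniform within
#'   bounds).
#' @param seed integer seed for the starts.
#' @param pharm pharmacology under which the traces were recorded.
#' @return list with `estimates` (named vector), `ssr`, `converged`,
#'   `identifiable`, `n_traces`, and the `fit` object of the best start.
#' @export
fit_intracellular <- function(traces, protocol,
                              free = c("gamma_pde", "gamma_erk"),
                              params = intracellular_params(),
                              lower = NULL, upper = NULL,
                              n_starts = 4, seed = 1,
                              pharm = pharmacology()) {
  if (is.data.frame(traces)) traces <- list(traces)
  stopifnot(length(traces) >= 1,
            all(free %in% names(unclass(params))))
  tgrid <- traces[[1]]$time
  for (tr in traces)
    if (!isTRUE(all.equal(tr$time, tgrid)))
      stop("all traces must share one time grid")
  t_on1 <- if (nrow(protocol$pulses)) protocol$pulses$t_on[1] else Inf
  pre <- tgrid < t_on1
  if (!any(pre)) pre <- tgrid == tgrid[1]
  obs <- vapply(traces, function(tr) tr$ktr_nc - mean(tr$ktr_nc[pre]),
                numeric(length(tgrid)))

  rng <- max(apply(obs, 2, function(x) diff(range(x))))
  if (!is.finite(rng) || rng < 1e-8) {
    return(list(estimates = setNames(rep(NA_real_, length(free)), free),
                ssr = NA_real_, converged = FALSE, identifiable = FALSE,
                n_traces = length(traces), fit = NULL))
  }

  lo <- setNames(rep(1e-3, length(free)), free)
  hi <- setNames(rep(10, length(free)), free)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  predict_shifted <- function(theta) {
    p <- unclass(params)
    p[free] <- as.list(pmin(pmax(theta, lo), hi))
    p <- do.call(intracellular_params, p)
    tr <- simulate_single_cell(p, protocol, pharm, t_grid = tgrid)
    tr$ktr_nc - mean(tr$ktr_nc[pre])
  }
  resid_fn <- function(theta) {
    pred <- predict_shifted(theta)
    as.vector(obs - pred)
  }

  set.seed(seed)
  centre <- pmin(pmax(unlist(unclass(params)[free]), lo * 1.0001),
                 hi * 0.9999)
  starts <- rbind(centre,
                  matrix(exp(stats::runif((n_starts - 1) * length(free),
                                          log(lo), log(hi))),
                         ncol = length(free), byrow = TRUE))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[k, ], lower = lo, upper = hi, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimisation starts failed")
  list(estimates = setNames(coef(best)[free], free),
       ssr = best$deviance,
       converged = best$info %in% 1:4,
       identifiable = TRUE,
       n_traces = length(traces),
       fit = best)
}
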