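#' Delay-chain derivatives
#'
#' Right-hand side of the gap-junction activation chain for one cell and one
#' population: inactive molecules `gj_na` enter the first delay step at rate
#' `k_act * f(pka_on)` (with `f` linear), transit `n_steps` first-order steps
#' each at rate `n_steps / tau_gj`, arrive in the active pool `gj_ca`, and
#' deactivate back to `gj_na` at rate `gamma_gj`. The chain is closed: the
#' derivatives sum to zero exactly.
#'
#' @param pool list with fields `gj_na` (scalar), `gj_d` (numeric vector of
#'   length `n_steps`), `gj_ca` (scalar), all non-negative.
#' @param pka_on PKA activity in \[0, 1\] driving activation.
#' @param p a [delay_chain_params()] set.
#' @return list of the same shape with the time derivatives.
#' @export
delay_chain_derivatives <- function(pool, pka_on, p) {
  stopifnot(inherits(p, "delay_chain_params"))
  if (length(pool$gj_d) != p$n_steps)
    stop("gj_d has length ", length(pool$gj_d),
         " but n_steps = ", p$n_steps)
  if (any(unlist(pool) < -1e-8))  # tolerate solver round-off excursions
    stop("chain pools must be non-negative")
  r <- p$n_steps / p$tau_gj
  entry <- p$k_act * pka_on * pool$gj_na
  d_d <- r * c(0, pool$gj_d[-p$n_steps]) - r * pool$gj_d
  d_d[1] <- d_d[1] + entry
  list(
    gj_na = p$gamma_gj * pool$gj_ca - entry,
    gj_d = d_d,
    gj_ca = r * pool$gj_d[p$n_steps] - p$gamma_gj * pool$gj_ca
  )
}

#' Closed-form delay-chain activation (Erlang oracle)
#'
#' Active amount at time `t` for a group of `K` molecules that all start in
#' the first delay step at `t = 0`, with deactivation off (`gamma_gj = 0`):
#' the transit time through `n_steps` steps of rate `n_steps / tau_gj` is
#' Erlang-distributed, so the active amount is `K * P(Erlang <= t)`. For
#' `n_steps = 1` this is `K * (1 - exp(-t / tau_gj))`; for large `n_steps` it
#' approaches the switch-like step `K * u(t - tau_gj)`.
#'
#' @param p a [delay_chain_params()] set with `gamma_gj = 0`.
#' @param K initial amount in the first delay step.
#' @param t time(s) in minutes, >= 0. Vectorised.
#' @return active amount(s).
#' @export
delay_chain_response <- function(p, K, t) {
  stopifnot(inherits(p, "delay_chain_params"))
  if (p$gamma_gj != 0)
    stop("the closed-form oracle is defined for gamma_gj = 0")
  if (any(t < 0)) stop("t must be >= 0")
  K * stats::pgamma(t, shape = p$n_steps, rate = p$n_steps / p$tau_gj)
}

#' Numerically integrated delay chain
#'
#' Integrates a single chain under a prescribed PKA drive. Used for
#' validating the chain against the closed-form Erlang response and for
#' isolated chain studies.
#'
#' @param p a [delay_chain_params()] set.
#' @param init list with `gj_na`, `gj_d` (length `n_steps`), `gj_ca`.
#' @param t_grid output times (min), strictly increasing from 0.
#' @param pka_fun function of time returning PKA activity (default 0).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time`, `gj_na`, `gj_d1..`, `gj_ca`, `total`.
#' @export
simulate_delay_chain <- function(p, init, t_grid, pka_fun = function(t) 0,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "delay_chain_params"))
  y0 <- c(gj_na = init$gj_na, setNames(init$gj_d,
                                       paste0("gj_d", seq_len(p$n_steps))),
          gj_ca = init$gj_ca)
  rhs <- function(t, y, parms) {
    pool <- list(gj_na = y[1], gj_d = y[2:(1 + p$n_steps)],
                 gj_ca = y[2 + p$n_steps])
    d <- delay_chain_derivatives(pool, pka_fun(t), p)
    list(c(d$gj_na, d$gj_d, d$gj_ca))
  }
  out <- deSolve::lsoda(y0, t_grid, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  out$total <- rowSums(out[, -1, drop = FALSE])
  out
}

#' Effective gap-junction permeability at an interface
#'
#' `rho_ij = scale * kappa_gj * omega_ij * (k_gj +
#'   k_gj_gjf / (p_bar * x_f^3) * (gj_ca_i / P_i + gj_ca_j / P_j))`,
#' symmetric in the two cells; each cell's active concentration is parsed
#' equally among its `P` coupled neighbours.
#'
#' @param gj_ca_i,gj_ca_j active gap-junction concentrations (a.u., summed
#'   over near/far populations).
#' @param P_i,P_j coupled-neighbour counts (>= 1 where `omega_ij = 1`).
#' @param cp a [coupling_params()] set.
#' @param omega_ij adjacency indicator, 0 or 1.
#' @param pharm_coupling_scale pharmacological coupling multiplier.
#' @return permeability in 1/min. Vectorised over interfaces.
#' @export
effective_permeability <- function(gj_ca_i, gj_ca_j, P_i, P_j, cp,
                                   omega_ij = 1, pharm_coupling_scale = 1) {
  stopifnot(inherits(cp, "coupling_params"))
  if (any(omega_ij == 1 & (P_i < 1 | P_j < 1)))
    stop("coupled cells must have at least one neighbour (P >= 1)")
  reg <- cp$k_gj_gjf / (cp$p_bar * cp$x_f^3) *
    (gj_ca_i / P_i + gj_ca_j / P_j)
  reg[omega_ij == 0] <- 0  # avoid 0/0 from unused interfaces
  pharm_coupling_scale * cp$kappa_gj * omega_ij * (cp$k_gj + reg)
}

#' Gap-junction cAMP flux into a cell
#'
#' `F_ij = rho_ij * (camp_j - camp_i)`: the flux of cAMP into cell `i` from
#' cell `j`, antisymmetric under swapping the cells.
#'
#' @param camp_i,camp_j cAMP concentrations (a.u.).
#' @param rho_ij interface permeability (1/min), >= 0.
#' @return flux in a.u./min. Vectorised.
#' @export
camp_flux <- function(camp_i, camp_j, rho_ij) {
  if (any(rho_ij < 0)) stop("rho_ij must be >= 0")
  rho_ij * (camp_j - camp_i)
}
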