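#' Run a named model variant
#'
#' Configures the parameter set of one of the recurring model variants and
#' delegates to [simulate_tissue()]:
#' \describe{
#'   \item{constant_permeability}{no regulated pools; every interface has the
#'     constant basal permeability `kappa_gj * k_gj`. `kappa_gj` in
#'     \{1/3, 1, 3\} spans the coupling-strength sweep.}
#'   \item{pka_pde_feedback}{constant permeability plus strong PKA feedback
#'     onto PDE with a lag (`pde_pka_feedback_gain = 8`, `tau_pde_fb = 8`
#'     min) — the intracellular mechanism that produces overshoot in every
#'     cell, emitters and receivers alike.}
#'   \item{delayed_regulation}{the base model: cAMP/PKA-driven delay-chain
#'     up-regulation of permeability (`tau_gj = 15`, `n_steps = 4`).}
#'   \item{near_far}{two inactive connexin populations — near the membrane
#'     (`tau_gj = 1`) and far/golgi (`tau_gj = 15`) — with the initial
#'     inactive pool split `far_frac` to the far population; pools are reset
#'     to the split at every pulse onset.}
#'   \item{undershoot}{faster-closing chain (`tau_gj = 10`, `n_steps = 7`),
#'     basal adenylyl-cyclase production, and (by default) a 3x higher
#'     emitter basal rate; options toggle the regulation and the basal
#'     differential (the 2x2 undershoot factorial) and an endogenous-AC PKA
#'     feedback (`ac_feedback`).}
#' }
#'
#' @param variant variant name.
#' @param graph a [build_scenario()] monolayer.
#' @param protocol a [light_protocol()].
#' @param kappa_erk ERK deactivation scaling preset (1 or 0.5).
#' @param kappa_gj global permeability scale (constant-permeability sweep).
#' @param far_frac fraction of the inactive pool in the far population
#'   (near_far variant; presets 1, 0.8, 0).
#' @param gj_regulation undershoot factorial axis: delayed regulation on?
#' @param basal_differential undershoot factorial axis: emitter basal
#'   production 3x the receiver rate?
#' @param ac_feedback undershoot option: PKA inhibition of the endogenous
#'   adenylyl cyclase (`ac_pka_inhibition_gain = 1`).
#' @param pharm a [pharmacology()] spec.
#' @param dt output cadence (min).
#' @param ... further arguments to [simulate_tissue()].
#' @return a `trace_set`.
#' @export
run_model_variant <- function(variant = c("constant_permeability",
                                          "pka_pde_feedback",
                                          "delayed_regulation",
                                          "near_far", "undershoot"),
                              graph, protocol, kappa_erk = 1, kappa_gj = 1,
                              far_frac = 1, gj_regulation = TRUE,
                              basal_differential = TRUE, ac_feedback = FALSE,
                              pharm = pharmacology(), dt = 1, ...) {
  variant <- match.arg(variant)
  switch(variant,
    constant_permeability = {
      ps <- param_preset("fig5", kappa_erk = kappa_erk)
      cp <- ps$coupling; cp$k_gj_gjf <- 0; cp$kappa_gj <- kappa_gj
      simulate_tissue(graph, ps$intra, protocol, pharm, chains = list(),
                      coupling = cp, dt = dt, ...)
    },
    pka_pde_feedback = {
      ps <- param_preset("fig5", kappa_erk = kappa_erk)
      intra <- unclass(ps$intra)
      intra$pde_pka_feedback_gain <- 8
      intra$tau_pde_fb <- 8
      intra <- do.call(intracellular_params, intra)
      cp <- ps$coupling; cp$k_gj_gjf <- 0; cp$kappa_gj <- kappa_gj
      simulate_tissue(graph, intra, protocol, pharm, chains = list(),
                      coupling = cp, dt = dt, ...)
    },
    delayed_regulation = {
      ps <- param_preset("fig5", kappa_erk = kappa_erk)
      ps$coupling$kappa_gj <- kappa_gj
      simulate_tissue(graph, ps$intra, protocol, pharm, chains = ps$chains,
                      coupling = ps$coupling, dt = dt, ...)
    },
    near_far = {
      stopifnot(far_frac >= 0, far_frac <= 1)
      ps <- param_preset("nearfar", kappa_erk = kappa_erk)
      ps$chains[[1]]$pool_frac <- 1 - far_frac
      ps$chains[[2]]$pool_frac <- far_frac
      simulate_tissue(graph, ps$intra, protocol, pharm, chains = ps$chains,
                      coupling = ps$coupling, dt = dt,
                      reset_pools_each_pulse = TRUE, ...)
    },
    undershoot = {
      ps <- param_preset("undershoot", kappa_erk = kappa_erk)
      intra <- unclass(ps$intra)
      if (ac_feedback) intra$ac_pka_inhibition_gain <- 1
      intra <- do.call(intracellular_params, intra)
      beta_0 <- ifelse(graph$cells$role == "emitter",
                       intra$beta_0 * if (basal_differential) 3 else 1,
                       intra$beta_0)
      chains <- ps$chains
      cp <- ps$coupling
      if (!gj_regulation) { chains <- list(); cp$k_gj_gjf <- 0 }
      simulate_tissue(graph, intra, protocol, pharm, chains = chains,
                      coupling = cp, dt = dt,
                      per_cell = list(beta_0 = beta_0), ...)
    }
  )
}

#' Classify a pulse response signature
#'
#' Assigns one of the three gap-junction heterogeneity signatures from the
#' per-pulse metrics of an emitter trace, using the (time-to-max,
#' overshoot-ratio) plane. The peak of an overshooting response sits just
#' before the permeability surge, so its timing reads out which connexin
#' population dominated:
#' \itemize{
#'   \item `"slow_overshoot"` — overshooting with the peak at or beyond
#'     `0.9 * tau_far`: the far (golgi) population alone sets the delay;
#'   \item `"biphasic"` — overshooting with an earlier peak (between
#'     `0.7 * tau_far` and `0.9 * tau_far`): a fast near-membrane component
#'     clamps the rise early so the response completes its first phase
#'     quickly, then the far component adds the delayed overshoot;
#'   \item `"fast_no_late_overshoot"` — everything else: either not
#'     overshooting, or the peak falls well before the far delay — the
#'     near-only signature, where permeability rises almost immediately and
#'     only a brief early transient survives the reporter's low-pass.
#' }
#'
#' @param time_to_max minutes from pulse onset to the signal maximum.
#' @param overshoot_ratio the pulse overshoot ratio.
#' @param overshoot_threshold ratio above which a response counts as
#'   overshooting (default 1.1).
#' @param tau_far mean delay (min) of the far population (default 15).
#' @return character vector of class labels.
#' @export
classify_pulse_response <- function(time_to_max, overshoot_ratio,
                                    overshoot_threshold = 1.1,
                                    tau_far = 15) {
  ifelse(overshoot_ratio <= overshoot_threshold | time_to_max <= 0.7 * tau_far,
         "fast_no_late_overshoot",
         ifelse(time_to_max > 0.9 * tau_far, "slow_overshoot", "biphasic"))
}

#' Is a response overshooting?
#'
#' @param overshoot_ratio numeric.
#' @param threshold classification threshold (default 1.1).
#' @export
is_overshooting <- function(overshoot_ratio, threshold = 1.1) {
  overshoot_ratio > threshold
}

#' Post-pulse half-decay time
#'
#' Time (min) after pulse shutoff for a signal to fall halfway from its
#' end-of-pulse value back to its pre-pulse baseline; `Inf` if the halfway
#' level is never reached within the trace.
#'
#' @param time,signal the sampled trace.
#' @param t_on,t_off the pulse window (min).
#' @return minutes from `t_off`, possibly `Inf`.
#' @export
half_decay_time <- function(time, signal, t_on, t_off) {
  s_start <- signal[which(time >= t_on)[1]]
  s_end <- signal[max(which(time <= t_off))]
  target <- (s_start + s_end) / 2
  post <- which(time > t_off)
  hit <- post[signal[post] <= target][1]
  if (is.na(hit)) Inf else time[hit] - t_off
}
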