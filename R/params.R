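#' Intracellular circuit parameters
#'
#' Rate constants of the single-cell circuit: light-driven bPAC cAMP
#' production, first-order PDE degradation, PKA activation by cAMP (Hill),
#' cAMP/PKA/Epac-driven ERK deactivation, and ERK-dependent nucleocytoplasmic
#' shuttling of the ERK-KTR reporter. Concentrations are in arbitrary units
#' (the cAMP scale is set by `beta_b / gamma_pde` with `bpac_ref = 1`), time
#' is in minutes throughout.
#'
#' @param beta_b cAMP production rate per unit bPAC expression per unit light
#'   amplitude (a.u./min).
#' @param bpac_ref reference bPAC expression level (dimensionless).
#' @param beta_0 endogenous adenylyl-cyclase basal cAMP production rate
#'   (a.u./min). Zero in the base circuit; positive in the undershoot model.
#' @param gamma_pde first-order cAMP degradation rate constant (1/min).
#' @param pde_pka_feedback_gain gain of PKA feedback onto PDE (dimensionless,
#'   0 = no feedback). Degradation becomes
#'   `gamma_pde * (1 + gain * pde_act) * camp`, where `pde_act` is the
#'   PKA-activated PDE fraction, a first-order low-pass of PKA activity.
#' @param tau_pde_fb relaxation time (min) of the PKA-activated PDE fraction
#'   toward current PKA activity (only relevant with a nonzero feedback
#'   gain).
#' @param ac_pka_inhibition_gain gain of PKA inhibition of the endogenous
#'   adenylyl cyclase (dimensionless, 0 = off); basal production becomes
#'   `beta_0 * (1 - gain * pka_on)`.
#' @param k_pka,n_pka half-saturation (a.u.) and Hill exponent of PKA
#'   activation by cAMP.
#' @param tau_pka relaxation time (min) of PKA activity toward its Hill
#'   equilibrium; small values give an effectively instantaneous read-out.
#' @param gamma_erk fitted ERK deactivation rate (1/min).
#' @param kappa_erk dimensionless scaling factor on the ERK deactivation
#'   rate; presets 1 and 0.5 bracket the fitted value.
#' @param k_erk_react ERK reactivation rate (1/min).
#' @param erk_tot total ERK per cell (a.u.).
#' @param k_ktr_in basal nuclear-import rate of ERK-KTR (1/min).
#' @param k_ktr_out ERK-driven nuclear-export rate coefficient
#'   (1/min per unit active ERK).
#' @param ktr_tot total ERK-KTR per cell (a.u.).
#' @param epac_gain relative weight of the Epac branch in the ERK
#'   deactivation drive (PKA and Epac are lumped with the same cAMP affinity).
#' @return an object of class `intracellular_params`.
#' @export
intracellular_params <- function(beta_b = 0.3,
                                 bpac_ref = 1,
                                 beta_0 = 0,
                                 gamma_pde = 0.3,
                                 pde_pka_feedback_gain = 0,
                                 tau_pde_fb = 8,
                                 ac_pka_inhibition_gain = 0,
                                 k_pka = 1,
                                 n_pka = 2,
                                 tau_pka = 1,
                                 gamma_erk = 1,
                                 kappa_erk = 1,
                                 k_erk_react = 0.3,
                                 erk_tot = 1,
                                 k_ktr_in = 0.15,
                                 k_ktr_out = 0.8,
                                 ktr_tot = 1,
                                 epac_gain = 0.5) {
  p <- list(beta_b = beta_b, bpac_ref = bpac_ref, beta_0 = beta_0,
            gamma_pde = gamma_pde,
            pde_pka_feedback_gain = pde_pka_feedback_gain,
            tau_pde_fb = tau_pde_fb,
            ac_pka_inhibition_gain = ac_pka_inhibition_gain,
            k_pka = k_pka, n_pka = n_pka, tau_pka = tau_pka,
            gamma_erk = gamma_erk, kappa_erk = kappa_erk,
            k_erk_react = k_erk_react, erk_tot = erk_tot,
            k_ktr_in = k_ktr_in, k_ktr_out = k_ktr_out, ktr_tot = ktr_tot,
            epac_gain = epac_gain)
  rates <- c("beta_b", "bpac_ref", "beta_0", "gamma_pde", "k_pka", "tau_pka", "tau_pde_fb",
             "gamma_erk", "k_erk_react", "erk_tot", "k_ktr_in", "k_ktr_out",
             "ktr_tot", "epac_gain")
  bad <- rates[vapply(p[rates], function(x) !is.numeric(x) || x < 0, TRUE)]
  if (length(bad)) stop("negative or non-numeric parameter(s): ",
                        paste(bad, collapse = ", "))
  if (p$n_pka < 1) stop("n_pka must be >= 1")
  if (p$kappa_erk <= 0) stop("kappa_erk must be > 0")
  if (p$ktr_tot <= 0) stop("ktr_tot must be > 0")
  structure(p, class = "intracellular_params")
}

#' Gap-junction delay-chain parameters
#'
#' One inactive connexin population that, when driven by PKA activity, enters
#' a linear chain of `n_steps` first-order delay steps (each at rate
#' `n_steps / tau_gj`, so the mean transit time of the chain is `tau_gj` and
#' its dispersion falls as `tau_gj^2 / n_steps`) before reaching the active,
#' membrane-coupled state; active molecules deactivate back to the inactive
#' pool at rate `gamma_gj`.
#'
#' @param tau_gj mean activation delay of the chain (min).
#' @param n_steps integer number of delay steps, >= 1.
#' @param gamma_gj deactivation (e.g. endocytosis) rate of the active pool
#'   (1/min).
#' @param k_act activation entry rate coefficient multiplying `f(pka_on)`
#'   (1/min); `f` is linear, `f(x) = x`.
#' @param pool_frac fraction of the cell's total inactive gap-junction pool
#'   assigned to this population (near/far populations of one cell must sum
#'   to 1).
#' @param label population name, `"near"` or `"far"`.
#' @return an object of class `delay_chain_params`.
#' @export
delay_chain_params <- function(tau_gj = 15, n_steps = 4, gamma_gj = 0.05,
                               k_act = 0.5, pool_frac = 1, label = "far") {
  stopifnot(tau_gj > 0, n_steps >= 1, n_steps == round(n_steps),
            gamma_gj >= 0, k_act >= 0, pool_frac >= 0, pool_frac <= 1,
            label %in% c("near", "far"))
  structure(list(tau_gj = tau_gj, n_steps = as.integer(n_steps),
                 gamma_gj = gamma_gj, k_act = k_act, pool_frac = pool_frac,
                 label = label),
            class = "delay_chain_params")
}

#' Gap-junction coupling parameters
#'
#' Parameters of the effective permeability at a cell-cell interface,
#' `rho_ij = kappa_gj * omega_ij * (k_gj +
#'   k_gj_gjf / (p_bar * x_f^3) * (GJCa_i / P_i + GJCa_j / P_j))`,
#' where `GJCa` is the active gap-junction concentration of each cell
#' (parsed equally over its `P` coupled neighbours) and `p_bar * x_f^3`
#' normalises the regulated gain to the dimensions of the basal term.
#'
#' @param k_gj basal permeability (1/min).
#' @param k_gj_gjf regulated permeability gain (1/min per normalised active
#'   concentration).
#' @param x_f normalisation constant, used cubed; the default makes
#'   `p_bar * x_f^3 = 1` so the regulated term is O(`k_gj_gjf`) at full
#'   activation.
#' @param p_bar average coupled-neighbour count.
#' @param kappa_gj global permeability scale (1 = reference; 1/3 and 3 are
#'   the constant-permeability sweep values).
#' @return an object of class `coupling_params`.
#' @export
coupling_params <- function(k_gj = 0.05, k_gj_gjf = 1,
                            x_f = (1 / 5)^(1 / 3), p_bar = 5, kappa_gj = 1) {
  stopifnot(k_gj >= 0, k_gj_gjf >= 0, x_f >= 0, p_bar > 0, kappa_gj >= 0)
  structure(list(k_gj = k_gj, k_gj_gjf = k_gj_gjf, x_f = x_f, p_bar = p_bar,
                 kappa_gj = kappa_gj),
            class = "coupling_params")
}

#' Pharmacology specification
#'
#' Parameter transformations representing drug or genetic perturbations.
#' Either give the effect scales directly or name a `drug`:
#' \describe{
#'   \item{IBMX}{PDE inhibition: `pde_scale = 0`.}
#'   \item{carbenoxolone}{gap-junction block: `coupling_scale = 0`.}
#'   \item{CX43-NGFP}{broken-connexin receivers: `coupling_scale = 0.2`.}
#'   \item{Brefeldin-A}{connexin-trafficking block: `coupling_scale = 0.25`.}
#'   \item{H89}{PKA inhibition: permeability regulation frozen
#'     (`regulation_enabled = FALSE`); a small basal `k_gj` is retained by
#'     default (`h89_basal_scale`), since coupling is greatly reduced, not
#'     abolished.}
#'   \item{ESI-09}{Epac inhibition: Epac branch removed from the ERK
#'     deactivation drive (`epac_enabled = FALSE`).}
#' }
#' The drug acts from `onset_time` onward (minutes; 0 = from the start).
#' Initial conditions are always equilibrated drug-free, so `onset_time = 0`
#' represents a drug added at the beginning of imaging.
#'
#' @param drug optional drug name (see Details); `NULL` builds the spec from
#'   the scale arguments.
#' @param pde_scale multiplier in \[0,1\] on the PDE degradation rate.
#' @param coupling_scale multiplier in \[0,1\] on all interface
#'   permeabilities.
#' @param regulation_enabled if `FALSE`, delay-chain activation is frozen
#'   (`k_act` effectively 0).
#' @param epac_enabled if `FALSE`, the Epac term is removed from the ERK
#'   deactivation drive.
#' @param h89_basal_scale coupling scale applied when regulation is frozen by
#'   H89 (retained basal permeability).
#' @param onset_time time (min) at which the perturbation switches on.
#' @return an object of class `pharmacology`.
#' @export
pharmacology <- function(drug = NULL, pde_scale = 1, coupling_scale = 1,
                         regulation_enabled = TRUE, epac_enabled = TRUE,
                         h89_basal_scale = 0.1, onset_time = 0) {
  if (!is.null(drug)) {
    known <- c("none", "IBMX", "carbenoxolone", "CX43-NGFP", "Brefeldin-A",
               "H89", "ESI-09")
    if (!drug %in% known)
      stop("unknown drug '", drug, "'; supported: ",
           paste(known, collapse = ", "))
    switch(drug,
      "IBMX" = { pde_scale <- 0 },
      "carbenoxolone" = { coupling_scale <- 0 },
      "CX43-NGFP" = { coupling_scale <- 0.2 },
      "Brefeldin-A" = { coupling_scale <- 0.25 },
      "H89" = { regulation_enabled <- FALSE
                coupling_scale <- coupling_scale * h89_basal_scale },
      "ESI-09" = { epac_enabled <- FALSE },
      "none" = {}
    )
  }
  stopifnot(pde_scale >= 0, pde_scale <= 1,
            coupling_scale >= 0, coupling_scale <= 1, onset_time >= 0)
  structure(list(drug = if (is.null(drug)) "none" else drug,
                 pde_scale = pde_scale, coupling_scale = coupling_scale,
                 regulation_enabled = isTRUE(regulation_enabled),
                 epac_enabled = isTRUE(epac_enabled),
                 onset_time = onset_time),
            class = "pharmacology")
}

#' Apply a pharmacology specification to a parameter set
#'
#' Returns the effective intracellular, chain and coupling parameters under a
#' perturbation. For `onset_time > 0` the simulator applies the returned set
#' only from the onset onward (piecewise integration); this helper returns
#' the post-onset effective values.
#'
#' @param params an [intracellular_params()] set.
#' @param chains list of [delay_chain_params()].
#' @param coupling a [coupling_params()] set.
#' @param pharm a [pharmacology()] spec.
#' @return list with elements `params`, `chains`, `coupling`,
#'   `coupling_scale`, `epac_enabled`.
#' @export
apply_pharmacology <- function(params, chains, coupling, pharm) {
  stopifnot(inherits(pharm, "pharmacology"))
  eff <- params
  eff$gamma_pde <- params$gamma_pde * pharm$pde_scale
  eff_chains <- lapply(chains, function(ch) {
    if (!pharm$regulation_enabled) ch$k_act <- 0
    ch
  })
  list(params = eff, chains = eff_chains, coupling = coupling,
       coupling_scale = pharm$coupling_scale,
       epac_enabled = pharm$epac_enabled)
}

#' Named parameter presets
#'
#' Frozen parameter sets for the recurring model configurations:
#' \describe{
#'   \item{fig5}{base circuit (no basal production, no feedbacks) with one
#'     slow ("far") delay chain, `tau_gj = 15`, `n_steps = 4`; the delayed
#'     regulation model that reproduces emitter overshoot without receiver
#'     overshoot.}
#'   \item{nearfar}{base circuit with two chains, near (`tau_gj = 1`, with
#'     a 4x faster activation entry, `k_act = 2`) and far (`tau_gj = 15`),
#'     both `n_steps = 4`; pool split set by the caller.}
#'   \item{undershoot}{circuit with basal adenylyl-cyclase production
#'     (receivers `beta_0 = 0.03`, emitters 3x via scenario override), a
#'     faster-closing chain (`tau_gj = 10`, `n_steps = 7`,
#'     `gamma_gj = 0.1`), a small basal permeability and a stronger
#'     regulated gain (`k_gj_gjf = 3`), so open gates drain the emitter
#'     well below its elevated basal level after shutoff.}
#' }
#'
#' @param name preset name.
#' @param kappa_erk ERK deactivation scaling preset (1 or 0.5).
#' @return list with elements `intra`, `chains`, `coupling`.
#' @export
param_preset <- function(name = c("fig5", "nearfar", "undershoot"),
                         kappa_erk = 1) {
  name <- match.arg(name)
  intra <- intracellular_params(kappa_erk = kappa_erk)
  switch(name,
    fig5 = list(
      intra = intra,
      chains = list(delay_chain_params(tau_gj = 15, n_steps = 4,
                                       gamma_gj = 0.05, pool_frac = 1,
                                       label = "far")),
      coupling = coupling_params()
    ),
    nearfar = list(
      intra = intra,
      chains = list(
        delay_chain_params(tau_gj = 1, n_steps = 4, gamma_gj = 0.05,
                           k_act = 2, pool_frac = 0, label = "near"),
        delay_chain_params(tau_gj = 15, n_steps = 4, gamma_gj = 0.05,
                           pool_frac = 1, label = "far")
      ),
      coupling = coupling_params()
    ),
    undershoot = list(
      intra = intracellular_params(kappa_erk = kappa_erk, beta_0 = 0.03),
      chains = list(delay_chain_params(tau_gj = 10, n_steps = 7,
                                       gamma_gj = 0.1, pool_frac = 1,
                                       label = "far")),
      coupling = coupling_params(k_gj = 0.003, k_gj_gjf = 3)
    )
  )
}
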