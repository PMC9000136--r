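---
title: "The gjcamp model: delayed gap-junction regulation of cAMP/PKA/ERK signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gjcamp model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjcamp)
```

## The system and the question

An epithelial monolayer in which a subset of cells ("emitters") carries
bPAC, a blue-light-driven adenylyl cyclase, and every cell carries an
ERK kinase-translocation reporter. Light pulses raise cAMP in emitters;
cAMP activates PKA and Epac, both of which inhibit ERK, and ERK inhibition
is read out as a rising nuclear/cytoplasmic reporter ratio (ERK-KTR N/C).
cAMP also crosses gap junctions into neighbouring cells. The modeling
question is what coupling law makes a *locally* perturbed emitter
overshoot (fast peak, partial relaxation under sustained light) while its
adjacent receivers and a *uniformly* perturbed monolayer do not.

## Intracellular circuit

Per cell: cAMP is produced at `beta_b * (b_i / bpac_ref) * u(t)` (plus an
optional basal term `beta_0`), degraded at `gamma_pde * [cAMP]`; PKA
activity relaxes with time constant `tau_pka` toward the Hill equilibrium
`camp^n / (K^n + camp^n)`; ERK is deactivated at rate
`kappa_erk * gamma_erk * psi` with `psi = PKA + epac_gain * Hill(cAMP)`
and reactivated at `k_erk_react * (ERKtot - ERK)`; the reporter shuttles
by mass action (import `k_ktr_in`, ERK-driven export `k_ktr_out * ERK`),
with the total pool conserved. The observable is
`N/C = KTRnuc / KTRcyt`.

Two deliberate structural choices:

* **PKA is a dynamic state**, not an algebraic function of cAMP. With the
  default `tau_pka = 1` min it is effectively a fast read-out, but the
  intracellular-feedback alternative model (below) needs a lagged species,
  and a single consistent state machinery serves both.
* **The PKA→PDE feedback acts through its own low-passed state**
  (`pde_act`, time constant `tau_pde_fb = 8` min). A feedback through the
  *same* fast PKA state that drives the reporter cancels in the read-out:
  the cAMP transient and the lagged deactivation drive offset each other
  almost exactly and no reporter overshoot survives. Mechanistically the
  lag is PDE phosphorylation/activation downstream of PKA.

## Gap-junction coupling

Flux at the interface of cells `i, j`:
`F_ij = rho_ij * ([cAMP]_j - [cAMP]_i)` with

```
rho_ij = omega_ij * ( k_gj + k_gj_gjf / (Pbar * Xf^3)
                        * (GJCa_i / P_i + GJCa_j / P_j) )
```

Each cell's active gap-junction pool `GJCa` comes from a linear chain:
inactive connexins enter at `k_act * f(PKA)` (`f` linear — the minimal
monotone choice, `k_act` absorbing the scale), pass `N` steps of rate
`N / tau_gj`, and deactivate at `gamma_gj`. The transit time is
Erlang(`N`, `N/tau_gj`): mean `tau_gj` for any `N`, single-exponential
accumulation `1 - exp(-t/tau_gj)` at `N = 1`, and a sharp switch at
`t = tau_gj` as `N` grows (sd `tau_gj / sqrt(N)`). The closed-form Erlang
CDF (`stats::pgamma`) is the package's independent oracle for the
integrated chain.

Cells are well-mixed and of equal volume, so the flux enters `d[cAMP]/dt`
directly with no volume factor; pairwise fluxes are antisymmetric, making
total cAMP exactly conserved under coupling alone — one of the standing
regression checks.

## Monolayer geometry

Scenarios are built on a hexagonal-disc lattice (interior degree 6,
boundary 3–5, mean ≈ 5, matching the observed "most P_i between 4 and 7"
with Pbar = 5). Only degree statistics are specified by the experimental
system; the hex disc is chosen over a random planar graph because it gives
deterministic layouts and clean graph-distance shells for the propagation
analysis. Presets: `all_emitter(n)` (default 46), `single_emitter_cluster`
(1 + 45 receivers; a 1 + 10 reduced variant), `small_emitter_cluster`
(≤ 15 emitters; more warns). Randomness enters only through expression
sampling.

## Parameters

All defaults live in `intracellular_params()`, `delay_chain_params()`,
`coupling_params()` and the frozen `param_preset()` sets. Units: minutes,
arbitrary concentration units with `bpac_ref = 1`; the cAMP scale is set
by `beta_b / gamma_pde = 1` at full drive. The rate constants are package
defaults calibrated once so that (i) a max-amplitude 40-min pulse drives
the reporter to near-steady state in roughly 5–8 min, (ii) the
delayed-regulation cluster reproduces the overshoot dichotomy, and (iii)
the undershoot variant reproduces the post-shutoff undershoot; they were
then frozen. Key values:

| parameter | default | meaning |
|---|---|---|
| `beta_b` | 0.3 /min | bPAC cAMP production at full light, unit expression |
| `gamma_pde` | 0.3 /min | first-order PDE degradation |
| `K_pka`, `n_pka` | 1, 2 | PKA half-saturation and Hill exponent |
| `gamma_erk`, `kappa_erk` | 1 /min, {1, 0.5} | ERK deactivation rate and preset scaling |
| `k_erk_react` | 0.3 /min | ERK reactivation |
| `k_ktr_in`, `k_ktr_out` | 0.15, 0.8 /min | reporter shuttling |
| `tau_gj`, `N` | 15 min, 4 | far-chain delay (base model) |
| `gamma_gj` | 0.05 /min | active-pool deactivation |
| `k_act` | 0.5 /min | chain entry coefficient on PKA activity |
| `k_gj`, `k_gj_gjf` | 0.05, 1 /min | basal and regulated permeability |
| `Pbar`, `Xf^3` | 5, 1/5 | Eq-normalisation constants (`Pbar * Xf^3 = 1`) |

Presets depart from these where the phenomenon requires it: the near/far
preset adds a membrane-proximal chain (`tau_gj = 1`, `N = 4`,
`k_act = 2` — entry is not rate-limiting for connexins already at the
membrane); the undershoot preset uses `tau_gj = 10`, `N = 7`,
`gamma_gj = 0.1`, basal production `beta_0 = 0.03` /min in receivers and
3× that in emitters (the direction is known, the magnitude is a package
default), a small basal permeability `k_gj = 0.003` and a stronger
regulated gain `k_gj_gjf = 3`, so that post-shutoff open gates drain the
emitter well below its elevated basal point before they close.

## Pulse metrics and classification

`compute_pulse_metrics()` works on the sampled grid without interpolation
(mirroring what a 3-min-cadence experiment can measure): `s_start`,
`s_max` (earliest attaining sample), `s_end`, `time_to_max`, `time_to_ss`
(first sample at or after the peak within 30% of `s_end` relative to
`s_max`; the band is two-sided — `|S - s_end| <= 0.3 (s_max - s_end)` — a
one-sided reading is available through the same band since an overshooting
signal approaches from above), `overshoot_ratio =
(s_max - s_start)/(s_end - s_start)`, and `undershoot_depth = max(0,
s_start - min)` over the post-pulse OFF window (not formally defined in
the experimental literature; the 5%-of-pulse-amplitude classification
threshold is a package choice). Responses with `|s_end - s_start|` under
1% of the trace's dynamic range are flagged invalid rather than producing
unbounded ratios. "Overshooting" means ratio > 1.1, a threshold that
robustly separates the constant-permeability from the delayed-regulation
model outputs.

The near/far signature classifier reads the (time-to-max, overshoot-ratio)
plane: non-overshooting or early-peak responses (`time_to_max <= 0.7
tau_far`) are "fast, no late overshoot" (near-only); overshooting
responses peaking beyond `0.9 tau_far` are "slow overshoot" (far-only);
the band between is "biphasic" (near + far: the fast component completes
the first rise early, the far component adds the delayed overshoot). The
region boundaries are expressed as fractions of the far delay so they are
meaningful for any `tau_far`.

## Synthetic data generator

`generate_trace_table()` emulates microscopy-extracted single-cell series:
3-min sampling, log-normal bPAC expression (CV 0.3 by default, mean 1),
static per-cell baseline offsets (sd 5% of the cohort's dynamic range),
additive white measurement noise (sd 2% of range — both magnitudes are
package defaults chosen to resemble single-cell reporter roughness, the
experimental noise level being unpublished), optional flat non-responders
(excluded downstream via the metrics `valid` flag, mirroring the discard
rule used for real cohorts), and per-pulse near/far pool resets. Every
noisy table carries its noiseless twin and the exact seeds. What it does
*not* emulate: segmentation/tracking artifacts, correlated (non-white)
noise, photobleaching trends, cell movement and division. Tests passing on
these cohorts therefore validate the analysis pipeline's logic, not its
robustness to imaging pathology.

## Numerical choices

Stiff-capable integration (`deSolve::lsoda`) at `rtol 1e-6`, `atol 1e-9`;
the piecewise-constant light input and any drug onset are handled by
restarting the integrator at each discontinuity, so pulse edges are exact.
Output cadence 1 min for model studies, 3 min when emulating experiments.
Initial conditions come from 500 simulated dark minutes (drug-free), so
every run starts at its basal steady state; a drug with `onset_time = 0`
acts from the start of imaging but not during pre-equilibration. Chain
pools are per-cell conserved; at a pulse-onset pool reset the recorded
sample at the onset keeps the left limit. Least-squares fitting uses
seeded multi-start Levenberg–Marquardt (`minpack.lm`) on baseline-shifted
reporter signals, which cancels additive per-cell offsets; flat traces
raise a non-identifiability flag instead of returning estimates. Problem
sizes used throughout the tests and the acceptance script — 46-cell
monolayers, two 40-min pulses, 20-cell fit cohorts, 1000-replicate null
calibration — are the study's own conditions.

## Known limitations

* **Reporter compression.** The Hill read-out (`K_pka = 1`, `n = 2`)
  saturates above `camp ≈ 1` and is insensitive below `camp ≈ 0.2`. Two
  consequences, both documented where asserted: in uniform monolayers with
  expression heterogeneity, single-cell cAMP overshoot ratios of ~1.18
  compress to ~1.07 in N/C (the sporadic-overshoot check therefore reads
  the cAMP signal); and the post-shutoff undershoot, ~7% of pulse
  amplitude in cAMP, appears at only ~3–4% in N/C, so the undershoot
  factorial is classified on cAMP.
* **Undershoot under a strict full PDE block.** With `pde_scale = 0`
  exactly and constitutive basal production, total cAMP can only grow: the
  post-pulse tissue-mean floor exceeds every cell's pre-pulse baseline, so
  no signal can return below its own start value, and the basal drift
  saturates PKA, which opens the permeability chains before the pulse —
  removing the closed-gate state the undershoot mechanism needs. The
  undershoot factorial's exclusivity therefore cannot survive an exact
  zero-degradation mapping in this model family (a partial block, as IBMX
  achieves pharmacologically, behaves like the wild-type mechanism). The
  corresponding acceptance check is left failing rather than weakened.
* The H89 mapping freezes chain activation and retains 10% basal coupling
  (observed coupling is greatly reduced, not abolished); whether basal
  permeability truly persists under PKA inhibition is unresolved and the
  retention factor is configurable.
* Near/far trafficking is a two-population caricature of a continuum, and
  pool resets at pulse onsets stand in for unmodeled inter-pulse
  recycling dynamics.
* The exact adjacency of the experimental fields of view is unknown; the
  hex disc reproduces only their degree statistics. Explicit edge lists
  can be supplied via `graph_from_edges()`.
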