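# gjcamp

Multicellular cAMP/PKA/ERK signaling with regulated gap-junction coupling.

## The problem

In an epithelial monolayer, cAMP produced inside one cell does not stay
there: it moves to neighbours through gap junctions. When cAMP is raised
optogenetically (bPAC, a blue-light-activated adenylyl cyclase) in *every*
cell at once, the downstream ERK inhibition — read out as the nuclear to
cytoplasmic ratio of an ERK kinase-translocation reporter, ERK-KTR N/C —
rises with simple, over-damped first-order kinetics. But when only a small
cluster of cells (or a single cell) is perturbed, the perturbed "emitter"
shows a pronounced transient **overshoot**: the signal peaks within ~10–15
minutes and partially relaxes despite sustained illumination, while the
surrounding "receiver" cells respond with no overshoot at all. A constant
cell–cell permeability cannot produce this asymmetry; this package
implements the model that can — gap junctions whose cAMP permeability is
itself up-regulated by cAMP/PKA **after a delay**, so that a localized
cAMP source first charges up and is then drained once the gates open.

`gjcamp` provides the full computational pipeline around that model:
single-cell and multicellular ODE simulation, monolayer scenario builders,
pharmacological perturbation mappings, pulse-response signal metrics, a
variability decomposition, group statistics, parameter fitting, and a
synthetic microscopy-like trace generator, all exercised on simulated
single-cell reporter traces (no imaging data needed).

## The model

Each cell `i` carries the intracellular circuit (time in minutes,
concentrations in arbitrary units):

```
d[cAMP]i/dt = beta_b (b_i/[bPAC0]) u(t) + beta_0 (1 - g_ac PKAon_i)
              - gamma_pde (1 + g_pde PDEact_i) [cAMP]i + sum_j Fc_ij
PKAon_i  ->  Hill([cAMP]i; K_pka, n_pka)        (first-order relaxation)
ERK_i    :   deactivated at kappa_erk gamma_erk psi([cAMP]i),
             reactivated at k_erk_react (ERKtot - ERK_i)
ERK-KTR  :   nuclear import k_ktr_in KTRcyt - export k_ktr_out ERK_i KTRnuc
```

with `u(t)` the light amplitude in [0, 1] and
`psi = PKAon + epac_gain * Hill(cAMP)` lumping the PKA and Epac branches.
The inter-cell flux follows the standard gap-junction form

```
Fc_ij = rho_ij ([cAMP]j - [cAMP]i)
rho_ij = omega_ij [ k_gj + k_gj,gjf / (Pbar Xf^3) ([GJCa]i/P_i + [GJCa]j/P_j) ]
```

where the active gap-junction concentration `[GJCa]` of each cell is
produced by a **linear delay chain**: inactive connexins enter at rate
`k_act f(PKAon)`, traverse `N` first-order steps of rate `N/tau_gj` (an
Erlang-distributed transit with mean `tau_gj` and dispersion shrinking as
`1/N`), arrive in the active membrane pool, and deactivate back at
`gamma_gj`. With `tau_gj = 15` min and `N = 4` this reproduces the
overshoot dichotomy; two chains with different delays (near-membrane
`tau_gj = 1` vs golgi `tau_gj = 15`) reproduce the pulse-to-pulse response
heterogeneity, and a variant with emitter-elevated basal adenylyl-cyclase
activity reproduces the post-shutoff undershoot.

## Worked example

```r
library(gjcamp)

graph    <- build_scenario("single_emitter_cluster", seed = 1)  # 1 + 45 cells
protocol <- two_pulse_protocol()                 # two 40-min ON/OFF pulses

wt    <- run_model_variant("delayed_regulation", graph, protocol)
const <- run_model_variant("constant_permeability", graph, protocol)

metrics <- pulse_metrics_table(wt)
subset(metrics, role == "emitter" & pulse_index == 1)
#>   cell_id    role pulse_index s_start     s_max     s_end time_to_max
#> 1       0 emitter           1  0.1875 0.3756215 0.2849517          14
#>   time_to_ss overshoot_ratio undershoot_depth valid
#> 1         28        1.930406                0  TRUE
```

The delayed-regulation emitter overshoots (ratio 1.93, peaking 14 min
after light onset and re-converging within 30% of its end-of-pulse value
by 28 min), while the same cell under constant permeability gives ratio
1.00 — a plain first-order rise — and its adjacent receivers stay at
ratio 1.00 in both cases. `pulse_metrics_table(wt, signal = "camp")`
applies the same metrics to the underlying cAMP signal, and
`as.data.frame(wt)` / `write_trace_table()` export the traces.

The numbered scripts under `analysis/` run the full study — the isolated
circuit and its fit, the overshoot dichotomy, pharmacology (IBMX, H89,
ESI-09, carbenoxolone, Brefeldin-A, CX43-NGFP), near/far trafficking
heterogeneity, the undershoot factorial, variability decomposition and
pooled group tests — and write their tables under `results/`.

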