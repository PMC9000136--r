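# Shared fixtures: expensive tissue simulations are computed once per test
# session and reused across files (including the acceptance suite).

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (!exists(name, envir = .sim_cache)) assign(name, fun(), .sim_cache)
  get(name, envir = .sim_cache)
}

std_protocol <- function() two_pulse_protocol()

cluster45 <- function() cached("g45", function()
  build_scenario("single_emitter_cluster", seed = 1))

cluster10 <- function() cached("g10", function()
  build_scenario("single_emitter_cluster", n_receivers = 10, seed = 1))

sim_delayed <- function(kappa_erk = 1, drug = "none") {
  key <- paste0("delayed_", kappa_erk, "_", drug)
  cached(key, function()
    run_model_variant("delayed_regulation", cluster45(), std_protocol(),
                      kappa_erk = kappa_erk, pharm = pharmacology(drug)))
}

sim_const <- function(kappa_gj = 1) {
  cached(paste0("const_", round(kappa_gj, 3)), function()
    run_model_variant("constant_permeability", cluster45(), std_protocol(),
                      kappa_gj = kappa_gj))
}

sim_nearfar <- function(far_frac, kappa_erk = 1) {
  cached(paste0("nf_", far_frac, "_", kappa_erk), function()
    run_model_variant("near_far", cluster45(), std_protocol(),
                      far_frac = far_frac, kappa_erk = kappa_erk))
}

sim_undershoot <- function(gj, basal, drug = "none") {
  cached(paste0("us_", gj, "_", basal, "_", drug), function()
    run_model_variant("undershoot", cluster45(),
                      one_pulse_protocol(lead = 90),
                      gj_regulation = gj, basal_differential = basal,
                      pharm = pharmacology(drug)))
}

emitter_metrics <- function(ts, signal = "ktr_nc", pulse = 1) {
  m <- pulse_metrics_table(ts, signal = signal)
  m[m$role == "emitter" & m$pulse_index == pulse, ]
}

adjacent_metrics <- function(ts, graph, signal = "ktr_nc", pulse = 1) {
  adj <- which(emitter_distance(graph) == 1) - 1L
  m <- pulse_metrics_table(ts, signal = signal)
  m[m$cell_id %in% adj & m$pulse_index == pulse, ]
}

# Brute-force index-scan oracle for pulse metrics: scans every sample
# directly, independent of the implementation's vectorised search.
oracle_pulse_metrics <- function(time, signal, t_on, t_off, off_end,
                                 ss_fraction = 0.3) {
  iw <- which(time >= t_on & time <= t_off)
  s_start <- signal[iw[1]]
  s_end <- signal[iw[length(iw)]]
  s_max <- -Inf; i_max <- NA
  for (i in iw) if (signal[i] > s_max) { s_max <- signal[i]; i_max <- i }
  t_max <- time[i_max] - t_on
  band <- ss_fraction * (s_max - s_end)
  t_ss <- NA
  for (i in iw[iw >= i_max])
    if (abs(signal[i] - s_end) <= band) { t_ss <- time[i] - t_on; break }
  if (is.na(t_ss)) t_ss <- time[iw[length(iw)]] - t_on
  io <- which(time > t_off & time <= off_end)
  und <- if (length(io)) max(0, s_start - min(signal[io])) else NA_real_
  list(s_start = s_start, s_max = s_max, s_end = s_end,
       time_to_max = t_max, time_to_ss = t_ss,
       overshoot_ratio = (s_max - s_start) / (s_end - s_start),
       undershoot_depth = und)
}

# Synthetic two-pulse cohort with one common shape and independent random
# per-pulse gains (the variability-decomposition study object).
gain_cohort <- function(n_cells = 40, gain_cv = 0.3, noise_sd = 0.002,
                        seed = 5) {
  proto <- std_protocol()
  tg <- seq(0, proto$t_end, by = 3)
  win <- pulse_windows(proto)
  shape <- numeric(length(tg))
  for (k in seq_len(nrow(win))) {
    on <- tg >= win$t_on[k] & tg < win$t_off[k]
    shape[on] <- 1 - exp(-(tg[on] - win$t_on[k]) / 6)
    off <- tg >= win$t_off[k] & tg < win$off_end[k]
    base <- 1 - exp(-(win$t_off[k] - win$t_on[k]) / 6)
    shape[off] <- base * exp(-(tg[off] - win$t_off[k]) / 8)
  }
  set.seed(seed)
  gains <- matrix(stats::rlnorm(n_cells * nrow(win),
                                -log(1 + gain_cv^2) / 2,
                                sqrt(log(1 + gain_cv^2))),
                  nrow = n_cells)
  traces <- sapply(seq_len(n_cells), function(i) {
    tr <- numeric(length(tg))
    for (k in seq_len(nrow(win))) {
      seg <- tg >= win$t_on[k] & tg < win$off_end[k]
      tr[seg] <- gains[i, k] * shape[seg]
    }
    tr + stats::rnorm(length(tg), 0, noise_sd)
  })
  list(time = tg, traces = traces, protocol = proto, windows = win)
}

in_pulse_sd <- function(traces, time, win, k) {
  sel <- time > win$t_on[k] & time <= win$t_off[k]
  mean(apply(traces[sel, , drop = FALSE], 1, stats::sd))
}

sim_delayed_small <- function() {
  cached("delayed_small", function()
    run_model_variant("delayed_regulation", cluster10(), std_protocol()))
}
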