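test_that("expression sampling hits the requested moments", {
  expect_equal(sample_expression_levels(5, cv = 0, seed = 1), rep(1, 5))
  a <- sample_expression_levels(20, cv = 0.3, seed = 3)
  b <- sample_expression_levels(20, cv = 0.3, seed = 3)
  expect_identical(a, b)
  big <- sample_expression_levels(1e5, cv = 0.3, seed = 4)
  expect_lt(abs(sd(big) / mean(big) - 0.3) / 0.3, 0.02)
  expect_lt(abs(mean(big) - 1), 0.01)
  expect_error(sample_expression_levels(10, cv = -1), "cv")
})

test_that("zero-noise trace tables equal the resampled simulation", {
  g <- build_scenario("all_emitter", n_cells = 6, seed = 1)
  gen <- generate_trace_table(
    g, intracellular_params(), two_pulse_protocol(),
    noise = noise_model(meas_sd = 0, baseline_sd = 0),
    het = heterogeneity_spec(bpac_cv = 0), seed = 1, chains = list())
  expect_equal(gen$table$ktr_nc, gen$table$ktr_nc_true)
  expect_equal(unique(diff(unique(gen$table$time_min))), 3)
  expect_true(all(gen$table$responder))
})

test_that("trace-table generation is reproducible and file round-trips", {
  g <- build_scenario("all_emitter", n_cells = 6, seed = 2)
  gen1 <- generate_trace_table(g, intracellular_params(),
                               two_pulse_protocol(), seed = 7,
                               chains = list())
  gen2 <- generate_trace_table(g, intracellular_params(),
                               two_pulse_protocol(), seed = 7,
                               chains = list())
  expect_identical(gen1$table, gen2$table)
  f <- tempfile(fileext = ".tsv")
  write_trace_table(gen1$table, f)
  back <- read_trace_table(f)
  expect_equal(back$ktr_nc, gen1$table$ktr_nc, tolerance = 1e-12)
})

test_that("measurement noise has the requested magnitude", {
  g <- build_scenario("all_emitter", n_cells = 40, seed = 1)
  gen <- generate_trace_table(
    g, intracellular_params(), two_pulse_protocol(),
    noise = noise_model(meas_sd = 0.05, baseline_sd = 0),
    het = heterogeneity_spec(bpac_cv = 0), seed = 5, chains = list())
  res <- gen$table$ktr_nc - gen$table$ktr_nc_true
  expect_lt(abs(sd(res) - 0.05) / 0.05, 0.05)
})

test_that("non-responders are flat and flagged for downstream exclusion", {
  g <- build_scenario("all_emitter", n_cells = 30, seed = 1)
  gen <- generate_trace_table(
    g, intracellular_params(), two_pulse_protocol(),
    noise = noise_model(meas_sd = 0, baseline_sd = 0,
                        nonresponder_fraction = 0.3),
    het = heterogeneity_spec(bpac_cv = 0), seed = 8, chains = list())
  tab <- gen$table
  expect_gt(sum(!tab$responder) / nrow(tab), 0)
  flat_ids <- unique(tab$cell_id[!tab$responder])
  for (id in flat_ids[1:2]) {
    tr <- tab[tab$cell_id == id, ]
    expect_lt(diff(range(tr$ktr_nc)), 1e-9)
  }
  # metrics flag them invalid
  m <- pulse_metrics_table(tab[!tab$responder, ],
                           protocol = two_pulse_protocol(),
                           signal = "ktr_nc",
                           eps = 0.01 * diff(range(tab$ktr_nc)))
  expect_true(all(!m$valid))
})

test_that("amplitude variability dominates and peak-normalizing removes it", {
  co <- gain_cohort(n_cells = 40, gain_cv = 0.3, noise_sd = 0.002, seed = 5)
  raw <- shift_traces(co$traces, co$time, co$protocol, 1)
  for (k in 1:2) {
    nz <- peak_normalize(co$traces, co$time, co$protocol, pulse_index = k)
    # rescale to comparable units before comparing spread
    scale_back <- mean(apply(raw[co$time >= co$windows$t_on[k] &
                                   co$time <= co$windows$t_off[k], ],
                             2, max))
    sd_raw <- in_pulse_sd(raw, co$time, co$windows, k)
    sd_norm <- in_pulse_sd(nz * scale_back, co$time, co$windows, k)
    expect_gt(sd_raw / sd_norm, 5)
    # the chosen pulse is constrained more than the other pulse
    other <- 3 - k
    expect_lt(in_pulse_sd(nz, co$time, co$windows, k),
              in_pulse_sd(nz, co$time, co$windows, other))
  }
})

test_that("the canonical fixture suite is complete and reproducible", {
  d1 <- tempfile("fx1")
  man1 <- make_fixture_suite(seed = 1, dir = d1)
  expect_gte(nrow(man1), 12)
  for (nm in man1$name) {
    expect_true(file.exists(file.path(d1, paste0(nm, ".tsv"))))
    expect_true(file.exists(file.path(d1, paste0(nm, ".json"))))
  }
  d2 <- tempfile("fx2")
  man2 <- make_fixture_suite(seed = 1, dir = d2)
  expect_equal(man1$checksum, man2$checksum)
  # end-to-end: the delayed-regulation fixture shows an overshooting
  # emitter with non-overshooting adjacent receivers
  tab <- read_trace_table(file.path(d1, "fig5I_delayed.tsv"))
  m <- pulse_metrics_table(tab, protocol = two_pulse_protocol())
  m1 <- m[m$pulse_index == 1, ]
  em <- m1[m1$role == "emitter", ]
  expect_true(is_overshooting(em$overshoot_ratio))
  g <- build_scenario("single_emitter_cluster", seed = 1)
  adj <- which(emitter_distance(g) == 1) - 1L
  expect_true(all(!is_overshooting(
    m1$overshoot_ratio[m1$cell_id %in% adj])))
})
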