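test_that("PKA activation is a Hill function of cAMP", {
  p <- intracellular_params(k_pka = 0.7, n_pka = 2)
  expect_equal(pka_activity(0, p), 0)
  expect_equal(pka_activity(0.7, p), 0.5)
  expect_lt(abs(pka_activity(1e6 * 0.7, p) - 1), 1e-6)
  camp <- seq(0, 5, by = 0.1)
  expect_false(is.unsorted(pka_activity(camp, p)))
  expect_error(pka_activity(-1, p), "camp")
})

test_that("cAMP derivative decomposes into its production/decay/flux terms", {
  proto <- one_pulse_protocol(amplitude = 1, on = 40, lead = 0, tail = 0)
  s <- c(camp = 0.4, pka = 0.1, erk = 0.8, ktr_nuc = 0.2, ktr_cyt = 0.8,
         pde_act = 0)
  # forced balance: no degradation, no basal -> production only
  p <- intracellular_params(gamma_pde = 0, beta_b = 0.3)
  d <- intracellular_derivatives(s, 10, p, proto, bpac_level = 2)
  expect_equal(unname(d["camp"]), 0.3 * 2)
  # dark, no production: derivative equals the influx exactly
  p2 <- intracellular_params(beta_b = 0.3)
  s2 <- s; s2["camp"] <- 0
  d2 <- intracellular_derivatives(s2, 50, p2, proto, camp_influx = 0.123)
  expect_equal(unname(d2["camp"]), 0.123)
  # KTR pool closed: nuclear and cytosolic derivatives cancel
  expect_equal(unname(d["ktr_nuc"] + d["ktr_cyt"]), 0)
  expect_error(intracellular_derivatives(replace(s, 1, -1), 0, p, proto),
               "invalid state")
})

test_that("dark pre-equilibration reaches a true steady state", {
  proto <- light_protocol(data.frame(), t_end = 10)
  p <- intracellular_params(beta_0 = 0.03)
  tr <- simulate_single_cell(p, proto)
  end <- nrow(tr)
  s <- c(camp = tr$camp[end], pka = tr$pka_on[end], erk = tr$erk_active[end],
         ktr_nuc = tr$ktr_nuc[end], ktr_cyt = tr$ktr_cyt[end],
         pde_act = tr$pka_on[end])
  d <- intracellular_derivatives(s, 5, p, proto)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("step input drives cAMP to its closed-form steady state", {
  proto <- one_pulse_protocol(amplitude = 1, on = 400, lead = 0, tail = 0)
  p <- intracellular_params(beta_b = 0.3, gamma_pde = 0.3, beta_0 = 0)
  tr <- simulate_single_cell(p, proto)
  expect_lt(abs(tr$camp[nrow(tr)] - 0.3 / 0.3), 1e-5)
})

test_that("PDE inhibition slows the post-pulse reporter turn-off", {
  proto <- two_pulse_protocol()
  wt <- simulate_single_cell(intracellular_params(), proto)
  ib <- simulate_single_cell(intracellular_params(), proto,
                             pharm = pharmacology("IBMX"))
  expect_gt(half_decay_time(ib$time, ib$ktr_nc, 40, 80),
            half_decay_time(wt$time, wt$ktr_nc, 40, 80))
})

test_that("a 6-min pulse gives an over-damped rise with no overshoot", {
  proto <- one_pulse_protocol(amplitude = 1, on = 6, lead = 15, tail = 45)
  tr <- simulate_single_cell(intracellular_params(), proto)
  m <- compute_pulse_metrics(tr$time, tr$ktr_nc, 15, 21, proto$t_end)
  expect_lte(m$overshoot_ratio, 1.1)
})

test_that("reporter steady-state response is monotone in pulse amplitude", {
  dnc <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    pr <- one_pulse_protocol(amplitude = a, on = 40, lead = 40, tail = 10)
    tr <- simulate_single_cell(intracellular_params(), pr)
    tr$ktr_nc[tr$time == 80] - tr$ktr_nc[tr$time == 40]
  }, numeric(1))
  expect_false(is.unsorted(dnc))
})

test_that("doubling expression is equivalent to doubling light amplitude", {
  p <- intracellular_params()
  hi_b <- simulate_single_cell(p, one_pulse_protocol(amplitude = 0.5),
                               bpac_level = 2)
  hi_u <- simulate_single_cell(p, one_pulse_protocol(amplitude = 1),
                               bpac_level = 1)
  expect_equal(hi_b$camp, hi_u$camp, tolerance = 1e-8)
})

test_that("ERK-KTR pool is conserved along simulated traces", {
  tr <- simulate_single_cell(intracellular_params(), two_pulse_protocol())
  expect_lt(max(abs(tr$ktr_nuc + tr$ktr_cyt - 1)), 1e-9)
})
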