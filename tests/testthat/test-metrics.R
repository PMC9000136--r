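test_that("pulse metrics reproduce analytic toy signals", {
  # rises to 2 at t=10, settles to 1 by t=20, flat to t=40
  tm <- 0:40
  sig <- approx(c(0, 10, 20, 40), c(0, 2, 1, 1), xout = tm)$y
  m <- compute_pulse_metrics(tm, sig, t_on = 0, t_off = 40)
  expect_equal(m$overshoot_ratio, 2)
  expect_equal(m$time_to_max, 10)
  expect_equal(m$s_start, 0)
  expect_equal(m$s_end, 1)
  expect_true(m$valid)
  # monotone saturating signal: ratio 1 and time_to_ss = time_to_max
  sat <- 1 - exp(-tm / 6)
  ms <- compute_pulse_metrics(tm, sat, 0, 40)
  expect_equal(ms$overshoot_ratio, 1)
  expect_equal(ms$time_to_ss, ms$time_to_max)
  # degenerate: no net response
  flat <- c(rep(0, 20), rep(0.001, 21))
  mf <- compute_pulse_metrics(tm, flat, 0, 40, eps = 0.01)
  expect_false(mf$valid)
  expect_true(is.na(mf$overshoot_ratio))
})

test_that("metrics equal a brute-force index-scan oracle on random signals", {
  set.seed(42)
  tm <- seq(0, 120, by = 3)
  for (i in 1:200) {
    knots <- sort(c(0, 120, runif(6, 0, 120)))
    sig <- approx(knots, rnorm(length(knots)), xout = tm)$y
    m <- compute_pulse_metrics(tm, sig, t_on = 15, t_off = 75,
                               off_end = 120, eps = 0)
    o <- oracle_pulse_metrics(tm, sig, 15, 75, 120)
    expect_equal(m$s_start, o$s_start)
    expect_equal(m$s_max, o$s_max)
    expect_equal(m$time_to_max, o$time_to_max)
    expect_equal(m$time_to_ss, o$time_to_ss)
    expect_equal(m$overshoot_ratio, o$overshoot_ratio)
    expect_equal(m$undershoot_depth, o$undershoot_depth)
  }
})

test_that("metrics are invariant to affine rescaling of the signal", {
  set.seed(7)
  tm <- seq(0, 80, by = 2)
  sig <- cumsum(rnorm(length(tm)))
  m1 <- compute_pulse_metrics(tm, sig, 10, 60, 80, eps = 0)
  m2 <- compute_pulse_metrics(tm, 3.7 * sig + 11, 10, 60, 80, eps = 0)
  expect_equal(m2$overshoot_ratio, m1$overshoot_ratio)
  expect_equal(m2$time_to_max, m1$time_to_max)
  expect_equal(m2$time_to_ss, m1$time_to_ss)
})

test_that("time-to-max takes the earliest sample attaining the maximum", {
  tm <- 0:10
  sig <- c(0, 1, 5, 2, 5, 5, 3, 2, 2, 2, 2)
  m <- compute_pulse_metrics(tm, sig, 0, 10)
  expect_equal(m$time_to_max, 2)
})

test_that("shifting zeroes every trace at the pulse onset", {
  proto <- two_pulse_protocol()
  tg <- seq(0, 200, by = 3)
  traces <- cbind(rep(5, length(tg)), sin(tg / 10) + 2)
  sh <- shift_traces(traces, tg, proto, pulse_index = 1)
  i_on <- which(tg >= 40)[1]
  expect_equal(unname(sh[i_on, ]), c(0, 0))
  expect_equal(sh[, 1], rep(0, length(tg)))  # constant trace -> all zeros
  expect_equal(apply(sh, 1, sd)[i_on], 0)
  # already-zero-at-onset trace is unchanged
  z <- traces[, 2, drop = FALSE] - traces[i_on, 2]
  expect_equal(shift_traces(z, tg, proto, 1), z)
})

test_that("peak normalization equalises amplitude-scaled copies", {
  co <- gain_cohort(n_cells = 30, gain_cv = 0.4, noise_sd = 0)
  nz <- peak_normalize(co$traces, co$time, co$protocol, pulse_index = 1)
  sel <- co$time > co$windows$t_on[1] & co$time <= co$windows$t_off[1]
  expect_lt(max(apply(nz[sel, ], 1, sd)), 1e-9)
  peaks <- apply(nz[sel, ], 2, max)
  expect_equal(unname(peaks), rep(1, ncol(nz)))
  # flat traces are excluded with a warning
  tr2 <- co$traces
  tr2[, 1] <- 0.2
  expect_warning(out <- peak_normalize(tr2, co$time, co$protocol, 1),
                 "excluded")
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("segment-wise population statistics match a direct computation", {
  proto <- two_pulse_protocol()
  tg <- seq(0, 200, by = 4)
  set.seed(11)
  traces <- matrix(rnorm(length(tg) * 8), ncol = 8)
  ms <- population_mean_sd(traces, tg, proto, shift = FALSE)
  i <- which(ms$time == 48)
  expect_equal(ms$mean[i], mean(traces[which(tg == 48), ]))
  expect_equal(ms$sd[i], sd(traces[which(tg == 48), ]))
  # identical traces -> sd 0; f and -f -> mean 0
  same <- cbind(sin(tg / 9), sin(tg / 9))
  expect_true(all(population_mean_sd(same, tg, proto,
                                     shift = FALSE)$sd == 0))
  pm <- population_mean_sd(cbind(sin(tg / 9), -sin(tg / 9)), tg, proto,
                           shift = FALSE)
  expect_lt(max(abs(pm$mean)), 1e-12)
  expect_error(population_mean_sd(traces[, 1, drop = FALSE], tg, proto),
               ">= 2 traces")
})
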