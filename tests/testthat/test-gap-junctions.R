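test_that("delay-chain derivatives implement the closed activation chain", {
  p <- delay_chain_params(tau_gj = 12, n_steps = 3, gamma_gj = 0.2,
                          k_act = 0.5)
  pool <- list(gj_na = 0.4, gj_d = c(0.1, 0.2, 0.05), gj_ca = 0.25)
  d <- delay_chain_derivatives(pool, pka_on = 0.6, p)
  r <- 3 / 12
  expect_equal(d$gj_na, 0.2 * 0.25 - 0.5 * 0.6 * 0.4)
  expect_equal(d$gj_d[1], 0.5 * 0.6 * 0.4 - r * 0.1)
  expect_equal(d$gj_d[2], r * (0.1 - 0.2))
  expect_equal(d$gj_ca, r * 0.05 - 0.2 * 0.25)
  # closed chain: derivatives sum to zero exactly
  expect_equal(d$gj_na + sum(d$gj_d) + d$gj_ca, 0)
  # no driving
  p0 <- delay_chain_params(gamma_gj = 0)
  still <- delay_chain_derivatives(list(gj_na = 1, gj_d = rep(0, 4),
                                        gj_ca = 0), 0, p0)
  expect_true(all(unlist(still) == 0))
  # flow direction out of the inactive pool only
  flow <- delay_chain_derivatives(list(gj_na = 1, gj_d = rep(0, 4),
                                       gj_ca = 0), 1, p0)
  expect_lt(flow$gj_na, 0)
  expect_gt(flow$gj_d[1], 0)
  expect_equal(flow$gj_d[-1], rep(0, 3))
  expect_error(delay_chain_derivatives(list(gj_na = 1, gj_d = 0,
                                            gj_ca = 0), 0, p0), "n_steps")
})

test_that("integrated chain matches the Erlang closed form", {
  tg <- seq(0, 60, by = 0.5)
  for (N in c(1, 4, 7, 50)) {
    p <- delay_chain_params(tau_gj = 15, n_steps = N, gamma_gj = 0,
                            k_act = 0)
    out <- simulate_delay_chain(p, list(gj_na = 0,
                                        gj_d = c(1, rep(0, N - 1)),
                                        gj_ca = 0), tg)
    expect_lt(max(abs(out$gj_ca - delay_chain_response(p, 1, tg))), 1e-4)
    expect_lt(max(abs(out$total - 1)), 1e-9)
  }
})

test_that("closed form reproduces the printed single-step and switch limits", {
  p1 <- delay_chain_params(tau_gj = 15, n_steps = 1, gamma_gj = 0)
  expect_equal(delay_chain_response(p1, 1, 15), 1 - exp(-1))
  expect_equal(delay_chain_response(p1, 2, c(0, 30)),
               c(0, 2 * (1 - exp(-2))))
  # large N approaches the perfect-delay step; transit sd is tau/sqrt(N)
  p400 <- delay_chain_params(tau_gj = 15, n_steps = 400, gamma_gj = 0)
  expect_lt(delay_chain_response(p400, 1, 15 - 1.5), 0.05)
  expect_gt(delay_chain_response(p400, 1, 15 + 1.5), 0.95)
  p2500 <- delay_chain_params(tau_gj = 15, n_steps = 2500, gamma_gj = 0)
  expect_lt(delay_chain_response(p2500, 1, 14.5), 0.05)
  expect_gt(delay_chain_response(p2500, 1, 15.5), 0.95)
  expect_error(delay_chain_response(p1, 1, -1), "t must be")
  expect_error(delay_chain_response(delay_chain_params(gamma_gj = 0.1),
                                    1, 1), "gamma_gj")
})

test_that("activation-time dispersion strictly decreases with N", {
  iqr <- vapply(c(1, 2, 4, 7, 20, 50), function(N) {
    r <- N / 15
    stats::qgamma(0.75, N, r) - stats::qgamma(0.25, N, r)
  }, numeric(1))
  expect_true(all(diff(iqr) < 0))
})

test_that("chain mass is conserved under an arbitrary PKA drive", {
  p <- delay_chain_params(tau_gj = 10, n_steps = 5, gamma_gj = 0.1,
                          k_act = 0.8)
  drive <- function(t) 0.5 * (1 + sin(t / 7))
  out <- simulate_delay_chain(p, list(gj_na = 0.7, gj_d = rep(0.02, 5),
                                      gj_ca = 0.2),
                              seq(0, 120, by = 1), pka_fun = drive)
  expect_lt(max(abs(out$total - 1)) / 1, 1e-9)
})

test_that("effective permeability follows the interface formula", {
  cp <- coupling_params(k_gj = 0.05, k_gj_gjf = 1)
  # basal term only
  expect_equal(effective_permeability(0, 0, 5, 5, cp), 0.05)
  # uncoupled interface
  expect_equal(effective_permeability(3, 2, 5, 4, cp, omega_ij = 0), 0)
  # symmetry under swapping the two cells
  r1 <- effective_permeability(0.8, 0.1, 6, 4, cp)
  r2 <- effective_permeability(0.1, 0.8, 4, 6, cp)
  expect_equal(r1, r2)
  # explicit value: p_bar * x_f^3 = 1 with the default normalisation
  expect_equal(r1, 0.05 + 0.8 / 6 + 0.1 / 4)
  # scales multiply through
  expect_equal(effective_permeability(0.8, 0.1, 6, 4, cp,
                                      pharm_coupling_scale = 0.2),
               0.2 * r1)
  expect_error(effective_permeability(0, 0, 0, 5, cp), "neighbour")
})

test_that("pairwise flux is proportional to the gradient and antisymmetric", {
  expect_equal(camp_flux(1, 1, 0.7), 0)
  expect_equal(camp_flux(1, 2, 1), 1)
  set.seed(1)
  ci <- runif(50); cj <- runif(50); rho <- runif(50)
  expect_equal(camp_flux(ci, cj, rho), -camp_flux(cj, ci, rho))
  expect_error(camp_flux(1, 2, -0.1), "rho")
})
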