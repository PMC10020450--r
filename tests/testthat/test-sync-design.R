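test_that("two-node loop with zero lag solves exactly", {
  set.seed(1)
  spec <- build_sync_couplings(2, gamma0 = 0.3)
  expect_equal(spec$coupling_w[1, 2], 0.3, tolerance = 1e-14)
  expect_equal(spec$coupling_w[2, 1], 0.3, tolerance = 1e-14)
  expect_equal(spec$coupling_delta[1, 2], 0)
  expect_equal(spec$coupling_delta[2, 1], 0)
})

test_that("a single mode is structurally infeasible", {
  expect_error(build_sync_couplings(1, gamma0 = 0.5), "infeasible")
})

test_that("built couplings satisfy both row conditions across sizes and seeds", {
  for (n in c(2, 3, 5, 10)) {
    # drive scaled to the row capacity (n-1 links of magnitude <= 0.2)
    g0 <- if (n == 2) 0.3 else 0.1 * (n - 1)
    for (s in 1:25) {
      spec <- build_sync_couplings(n, gamma0 = g0, seed = s)
      ver <- verify_sync_conditions(spec)
      expect_lt(max(abs(ver$amp_residual)), 1e-10)
      expect_lt(max(abs(ver$phase_residual)), 1e-10)
      expect_true(all(spec$coupling_w >= 0))
    }
  }
})

test_that("verification reports the drive as residual for empty couplings", {
  p <- mode_params()
  z <- network_spec(list(p, p, p), matrix(0, 3, 3), matrix(0, 3, 3))
  ver <- verify_sync_conditions(z, gamma0 = 0.7)
  expect_equal(abs(ver$amp_residual), rep(0.7, 3))
  expect_equal(ver$phase_residual, rep(0, 3))
})

test_that("verification matches direct summation on a hand-built case", {
  p <- mode_params()
  W <- matrix(c(0, 0.2, 0.1,
                0.3, 0, 0.4,
                0.1, 0.1, 0), 3, 3, byrow = TRUE)
  D <- matrix(c(0, 0.5, -0.3,
                1.0, 0, 0.2,
                -0.7, 0.4, 0), 3, 3, byrow = TRUE)
  spec <- network_spec(list(p, p, p), W, D)
  ver <- verify_sync_conditions(spec, gamma0 = 0.25)
  for (i in 1:3) {
    expect_equal(ver$amp_residual[i], sum(W[i, ] * cos(D[i, ])) - 0.25)
    expect_equal(ver$phase_residual[i], sum(W[i, ] * sin(D[i, ])))
  }
})

test_that("frequency prediction flags supercritical and inconsistent specs", {
  # zero coupling, no drive: omega_s equals each mode's linear frequency
  ps <- list(mode_params(omega = 0.8), mode_params(omega = 1.3))
  z <- network_spec(ps, matrix(0, 2, 2), matrix(0, 2, 2))
  pred <- predict_network_frequency(z)
  expect_equal(pred$omega_s_pred, c(0.8, 1.3))
  expect_false(pred$consistent[1])   # two different predictions
  # a homogeneous loop predicts the driven single-mode frequency everywhere
  set.seed(2)
  spec <- build_sync_couplings(5, gamma0 = 1.8, w_range = c(0, 0.6))
  pred <- predict_network_frequency(spec)
  expect_equal(pred$omega_s_pred, rep(sqrt(0.19), 5), tolerance = 1e-10)
  expect_true(all(pred$consistent))
  # supercritical effective drive is flagged, not raised
  spec2 <- build_sync_couplings(5, gamma0 = 2.5, w_range = c(0, 0.9))
  pred2 <- predict_network_frequency(spec2)
  expect_true(all(pred2$supercritical))
  expect_true(all(is.na(pred2$omega_s_pred)))
})

test_that("heterogeneous tuning equalizes predicted frequencies", {
  modes <- list(mode_params(omega = 0.8, gamma0 = 0.9),
                mode_params(omega = 1.4, gamma0 = 0.9),
                mode_params(omega = 1.1, gamma0 = 0.9))
  spec <- heterogeneous_tune(modes, omega_s_target = 0.85, w_range = c(0, 0.6),
                             seed = 4)
  pred <- predict_network_frequency(spec)
  expect_equal(pred$omega_s_pred, rep(0.85, 3), tolerance = 1e-8)
  expect_true(all(pred$consistent))
  # identical modes with their natural target reduce to the homogeneous rows
  same <- list(mode_params(gamma0 = 1), mode_params(gamma0 = 1),
               mode_params(gamma0 = 1))
  nat <- sqrt(1 - (1 * 0.5)^2)
  spec2 <- heterogeneous_tune(same, omega_s_target = nat, w_range = c(0, 0.6),
                              seed = 4)
  ver <- verify_sync_conditions(spec2, gamma0 = 1, phase_target = 0)
  expect_lt(max(abs(ver$amp_residual)), 1e-10)
  expect_lt(max(abs(ver$phase_residual)), 1e-10)
})

test_that("unreachable targets raise an infeasibility error listing modes", {
  modes <- list(mode_params(omega = 1, gamma0 = 0.5),
                mode_params(omega = 1, gamma0 = 0.5))
  expect_error(heterogeneous_tune(modes, omega_s_target = 5),
               "infeasible.*mode")
})

test_that("a two-node memory loop replicates the driven single mode", {
  # the loop's coupling feeds back exactly the drive gamma0 = 1.8; with
  # identical initial conditions its modes reduce to the driven single mode
  drive <- 1.8
  single <- integrate_mode(mode_params(gamma = drive), t_end = 180)
  ws_single <- measured_frequency(single)
  set.seed(6)
  loop <- build_sync_couplings(2, gamma0 = drive, w_range = c(0, 2))
  tr <- integrate_network(loop, t_end = 180)
  rep <- sync_metrics(tr)
  ws_loop <- mean(rep$frequencies$omega_s_hat)
  expect_lt(abs(ws_loop - ws_single) / ws_single, 0.02)
})

test_that("tuned ten-mode networks lock tightly at a common frequency", {
  spec <- sync_demo_network("subcritical", seed = 2)
  set.seed(20)
  init <- list(amplitude = rep(1e-3, 10), phase = runif(10, -pi, pi))
  tr <- integrate_network(spec, init = init, t_end = 120, dt_out = 0.05)
  g <- glance(sync_metrics(tr))
  expect_lt(g$freq_spread, 0.02)
  expect_lt(g$max_offset_frac, 0.05)
  # replication: the common frequency matches a single mode driven at the
  # loop's effective parameters (gamma_bar = 1, omega_bar = 1)
  single <- integrate_mode(mode_params(gamma = 1), t_end = 120)
  ws_single <- measured_frequency(single)
  expect_lt(abs(2 * pi / g$common_period - ws_single) / ws_single, 0.02)
})
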