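test_that("mode_rhs evaluates the printed right-hand sides exactly", {
  p <- mode_params(gamma = 0.7, gamma0 = 0.3)
  # origin is a fixed point of the amplitude with free phase rotation
  expect_equal(unname(mode_rhs(c(0, 1.3), p)), c(0, p$omega))
  # A = 1, phi = psi: cos(0) = 1
  expect_equal(mode_rhs(c(1, p$psi), p)[["dA"]],
               (p$gamma + p$gamma0) + (p$w_a - p$alpha))
  # randomized states against an independent re-evaluation of the formulas
  set.seed(7)
  for (i in 1:30) {
    q <- random_mode_params()
    A <- runif(1, 0, 2); phi <- runif(1, -10, 10)
    got <- mode_rhs(c(A, phi), q)
    g <- q$gamma + q$gamma0
    expect_equal(got[["dA"]],
                 g * A + A^2 * (q$w_a * cos(phi - q$psi) - q$alpha))
    expect_equal(got[["dphi"]], q$omega + A * q$w_phi * cos(phi))
  }
})

test_that("damped modes decay and supercritical modes spike at most once", {
  # net damping: amplitude decays monotonically after a short transient
  traj <- integrate_mode(mode_params(gamma = -0.5), init = c(0.1, 0), t_end = 30)
  late <- traj$amplitude[traj$time > 5]
  expect_true(all(diff(late) <= 1e-12))
  expect_lt(late[length(late)], 1e-3)

  # c_r = 1.2: a single spike-like transition followed by silence
  p <- mode_params(gamma = 1.2 * 2)   # gamma_c = 2
  traj <- integrate_mode(p, t_end = 50 * 2 * pi)
  spk <- detect_spikes(traj, refractory = 0)
  expect_lte(nrow(spk), 1)
  # the mode locks: phase stops advancing
  ph <- traj$phase[traj$time > 200]
  expect_lt(diff(range(ph)), 0.01)
})

test_that("spiking onset sits at the closed-form critical rate", {
  # just below gamma_c the mode still spikes repeatedly; just above it locks
  gamma_c <- critical_thresholds(mode_params(gamma = 1))[["gamma_c"]]
  below <- integrate_mode(mode_params(gamma = 0.97 * gamma_c), t_end = 500)
  ph_below <- below$phase[below$time > 250]
  expect_gt(diff(range(ph_below)), 4 * pi)  # keeps rotating
  above <- integrate_mode(mode_params(gamma = 1.03 * gamma_c), t_end = 500)
  ph_above <- above$phase[above$time > 250]
  expect_lt(diff(range(ph_above)), 0.01)    # locked
})

test_that("measured frequency tracks the closed form at low criticality", {
  # weak drive: amplitude is nearly pinned and the closed form is accurate
  p <- mode_params(gamma = 0.1 * 2)
  traj <- integrate_mode(p, t_end = 260)
  ws <- measured_frequency(traj)
  expect_lt(abs(ws - effective_frequency(p)) / effective_frequency(p), 0.03)
})

test_that("polar and complex-form integrations agree for general parameters", {
  set.seed(11)
  for (i in 1:3) {
    p <- random_mode_params()
    p$gamma <- min(p$gamma + p$gamma0, 0.8 * critical_thresholds(p)[["gamma_c"]])
    p$gamma0 <- 0
    polar <- integrate_mode(p, init = c(1e-3, 0.4), t_end = 40)
    cart <- integrate_complex_mode(as_complex_params(p),
                                   init = 1e-3 * exp(0.4i), t_end = 40)
    expect_lt(max(abs(polar$amplitude - cart$amplitude)), 1e-4)
    expect_lt(max(abs(polar$phase - cart$phase)), 1e-4)
  }
})

test_that("complex-form limits: harmonic rotation and pure exponential decay", {
  cp <- complex_mode_params(Gamma = 2i)
  traj <- integrate_complex_mode(cp, init = 0.5 + 0i, t_end = 20)
  expect_equal(traj$amplitude, rep(0.5, nrow(traj)), tolerance = 1e-7)
  expect_equal(traj$phase, 2 * traj$time, tolerance = 1e-6)

  cp <- complex_mode_params(Gamma = -0.3 + 0i)
  traj <- integrate_complex_mode(cp, init = 1 + 0i, t_end = 10)
  expect_equal(traj$amplitude, exp(-0.3 * traj$time), tolerance = 1e-7)
})

test_that("phase wrap and unwrap are mutually consistent", {
  phi <- cumsum(runif(200, -0.4, 0.9))
  w <- wrap_phase(phi)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(unwrap_phase(w) - unwrap_phase(w)[1], phi - phi[1],
               tolerance = 1e-12)
})

test_that("LIF baseline: fixed points, threshold behavior, closed-form period", {
  lif <- lif_params(tau_m = 0.8, U_rest = -0.2, R = 1.5, Theta = 1)
  # no input: flat at rest
  out <- integrate_lif(lif, I = 0, t_end = 5)
  expect_equal(out$trace$voltage, rep(-0.2, nrow(out$trace)))
  expect_length(out$spike_times, 0)
  # subthreshold: relaxes to U_rest + R I, never spikes
  I_sub <- (lif$Theta - lif$U_rest) / lif$R * 0.9
  out <- integrate_lif(lif, I = I_sub, t_end = 10)
  expect_length(out$spike_times, 0)
  expect_equal(out$trace$voltage[nrow(out$trace)],
               lif$U_rest + lif$R * I_sub, tolerance = 1e-3)
  # suprathreshold: periodic with the first-passage period
  I_sup <- (lif$Theta - lif$U_rest) / lif$R * 1.5
  out <- integrate_lif(lif, I = I_sup, t_end = 30, dt = 5e-4)
  gaps <- diff(out$spike_times)
  expect_gt(length(gaps), 5)
  expect_equal(median(gaps), lif_period(lif, I_sup), tolerance = 1e-3)
})
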