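single_mode_net <- function(p) {
  network_spec(list(p), matrix(0, 1, 1), matrix(0, 1, 1))
}

test_that("network_rhs with one mode is bit-identical to mode_rhs", {
  set.seed(3)
  for (i in 1:10) {
    p <- random_mode_params()
    state <- c(runif(1, 0, 2), runif(1, -5, 5))
    expect_identical(unname(network_rhs(state, single_mode_net(p))),
                     unname(mode_rhs(state, p)))
  }
})

test_that("zero coupling leaves modes independent", {
  ps <- list(mode_params(gamma = 1.0), mode_params(gamma = 1.4, omega = 1.3),
             mode_params(gamma = 0.6, omega = 0.8))
  net <- network_spec(ps, matrix(0, 3, 3), matrix(0, 3, 3))
  tr <- integrate_network(net, t_end = 40)
  for (m in 1:3) {
    solo <- integrate_mode(ps[[m]], t_end = 40)
    sub <- tr[tr$mode == m, ]
    expect_lt(max(abs(sub$amplitude - solo$amplitude)), 1e-5)
    expect_lt(max(abs(sub$phase - solo$phase)), 1e-5)
  }
})

test_that("aligned phases make a link purely excitatory", {
  p <- mode_params(gamma = 0.5)
  W <- matrix(c(0, 0.3, 0.2, 0), 2, 2, byrow = TRUE)
  D <- matrix(c(0, 0.7, -0.4, 0), 2, 2, byrow = TRUE)
  net <- network_spec(list(p, p), W, D)
  # choose phases so that phi_2 - phi_1 - delta_12 = 0
  phi1 <- 0.3; phi2 <- phi1 + D[1, 2]
  A <- c(0.8, 0.5)
  rhs <- network_rhs(c(A, phi1, phi2), net)
  base <- mode_rhs(c(A[1], phi1), p)
  expect_equal(rhs[1], base[["dA"]] + W[1, 2] * A[2])        # cos 0 = 1
  expect_equal(rhs[3], base[["dphi"]])                       # sin 0 = 0
})

test_that("constant-amplitude limit reduces to sin-coupled phase oscillators", {
  set.seed(5)
  n <- 4
  spec <- random_network(n, seed = 5, gamma = 0.2)
  A <- rep(0.37, n)                   # clamped common amplitude
  phi <- runif(n, -pi, pi)
  rhs <- network_rhs(c(A, phi), spec)
  om <- vapply(spec$modes, `[[`, numeric(1), "omega")
  wp <- vapply(spec$modes, `[[`, numeric(1), "w_phi")
  kuramoto <- vapply(seq_len(n), function(i) {
    om[i] + A[i] * wp[i] * cos(phi[i]) +
      sum(spec$coupling_w[i, ] * sin(phi - phi[i] - spec$coupling_delta[i, ]))
  }, numeric(1))
  expect_equal(rhs[n + seq_len(n)], kuramoto, tolerance = 1e-14)
})

test_that("identical uncoupled copies produce identical traces", {
  p <- mode_params(gamma = 1.8)
  n <- 4
  net <- network_spec(replicate(n, p, simplify = FALSE),
                      matrix(0, n, n), matrix(0, n, n))
  tr <- integrate_network(net, t_end = 60)
  wide <- tidyr::pivot_wider(tibble::as_tibble(tr)[c("time", "mode", "amplitude")],
                             names_from = "mode", values_from = "amplitude")
  for (m in 2:n) expect_equal(wide[[m + 1]], wide[[2]], tolerance = 1e-10)
})

test_that("polar and Cartesian network integrations agree", {
  # the exported polar RHS and the internal Cartesian integrator describe
  # the same dynamics away from the amplitude floor
  spec <- sync_demo_network("subcritical", seed = 3, n = 5)
  tr <- integrate_network(spec, t_end = 30, dt_out = 0.01)
  rhs_fun <- function(t, y, p) list(network_rhs(y, spec))
  y0 <- c(rep(1e-3, 5), rep(0, 5))
  sol <- deSolve::ode(y0, seq(0, 30, 0.01), rhs_fun, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  for (m in 1:5) {
    expect_lt(max(abs(tr$amplitude[tr$mode == m] - sol[, 1 + m])), 1e-5)
  }
})

test_that("Hamiltonian evaluations match brute-force expansion", {
  cp <- complex_mode_params(Gamma = 0.4 + 1.2i, beta_a = 0.3 - 0.1i,
                            beta_adag = -0.2 + 0.5i, alpha_c = 1 + 0.2i)
  expect_equal(hamiltonian_single(0 + 0i, cp), 0 + 0i)
  cp0 <- complex_mode_params(Gamma = 0.4 + 1.2i)
  expect_equal(hamiltonian_single(0.3 - 0.7i, cp0),
               (0.4 + 1.2i) * Mod(0.3 - 0.7i)^2)
  set.seed(8)
  for (i in 1:10) {
    a <- complex(real = rnorm(1), imaginary = rnorm(1))
    got <- hamiltonian_single(a, cp)
    aa <- a * Conj(a)
    want <- cp$Gamma * aa +
      aa * (cp$beta_a * a + cp$beta_adag * Conj(a) - 2 * cp$alpha_c * sqrt(Re(aa)))
    expect_equal(got, want, tolerance = 1e-14)
  }
})

test_that("network Hamiltonian is additive and matches hand expansion", {
  cp <- complex_mode_params(Gamma = 0.4 + 1.2i, beta_a = 0.3 - 0.1i,
                            beta_adag = -0.2 + 0.5i, alpha_c = 1 + 0i)
  a <- c(0.4 + 0.2i, -0.3 + 0.6i)
  r0 <- matrix(0 + 0i, 2, 2)
  expect_equal(hamiltonian_network(a, cp, r0),
               hamiltonian_single(a[1], cp) + hamiltonian_single(a[2], cp))
  expect_equal(hamiltonian_network(c(0i, 0i), cp, r0), 0 + 0i)
  r <- matrix(c(0, 0.1 * exp(0.3i), 0.2 * exp(-0.5i), 0), 2, 2, byrow = TRUE)
  want <- hamiltonian_single(a[1], cp) + hamiltonian_single(a[2], cp) +
    a[1] * r[1, 2] * Conj(a[2]) + Conj(a[1]) * Conj(r[1, 2]) * a[2] +
    a[2] * r[2, 1] * Conj(a[1]) + Conj(a[2]) * Conj(r[2, 1]) * a[1]
  expect_equal(hamiltonian_network(a, cp, r), want, tolerance = 1e-14)
})

test_that("effective parameters match direct summation", {
  spec <- random_network(6, seed = 9, gamma = 0.3)
  eff <- effective_params(spec)
  for (i in 1:6) {
    expect_equal(eff$gamma_bar[i],
                 0.3 + sum(spec$coupling_w[i, ] * cos(spec$coupling_delta[i, ])))
    expect_equal(eff$omega_bar[i],
                 spec$modes[[i]]$omega -
                   sum(spec$coupling_w[i, ] * sin(spec$coupling_delta[i, ])))
  }
  # zero coupling: effective parameters are the bare ones
  z <- network_spec(spec$modes, matrix(0, 6, 6), matrix(0, 6, 6))
  effz <- effective_params(z)
  expect_equal(effz$gamma_bar, rep(0.3, 6))
  expect_equal(effz$omega_bar, vapply(spec$modes, `[[`, numeric(1), "omega"))
})

test_that("network spec validation catches shape and sign violations", {
  p <- mode_params()
  expect_error(network_spec(list(p, p), matrix(0, 3, 3), matrix(0, 3, 3)),
               "2 x 2")
  W <- matrix(0.1, 2, 2)
  expect_error(network_spec(list(p, p), W, matrix(0, 2, 2)), "diagonal")
  W <- matrix(c(0, -0.1, 0.1, 0), 2, 2)
  expect_error(network_spec(list(p, p), W, matrix(0, 2, 2)), ">= 0")
})
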