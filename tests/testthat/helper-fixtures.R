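# shared fixtures and small utilities for the suite

ref_params <- function(gamma = 0, ...) mode_params(gamma = gamma, ...)

# random valid mode parameters (alpha comfortably above |w_a sin psi|)
random_mode_params <- function() {
  w_a <- runif(1, 0, 3)
  psi <- runif(1, -pi, pi)
  mode_params(
    gamma = runif(1, -1, 2),
    omega = runif(1, 0.2, 3),
    alpha = abs(w_a * sin(psi)) + runif(1, 0.3, 3),
    psi = psi,
    w_a = w_a,
    w_phi = runif(1, 0, 3),
    gamma0 = runif(1, 0, 1)
  )
}

# measured post-transient effective frequency of a single-mode trajectory
measured_frequency <- function(traj, transient_frac = 0.25) {
  t_end <- max(traj$time)
  late <- traj[traj$time >= transient_frac * t_end, ]
  attr(late, "params") <- NULL
  est <- estimate_effective_frequency(detect_spikes(late))
  est$omega_s_hat[1]
}

# synthetic periodic pulse train: smooth bumps of period `period`
pulse_trajectory <- function(period = 5, n_pulses = 10, dt = 0.01) {
  t_end <- period * (n_pulses + 0.5)
  tt <- seq(0, t_end, by = dt)
  centers <- period * (seq_len(n_pulses) - 0.25)
  amp <- rowSums(vapply(centers,
                        function(c0) exp(-((tt - c0) / (period / 12))^2),
                        numeric(length(tt))))
  tibble::tibble(time = tt, mode = 1L, amplitude = amp, phase = 0)
}

# two orthogonal 7x7 prototypes and a tiny labeled dataset around them
orthogonal_patterns <- function(n_per_class = 2) {
  a <- matrix(0, 7, 7); a[, 1:3] <- 1
  b <- matrix(0, 7, 7); b[, 5:7] <- 1
  tibble::tibble(
    id = seq_len(2 * n_per_class),
    class = rep(0:1, each = n_per_class),
    split = "train",
    pattern = c(replicate(n_per_class, a, simplify = FALSE),
                replicate(n_per_class, b, simplify = FALSE))
  )
}
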