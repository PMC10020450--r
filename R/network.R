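#' Wave-mode network specification
#'
#' A directed network of amplitude-phase modes.  Mode `i` receives from mode
#' `j` the amplitude input \eqn{w_{ij} A_j \cos(\phi_j - \phi_i -
#' \delta_{ij})} and the phase input \eqn{w_{ij} (A_j/A_i) \sin(\phi_j -
#' \phi_i - \delta_{ij})}; the phase difference dynamically decides whether
#' the link acts excitatory (difference within \eqn{\pm\pi/2}) or
#' inhibitory.
#'
#' @param modes List of [mode_params()] objects, one per node.
#' @param coupling_w N x N matrix of nonnegative coupling magnitudes
#'   \eqn{w_{ij}}, zero diagonal.
#' @param coupling_delta N x N matrix of phase offsets \eqn{\delta_{ij}} in
#'   \eqn{(-\pi, \pi]}.
#' @param directed Couplings need not be symmetric; set `FALSE` to assert
#'   symmetry at construction.
#' @param seed Optional integer recorded for provenance.
#' @return An object of class `wetcow_network`.
#' @seealso [integrate_network()], [build_sync_couplings()],
#'   [random_network()]
#' @export
network_spec <- function(modes, coupling_w, coupling_delta,
                         directed = TRUE, seed = NA_integer_) {
  if (inherits(modes, "wetcow_mode_params")) modes <- list(modes)
  n <- length(modes)
  stopifnot(n >= 1)
  lapply(modes, validate_mode_params)
  coupling_w <- as.matrix(coupling_w)
  coupling_delta <- as.matrix(coupling_delta)
  if (!all(dim(coupling_w) == c(n, n)) || !all(dim(coupling_delta) == c(n, n))) {
    stop("coupling matrices must be ", n, " x ", n, call. = FALSE)
  }
  if (any(diag(coupling_w) != 0)) {
    stop("invariant violated: diagonal of coupling_w must be 0", call. = FALSE)
  }
  if (any(coupling_w < 0)) {
    stop("invariant violated: all coupling magnitudes w_ij >= 0", call. = FALSE)
  }
  if (!directed &&
      (any(coupling_w != t(coupling_w)) || any(coupling_delta != t(coupling_delta)))) {
    stop("couplings are not symmetric but directed = FALSE", call. = FALSE)
  }
  structure(list(modes = modes, coupling_w = coupling_w,
                 coupling_delta = coupling_delta, directed = directed,
                 seed = seed),
            class = "wetcow_network")
}

#' @export
print.wetcow_network <- function(x, ...) {
  n <- length(x$modes)
  cat("<wetcow network> ", n, " modes, ",
      sum(x$coupling_w > 0), " directed links\n", sep = "")
  om <- vapply(x$modes, `[[`, numeric(1), "omega")
  cat("  omega: [", paste(format(round(om, 3)), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Number of modes in a network
#' @param spec A [network_spec()] object.
#' @return Integer count.
#' @export
n_modes <- function(spec) length(spec$modes)

#' Replace the sensory drive of every mode
#'
#' Returns a copy of the network with each mode's `gamma0` set from a
#' vector, e.g. to present an encoded stimulus to a memory loop.
#'
#' @param spec A [network_spec()] object.
#' @param gamma0 Scalar or length-N vector of drive rates.
#' @return The modified `wetcow_network`.
#' @export
set_drive <- function(spec, gamma0) {
  n <- n_modes(spec)
  gamma0 <- rep_len(gamma0, n)
  spec$modes <- lapply(seq_len(n), function(i) {
    m <- spec$modes[[i]]
    m$gamma0 <- gamma0[[i]]
    m
  })
  spec
}

mode_field <- function(spec, field) {
  vapply(spec$modes, `[[`, numeric(1), field)
}

#' Right-hand side of the coupled network system
#'
#' Evaluates the coupled amplitude and phase derivatives for all modes.  The
#' phase coupling is divided by the receiving amplitude with the same floor
#' rule as [integrate_mode()].
#'
#' @param state Numeric vector `c(A_1..A_N, phi_1..phi_N)`.
#' @param spec A [network_spec()] object.
#' @return Numeric vector of derivatives in the same layout.
#' @export
network_rhs <- function(state, spec) {
  n <- n_modes(spec)
  A <- pmax(state[seq_len(n)], 0)
  phi <- state[n + seq_len(n)]
  gam <- mode_field(spec, "gamma") + mode_field(spec, "gamma0")
  om <- mode_field(spec, "omega")
  alp <- mode_field(spec, "alpha")
  psi <- mode_field(spec, "psi")
  wa <- mode_field(spec, "w_a")
  wp <- mode_field(spec, "w_phi")
  dA <- gam * A + A^2 * (wa * cos(phi - psi) - alp)
  dphi <- om + A * wp * cos(phi)
  if (n > 1) {
    # z_i = sum_j w_ij e^{-i delta_ij} A_j e^{i phi_j}; then the amplitude
    # coupling is Re(z_i e^{-i phi_i}) and the phase coupling Im(z_i e^{-i phi_i})
    M <- spec$coupling_w * exp(-1i * spec$coupling_delta)
    z <- drop(M %*% (A * exp(1i * phi))) * exp(-1i * phi)
    dA <- dA + Re(z)
    low <- A < A_FLOOR
    dphi <- dphi + ifelse(low, 0, Im(z) / pmax(A, A_FLOOR))
    dphi[low] <- om[low]
    dA[low & dA < 0] <- 0
  }
  c(dA, dphi)
}

#' Integrate a wave-mode network
#'
#' Integrates all modes on a common output grid.  The user-facing state
#' layout is a flat vector of amplitudes `A_1..A_N` followed by phases
#' `phi_1..phi_N` (as in [network_rhs()]).  Internally the system is
#' integrated in complex Cartesian coordinates \eqn{z_i = A_i
#' e^{i\phi_i}}, in which the identical dynamics
#' \deqn{\dot z_i = (\gamma_i + i\omega_i) z_i + z_i\left[w^a_i
#'   \mathrm{Re}(z_i e^{-i\psi_i}) + i w^\phi_i \mathrm{Re}(z_i)
#'   - \alpha_i |z_i|\right] + \sum_{j\ne i} w_{ij} e^{-i\delta_{ij}} z_j}
#' are polynomial and free of the polar \eqn{1/A_i} singularity, so deep
#' amplitude dips between spikes do not stiffen the integration.  Phases
#' are unwrapped from the sampled output; choose `dt_out` small enough that
#' the phase advances less than half a turn per sample.
#'
#' @param spec A [network_spec()] object.
#' @param init Either `NULL` (defaults: every amplitude `1e-3`, every phase
#'   0), or a list with elements `amplitude` and `phase` (vectors of length
#'   N).
#' @param t_end End time.
#' @param dt_out Output grid spacing.
#' @param solver Optional solver overrides as in [integrate_mode()].
#' @return A `wetcow_trajectory` tibble in long format (`time`, `mode`,
#'   `amplitude`, `phase`).
#' @export
#' @examples
#' net <- sync_demo_network("subcritical", seed = 1)
#' traj <- integrate_network(net, t_end = 40)
integrate_network <- function(spec, init = NULL, t_end, dt_out = 0.02,
                              solver = list()) {
  stopifnot(inherits(spec, "wetcow_network"), t_end > 0)
  n <- n_modes(spec)
  if (is.null(init)) init <- list(amplitude = rep(1e-3, n), phase = rep(0, n))
  stopifnot(length(init$amplitude) == n, length(init$phase) == n,
            all(init$amplitude >= 0))
  so <- utils::modifyList(default_solver(dt_out), solver)
  times <- seq(0, t_end, by = dt_out)
  gam <- mode_field(spec, "gamma") + mode_field(spec, "gamma0")
  om <- mode_field(spec, "omega")
  alp <- mode_field(spec, "alpha")
  psi <- mode_field(spec, "psi")
  wa <- mode_field(spec, "w_a")
  wp <- mode_field(spec, "w_phi")
  lin <- complex(real = gam, imaginary = om)
  eip <- exp(-1i * psi)
  M <- spec$coupling_w * exp(-1i * spec$coupling_delta)
  rhs <- function(t, y, p) {
    z <- complex(real = y[seq_len(n)], imaginary = y[n + seq_len(n)])
    dz <- lin * z + z * (wa * Re(z * eip) + 1i * wp * Re(z) - alp * Mod(z)) +
      drop(M %*% z)
    list(c(Re(dz), Im(dz)))
  }
  y0 <- c(init$amplitude * cos(init$phase), init$amplitude * sin(init$phase))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = so$method, rtol = so$rtol, atol = so$atol)
  check_ode_complete(sol, max(times))
  re <- sol[, 1 + seq_len(n), drop = FALSE]
  im <- sol[, 1 + n + seq_len(n), drop = FALSE]
  amp <- sqrt(re^2 + im^2)
  ph <- apply(atan2(im, re), 2, unwrap_phase)
  # restore the requested starting branch of each unwrapped phase
  ph <- sweep(ph, 2, init$phase - ph[1, ], `+`)
  df <- tibble::tibble(
    time = rep(sol[, 1], n),
    mode = rep(seq_len(n), each = nrow(sol)),
    amplitude = as.vector(amp),
    phase = as.vector(ph)
  )
  new_trajectory(df, params = spec, solver = so, seed = spec$seed)
}

#' Single-mode Hamiltonian
#'
#' Evaluates \eqn{H^s(a, a^\dagger) = \Gamma a a^\dagger + a a^\dagger
#' [\beta_a a + \beta_{a^\dagger} a^\dagger - 2\alpha (a a^\dagger)^{1/2}]}.
#'
#' @param a Complex amplitude.
#' @param cparams A [complex_mode_params()] object.
#' @return Complex Hamiltonian value.
#' @export
hamiltonian_single <- function(a, cparams) {
  stopifnot(inherits(cparams, "wetcow_complex_params"))
  a <- as.complex(a)
  aa <- a * Conj(a)
  cparams$Gamma * aa +
    aa * (cparams$beta_a * a + cparams$beta_adag * Conj(a) -
            2 * cparams$alpha_c * sqrt(Re(aa)))
}

#' Network Hamiltonian
#'
#' Sum of single-mode Hamiltonians plus the bilinear coupling
#' \eqn{\sum_n \sum_{m\neq n} (a_n r_{nm} a_m^\dagger + a_n^\dagger
#' r^*_{nm} a_m)} with complex adjacency \eqn{r_{nm} = w_{nm}
#' e^{i\delta_{nm}}}.
#'
#' @param a Complex vector of mode amplitudes.
#' @param cparams List of [complex_mode_params()], one per mode (recycled if
#'   length one).
#' @param r Complex adjacency matrix; defaults to the adjacency implied by
#'   `spec` when one is given instead.
#' @return Complex Hamiltonian value.
#' @export
hamiltonian_network <- function(a, cparams, r) {
  a <- as.complex(a)
  n <- length(a)
  if (inherits(cparams, "wetcow_complex_params")) cparams <- list(cparams)
  cparams <- rep_len(cparams, n)
  r <- as.matrix(r)
  if (!all(dim(r) == c(n, n))) stop("adjacency r must be ", n, " x ", n, call. = FALSE)
  hs <- sum(vapply(seq_len(n), function(i) hamiltonian_single(a[i], cparams[[i]]),
                   complex(1)))
  coup <- 0 + 0i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) coup <- coup + a[i] * r[i, j] * Conj(a[j]) +
          Conj(a[i]) * Conj(r[i, j]) * a[j]
    }
  }
  hs + coup
}

#' Complex adjacency of a network
#'
#' @param spec A [network_spec()] object.
#' @return The complex matrix \eqn{r_{ij} = w_{ij} e^{i\delta_{ij}}}.
#' @export
complex_adjacency <- function(spec) {
  spec$coupling_w * exp(1i * spec$coupling_delta)
}

#' Effective per-mode excitation and frequency
#'
#' In a fully synchronized state (all phases equal, all amplitudes equal)
#' the coupling terms reduce to constants and each mode behaves like a
#' single mode with effective parameters
#' \deqn{\bar\gamma_i = \gamma_i + \sum_j w_{ij}\cos\delta_{ij}, \qquad
#'       \bar\omega_i = \omega_i - \sum_j w_{ij}\sin\delta_{ij}.}
#' The sign of the phase sum follows from evaluating the coupling
#' \eqn{\sin(\phi_j-\phi_i-\delta_{ij})} at \eqn{\phi_j=\phi_i}.
#'
#' @param spec A [network_spec()] object.
#' @param include_drive Add each mode's `gamma0` to the effective rate
#'   (default `TRUE`).
#' @return A tibble with columns `mode`, `gamma_bar`, `omega_bar`.
#' @export
effective_params <- function(spec, include_drive = TRUE) {
  stopifnot(inherits(spec, "wetcow_network"))
  gam <- mode_field(spec, "gamma")
  if (include_drive) gam <- gam + mode_field(spec, "gamma0")
  tibble::tibble(
    mode = seq_len(n_modes(spec)),
    gamma_bar = gam + rowSums(spec$coupling_w * cos(spec$coupling_delta)),
    omega_bar = mode_field(spec, "omega") -
      rowSums(spec$coupling_w * sin(spec$coupling_delta))
  )
}
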