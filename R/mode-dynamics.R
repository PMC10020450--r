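#' Right-hand side of the single-mode amplitude-phase system
#'
#' Evaluates
#' \deqn{dA/dt = (\gamma_0+\gamma) A + A^2 [w^a \cos(\phi-\psi) - \alpha]}
#' \deqn{d\phi/dt = \omega + A w^\phi \cos\phi}
#' at one state.  The sensory drive contributes to the amplitude equation
#' only.
#'
#' @param state Numeric vector `c(A, phi)` with `A >= 0`.
#' @param params A [mode_params()] object.
#' @return Numeric vector `c(dA, dphi)`.
#' @export
mode_rhs <- function(state, params) {
  A <- state[[1]]
  phi <- state[[2]]
  dA <- total_drive(params) * A +
    A^2 * (params$w_a * cos(phi - params$psi) - params$alpha)
  dphi <- params$omega + A * params$w_phi * cos(phi)
  c(dA = dA, dphi = dphi)
}

# amplitude floor below which the phase equation falls back to its linear
# part; avoids the polar singularity of the 1/A coupling term
A_FLOOR <- 1e-12

new_trajectory <- function(df, params, solver, seed = NA_integer_) {
  tibble::new_tibble(df, params = params, solver = solver, seed = seed,
                     class = "wetcow_trajectory")
}

default_solver <- function(dt_out) {
  list(method = "lsoda", rtol = 1e-8, atol = 1e-10, dt_out = dt_out,
       a_floor = A_FLOOR)
}

#' Integrate a single wave mode
#'
#' Integrates the amplitude-phase system with an adaptive solver and returns
#' the trajectory on a uniform output grid.  The phase is stored unwrapped
#' (continuous); use [wrap_phase()] for a wrapped view.  An amplitude floor
#' (`1e-12`) guards the origin: below it the amplitude derivative is not
#' allowed to be negative and the phase advances at the linear frequency.
#'
#' @param params A [mode_params()] object.
#' @param init Numeric vector `c(A, phi)`; default `c(1e-3, 0)`.
#' @param t_end End time (> 0).
#' @param dt_out Output grid spacing.
#' @param solver Optional list overriding `method`, `rtol`, `atol`.
#' @return A tibble of class `wetcow_trajectory` with columns `time`,
#'   `mode`, `amplitude`, `phase`; solver settings are kept in attributes.
#' @seealso [integrate_complex_mode()], [integrate_network()],
#'   [detect_spikes()]
#' @export
#' @examples
#' traj <- integrate_mode(mode_params(gamma = 1.8), t_end = 60)
#' dplyr::glimpse(traj)
integrate_mode <- function(params, init = c(1e-3, 0), t_end, dt_out = 0.02,
                           solver = list()) {
  validate_mode_params(params)
  stopifnot(t_end > 0, init[[1]] >= 0)
  so <- utils::modifyList(default_solver(dt_out), solver)
  times <- seq(0, t_end, by = dt_out)
  rhs <- function(t, y, p) {
    A <- max(y[[1]], 0)
    dA <- total_drive(params) * A +
      A^2 * (params$w_a * cos(y[[2]] - params$psi) - params$alpha)
    if (A < so$a_floor) {
      if (dA < 0) dA <- 0
      dphi <- params$omega
    } else {
      dphi <- params$omega + A * params$w_phi * cos(y[[2]])
    }
    list(c(dA, dphi))
  }
  sol <- deSolve::ode(y = c(A = init[[1]], phi = init[[2]]), times = times,
                      func = rhs, parms = NULL, method = so$method,
                      rtol = so$rtol, atol = so$atol)
  check_ode_complete(sol, max(times))
  new_trajectory(
    tibble::tibble(time = sol[, "time"], mode = 1L,
                   amplitude = pmax(sol[, "A"], 0), phase = sol[, "phi"]),
    params = params, solver = so
  )
}

check_ode_complete <- function(sol, t_last) {
  if (nrow(sol) == 0 || max(sol[, 1]) < t_last - 1e-9 || anyNA(sol)) {
    last_ok <- if (nrow(sol)) max(sol[stats::complete.cases(sol), 1], -Inf) else -Inf
    stop("integration failed to reach t_end; last valid time = ",
         format(last_ok), call. = FALSE)
  }
  invisible(sol)
}

#' Integrate the complex-form mode equation
#'
#' Integrates \eqn{da/dt = \Gamma a + \beta_{a^\dagger} a a^\dagger +
#' \beta_a a^2 - \alpha_c a(aa^\dagger)^{1/2}} in Cartesian components
#' (`Re a`, `Im a`), which has no polar singularity at the origin.  Returns
#' the modulus as `amplitude` and the unwrapped argument as `phase`.
#'
#' @param cparams A [complex_mode_params()] object (see
#'   [as_complex_params()] for the exact polar correspondence).
#' @param init Complex initial amplitude.
#' @param t_end End time.
#' @param dt_out Output grid spacing.
#' @param solver Optional solver overrides as in [integrate_mode()].
#' @return A `wetcow_trajectory` tibble.
#' @export
integrate_complex_mode <- function(cparams, init = 1e-3 + 0i, t_end,
                                   dt_out = 0.02, solver = list()) {
  stopifnot(inherits(cparams, "wetcow_complex_params"), t_end > 0)
  init <- as.complex(init)
  if (!is.finite(Re(init)) || !is.finite(Im(init))) {
    stop("init must be a finite complex number", call. = FALSE)
  }
  so <- utils::modifyList(default_solver(dt_out), solver)
  times <- seq(0, t_end, by = dt_out)
  rhs <- function(t, y, p) {
    a <- complex(real = y[[1]], imaginary = y[[2]])
    da <- cparams$Gamma * a + cparams$beta_adag * a * Conj(a) +
      cparams$beta_a * a^2 - cparams$alpha_c * a * Mod(a)
    list(c(Re(da), Im(da)))
  }
  sol <- deSolve::ode(y = c(x = Re(init), y = Im(init)), times = times,
                      func = rhs, parms = NULL, method = so$method,
                      rtol = so$rtol, atol = so$atol)
  if (anyNA(sol) || max(abs(sol[stats::complete.cases(sol), c("x", "y")])) > 1e8) {
    ok <- stats::complete.cases(sol) & rowSums(abs(sol[, c("x", "y"), drop = FALSE]) > 1e8) == 0
    stop("diverged trajectory; blow-up near t = ",
         format(if (any(ok)) max(sol[ok, 1]) else 0), call. = FALSE)
  }
  check_ode_complete(sol, max(times))
  amp <- sqrt(sol[, "x"]^2 + sol[, "y"]^2)
  ph <- unwrap_phase(atan2(sol[, "y"], sol[, "x"]))
  new_trajectory(
    tibble::tibble(time = sol[, "time"], mode = 1L, amplitude = amp, phase = ph),
    params = cparams, solver = so
  )
}

#' Wrap phases into (-pi, pi]
#'
#' @param phi Numeric vector of phases (rad).
#' @return Phases wrapped to the half-open interval \eqn{(-\pi, \pi]}.
#' @export
wrap_phase <- function(phi) {
  out <- -((-phi + pi) %% (2 * pi) - pi)
  out[out == -pi] <- pi
  out
}

#' Unwrap a sampled phase series
#'
#' Removes 2*pi jumps from a wrapped phase series so that it is continuous.
#'
#' @param phi Numeric vector of wrapped phases.
#' @return Continuous (unwrapped) phase series.
#' @export
unwrap_phase <- function(phi) {
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

#' Integrate a leaky integrate-and-fire neuron
#'
#' Voltage follows \eqn{\tau_m \, dU/dt = -(U - U_{rest}) + R I(t)}; when
#' `U >= Theta` a spike time is recorded and the voltage is reset to
#' `U_rest`.  Between samples of the (piecewise-constant) input current the
#' update uses the exact exponential solution, and threshold crossings are
#' located by inverting it, so accuracy is limited only by the sampling of
#' `I`.
#'
#' @param params A [lif_params()] object.
#' @param I Input current: either a function of time or a numeric vector
#'   sampled on the integration grid.
#' @param init Initial voltage; defaults to the resting potential.
#' @param t_end End time.
#' @param dt Integration step.
#' @return A list with `trace` (tibble: `time`, `voltage`) and
#'   `spike_times` (numeric vector).
#' @export
#' @examples
#' lif <- lif_params(tau_m = 1, U_rest = 0, R = 1, Theta = 1)
#' out <- integrate_lif(lif, I = function(t) 1.5, t_end = 10)
#' out$spike_times
integrate_lif <- function(params, I, init = NULL, t_end, dt = 1e-3) {
  stopifnot(inherits(params, "wetcow_lif_params"), t_end > 0)
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  Iv <- if (is.function(I)) vapply(times, I, numeric(1)) else rep_len(I, n)
  U <- numeric(n)
  U[1] <- if (is.null(init)) params$U_rest else init
  spikes <- numeric(0)
  decay <- exp(-dt / params$tau_m)
  for (k in seq_len(n - 1)) {
    target <- params$U_rest + params$R * Iv[k]   # fixed point for this step
    U[k + 1] <- target + (U[k] - target) * decay
    if (U[k + 1] >= params$Theta) {
      # exact crossing time within the step from the exponential solution
      frac <- if (U[k] < params$Theta && target > U[k]) {
        params$tau_m / dt * log((target - U[k]) / (target - params$Theta))
      } else 0
      spikes <- c(spikes, times[k] + min(max(frac, 0), 1) * dt)
      U[k + 1] <- params$U_rest
    }
  }
  list(trace = tibble::tibble(time = times, voltage = U),
       spike_times = spikes)
}

#' Closed-form LIF firing period under constant current
#'
#' For constant input with `R*I > Theta - U_rest` the first-passage time
#' from rest gives the period \eqn{T = \tau_m \log[RI / (RI - \Theta +
#' U_{rest})]}.
#'
#' @param params A [lif_params()] object.
#' @param I Constant input current.
#' @return The firing period, or `Inf` when the input is subthreshold.
#' @export
lif_period <- function(params, I) {
  stopifnot(inherits(params, "wetcow_lif_params"))
  drive <- params$R * I
  gap <- params$Theta - params$U_rest
  if (drive <= gap) return(Inf)
  params$tau_m * log(drive / (drive - gap))
}
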