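#' Single wave-mode parameters
#'
#' Bundles the constants of one weakly evanescent wave mode.  The mode is a
#' two-dimensional dynamical system in amplitude `A` and phase `phi`:
#'
#' \deqn{dA/dt = (\gamma_0 + \gamma) A + A^2 [w^a \cos(\phi - \psi) - \alpha]}
#' \deqn{d\phi/dt = \omega + A w^\phi \cos\phi}
#'
#' The total excitation rate is the sum of the background activation `gamma`
#' and the sensory drive `gamma0`; the drive enters only the amplitude
#' equation.
#'
#' @param gamma Background excitation (positive) or damping (negative) rate,
#'   in inverse time units (units are arbitrary throughout).
#' @param omega Linear angular frequency of the mode, rad/time; must be
#'   positive.
#' @param alpha Nonlinear saturation strength; must exceed
#'   `abs(w_a * sin(psi))` so that the critical phase is defined.
#' @param psi Phase offset of the amplitude nonlinearity, rad.
#' @param w_a Amplitude nonlinearity strength, nonnegative.
#' @param w_phi Phase nonlinearity strength, nonnegative.
#' @param gamma0 Sensory drive rate added to `gamma`, default 0.
#'
#' @details The defaults are the reference constants used throughout the
#' package's synchronization examples: \eqn{w^a = w^\phi = \sqrt 5},
#' \eqn{\psi = 2\arctan(1/3)}, \eqn{\alpha = 3}, \eqn{\omega = 1}, for which
#' the critical phase is \eqn{\arctan(1/2)} and the combined coupling factor
#' is exactly 1/2.
#'
#' @return An object of class `wetcow_mode_params`.
#' @seealso [criticality()], [integrate_mode()], [as_complex_params()]
#' @export
#' @examples
#' p <- mode_params(gamma = 1.8)
#' criticality(p)
mode_params <- function(gamma = 0, omega = 1, alpha = 3,
                        psi = 2 * atan(1 / 3),
                        w_a = sqrt(5), w_phi = sqrt(5),
                        gamma0 = 0) {
  p <- list(gamma = gamma, omega = omega, alpha = alpha, psi = psi,
            w_a = w_a, w_phi = w_phi, gamma0 = gamma0)
  p <- lapply(p, as.numeric)
  class(p) <- "wetcow_mode_params"
  validate_mode_params(p)
  p
}

validate_mode_params <- function(p) {
  for (f in c("gamma", "omega", "alpha", "psi", "w_a", "w_phi", "gamma0")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      stop("mode_params field '", f, "' must be a finite scalar", call. = FALSE)
    }
  }
  if (p$omega <= 0) stop("invariant violated: omega > 0", call. = FALSE)
  if (p$w_a < 0) stop("invariant violated: w_a >= 0", call. = FALSE)
  if (p$w_phi < 0) stop("invariant violated: w_phi >= 0", call. = FALSE)
  s <- p$w_a * sin(p$psi)
  if (p$alpha <= abs(s)) {
    stop("invariant violated: alpha > |w_a * sin(psi)| ",
         "(alpha = ", format(p$alpha), ", |w_a sin psi| = ", format(abs(s)), ")",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.wetcow_mode_params <- function(x, ...) {
  cat("<wetcow mode parameters>\n")
  cat(sprintf("  gamma  = %g  (+ drive gamma0 = %g)\n", x$gamma, x$gamma0))
  cat(sprintf("  omega  = %g\n", x$omega))
  cat(sprintf("  alpha  = %g, psi = %g, w_a = %g, w_phi = %g\n",
              x$alpha, x$psi, x$w_a, x$w_phi))
  invisible(x)
}

#' Total excitation rate of a mode
#'
#' Background activation plus sensory drive, `gamma + gamma0`.  This is the
#' rate that enters the amplitude equation and the criticality parameter.
#'
#' @param params A [mode_params()] object.
#' @return Scalar rate.
#' @export
total_drive <- function(params) {
  validate_mode_params(params)
  params$gamma + params$gamma0
}

#' Complex-form mode parameters
#'
#' Coefficients of the complex amplitude equation
#' \deqn{da/dt = \Gamma a + \beta_{a^\dagger} a a^\dagger + \beta_a a^2
#'   - \alpha_c a (a a^\dagger)^{1/2}}
#' which is the Cartesian (polar-singularity-free) form of the
#' amplitude-phase system.
#'
#' @param Gamma Complex linear rate, `i*omega + gamma`.
#' @param beta_a Complex cubic coefficient multiplying `a^2`.
#' @param beta_adag Complex cubic coefficient multiplying `a * Conj(a)`.
#' @param alpha_c Complex saturation coefficient.
#' @return An object of class `wetcow_complex_params`.
#' @seealso [as_complex_params()] for the exact mapping from [mode_params()].
#' @export
complex_mode_params <- function(Gamma, beta_a = 0 + 0i, beta_adag = 0 + 0i,
                                alpha_c = 0 + 0i) {
  p <- list(Gamma = as.complex(Gamma), beta_a = as.complex(beta_a),
            beta_adag = as.complex(beta_adag), alpha_c = as.complex(alpha_c))
  bad <- !vapply(p, function(z) length(z) == 1L && is.finite(Re(z)) && is.finite(Im(z)),
                 logical(1))
  if (any(bad)) {
    stop("complex_mode_params fields must be finite scalars: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "wetcow_complex_params")
}

#' Map polar mode parameters to the complex form
#'
#' The polar system in `(A, phi)` and the complex equation in `a` are the
#' same dynamics under `a = A exp(i phi)`.  Matching terms gives the exact
#' correspondence
#' \deqn{\Gamma = (\gamma_0 + \gamma) + i\omega, \quad \alpha_c = \alpha,}
#' \deqn{\beta_{a^\dagger} = \tfrac{1}{2} w^a\cos\psi +
#'   \tfrac{i}{2}(w^\phi + w^a\sin\psi), \quad
#'   \beta_a = \tfrac{1}{2} w^a\cos\psi + \tfrac{i}{2}(w^\phi - w^a\sin\psi),}
#' valid for every parameter set: the `a*Conj(a)` term carries no phase
#' factor, the `a^2` term carries `exp(2i phi)`, and their real/imaginary
#' parts combine into `w_a cos(phi - psi)` in the amplitude equation and
#' `w_phi cos(phi)` in the phase equation.
#'
#' @param params A [mode_params()] object.
#' @return A [complex_mode_params()] object describing identical dynamics.
#' @export
as_complex_params <- function(params) {
  validate_mode_params(params)
  cc <- params$w_a * cos(params$psi) / 2
  sd <- (params$w_phi + params$w_a * sin(params$psi)) / 2
  sa <- (params$w_phi - params$w_a * sin(params$psi)) / 2
  complex_mode_params(
    Gamma = complex(real = total_drive(params), imaginary = params$omega),
    beta_adag = complex(real = cc, imaginary = sd),
    beta_a = complex(real = cc, imaginary = sa),
    alpha_c = complex(real = params$alpha, imaginary = 0)
  )
}

#' Leaky integrate-and-fire parameters
#'
#' The baseline threshold unit: membrane voltage integrates input current
#' with a leak, and is reset to rest when it reaches the firing threshold.
#'
#' @param tau_m Membrane time constant, must be positive.
#' @param U_rest Resting potential.
#' @param R Input resistance.
#' @param Theta Firing threshold; must exceed `U_rest`.
#' @return An object of class `wetcow_lif_params`.
#' @export
lif_params <- function(tau_m = 1, U_rest = 0, R = 1, Theta = 1) {
  if (!is.numeric(tau_m) || tau_m <= 0) stop("tau_m must be positive", call. = FALSE)
  if (Theta <= U_rest) stop("invariant violated: Theta > U_rest", call. = FALSE)
  structure(list(tau_m = as.numeric(tau_m), U_rest = as.numeric(U_rest),
                 R = as.numeric(R), Theta = as.numeric(Theta)),
            class = "wetcow_lif_params")
}
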