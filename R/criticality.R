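#' Critical phase of a wave mode
#'
#' The phase at which the joint amplitude-phase fixed point appears, from
#' \deqn{\phi^c = \arctan\left[\frac{w^a \sin\psi}
#'   {\sqrt{\alpha^2 - (w^a \sin\psi)^2}}\right].}
#' Requires \eqn{\alpha^2 > (w^a \sin\psi)^2}; the result lies in
#' \eqn{(-\pi/2, \pi/2)}.
#'
#' @param params A [mode_params()] object.
#' @return Critical phase in radians.
#' @export
#' @examples
#' critical_phase(mode_params())  # arctan(1/2) for the reference constants
critical_phase <- function(params) {
  validate_mode_params(params)
  s <- params$w_a * sin(params$psi)
  disc <- params$alpha^2 - s^2
  if (disc <= 0) {
    stop("domain error: alpha^2 > (w_a * sin(psi))^2 is violated", call. = FALSE)
  }
  atan(s / sqrt(disc))
}

#' Saturation strength implied by a critical phase
#'
#' Inverts the critical-phase relation: since
#' \eqn{\sin\phi^c = w^a \sin\psi / \alpha}, the saturation strength is
#' \eqn{\alpha = w^a \sin\psi / \sin\phi^c}.  Useful for recovering the
#' saturation constant from a reported critical phase.
#'
#' @param w_a Amplitude nonlinearity strength.
#' @param psi Amplitude-coupling phase offset, rad.
#' @param phi_c Critical phase, rad, nonzero and in \eqn{(-\pi/2, \pi/2)}.
#' @return The saturation strength `alpha`.
#' @export
#' @examples
#' # the reference chain: phi_c = arctan(1/2) with w_a = sqrt(5),
#' # psi = 2*arctan(1/3) recovers alpha = 3
#' saturation_from_phase(sqrt(5), 2 * atan(1 / 3), atan(1 / 2))
saturation_from_phase <- function(w_a, psi, phi_c) {
  if (abs(phi_c) >= pi / 2 || phi_c == 0) {
    stop("phi_c must be nonzero and inside (-pi/2, pi/2)", call. = FALSE)
  }
  w_a * sin(psi) / sin(phi_c)
}

#' Combined coupling factor
#'
#' The dimensionless factor linking excitation rate and critical frequency,
#' \deqn{w = \frac{w^\phi \cos\phi^c}{\alpha + w^a \cos(\phi^c + \psi)}.}
#'
#' @param params A [mode_params()] object.
#' @param phi_c Critical phase; computed from `params` when omitted.
#' @return The coupling factor; its sign follows the numerator.
#' @export
coupling_factor <- function(params, phi_c = NULL) {
  validate_mode_params(params)
  if (is.null(phi_c)) phi_c <- critical_phase(params)
  den <- params$alpha + params$w_a * cos(phi_c + params$psi)
  if (abs(den) < 1e-14) {
    stop("degenerate parameters: zero denominator in coupling factor",
         call. = FALSE)
  }
  params$w_phi * cos(phi_c) / den
}

#' Critical frequency and critical excitation rate
#'
#' \deqn{\omega_c = \gamma w, \qquad \gamma_c = \omega / w,}
#' where `gamma` is the total drive (`gamma + gamma0`).  The product
#' identity \eqn{\gamma_c \omega_c = \gamma\omega} holds whenever both are
#' finite.
#'
#' @param params A [mode_params()] object.
#' @param w Coupling factor; computed from `params` when omitted.
#' @return Named numeric vector with elements `omega_c` and `gamma_c`.
#' @export
critical_thresholds <- function(params, w = NULL) {
  validate_mode_params(params)
  if (is.null(w)) w <- coupling_factor(params)
  if (w == 0) {
    stop("degenerate coupling factor w = 0: gamma_c is infinite", call. = FALSE)
  }
  c(omega_c = total_drive(params) * w, gamma_c = params$omega / w)
}

#' Criticality report for a single mode
#'
#' Collects the closed-form criticality quantities of one mode into a
#' one-row tibble: critical phase `phi_c`, coupling factor `w`, critical
#' frequency `omega_c`, critical rate `gamma_c`, criticality parameter
#' \eqn{c_r = \gamma/\gamma_c = w\gamma/\omega} (with `gamma` the total
#' drive), effective spiking frequency
#' \eqn{\omega_s = \sqrt{\omega^2 - \omega_c^2}} and effective period
#' \eqn{T_s = 2\pi/\omega_s}.
#'
#' `omega_s` is real only in the subcritical regime \eqn{c_r < 1}; above it
#' the mode performs a single spike-like transition and then locks, and
#' `omega_s`/`T_s` are reported as `NA` with `supercritical = TRUE`.
#'
#' @param params A [mode_params()] object.
#' @return A one-row tibble with columns `phi_c`, `w`, `omega_c`, `gamma_c`,
#'   `c_r`, `omega_s`, `T_s`, `supercritical`.
#' @export
#' @examples
#' criticality(mode_params(gamma = 1.8))
criticality <- function(params) {
  validate_mode_params(params)
  phi_c <- critical_phase(params)
  w <- coupling_factor(params, phi_c)
  th <- critical_thresholds(params, w)
  g <- total_drive(params)
  c_r <- g / th[["gamma_c"]]
  sup <- c_r >= 1
  disc <- params$omega^2 - th[["omega_c"]]^2
  omega_s <- if (sup || disc <= 0) NA_real_ else sqrt(disc)
  T_s <- if (is.na(omega_s) || omega_s == 0) NA_real_ else 2 * pi / omega_s
  tibble::tibble(
    phi_c = phi_c, w = w,
    omega_c = th[["omega_c"]], gamma_c = th[["gamma_c"]],
    c_r = c_r, omega_s = omega_s, T_s = T_s,
    supercritical = sup
  )
}

#' Effective spiking frequency of a driven mode
#'
#' Convenience accessor for the closed-form effective frequency
#' \eqn{\omega_s = \sqrt{\omega^2 - (\gamma_0+\gamma)^2 w^2}} of a mode
#' under total drive; `NA` in the supercritical regime.
#'
#' @param params A [mode_params()] object.
#' @return Scalar frequency, or `NA` when `c_r >= 1`.
#' @export
effective_frequency <- function(params) {
  criticality(params)$omega_s
}
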