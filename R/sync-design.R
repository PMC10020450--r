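#' @title Constructing critically synchronized memory loops
#' @description
#' A driven single mode with total excitation \eqn{\gamma_0 + \gamma} spikes
#' at the effective frequency \eqn{\omega_s = \sqrt{\omega^2 -
#' (\gamma_0+\gamma)^2 w^2}}.  A network can replicate that activity with no
#' external drive when every row of the coupling matrix feeds back the same
#' effective inputs: for each mode `i`
#' \deqn{\sum_j w_{ij}\cos\delta_{ij} = \gamma_0 \quad\text{(amplitude)},
#' \qquad \sum_j w_{ij}\sin\delta_{ij} = s_i \quad\text{(phase)},}
#' where the phase-side target \eqn{s_i} is 0 for identical modes and
#' \eqn{\omega_i - \bar\omega} when heterogeneous linear frequencies are
#' pulled to a common effective frequency.  These row conditions are
#' necessary but not sufficient; [integrate_network()] plus
#' [sync_metrics()] provide the empirical check.
#' @name sync_design
NULL

# Solve one coupling row: find m nonnegative magnitudes w and phase lags d
# within the requested ranges with sum(w cos d) = C_t and sum(w sin d) = S_t.
# Random candidates are corrected by the least-norm additive adjustment of w;
# on repeated failure the sampled lags concentrate around the target
# direction, and finally a deterministic two-angle split is attempted.
solve_coupling_row <- function(m, C_t, S_t, w_range = c(0, 0.2),
                               delta_range = c(-pi / 2, pi / 2),
                               max_try = 400) {
  wlo <- w_range[1]; whi <- w_range[2]
  dlo <- delta_range[1]; dhi <- delta_range[2]
  theta <- atan2(S_t, C_t)
  norm_t <- sqrt(C_t^2 + S_t^2)
  if (m == 1L) {
    # single link: the solution is unique
    if (theta < dlo || theta > dhi) return(NULL)
    return(list(w = norm_t, delta = theta, exact = TRUE))
  }
  if (theta < dlo || theta > dhi) return(NULL)
  for (tr in seq_len(max_try)) {
    if (tr <= max_try / 2) {
      dr <- stats::runif(m, dlo, dhi)
    } else {
      frac <- max(0.05, 2 * (max_try - tr) / max_try)
      half <- (dhi - dlo) / 2 * frac
      dr <- pmin(pmax(stats::runif(m, theta - half, theta + half), dlo), dhi)
    }
    wr <- stats::runif(m, wlo, whi)
    Cm <- rbind(cos(dr), sin(dr))
    M <- Cm %*% t(Cm)
    if (rcond(M) < 1e-10) next
    dw <- drop(t(Cm) %*% solve(M, c(C_t - sum(wr * cos(dr)),
                                    S_t - sum(wr * sin(dr)))))
    w2 <- wr + dw
    if (all(w2 >= wlo) && all(w2 <= whi)) {
      return(list(w = w2, delta = dr, exact = FALSE))
    }
  }
  # deterministic fallback: split links between two angles around theta
  for (eta in c(0.4, 0.2, 0.1, 0.05)) {
    th1 <- max(dlo, min(dhi, theta + eta))
    th2 <- max(dlo, min(dhi, theta - eta))
    if (th1 == th2) next
    M <- matrix(c(cos(th1), sin(th1), cos(th2), sin(th2)), 2, 2)
    if (rcond(M) < 1e-10) next
    g <- solve(M, c(C_t, S_t))
    m1 <- ceiling(m / 2); m2 <- m - m1
    if (m2 == 0) next
    w1 <- g[1] / m1; w2 <- g[2] / m2
    if (all(c(w1, w2) >= wlo) && all(c(w1, w2) <= whi)) {
      return(list(w = c(rep(w1, m1), rep(w2, m2)),
                  delta = c(rep(th1, m1), rep(th2, m2)), exact = FALSE))
    }
  }
  # last resort near the capacity limit: every link points at the target
  # direction with equal magnitude (exact, if inside the ranges)
  if (norm_t / m >= wlo && norm_t / m <= whi) {
    return(list(w = rep(norm_t / m, m), delta = rep(theta, m), exact = FALSE))
  }
  NULL
}

default_sync_modes <- function(n, gamma = 0) {
  lapply(seq_len(n), function(i) mode_params(gamma = gamma))
}

assemble_sync_spec <- function(modes, amp_targets, phase_targets,
                               w_range, delta_range, seed) {
  n <- length(modes)
  W <- matrix(0, n, n)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- solve_coupling_row(n - 1L, amp_targets[i], phase_targets[i],
                              w_range = w_range, delta_range = delta_range)
    if (is.null(row)) {
      stop("infeasible coupling row for mode ", i,
           " (targets C = ", format(amp_targets[i]),
           ", S = ", format(phase_targets[i]),
           "); resample or widen the coupling ranges", call. = FALSE)
    }
    j <- setdiff(seq_len(n), i)
    W[i, j] <- row$w
    D[i, j] <- row$delta
  }
  spec <- network_spec(modes, W, D, seed = seed)
  spec$sync_targets <- tibble::tibble(mode = seq_len(n),
                                      amp_target = amp_targets,
                                      phase_target = phase_targets)
  spec
}

#' Build couplings for a critically synchronized loop
#'
#' Constructs coupling matrices whose row sums satisfy the synchronization
#' conditions \eqn{\sum_j w_{ij}\cos\delta_{ij} = \gamma_0} and
#' \eqn{\sum_j w_{ij}\sin\delta_{ij} = 0} to machine accuracy, so that the
#' undriven network replicates a mode driven at rate `gamma0`.  Candidate
#' magnitudes and lags are sampled uniformly inside the requested ranges and
#' the magnitudes receive a least-norm additive correction; rows that would
#' need a negative magnitude are resampled.
#'
#' A single mode is structurally infeasible (an empty coupling sum cannot
#' equal a positive drive).  For two modes each row has a single link and
#' the unique exact solution is returned (`delta = 0`, `w = gamma0`), which
#' may exceed the requested magnitude range: a two-node loop can require a
#' large coupling.
#'
#' @param n Number of modes (>= 2).
#' @param gamma0 Drive rate to replicate (> 0).
#' @param modes Optional list of [mode_params()]; defaults to `n` copies of
#'   the reference constants with zero background drive.
#' @param w_range,delta_range Sampling ranges for magnitudes and lags.
#' @param seed Optional integer seed (recorded in the spec).
#' @return A [network_spec()] with row targets stored for
#'   [verify_sync_conditions()].
#' @export
#' @examples
#' spec <- build_sync_couplings(10, gamma0 = 1, seed = 1)
#' verify_sync_conditions(spec)
build_sync_couplings <- function(n, gamma0, modes = NULL,
                                 w_range = c(0, 0.2),
                                 delta_range = c(-pi / 2, pi / 2),
                                 seed = NULL) {
  if (n < 2) {
    stop("structurally infeasible: a single mode has no couplings, and an ",
         "empty sum cannot equal gamma0 > 0", call. = FALSE)
  }
  stopifnot(gamma0 > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(modes)) modes <- default_sync_modes(n)
  assemble_sync_spec(modes, rep(gamma0, n), rep(0, n),
                     w_range, delta_range, seed = seed %||% NA_integer_)
}

#' Verify synchronization conditions of a network
#'
#' Computes the per-row residuals of the amplitude and phase conditions and
#' the per-mode predicted effective frequency.  Row targets stored by the
#' constructors are used by default; otherwise `gamma0` (amplitude target)
#' and `phase_target` default to a homogeneous drive and zero phase sum.
#'
#' @param spec A [network_spec()] object.
#' @param gamma0 Amplitude-side target (scalar or per-mode); default the
#'   stored construction targets, else 0.
#' @param phase_target Phase-side target (scalar or per-mode); same default.
#' @return A tibble with columns `mode`, `amp_residual`, `phase_residual`,
#'   `omega_s_pred`.
#' @export
verify_sync_conditions <- function(spec, gamma0 = NULL, phase_target = NULL) {
  stopifnot(inherits(spec, "wetcow_network"))
  n <- n_modes(spec)
  if (is.null(gamma0)) {
    gamma0 <- if (!is.null(spec$sync_targets)) spec$sync_targets$amp_target else 0
  }
  if (is.null(phase_target)) {
    phase_target <- if (!is.null(spec$sync_targets)) spec$sync_targets$phase_target else 0
  }
  camp <- rowSums(spec$coupling_w * cos(spec$coupling_delta))
  cph <- rowSums(spec$coupling_w * sin(spec$coupling_delta))
  tibble::tibble(
    mode = seq_len(n),
    amp_residual = camp - rep_len(gamma0, n),
    phase_residual = cph - rep_len(phase_target, n),
    omega_s_pred = predict_network_frequency(spec)$omega_s_pred
  )
}

#' Predicted common effective frequency of a synchronized network
#'
#' Applies the single-mode closed form to each mode's effective parameters:
#' \eqn{\omega_{s,i} = \sqrt{\bar\omega_i^2 - \bar\gamma_i^2 w_i^2}} with
#' \eqn{\bar\gamma_i, \bar\omega_i} from [effective_params()].  Modes whose
#' effective drive is supercritical are flagged rather than raised.  When
#' the per-mode predictions differ the configuration cannot synchronize at a
#' common frequency and `consistent` is `FALSE`.
#'
#' @param spec A [network_spec()] object.
#' @param tol Relative spread below which predictions count as equal.
#' @return A tibble with columns `mode`, `omega_s_pred`, `supercritical`,
#'   and attribute-free column `consistent` (same value for all rows).
#' @export
predict_network_frequency <- function(spec, tol = 1e-8) {
  stopifnot(inherits(spec, "wetcow_network"))
  eff <- effective_params(spec)
  wfac <- vapply(spec$modes, coupling_factor, numeric(1))
  disc <- eff$omega_bar^2 - eff$gamma_bar^2 * wfac^2
  sup <- disc <= 0
  ws <- ifelse(sup, NA_real_, sqrt(pmax(disc, 0)))
  ok <- ws[!sup]
  consistent <- length(ok) == n_modes(spec) &&
    (length(ok) < 2 || diff(range(ok)) <= tol * max(abs(ok)))
  tibble::tibble(mode = eff$mode, omega_s_pred = ws,
                 supercritical = sup, consistent = consistent)
}

#' Tune couplings for heterogeneous modes to a common effective frequency
#'
#' For modes with unequal linear frequencies (or drives) the plain row
#' conditions leave each mode with a different predicted effective
#' frequency, and the network only loosely frequency-locks.  This tuner
#' additionally shifts each mode's effective frequency through the
#' phase-lag sums so that every mode predicts exactly `omega_s_target`:
#' row `i` solves
#' \deqn{\sum_j w_{ij}\cos\delta_{ij} = \gamma_{0,i}, \qquad
#'       \sum_j w_{ij}\sin\delta_{ij} = \omega_i - \bar\omega_i,}
#' with \eqn{\bar\omega_i = \sqrt{\omega_s^2 + \bar\gamma_i^2 w_i^2}} and
#' \eqn{\bar\gamma_i = \gamma_i + \gamma_{0,i}}.  Each mode's `gamma0`
#' field is read as the drive its coupling row must replicate; the returned
#' network carries no external drive.
#'
#' @param modes List of [mode_params()] objects; their `gamma0` fields give
#'   the per-mode amplitude targets.
#' @param omega_s_target Desired common effective frequency (> 0).
#' @param w_range,delta_range Sampling ranges as in
#'   [build_sync_couplings()].
#' @param seed Optional integer seed.
#' @return A [network_spec()] whose [predict_network_frequency()] equals
#'   `omega_s_target` for every mode; modes are returned with `gamma0 = 0`.
#' @export
heterogeneous_tune <- function(modes, omega_s_target,
                               w_range = c(0, 0.2),
                               delta_range = c(-pi / 2, pi / 2),
                               seed = NULL) {
  stopifnot(omega_s_target > 0, length(modes) >= 2)
  lapply(modes, validate_mode_params)
  if (!is.null(seed)) set.seed(seed)
  n <- length(modes)
  g0 <- vapply(modes, `[[`, numeric(1), "gamma0")
  gbar <- vapply(modes, `[[`, numeric(1), "gamma") + g0
  wfac <- vapply(modes, coupling_factor, numeric(1))
  om <- vapply(modes, `[[`, numeric(1), "omega")
  omega_bar <- sqrt(omega_s_target^2 + gbar^2 * wfac^2)
  shift <- om - omega_bar
  max_row <- (n - 1) * max(w_range)
  need <- sqrt(g0^2 + shift^2)
  bad <- need > max_row
  if (any(bad)) {
    stop("infeasible target omega_s = ", format(omega_s_target),
         " for mode(s) ", paste(which(bad), collapse = ", "),
         ": required row magnitude exceeds the coupling range", call. = FALSE)
  }
  undriven <- lapply(modes, function(m) { m$gamma0 <- 0; m })
  spec <- assemble_sync_spec(undriven, g0, shift, w_range, delta_range,
                             seed = seed %||% NA_integer_)
  spec$omega_s_target <- omega_s_target
  spec
}
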