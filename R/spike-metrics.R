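#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

# local maxima of x with topographic prominence >= prom; returns indices
find_peaks <- function(x, prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    left <- x[seq_len(i)]
    right <- x[i:n]
    hi_l <- which(left > x[i])
    hi_r <- which(right > x[i])
    base_l <- if (length(hi_l)) min(left[max(hi_l):i]) else min(left)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
    keep[k] <- (x[i] - max(base_l, base_r)) >= prom
  }
  cand[keep]
}

# quadratic sub-sample refinement of a peak location on a uniform grid
refine_peak_time <- function(tt, x, i) {
  if (i <= 1 || i >= length(x)) return(tt[i])
  y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(tt[i])
  tt[i] + 0.5 * (y1 - y3) / den * (tt[2] - tt[1])
}

#' Detect amplitude spikes in a trajectory
#'
#' Spikes are local maxima of the amplitude series with topographic
#' prominence at least `prominence_frac` of the mode's amplitude range,
#' separated by at least a refractory gap.  Peak times are refined by
#' quadratic interpolation on the output grid.
#'
#' @param traj A `wetcow_trajectory` tibble (possibly multi-mode).
#' @param modes Which modes to analyse; default all.
#' @param prominence_frac Fraction of the per-mode amplitude range required
#'   as prominence (default 0.5).
#' @param refractory Minimum gap between spikes; default half the analytic
#'   effective period when it is defined for the trajectory's parameters,
#'   else 0.
#' @param min_periods Minimum number of expected periods the trajectory
#'   must cover when the analytic period is known (default 3).
#' @return A tibble of class `wetcow_spikes` with columns `mode`,
#'   `spike_time`; detection settings are stored as attributes.
#' @export
detect_spikes <- function(traj, modes = NULL, prominence_frac = 0.5,
                          refractory = NULL, min_periods = 3) {
  stopifnot(is.data.frame(traj),
            all(c("time", "mode", "amplitude") %in% names(traj)))
  p <- attr(traj, "params")
  T_s <- NA_real_
  if (inherits(p, "wetcow_mode_params")) {
    T_s <- suppressWarnings(criticality(p)$T_s)
  }
  if (is.null(refractory)) refractory <- if (is.finite(T_s)) T_s / 2 else 0
  if (is.finite(T_s) && diff(range(traj$time)) < min_periods * T_s) {
    stop("insufficient data: trajectory covers fewer than ", min_periods,
         " expected periods", call. = FALSE)
  }
  modes <- modes %||% sort(unique(traj$mode))
  out <- lapply(modes, function(m) {
    d <- traj[traj$mode == m, ]
    rng <- diff(range(d$amplitude))
    if (rng <= 0) return(tibble::tibble(mode = m, spike_time = numeric(0)))
    idx <- find_peaks(d$amplitude, prom = prominence_frac * rng)
    st <- vapply(idx, function(i) refine_peak_time(d$time, d$amplitude, i),
                 numeric(1))
    if (refractory > 0 && length(st) > 1) {
      kept <- st[1]
      for (s in st[-1]) if (s - kept[length(kept)] >= refractory) kept <- c(kept, s)
      st <- kept
    }
    tibble::tibble(mode = m, spike_time = st)
  })
  tibble::new_tibble(dplyr::bind_rows(out),
                     detection = list(prominence_frac = prominence_frac,
                                      refractory = refractory),
                     class = "wetcow_spikes")
}

#' Effective frequency from a spike train
#'
#' Robust peak-to-peak estimate: \eqn{\hat\omega_s = 2\pi /
#' \mathrm{median}(\Delta t)} with the interquartile range of the
#' inter-spike intervals as dispersion.  Modes with fewer than three spikes
#' yield an explicit undefined result (`NA`), not an error.
#'
#' @param spikes A `wetcow_spikes` tibble from [detect_spikes()].
#' @return A tibble with columns `mode`, `n_spikes`, `omega_s_hat`,
#'   `dispersion`, `defined`.
#' @export
estimate_effective_frequency <- function(spikes) {
  stopifnot(is.data.frame(spikes),
            all(c("mode", "spike_time") %in% names(spikes)))
  spikes |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      n_spikes = dplyr::n(),
      omega_s_hat = if (dplyr::n() >= 3) {
        2 * pi / stats::median(diff(.data$spike_time))
      } else NA_real_,
      dispersion = if (dplyr::n() >= 3) {
        stats::IQR(diff(.data$spike_time))
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(defined = !is.na(.data$omega_s_hat))
}

#' Synchronization metrics for a multi-mode trajectory
#'
#' Computes per-mode measured effective frequencies, the matrix of pairwise
#' nearest-spike offsets normalized by the common period, the Kuramoto
#' order parameter \eqn{R(t) = |\langle e^{i\phi}\rangle|} on wrapped
#' phases, and the synchronization time: the earliest time from which
#' \eqn{R(t)} stays at or above `order_threshold` until the end of the run.
#' Spike statistics discard an initial transient.
#'
#' @param traj A multi-mode `wetcow_trajectory`.
#' @param spikes Optional precomputed `wetcow_spikes` (computed on the
#'   post-transient window when omitted).
#' @param transient_frac Fraction of the run discarded for spike statistics
#'   (default 0.25).
#' @param order_threshold Order-parameter level defining "synchronized"
#'   (default 0.95).
#' @return An object of class `wetcow_sync_report`: a list with
#'   `frequencies` (tibble), `offsets` (tibble `mode_i`, `mode_j`,
#'   `offset`, `offset_frac`), `order_parameter` (tibble `time`, `R`),
#'   `sync_time`, `common_period`, `freq_spread`.
#' @export
sync_metrics <- function(traj, spikes = NULL, transient_frac = 0.25,
                         order_threshold = 0.95) {
  stopifnot(is.data.frame(traj), length(unique(traj$mode)) >= 2)
  t_end <- max(traj$time)
  late <- traj[traj$time >= transient_frac * t_end, ]
  attr(late, "params") <- NULL
  if (is.null(spikes)) spikes <- detect_spikes(late)
  freq <- estimate_effective_frequency(spikes)
  ws <- freq$omega_s_hat[freq$defined]
  common_period <- if (length(ws)) 2 * pi / mean(ws) else NA_real_
  freq_spread <- if (length(ws) >= 2) stats::sd(ws) / mean(ws) else NA_real_
  modes <- sort(unique(traj$mode))
  trains <- lapply(modes, function(m) spikes$spike_time[spikes$mode == m])
  pairs <- utils::combn(seq_along(modes), 2)
  offs <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    si <- trains[[i]]; sj <- trains[[j]]
    off <- if (length(si) && length(sj)) {
      stats::median(vapply(si, function(s) min(abs(sj - s)), numeric(1)))
    } else NA_real_
    tibble::tibble(mode_i = modes[i], mode_j = modes[j], offset = off,
                   offset_frac = off / common_period)
  })
  ph <- traj |>
    dplyr::select("time", "mode", "phase") |>
    tidyr::pivot_wider(names_from = "mode", values_from = "phase")
  tt <- ph$time
  R <- abs(rowMeans(exp(1i * as.matrix(ph[, -1]))))
  below <- which(R < order_threshold)
  sync_time <- if (length(below) == 0) {
    0
  } else if (max(below) == length(R)) {
    NA_real_
  } else {
    tt[max(below) + 1]
  }
  structure(list(frequencies = freq, offsets = offs,
                 order_parameter = tibble::tibble(time = tt, R = R),
                 sync_time = sync_time, common_period = common_period,
                 freq_spread = freq_spread,
                 order_threshold = order_threshold),
            class = "wetcow_sync_report")
}

#' @export
print.wetcow_sync_report <- function(x, ...) {
  cat("<wetcow sync report>\n")
  cat(sprintf("  common period: %s, frequency spread: %s\n",
              format(x$common_period), format(x$freq_spread)))
  cat(sprintf("  sync time (R >= %g sustained): %s\n",
              x$order_threshold, format(x$sync_time)))
  cat(sprintf("  max pairwise spike offset: %s of common period\n",
              format(max(x$offsets$offset_frac))))
  invisible(x)
}

#' @rdname sync_metrics
#' @param x A `wetcow_sync_report`.
#' @param ... Unused.
#' @method tidy wetcow_sync_report
#' @export
tidy.wetcow_sync_report <- function(x, ...) {
  x$frequencies
}

#' @rdname sync_metrics
#' @method glance wetcow_sync_report
#' @export
glance.wetcow_sync_report <- function(x, ...) {
  tibble::tibble(common_period = x$common_period,
                 freq_spread = x$freq_spread,
                 sync_time = x$sync_time,
                 max_offset_frac = max(x$offsets$offset_frac))
}

#' Classify the dynamical regime of a single-mode trajectory
#'
#' Labels a trajectory as one of `linear`, `anharmonic`,
#' `subcritical_spiking`, or `supercritical`, combining the criticality
#' parameter with trajectory shape.  The numeric boundaries are documented
#' heuristics: `supercritical` when \eqn{c_r \ge 1} or at most one spike is
#' followed by silence; `subcritical_spiking` when at least three spikes
#' are detected; otherwise `linear` when the post-transient amplitude
#' stays below 10% of the saturation scale and the waveform's harmonic
#' distortion is below 5%, else `anharmonic`.
#'
#' @param params The [mode_params()] used to produce the trajectory.
#' @param traj A single-mode `wetcow_trajectory` covering at least
#'   `min_periods` linear periods.
#' @param min_periods Minimum coverage in linear periods (default 20).
#' @return A one-row tibble with columns `regime`, `c_r`, `n_spikes`,
#'   `confident`.
#' @export
classify_regime <- function(params, traj, min_periods = 20) {
  validate_mode_params(params)
  lin_period <- 2 * pi / params$omega
  if (diff(range(traj$time)) < min_periods * lin_period) {
    stop("trajectory too short: need at least ", min_periods,
         " linear periods", call. = FALSE)
  }
  cr <- criticality(params)$c_r
  t_end <- max(traj$time)
  late <- traj[traj$time >= 0.25 * t_end, ]
  attr(late, "params") <- NULL
  spikes <- detect_spikes(late)
  n_spk <- nrow(spikes)
  # "spiky" steady state: the amplitude sweeps most of its own scale each
  # cycle (relaxation spikes dip toward zero); small oscillations do not
  spiky <- diff(range(late$amplitude)) > 0.5 * max(late$amplitude)
  full_spk <- nrow(detect_spikes(traj))   # prominent events incl. transient
  if (cr >= 1 || (!spiky && full_spk >= 1)) {
    # at most one spike-like transition followed by silence
    return(tibble::tibble(regime = "supercritical", c_r = cr,
                          n_spikes = min(full_spk, 1L),
                          confident = cr >= 1 || full_spk <= 1))
  }
  if (spiky && n_spk >= 3) {
    return(tibble::tibble(regime = "subcritical_spiking", c_r = cr,
                          n_spikes = n_spk, confident = TRUE))
  }
  # small-signal regimes: compare peak amplitude to the spiking amplitude
  # scale omega/(w_phi cos phi_c), at which phase rotation can stall
  sat <- params$omega / max(params$w_phi * cos(critical_phase(params)), 1e-6)
  amp <- late$amplitude
  distortion <- harmonic_distortion(amp * cos(late$phase))
  lab <- if (max(amp) < 0.1 * sat && distortion < 0.05) "linear" else "anharmonic"
  tibble::tibble(regime = lab, c_r = cr, n_spikes = n_spk,
                 confident = distortion < 0.04 || distortion > 0.06)
}

# fraction of AC power outside the fundamental band of the waveform;
# Hann-windowed to suppress leakage from non-integer period counts
harmonic_distortion <- function(x) {
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  x <- x * (0.5 - 0.5 * cos(2 * pi * seq_along(x) / length(x)))
  sp <- Mod(stats::fft(x))^2
  n <- length(sp)
  half <- sp[2:floor(n / 2)]
  if (!length(half)) return(0)
  k <- which.max(half)
  band <- intersect(seq(k - 2, k + 2), seq_along(half))
  1 - sum(half[band]) / sum(half)
}
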