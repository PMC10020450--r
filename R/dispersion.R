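#' Conductivity tensor field on a regular grid
#'
#' Stores a permittivity-scaled conductivity tensor \eqn{\Sigma_{ij}} at
#' every point of a regular 1-3 dimensional grid.  Lower-dimensional fields
#' are embedded as degenerate 3D tensors internally; coordinate order is
#' `(x, y, z)`.
#'
#' @param sigma Numeric array of tensor entries.  For a grid with `d`
#'   spatial dimensions the array has `d + 2` dimensions: grid dims first,
#'   then the `d x d` tensor indices.  A single `d x d` matrix is accepted
#'   for a homogeneous field on a grid given by `dims`.
#' @param spacing Grid spacing per dimension (recycled; arbitrary length
#'   units).
#' @param dims Grid dimensions, required only when `sigma` is a single
#'   matrix.
#' @return An object of class `wetcow_field`.
#' @export
#' @examples
#' f <- conductivity_field(diag(3) * 2, spacing = 0.1, dims = c(5, 5, 5))
#' dispersion_rates(f, point = c(3, 3, 3), k = c(1, 0, 0))
conductivity_field <- function(sigma, spacing = 1, dims = NULL) {
  if (is.matrix(sigma) && !is.null(dims)) {
    d <- length(dims)
    stopifnot(all(dim(sigma) == c(d, d)))
    arr <- array(0, dim = c(dims, d, d))
    for (i in seq_len(d)) for (j in seq_len(d)) {
      arr[slice.index(arr, length(dims) + 1) == i &
            slice.index(arr, length(dims) + 2) == j] <- sigma[i, j]
    }
    sigma <- arr
  }
  nd <- length(dim(sigma))
  d <- (nd - 2)
  if (d < 1 || d > 3 ||
      dim(sigma)[nd - 1] != d || dim(sigma)[nd] != d) {
    stop("sigma must have d grid dimensions plus a d x d tensor, d in 1..3",
         call. = FALSE)
  }
  if (!all(is.finite(sigma))) stop("tensor entries must be finite", call. = FALSE)
  structure(list(sigma = sigma, spacing = rep_len(spacing, d), d = d,
                 dims = dim(sigma)[seq_len(d)]),
            class = "wetcow_field")
}

# tensor at one grid point (d x d matrix)
field_tensor <- function(field, point) {
  idx <- as.list(point)
  d <- field$d
  do.call(`[`, c(list(field$sigma), idx, list(TRUE, TRUE), drop = FALSE)) |>
    array(dim = c(d, d))
}

# divergence of the tensor: vector over j of sum_i dSigma_ij/dx_i,
# central differences, one-sided at boundaries (flagged)
field_divergence <- function(field, point) {
  d <- field$d
  div <- numeric(d)
  boundary <- FALSE
  for (i in seq_len(d)) {
    lo <- point; hi <- point
    h <- field$spacing[i]
    if (point[i] > 1 && point[i] < field$dims[i]) {
      lo[i] <- point[i] - 1; hi[i] <- point[i] + 1
      step <- 2 * h
    } else if (point[i] < field$dims[i]) {
      hi[i] <- point[i] + 1
      step <- h
      boundary <- TRUE
    } else if (point[i] > 1) {
      lo[i] <- point[i] - 1
      step <- h
      boundary <- TRUE
    } else {
      next  # single-layer dimension: derivative 0
    }
    div <- div + (field_tensor(field, hi)[i, ] - field_tensor(field, lo)[i, ]) / step
  }
  list(div = div, boundary = boundary)
}

#' Dispersion rates at a point
#'
#' Evaluates the linear dispersion relation of weakly evanescent waves in
#' an anisotropic, inhomogeneous conductive medium: for wavevector `k` the
#' temporal growth/damping rate and oscillation frequency are
#' \deqn{\gamma = \frac{\Sigma_{ij} k_i k_j}{k^2}, \qquad
#'       \omega = -\frac{(\partial_i \Sigma_{ij})\, k_j}{k^2}.}
#' Tensor gradients use central differences (one-sided at grid boundaries,
#' flagged as lower accuracy).
#'
#' @param field A [conductivity_field()].
#' @param point Integer grid indices (1-based, length = field dimension).
#' @param k Wavevector (nonzero, same length).
#' @return A one-row tibble with columns `gamma`, `omega`, `k_norm`,
#'   `boundary`.
#' @export
dispersion_rates <- function(field, point, k) {
  stopifnot(inherits(field, "wetcow_field"),
            length(point) == field$d, length(k) == field$d)
  if (all(k == 0)) stop("wavevector k must be nonzero", call. = FALSE)
  if (any(point < 1) || any(point > field$dims)) {
    stop("point outside grid", call. = FALSE)
  }
  k2 <- sum(k^2)
  S <- field_tensor(field, point)
  dv <- field_divergence(field, point)
  tibble::tibble(
    gamma = drop(t(k) %*% S %*% k) / k2,
    omega = -sum(dv$div * k) / k2,
    k_norm = sqrt(k2),
    boundary = dv$boundary
  )
}

# n roughly uniform directions: circle in 2D, Fibonacci sphere in 3D
scan_directions <- function(d, n) {
  if (d == 1) return(matrix(c(1, -1), ncol = 1)[seq_len(min(n, 2)), , drop = FALSE])
  if (d == 2) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(cos(th), sin(th)))
  }
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Directional scan of the dispersion rates
#'
#' Samples wave propagation directions uniformly and evaluates the growth
#' rate and frequency along each; in anisotropic tissue some directions
#' support much stronger growth than others (fiber directions).  The
#' direction maximizing `gamma` is flagged.
#'
#' @param field A [conductivity_field()].
#' @param point Grid indices.
#' @param k_magnitude Wavevector magnitude used for every direction.
#' @param n_directions Number of directions (>= 4).
#' @return A tibble with one row per direction: direction components
#'   (`dir_x`, ...), `gamma`, `omega`, `is_max_gamma`.
#' @export
direction_scan <- function(field, point, k_magnitude = 1, n_directions = 32) {
  stopifnot(n_directions >= 4)
  dirs <- scan_directions(field$d, n_directions)
  res <- purrr::map_dfr(seq_len(nrow(dirs)), function(r) {
    dispersion_rates(field, point, k_magnitude * dirs[r, ])
  })
  dir_df <- tibble::as_tibble(as.data.frame(dirs))
  names(dir_df) <- paste0("dir_", c("x", "y", "z")[seq_len(field$d)])
  out <- dplyr::bind_cols(dir_df, res[c("gamma", "omega")])
  out$is_max_gamma <- seq_len(nrow(out)) == which.max(out$gamma)
  out
}
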