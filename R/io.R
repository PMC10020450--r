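#' @title File formats
#' @description
#' All artifacts serialize to plain-text formats: trajectories and spike
#' rasters as CSV (comma-separated, header row, `.` decimal, no index
#' column), parameter sets and reports as JSON with snake_case keys,
#' network specifications as YAML or JSON, and image datasets optionally in
#' the binary IDX container.  Writers produce a sidecar or embedded
#' metadata block sufficient to reconstruct the object.
#' @name wetcow_io
NULL

mode_params_to_list <- function(p) {
  unclass(p)
}

mode_params_from_list <- function(l) {
  do.call(mode_params, l[c("gamma", "omega", "alpha", "psi", "w_a", "w_phi",
                           "gamma0")])
}

#' Write and read trajectories
#'
#' The trajectory goes to CSV (`time`, `mode`, `amplitude`, `phase`); the
#' generating parameters, solver settings and seed go to a JSON sidecar
#' named `<path>.json`.
#'
#' @param traj A `wetcow_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory with attributes restored.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "wetcow_trajectory"))
  readr::write_csv(tibble::as_tibble(traj), path)
  p <- attr(traj, "params")
  meta <- list(
    format_version = 1L,
    params = if (inherits(p, "wetcow_mode_params")) mode_params_to_list(p)
             else if (inherits(p, "wetcow_network")) network_to_list(p)
             else NULL,
    params_kind = class(p)[1],
    solver = attr(traj, "solver"),
    seed = attr(traj, "seed")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(path, ".json")
  params <- NULL; solver <- NULL; seed <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$format_version) && meta$format_version > 1L) {
      stop("incompatible trajectory format version ", meta$format_version,
           call. = FALSE)
    }
    solver <- meta$solver
    seed <- meta$seed %||% NA_integer_
    if (identical(meta$params_kind, "wetcow_mode_params")) {
      params <- mode_params_from_list(meta$params)
    } else if (identical(meta$params_kind, "wetcow_network")) {
      params <- network_from_list(meta$params)
    }
  }
  df$mode <- as.integer(df$mode)
  new_trajectory(df, params = params, solver = solver, seed = seed)
}

network_to_list <- function(spec) {
  list(
    format_version = 1L,
    modes = lapply(spec$modes, mode_params_to_list),
    coupling_w = apply(spec$coupling_w, 1, as.numeric, simplify = FALSE),
    coupling_delta = apply(spec$coupling_delta, 1, as.numeric, simplify = FALSE),
    directed = spec$directed,
    seed = if (is.na(spec$seed)) NULL else spec$seed,
    omega_s_target = spec$omega_s_target,
    sync_targets = if (!is.null(spec$sync_targets)) {
      as.list(spec$sync_targets)
    }
  )
}

network_from_list <- function(l) {
  if (!is.null(l$format_version) && l$format_version > 1L) {
    stop("incompatible network format version ", l$format_version, call. = FALSE)
  }
  n <- length(l$modes)
  W <- do.call(rbind, lapply(l$coupling_w, as.numeric))
  D <- do.call(rbind, lapply(l$coupling_delta, as.numeric))
  spec <- network_spec(lapply(l$modes, mode_params_from_list), W, D,
                       directed = l$directed %||% TRUE,
                       seed = l$seed %||% NA_integer_)
  spec$omega_s_target <- l$omega_s_target
  if (!is.null(l$sync_targets)) {
    spec$sync_targets <- tibble::as_tibble(lapply(l$sync_targets, unlist))
  }
  spec
}

#' Write and read network specifications
#'
#' Format chosen by file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param spec A [network_spec()].
#' @param path Output path.
#' @return `write_network_spec` returns `path` invisibly;
#'   `read_network_spec` the restored spec.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "wetcow_network"))
  l <- network_to_list(spec)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(l, path)
  } else {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  l <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  network_from_list(l)
}

#' Write spike trains as a CSV raster
#'
#' @param spikes A `wetcow_spikes` tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(tibble::as_tibble(spikes), path)
  invisible(path)
}

#' Write a synchronization report as JSON
#'
#' @param report A `wetcow_sync_report`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_sync_report <- function(report, path) {
  stopifnot(inherits(report, "wetcow_sync_report"))
  jsonlite::write_json(
    list(frequencies = report$frequencies, offsets = report$offsets,
         sync_time = report$sync_time, common_period = report$common_period,
         freq_spread = report$freq_spread,
         order_threshold = report$order_threshold),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write and read pattern datasets
#'
#' Patterns are flattened row-major into a CSV (one row per sample, pixel
#' columns `p1..pK` plus `id`, `class`, `split`); the generating
#' configuration goes to a JSON sidecar.
#'
#' @param data A `wetcow_patterns` tibble.
#' @param path CSV path.
#' @return `write_pattern_dataset` returns `path` invisibly;
#'   `read_pattern_dataset` the restored dataset.
#' @export
write_pattern_dataset <- function(data, path) {
  stopifnot(is.data.frame(data), "pattern" %in% names(data))
  shape <- dim(data$pattern[[1]])
  px <- t(vapply(data$pattern, function(m) as.vector(t(m)),
                 numeric(prod(shape))))
  colnames(px) <- paste0("p", seq_len(ncol(px)))
  readr::write_csv(dplyr::bind_cols(data[c("id", "class", "split")],
                                    tibble::as_tibble(px)), path)
  jsonlite::write_json(list(shape = shape, config = attr(data, "config")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pattern_dataset
#' @export
read_pattern_dataset <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  px <- as.matrix(df[grepl("^p\\d+$", names(df))])
  pats <- lapply(seq_len(nrow(px)), function(r) {
    matrix(px[r, ], shape[1], shape[2], byrow = TRUE)
  })
  tibble::new_tibble(
    tibble::tibble(id = as.integer(df$id), class = as.integer(df$class),
                   split = df$split, pattern = pats),
    config = meta$config, class = "wetcow_patterns")
}

#' Read and write IDX image/label files
#'
#' The IDX container used by MNIST-style datasets: big-endian magic number
#' (2051 for unsigned-byte image tensors, 2049 for label vectors), then one
#' big-endian 32-bit size per dimension, then the row-major payload.
#'
#' @param path IDX file path.
#' @return `read_idx` returns an array (dimensions as stored; images scaled
#'   to `[0, 1]` when `scale = TRUE`); `write_idx` returns `path`
#'   invisibly.
#' @param scale Divide unsigned-byte image data by 255.
#' @export
read_idx <- function(path, scale = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  ndim <- magic %% 256
  type <- (magic %/% 256) %% 256
  if (!type %in% c(8L)) stop("unsupported IDX data type ", type, call. = FALSE)
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  raw <- readBin(con, "integer", n = prod(dims), size = 1, signed = FALSE)
  arr <- array(raw, dim = rev(dims))   # stored row-major; R fills col-major
  arr <- aperm(arr, rev(seq_len(ndim)))
  if (scale && ndim > 1) arr <- arr / 255
  arr
}

#' @rdname read_idx
#' @param x Array (images; values in `[0, 1]` are scaled to bytes) or
#'   integer vector (labels).
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- dim(x) %||% length(x)
  ndim <- length(dims)
  magic <- 8L * 256L + ndim   # unsigned byte
  writeBin(as.integer(magic), con, size = 4, endian = "big")
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  v <- if (is.array(x)) as.vector(aperm(x, rev(seq_len(ndim)))) else x
  if (is.double(v)) v <- round(v * 255)
  writeBin(as.integer(pmin(pmax(v, 0), 255)), con, size = 1)
  invisible(path)
}

#' Load an IDX image/label pair as a pattern dataset
#'
#' Reads MNIST-style files, applies [downsample_center()] to each image and
#' returns a `wetcow_patterns` tibble.  Intended for the optional
#' external-data demo; all package tests use synthetic data.
#'
#' @param image_path,label_path IDX files (magic 2051 and 2049).
#' @param size Downsampled side length.
#' @param split Split tag given to all rows.
#' @param n_max Optional cap on the number of images loaded.
#' @return A `wetcow_patterns` tibble.
#' @export
read_idx_dataset <- function(image_path, label_path, size = 7,
                             split = "train", n_max = NULL) {
  imgs <- read_idx(image_path)
  labs <- read_idx(label_path, scale = FALSE)
  n <- dim(imgs)[1]
  if (!is.null(n_max)) n <- min(n, n_max)
  pats <- lapply(seq_len(n), function(i) {
    suppressWarnings(downsample_center(matrix(imgs[i, , ], dim(imgs)[2],
                                              dim(imgs)[3]), size = size))
  })
  tibble::new_tibble(
    tibble::tibble(id = seq_len(n), class = as.integer(labs[seq_len(n)]),
                   split = split, pattern = pats),
    config = list(source = image_path), class = "wetcow_patterns")
}
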