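#' Center, rescale and downsample an intensity image
#'
#' Moves an image into a common reference frame and reduces it to a small
#' grid: the intensity centroid is shifted (by whole pixels) to the image
#' center, the bounding box of nonzero intensity is rescaled so its longer
#' side fills the frame (bilinear interpolation), and the frame is reduced
#' by block averaging.  With the defaults a 28 x 28 image becomes 7 x 7.
#' Integer translations of a pattern therefore map to identical outputs.
#'
#' @param image Nonnegative numeric matrix.
#' @param size Output side length (must divide the input side), default 7.
#' @param center Shift the intensity centroid to the frame center.
#' @param rescale Rescale the nonzero bounding box to fill the frame.
#' @return A `size` x `size` matrix in `[0, 1]`; an all-zero input is
#'   returned block-averaged unchanged with attribute `empty = TRUE`.
#' @export
downsample_center <- function(image, size = 7, center = TRUE, rescale = TRUE) {
  stopifnot(is.matrix(image), all(image >= 0))
  nr <- nrow(image); nc <- ncol(image)
  stopifnot(nr == nc, nr %% size == 0)
  if (all(image == 0)) {
    warning("all-zero image: returned unchanged", call. = FALSE)
    out <- block_mean(image, nr / size)
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (center) {
    tot <- sum(image)
    cr <- sum(row(image) * image) / tot
    cc <- sum(col(image) * image) / tot
    image <- shift_image(image, round((nr + 1) / 2 - cr), round((nc + 1) / 2 - cc))
  }
  if (rescale) {
    nz <- which(image > 0, arr.ind = TRUE)
    r1 <- min(nz[, 1]); r2 <- max(nz[, 1])
    c1 <- min(nz[, 2]); c2 <- max(nz[, 2])
    side <- max(r2 - r1 + 1, c2 - c1 + 1)
    # square box around the bounding box, clipped to the frame
    rc <- (r1 + r2) / 2; cc2 <- (c1 + c2) / 2
    r1 <- max(1, min(nr - side + 1, round(rc - side / 2 + 0.5)))
    c1 <- max(1, min(nc - side + 1, round(cc2 - side / 2 + 0.5)))
    image <- bilinear_resize(image[r1:(r1 + side - 1), c1:(c1 + side - 1),
                                   drop = FALSE], nr)
  }
  out <- block_mean(image, nr / size)
  pmin(pmax(out, 0), 1)
}

shift_image <- function(image, dr, dc) {
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- image[src_r[ok_r], src_c[ok_c]]
  out
}

bilinear_resize <- function(image, out_side) {
  n <- nrow(image)
  if (n == out_side) return(image)
  # map output pixel centers onto input pixel centers
  pos <- (seq_len(out_side) - 0.5) * n / out_side + 0.5
  lo <- pmin(pmax(floor(pos), 1), n)
  hi <- pmin(lo + 1, n)
  fr <- pos - lo
  out <- matrix(0, out_side, out_side)
  for (i in seq_len(out_side)) {
    ri <- (1 - fr[i]) * image[lo[i], ] + fr[i] * image[hi[i], ]
    out[i, ] <- (1 - fr) * ri[lo] + fr * ri[hi]
  }
  out
}

block_mean <- function(image, f) {
  n <- nrow(image) / f
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- mean(image[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  }
  out
}

#' Pattern-to-drive encoder
#'
#' Maps a small intensity grid to a vector of sensory drive rates, one per
#' mode of a memory loop.  Pixels (row-major) are split into `n_groups`
#' nearly equal contiguous groups; each group's mean intensity is mapped
#' affinely into a subcritical drive range expressed through the
#' criticality parameter: intensity 0 gives `c_r = cr_range[1]`, intensity
#' 1 gives `c_r = cr_range[2]`, converted to a rate via \eqn{\gamma = c_r
#' \,\omega / w} with the reference mode constants.
#'
#' @param n_groups Number of drive channels (modes per loop).
#' @param cr_range Criticality range the drives map into.
#' @param reference A [mode_params()] supplying `omega` and the coupling
#'   factor.
#' @return An encoder object (class `wetcow_encoder`).
#' @export
make_encoder <- function(n_groups = 10, cr_range = c(0.1, 0.95),
                         reference = mode_params()) {
  stopifnot(n_groups >= 1, cr_range[1] >= 0, cr_range[2] > cr_range[1])
  wfac <- coupling_factor(reference)
  structure(list(n_groups = n_groups, cr_range = cr_range,
                 omega = reference$omega, wfac = wfac,
                 gamma_range = cr_range * reference$omega / wfac),
            class = "wetcow_encoder")
}

#' Encode a pattern as per-mode sensory drives
#'
#' @param pattern Numeric matrix with intensities in `[0, 1]`.
#' @param encoder A [make_encoder()] object.
#' @return Numeric drive vector of length `encoder$n_groups`.
#' @export
encode_excitations <- function(pattern, encoder) {
  stopifnot(inherits(encoder, "wetcow_encoder"),
            all(pattern >= 0), all(pattern <= 1))
  v <- as.vector(t(pattern))  # row-major
  groups <- split(v, cut(seq_along(v), encoder$n_groups, labels = FALSE))
  m <- vapply(groups, mean, numeric(1))
  gr <- encoder$gamma_range
  unname(gr[1] + m * (gr[2] - gr[1]))
}

class_loop_seed <- function(seed, class) seed + 1000L * (class + 1L)

# build one class's memory loop: couplings replicate the class mean drive
# on the amplitude side and equalize effective frequencies for the doubled
# drive (construction drive + an equal presented drive), so that presenting
# the class prototype reproduces the loop's reference response exactly
build_class_loop <- function(mean_drive, n_modes, seed) {
  set.seed(seed)
  modes <- lapply(seq_len(n_modes), function(i) mode_params(gamma = 0))
  wfac <- coupling_factor(modes[[1]])
  gbar <- 2 * mean_drive            # coupling feedback + presented drive
  t2 <- 1 - mean((gbar * wfac)^2)   # balances effective frequencies around omega = 1
  if (t2 <= 0) {
    stop("construction error: class mean drive too strong for a subcritical loop",
         call. = FALSE)
  }
  omega_bar <- sqrt(t2 + (gbar * wfac)^2)
  # small loops need proportionally stronger links to carry the row sums
  w_hi <- max(0.2, 1.5 / (n_modes - 1))
  spec <- assemble_sync_spec(modes, amp_targets = mean_drive,
                             phase_targets = 1 - omega_bar,
                             w_range = c(0, w_hi),
                             delta_range = c(-pi / 2, pi / 2),
                             seed = seed)
  spec$omega_s_target <- sqrt(t2)
  spec
}

# integrate a loop under a presented drive and return per-mode measured
# spiking frequencies (NA replaced by 0: silent or locked modes)
loop_response <- function(spec, drive, t_sim, dt_out = 0.05) {
  traj <- integrate_network(set_drive(spec, drive), t_end = t_sim,
                            dt_out = dt_out)
  late <- traj[traj$time >= 0.25 * t_sim, ]
  attr(late, "params") <- NULL
  freq <- estimate_effective_frequency(detect_spikes(late))
  f <- freq$omega_s_hat
  f[is.na(f)] <- 0
  f
}

#' Construct a shallow synchronization classifier
#'
#' Single-pass construction: each class's training patterns are encoded
#' once, their mean drive vector is computed, and a critically synchronized
#' memory loop is built in closed form whose couplings replicate that mean
#' drive and equalize the modes' effective frequencies.  The loop's
#' reference response (per-mode measured spiking frequencies under the
#' class mean drive) is recorded; classification later compares a
#' pattern's response against each class's reference.  No example is
#' visited twice and no gradient step is taken.
#'
#' Per-class loops are disjoint and are built from a per-class random
#' stream, so constructing an additional class leaves existing loops
#' bit-identical (see [add_classes()]).
#'
#' @param train A `wetcow_patterns` tibble (rows tagged `split == "train"`
#'   are used; other rows are ignored).
#' @param n_modes Modes per class loop (default 10).
#' @param cr_range Encoder criticality range (default `c(0.1, 0.45)` so
#'   that construction-plus-presented drive stays subcritical).
#' @param seed Integer seed; class `c` uses the derived stream
#'   `seed + 1000*(c+1)`.
#' @param t_sim Response integration horizon; default 20 periods of the
#'   loop target frequency.
#' @return An object of class `wetcow_classifier` with attribute
#'   `n_example_visits` counting training-example encodings.
#' @seealso [predict.wetcow_classifier()], [refine_classifier()],
#'   [evaluate_classifier()]
#' @export
construct_classifier <- function(train, n_modes = 10, cr_range = c(0.1, 0.45),
                                 seed = 1, t_sim = NULL) {
  stopifnot(is.data.frame(train), all(c("class", "pattern") %in% names(train)))
  if ("split" %in% names(train)) train <- train[train$split == "train", ]
  if (nrow(train) == 0) stop("no training examples", call. = FALSE)
  classes <- sort(unique(train$class))
  encoder <- make_encoder(n_groups = n_modes, cr_range = cr_range)
  visits <- 0L
  loops <- list()
  refs <- list()
  for (cl in classes) {
    pats <- train$pattern[train$class == cl]
    drives <- vapply(pats, encode_excitations, numeric(encoder$n_groups),
                     encoder = encoder)
    visits <- visits + length(pats)
    mean_drive <- rowMeans(matrix(drives, nrow = encoder$n_groups))
    if (all(mean_drive == 0)) {
      stop("degenerate class ", cl, ": zero mean drive", call. = FALSE)
    }
    loop <- build_class_loop(mean_drive, n_modes,
                             seed = class_loop_seed(seed, cl))
    horizon <- t_sim %||% (20 * 2 * pi / loop$omega_s_target)
    refs[[as.character(cl)]] <- loop_response(loop, mean_drive, t_sim = horizon)
    loop$mean_drive <- mean_drive
    loop$horizon <- horizon
    loops[[as.character(cl)]] <- loop
  }
  structure(list(classes = classes, loops = loops, reference = refs,
                 encoder = encoder, seed = seed,
                 tie_tol = 1e-9),
            class = "wetcow_classifier",
            n_example_visits = visits)
}

#' Add classes to an existing classifier
#'
#' Builds loops for classes present in `train` but absent from the model;
#' loops of existing classes are untouched (the continual-learning probe:
#' new knowledge occupies new loops).
#'
#' @param model A `wetcow_classifier`.
#' @param train A `wetcow_patterns` tibble containing the new classes.
#' @return The extended `wetcow_classifier`.
#' @export
add_classes <- function(model, train) {
  stopifnot(inherits(model, "wetcow_classifier"))
  if ("split" %in% names(train)) train <- train[train$split == "train", ]
  new_cl <- setdiff(sort(unique(train$class)), model$classes)
  if (!length(new_cl)) return(model)
  visits <- attr(model, "n_example_visits")
  for (cl in new_cl) {
    pats <- train$pattern[train$class == cl]
    drives <- vapply(pats, encode_excitations,
                     numeric(model$encoder$n_groups), encoder = model$encoder)
    visits <- visits + length(pats)
    mean_drive <- rowMeans(matrix(drives, nrow = model$encoder$n_groups))
    loop <- build_class_loop(mean_drive, model$encoder$n_groups,
                             seed = class_loop_seed(model$seed, cl))
    horizon <- 20 * 2 * pi / loop$omega_s_target
    model$reference[[as.character(cl)]] <- loop_response(loop, mean_drive,
                                                         t_sim = horizon)
    loop$mean_drive <- mean_drive
    loop$horizon <- horizon
    model$loops[[as.character(cl)]] <- loop
  }
  model$classes <- sort(c(model$classes, new_cl))
  attr(model, "n_example_visits") <- visits
  model
}

score_pattern <- function(model, pattern) {
  drive <- encode_excitations(pattern, model$encoder)
  vapply(as.character(model$classes), function(cl) {
    loop <- model$loops[[cl]]
    f <- loop_response(loop, drive, t_sim = loop$horizon)
    -sqrt(mean((f - model$reference[[cl]])^2))
  }, numeric(1))
}

#' Classify patterns by synchronization response
#'
#' Each candidate loop is driven with the encoded pattern and integrated;
#' the score of class `c` is the negative root-mean-square deviation of the
#' measured per-mode spiking frequencies from the class's reference
#' response.  The label is the argmax score; ties (within `tie_tol`) break
#' to the lowest class index.
#'
#' @param object A `wetcow_classifier`.
#' @param newdata A `wetcow_patterns` tibble, a list of matrices, or one
#'   matrix.
#' @param ... Unused.
#' @return A tibble with columns `pred_class` and one `score_<class>`
#'   column per class (plus `id`, `class` when present in `newdata`).
#' @export
predict.wetcow_classifier <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- tibble::tibble(pattern = list(newdata))
  if (is.list(newdata) && !is.data.frame(newdata)) {
    newdata <- tibble::tibble(pattern = newdata)
  }
  stopifnot("pattern" %in% names(newdata))
  out <- purrr::map_dfr(seq_len(nrow(newdata)), function(r) {
    sc <- score_pattern(object, newdata$pattern[[r]])
    best <- max(sc)
    pred <- object$classes[which(sc >= best - object$tie_tol)[1]]
    row <- tibble::as_tibble(as.list(stats::setNames(
      sc, paste0("score_", object$classes))))
    row$pred_class <- pred
    row
  })
  keep <- intersect(c("id", "class"), names(newdata))
  dplyr::bind_cols(newdata[keep], out[c("pred_class",
                                        setdiff(names(out), "pred_class"))])
}

#' Refine a classifier by seeded coordinate search
#'
#' Gradient-free improvement: each iteration re-solves one coupling row of
#' one class loop with a fresh random draw (row targets, and hence the
#' synchronization conditions, are preserved exactly), recomputes that
#' class's reference response, and keeps the change only if training error
#' does not increase.  Stops early at zero training error.  Runs are
#' reproducible for a fixed seed.
#'
#' @param model A `wetcow_classifier`.
#' @param train Training `wetcow_patterns`.
#' @param n_iter Number of proposals (>= 1).
#' @param seed Integer seed for the proposal stream.
#' @return The best-on-train `wetcow_classifier`.
#' @export
refine_classifier <- function(model, train, n_iter = 5, seed = 1) {
  stopifnot(inherits(model, "wetcow_classifier"), n_iter >= 1)
  if ("split" %in% names(train)) train <- train[train$split == "train", ]
  train_err <- function(m) {
    pr <- stats::predict(m, train)
    sum(pr$pred_class != train$class)
  }
  best_err <- train_err(model)
  if (best_err == 0) return(model)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    cl <- as.character(sample(model$classes, 1))
    loop <- model$loops[[cl]]
    n <- n_modes(loop)
    i <- sample(n, 1)
    row <- solve_coupling_row(n - 1L,
                              loop$sync_targets$amp_target[i],
                              loop$sync_targets$phase_target[i],
                              w_range = c(0, 0.2),
                              delta_range = c(-pi / 2, pi / 2))
    if (is.null(row)) next
    cand <- model
    j <- setdiff(seq_len(n), i)
    cand$loops[[cl]]$coupling_w[i, j] <- row$w
    cand$loops[[cl]]$coupling_delta[i, j] <- row$delta
    cand$reference[[cl]] <- loop_response(cand$loops[[cl]],
                                          cand$loops[[cl]]$mean_drive,
                                          t_sim = cand$loops[[cl]]$horizon)
    err <- train_err(cand)
    if (err <= best_err) {
      model <- cand
      best_err <- err
      if (best_err == 0) break
    }
  }
  model
}

#' Evaluate a classifier on a held-out split
#'
#' @param model A `wetcow_classifier`.
#' @param test A `wetcow_patterns` tibble; rows tagged `split == "test"`
#'   are used when the tag is present.  An empty test set is an error.
#' @return A list with `accuracy`, `errors` (count), `n`, `predictions`
#'   (tibble) and `confusion` (tibble `class`, `pred_class`, `n`).
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "wetcow_classifier"))
  if ("split" %in% names(test)) test <- test[test$split == "test", ]
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  pr <- stats::predict(model, test)
  acc <- mean(pr$pred_class == test$class)
  conf <- pr |>
    dplyr::count(.data$class, .data$pred_class, name = "n")
  list(accuracy = acc, errors = sum(pr$pred_class != test$class),
       n = nrow(test), predictions = pr, confusion = conf)
}

#' @rdname construct_classifier
#' @param x A `wetcow_classifier`.
#' @param ... Unused.
#' @method tidy wetcow_classifier
#' @export
tidy.wetcow_classifier <- function(x, ...) {
  purrr::map_dfr(as.character(x$classes), function(cl) {
    loop <- x$loops[[cl]]
    tibble::tibble(
      class = as.integer(cl),
      n_modes = n_modes(loop),
      omega_s_target = loop$omega_s_target,
      mean_drive = mean(loop$mean_drive),
      max_amp_residual = max(abs(verify_sync_conditions(loop)$amp_residual)),
      reference_freq = stats::median(x$reference[[cl]])
    )
  })
}

#' @rdname construct_classifier
#' @method glance wetcow_classifier
#' @export
glance.wetcow_classifier <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_modes_per_loop = x$encoder$n_groups,
    n_example_visits = attr(x, "n_example_visits"),
    seed = x$seed
  )
}

#' @export
print.wetcow_classifier <- function(x, ...) {
  cat("<wetcow shallow classifier> ", length(x$classes), " classes, ",
      x$encoder$n_groups, " modes per loop\n", sep = "")
  invisible(x)
}
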