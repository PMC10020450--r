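test_that("downsampling is invariant to uniformity and translation", {
  u <- matrix(0.6, 28, 28)
  expect_equal(downsample_center(u), matrix(0.6, 7, 7))
  # integer translation maps to the identical output
  pat <- matrix(0, 28, 28)
  pat[9:14, 11:16] <- matrix(runif(36), 6, 6)
  shifted <- wetcow:::shift_image(pat, 5, -3)
  expect_equal(downsample_center(pat), downsample_center(shifted),
               tolerance = 1e-6)
})

test_that("a bright block maps to a single bright output pixel", {
  # block-mean path without rescaling: a centered 4x4 block of value 0.8
  # lands in exactly one output cell
  img <- matrix(0, 28, 28)
  img[5:8, 21:24] <- 0.8
  out <- downsample_center(img, rescale = FALSE)   # centering moves it to the middle
  expect_equal(sum(out > 0), 1)
  expect_equal(out[4, 4], 0.8)
  expect_equal(sum(out), 0.8)
})

test_that("all-zero images are returned unchanged with a warning", {
  expect_warning(out <- downsample_center(matrix(0, 28, 28)), "all-zero")
  expect_equal(unclass(out)[1:7, 1:7], matrix(0, 7, 7), ignore_attr = TRUE)
  expect_true(attr(out, "empty"))
})

test_that("the encoder is affine from intensity to drive", {
  enc <- make_encoder(n_groups = 7, cr_range = c(0.1, 0.95))
  lo <- encode_excitations(matrix(0, 7, 7), enc)
  hi <- encode_excitations(matrix(1, 7, 7), enc)
  mid <- encode_excitations(matrix(0.5, 7, 7), enc)
  expect_equal(lo, rep(enc$gamma_range[1], 7))
  expect_equal(hi, rep(enc$gamma_range[2], 7))
  expect_equal(mid, (lo + hi) / 2)
  # the reference drive range is c_r * omega / w with w = 1/2
  expect_equal(enc$gamma_range, c(0.1, 0.95) / 0.5)
})

test_that("noiseless orthogonal prototypes are classified perfectly", {
  train <- orthogonal_patterns(n_per_class = 2)
  model <- construct_classifier(train, n_modes = 4, seed = 1)
  pr <- predict(model, train)
  expect_equal(pr$pred_class, train$class)
  # every class loop satisfies its construction-drive row conditions
  for (cl in c("0", "1")) {
    ver <- verify_sync_conditions(model$loops[[cl]])
    expect_lt(max(abs(ver$amp_residual)), 1e-10)
    expect_lt(max(abs(ver$phase_residual)), 1e-10)
  }
})

test_that("construction is single-pass and a lone class always wins", {
  train <- orthogonal_patterns(n_per_class = 3)
  model <- construct_classifier(train, n_modes = 4, seed = 2)
  expect_identical(attr(model, "n_example_visits"), 6L)
  one <- train[train$class == 0, ]
  m1 <- construct_classifier(one, n_modes = 4, seed = 2)
  pr <- predict(m1, train)
  expect_true(all(pr$pred_class == 0))
})

test_that("exact score ties break to the lowest class index", {
  train <- orthogonal_patterns()
  model <- construct_classifier(train, n_modes = 4, seed = 3)
  # force two identical class loops: scores tie exactly on any input
  model$loops[["1"]] <- model$loops[["0"]]
  model$reference[["1"]] <- model$reference[["0"]]
  pr <- predict(model, matrix(0.5, 7, 7))
  expect_equal(pr$pred_class, 0L)
  expect_equal(pr$score_0, pr$score_1)
})

test_that("adding a class leaves existing loops bit-identical", {
  set.seed(99)  # construction must not depend on ambient RNG state
  data3 <- make_pattern_dataset(n_classes = 3, n_per_class = 4, noise = 0.1,
                                seed = 5, test_frac = 0.25)
  first_two <- data3[data3$class < 2, ]
  m2 <- construct_classifier(first_two, n_modes = 4, seed = 7)
  m3 <- add_classes(m2, data3)
  expect_identical(m3$loops[["0"]], m2$loops[["0"]])
  expect_identical(m3$loops[["1"]], m2$loops[["1"]])
  expect_identical(m3$reference[["0"]], m2$reference[["0"]])
  expect_setequal(m3$classes, 0:2)
  # and the extended model equals a fresh three-class construction
  m3_direct <- construct_classifier(data3, n_modes = 4, seed = 7)
  expect_identical(m3$loops, m3_direct$loops)
})

test_that("evaluation bookkeeping: accuracy, errors, confusion sums", {
  data <- make_pattern_dataset(n_classes = 2, n_per_class = 6, noise = 0,
                               seed = 11, test_frac = 0.5)
  model <- construct_classifier(data, n_modes = 4, seed = 1)
  ev <- evaluate_classifier(model, data)
  expect_equal(ev$n, 6)
  expect_equal(ev$errors, round((1 - ev$accuracy) * ev$n))
  counts <- dplyr::count(ev$predictions, class)
  expect_equal(counts$n, rep(3, 2))   # row sums = per-class test counts
  expect_error(evaluate_classifier(model, data[data$split == "train", ][0, ]),
               "empty test set")
})

test_that("refinement is reproducible, monotone, and a no-op when perfect", {
  train <- orthogonal_patterns(n_per_class = 2)
  model <- construct_classifier(train, n_modes = 4, seed = 1)
  # perfect on train: early return leaves the model untouched
  expect_identical(refine_classifier(model, train, n_iter = 3, seed = 5), model)
  # a degraded model: refinement never increases training error
  noisy <- make_pattern_dataset(n_classes = 2, n_per_class = 4, noise = 0.35,
                                seed = 13, test_frac = 0.25)
  m0 <- construct_classifier(noisy, n_modes = 4, seed = 2)
  err0 <- sum(predict(m0, noisy[noisy$split == "train", ])$pred_class !=
                noisy$class[noisy$split == "train"])
  r1 <- refine_classifier(m0, noisy, n_iter = 2, seed = 21)
  r2 <- refine_classifier(m0, noisy, n_iter = 2, seed = 21)
  expect_identical(r1, r2)   # seeded reproducibility
  err1 <- sum(predict(r1, noisy[noisy$split == "train", ])$pred_class !=
                noisy$class[noisy$split == "train"])
  expect_lte(err1, err0)
})

test_that("tidy and glance summarize the fitted classifier", {
  train <- orthogonal_patterns()
  model <- construct_classifier(train, n_modes = 4, seed = 1)
  td <- tidy(model)
  expect_equal(td$class, 0:1)
  expect_true(all(td$max_amp_residual < 1e-10))
  gl <- glance(model)
  expect_equal(gl$n_classes, 2L)
  expect_equal(gl$n_example_visits, 4L)
})
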