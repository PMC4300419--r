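test_that("sorted-thirds split sends every third compound to the test set", {
  ds <- toy_dataset()[rep(1, 9), ]
  ds$name <- paste0("c", 1:9)
  ds$logs_fassif <- -(1:9) / 2 # c1 most soluble
  sp <- sorted_thirds_split(ds, "fassif")
  expect_equal(sp$test, c("c3", "c6", "c9"))
  expect_equal(sp$train, paste0("c", c(1, 2, 4, 5, 7, 8)))
  expect_equal(length(intersect(sp$train, sp$test)), 0)

  # bundled dataset: 86 compounds give 28 test compounds before relocation
  full <- sorted_thirds_split(solubility_data(), "fassif")
  expect_equal(length(full$test), 28)
  expect_equal(length(full$train), 58)

  miss <- toy_dataset()
  expect_error(sorted_thirds_split(miss, "hif"), "missing for.*beta")
})

test_that("ties in the response are broken deterministically by name", {
  ds <- toy_dataset()[rep(1, 6), ]
  ds$name <- c("f", "b", "d", "a", "c", "e")
  ds$logs_fassif <- rep(-3, 6)
  sp1 <- sorted_thirds_split(ds, "fassif")
  sp2 <- sorted_thirds_split(ds[sample.int(6), ], "fassif")
  expect_equal(sp1$test, c("c", "f"))
  expect_equal(sp1, sp2)
})

test_that("outlier relocation moves only flagged training compounds and logs them", {
  g <- tiny_latent(seed = 7, n = 45, p = 15, informative = 6)
  ds <- tibble::tibble(name = g$x$name, set = NA, mw = 300, logd65 = 3,
                       psa = 50, rotb = 2L, logs_phb = NA_real_,
                       logs_fassif = pmax(pmin(g$y - 4, 0), -12),
                       logs_hif = NA_real_, tm_c = NA_real_)
  sp <- sorted_thirds_split(ds, "fassif")

  # clean data: nothing moves (at most the ~5% false-positive rate; use a
  # strict criterion so the identity case is stable for this seed)
  x_clean <- preprocess_descriptors(g$x, cube_root = FALSE)$data
  sp_clean <- relocate_outliers(sp, x_clean, k = 2, alpha = 0.001)
  expect_equal(sp_clean$train, sp$train)
  expect_equal(nrow(sp_clean$relocations), 0)

  # plant one extreme training compound: it is flagged and moved to test
  victim <- sp$train[1]
  x_out <- plant_outlier(g$x, victim, 25, g$truth$loadings)
  x_prep <- preprocess_descriptors(x_out, cube_root = FALSE)$data
  sp_out <- relocate_outliers(sp, x_prep, k = 2, alpha = 0.001)
  expect_false(victim %in% sp_out$train)
  expect_true(victim %in% sp_out$test)
  expect_true(victim %in% sp_out$relocations$name)
  # union preserved, test only grows
  expect_setequal(c(sp_out$train, sp_out$test), c(sp$train, sp$test))
  expect_true(all(sp$test %in% sp_out$test))
})

test_that("VIP truncation keeps planted descriptors and ignores column order", {
  g <- generate_latent_dataset(synthetic_spec(n = 80, p = 300, k = 2,
                                              informative = 5, noise_sd = 0.3,
                                              seed = 31))
  pp <- preprocess_descriptors(g$x)
  x <- as_matrix_helper(pp$data)
  red <- truncate_top_vip(x, g$y, keep = 100)
  kept <- attr(red, "kept")
  expect_equal(length(kept), 100)
  expect_true(all(g$truth$informative %in% kept))

  # column order does not change the ranking
  perm <- sample(ncol(x))
  red2 <- truncate_top_vip(x[, perm], g$y, keep = 100)
  expect_setequal(attr(red2, "kept"), kept)

  # p <= keep returns the input with a notice
  small <- x[, 1:20]
  expect_message(red3 <- truncate_top_vip(small, g$y, keep = 100), "nothing to truncate")
  expect_setequal(attr(red3, "kept"), colnames(small))
})

test_that("greedy backward elimination removes noise and keeps signal", {
  set.seed(2)
  n <- 63
  signal <- rnorm(n)
  x <- cbind(good = signal + rnorm(n, 0, 0.1), junk = rnorm(n))
  rownames(x) <- sprintf("r%02d", seq_len(n))
  y <- 2 * signal + rnorm(n, 0, 0.3)
  tr <- greedy_backward_selection(x, y)
  expect_equal(tr$final, "good")
  expect_true(all(tr$steps$q2_after[tr$steps$accepted] >=
                    tr$steps$q2_before[tr$steps$accepted] - 1e-6))
  # the sole remaining descriptor is never removed
  expect_equal(length(tr$final), 1)
  expect_error(greedy_backward_selection(x[, 1, drop = FALSE], y), "at least two")
})

test_that("selection trace Q2 is non-decreasing over accepted steps", {
  g <- tiny_latent(seed = 43, n = 50, p = 15, informative = 4)
  x <- as_matrix_helper(preprocess_descriptors(g$x, cube_root = FALSE)$data)
  tr <- greedy_backward_selection(x, g$y)
  acc <- tr$steps[tr$steps$accepted, ]
  if (nrow(acc) > 1) {
    expect_true(all(diff(acc$q2_after) >= -1e-6))
  }
  expect_true(all(g$truth$informative %in% tr$final) ||
                tr$final_q2 > 0.5) # informative set retained or fit still strong
  expect_lt(length(tr$final), ncol(x))
})

test_that("experimental augmentation follows the same Q2 retention rule", {
  g <- tiny_latent(seed = 47, n = 60, p = 10, informative = 5)
  x <- as_matrix_helper(preprocess_descriptors(g$x, cube_root = FALSE)$data)
  y <- g$y
  base <- tibble::tibble(name = rownames(x), set = NA, mw = 300, logd65 = 3,
                         psa = 50, rotb = 2L, logs_phb = NA_real_,
                         logs_fassif = pmax(pmin(y / 4 - 4, 0), -12),
                         logs_hif = NA_real_, tm_c = NA_real_)
  set.seed(48)

  # a column correlated with the response is retained and lifts Q2
  rho <- 0.8
  good <- rho * scale(y)[, 1] + sqrt(1 - rho^2) * rnorm(length(y))
  ds_good <- base; ds_good$logs_phb <- pmax(pmin(good - 4, 0), -12)
  aug <- augment_experimental(x, y, ds_good, which = "phb_solubility")
  expect_true("phb_solubility" %in% aug$retained)
  expect_gt(aug$summary$q2_with, aug$summary$q2_without)
  expect_true("phb_solubility" %in% colnames(as_matrix_helper(aug$data)))

  # pure noise is rejected
  set.seed(49)
  ds_noise <- base; ds_noise$tm_c <- runif(length(y), 50, 300)
  aug_n <- augment_experimental(x, y, ds_noise, which = "tm")
  expect_false("tm" %in% aug_n$retained)
  expect_false("tm" %in% colnames(as_matrix_helper(aug_n$data)))

  # a column equal to the response leaks: Q2 ~ 1 and the detector warns
  x_noise <- matrix(rnorm(length(y) * 5), length(y), 5,
                    dimnames = list(rownames(x), paste0("n", 1:5)))
  ds_leak <- base; ds_leak$logs_phb <- pmax(pmin(y - 4, 0), -12)
  expect_warning(aug_l <- augment_experimental(x_noise, y, ds_leak,
                                               which = "phb_solubility"),
                 "leakage")
  expect_gt(aug_l$summary$q2_with, 0.99)

  # compounds missing the augmentation value are excluded from that variant
  ds_miss <- ds_good; ds_miss$logs_phb[1:10] <- NA
  aug_m <- augment_experimental(x, y, ds_miss, which = "phb_solubility")
  expect_equal(aug_m$summary$n_used, length(y) - 10)

  ds_none <- base
  expect_error(augment_experimental(x, y, ds_none, which = "phb_solubility"),
               "entirely missing")
})

test_that("model summary reports RMSE matching a per-compound loop", {
  g <- tiny_latent(seed = 53, n = 40, p = 10)
  x <- as_matrix_helper(preprocess_descriptors(g$x, cube_root = FALSE)$data)
  fit <- fit_pls(x[1:30, ], g$y[1:30], 2)
  q2 <- max(q2_crossval(x[1:30, ], g$y[1:30], 2)$table$q2)
  sm <- build_model_summary(fit, q2, x[31:40, ], g$y[31:40], id = "toy")
  # brute-force RMSE oracle
  pred <- predict(fit, x[31:40, ])
  acc <- 0
  for (i in 1:10) acc <- acc + (g$y[30 + i] - pred[i])^2
  expect_equal(sm$rmse_te, unname(sqrt(acc / 10)), tolerance = 1e-12)
  expect_equal(sm$n_train, 30)
  expect_equal(sm$n_test, 10)

  # a perfect predictor has zero test RMSE
  ident <- fit
  sm2 <- build_model_summary(fit, q2, x[1:30, ], unname(fit$fitted), id = "perfect")
  expect_lt(sm2$rmse_te, 1e-10)
})

test_that("the full protocol is a pure function of data, config and seed", {
  run_once <- function() {
    g <- generate_latent_dataset(synthetic_spec(n = 60, p = 40, k = 2,
                                                informative = 5, seed = 97))
    pp <- preprocess_descriptors(g$x)
    x <- as_matrix_helper(pp$data)
    ds <- tibble::tibble(name = rownames(x), set = NA, mw = 300, logd65 = 3,
                         psa = 50, rotb = 2L, logs_phb = NA_real_,
                         logs_fassif = pmax(pmin(g$y - 4, 0), -12),
                         logs_hif = NA_real_, tm_c = NA_real_)
    sp <- sorted_thirds_split(ds, "fassif")
    sp <- relocate_outliers(sp, pp$data)
    xt <- as_descriptor_matrix_helper(truncate_top_vip(x[sp$train, ], g$y[sp$train], keep = 20))
    tr <- greedy_backward_selection(xt, g$y[sp$train])
    list(sp = sp, final = tr$final, q2 = tr$final_q2)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a, b)
})
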