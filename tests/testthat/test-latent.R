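test_that("PCA matches an eigendecomposition oracle and respects rank", {
  m <- random_matrix(20, 5, seed = 7)
  k <- 4
  pca <- fit_pca(m, k)
  # oracle: eigendecomposition of the sample covariance
  mc <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(mc) / (nrow(m) - 1), symmetric = TRUE)
  expect_lt(max(abs(pca$explained_variance - eig$values[1:k])), 1e-8)
  for (a in seq_len(k)) {
    v <- eig$vectors[, a]
    expect_lt(min(sum((pca$loadings[, a] - v)^2),
                  sum((pca$loadings[, a] + v)^2)), 1e-16)
  }
  # orthonormal loadings, orthogonal scores
  expect_lt(max(abs(crossprod(pca$loadings) - diag(k))), 1e-8)
  off <- crossprod(pca$scores); diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)

  # rank-1 matrix explains everything with one component
  r1 <- outer(rnorm(12), rnorm(4))
  dimnames(r1) <- list(sprintf("r%02d", 1:12), sprintf("c%02d", 1:4))
  expect_equal(fit_pca(r1, 1)$prop_variance, 1, tolerance = 1e-10)

  # permuting rows permutes scores, loadings unchanged
  perm <- sample(nrow(m))
  pca_p <- fit_pca(m[perm, ], k)
  expect_equal(pca_p$loadings, pca$loadings)
  expect_equal(pca_p$scores, pca$scores[perm, ])

  expect_error(fit_pca(m, 10), "exceeds")
})

test_that("NIPALS PLS agrees with closed-form regression in the univariate case", {
  set.seed(21)
  x <- matrix(rnorm(25), 25, 1, dimnames = list(sprintf("r%02d", 1:25), "d1"))
  y <- 2 - 0.7 * x[, 1] + rnorm(25, 0, 0.1)
  fit <- fit_pls(x, y, 1)
  ols <- lm(y ~ x[, 1])
  expect_lt(max(abs(unname(fit$fitted) - unname(fitted(ols)))), 1e-10)

  # a descriptor exactly proportional to y gives a perfect one-component fit
  y2 <- rnorm(20)
  x2 <- matrix(3 * y2, 20, 1, dimnames = list(sprintf("r%02d", 1:20), "d1"))
  expect_equal(fit_pls(x2, y2, 1)$r2, 1, tolerance = 1e-12)

  expect_error(fit_pls(x, rep(1, 25), 1), "zero variance")
  expect_error(fit_pls(x, y, 5), "ncomp")
})

test_that("PLS scores are orthogonal, R2 is monotone and fitted values reproduce", {
  g <- tiny_latent(seed = 13, informative = 8, x_noise_sd = 0.1)
  x <- as_matrix_helper(preprocess_descriptors(g$x, cube_root = FALSE)$data)
  fit <- fit_pls(x, g$y, 4)
  off <- crossprod(fit$scores); diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
  expect_true(all(diff(fit$r2_cum) >= -1e-12))
  expect_lt(max(abs(predict(fit, x) - fit$fitted)), 1e-10)

  # two-latent-factor data: second component adds fit, residual ~ planted noise
  r2_1 <- fit_pls(x, g$y, 1)$r2
  r2_2 <- fit_pls(x, g$y, 2)$r2
  expect_gt(r2_2, r2_1)
  resid_var <- mean((g$y - fit_pls(x, g$y, 2)$fitted)^2)
  expect_lt(abs(sqrt(resid_var) - g$truth$noise_sd), 0.12)
})

test_that("predictions equal the explicit coefficient-matrix form and mixOmics", {
  for (seed in c(1, 2, 3)) {
    n <- 30; p <- 8; a <- 3
    x <- random_matrix(n, p, seed = seed)
    set.seed(seed + 100)
    y <- rnorm(n)
    fit <- fit_pls(x, y, a)
    xn <- random_matrix(10, p, seed = seed + 200)

    # oracle 1: B = W (P'W)^{-1} q computed from the stored matrices
    b <- fit$W %*% solve(crossprod(fit$P, fit$W), fit$q)
    manual <- fit$y_center + sweep(xn, 2, fit$x_center, "-") %*% b
    expect_lt(max(abs(predict(fit, xn) - drop(manual))), 1e-10)

    # oracle 2: independent NIPALS implementation (mixOmics)
    mo <- mixOmics::pls(x, y, ncomp = a, mode = "regression", scale = FALSE)
    expect_lt(max(abs(predict(fit, xn) -
                        drop(predict(mo, xn)$predict[, , a]))), 1e-8)
  }

  # an all-centred observation predicts the training response mean
  g <- tiny_latent(seed = 4)
  x <- as_matrix_helper(g$x)
  fit <- fit_pls(x, g$y, 2)
  at_center <- matrix(fit$x_center, 1, dimnames = list("c0", names(fit$x_center)))
  expect_equal(unname(predict(fit, at_center)), fit$y_center)

  expect_error(predict(fit, x[, -1]), "lacks descriptor")
})

test_that("cross-validated Q2 equals a naive refit-per-fold oracle", {
  g <- tiny_latent(seed = 17, n = 35, p = 10)
  x <- as_matrix_helper(g$x)
  cv <- q2_crossval(x, g$y, 3, groups = 7)

  # independent loop: refit per fold, accumulate PRESS per component count
  folds <- ((seq_len(nrow(x)) - 1L) %% 7L) + 1L
  press <- numeric(3)
  for (a in 1:3) {
    for (gp in 1:7) {
      fit <- fit_pls(x[folds != gp, ], g$y[folds != gp], a)
      pred <- predict(fit, x[folds == gp, , drop = FALSE])
      press[a] <- press[a] + sum((g$y[folds == gp] - pred)^2)
    }
  }
  q2_oracle <- 1 - press / sum((g$y - mean(g$y))^2)
  expect_lt(max(abs(cv$table$q2 - q2_oracle)), 1e-10)
  expect_true(all(cv$table$press >= 0))
  expect_true(all(cv$table$q2 <= 1))
  expect_true(max(table(cv$folds)) - min(table(cv$folds)) <= 1)

  # exact noise-free relation
  set.seed(30)
  xe <- random_matrix(30, 3, seed = 31)
  ye <- drop(xe %*% c(1, -2, 0.5))
  expect_gt(max(q2_crossval(xe, ye, 3)$table$q2), 0.999)

  # pure-noise response has no predictive power
  set.seed(32)
  xn <- random_matrix(120, 10, seed = 33)
  yn <- rnorm(120)
  expect_lt(q2_crossval(xn, yn, 2)$table$q2[2], 0)

  expect_error(q2_crossval(xe, ye, 2, groups = 50), "groups")
})

test_that("VIP satisfies its normalisation identity and separates signal from noise", {
  # p = 1 forces VIP = 1
  set.seed(40)
  x1 <- matrix(rnorm(20), 20, 1, dimnames = list(sprintf("r%02d", 1:20), "d1"))
  expect_equal(vip(fit_pls(x1, rnorm(20) + x1[, 1], 1))$vip, 1)

  for (seed in c(5, 6)) {
    g <- tiny_latent(seed = seed, n = 60, p = 30, informative = 5)
    x <- as_matrix_helper(preprocess_descriptors(g$x)$data)
    fit <- fit_pls(x, g$y, 2)
    v <- vip(fit)
    expect_lt(abs(mean(v$vip^2) - 1), 1e-8)
    informative <- v$vip[v$descriptor %in% g$truth$informative]
    noise <- v$vip[!v$descriptor %in% g$truth$informative]
    expect_gt(median(informative), median(noise))
  }
})

test_that("component choice follows the incremental Q2 rule", {
  g1 <- tiny_latent(seed = 19, k = 1, n = 50, p = 10, informative = 4)
  x1 <- as_matrix_helper(g1$x)
  expect_equal(choose_components(x1, g1$y)$ncomp, 1L)

  set.seed(50)
  xn <- random_matrix(60, 8, seed = 51)
  yn <- rnorm(60)
  noise_pick <- choose_components(xn, yn)
  expect_equal(noise_pick$ncomp, 1L)
  expect_false(noise_pick$predictive)

  # data where the covariance direction is contaminated by an irrelevant
  # factor, so a second component is genuinely needed
  set.seed(101)
  n <- 60; t1 <- rnorm(n); g0 <- rnorm(n)
  x2 <- cbind(a = t1 + 3 * g0 + rnorm(n, 0, 0.1),
              b = 2 * t1 - g0 + rnorm(n, 0, 0.1),
              c = g0 + rnorm(n, 0, 0.1))
  rownames(x2) <- sprintf("r%02d", seq_len(n))
  y2 <- t1 + rnorm(n, 0, 0.1)
  expect_equal(choose_components(x2, y2, threshold = Inf)$ncomp, 1L)
  expect_gte(choose_components(x2, y2)$ncomp, 2L)
})

test_that("Hotelling T2 is zero at the origin and calibrated near 5%", {
  g <- tiny_latent(seed = 29, n = 400, p = 10, informative = 6, noise_sd = 0.1)
  x <- as_matrix_helper(g$x)
  pca <- fit_pca(x, 2)
  t2 <- hotelling_t2(pca)
  expect_true(all(t2$t2 >= 0))
  # scores are near-normal: roughly 5% of training points beyond the limit
  expect_lt(abs(mean(t2$flagged) - 0.05), 0.035)

  # an observation at the centre of the model has T2 = 0
  at_center <- matrix(pca$centers, 1, dimnames = list("c0", names(pca$centers)))
  expect_equal(hotelling_t2(pca, at_center)$t2, 0)

  # same machinery applies to PLS models
  fit <- fit_pls(x, g$y, 2)
  expect_true(all(hotelling_t2(fit)$t2 >= 0))
})

test_that("DModX measures orthogonal distance on the expected scale", {
  g <- tiny_latent(seed = 31, n = 80, p = 20, informative = 8)
  x <- as_matrix_helper(g$x)
  pca <- fit_pca(x, 2)
  dx <- dmodx(pca)
  expect_true(all(dx$dmodx >= 0))
  # normalised training distances average about one
  expect_lt(abs(mean(dx$dmodx^2) - 1), 0.15)

  # a point exactly in the model plane has DModX 0
  in_plane <- matrix(pca$centers + drop(pca$loadings %*% c(1.5, -2)), 1,
                     dimnames = list("p0", names(pca$centers)))
  expect_lt(dmodx(pca, in_plane)$dmodx, 1e-8)

  # doubling the orthogonal residual doubles the distance
  resid_dir <- rep(1, ncol(x)) - drop(pca$loadings %*% crossprod(pca$loadings, rep(1, ncol(x))))
  off1 <- matrix(pca$centers + resid_dir, 1,
                 dimnames = list("o1", names(pca$centers)))
  off2 <- matrix(pca$centers + 2 * resid_dir, 1,
                 dimnames = list("o2", names(pca$centers)))
  expect_equal(dmodx(pca, off2)$dmodx, 2 * dmodx(pca, off1)$dmodx,
               tolerance = 1e-10)
})

test_that("tidy, glance and augment expose broom-style views", {
  g <- tiny_latent(seed = 37)
  x <- as_matrix_helper(g$x)
  fit <- fit_pls(x, g$y, 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "vip"))
  expect_equal(nrow(td), ncol(x))
  gl <- glance(fit)
  expect_equal(gl$ncomp, 2)
  expect_equal(gl$nobs, nrow(x))
  au <- augment(fit)
  expect_equal(au$.resid, g$y - unname(fit$fitted), ignore_attr = TRUE)
  pca <- fit_pca(x, 2)
  expect_equal(nrow(tidy(pca)), ncol(x))
  expect_equal(glance(pca)$ncomp, 2)
})

test_that("model bundles round-trip through the plain-text serialisation", {
  g <- tiny_latent(seed = 41)
  x <- as_matrix_helper(g$x)
  fit <- fit_pls(x, g$y, 2)
  dir <- withr::local_tempdir()
  write_pls_model(fit, dir)
  back <- read_pls_model(dir)
  xn <- random_matrix(8, ncol(x), seed = 42)
  colnames(xn) <- colnames(x)
  expect_equal(predict(back, xn), predict(fit, xn), tolerance = 1e-10)
  expect_equal(back$ncomp, fit$ncomp)
})
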