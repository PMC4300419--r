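fix_component_signs <- function(loadings) {
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  flip
}

#' Principal component analysis of a descriptor matrix
#'
#' Thin wrapper around the singular value decomposition with a deterministic
#' sign convention (the largest-magnitude loading of each component is
#' positive). Input is expected to be preprocessed (see
#' [preprocess_descriptors()]); the matrix is re-centred internally and the
#' centres stored so new observations can be projected.
#'
#' @param x Descriptor table or matrix.
#' @param k Number of components, at most `min(n - 1, p)`.
#' @return A `pca_model` with loadings, scores, explained variance and
#'   centring information.
#' @export
fit_pca <- function(x, k) {
  m <- as_descriptor_matrix(x)
  n <- nrow(m); p <- ncol(m)
  if (k > min(n - 1, p)) {
    abort(paste0("k = ", k, " exceeds min(n - 1, p) = ", min(n - 1, p)))
  }
  centers <- colMeans(m)
  mc <- sweep(m, 2, centers, "-")
  sv <- svd(mc)
  flip <- fix_component_signs(sv$v[, seq_len(k), drop = FALSE])
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, "*")
  rownames(loadings) <- colnames(m)
  rownames(scores) <- rownames(m)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  ev <- sv$d^2 / (n - 1)
  structure(
    list(ncomp = k, loadings = loadings, scores = scores,
         explained_variance = ev[seq_len(k)],
         prop_variance = ev[seq_len(k)] / sum(ev),
         centers = centers, n = n, p = p,
         descriptors = colnames(m), train_matrix = m),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", x$ncomp, "components,", x$n, "observations,",
      x$p, "descriptors\n")
  cat("  proportion of variance:",
      paste(sprintf("%.3f", x$prop_variance), collapse = " "), "\n")
  invisible(x)
}

#' Fit a PLS regression by NIPALS
#'
#' Partial least squares projection to latent structures for a single
#' response, computed with the NIPALS algorithm: for each component the
#' weight vector is iterated to convergence (tolerance 1e-12, at most 500
#' iterations), scores and loadings are extracted and the descriptor matrix
#' deflated. Components use the same sign convention as [fit_pca()].
#'
#' Descriptors are expected preprocessed (centred/scaled); the response is
#' centred internally. If the response is numerically exhausted before
#' `ncomp` components the model is truncated with a warning.
#'
#' @param x Descriptor table or matrix (n x p).
#' @param y Numeric response vector of length n.
#' @param ncomp Number of latent components, at most `min(n - 1, p)`.
#' @return A `pls_model` with weights `W`, x-loadings `P`, y-loadings `q`,
#'   scores `T`, regression coefficients, fitted values and training-set
#'   summary statistics (cumulative R2, RMSE).
#' @export
fit_pls <- function(x, y, ncomp) {
  m <- as_descriptor_matrix(x)
  n <- nrow(m); p <- ncol(m)
  if (length(y) != n) abort("length(y) must equal nrow(x)")
  if (var(y) <= 0) abort("response has zero variance")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    abort(paste0("ncomp must lie in [1, ", min(n - 1, p), "]"))
  }
  x_center <- colMeans(m)
  y_center <- mean(y)
  E <- sweep(m, 2, x_center, "-")
  f <- y - y_center
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    if (sqrt(sum(w^2)) < 1e-14) break
    w <- w / sqrt(sum(w^2))
    # NIPALS iteration (single-response PLS converges immediately, the loop
    # guards the general contract)
    for (it in seq_len(500)) {
      t_a <- drop(E %*% w)
      q_a <- sum(t_a * f) / sum(t_a^2)
      u <- f / q_a
      w_new <- drop(crossprod(E, u))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((w_new - w)^2) < (1e-12)^2) { w <- w_new; break }
      w <- w_new
    }
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-28) break
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(t_a * f) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    used <- a
  }
  if (used == 0L) abort("response is orthogonal to every descriptor")
  if (used < ncomp) {
    warn(paste0("response exhausted after ", used, " component(s); ncomp reduced"))
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    Tm <- Tm[, seq_len(used), drop = FALSE]
    q <- q[seq_len(used)]
    ncomp <- used
  }
  flip <- fix_component_signs(P)
  W <- sweep(W, 2, flip, "*"); P <- sweep(P, 2, flip, "*")
  Tm <- sweep(Tm, 2, flip, "*"); q <- q * flip
  dimnames(W) <- dimnames(P) <- list(colnames(m), paste0("LV", seq_len(ncomp)))
  dimnames(Tm) <- list(rownames(m), paste0("LV", seq_len(ncomp)))

  ss_y <- sum((y - y_center)^2)
  tt <- colSums(Tm^2)
  ssy_comp <- q^2 * tt
  r2_cum <- cumsum(ssy_comp) / ss_y
  coef_full <- pls_coefficients(W, P, q, ncomp)
  fitted <- drop(y_center + sweep(m, 2, x_center, "-") %*% coef_full)
  model <- structure(
    list(ncomp = ncomp, W = W, P = P, q = q, scores = Tm,
         coefficients = coef_full, x_center = x_center, y_center = y_center,
         fitted = setNames(fitted, rownames(m)), y = y,
         r2 = unname(r2_cum[ncomp]), r2_cum = r2_cum,
         rmse_tr = sqrt(mean((y - fitted)^2)),
         ssy_comp = ssy_comp, n = n, p = p,
         descriptors = colnames(m), train_matrix = m),
    class = "pls_model"
  )
  model
}

# B = W (P'W)^{-1} q, using the first `a` components
pls_coefficients <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>", x$ncomp, "components,", x$p, "descriptors,",
      x$n, "training compounds\n")
  cat(sprintf("  R2 = %.3f, RMSE(train) = %.3f\n", x$r2, x$rmse_tr))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Linear prediction `y_hat = y_center + (x - x_center) B` with
#' `B = W (P'W)^{-1} q`. New data must carry the model's descriptors (matched
#' by name) and have been preprocessed with the same state as the training
#' matrix.
#'
#' @param object A `pls_model`.
#' @param newdata Descriptor table or matrix; defaults to refitting on the
#'   training scores (returns fitted values).
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata = NULL, ncomp = object$ncomp, ...) {
  if (is.null(newdata)) return(object$fitted)
  m <- as_descriptor_matrix(newdata)
  missing_cols <- setdiff(object$descriptors, colnames(m))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata lacks descriptor(s): ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  m <- m[, object$descriptors, drop = FALSE]
  b <- if (ncomp == object$ncomp) object$coefficients else
    pls_coefficients(object$W, object$P, object$q, ncomp)
  drop(object$y_center + sweep(m, 2, object$x_center, "-") %*% b)
}

#' Variable importance to projection
#'
#' VIP of descriptor j over the A components of a fitted PLS model:
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a = q_a^2 t_a' t_a` is the response sum of squares explained by
#' component a. Squared VIPs average to 1 over the descriptors.
#'
#' @param model A `pls_model`.
#' @return A tibble with columns `descriptor` and `vip`, in model column
#'   order.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  tibble::tibble(descriptor = model$descriptors, vip = unname(vip_scores(model)))
}

vip_scores <- function(model) {
  W <- model$W
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  ssy <- model$ssy_comp
  setNames(sqrt(model$p * drop(wn %*% ssy) / sum(ssy)), model$descriptors)
}

cv_fold_assignment <- function(n, groups, assignment = c("venetian", "blocks")) {
  assignment <- match.arg(assignment)
  if (groups > n) abort("more cross-validation groups than observations")
  if (assignment == "venetian") {
    ((seq_len(n) - 1L) %% groups) + 1L
  } else {
    sort(((seq_len(n) - 1L) * groups) %/% n + 1L)
  }
}

#' Cross-validated Q2 for a PLS model
#'
#' Grouped cross-validation: observations are assigned to `groups` folds
#' (round-robin by index by default, contiguous blocks as an alternative),
#' each fold is predicted from a model fitted without it, and
#' `Q2(a) = 1 - PRESS(a) / SS_y` is reported for every cumulative component
#' count, with `SS_y` taken about the full-data mean.
#'
#' @param x Descriptor table or matrix.
#' @param y Numeric response.
#' @param ncomp Maximum number of components to evaluate.
#' @param groups Number of folds (default 7).
#' @param assignment `"venetian"` (round-robin, default) or `"blocks"`.
#' @return A `cv_result`: list with `table` (tibble of `ncomp`, `press`,
#'   `q2`), `folds`, `ss_y` and `predictions` (n x ncomp matrix of held-out
#'   predictions).
#' @export
q2_crossval <- function(x, y, ncomp, groups = 7,
                        assignment = c("venetian", "blocks")) {
  m <- as_descriptor_matrix(x)
  n <- nrow(m)
  if (length(y) != n) abort("length(y) must equal nrow(x)")
  folds <- cv_fold_assignment(n, groups, assignment)
  ncomp_max <- min(ncomp, n - max(table(folds)) - 1, ncol(m))
  preds <- matrix(NA_real_, n, ncomp_max)
  for (g in seq_len(groups)) {
    inb <- folds != g
    fit <- suppressWarnings(fit_pls(m[inb, , drop = FALSE], y[inb], ncomp_max))
    for (a in seq_len(ncomp_max)) {
      a_use <- min(a, fit$ncomp)
      preds[!inb, a] <- predict(fit, m[!inb, , drop = FALSE], ncomp = a_use)
    }
  }
  ss_y <- sum((y - mean(y))^2)
  press <- colSums((preds - y)^2)
  structure(
    list(table = tibble::tibble(ncomp = seq_len(ncomp_max), press = press,
                                q2 = 1 - press / ss_y),
         folds = folds, ss_y = ss_y, predictions = preds),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", max(x$table$ncomp), "components,",
      length(unique(x$folds)), "folds\n")
  print(x$table)
  invisible(x)
}

#' Choose the number of PLS components by cross-validation
#'
#' Components are added while the incremental gain in Q2 exceeds `threshold`
#' (default 0.01). A model whose best Q2 is non-positive is flagged.
#'
#' @inheritParams q2_crossval
#' @param max_a Largest component count to consider.
#' @param threshold Minimum Q2 improvement to accept another component.
#' @return List with `ncomp` (chosen count), `q2` (at the chosen count),
#'   `cv` (the full `cv_result`) and `predictive` (FALSE when Q2 <= 0).
#' @export
choose_components <- function(x, y, max_a = 5, groups = 7, threshold = 0.01,
                              assignment = c("venetian", "blocks")) {
  cv <- q2_crossval(x, y, max_a, groups = groups, assignment = assignment)
  q2 <- cv$table$q2
  a <- 1L
  while (a < length(q2) && (q2[a + 1] - q2[a]) > threshold) a <- a + 1L
  list(ncomp = a, q2 = q2[a], cv = cv, predictive = q2[a] > 0)
}

project_scores <- function(model, m) {
  mc <- sweep(m, 2, if (inherits(model, "pls_model")) model$x_center else model$centers, "-")
  if (inherits(model, "pls_model")) {
    R <- model$W %*% solve(crossprod(model$P, model$W))
    mc %*% R
  } else {
    mc %*% model$loadings
  }
}

model_dims <- function(model) {
  list(n = model$n, p = model$p, a = model$ncomp)
}

#' Hotelling T2 in the model's score space
#'
#' Leverage of each observation in the latent-variable plane:
#' `T2_i = sum_a t_ia^2 / s_a^2` with `s_a^2` the training-score variance of
#' component a. The critical limit at level `alpha` uses the F approximation
#' `A (n^2 - 1) / (n (n - A)) F(1 - alpha; A, n - A)`.
#'
#' @param model A `pca_model` or `pls_model`.
#' @param newdata Optional descriptor table to project; defaults to the
#'   training scores.
#' @param alpha Significance level of the limit (default 0.05).
#' @return Tibble with columns `name`, `t2`, `limit`, `flagged`.
#' @export
hotelling_t2 <- function(model, newdata = NULL, alpha = 0.05) {
  d <- model_dims(model)
  scores <- if (is.null(newdata)) model$scores else
    project_scores(model, as_descriptor_matrix(newdata)[, model$descriptors, drop = FALSE])
  s2 <- colSums(model$scores^2) / (d$n - 1)
  t2 <- drop(sweep(scores^2, 2, s2, "/") %*% rep(1, d$a))
  limit <- d$a * (d$n^2 - 1) / (d$n * (d$n - d$a)) *
    qf(1 - alpha, d$a, d$n - d$a)
  tibble::tibble(name = rownames(scores) %||% as.character(seq_along(t2)),
                 t2 = unname(t2), limit = limit, flagged = t2 > limit)
}

model_residuals <- function(model, m) {
  if (inherits(model, "pls_model")) {
    center <- model$x_center
    load <- model$P
  } else {
    center <- model$centers
    load <- model$loadings
  }
  mc <- sweep(m, 2, center, "-")
  scores <- project_scores(model, m)
  mc - tcrossprod(scores, load)
}

#' Distance to the model in descriptor space (DModX)
#'
#' Normalised orthogonal residual of each observation:
#' `DModX_i = s_i / s0` where `s_i = sqrt(sum_j e_ij^2 / (p - A))` and `s0`
#' pools the training residuals over `(n - A - 1)(p - A)` degrees of freedom.
#' Observations in the model plane have DModX 0 and training observations
#' average about 1. The critical limit at level `alpha` is
#' `sqrt(F(1 - alpha; p - A, (n - A - 1)(p - A)))`.
#'
#' @inheritParams hotelling_t2
#' @return Tibble with columns `name`, `dmodx`, `limit`, `flagged`.
#' @export
dmodx <- function(model, newdata = NULL, alpha = 0.05) {
  d <- model_dims(model)
  if (d$p <= d$a) abort("DModX undefined: no residual dimensions (p <= A)")
  train_m <- model$train_matrix
  E_train <- model_residuals(model, train_m)
  s0 <- sqrt(sum(E_train^2) / ((d$n - d$a - 1) * (d$p - d$a)))
  m <- if (is.null(newdata)) train_m else
    as_descriptor_matrix(newdata)[, model$descriptors, drop = FALSE]
  E <- model_residuals(model, m)
  s_i <- sqrt(rowSums(E^2) / (d$p - d$a))
  limit <- sqrt(qf(1 - alpha, d$p - d$a, (d$n - d$a - 1) * (d$p - d$a)))
  tibble::tibble(name = rownames(m) %||% as.character(seq_along(s_i)),
                 dmodx = unname(s_i / s0), limit = limit,
                 flagged = s_i / s0 > limit)
}

#' Tidy a fitted PLS model
#'
#' One row per descriptor with its regression coefficient (on the
#' preprocessed scale) and VIP score.
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `vip`.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    term = x$descriptors,
    estimate = unname(x$coefficients),
    vip = unname(vip_scores(x))
  )
}

#' One-row summary of a fitted PLS model
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, r.squared = x$r2, rmse = x$rmse_tr,
                 nobs = x$n, n_descriptors = x$p)
}

#' Tidy PCA loadings
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble of loadings, one row per descriptor.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, ...) {
  tibble::as_tibble(x$loadings) |>
    dplyr::mutate(term = x$descriptors, .before = 1)
}

#' One-row summary of a PCA model
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, prop_variance = sum(x$prop_variance),
                 nobs = x$n, n_descriptors = x$p)
}

#' Predictions with observations for a PLS model
#' @param x A `pls_model`.
#' @param newdata Optional preprocessed descriptor table.
#' @param y Optional observed response aligned with `newdata`.
#' @param ... Unused.
#' @return A tibble with `.fitted` and, when available, `.observed`, `.resid`.
#' @method augment pls_model
#' @export
augment.pls_model <- function(x, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata)) {
    return(tibble::tibble(name = names(x$fitted), .fitted = unname(x$fitted),
                          .observed = x$y, .resid = x$y - unname(x$fitted)))
  }
  pred <- predict(x, newdata)
  out <- tibble::tibble(name = names(pred) %||% as.character(seq_along(pred)),
                        .fitted = unname(pred))
  if (!is.null(y)) {
    out$.observed <- y
    out$.resid <- y - out$.fitted
  }
  out
}
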