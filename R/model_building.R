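#' Response-sorted train/test split
#'
#' Sorts compounds by the response solubility in descending order (ties broken
#' by compound name for determinism) and assigns every third compound -
#' 1-based positions divisible by three - to the test set, giving an even
#' spread of the response across both sets and the widest possible predictive
#' range.
#'
#' @param ds A solubility dataset.
#' @param medium Response medium (`"phb"`, `"fassif"` or `"hif"`).
#' @return A `split_result`: list with character vectors `train` and `test`
#'   and an empty `relocations` log.
#' @export
sorted_thirds_split <- function(ds, medium) {
  ds <- validate_solubility_data(ds)
  col <- medium_column(medium)
  missing_resp <- ds$name[is.na(ds[[col]])]
  if (length(missing_resp) > 0) {
    abort(paste0("response '", medium, "' missing for: ",
                 paste(head(missing_resp, 5), collapse = ", "),
                 if (length(missing_resp) > 5) ", ..." else ""))
  }
  ord <- order(-ds[[col]], ds$name)
  sorted_names <- ds$name[ord]
  pos <- seq_along(sorted_names)
  test <- sorted_names[pos %% 3 == 0]
  structure(
    list(train = sorted_names[pos %% 3 != 0], test = test,
         relocations = tibble::tibble(name = character(), criterion = character(),
                                      pass = integer())),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result>", length(x$train), "train /", length(x$test), "test;",
      nrow(x$relocations), "relocation(s)\n")
  invisible(x)
}

#' Relocate multivariate training-set outliers to the test set
#'
#' Fits a PCA on the training-compound descriptors and moves any training
#' compound beyond the 95% Hotelling T2 or DModX limit to the test set, so
#' that atypical chemistry does not dominate the regression. The check is
#' repeated (the PCA refitted) until no training outlier remains or
#' `max_passes` is reached; every move is logged. Test compounds are never
#' touched.
#'
#' @param split A `split_result`.
#' @param x Preprocessed descriptor table covering at least the training
#'   compounds.
#' @param k Number of PCA components (default 2).
#' @param criterion `"both"` (default), `"t2"` or `"dmodx"`.
#' @param alpha Significance level of the limits (default 0.05).
#' @param max_passes Maximum refit rounds (default 5).
#' @return The updated `split_result` with an appended relocation log.
#' @export
relocate_outliers <- function(split, x, k = 2, criterion = c("both", "t2", "dmodx"),
                              alpha = 0.05, max_passes = 5) {
  stopifnot(inherits(split, "split_result"))
  criterion <- match.arg(criterion)
  m <- as_descriptor_matrix(x)
  train <- split$train
  test <- split$test
  log <- split$relocations
  for (pass in seq_len(max_passes)) {
    absent <- setdiff(train, rownames(m))
    if (length(absent) > 0) {
      abort(paste0("descriptors missing for training compound(s): ",
                   paste(head(absent, 5), collapse = ", ")))
    }
    mt <- m[train, , drop = FALSE]
    pca <- fit_pca(mt, min(k, nrow(mt) - 1, ncol(mt)))
    flagged <- character()
    if (criterion %in% c("both", "t2")) {
      t2 <- hotelling_t2(pca, alpha = alpha)
      flagged <- union(flagged, t2$name[t2$flagged])
    }
    if (criterion %in% c("both", "dmodx")) {
      dx <- dmodx(pca, alpha = alpha)
      flagged <- union(flagged, dx$name[dx$flagged])
    }
    if (length(flagged) == 0) break
    if (length(setdiff(train, flagged)) < 2) {
      abort("relocation would empty the training set")
    }
    log <- dplyr::bind_rows(log, tibble::tibble(
      name = flagged,
      criterion = vapply(flagged, function(nm) {
        hit_t2 <- criterion %in% c("both", "t2") && nm %in% t2$name[t2$flagged]
        hit_dx <- criterion %in% c("both", "dmodx") && exists("dx") &&
          nm %in% dx$name[dx$flagged]
        paste(c(if (hit_t2) "t2", if (hit_dx) "dmodx"), collapse = "+")
      }, character(1)),
      pass = pass
    ))
    train <- setdiff(train, flagged)
    test <- c(test, flagged)
  }
  structure(list(train = train, test = test, relocations = log),
            class = "split_result")
}

#' Keep the top descriptors by VIP
#'
#' Fits a preliminary PLS on all descriptors and retains the `keep` highest
#' ranked by VIP (ties at the boundary broken by descriptor name). When the
#' matrix already has `keep` or fewer descriptors it is returned unchanged
#' with a message.
#'
#' @param x Preprocessed descriptor table or matrix (training compounds).
#' @param y Response vector.
#' @param keep Number of descriptors to retain (default 100).
#' @param ncomp Components for the preliminary model; chosen by
#'   cross-validation when `NULL`.
#' @param groups CV folds used when choosing `ncomp`.
#' @return The reduced descriptor tibble; the retained names are also
#'   available via `attr(, "kept")`.
#' @export
truncate_top_vip <- function(x, y, keep = 100, ncomp = NULL, groups = 7) {
  m <- as_descriptor_matrix(x)
  if (ncol(m) <= keep) {
    message("descriptor count (", ncol(m), ") <= keep (", keep, "): nothing to truncate")
    out <- descriptor_tbl(m)
    attr(out, "kept") <- colnames(m)
    return(out)
  }
  if (is.null(ncomp)) ncomp <- choose_components(m, y, groups = groups)$ncomp
  fit <- fit_pls(m, y, ncomp)
  v <- vip_scores(fit)
  ord <- order(-v, names(v))
  kept <- sort(names(v)[ord[seq_len(keep)]])
  out <- descriptor_tbl(m[, kept, drop = FALSE])
  attr(out, "kept") <- kept
  out
}

#' Greedy backward descriptor elimination monitored by Q2
#'
#' One pass visits the current descriptors in ascending-VIP order (VIP ranks
#' recomputed once per pass); a descriptor is permanently removed when the
#' model refitted without it - with the component count re-chosen - has a
#' cross-validated Q2 at least equal to the current one (equality within
#' `tol`). Passes repeat until a full pass removes nothing. Every trial is
#' recorded.
#'
#' @param x Preprocessed descriptor table or matrix (training compounds).
#' @param y Response vector.
#' @param groups CV folds (default 7).
#' @param max_a Maximum components considered when (re)choosing the count.
#' @param threshold Q2-gain threshold for adding a component.
#' @param tol Tolerance for "equal Q2" (default 1e-6).
#' @return A `selection_trace`: list with `steps` (tibble of every trial:
#'   `pass`, `descriptor`, `q2_before`, `q2_after`, `accepted`), `final`
#'   (descriptor names), `final_q2`, `final_ncomp`.
#' @export
greedy_backward_selection <- function(x, y, groups = 7, max_a = 5,
                                      threshold = 0.01, tol = 1e-6) {
  m <- as_descriptor_matrix(x)
  if (ncol(m) < 2) abort("need at least two descriptors to select from")
  pick <- function(mm) {
    choose_components(mm, y, max_a = min(max_a, ncol(mm), nrow(mm) - 1),
                      groups = groups, threshold = threshold)
  }
  sel <- pick(m)
  a <- sel$ncomp
  q2_cur <- sel$q2
  steps <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    removed_any <- FALSE
    v <- vip_scores(fit_pls(m, y, min(a, ncol(m), nrow(m) - 1)))
    for (cand in names(sort(v))) {
      if (ncol(m) < 2) break
      m_try <- m[, setdiff(colnames(m), cand), drop = FALSE]
      sel_try <- pick(m_try)
      accepted <- sel_try$q2 >= q2_cur - tol
      steps[[length(steps) + 1]] <- tibble::tibble(
        pass = pass, descriptor = cand,
        q2_before = q2_cur, q2_after = sel_try$q2, accepted = accepted
      )
      if (accepted) {
        m <- m_try
        a <- sel_try$ncomp
        q2_cur <- sel_try$q2
        removed_any <- TRUE
      }
    }
    if (!removed_any || ncol(m) < 2) break
  }
  structure(
    list(steps = dplyr::bind_rows(steps), final = colnames(m),
         final_q2 = q2_cur, final_ncomp = a),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>", nrow(x$steps), "trials,",
      sum(x$steps$accepted), "removals;", length(x$final),
      sprintf("descriptors retained (Q2 = %.3f, %d comp)\n", x$final_q2, x$final_ncomp))
  invisible(x)
}

#' Augment a descriptor matrix with experimental properties
#'
#' Appends measured properties (apparent solubility in blank buffer, melting
#' point, logD at pH 6.5) to a preprocessed descriptor matrix - autoscaled the
#' same way - refits the model and keeps each augmentation only when the
#' cross-validated Q2 strictly improves (the mirror image of the elimination
#' rule: on equality the simpler model wins). Compounds missing a requested
#' property are excluded
#' from that comparison (set `impute = "mean"` to keep them instead). A Q2
#' close to 1 after augmentation triggers a response-leakage warning.
#'
#' @param x Preprocessed descriptor table (training compounds; rownames/name
#'   column must match `ds$name`).
#' @param y Response vector aligned with `x`.
#' @param ds Solubility dataset supplying the experimental columns.
#' @param which Subset of `c("phb_solubility", "tm", "logd")`.
#' @param groups CV folds.
#' @param max_a,threshold Component-choice settings (see
#'   [choose_components()]).
#' @param impute `"none"` (default: drop compounds missing the property) or
#'   `"mean"`.
#' @param tol Tolerance for Q2 comparison.
#' @return A list with `data` (augmented descriptor tibble restricted to the
#'   compounds used), `y` (correspondingly subset response), `summary`
#'   (tibble: one row per candidate with Q2 without/with and the decision)
#'   and `retained` (character vector of accepted augmentations).
#' @export
augment_experimental <- function(x, y, ds, which = c("phb_solubility", "tm", "logd"),
                                 groups = 7, max_a = 5, threshold = 0.01,
                                 impute = c("none", "mean"), tol = 1e-6) {
  which <- match.arg(which, several.ok = TRUE)
  impute <- match.arg(impute)
  ds <- validate_solubility_data(ds)
  m <- as_descriptor_matrix(x)
  if (length(y) != nrow(m)) abort("length(y) must equal nrow(x)")
  col_of <- c(phb_solubility = "logs_phb", tm = "tm_c", logd = "logd65")
  summary <- list()
  retained <- character()
  for (w in which) {
    col <- col_of[[w]]
    vals <- ds[[col]][match(rownames(m), ds$name)]
    if (all(is.na(vals))) abort(paste0("augmentation column '", col, "' entirely missing"))
    if (impute == "mean") vals[is.na(vals)] <- mean(vals, na.rm = TRUE)
    use <- !is.na(vals)
    m_base <- m[use, , drop = FALSE]
    y_use <- y[use]
    sel0 <- choose_components(m_base, y_use, max_a = max_a, groups = groups,
                              threshold = threshold)
    zcol <- (vals[use] - mean(vals[use])) / sd(vals[use])
    m_aug <- cbind(m_base, matrix(zcol, ncol = 1, dimnames = list(NULL, w)))
    sel1 <- choose_components(m_aug, y_use, max_a = max_a, groups = groups,
                              threshold = threshold)
    if (sel1$q2 > 0.99) {
      warn(paste0("augmentation '", w, "' yields Q2 ~ 1: possible response leakage"))
    }
    keep <- sel1$q2 > sel0$q2 + tol
    if (keep) {
      m <- m[use, , drop = FALSE]
      y <- y_use
      m <- cbind(m, matrix(zcol, ncol = 1, dimnames = list(NULL, w)))
      retained <- c(retained, w)
    }
    summary[[w]] <- tibble::tibble(
      augmentation = w, n_used = sum(use),
      q2_without = sel0$q2, q2_with = sel1$q2, retained = keep
    )
  }
  list(data = descriptor_tbl(m), y = y,
       summary = dplyr::bind_rows(summary), retained = retained)
}

rmse <- function(observed, predicted) sqrt(mean((observed - predicted)^2))

#' Summarise a fitted model against its split
#'
#' Collects the headline statistics of a fitted PLS model into a one-row
#' table: descriptor count, training R2, cross-validated Q2, training and
#' test RMSE and the split sizes. Test R2 uses the conventional
#' `1 - SS_res / SS_tot` about the test mean (a constant predictor scores 0
#' or below).
#'
#' @param model A `pls_model`.
#' @param q2 Cross-validated Q2 of the model (from the selection trace or
#'   [q2_crossval()]).
#' @param x_test Preprocessed test descriptor table (or `NULL`).
#' @param y_test Test response values aligned with `x_test`.
#' @param id Model identifier string.
#' @param augmentations Character vector of experimental augmentations used.
#' @return A one-row tibble (columns: `id`, `n_descriptors`, `descriptors`,
#'   `r2`, `q2`, `rmse_tr`, `rmse_te`, `r2_te`, `n_train`, `n_test`,
#'   `augmentations`).
#' @export
build_model_summary <- function(model, q2, x_test = NULL, y_test = NULL,
                                id = "model", augmentations = character()) {
  stopifnot(inherits(model, "pls_model"))
  rmse_te <- r2_te <- NA_real_
  n_test <- 0L
  if (!is.null(x_test) && !is.null(y_test) && length(y_test) > 0) {
    pred <- predict(model, x_test)
    rmse_te <- rmse(y_test, pred)
    ss_tot <- sum((y_test - mean(y_test))^2)
    r2_te <- if (ss_tot > 0) 1 - sum((y_test - pred)^2) / ss_tot else NA_real_
    n_test <- length(y_test)
  }
  tibble::tibble(
    id = id, n_descriptors = model$p,
    descriptors = paste(model$descriptors, collapse = ";"),
    r2 = model$r2, q2 = q2, rmse_tr = model$rmse_tr,
    rmse_te = rmse_te, r2_te = r2_te,
    n_train = model$n, n_test = n_test,
    augmentations = paste(augmentations, collapse = ";")
  )
}
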