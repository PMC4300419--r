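#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with nonzero
#'   variance.
#' @return The squared Pearson correlation coefficient.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired values")
  if (var(x) <= 0 || var(y) <= 0) abort("zero variance in x or y")
  cor(x, y)^2
}

#' Inter-medium correlation, optionally stratified by lipophilicity
#'
#' Computes the squared Pearson correlation between the log solubilities of
#' two media over complete cases, overall and within logD strata. Strata are
#' half-open intervals on calculated logD at pH 6.5: with the default breaks
#' `c(3, 4)` they are `logD < 3`, `3 <= logD < 4` and `logD >= 4`. Strata with
#' fewer than 3 pairs report `NA` rather than failing.
#'
#' @param ds A solubility dataset with `logd65`.
#' @param medium_a,medium_b Two distinct medium codes.
#' @param logd_breaks Numeric break points (default `c(3, 4)`); use
#'   `numeric(0)` for the overall correlation only.
#' @return Tibble with columns `medium_a`, `medium_b`, `stratum`, `n`, `r2`.
#' @examples
#' stratified_correlation(solubility_data(), "phb", "fassif")
#' @export
stratified_correlation <- function(ds, medium_a, medium_b, logd_breaks = c(3, 4)) {
  pairs <- paired_solubility(ds, medium_a, medium_b)
  ds <- validate_solubility_data(ds)
  logd <- ds$logd65[match(pairs$name, ds$name)]
  if (anyNA(logd)) {
    abort(paste0("logd65 missing for paired compound(s): ",
                 paste(head(pairs$name[is.na(logd)], 5), collapse = ", ")))
  }
  breaks <- sort(unique(logd_breaks))
  edges <- c(-Inf, breaks, Inf)
  labels <- if (length(breaks) == 0) "all" else {
    vapply(seq_len(length(edges) - 1), function(i) {
      lo <- edges[i]; hi <- edges[i + 1]
      if (is.infinite(lo)) paste0("logd_lt", hi)
      else if (is.infinite(hi)) paste0("logd_ge", lo)
      else paste0("logd_", lo, "to", hi)
    }, character(1))
  }
  safe_r2 <- function(a, b) {
    if (length(a) < 3 || var(a) <= 0 || var(b) <= 0) NA_real_ else cor(a, b)^2
  }
  rows <- list(tibble::tibble(
    stratum = "all", n = nrow(pairs),
    r2 = safe_r2(pairs$value_a, pairs$value_b)
  ))
  if (length(breaks) > 0) {
    idx <- findInterval(logd, breaks) + 1L  # half-open [lo, hi)
    for (i in seq_along(labels)) {
      inb <- idx == i
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = labels[i], n = sum(inb),
        r2 = safe_r2(pairs$value_a[inb], pairs$value_b[inb])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  tibble::tibble(medium_a = match.arg(tolower(medium_a), media_codes()),
                 medium_b = match.arg(tolower(medium_b), media_codes()),
                 out)
}

#' Unweighted consensus of two prediction sets
#'
#' Averages the predictions of two independent models per compound - no
#' weighting - and, when observations are supplied, reports residuals for
#' each model and the consensus.
#'
#' @param pred_a,pred_b Data frames with columns `name` and `pred` (or named
#'   numeric vectors). Compound coverage must match.
#' @param observed Optional data frame with columns `name` and `observed`
#'   (or named numeric vector).
#' @return Tibble with columns `name`, `pred_a`, `pred_b`, `consensus` and,
#'   when observations are given, `observed`, `resid_a`, `resid_b`,
#'   `resid_consensus`.
#' @export
consensus_average <- function(pred_a, pred_b, observed = NULL) {
  norm <- function(p, what) {
    if (is.data.frame(p)) {
      if (!all(c("name", "pred") %in% names(p))) {
        abort(paste0(what, " must have columns 'name' and 'pred'"))
      }
      setNames(p$pred, p$name)
    } else if (!is.null(names(p))) p
    else abort(paste0(what, " must be a data frame or a named vector"))
  }
  a <- norm(pred_a, "pred_a")
  b <- norm(pred_b, "pred_b")
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0("prediction coverage mismatch; missing from pred_b: ",
                 paste(head(only_a, 5), collapse = ", "),
                 "; missing from pred_a: ",
                 paste(head(only_b, 5), collapse = ", ")))
  }
  b <- b[names(a)]
  out <- tibble::tibble(name = names(a), pred_a = unname(a), pred_b = unname(b),
                        consensus = (unname(a) + unname(b)) / 2)
  if (!is.null(observed)) {
    obs <- if (is.data.frame(observed)) {
      setNames(observed$observed %||% observed[[2]], observed$name)
    } else observed
    out$observed <- unname(obs[out$name])
    out$resid_a <- out$pred_a - out$observed
    out$resid_b <- out$pred_b - out$observed
    out$resid_consensus <- out$consensus - out$observed
  }
  out
}

#' Report large prediction residuals
#'
#' Lists compounds whose signed residual (predicted minus observed) is at
#' least `threshold` in magnitude, sorted by decreasing absolute residual.
#' Positive residuals are over-predictions.
#'
#' @param predictions Named numeric vector (or data frame with `name`,
#'   `pred`).
#' @param observed Named numeric vector aligned by name (or data frame with
#'   `name`, `observed`).
#' @param threshold Absolute log10 residual cut-off (default 1).
#' @return Tibble with `name`, `observed`, `predicted`, `residual`,
#'   `direction`.
#' @export
residual_report <- function(predictions, observed, threshold = 1.0) {
  if (is.data.frame(predictions)) predictions <- setNames(predictions$pred, predictions$name)
  if (is.data.frame(observed)) observed <- setNames(observed$observed, observed$name)
  if (is.null(names(predictions)) || is.null(names(observed))) {
    if (length(predictions) != length(observed)) {
      abort("predictions and observed must align")
    }
    names(predictions) <- names(observed) <- as.character(seq_along(observed))
  }
  common <- intersect(names(predictions), names(observed))
  resid <- predictions[common] - observed[common]
  big <- abs(resid) >= threshold
  out <- tibble::tibble(
    name = common[big],
    observed = unname(observed[common][big]),
    predicted = unname(predictions[common][big]),
    residual = unname(resid[big]),
    direction = unname(ifelse(resid[big] > 0, "over-predicted", "under-predicted"))
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$residual)))
}

#' Per-medium solubility fold range
#'
#' The ratio between the most and least soluble compound of each medium,
#' `10^(max - min)` on the log10 scale, rounded to 2 significant figures for
#' reporting (the raw value is kept alongside).
#'
#' @param ds A solubility dataset.
#' @param media Medium codes to report (default: all with data).
#' @return Tibble with `medium`, `n`, `fold_range`, `fold_range_2sf`.
#' @export
fold_range <- function(ds, media = media_codes()) {
  ds <- validate_solubility_data(ds)
  rows <- lapply(media, function(m) {
    v <- ds[[medium_column(m)]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    fr <- 10^(max(v) - min(v))
    tibble::tibble(medium = m, n = length(v), fold_range = fr,
                   fold_range_2sf = signif(fr, 2))
  })
  dplyr::bind_rows(rows)
}
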