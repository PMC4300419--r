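#' @section Descriptor tables:
#' Descriptor matrices are passed around as data frames whose first column,
#' `name`, identifies the compound and whose remaining columns are numeric
#' descriptors. Helpers accept plain matrices with rownames too.
#' @name descriptor-tables
NULL

# data frame (name + descriptors) or matrix -> numeric matrix with rownames
as_descriptor_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.data.frame(x)
  if (!"name" %in% names(x)) abort("descriptor table must have a 'name' column")
  m <- as.matrix(x[setdiff(names(x), "name")])
  storage.mode(m) <- "double"
  rownames(m) <- x$name
  if (anyNA(m)) abort("descriptor matrix contains missing cells")
  if (anyDuplicated(colnames(m))) abort("descriptor names must be unique")
  if (anyDuplicated(rownames(m))) abort("compound names must be unique")
  m
}

descriptor_tbl <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(name = rownames(m)),
    tibble::as_tibble(m)
  ))
}

#' Read a descriptor matrix from CSV
#'
#' First column must be the compound name; all remaining columns are numeric
#' descriptors from any provider.
#'
#' @param path Path to a CSV file.
#' @return A tibble with a `name` column followed by numeric descriptors.
#' @export
load_descriptor_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "name"
  raw$name <- as.character(raw$name)
  descriptor_tbl(as_descriptor_matrix(raw))
}

#' Blind descriptor names
#'
#' Replaces descriptor names with opaque aliases (`D0001`, `D0002`, ...) so
#' that downstream variable selection cannot be steered by recognising named
#' descriptors. Values are untouched; the returned key is a bijection that
#' [unblind_descriptors()] inverts for reporting.
#'
#' @param x Descriptor table or matrix.
#' @return A list with elements `data` (aliased descriptor tibble) and
#'   `key` (tibble with columns `alias`, `descriptor`).
#' @export
blind_descriptors <- function(x) {
  m <- as_descriptor_matrix(x)
  alias <- sprintf("D%04d", seq_len(ncol(m)))
  key <- tibble::tibble(alias = alias, descriptor = colnames(m))
  colnames(m) <- alias
  list(data = descriptor_tbl(m), key = key)
}

#' Restore original descriptor names
#'
#' @param x Blinded descriptor table or matrix.
#' @param key Alias key returned by [blind_descriptors()].
#' @return Descriptor tibble with original names.
#' @export
unblind_descriptors <- function(x, key) {
  m <- as_descriptor_matrix(x)
  idx <- match(colnames(m), key$alias)
  if (anyNA(idx)) abort("key does not cover all aliased descriptors")
  colnames(m) <- key$descriptor[idx]
  descriptor_tbl(m)
}

#' Unblind a character vector of aliases
#' @param aliases Character vector of aliases (unknown names pass through).
#' @param key Alias key from [blind_descriptors()].
#' @return Character vector of original descriptor names.
#' @export
unblind_names <- function(aliases, key) {
  idx <- match(aliases, key$alias)
  ifelse(is.na(idx), aliases, key$descriptor[idx])
}

#' Signed cube-root transform
#'
#' Replaces every cell x by `sign(x) * |x|^(1/3)`, a monotone variance
#' stabiliser that tames the heavy tails typical of counting and 3D
#' descriptors while remaining defined for negative values.
#'
#' @param x Descriptor table or matrix.
#' @return Transformed descriptor tibble (or matrix if a matrix was given).
#' @export
signed_cube_root <- function(x) {
  if (is.matrix(x)) {
    return(sign(x) * abs(x)^(1/3))
  }
  m <- as_descriptor_matrix(x)
  descriptor_tbl(sign(m) * abs(m)^(1/3))
}

#' Centre and scale descriptors to unit variance
#'
#' Mean-centres and scales every descriptor to unit variance using the sample
#' (n-1) standard deviation. Columns with variance below `const_tol` are
#' dropped and recorded in the returned state.
#'
#' @param x Descriptor table or matrix.
#' @param const_tol Variance below which a column is treated as constant.
#' @return A list with `data` (scaled descriptor tibble) and `state`, a
#'   `preprocess_state` holding centers, scales and dropped columns, which
#'   [apply_preprocess()] replays onto new observations.
#' @export
autoscale <- function(x, const_tol = 1e-12) {
  m <- as_descriptor_matrix(x)
  v <- apply(m, 2, var)
  constant <- colnames(m)[v < const_tol]
  if (length(constant) == ncol(m)) abort("all descriptor columns are constant")
  keep <- setdiff(colnames(m), constant)
  m <- m[, keep, drop = FALSE]
  centers <- colMeans(m)
  scales <- apply(m, 2, sd)
  scaled <- sweep(sweep(m, 2, centers, "-"), 2, scales, "/")
  state <- structure(
    list(cube_root_applied = FALSE, centers = centers, scales = scales,
         retained = keep, dropped_constant = constant),
    class = "preprocess_state"
  )
  list(data = descriptor_tbl(scaled), state = state)
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat("<preprocess_state>", length(x$retained), "descriptors retained;",
      length(x$dropped_constant), "constant dropped;",
      if (isTRUE(x$cube_root_applied)) "cube-root applied" else "no cube-root", "\n")
  invisible(x)
}

#' Replay a preprocessing state onto new observations
#'
#' Applies the stored transform (optional signed cube root, then centring and
#' scaling with the training centers/scales) to a new descriptor table, e.g.
#' test-set compounds. Columns are matched by name; extra columns are dropped.
#'
#' @param state A `preprocess_state` from [autoscale()] or
#'   [preprocess_descriptors()].
#' @param x New descriptor table or matrix.
#' @return Scaled descriptor tibble with the training descriptor set.
#' @export
apply_preprocess <- function(state, x) {
  stopifnot(inherits(state, "preprocess_state"))
  m <- as_descriptor_matrix(x)
  missing_cols <- setdiff(state$retained, colnames(m))
  if (length(missing_cols) > 0) {
    abort(paste0("descriptor(s) absent from new data: ",
                 paste(head(missing_cols, 5), collapse = ", ")))
  }
  m <- m[, state$retained, drop = FALSE]
  if (isTRUE(state$cube_root_applied)) m <- sign(m) * abs(m)^(1/3)
  scaled <- sweep(sweep(m, 2, state$centers, "-"), 2, state$scales, "/")
  descriptor_tbl(scaled)
}

column_skewness <- function(v) {
  n <- length(v)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((v - m)^3) / s2^1.5
}

column_kurtosis <- function(v) {
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((v - m)^4) / s2^2 - 3
}

#' Screen descriptors for approximate normality
#'
#' Excludes descriptors whose marginal distribution is far from normal.
#' The default screen is moment based: a descriptor is excluded when
#' `|skewness| > skew_limit` or `|excess kurtosis| > kurt_limit` (constant
#' columns are always excluded). A formal Shapiro-Wilk mode at a fixed alpha
#' is available as an alternative. The screen is invariant to centring and
#' scaling, so its position before or after autoscaling is immaterial.
#'
#' @param x Descriptor table or matrix.
#' @param skew_limit,kurt_limit Moment limits (defaults 2 and 7).
#' @param method `"moments"` (default) or `"shapiro"`.
#' @param alpha Significance level for the Shapiro-Wilk mode.
#' @return A list with `data` (retained descriptors) and `excluded`
#'   (character vector of removed descriptor names).
#' @export
normality_filter <- function(x, skew_limit = 2, kurt_limit = 7,
                             method = c("moments", "shapiro"), alpha = 0.05) {
  method <- match.arg(method)
  m <- as_descriptor_matrix(x)
  if (method == "moments") {
    sk <- apply(m, 2, column_skewness)
    ku <- apply(m, 2, column_kurtosis)
    bad <- is.na(sk) | abs(sk) > skew_limit | abs(ku) > kurt_limit
  } else {
    pv <- apply(m, 2, function(v) {
      if (var(v) <= 0) return(0)
      stats::shapiro.test(v)$p.value
    })
    bad <- pv < alpha
  }
  excluded <- colnames(m)[bad]
  if (all(bad)) warn("normality filter excluded every descriptor")
  list(data = descriptor_tbl(m[, !bad, drop = FALSE]), excluded = excluded)
}

#' Full descriptor preprocessing chain
#'
#' Runs the standard preparation for latent-variable modelling in one call:
#' signed cube-root transform, normality screen, then autoscaling. The
#' returned state replays the identical transform onto new compounds.
#'
#' @inheritParams normality_filter
#' @param cube_root Apply the signed cube-root transform first (default TRUE).
#' @param const_tol Variance below which a column is treated as constant.
#' @return A list with `data` (preprocessed descriptor tibble), `state`
#'   (a `preprocess_state`) and `excluded` (descriptors removed by the
#'   normality screen).
#' @export
preprocess_descriptors <- function(x, cube_root = TRUE, skew_limit = 2,
                                   kurt_limit = 7, method = c("moments", "shapiro"),
                                   alpha = 0.05, const_tol = 1e-12) {
  m <- as_descriptor_matrix(x)
  if (cube_root) m <- sign(m) * abs(m)^(1/3)
  nf <- normality_filter(m, skew_limit = skew_limit, kurt_limit = kurt_limit,
                         method = method, alpha = alpha)
  sc <- autoscale(nf$data, const_tol = const_tol)
  sc$state$cube_root_applied <- cube_root
  list(data = sc$data, state = sc$state, excluded = nf$excluded)
}
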