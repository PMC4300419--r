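strata_label <- function(logd, breaks = c(3, 4)) {
  cut(logd, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c(paste0("logD < ", breaks[1]),
                 paste0(breaks[1], " ≤ logD < ", breaks[2]),
                 paste0("logD ≥ ", breaks[2])))
}

#' Scatter plot of apparent solubility in two media
#'
#' Complete-case scatter of log10 molar solubilities with points coloured by
#' lipophilicity stratum and the identity line for reference; the overall
#' squared correlation is shown in the subtitle.
#'
#' @param ds A solubility dataset.
#' @param medium_a,medium_b Medium codes for the x and y axes.
#' @param logd_breaks Strata break points (default `c(3, 4)`).
#' @return A ggplot object.
#' @export
plot_media_correlation <- function(ds, medium_a, medium_b, logd_breaks = c(3, 4)) {
  pairs <- paired_solubility(ds, medium_a, medium_b)
  ds <- validate_solubility_data(ds)
  pairs$stratum <- strata_label(ds$logd65[match(pairs$name, ds$name)], logd_breaks)
  r2 <- pearson_r2(pairs$value_a, pairs$value_b)
  ggplot2::ggplot(pairs, ggplot2::aes(.data$value_a, .data$value_b,
                                      colour = .data$stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::scale_colour_grey(start = 0.75, end = 0.15, name = NULL) +
    ggplot2::labs(
      x = paste0("log S (", toupper(medium_a), ", M)"),
      y = paste0("log S (", toupper(medium_b), ", M)"),
      subtitle = sprintf("n = %d, r² = %.2f", nrow(pairs), r2)
    ) +
    ggplot2::theme_classic()
}

#' Strip plot of per-set solubility ranges
#'
#' Shows the response distribution of each split label (and unlabelled
#' compounds) for one medium, the usual check that a test set spans the same
#' range as the training set.
#'
#' @param ds A solubility dataset with a `set` column.
#' @param medium Medium code (default `"fassif"`).
#' @return A ggplot object.
#' @export
plot_solubility_ranges <- function(ds, medium = "fassif") {
  ds <- validate_solubility_data(ds)
  col <- medium_column(medium)
  dat <- tibble::tibble(
    set = ifelse(is.na(ds$set), "unlabelled", ds$set),
    value = ds[[col]]
  )
  dat <- dat[!is.na(dat$value), ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$set, .data$value, colour = .data$set)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8,
                         show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = paste0("log S (", toupper(medium), ", M)")) +
    ggplot2::theme_classic()
}

plot_observed_predicted <- function(obs_pred) {
  dat <- obs_pred[!is.na(obs_pred$observed), ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$observed, .data$predicted,
                                    colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.85) +
    ggplot2::labs(x = "observed log S (M)", y = "predicted log S (M)") +
    ggplot2::theme_classic()
}

#' Observed versus fitted response of a PLS model
#' @param object A `pls_model` fitted by [fit_pls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pls_model
#' @export
autoplot.pls_model <- function(object, ...) {
  dat <- tibble::tibble(observed = object$y, predicted = unname(object$fitted))
  ggplot2::ggplot(dat, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.85, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "observed log S (M)", y = "fitted log S (M)",
      subtitle = sprintf("%d components, R² = %.2f", object$ncomp, object$r2)
    ) +
    ggplot2::theme_classic()
}

#' Q2 trajectory of a greedy backward elimination
#' @param object A `selection_trace` from [greedy_backward_selection()].
#' @param ... Unused.
#' @return A ggplot object showing Q2 after each accepted removal.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  acc <- object$steps[object$steps$accepted, ]
  dat <- tibble::tibble(
    removal = seq_len(nrow(acc) + 1) - 1,
    q2 = c(if (nrow(acc) > 0) acc$q2_before[1] else object$final_q2, acc$q2_after)
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$removal, .data$q2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "#2c7fb8") +
    ggplot2::labs(x = "accepted removals", y = expression(Q^2)) +
    ggplot2::theme_classic()
}
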