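# ggplot2 displays for the main result types.

#' Observed versus out-of-fold predicted outcome
#'
#' Scatter of the out-of-fold predictions against the observed outcome with
#' the identity line; predictions are expected to cover a narrower range
#' than the observations (shrinkage).
#'
#' @param object A `stress_enet`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_enet
#' @export
autoplot.stress_enet <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted_oof)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#b58b00") +
    ggplot2::labs(x = "observed outcome", y = "out-of-fold prediction",
                  title = sprintf("nested-CV elastic net (delta R2 = %.3f)",
                                  object$delta_r2)) +
    ggplot2::theme_minimal()
}

#' Permutation null distribution
#'
#' Histogram of the null increments with the observed statistic marked.
#'
#' @param object A `stress_perm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stress_perm
#' @export
autoplot.stress_perm <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(delta_r2 = object$null_delta_r2),
                  ggplot2::aes(x = .data$delta_r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "#7a6ea8", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_delta_r2,
                        colour = "#b58b00", linewidth = 1) +
    ggplot2::labs(x = "null delta R2 (outcome + confounds permuted)",
                  y = "count",
                  title = sprintf("p_perm = %.4g (B = %d)",
                                  object$p_perm, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Feature-set importance bar chart
#'
#' @param importance Tibble from [feature_set_importance()].
#' @return A ggplot.
#' @export
plot_feature_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$group, .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col(fill = "#b58b00") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "R2 lost when the feature set is left out") +
    ggplot2::theme_minimal()
}

#' Group-average trajectory of one feature unit
#'
#' Mean feature value across subjects per timepoint for one region or
#' subnetwork, with one line per subject underneath.
#'
#' @param features Feature tibble (`participant_id` + feature columns).
#' @param unit Region or subnetwork label (see [feature_labels()]).
#' @return A ggplot.
#' @export
plot_trajectory <- function(features, unit) {
  lab <- feature_labels(features)
  cols <- lab$feature[lab$unit == unit]
  abort_if(length(cols) == 0, sprintf("no features for unit '%s'", unit))
  long <- features |>
    dplyr::select("participant_id", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(-"participant_id", names_to = "feature") |>
    dplyr::left_join(lab, by = "feature")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.2, colour = "grey50") +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "#b58b00", linewidth = 1.2) +
    ggplot2::labs(x = NULL, y = "estimate", title = unit) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
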