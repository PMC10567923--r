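# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy elastic-net weights
#'
#' One row per feature with the mean standardized weight across outer folds
#' and the retention fraction (stability).
#'
#' @param x A `stress_enet`.
#' @param ... Unused.
#' @return Tibble: `feature`, `mean_weight`, `stability`, `n_nonzero`.
#' @method tidy stress_enet
#' @export
tidy.stress_enet <- function(x, ...) {
  W <- x$weights
  tibble::tibble(
    feature = rownames(W),
    mean_weight = rowMeans(W),
    stability = rowSums(W != 0) / ncol(W),
    n_nonzero = rowSums(W != 0)
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$mean_weight)))
}

#' @rdname tidy.stress_enet
#' @method glance stress_enet
#' @export
glance.stress_enet <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$predictions),
    n_features = nrow(x$weights),
    r2_full = x$r2_full,
    r2_baseline = x$r2_baseline,
    delta_r2 = x$delta_r2,
    oof_cor = stats::cor(x$predictions$predicted_oof, x$predictions$observed)
  )
}

#' Tidy permutation results
#'
#' @param x A `stress_perm`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistics, p-value, and null
#'   bounds.
#' @method tidy stress_perm
#' @export
tidy.stress_perm <- function(x, ...) {
  tibble::tibble(
    observed_delta_r2 = x$observed_delta_r2,
    observed_r2 = x$observed_r2,
    r2_baseline = x$r2_baseline,
    p_perm = x$p_perm,
    null_r2_lo = x$null_r2_bounds[1],
    null_r2_hi = x$null_r2_bounds[2],
    n_perm = x$n_perm
  )
}

#' @rdname tidy.stress_perm
#' @method glance stress_perm
#' @export
glance.stress_perm <- tidy.stress_perm

#' Tidy cross-sex transfer results
#'
#' @param x A `stress_transfer`.
#' @param ... Unused.
#' @return The transfer tibble joined with the per-sex nested-CV results.
#' @method tidy stress_transfer
#' @export
tidy.stress_transfer <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$transfer, analysis = "transfer"),
    x$stratified |>
      dplyr::transmute(train_sex = .data$sex, test_sex = .data$sex,
                       r = .data$oof_cor, r2 = .data$r2_full,
                       analysis = "stratified")
  )
}

#' Tidy weighted-resampling results
#'
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @return One-row tibble: statistic mean, percentile interval, achieved
#'   and reference moments.
#' @method tidy resampling_result
#' @export
tidy.resampling_result <- function(x, ...) {
  tibble::tibble(
    estimate = mean(x$estimates),
    conf_low = x$ci[1], conf_high = x$ci[2],
    mean_resampled = x$achieved$mean_resampled,
    sd_resampled = x$achieved$sd_resampled,
    mean_reference = x$achieved$mean_reference,
    sd_reference = x$achieved$sd_reference,
    n_resamples = x$B
  )
}
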