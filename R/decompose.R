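#' Screen markers by partial correlation with the outcome
#'
#' Computes, per marker, the partial correlation with the outcome given the
#' confounds, with a t-test on `n - 2 - k` degrees of freedom. Intended as
#' a selection step for the component regressions, so no multiple-testing
#' correction is applied (uncorrected p < 0.05 selects).
#'
#' @param panel A `normalized_panel` or a tibble `participant_id` + marker
#'   columns.
#' @param outcome Numeric outcome aligned with panel rows.
#' @param confounds Data frame of confound columns aligned with panel rows.
#' @param level Selection level (default 0.05).
#' @return Tibble: `marker`, `partial_r`, `statistic`, `df`, `p_value`,
#'   `selected`.
#' @export
screen_markers <- function(panel, outcome, confounds, level = 0.05) {
  values <- if (inherits(panel, "normalized_panel")) panel$values else panel
  markers <- setdiff(names(values), "participant_id")
  C <- confound_matrix(confounds)
  n <- length(outcome)
  k <- ncol(C)
  abort_if(n <= k + 2, "too few observations for partial correlation")
  y_res <- residualize(outcome, C)
  purrr::map_dfr(markers, function(m) {
    x_res <- residualize(values[[m]], C)
    r <- stats::cor(x_res, y_res)[1, 1]
    df <- n - 2 - k
    tt <- r * sqrt(df / max(1 - r^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df)
    tibble::tibble(marker = m, partial_r = r, statistic = tt, df = df,
                   p_value = p, selected = p < level)
  })
}

#' Split the outcome into brain-predicted and residual components
#'
#' Per subject, `residual = observed - predicted`, where the prediction is
#' the out-of-fold elastic-net prediction; the additive identity
#' `observed = predicted + residual` holds exactly. Orthogonality is *not*
#' assumed: out-of-fold predictions need not be uncorrelated with the
#' residuals.
#'
#' @param prediction A `stress_enet` fit or its `predictions` tibble
#'   (columns `participant_id`, `observed`, `predicted_oof`).
#' @return Tibble: `participant_id`, `observed`, `predicted`, `residual`.
#' @export
decompose_outcome <- function(prediction) {
  preds <- if (inherits(prediction, "stress_enet")) prediction$predictions else {
    tibble::as_tibble(prediction)
  }
  abort_if(!all(c("participant_id", "observed", "predicted_oof") %in% names(preds)),
           "predictions must have participant_id, observed, predicted_oof")
  abort_if(anyNA(preds$predicted_oof), "missing out-of-fold predictions")
  tibble::tibble(
    participant_id = preds$participant_id,
    observed = preds$observed,
    predicted = preds$predicted_oof,
    residual = preds$observed - preds$predicted_oof
  )
}

#' Regress outcome components on markers
#'
#' For each selected marker and each component (observed, brain-predicted,
#' residual outcome), fits
#' `component ~ marker + sex + marker:sex + age + diagnosis + medication`.
#' An association with the predicted component indicates variance shared
#' with the brain response; an association with only the residual component
#' indicates variance the brain-based model does not capture.
#'
#' @param markers A `normalized_panel` or tibble `participant_id` + marker
#'   columns (typically restricted to screened markers).
#' @param components Output of [decompose_outcome()].
#' @param participants Participants tibble providing `sex`, `age`,
#'   `diagnosis`, `medication`.
#' @return Object of class `stress_decomposition`: tibble `marker`,
#'   `component`, `term`, `estimate`, `std_error`, `statistic`, `p_value`.
#' @export
marker_component_regression <- function(markers, components, participants) {
  values <- if (inherits(markers, "normalized_panel")) markers$values else markers
  mk <- setdiff(names(values), "participant_id")
  abort_if(length(mk) == 0, "no markers to regress")
  dat <- components |>
    dplyr::inner_join(values, by = "participant_id") |>
    dplyr::inner_join(
      dplyr::select(participants, "participant_id", "sex", "age",
                    "diagnosis", "medication"),
      by = "participant_id"
    )
  comps <- c("observed", "predicted", "residual")
  out <- purrr::map_dfr(mk, function(m) {
    purrr::map_dfr(comps, function(cc) {
      d <- dat
      d$.marker <- d[[m]]
      d$.y <- d[[cc]]
      fit <- stats::lm(.y ~ .marker * sex + age + diagnosis + medication, data = d)
      co <- summary(fit)$coefficients
      if (anyNA(stats::coef(fit))) {
        rlang::warn(sprintf("collinear covariate(s) dropped for marker %s", m))
      }
      tibble::tibble(
        marker = m, component = cc,
        term = sub("^\\.marker", m, rownames(co)),
        estimate = co[, 1], std_error = co[, 2],
        statistic = co[, 3], p_value = co[, 4]
      )
    })
  })
  structure(out, class = c("stress_decomposition", class(out)))
}

#' Weighted bootstrap matching a group to a reference distribution
#'
#' Reweights one group so that a statistic is evaluated under an outcome
#' distribution whose first two moments match another group's: observations
#' with very high or low outcome values receive higher weight. The default
#' `"raking"` weights are an exponential tilt `w ~ exp(l1*c1 + l2*c2)`
#' calibrated (entropy balancing) so the weighted mean and variance equal
#' the reference moments exactly whenever they are attainable on the
#' group's support. `"density_ratio"` weights - the ratio of a normal
#' density with the reference moments to one with the group's own moments,
#' clipped at the 99th weight percentile - are provided as a simpler
#' alternative, but cannot stretch the weighted SD beyond what the group's
#' observed range supports. `B` weighted bootstrap resamples recompute the
#' statistic.
#'
#' @param data Data frame containing `group_col` and `outcome_col`.
#' @param group Level of `group_col` to reweight (e.g. `"male"`).
#' @param reference Level providing the target moments (e.g. `"female"`).
#' @param statistic Function `data -> scalar` applied to each resampled
#'   group subset.
#' @param outcome_col,group_col Column names.
#' @param B Number of resamples.
#' @param seed Seed.
#' @param method Weight construction, see above.
#' @param reference_moments Optional named vector `c(mean, sd)` giving the
#'   target moments directly (e.g. published cohort moments); when supplied
#'   the reference group's sample moments are not used.
#' @return Object of class `resampling_result`: `estimates` (length `B`),
#'   `ci` (2.5/97.5 percentiles), `weights`, and `achieved` moments
#'   (average resampled mean/SD against the reference).
#' @export
weighted_resample_match <- function(data, group = "male", reference = "female",
                                    statistic = function(d) mean(d$bmi),
                                    outcome_col = "bmi", group_col = "sex",
                                    B = 1000L, seed = 1L,
                                    method = c("raking", "density_ratio"),
                                    reference_moments = NULL) {
  method <- match.arg(method)
  g <- data[data[[group_col]] == group, , drop = FALSE]
  r <- data[data[[group_col]] == reference, , drop = FALSE]
  abort_if(nrow(g) == 0 || (is.null(reference_moments) && nrow(r) == 0),
           "both groups must be nonempty")
  x <- g[[outcome_col]]
  g_mu <- mean(x); g_sd <- stats::sd(x)
  if (is.null(reference_moments)) {
    r_mu <- mean(r[[outcome_col]]); r_sd <- stats::sd(r[[outcome_col]])
  } else {
    r_mu <- reference_moments[["mean"]]; r_sd <- reference_moments[["sd"]]
  }
  abort_if(!is.finite(g_sd) || g_sd == 0, "degenerate group SD")
  if (method == "density_ratio") {
    w <- stats::dnorm(x, r_mu, r_sd) / pmax(stats::dnorm(x, g_mu, g_sd), 1e-300)
    w <- pmin(w, stats::quantile(w, 0.99))
  } else {
    w <- raking_weights(x, r_mu, r_sd)
  }
  w <- w / sum(w)
  res <- with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      idx <- sample.int(nrow(g), nrow(g), replace = TRUE, prob = w)
      d <- g[idx, , drop = FALSE]
      list(stat = statistic(d), mu = mean(d[[outcome_col]]),
           sd = stats::sd(d[[outcome_col]]))
    })
  })
  est <- purrr::map_dbl(res, "stat")
  structure(list(
    estimates = est,
    ci = stats::quantile(est, c(0.025, 0.975), names = FALSE),
    weights = w,
    achieved = tibble::tibble(
      mean_resampled = mean(purrr::map_dbl(res, "mu")),
      sd_resampled = mean(purrr::map_dbl(res, "sd")),
      mean_reference = r_mu, sd_reference = r_sd
    ),
    B = B
  ), class = "resampling_result")
}

# Entropy-balancing weights: minimize the convex dual
# log(mean(exp(l %*% c))) so that weighted means of the constraint columns
# c1 = x - mu, c2 = (x - mu)^2 - sd^2 are zero. Falls back to unclipped
# density-ratio weights with a warning if the targets are unattainable on
# the sample's support.
raking_weights <- function(x, mu, sd_) {
  c1 <- x - mu
  c2 <- (x - mu)^2 - sd_^2
  CC <- cbind(c1 / stats::sd(c1), c2 / stats::sd(c2))
  dual <- function(l) {
    eta <- CC %*% l
    m <- max(eta)
    log(mean(exp(eta - m))) + m
  }
  grad <- function(l) {
    w <- exp(CC %*% l - max(CC %*% l))
    w <- w / sum(w)
    colSums(CC * as.vector(w))
  }
  fit <- stats::optim(c(0, 0), dual, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  w <- as.vector(exp(CC %*% fit$par))
  w <- w / sum(w)
  ok <- abs(sum(w * c1)) < 0.05 * sd_ && abs(sum(w * c2)) < 0.2 * sd_^2
  if (!ok) {
    rlang::warn("reference moments not attainable on the group's support; falling back to density-ratio weights")
    g_mu <- mean(x); g_sd <- stats::sd(x)
    w <- stats::dnorm(x, mu, sd_) / pmax(stats::dnorm(x, g_mu, g_sd), 1e-300)
  }
  w
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "<resampling_result> B = %d, statistic %.3f [%.3f, %.3f]; resampled mean %.2f (ref %.2f), SD %.2f (ref %.2f)\n",
    x$B, mean(x$estimates), x$ci[1], x$ci[2],
    x$achieved$mean_resampled, x$achieved$mean_reference,
    x$achieved$sd_resampled, x$achieved$sd_reference
  ))
  invisible(x)
}
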