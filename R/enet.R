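#' Configuration for confound-aware nested-CV elastic-net prediction
#'
#' @param alpha Elastic-net mixing parameter (1 = lasso); fixed at 0.5 by
#'   convention for correlated feature sets.
#' @param outer_folds,inner_folds Fold counts of the nested cross-validation.
#' @param n_lambda Length of the penalty path (log-spaced from the
#'   null-model penalty, as computed by \pkg{glmnet}).
#' @param n_perm Permutation iterations for [permutation_test()]; 1000 is a
#'   desk-scale default, 10000 the reference setting.
#' @param seed Seed controlling folds and permutations.
#' @param stability_threshold Fraction of outer folds in which a weight must
#'   be retained to count as stable.
#' @param confounds Confound column names looked up in the participants
#'   table: age, sex, diagnosis, pre-task cortisol responder, log mean
#'   framewise displacement.
#' @param penalize_confounds Penalize confound columns like features?
#'   Default `FALSE`: confounds are always-in, unpenalized columns, and a
#'   confound-only baseline is fit with ordinary least squares on the same
#'   fold partition.
#' @param thresh Coordinate-descent convergence threshold passed to glmnet.
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(alpha = 0.5, outer_folds = 10L, inner_folds = 10L,
                              n_lambda = 100L, n_perm = 1000L, seed = 1L,
                              stability_threshold = 0.80,
                              confounds = c("age", "sex", "diagnosis",
                                            "pretask_responder", "log_mean_fd"),
                              penalize_confounds = FALSE,
                              thresh = 1e-7) {
  abort_if(!(alpha > 0 && alpha <= 1), "alpha must be in (0, 1]")
  abort_if(!is_count(outer_folds, 2) || !is_count(inner_folds, 2),
           "fold counts must be >= 2")
  abort_if(!is_count(n_perm, 1), "n_perm must be a count")
  abort_if(!(stability_threshold > 0 && stability_threshold <= 1),
           "stability_threshold must be in (0, 1]")
  structure(list(alpha = alpha, outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 n_lambda = as.integer(n_lambda), n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 stability_threshold = stability_threshold,
                 confounds = confounds,
                 penalize_confounds = isTRUE(penalize_confounds),
                 thresh = thresh),
            class = "prediction_config")
}

# Numeric confound matrix from a participants-style data frame.
confound_matrix <- function(confounds) {
  df <- as.data.frame(confounds)
  abort_if(anyNA(df), "missing values in confounds")
  num <- lapply(df, function(x) {
    if (is.numeric(x)) return(x)
    if (is.logical(x)) return(as.numeric(x))
    if (is.character(x) || is.factor(x)) {
      x <- as.factor(x)
      abort_if(nlevels(x) > 2, "only binary categorical confounds are supported")
      return(as.numeric(x) - 1)
    }
    rlang::abort("unsupported confound column type")
  })
  m <- do.call(cbind, num)
  colnames(m) <- names(df)
  m
}

# The workhorse: nested cross-validated elastic net on plain matrices.
# Returns out-of-fold predictions for the full and the confound-only
# baseline model, R^2 values, and (optionally) per-fold feature weights.
nested_cv_core <- function(X, y, C, cfg, seed, record_weights = FALSE) {
  n <- length(y)
  p <- ncol(X)
  k <- cfg$outer_folds
  pen <- c(rep(if (cfg$penalize_confounds) 1 else 0, ncol(C)), rep(1, p))
  seeds <- derive_seeds(seed, k + 1L)
  fold <- with_seed(seeds[k + 1L], sample(rep(seq_len(k), length.out = n)))

  pred <- pred_base <- rep(NA_real_, n)
  W <- if (record_weights) matrix(0, p, k, dimnames = list(colnames(X), NULL)) else NULL
  lambdas <- numeric(k)

  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd_, `/`)
    A <- cbind(C, Xs)

    path <- glmnet::glmnet(A[tr, , drop = FALSE], y[tr], alpha = cfg$alpha,
                           penalty.factor = pen, nlambda = cfg$n_lambda,
                           standardize = FALSE, thresh = cfg$thresh)
    lam <- path$lambda
    ifold <- with_seed(seeds[f],
                       sample(rep(seq_len(cfg$inner_folds), length.out = sum(tr))))
    tr_idx <- which(tr)
    sse <- matrix(0, cfg$inner_folds, length(lam))
    for (j in seq_len(cfg$inner_folds)) {
      itr <- tr_idx[ifold != j]
      ite <- tr_idx[ifold == j]
      fj <- glmnet::glmnet(A[itr, , drop = FALSE], y[itr], alpha = cfg$alpha,
                           penalty.factor = pen, lambda = lam,
                           standardize = FALSE, thresh = cfg$thresh)
      pj <- cbind(1, A[ite, , drop = FALSE]) %*% rbind(fj$a0, as.matrix(fj$beta))
      nl <- ncol(pj)
      sse[j, seq_len(nl)] <- colSums((pj - y[ite])^2)
      if (nl < length(lam)) sse[j, (nl + 1):length(lam)] <- sse[j, nl]
    }
    best <- which.min(colSums(sse))
    lambdas[f] <- lam[best]
    beta <- as.matrix(path$beta)[, best]
    a0 <- path$a0[best]
    te <- which(!tr)
    pred[te] <- a0 + A[te, , drop = FALSE] %*% beta
    if (record_weights) W[, f] <- beta[(ncol(C) + 1):(ncol(C) + p)]

    cb <- ols_fit(cbind(1, C[tr, , drop = FALSE]), y[tr])$coef
    cb[is.na(cb)] <- 0
    pred_base[te] <- cbind(1, C[te, , drop = FALSE]) %*% cb
  }

  sst <- sum((y - mean(y))^2)
  r2_full <- 1 - sum((y - pred)^2) / sst
  r2_base <- 1 - sum((y - pred_base)^2) / sst
  list(pred = pred, pred_base = pred_base, fold = fold,
       r2_full = r2_full, r2_base = r2_base, delta_r2 = r2_full - r2_base,
       weights = W, lambdas = lambdas)
}

check_prediction_inputs <- function(X, y, C, cfg) {
  abort_if(anyNA(X), "missing feature values")
  abort_if(anyNA(y), "missing outcome values")
  abort_if(stats::sd(y) == 0, "outcome is constant; R^2 undefined")
  abort_if(length(y) < 2 * cfg$outer_folds,
           "need at least 2 x outer_folds subjects")
}

#' Nested cross-validated elastic-net prediction of the outcome
#'
#' Predicts a continuous outcome from trajectory features with an elastic
#' net under nested cross-validation: outer folds give each subject exactly
#' one out-of-fold prediction from a model never trained on it; the penalty
#' is selected within each training fold by inner cross-validation (minimum
#' mean squared error). Features are standardized with training-fold means
#' and SDs only. Confounds enter as unpenalized columns, and a confound-only
#' ordinary-least-squares baseline is evaluated on the same fold partition;
#' the incremental variance explained by the features is
#' `delta_r2 = r2_full - r2_baseline`. Out-of-fold predictions cover a
#' narrower range than the observed outcome (shrinkage toward the training
#' mean); this is expected, not an error.
#'
#' @param features Tibble `participant_id` + numeric feature columns.
#' @param outcome Numeric outcome vector aligned with `features` rows.
#' @param confounds Data frame of confound columns aligned with `features`
#'   rows (numeric, logical, or binary categorical).
#' @param cfg A [prediction_config()].
#' @return Object of class `stress_enet`: predictions tibble, R^2 values,
#'   per-fold penalties and feature weights, and the config.
#' @export
nested_cv_elastic_net <- function(features, outcome, confounds,
                                  cfg = prediction_config()) {
  X <- feature_matrix_of(features)
  C <- confound_matrix(confounds)
  abort_if(nrow(C) != nrow(X) || length(outcome) != nrow(X),
           "features, outcome, and confounds must align")
  check_prediction_inputs(X, outcome, C, cfg)
  core <- nested_cv_core(X, outcome, C, cfg, cfg$seed, record_weights = TRUE)
  structure(list(
    predictions = tibble::tibble(
      participant_id = features$participant_id,
      observed = outcome,
      predicted_oof = core$pred,
      baseline_oof = core$pred_base,
      fold = core$fold
    ),
    r2_full = core$r2_full, r2_baseline = core$r2_base,
    delta_r2 = core$delta_r2,
    lambdas = core$lambdas,
    weights = core$weights,
    cfg = cfg
  ), class = "stress_enet")
}

feature_matrix_of <- function(features) {
  abort_if(!"participant_id" %in% names(features),
           "`features` needs a participant_id column")
  as.matrix(features[setdiff(names(features), "participant_id")])
}

#' @export
print.stress_enet <- function(x, ...) {
  cat(sprintf(
    "<stress_enet> n = %d, %d features, R2 full %.3f, baseline %.3f, delta %.3f\n",
    nrow(x$predictions), nrow(x$weights), x$r2_full, x$r2_baseline, x$delta_r2
  ))
  invisible(x)
}

#' Stable elastic-net weights across outer folds
#'
#' Features with a non-zero weight in at least `threshold` of the outer
#' folds, with retention fraction, sign, and mean standardized weight.
#'
#' @param fit A `stress_enet`.
#' @param threshold Retention fraction; defaults to the fit's configured
#'   stability threshold (0.80).
#' @return Tibble: `feature`, `n_nonzero`, `stability`, `mean_weight`,
#'   `sign`.
#' @export
weight_stability <- function(fit, threshold = NULL) {
  abort_if(!inherits(fit, "stress_enet"), "`fit` must be a stress_enet")
  threshold <- threshold %||% fit$cfg$stability_threshold
  W <- fit$weights
  k <- ncol(W)
  out <- tibble::tibble(
    feature = rownames(W),
    n_nonzero = unname(rowSums(W != 0)),
    stability = unname(rowSums(W != 0) / k),
    mean_weight = unname(rowMeans(W))
  ) |>
    dplyr::filter(.data$stability >= threshold) |>
    dplyr::mutate(sign = sign(.data$mean_weight)) |>
    dplyr::arrange(dplyr::desc(abs(.data$mean_weight)))
  out
}
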