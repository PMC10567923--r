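#' Permutation inference preserving the outcome-confound correlation
#'
#' Tests whether the features add predictive information beyond the
#' confounds. Each iteration permutes the rows of (outcome, confounds)
#' *jointly* against the feature rows - so the confound-outcome structure
#' survives under the null - and recomputes the full nested-CV increment
#' `delta_r2` with a freshly drawn fold partition, propagating partition
#' variance into the null. The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @inheritParams nested_cv_elastic_net
#' @return Object of class `stress_perm`: observed statistics, the null
#'   distributions of `delta_r2` and full-model R^2, `p_perm`, and 95%
#'   percentile bounds of the null R^2 (the reference band for judging the
#'   observed model against confound-only performance).
#' @export
permutation_test <- function(features, outcome, confounds,
                             cfg = prediction_config()) {
  abort_if(cfg$n_perm < 100, "need at least 100 permutation iterations")
  X <- feature_matrix_of(features)
  C <- confound_matrix(confounds)
  abort_if(nrow(C) != nrow(X) || length(outcome) != nrow(X),
           "features, outcome, and confounds must align")
  check_prediction_inputs(X, outcome, C, cfg)

  B <- cfg$n_perm
  seeds <- derive_seeds(cfg$seed, 2L * B + 1L)
  obs <- nested_cv_core(X, outcome, C, cfg, cfg$seed)

  null_delta <- null_r2 <- numeric(B)
  n <- length(outcome)
  for (b in seq_len(B)) {
    perm <- with_seed(seeds[b], sample.int(n))
    res <- nested_cv_core(X, outcome[perm], C[perm, , drop = FALSE],
                          cfg, seeds[B + b])
    null_delta[b] <- res$delta_r2
    null_r2[b] <- res$r2_full
  }
  p_perm <- (1 + sum(null_delta >= obs$delta_r2)) / (B + 1)
  structure(list(
    observed_delta_r2 = obs$delta_r2,
    observed_r2 = obs$r2_full,
    r2_baseline = obs$r2_base,
    null_delta_r2 = null_delta,
    null_r2 = null_r2,
    p_perm = p_perm,
    null_r2_bounds = stats::quantile(null_r2, c(0.025, 0.975), names = FALSE),
    n_perm = B, cfg = cfg
  ), class = "stress_perm")
}

#' @export
print.stress_perm <- function(x, ...) {
  cat(sprintf(
    "<stress_perm> delta R2 = %.3f, p_perm = %.4g (B = %d)\n",
    x$observed_delta_r2, x$p_perm, x$n_perm
  ))
  invisible(x)
}

#' Leave-feature-set-out importance
#'
#' Quantifies how much predictive accuracy is lost when all timepoints of a
#' feature set (by default, all features of one region or subnetwork) are
#' left out: `importance = r2_full - r2_without`, both from nested CV with
#' identical fold seeds.
#'
#' @inheritParams nested_cv_elastic_net
#' @param grouping Named list mapping group label to a character vector of
#'   feature columns; default groups by region/subnetwork across all
#'   timepoints via [feature_labels()]. Groups must be subsets of the
#'   feature columns.
#' @return Tibble sorted by decreasing importance: `group`, `n_features`,
#'   `r2_without`, `importance`.
#' @export
feature_set_importance <- function(features, outcome, confounds,
                                   cfg = prediction_config(), grouping = NULL) {
  X <- feature_matrix_of(features)
  C <- confound_matrix(confounds)
  check_prediction_inputs(X, outcome, C, cfg)
  if (is.null(grouping)) {
    lab <- feature_labels(features)
    grouping <- split(lab$feature, lab$unit)
  }
  all_cols <- colnames(X)
  for (g in names(grouping)) {
    abort_if(!all(grouping[[g]] %in% all_cols),
             sprintf("group '%s' names unknown feature columns", g))
  }
  full <- nested_cv_core(X, outcome, C, cfg, cfg$seed)
  out <- purrr::map_dfr(names(grouping), function(g) {
    keep <- setdiff(all_cols, grouping[[g]])
    res <- nested_cv_core(X[, keep, drop = FALSE], outcome, C, cfg, cfg$seed)
    tibble::tibble(group = g, n_features = length(grouping[[g]]),
                   r2_without = res$r2_full,
                   importance = full$r2_full - res$r2_full)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  attr(out, "r2_full") <- full$r2_full
  out
}

#' Sex-stratified and cross-sex prediction
#'
#' Trains an elastic net (penalty chosen by inner CV only) on one sex and
#' applies it unchanged to the other, both directions, reporting the
#' transfer correlation and R^2. Additionally runs the full nested CV
#' within each sex (with sex dropped from the confounds).
#'
#' @inheritParams nested_cv_elastic_net
#' @param sex Character vector (`"female"`/`"male"`) aligned with rows.
#' @return Object of class `stress_transfer`: `transfer` tibble (train sex,
#'   test sex, r, R^2) and `stratified` tibble (sex, r2_full, r2_baseline,
#'   delta_r2, oof correlation).
#' @export
cross_sex_transfer <- function(features, outcome, confounds, sex,
                               cfg = prediction_config()) {
  X <- feature_matrix_of(features)
  C <- confound_matrix(confounds)
  sexes <- c("female", "male")
  abort_if(!all(sex %in% sexes), "sex must be 'female' or 'male'")
  abort_if(!all(sexes %in% sex), "both sexes must be present")
  n_by <- table(sex)
  abort_if(any(n_by < 10), "refusing stratified training with a sex of n < 10")
  C_nosex <- C[, setdiff(colnames(C), "sex"), drop = FALSE]
  seeds <- derive_seeds(cfg$seed, 4L)

  train_apply <- function(train_sex, seed) {
    tr <- sex == train_sex
    te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd); sd_[sd_ == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd_, `/`)
    A <- cbind(C_nosex, Xs)
    pen <- c(rep(if (cfg$penalize_confounds) 1 else 0, ncol(C_nosex)),
             rep(1, ncol(X)))
    path <- glmnet::glmnet(A[tr, , drop = FALSE], outcome[tr], alpha = cfg$alpha,
                           penalty.factor = pen, nlambda = cfg$n_lambda,
                           standardize = FALSE, thresh = cfg$thresh)
    lam <- path$lambda
    ifold <- with_seed(seed, sample(rep(seq_len(cfg$inner_folds), length.out = sum(tr))))
    tr_idx <- which(tr)
    sse <- rep(0, length(lam))
    for (j in seq_len(cfg$inner_folds)) {
      itr <- tr_idx[ifold != j]; ite <- tr_idx[ifold == j]
      fj <- glmnet::glmnet(A[itr, , drop = FALSE], outcome[itr], alpha = cfg$alpha,
                           penalty.factor = pen, lambda = lam,
                           standardize = FALSE, thresh = cfg$thresh)
      pj <- cbind(1, A[ite, , drop = FALSE]) %*% rbind(fj$a0, as.matrix(fj$beta))
      nl <- ncol(pj)
      contrib <- colSums((pj - outcome[ite])^2)
      if (nl < length(lam)) contrib <- c(contrib, rep(contrib[nl], length(lam) - nl))
      sse <- sse + contrib
    }
    best <- which.min(sse)
    pred <- as.vector(cbind(1, A[te, , drop = FALSE]) %*%
                        rbind(path$a0[best], as.matrix(path$beta)[, best, drop = FALSE]))
    y_te <- outcome[te]
    sst <- sum((y_te - mean(y_te))^2)
    tibble::tibble(
      train_sex = train_sex, test_sex = setdiff(sexes, train_sex),
      r = if (stats::sd(pred) > 0) stats::cor(pred, y_te) else 0,
      r2 = 1 - sum((y_te - pred)^2) / sst
    )
  }
  transfer <- dplyr::bind_rows(train_apply("female", seeds[1]),
                               train_apply("male", seeds[2]))

  stratified <- purrr::map_dfr(sexes, function(s) {
    idx <- sex == s
    cfg_s <- cfg
    cfg_s$seed <- seeds[3 + (s == "male")]
    core <- nested_cv_core(X[idx, , drop = FALSE], outcome[idx],
                           C_nosex[idx, , drop = FALSE], cfg_s, cfg_s$seed)
    tibble::tibble(
      sex = s, r2_full = core$r2_full, r2_baseline = core$r2_base,
      delta_r2 = core$delta_r2,
      oof_cor = if (stats::sd(core$pred) > 0) stats::cor(core$pred, outcome[idx]) else 0
    )
  })
  structure(list(transfer = transfer, stratified = stratified, cfg = cfg),
            class = "stress_transfer")
}

#' @export
print.stress_transfer <- function(x, ...) {
  cat("<stress_transfer>\n")
  print(x$transfer)
  print(x$stratified)
  invisible(x)
}
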