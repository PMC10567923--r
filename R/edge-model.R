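#' Fit the hierarchical trajectory model for one edge
#'
#' For an unordered ROI pair, regresses the dependent ROI's concatenated
#' signal on: an intercept, 17 timepoint regressors (15 task blocks plus the
#' two flanking resting-states), the centered predictor-ROI timeseries, the
#' 17 timepoint-by-predictor interactions capturing block-wise connectivity
#' changes, and HRF-convolved motor and feedback regressors. Activation and
#' interaction terms vary by participant; per-subject estimates are partial
#' pooled (group effect plus a shrunken subject deviation).
#'
#' Two engines are available. `"mom"` (default) is a two-stage estimator:
#' per-subject least squares followed by empirical-Bayes shrinkage with
#' DerSimonian-Laird method-of-moments variance components per term - fast,
#' deterministic, and exact in the no-noise and single-subject limits.
#' `"reml"` fits the full linear mixed model with independent (diagonal)
#' random effects by restricted maximum likelihood via \pkg{lme4}, falling
#' back to maximum likelihood if REML does not converge.
#'
#' @param concat Cohort tibble from [concatenate_cohort()] (`participant_id`,
#'   `series` list-column) or a single concatenated tibble for one subject.
#' @param roi_a Dependent ROI (canonically the first of the pair).
#' @param roi_b Predictor ROI.
#' @param design The [task_design()].
#' @param engine `"mom"` or `"reml"`.
#' @param re_terms Terms with participant-level deviations: `"all"`
#'   (activation + interaction) or `"activation"`.
#' @return Object of class `edge_estimates`: list with `roi_a`, `roi_b`,
#'   `fixed` (tibble `term`, `kind`, `timepoint`, `estimate`), `subject`
#'   (tibble `participant_id`, `term`, `kind`, `timepoint`, `ols`, `se`,
#'   `estimate` (partial-pooled), `tau2`), and `diagnostics`.
#' @export
fit_edge_model <- function(concat, roi_a, roi_b, design = task_design(),
                           engine = c("mom", "reml"), re_terms = c("all", "activation")) {
  engine <- match.arg(engine)
  re_terms <- match.arg(re_terms)
  concat <- as_concat_set(concat)
  pre <- precompute_designs(concat, design)
  fit_edge_internal(concat, pre, roi_a, roi_b, engine, re_terms)
}

as_concat_set <- function(concat) {
  if (is.data.frame(concat) && "series" %in% names(concat)) return(concat)
  if (is.data.frame(concat) && "timepoint" %in% names(concat)) {
    return(tibble::tibble(participant_id = "sub-001", series = list(concat)))
  }
  rlang::abort("`concat` must be a concatenate_cohort() result or one concatenated tibble")
}

edge_term_info <- function() {
  tps <- timepoint_labels()
  tibble::tibble(
    term = c(paste0("tp_", tps), paste0("fc_", tps)),
    kind = rep(c("activation", "fc"), each = 17),
    timepoint = rep(tps, 2)
  )
}

# Per-subject shared design pieces: timepoint indicators, intercept, motor
# and feedback regressors, and the ROI signal matrix.
precompute_designs <- function(concat, design) {
  ev <- design$events
  motor_ev <- ev[ev$trial_type == "motor_response", ]
  fb_ev <- ev[ev$trial_type == "verbal_feedback", ]
  tps <- timepoint_labels()
  purrr::map(concat$series, function(s) {
    lab <- s$timepoint
    I17 <- vapply(tps, function(tp) as.numeric(lab == tp), numeric(nrow(s)))
    task_rows <- s$segment == "task"
    task_t <- s$time_s[task_rows] - min(s$time_s[task_rows])
    motor <- feedback <- rep(0, nrow(s))
    motor[task_rows] <- convolve_events(motor_ev$onset_s, motor_ev$duration_s, task_t)
    feedback[task_rows] <- convolve_events(fb_ev$onset_s, fb_ev$duration_s, task_t)
    roi_cols <- setdiff(names(s), c("time_s", "segment", "timepoint"))
    # per-segment linear drift columns: the prep stage detrends each segment,
    # so matching drift terms in the design keep block coefficients unbiased
    segs <- unique(s$segment)
    drift <- vapply(segs, function(sg) {
      v <- rep(0, nrow(s))
      r <- s$segment == sg
      v[r] <- (s$time_s[r] - mean(s$time_s[r])) / diff(range(s$time_s[r]))
      v
    }, numeric(nrow(s)))
    colnames(drift) <- paste0("drift_", segs)
    list(I17 = I17, motor = motor, feedback = feedback, drift = drift,
         Y = as.matrix(s[roi_cols]), rois = roi_cols)
  })
}

fit_edge_internal <- function(concat, pre, roi_a, roi_b, engine, re_terms) {
  info <- edge_term_info()
  n_subj <- nrow(concat)
  abort_if(n_subj < 1, "need at least one subject")

  per_subject <- purrr::map(seq_len(n_subj), function(i) {
    p <- pre[[i]]
    ia <- match(roi_a, p$rois); ib <- match(roi_b, p$rois)
    abort_if(is.na(ia) || is.na(ib),
             sprintf("ROI '%s' or '%s' absent from series", roi_a, roi_b))
    y <- p$Y[, ia]
    x2 <- p$Y[, ib] - mean(p$Y[, ib])
    X <- cbind(1, p$I17, x2, p$I17 * x2, p$motor, p$feedback, p$drift)
    colnames(X) <- c("(Intercept)", paste0("tp_", timepoint_labels()), "x2",
                     paste0("fc_", timepoint_labels()), "motor", "feedback",
                     colnames(p$drift))
    list(X = X, y = y)
  })

  if (engine == "mom") {
    fits <- purrr::map(per_subject, function(d) ols_fit(d$X, d$y))
    B <- t(vapply(fits, function(f) f$coef[info$term], numeric(nrow(info))))
    SE <- t(vapply(fits, function(f) f$se[info$term], numeric(nrow(info))))
    pooled <- pool_mom(B, SE)
    subject <- tidyr::expand_grid(
      participant_id = concat$participant_id, info
    ) |>
      dplyr::arrange(match(.data$participant_id, concat$participant_id))
    subject$ols <- as.vector(t(B))
    subject$se <- as.vector(t(SE))
    subject$estimate <- as.vector(t(pooled$subject))
    subject$tau2 <- rep(pooled$tau2, times = n_subj)
    fixed <- dplyr::mutate(info, estimate = pooled$fixed)
    diagnostics <- tibble::tibble(engine = "mom", converged = TRUE,
                                  n_subjects = n_subj,
                                  note = NA_character_)
  } else {
    res <- fit_edge_reml(concat, per_subject, info, re_terms)
    subject <- res$subject
    fixed <- res$fixed
    diagnostics <- res$diagnostics
  }

  structure(list(roi_a = roi_a, roi_b = roi_b, fixed = fixed,
                 subject = subject, diagnostics = diagnostics),
            class = "edge_estimates")
}

# DerSimonian-Laird partial pooling per term over subjects.
# B, SE: n_subj x n_terms matrices. Returns fixed effects, per-term tau2,
# and the matrix of partial-pooled subject estimates.
pool_mom <- function(B, SE) {
  n <- nrow(B); k <- ncol(B)
  fixed <- numeric(k); tau2 <- numeric(k)
  subject <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    b <- B[, j]; v <- SE[, j]^2
    ok <- !is.na(b) & !is.na(v)
    if (!any(ok)) next
    if (sum(ok) == 1L) {
      fixed[j] <- b[ok]; tau2[j] <- Inf
      subject[, j] <- b
      next
    }
    v <- pmax(v, 1e-12)
    w <- 1 / v[ok]
    bw <- sum(w * b[ok]) / sum(w)
    Q <- sum(w * (b[ok] - bw)^2)
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2[j] <- max(0, (Q - (sum(ok) - 1)) / max(denom, 1e-12))
    w2 <- 1 / (v[ok] + tau2[j])
    fixed[j] <- sum(w2 * b[ok]) / sum(w2)
    shrink <- tau2[j] / (tau2[j] + v)
    subject[, j] <- fixed[j] + shrink * (b - fixed[j])
    subject[!ok, j] <- fixed[j]
  }
  list(fixed = fixed, tau2 = tau2, subject = subject)
}

fit_edge_reml <- function(concat, per_subject, info, re_terms) {
  dat <- purrr::map2_dfr(seq_along(per_subject), concat$participant_id, function(i, id) {
    d <- per_subject[[i]]
    df <- tibble::as_tibble(d$X[, -1, drop = FALSE], .name_repair = "minimal")
    names(df) <- make.names(colnames(d$X)[-1])
    df$y <- d$y
    df$participant_id <- id
    df
  })
  fe_cols <- make.names(colnames(per_subject[[1]]$X)[-1])
  re_cols <- if (re_terms == "all") make.names(info$term) else {
    make.names(info$term[info$kind == "activation"])
  }
  fml <- stats::as.formula(paste(
    "y ~", paste(fe_cols, collapse = " + "),
    "+ (0 +", paste(re_cols, collapse = " + "), "|| participant_id)"
  ))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.nobs.vs.nRE = "ignore")
  note <- NA_character_
  fit <- tryCatch(
    lme4::lmer(fml, data = dat, REML = TRUE, control = ctrl),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    note <- "REML failed; refit with ML"
    fit <- lme4::lmer(fml, data = dat, REML = FALSE, control = ctrl)
  }
  fe <- lme4::fixef(fit)
  names(fe) <- sub("^X", "", names(fe))
  term_map <- stats::setNames(info$term, make.names(info$term))
  fixed <- dplyr::mutate(info, estimate = unname(fe[make.names(info$term)]))
  re <- lme4::ranef(fit)$participant_id
  subject <- tidyr::expand_grid(participant_id = concat$participant_id, info) |>
    dplyr::arrange(match(.data$participant_id, concat$participant_id))
  dev <- matrix(0, nrow(concat), nrow(info),
                dimnames = list(concat$participant_id, info$term))
  for (cn in colnames(re)) {
    tm <- term_map[cn]
    if (!is.na(tm)) dev[rownames(re), tm] <- re[[cn]]
  }
  subject$ols <- NA_real_
  subject$se <- NA_real_
  subject$estimate <- fixed$estimate[match(subject$term, fixed$term)] +
    dev[cbind(subject$participant_id, subject$term)]
  subject$tau2 <- NA_real_
  list(fixed = fixed, subject = subject,
       diagnostics = tibble::tibble(engine = "reml",
                                    converged = length(fit@optinfo$conv$lme4) == 0,
                                    n_subjects = nrow(concat), note = note))
}

#' @export
print.edge_estimates <- function(x, ...) {
  cat(sprintf("<edge_estimates> %s ~ %s, %d subjects (%s engine)\n",
              x$roi_a, x$roi_b,
              dplyr::n_distinct(x$subject$participant_id),
              x$diagnostics$engine[1]))
  invisible(x)
}

#' Fit all edge models of an atlas
#'
#' One hierarchical model per unordered ROI pair in canonical
#' (upper-triangle) order; the first ROI of each pair is the dependent
#' variable. Edge failures are recorded and the pipeline continues.
#'
#' @inheritParams fit_edge_model
#' @param atlas A [roi_atlas()].
#' @param progress Print a progress note every 50 edges?
#' @return List of `edge_estimates` (failed edges carry `NULL` and a
#'   warning summarizes them); attribute `"failed"` lists failed edge ids.
#' @export
fit_all_edges <- function(concat, atlas, design = task_design(),
                          engine = c("mom", "reml"), re_terms = c("all", "activation"),
                          progress = FALSE) {
  engine <- match.arg(engine)
  re_terms <- match.arg(re_terms)
  concat <- as_concat_set(concat)
  pre <- precompute_designs(concat, design)
  edges <- atlas$edges
  out <- vector("list", nrow(edges))
  failed <- integer()
  for (e in seq_len(nrow(edges))) {
    res <- tryCatch(
      fit_edge_internal(concat, pre, edges$roi_a[e], edges$roi_b[e], engine, re_terms),
      error = function(err) NULL
    )
    if (is.null(res)) failed <- c(failed, e) else out[[e]] <- res
    if (progress && e %% 50 == 0) message(sprintf("fitted %d/%d edges", e, nrow(edges)))
  }
  if (length(failed) > 0) {
    rlang::warn(sprintf("%d edge model(s) failed and are excluded from aggregation",
                        length(failed)))
  }
  attr(out, "failed") <- failed
  out
}
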