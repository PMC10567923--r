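#' Positive and negative affect sum scores
#'
#' Sums the 5 positive-scale items (activity, wakefulness, self-certainty,
#' focus, relaxed state; columns `item_01`..`item_05`) and the 10
#' negative-scale items (internal/external agitation, anxiety, sadness,
#' anger, dysphoria, sensitivity, and three somatic items; `item_06`..
#' `item_15`), each rated 1-6. Rows with any missing item get missing
#' scores (such subjects are excluded from affect analyses).
#'
#' @param ratings Tibble: `participant_id`, `timepoint` (T3/T6/T8),
#'   `item_01`..`item_15`.
#' @return Tibble: `participant_id`, `timepoint`, `positive` (5-30),
#'   `negative` (10-60).
#' @export
affect_scores <- function(ratings) {
  items <- sprintf("item_%02d", 1:15)
  abort_if(!all(items %in% names(ratings)), "need item_01..item_15 columns")
  vals <- as.matrix(ratings[items])
  in_range <- is.na(vals) | (vals >= 1 & vals <= 6)
  abort_if(!all(in_range), "item scores must lie in 1..6")
  tibble::tibble(
    participant_id = ratings$participant_id,
    timepoint = ratings$timepoint,
    positive = rowSums(vals[, 1:5, drop = FALSE]),
    negative = rowSums(vals[, 6:15, drop = FALSE])
  )
}

#' Affect change scores relative to the pre-task baseline
#'
#' Deltas at T6 (directly after the task) and T8 (after the 30-min rest)
#' relative to T3 (directly before the task), for both scales. Missing
#' timepoints yield missing deltas.
#'
#' @param scores Output of [affect_scores()].
#' @return Tibble: `participant_id`, `delta_pos_t6`, `delta_pos_t8`,
#'   `delta_neg_t6`, `delta_neg_t8`.
#' @export
affect_deltas <- function(scores) {
  wide <- scores |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "timepoint",
                       values_from = c("positive", "negative"))
  for (col in c("positive_T3", "positive_T6", "positive_T8",
                "negative_T3", "negative_T6", "negative_T8")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  tibble::tibble(
    participant_id = wide$participant_id,
    delta_pos_t6 = wide$positive_T6 - wide$positive_T3,
    delta_pos_t8 = wide$positive_T8 - wide$positive_T3,
    delta_neg_t6 = wide$negative_T6 - wide$negative_T3,
    delta_neg_t8 = wide$negative_T8 - wide$negative_T3
  )
}

#' Endocrine stress response
#'
#' Cortisol change from the pre-task measurement T2 to directly after the
#' task (T6) and after the rest period (T8), in nmol/l.
#'
#' @param series Tibble with columns `participant_id`, `t2`, `t6`, `t8`
#'   (and typically `t0`, `t1`).
#' @return Tibble: `participant_id`, `delta_cort_t6`, `delta_cort_t8`.
#' @export
cortisol_response <- function(series) {
  abort_if(!all(c("t2", "t6", "t8") %in% names(series)),
           "need t2, t6, t8 columns")
  tibble::tibble(
    participant_id = series$participant_id,
    delta_cort_t6 = series$t6 - series$t2,
    delta_cort_t8 = series$t8 - series$t2
  )
}

#' Pre-task cortisol responder classification
#'
#' A participant is a pre-task responder when cortisol at T1 (after
#' catheter placement) exceeds the T0 baseline by strictly more than
#' 2.5 nmol/l. A rise of exactly 2.5 does not classify as responder.
#'
#' @param series Tibble with `participant_id`, `t0`, `t1`.
#' @param threshold Rise threshold in nmol/l.
#' @return Tibble: `participant_id`, `pretask_responder` (NA when T0 or T1
#'   is missing).
#' @export
classify_pre_task_responder <- function(series, threshold = 2.5) {
  abort_if(!all(c("t0", "t1") %in% names(series)), "need t0 and t1 columns")
  tibble::tibble(
    participant_id = series$participant_id,
    pretask_responder = (series$t1 - series$t0) > threshold
  )
}

# Core artifact filter on one ordered IBI vector. Returns a logical keep
# mask. Stage 1 removes implausible durations; stage 2 removes beats whose
# relative deviation from the previous accepted beat, the following beat,
# AND the trailing running mean of accepted beats all exceed the current
# threshold. The threshold adapts to the trailing mean absolute successive
# relative difference of accepted beats (doubled), bounded to
# [initial_threshold, max_threshold].
filter_ibi_vec <- function(x, window = 50L, initial_threshold = 0.13,
                           max_threshold = 0.30, range = c(0.3, 2.4)) {
  keep <- x >= range[1] & x <= range[2]
  idx <- which(keep)
  if (length(idx) < 2) return(keep)
  accepted <- numeric(0)
  thr <- initial_threshold
  for (k in seq_along(idx)) {
    i <- idx[k]
    xi <- x[i]
    dev_prev <- if (length(accepted) > 0) {
      abs(xi - accepted[length(accepted)]) / accepted[length(accepted)]
    } else {
      0
    }
    nxt <- if (k < length(idx)) x[idx[k + 1]] else NA_real_
    dev_next <- if (!is.na(nxt)) abs(xi - nxt) / nxt else 0
    run <- if (length(accepted) > 0) {
      mean(utils::tail(accepted, window))
    } else {
      xi
    }
    dev_run <- abs(xi - run) / run
    if (dev_prev > thr && dev_next > thr && dev_run > thr) {
      keep[i] <- FALSE
    } else {
      accepted <- c(accepted, xi)
      if (length(accepted) >= 2) {
        tailed <- utils::tail(accepted, window)
        msd <- mean(abs(diff(tailed)) / utils::head(tailed, -1))
        thr <- min(max_threshold, max(initial_threshold, 2 * msd))
      }
    }
  }
  keep
}

#' Filter interbeat-interval artifacts
#'
#' Two-stage cleaning of IBI series per participant and block: intervals
#' outside 0.3-2.4 s are removed; an interval is removed when its relative
#' deviation from the previous accepted interval, the following interval,
#' and the trailing running average of (up to) `window` accepted beats all
#' exceed the adaptive threshold, which starts at `initial_threshold` (13%
#' beat-to-beat change) and tracks twice the trailing mean absolute
#' successive relative difference, bounded above at 0.30. The filter is
#' idempotent on its own output.
#'
#' @param series Tibble: `participant_id`, `block_index`, `ibi_s` (ordered
#'   within block).
#' @param window Running-average length in beats.
#' @param initial_threshold Initial relative-deviation threshold.
#' @return The cleaned tibble; attribute `"report"` holds per-block counts
#'   (`n_input`, `n_removed`, `usable` - a block with no surviving beats is
#'   flagged unusable).
#' @export
filter_ibi <- function(series, window = 50L, initial_threshold = 0.13) {
  abort_if(!all(c("participant_id", "block_index", "ibi_s") %in% names(series)),
           "need participant_id, block_index, ibi_s columns")
  abort_if(any(series$ibi_s <= 0), "interbeat intervals must be positive")
  grp <- dplyr::group_by(series, .data$participant_id, .data$block_index)
  keys <- dplyr::group_keys(grp)
  idx_list <- dplyr::group_rows(grp)
  keep <- rep(FALSE, nrow(series))
  report <- purrr::map_dfr(seq_along(idx_list), function(g) {
    rows <- idx_list[[g]]
    k <- filter_ibi_vec(series$ibi_s[rows], window, initial_threshold)
    keep[rows] <<- k
    tibble::tibble(keys[g, ], n_input = length(rows),
                   n_removed = sum(!k), usable = any(k))
  })
  out <- series[keep, , drop = FALSE]
  attr(out, "report") <- report
  out
}

#' Block heart rate and stress contrasts
#'
#' Heart rate per task block as `60 / mean(IBI)` (bpm) from cleaned
#' intervals, and phase contrasts: `delta_hr_stress` = mean HR over the 5
#' Stress blocks (6-10) minus the 5 PreStress blocks (1-5);
#' `delta_hr_poststress` analogously for blocks 11-15. Unusable blocks are
#' excluded from phase means; a phase with no usable block yields a missing
#' contrast.
#'
#' @param cleaned Output of [filter_ibi()] (or any tibble
#'   `participant_id`, `block_index`, `ibi_s`).
#' @return List: `block_hr` (tibble `participant_id`, `block_index`,
#'   `hr_bpm`, `n_beats`) and `deltas` (tibble `participant_id`,
#'   `delta_hr_stress`, `delta_hr_poststress`).
#' @export
block_heart_rate <- function(cleaned) {
  block_hr <- cleaned |>
    dplyr::summarise(hr_bpm = 60 / mean(.data$ibi_s), n_beats = dplyr::n(),
                     .by = c("participant_id", "block_index"))
  phase_mean <- function(df, blocks) {
    x <- df$hr_bpm[df$block_index %in% blocks]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  deltas <- block_hr |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      delta_hr_stress = phase_mean(dplyr::pick(dplyr::everything()), 6:10) -
        phase_mean(dplyr::pick(dplyr::everything()), 1:5),
      delta_hr_poststress = phase_mean(dplyr::pick(dplyr::everything()), 11:15) -
        phase_mean(dplyr::pick(dplyr::everything()), 1:5),
      .groups = "drop"
    )
  list(block_hr = block_hr, deltas = deltas)
}

#' Derive all stress-response variables for a cohort
#'
#' Convenience wrapper over the marker operations: affect deltas, cortisol
#' deltas, responder flags, and heart-rate contrasts, one row per subject.
#'
#' @param affect,cortisol,ibi Raw marker tibbles as produced by
#'   [simulate_biomarkers()] (or read from their TSV interfaces).
#' @return Tibble keyed by `participant_id`.
#' @export
stress_responses <- function(affect, cortisol, ibi) {
  deltas <- affect_deltas(affect_scores(affect))
  cort <- cortisol_response(cortisol)
  resp <- classify_pre_task_responder(cortisol)
  hr <- block_heart_rate(filter_ibi(ibi))$deltas
  deltas |>
    dplyr::full_join(cort, by = "participant_id") |>
    dplyr::full_join(resp, by = "participant_id") |>
    dplyr::full_join(hr, by = "participant_id")
}

#' Association models of stress responses with BMI and sex
#'
#' Per response variable, fits
#' `response ~ bmi * sex + age + diagnosis + pretask_responder`
#' (sex dummy-coded with females as reference) and reports the coefficient
#' table. When all four affect deltas are present, a joint multivariate
#' test (Pillai trace over the stacked responses) for the BMI effect is
#' added.
#'
#' @param responses Tibble `participant_id` + response columns (e.g. from
#'   [stress_responses()]).
#' @param participants Participants tibble (`bmi`, `sex`, `age`,
#'   `diagnosis`, `pretask_responder`).
#' @param response_cols Response columns to model; default all numeric
#'   non-id columns.
#' @return List: `coefficients` (tibble `response`, `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `n`), and `multivariate` (tibble
#'   of Pillai tests for the affect block, or NULL).
#' @export
stress_association_models <- function(responses, participants,
                                      response_cols = NULL) {
  dat <- dplyr::inner_join(
    responses,
    dplyr::select(participants, "participant_id", "bmi", "sex", "age",
                  "diagnosis", "pretask_responder"),
    by = "participant_id",
    suffix = c("", ".participants")
  )
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  if (is.null(response_cols)) {
    response_cols <- setdiff(
      names(responses)[vapply(responses, is.numeric, logical(1))],
      c("participant_id", "bmi", "age")
    )
  }
  coefs <- purrr::map_dfr(response_cols, function(rc) {
    d <- dat[!is.na(dat[[rc]]), , drop = FALSE]
    d$.y <- d[[rc]]
    fit <- stats::lm(.y ~ bmi * sex + age + diagnosis + pretask_responder, data = d)
    if (anyNA(stats::coef(fit))) {
      rlang::warn(sprintf("collinear term(s) dropped for response %s", rc))
    }
    co <- summary(fit)$coefficients
    tibble::tibble(response = rc, term = rownames(co), estimate = co[, 1],
                   std_error = co[, 2], statistic = co[, 3], p_value = co[, 4],
                   n = nrow(d))
  })
  affect_cols <- c("delta_neg_t6", "delta_neg_t8", "delta_pos_t6", "delta_pos_t8")
  multivariate <- NULL
  if (all(affect_cols %in% response_cols)) {
    cc <- stats::complete.cases(dat[c(affect_cols, "bmi", "sex", "age",
                                      "diagnosis", "pretask_responder")])
    d <- dat[cc, , drop = FALSE]
    Y <- as.matrix(d[affect_cols])
    mfit <- stats::lm(Y ~ bmi * sex + age + diagnosis + pretask_responder, data = d)
    av <- stats::anova(mfit, test = "Pillai")
    multivariate <- tibble::tibble(
      term = rownames(av),
      pillai = av[["Pillai"]],
      approx_f = av[["approx F"]],
      p_value = av[["Pr(>F)"]]
    ) |>
      dplyr::filter(!is.na(.data$pillai))
  }
  list(coefficients = coefs, multivariate = multivariate)
}
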