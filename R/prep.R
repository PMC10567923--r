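#' Denoise one segment's ROI timeseries
#'
#' Per ROI, in order: linear detrend (no quadratic term, so slow task-locked
#' patterns with non-stress phases flanking the acute stress are preserved),
#' despiking by winsorizing samples more than `despike_k` robust deviations
#' from an 11-sample running median, projection of nuisance regressors, and
#' demeaning, so each segment leaves with mean zero per ROI.
#'
#' @param series Tibble `time_s` + one numeric column per ROI.
#' @param nuisance Optional data frame of nuisance regressors, one row per
#'   sample (motion, derivatives, physiological components, framewise
#'   displacement). Collinear columns are dropped with a warning.
#' @param despike_k Winsorization threshold in median-absolute-deviation
#'   units of the running-median residual.
#' @param despike_window Running-median window (odd number of samples).
#' @return Tibble of the same shape with denoised signals.
#' @export
preprocess_segment <- function(series, nuisance = NULL, despike_k = 4,
                               despike_window = 11L) {
  abort_if(!"time_s" %in% names(series), "`series` needs a time_s column")
  abort_if(is.unsorted(series$time_s, strictly = TRUE),
           "time must be strictly increasing")
  roi_cols <- setdiff(names(series), "time_s")
  X <- as.matrix(series[roi_cols])
  abort_if(anyNA(X), "missing samples in segment")
  tt <- series$time_s
  n <- length(tt)

  # linear detrend
  X <- residualize(X, tt)

  # despike: winsorize residuals from a running median
  if (despike_k > 0 && n >= 3) {
    w <- min(despike_window, if (n %% 2 == 1) n else n - 1)
    for (j in seq_len(ncol(X))) {
      med <- stats::runmed(X[, j], w, endrule = "median")
      r <- X[, j] - med
      s <- stats::mad(r)
      if (s > 0) {
        X[, j] <- med + pmin(pmax(r, -despike_k * s), despike_k * s)
      }
    }
  }

  if (!is.null(nuisance)) {
    N <- as.matrix(nuisance)
    abort_if(nrow(N) != n, "nuisance rows must match the segment")
    keep <- apply(N, 2, function(x) stats::sd(x) > 0)
    N <- N[, keep, drop = FALSE]
    if (ncol(N) > 0) {
      qr_n <- qr(scale(N))
      if (qr_n$rank < ncol(N)) {
        drop_idx <- qr_n$pivot[-seq_len(qr_n$rank)]
        rlang::warn(sprintf("dropping %d collinear nuisance column(s): %s",
                            length(drop_idx),
                            paste(colnames(N)[drop_idx], collapse = ", ")))
        N <- N[, -drop_idx, drop = FALSE]
      }
      X <- residualize(X, N)
    }
  }

  X <- sweep(X, 2, colMeans(X))
  out <- series
  out[roi_cols] <- X
  out
}

#' Concatenate rest-task-rest segments with baseline offset matching
#'
#' Joins the three denoised segments per subject into one annotated series.
#' Per ROI, the mean over the PreStress fixation samples of the task segment
#' is computed and subtracted from the entire task segment; each flanking
#' resting-state is shifted so its mean equals that (now zero) PreStress
#' fixation mean. Within-segment differences are untouched, so the operation
#' is idempotent.
#'
#' Every sample carries one annotation: `rest1`, `block_01`..`block_15`,
#' `rest2`, or (inside the task segment, excluded from block means)
#' `task_fixation` / `feedback_gap`.
#'
#' @param rest1,task,rest2 Preprocessed segment tibbles (`time_s` + ROI
#'   columns) with identical ROI sets.
#' @param design The [task_design()] describing the task segment.
#' @return Tibble with columns `time_s` (session-cumulative), `segment`,
#'   `timepoint`, plus the ROI columns.
#' @export
match_offsets <- function(rest1, task, rest2, design) {
  roi_cols <- setdiff(names(task), "time_s")
  abort_if(!setequal(roi_cols, setdiff(names(rest1), "time_s")) ||
             !setequal(roi_cols, setdiff(names(rest2), "time_s")),
           "segments must share one ROI set")
  ev <- design$events
  fix <- ev[ev$trial_type == "rest_fixation", ]
  abort_if(nrow(fix) == 0, "design has no fixation blocks")
  first_task <- min(ev$onset_s[ev$trial_type == "prestress_task"])
  last_pre <- max(ev$onset_s[ev$trial_type == "prestress_task"] +
                    ev$duration_s[ev$trial_type == "prestress_task"])
  pre_fix <- fix[fix$onset_s < last_pre, ]
  abort_if(nrow(pre_fix) == 0, "design has no PreStress fixation blocks")

  tt <- task$time_s
  in_fix <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(pre_fix))) {
    in_fix <- in_fix | (tt >= pre_fix$onset_s[i] &
                          tt < pre_fix$onset_s[i] + pre_fix$duration_s[i])
  }
  abort_if(!any(in_fix), "no task samples fall in PreStress fixation blocks")

  task_m <- as.matrix(task[roi_cols])
  offset <- colMeans(task_m[in_fix, , drop = FALSE])
  task_m <- sweep(task_m, 2, offset)
  r1 <- sweep(as.matrix(rest1[roi_cols]), 2, colMeans(as.matrix(rest1[roi_cols])))
  r2 <- sweep(as.matrix(rest2[roi_cols]), 2, colMeans(as.matrix(rest2[roi_cols])))

  lab_task <- label_task_samples(tt, design)
  t1 <- max(rest1$time_s) + diff(rest1$time_s[1:2])
  t2 <- t1 + max(tt) + diff(tt[1:2])
  assemble <- function(times, seg, lab, m) {
    dplyr::bind_cols(
      tibble::tibble(time_s = times, segment = seg, timepoint = lab),
      tibble::as_tibble(m, .name_repair = "minimal")
    )
  }
  out <- dplyr::bind_rows(
    assemble(rest1$time_s, "rest1", "rest1", r1),
    assemble(tt + t1, "task", lab_task, task_m),
    assemble(rest2$time_s + t2, "rest2", "rest2", r2)
  )
  names(out)[-(1:3)] <- roi_cols
  out
}

#' Preprocess and concatenate a whole cohort
#'
#' Runs [preprocess_segment()] and [match_offsets()] per subject. Subjects
#' missing any of the three segments are skipped and listed, mirroring
#' per-analysis exclusion of incomplete data.
#'
#' @param timeseries Nested tibble as produced by [simulate_timeseries()]
#'   (`participant_id`, `segment`, `series` list-column).
#' @param nuisance Optional matching nested tibble of nuisance tables.
#' @param design The [task_design()].
#' @param despike_k Despiking threshold, see [preprocess_segment()].
#' @return List: `data` (tibble `participant_id`, `series` list-column of
#'   concatenated annotated tibbles) and `exclusions` (tibble
#'   `participant_id`, `missing`).
#' @export
concatenate_cohort <- function(timeseries, nuisance = NULL, design = task_design(),
                               despike_k = 4) {
  ids <- unique(timeseries$participant_id)
  if (length(ids) == 0) {
    rlang::warn("empty input: no subjects to concatenate")
    return(list(
      data = tibble::tibble(participant_id = character(), series = list()),
      exclusions = tibble::tibble(participant_id = character(), missing = character())
    ))
  }
  res <- purrr::map(ids, function(id) {
    rows <- timeseries[timeseries$participant_id == id, ]
    have <- rows$segment
    need <- c("rest1", "task", "rest2")
    if (!all(need %in% have)) {
      return(list(excl = paste(setdiff(need, have), collapse = ",")))
    }
    segs <- purrr::map(need, function(sg) {
      s <- rows$series[[which(rows$segment == sg)]]
      nz <- NULL
      if (!is.null(nuisance)) {
        nr <- nuisance[nuisance$participant_id == id & nuisance$segment == sg, ]
        if (nrow(nr) == 1) nz <- nr$data[[1]]
      }
      preprocess_segment(s, nz, despike_k = despike_k)
    })
    list(concat = match_offsets(segs[[1]], segs[[2]], segs[[3]], design))
  })
  excl <- purrr::map_chr(res, function(r) if (is.null(r$concat)) r$excl else NA_character_)
  keep <- is.na(excl)
  if (any(!keep)) {
    rlang::warn(sprintf("skipped %d subject(s) with missing segments", sum(!keep)))
  }
  list(
    data = tibble::tibble(participant_id = ids[keep],
                          series = purrr::map(res[keep], "concat")),
    exclusions = tibble::tibble(participant_id = ids[!keep],
                                missing = excl[!keep])
  )
}
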