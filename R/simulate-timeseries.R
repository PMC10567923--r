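#' Simulate ROI timeseries for a cohort
#'
#' Realizes the latent ground truth as raw per-segment ROI signals: a
#' baseline intensity offset and linear drift per segment, boxcar block
#' activation (group mean plus subject deviation), HRF-convolved motor and
#' feedback responses, edge-wise shared latent signals whose block-wise
#' coupling realizes the subject's connectivity effects, nuisance-component
#' leakage, and white observation noise. Nuisance regressors (six motion
#' parameters, their temporal derivatives, ten physiological components,
#' framewise displacement) are emitted alongside as tables.
#'
#' @param participants Output of [simulate_participants()].
#' @param truth Matching [simulate_ground_truth()] output.
#' @param design A [task_design()].
#' @param spec The [cohort_spec()].
#' @return List with `timeseries` (tibble: `participant_id`, `segment`,
#'   `tr_s`, list-column `series` of tibbles `time_s` + one column per ROI)
#'   and `nuisance` (same shape, list-column `data`).
#' @export
simulate_timeseries <- function(participants, truth, design, spec) {
  abort_if(!inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  rois <- unique(truth$group_activation$roi)
  n_roi <- length(rois)
  missing_subj <- setdiff(participants$participant_id,
                          unique(truth$activation$participant_id))
  abort_if(length(missing_subj) > 0,
           "ground truth does not cover all participants")
  abort_if(max(truth$activation$block_index) > 15,
           "truth block indices exceed the 15-block design")

  segs <- design$segments
  ev <- design$events
  task_blocks <- ev[grepl("task$", ev$trial_type) & !is.na(ev$block_index), ]
  abort_if(nrow(task_blocks) != 15, "design must contain 15 task blocks")

  # shared regressors per segment
  seg_times <- purrr::map(seq_len(nrow(segs)), function(i) {
    (seq_len(segs$volumes[i]) - 1) * segs$tr_s[i]
  })
  names(seg_times) <- segs$segment
  task_t <- seg_times[["task"]]
  boxcars <- vapply(seq_len(15), function(b) {
    as.numeric(task_t >= task_blocks$onset_s[b] &
                 task_t < task_blocks$onset_s[b] + task_blocks$duration_s[b])
  }, numeric(length(task_t)))
  motor_ev <- ev[ev$trial_type == "motor_response", ]
  feedback_ev <- ev[ev$trial_type == "verbal_feedback", ]
  motor_reg <- convolve_events(motor_ev$onset_s, motor_ev$duration_s, task_t)
  feedback_reg <- convolve_events(feedback_ev$onset_s, feedback_ev$duration_s, task_t)

  # per-segment timepoint index (1 = rest1, 2..16 = blocks, 17 = rest2)
  tp_index <- list(
    rest1 = rep(1L, length(seg_times$rest1)),
    task = {
      lab <- label_task_samples(task_t, design)
      idx <- rep(NA_integer_, length(task_t))
      blk <- grepl("^block_", lab)
      idx[blk] <- as.integer(sub("block_", "", lab[blk])) + 1L
      idx
    },
    rest2 = rep(17L, length(seg_times$rest2))
  )

  active_edges <- dplyr::distinct(truth$fc, .data$roi_a, .data$roi_b)
  subj_seeds <- derive_seeds(spec$seed + 2L, nrow(participants))

  sim_one <- function(id, seed) {
    with_seed(seed, {
      amp <- truth$group_activation |>
        dplyr::left_join(
          dplyr::filter(truth$activation, .data$participant_id == id),
          by = c("roi", "block_index")
        ) |>
        dplyr::mutate(total = .data$mean + .data$deviation)
      amp_mat <- matrix(amp$total[order(match(amp$roi, rois), amp$block_index)],
                        nrow = 15, ncol = n_roi)

      fc_s <- dplyr::filter(truth$fc, .data$participant_id == id)
      leak_motion <- matrix(stats::rnorm(6 * n_roi), 6, n_roi)
      leak_comp <- matrix(stats::rnorm(10 * n_roi), 10, n_roi)

      # edge latents span the whole session so couplings act per timepoint
      edge_z <- purrr::map(seq_len(nrow(active_edges)), function(e) {
        lapply(seg_times, function(tt) stats::rnorm(length(tt)))
      })

      series <- list()
      nuis <- list()
      for (i in seq_len(nrow(segs))) {
        sg <- segs$segment[i]
        tt <- seg_times[[sg]]
        T_ <- length(tt)

        motion <- apply(matrix(stats::rnorm(T_ * 6, 0, 0.02), T_, 6), 2, cumsum)
        dmotion <- rbind(0, diff(motion))
        comp <- apply(matrix(stats::rnorm(T_ * 10), T_, 10), 2, function(x) {
          as.numeric(stats::filter(x, 0.9, method = "recursive"))
        })
        fd <- c(0, rowSums(abs(diff(motion))))
        nuis_tbl <- tibble::as_tibble(cbind(motion, dmotion, comp, fd),
                                      .name_repair = "minimal")
        names(nuis_tbl) <- c(paste0("motion_", 1:6), paste0("dmotion_", 1:6),
                             paste0("compcor_", 1:10), "fd")

        sig <- matrix(stats::rnorm(T_ * n_roi, 0, spec$noise_sd), T_, n_roi)
        sig <- sig + spec$baseline_offset +
          matrix(stats::rnorm(n_roi, 0, spec$offset_sd), T_, n_roi, byrow = TRUE)
        if (spec$drift_sd > 0) {
          slopes <- stats::rnorm(n_roi, 0, spec$drift_sd)
          sig <- sig + outer(tt - mean(tt), slopes)
        }
        if (spec$nuisance_leak > 0) {
          sig <- sig + spec$nuisance_leak * (motion %*% leak_motion +
                                               0.3 * comp %*% leak_comp)
        }
        if (sg == "task") {
          sig <- sig + boxcars %*% amp_mat
          sig <- sig + outer(motor_reg, rep(spec$motor_scale, n_roi)) +
            outer(feedback_reg, rep(spec$feedback_scale, n_roi))
        }
        if (nrow(active_edges) > 0 && nrow(fc_s) > 0) {
          tp <- tp_index[[sg]]
          for (e in seq_len(nrow(active_edges))) {
            ia <- match(active_edges$roi_a[e], rois)
            ib <- match(active_edges$roi_b[e], rois)
            if (is.na(ia) || is.na(ib)) next
            z <- edge_z[[e]][[sg]]
            cp <- fc_s |>
              dplyr::filter(.data$roi_a == active_edges$roi_a[e],
                            .data$roi_b == active_edges$roi_b[e])
            cvec <- rep(0, length(z))
            ok <- !is.na(tp)
            cvec[ok] <- cp$coupling[match(tp[ok], cp$timepoint)]
            cvec[is.na(cvec)] <- 0
            sig[, ib] <- sig[, ib] + z
            sig[, ia] <- sig[, ia] + cvec * z
          }
        }
        ts_tbl <- tibble::as_tibble(sig, .name_repair = "minimal")
        names(ts_tbl) <- rois
        series[[sg]] <- dplyr::bind_cols(tibble::tibble(time_s = tt), ts_tbl)
        nuis[[sg]] <- nuis_tbl
      }
      list(series = series, nuisance = nuis)
    })
  }

  out <- purrr::map2(participants$participant_id, subj_seeds, sim_one)
  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    segment = segs$segment
  ) |>
    dplyr::left_join(dplyr::select(segs, "segment", "tr_s"), by = "segment")
  sidx <- match(grid$participant_id, participants$participant_id)
  list(
    timeseries = dplyr::mutate(
      grid,
      series = purrr::map2(sidx, .data$segment, function(i, sg) out[[i]]$series[[sg]])
    ),
    nuisance = dplyr::mutate(
      grid,
      data = purrr::map2(sidx, .data$segment, function(i, sg) out[[i]]$nuisance[[sg]])
    )
  )
}
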