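#' Block design of the psycho-social stress task
#'
#' Builds the three-segment session layout (baseline resting-state, stress
#' task, recovery resting-state) and the task's block structure: 15 task
#' blocks of `block_s` seconds (5 PreStress, 5 Stress, 5 PostStress), each
#' preceded by a fixation block of `fixation_s` seconds, plus auxiliary motor
#' response and verbal feedback events. Defaults reproduce the acquisition
#' layout of the study design (155 resting volumes at TR 2.5 s flanking 755
#' task volumes at TR 2 s); passing shorter blocks yields a scaled design
#' with identical structure for simulation studies.
#'
#' @param block_s Task block duration in seconds.
#' @param fixation_s Fixation (rest) block duration in seconds.
#' @param tail_s Trailing fixation after the last block, seconds.
#' @param tr_task Repetition time of the task segment, seconds.
#' @param tr_rest Repetition time of the resting segments, seconds.
#' @param rest_volumes Number of volumes per resting segment.
#' @return Object of class `task_design`: list with tibbles `segments`
#'   (`segment`, `tr_s`, `volumes`) and `events` (`onset_s`, `duration_s`,
#'   `trial_type`, `block_index`). Onsets are relative to task segment start.
#' @examples
#' d <- task_design()
#' subset(d$events, trial_type == "stress_task")
#' @export
task_design <- function(block_s = 60, fixation_s = 40, tail_s = 10,
                        tr_task = 2, tr_rest = 2.5, rest_volumes = 155) {
  abort_if(block_s <= 0 || fixation_s <= 0 || tail_s < 0, "durations must be positive")
  task_dur <- 15 * (block_s + fixation_s) + tail_s
  task_volumes <- task_dur / tr_task
  abort_if(abs(task_volumes - round(task_volumes)) > 1e-9,
           "task duration must be a whole number of volumes")
  task_volumes <- as.integer(round(task_volumes))

  segments <- tibble::tibble(
    segment = c("rest1", "task", "rest2"),
    tr_s = c(tr_rest, tr_task, tr_rest),
    volumes = c(rest_volumes, task_volumes, rest_volumes)
  )

  phase <- rep(c("prestress_task", "stress_task", "poststress_task"), each = 5)
  cycle_start <- (seq_len(15) - 1) * (block_s + fixation_s)
  blocks <- dplyr::bind_rows(
    tibble::tibble(
      onset_s = cycle_start, duration_s = fixation_s,
      trial_type = "rest_fixation", block_index = NA_integer_
    ),
    tibble::tibble(
      onset_s = cycle_start + fixation_s, duration_s = block_s,
      trial_type = phase, block_index = seq_len(15)
    ),
    tibble::tibble(
      onset_s = 15 * (block_s + fixation_s), duration_s = tail_s,
      trial_type = "rest_fixation", block_index = NA_integer_
    )
  )

  # motor responses: one short press per arithmetic trial inside task blocks
  press_gap <- max(block_s / 10, 2)
  motor <- purrr::map_dfr(seq_len(15), function(b) {
    on <- cycle_start[b] + fixation_s + seq(press_gap / 2, block_s - 1, by = press_gap)
    tibble::tibble(onset_s = on, duration_s = 0.5,
                   trial_type = "motor_response", block_index = b)
  })
  # verbal feedback delivered right after each Stress block
  fb_dur <- min(6, fixation_s * 0.75)
  feedback <- tibble::tibble(
    onset_s = cycle_start[6:10] + fixation_s + block_s + 1,
    duration_s = fb_dur,
    trial_type = "verbal_feedback",
    block_index = 6:10
  )

  events <- dplyr::arrange(
    dplyr::bind_rows(blocks, motor, feedback),
    .data$onset_s, .data$trial_type
  )
  abort_if(any(events$onset_s + events$duration_s > task_dur + 1e-9),
           "events exceed task segment bounds")
  structure(list(segments = segments, events = events), class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  dur <- sum(x$segments$tr_s * x$segments$volumes)
  cat(sprintf("<task_design> %d segments, %d task blocks, %.0f s total\n",
              nrow(x$segments), sum(!is.na(x$events$block_index) &
                                      grepl("task$", x$events$trial_type)), dur))
  invisible(x)
}

# The 17 concatenated timepoint labels: baseline rest, 15 task blocks,
# recovery rest.
timepoint_labels <- function() {
  c("rest1", sprintf("block_%02d", 1:15), "rest2")
}

block_phase <- function(block_index) {
  c(rep("PreStress", 5), rep("Stress", 5), rep("PostStress", 5))[block_index]
}

# Canonical double-gamma haemodynamic response function (peak 6 s,
# undershoot 16 s, ratio 1/6), unit peak-normalized.
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# Convolve a set of events with the HRF and sample at volume times.
# Returns a numeric vector of length(times).
convolve_events <- function(onsets, durations, times, dt = 0.1) {
  if (length(onsets) == 0) return(rep(0, length(times)))
  t_max <- max(times) + 32
  grid <- seq(0, t_max, by = dt)
  box <- rep(0, length(grid))
  for (i in seq_along(onsets)) {
    box[grid >= onsets[i] & grid < onsets[i] + durations[i]] <- 1
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  stats::approx(grid, conv, xout = times, rule = 2)$y
}

# Map task-segment sample times to block labels. Samples inside a task block
# get its label; samples inside a verbal feedback event get "feedback_gap";
# remaining fixation samples get "task_fixation".
label_task_samples <- function(times, design) {
  ev <- design$events
  lab <- rep("task_fixation", length(times))
  fb <- ev[ev$trial_type == "verbal_feedback", ]
  for (i in seq_len(nrow(fb))) {
    lab[times >= fb$onset_s[i] & times < fb$onset_s[i] + fb$duration_s[i]] <- "feedback_gap"
  }
  tb <- ev[grepl("task$", ev$trial_type) & !is.na(ev$block_index), ]
  for (i in seq_len(nrow(tb))) {
    sel <- times >= tb$onset_s[i] & times < tb$onset_s[i] + tb$duration_s[i]
    lab[sel] <- sprintf("block_%02d", tb$block_index[i])
  }
  lab
}
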