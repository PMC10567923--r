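# Plain-text interfaces: TSV tables plus key-value sidecars.

#' Write one segment's timeseries with a metadata sidecar
#'
#' @param series Tibble `time_s` + ROI columns.
#' @param path Output TSV path; the sidecar is written next to it with
#'   extension `.meta.tsv`.
#' @param metadata Named list/vector of key-value pairs (e.g. `segment`,
#'   `repetition_time_s`).
#' @return `path`, invisibly.
#' @export
write_segment_tsv <- function(series, path, metadata = list()) {
  readr::write_tsv(series, path, progress = FALSE)
  meta <- vapply(metadata, as.character, character(1))
  writeLines(paste(names(meta), meta, sep = "\t"),
             sub("\\.tsv$", ".meta.tsv", path))
  invisible(path)
}

#' @rdname write_segment_tsv
#' @export
read_segment_tsv <- function(path) {
  series <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                            progress = FALSE)
  meta_path <- sub("\\.tsv$", ".meta.tsv", path)
  meta <- list()
  if (file.exists(meta_path)) {
    lines <- strsplit(readLines(meta_path), "\t")
    meta <- stats::setNames(lapply(lines, `[`, 2), vapply(lines, `[`, "", 1))
  }
  attr(series, "metadata") <- meta
  series
}

#' Write a simulated cohort to a directory
#'
#' Materializes the external interface of the generator: participants,
#' per-subject-segment timeseries TSVs with sidecars, events, nuisance
#' tables, and all marker tables.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "nuisance"), showWarnings = FALSE)
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"),
                   progress = FALSE)
  ev <- cohort$design$events
  readr::write_tsv(
    tibble::tibble(onset = ev$onset_s, duration = ev$duration_s,
                   trial_type = ev$trial_type, block_index = ev$block_index),
    file.path(dir, "events.tsv"), progress = FALSE
  )
  for (i in seq_len(nrow(cohort$timeseries))) {
    row <- cohort$timeseries[i, ]
    fn <- sprintf("%s_%s.tsv", row$participant_id, row$segment)
    write_segment_tsv(row$series[[1]], file.path(dir, "timeseries", fn),
                      list(participant_id = row$participant_id,
                           segment = row$segment,
                           repetition_time_s = row$tr_s))
    nrow_ <- cohort$nuisance[cohort$nuisance$participant_id == row$participant_id &
                               cohort$nuisance$segment == row$segment, ]
    readr::write_tsv(nrow_$data[[1]], file.path(dir, "nuisance", fn),
                     progress = FALSE)
  }
  bio <- cohort$biomarkers
  readr::write_tsv(bio$cytokines, file.path(dir, "cytokines.tsv"), progress = FALSE)
  readr::write_tsv(bio$detection_limits, file.path(dir, "detection_limits.tsv"),
                   progress = FALSE)
  readr::write_tsv(bio$baseline_cortisol, file.path(dir, "baseline_cortisol.tsv"),
                   progress = FALSE)
  readr::write_tsv(bio$cortisol, file.path(dir, "cortisol.tsv"), progress = FALSE)
  readr::write_tsv(bio$affect, file.path(dir, "affect.tsv"), progress = FALSE)
  readr::write_tsv(bio$ibi, file.path(dir, "ibi.tsv"), progress = FALSE)
  export_ground_truth(cohort$truth, file.path(dir, "ground_truth"))
  invisible(dir)
}

#' Read cohort timeseries back from a directory
#'
#' Restores the nested timeseries/nuisance tibbles written by
#' [write_cohort()], ready for [concatenate_cohort()].
#'
#' @param dir Cohort directory.
#' @return List: `timeseries`, `nuisance` (nested tibbles).
#' @export
read_cohort_timeseries <- function(dir) {
  files <- list.files(file.path(dir, "timeseries"), pattern = "\\.tsv$",
                      full.names = TRUE)
  files <- files[!grepl("\\.meta\\.tsv$", files)]
  rows <- purrr::map_dfr(files, function(f) {
    s <- read_segment_tsv(f)
    meta <- attr(s, "metadata")
    nf <- file.path(dir, "nuisance", basename(f))
    tibble::tibble(
      participant_id = meta$participant_id,
      segment = meta$segment,
      tr_s = as.numeric(meta$repetition_time_s),
      series = list(s),
      nuisance = list(if (file.exists(nf)) {
        readr::read_tsv(nf, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
      } else {
        NULL
      })
    )
  })
  list(
    timeseries = dplyr::select(rows, "participant_id", "segment", "tr_s", "series"),
    nuisance = rows |>
      dplyr::select("participant_id", "segment", data = "nuisance")
  )
}
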