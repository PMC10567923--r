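#' Simulate latent ground truth for a cohort
#'
#' Draws the per-subject latent block-activation deviations and block-wise
#' connectivity couplings that the timeseries generator realizes and that
#' recovery experiments compare estimates against. Planted effects load on
#' the subject's brain-linked latent score (females only under
#' `female_specific`); non-outcome-related heterogeneity is added with SD
#' `spec$subject_sd`.
#'
#' @param participants Output of [simulate_participants()].
#' @param atlas A [roi_atlas()].
#' @param design A [task_design()].
#' @param spec The [cohort_spec()] used for the participants.
#' @param group_profile Group-mean activation per phase (PreStress, Stress,
#'   PostStress), signal units.
#' @return Object of class `ground_truth`: list with tibbles
#'   `group_activation` (`roi`, `block_index`, `mean`), `activation`
#'   (`participant_id`, `roi`, `block_index`, `deviation`), `fc`
#'   (`participant_id`, `roi_a`, `roi_b`, `timepoint`, `coupling`; only
#'   edges carrying any coupling), and the planted effect tables.
#' @export
simulate_ground_truth <- function(participants, atlas, design, spec,
                                  group_profile = c(0.4, 1.0, 0.6)) {
  abort_if(!inherits(atlas, "roi_atlas"), "`atlas` must be a roi_atlas")
  abort_if(!inherits(design, "task_design"), "`design` must be a task_design")
  eff <- spec$effect_activation
  unknown <- setdiff(eff$region, atlas$rois$region)
  # planted regions absent from a reduced atlas are silently dropped so the
  # same spec works across atlas sizes
  eff <- dplyr::filter(eff, !.data$region %in% unknown)
  lat <- cohort_latents(participants)

  grid <- tidyr::expand_grid(roi = atlas$rois$roi, block_index = 1:15)
  group_activation <- grid |>
    dplyr::mutate(mean = group_profile[ceiling(.data$block_index / 5)])

  with_seed(spec$seed + 1L, {
    act <- tidyr::expand_grid(participant_id = participants$participant_id, grid) |>
      dplyr::left_join(
        dplyr::select(atlas$rois, "roi", "region"), by = "roi"
      ) |>
      dplyr::left_join(
        dplyr::rename(eff, planted = "effect"),
        by = c("region", "block_index")
      ) |>
      dplyr::left_join(
        dplyr::select(participants, "participant_id", "sex"), by = "participant_id"
      ) |>
      dplyr::left_join(lat, by = "participant_id") |>
      dplyr::mutate(
        planted = tidyr::replace_na(.data$planted, 0),
        active = .data$sex == "female" | !spec$female_specific,
        deviation = .data$planted * .data$brain_score * .data$active +
          stats::rnorm(dplyr::n(), 0, spec$subject_sd)
      ) |>
      dplyr::select("participant_id", "roi", "block_index", "deviation")

    fc_eff <- spec$effect_fc
    fc <- if (nrow(fc_eff) == 0) {
      tibble::tibble(participant_id = character(), roi_a = character(),
                     roi_b = character(), timepoint = integer(),
                     coupling = double())
    } else {
      tidyr::expand_grid(
        participant_id = participants$participant_id,
        dplyr::distinct(fc_eff, .data$roi_a, .data$roi_b) |>
          tidyr::expand_grid(timepoint = 1:17)
      ) |>
        dplyr::left_join(fc_eff, by = c("roi_a", "roi_b", "timepoint")) |>
        dplyr::left_join(
          dplyr::select(participants, "participant_id", "sex"),
          by = "participant_id"
        ) |>
        dplyr::left_join(lat, by = "participant_id") |>
        dplyr::mutate(
          effect = tidyr::replace_na(.data$effect, 0),
          active = .data$sex == "female" | !spec$female_specific,
          coupling = .data$effect * .data$brain_score * .data$active +
            stats::rnorm(dplyr::n(), 0, spec$subject_sd / 3)
        ) |>
        dplyr::select("participant_id", "roi_a", "roi_b", "timepoint", "coupling")
    }

    structure(list(
      group_activation = group_activation,
      activation = act,
      fc = fc,
      effect_activation = eff,
      effect_fc = fc_eff,
      marker_pathways = NULL,
      seed = spec$seed
    ), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d subjects, %d activation cells, %d fc cells\n",
              dplyr::n_distinct(x$activation$participant_id),
              nrow(x$activation), nrow(x$fc)))
  invisible(x)
}

#' Aggregate latent ground truth to the feature grid
#'
#' Computes the noise-free feature matrix implied by the latent truth:
#' activation deviations averaged over the ROIs of each anatomical region
#' for all 15 blocks, and couplings averaged over each subnetwork's edges
#' for all 17 timepoints. Used as the recovery oracle and by
#' [simulate_feature_cohort()].
#'
#' @param truth A `ground_truth`.
#' @param atlas The matching `roi_atlas`.
#' @return Tibble: `participant_id` plus `act_<region>_b<block>` and
#'   `fc_net<k>_t<timepoint>` columns.
#' @export
truth_features <- function(truth, atlas) {
  act <- truth$activation |>
    dplyr::left_join(dplyr::select(atlas$rois, "roi", "region"), by = "roi") |>
    dplyr::summarise(value = mean(.data$deviation),
                     .by = c("participant_id", "region", "block_index")) |>
    dplyr::mutate(feature = sprintf("act_%s_b%02d", .data$region, .data$block_index))

  subj <- dplyr::distinct(truth$activation, .data$participant_id)
  nets <- sort(unique(atlas$edges$subnetwork))
  fc_grid <- tidyr::expand_grid(participant_id = subj$participant_id,
                                subnetwork = nets, timepoint = 1:17)
  fc_vals <- if (nrow(truth$fc) == 0) {
    dplyr::mutate(fc_grid, value = 0)
  } else {
    edge_net <- dplyr::select(atlas$edges, "roi_a", "roi_b", "subnetwork")
    n_edges <- dplyr::count(edge_net, .data$subnetwork, name = "n_edges")
    truth$fc |>
      dplyr::left_join(edge_net, by = c("roi_a", "roi_b")) |>
      dplyr::summarise(total = sum(.data$coupling),
                       .by = c("participant_id", "subnetwork", "timepoint")) |>
      dplyr::right_join(fc_grid, by = c("participant_id", "subnetwork", "timepoint")) |>
      dplyr::left_join(n_edges, by = "subnetwork") |>
      dplyr::mutate(value = tidyr::replace_na(.data$total, 0) / .data$n_edges) |>
      dplyr::select("participant_id", "subnetwork", "timepoint", "value")
  }
  fc_vals <- dplyr::mutate(
    fc_vals, feature = sprintf("fc_net%d_t%02d", .data$subnetwork, .data$timepoint)
  )

  feats <- dplyr::bind_rows(
    dplyr::select(act, "participant_id", "feature", "value"),
    dplyr::select(fc_vals, "participant_id", "feature", "value")
  )
  tidyr::pivot_wider(feats, id_cols = "participant_id",
                     names_from = "feature", values_from = "value")
}

#' Write ground truth to plain-text files
#'
#' Serializes every table of a `ground_truth` as TSV plus a key-value
#' metadata sidecar; [read_ground_truth()] restores an equal structure.
#'
#' @param truth A `ground_truth`.
#' @param path Directory (created if missing).
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(truth, path) {
  abort_if(!inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(path), sprintf("cannot create directory '%s'", path))
  readr::write_tsv(truth$group_activation, file.path(path, "group_activation.tsv"))
  readr::write_tsv(truth$activation, file.path(path, "activation.tsv"))
  readr::write_tsv(truth$fc, file.path(path, "fc.tsv"))
  readr::write_tsv(truth$effect_activation, file.path(path, "effect_activation.tsv"))
  readr::write_tsv(truth$effect_fc, file.path(path, "effect_fc.tsv"))
  if (!is.null(truth$marker_pathways)) {
    readr::write_tsv(truth$marker_pathways, file.path(path, "marker_pathways.tsv"))
  }
  writeLines(c(sprintf("seed\t%d", truth$seed),
               sprintf("exported_rows\t%d", nrow(truth$activation))),
             file.path(path, "metadata.tsv"))
  invisible(path)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(path) {
  rd <- function(f, types) {
    readr::read_tsv(file.path(path, f), col_types = types, progress = FALSE)
  }
  meta <- utils::read.delim(file.path(path, "metadata.tsv"), header = FALSE)
  mp_file <- file.path(path, "marker_pathways.tsv")
  structure(list(
    group_activation = rd("group_activation.tsv", "cid"),
    activation = rd("activation.tsv", "ccid"),
    fc = rd("fc.tsv", "cccid"),
    effect_activation = rd("effect_activation.tsv", "cid"),
    effect_fc = rd("effect_fc.tsv", "ccid"),
    marker_pathways = if (file.exists(mp_file)) {
      readr::read_tsv(mp_file, col_types = "cc", progress = FALSE)
    } else {
      NULL
    },
    seed = as.integer(meta$V2[meta$V1 == "seed"])
  ), class = "ground_truth")
}
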