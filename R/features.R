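#' Aggregate per-edge activation estimates to region-by-block features
#'
#' For each ROI, averages the per-subject block-activation estimates across
#' all edge models in which that ROI is the dependent variable, then
#' averages the left/right members of each bilateral pair, yielding one
#' feature per anatomical region and task block (12 x 15 = 180 for the full
#' atlas). Only the 15 task blocks feed activation features; the flanking
#' resting-state coefficients serve as reference levels in the edge models.
#'
#' @param edges List of `edge_estimates` from [fit_all_edges()].
#' @param atlas The matching [roi_atlas()].
#' @return Tibble: `participant_id` plus `act_<region>_b<block>` columns.
#' @export
aggregate_activation <- function(edges, atlas) {
  edges <- purrr::compact(edges)
  abort_if(length(edges) == 0, "no edge estimates to aggregate")
  per_edge <- purrr::map_dfr(edges, function(e) {
    e$subject |>
      dplyr::filter(.data$kind == "activation",
                    startsWith(.data$timepoint, "block_")) |>
      dplyr::mutate(roi = e$roi_a,
                    block_index = as.integer(sub("block_", "", .data$timepoint))) |>
      dplyr::select("participant_id", "roi", "block_index", "estimate")
  })
  roi_level <- per_edge |>
    dplyr::summarise(estimate = mean(.data$estimate),
                     .by = c("participant_id", "roi", "block_index"))
  covered <- unique(roi_level$roi)
  region_map <- dplyr::select(atlas$rois, "roi", "region")
  uncovered_regions <- region_map |>
    dplyr::summarise(any_cov = any(.data$roi %in% covered), .by = "region") |>
    dplyr::filter(!.data$any_cov)
  abort_if(nrow(uncovered_regions) > 0,
           sprintf("region(s) with no dependent-role model: %s",
                   paste(uncovered_regions$region, collapse = ", ")))
  roi_level |>
    dplyr::left_join(region_map, by = "roi") |>
    dplyr::summarise(value = mean(.data$estimate),
                     .by = c("participant_id", "region", "block_index")) |>
    dplyr::mutate(feature = sprintf("act_%s_b%02d", .data$region, .data$block_index)) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "feature",
                       values_from = "value")
}

#' Aggregate per-edge connectivity estimates to subnetwork trajectories
#'
#' Averages each subject's timepoint-connectivity estimates within each
#' subnetwork across its member edges, for all 17 timepoints (4 x 17 = 68
#' features for the standard four-subnetwork map).
#'
#' @inheritParams aggregate_activation
#' @return Tibble: `participant_id` plus `fc_net<k>_t<timepoint>` columns.
#' @export
aggregate_connectivity <- function(edges, atlas) {
  edges <- purrr::compact(edges)
  abort_if(length(edges) == 0, "no edge estimates to aggregate")
  net_map <- dplyr::select(atlas$edges, "roi_a", "roi_b", "subnetwork")
  per_edge <- purrr::map_dfr(edges, function(e) {
    e$subject |>
      dplyr::filter(.data$kind == "fc") |>
      dplyr::mutate(roi_a = e$roi_a, roi_b = e$roi_b) |>
      dplyr::select("participant_id", "roi_a", "roi_b", "timepoint", "estimate")
  }) |>
    dplyr::left_join(net_map, by = c("roi_a", "roi_b"))
  empty <- setdiff(unique(atlas$edges$subnetwork), unique(per_edge$subnetwork))
  abort_if(length(empty) > 0,
           sprintf("subnetwork(s) with no fitted edges: %s",
                   paste(empty, collapse = ", ")))
  tps <- timepoint_labels()
  out <- per_edge |>
    dplyr::summarise(value = mean(.data$estimate),
                     .by = c("participant_id", "subnetwork", "timepoint")) |>
    dplyr::mutate(feature = sprintf("fc_net%d_t%02d", .data$subnetwork,
                                    match(.data$timepoint, tps))) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "feature",
                       values_from = "value")
  out[, c("participant_id", sort(setdiff(names(out), "participant_id")))]
}

#' Assemble the prediction feature matrix
#'
#' Column-concatenates the activation and connectivity blocks according to
#' `mode`; for the full 21-ROI atlas this yields 180 (`"activation"`), 68
#' (`"fc"`), or 248 (`"combined"`) features.
#'
#' @param activation Output of [aggregate_activation()].
#' @param fc Output of [aggregate_connectivity()].
#' @param mode Feature set to return.
#' @return Tibble `participant_id` + labeled feature columns.
#' @export
assemble_feature_matrix <- function(activation, fc,
                                    mode = c("combined", "activation", "fc")) {
  mode <- match.arg(mode)
  if (mode == "activation") return(activation)
  if (mode == "fc") return(fc)
  abort_if(!identical(sort(activation$participant_id), sort(fc$participant_id)),
           "activation and fc blocks cover different subjects")
  dplyr::inner_join(activation, fc, by = "participant_id")
}

#' Parse feature labels
#'
#' Maps each feature column back to its (kind, region-or-subnetwork,
#' timepoint) triple.
#'
#' @param features A feature tibble (with `participant_id` column) or a
#'   character vector of feature names.
#' @return Tibble: `feature`, `kind`, `unit`, `timepoint`.
#' @export
feature_labels <- function(features) {
  nm <- if (is.character(features)) features else {
    setdiff(names(features), "participant_id")
  }
  tps <- timepoint_labels()
  tibble::tibble(feature = nm) |>
    dplyr::mutate(
      kind = dplyr::case_when(
        startsWith(.data$feature, "act_") ~ "activation",
        startsWith(.data$feature, "fc_") ~ "fc",
        TRUE ~ NA_character_
      ),
      unit = dplyr::case_when(
        .data$kind == "activation" ~ sub("^act_(.*)_b\\d+$", "\\1", .data$feature),
        .data$kind == "fc" ~ sub("^fc_(net\\d+)_t\\d+$", "\\1", .data$feature)
      ),
      timepoint = dplyr::case_when(
        .data$kind == "activation" ~ sprintf("block_%s", sub(".*_b(\\d+)$", "\\1", .data$feature)),
        .data$kind == "fc" ~
          tps[suppressWarnings(as.integer(sub(".*_t(\\d+)$", "\\1", .data$feature)))]
      )
    )
}

#' Build feature matrices straight from concatenated timeseries
#'
#' Convenience wrapper: fits all edge models and aggregates both blocks.
#'
#' @inheritParams fit_all_edges
#' @param mode Feature set to return.
#' @return Tibble `participant_id` + feature columns.
#' @export
trajectory_features <- function(concat, atlas, design = task_design(),
                                mode = c("combined", "activation", "fc"),
                                engine = c("mom", "reml")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  edges <- fit_all_edges(concat, atlas, design, engine = engine)
  act <- if (mode != "fc") aggregate_activation(edges, atlas) else NULL
  fcm <- if (mode != "activation") aggregate_connectivity(edges, atlas) else NULL
  switch(mode,
    activation = act,
    fc = fcm,
    combined = assemble_feature_matrix(act, fcm, "combined")
  )
}
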