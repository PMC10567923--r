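#' Simulate peripheral and behavioural stress markers
#'
#' Generates, per participant: a multiplex cytokine panel (log-normal
#' concentrations, assay batch effects, completely-at-random missingness,
#' detection limits at the generator's 2.5th/97.5th percentiles), baseline
#' plasma cortisol negatively correlated with BMI, a salivary cortisol
#' series (T0, T1, T2, T6, T8) with a stress bump and a pre-task rise for
#' catheter responders, 15-item affect ratings at T3/T6/T8 with a planted
#' BMI-scaled negative-affect response, and per-block interbeat-interval
#' series with injected artifacts.
#'
#' Markers with a non-zero target BMI correlation split into two pathways:
#' `brain_mediated` markers load on the brain-linked latent score (the same
#' score that drives the planted trajectory features), `independent` markers
#' on the residual score. The pathway labels are returned for attribution
#' experiments.
#'
#' @param participants Output of [simulate_participants()].
#' @param truth Optional `ground_truth`; when supplied, pathway labels are
#'   attached to it (returned as `truth`).
#' @param spec The [cohort_spec()].
#' @return List of tibbles: `cytokines` (`participant_id`, `batch`, one
#'   column per marker, NA = missing), `detection_limits` (`marker`,
#'   `lower`, `upper`), `baseline_cortisol`, `cortisol` (saliva, nmol/l),
#'   `affect` (`participant_id`, `timepoint`, `item_01`..`item_15`; items
#'   1-5 positive scale, 6-15 negative scale), `ibi` (`participant_id`,
#'   `block_index`, `beat`, `ibi_s`), `marker_pathways`, and `truth`.
#' @export
simulate_biomarkers <- function(participants, truth = NULL, spec) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  lat <- cohort_latents(participants)
  n <- nrow(participants)
  with_seed(spec$seed + 3L, {
    markers <- sprintf("cyt_%02d", seq_len(spec$n_cytokines))
    rho <- spec$cytokine_bmi_corr
    sig_idx <- which(rho != 0)
    pathway <- rep("null", spec$n_cytokines)
    if (length(sig_idx) > 0) {
      half <- ceiling(length(sig_idx) / 2)
      pathway[sig_idx[seq_len(half)]] <- "brain_mediated"
      pathway[sig_idx[-seq_len(half)]] <- "independent"
    }
    pathways <- tibble::tibble(marker = markers, pathway = pathway)

    batch <- sample(seq_len(spec$n_batches), n, replace = TRUE)
    batch_offset <- stats::rnorm(spec$n_batches, 0, 0.3)

    cyt_z <- vapply(seq_len(spec$n_cytokines), function(m) {
      score <- switch(pathway[m],
        brain_mediated = lat$brain_score,
        independent = lat$resid_score,
        rep(0, n)
      )
      share <- switch(pathway[m],
        brain_mediated = spec$bmi_brain_share,
        independent = spec$bmi_resid_share,
        1
      )
      load <- min(abs(rho[m]) / max(sqrt(share), 1e-9), 0.95) * sign(rho[m])
      load * score + sqrt(1 - load^2) * stats::rnorm(n)
    }, numeric(n))

    mu <- stats::runif(spec$n_cytokines, 0, 3)
    sg <- stats::runif(spec$n_cytokines, 0.4, 0.9)
    conc <- exp(sweep(sweep(cyt_z, 2, sg, `*`), 2, mu, `+`) + batch_offset[batch])
    limits <- tibble::tibble(
      marker = markers,
      lower = exp(mu + stats::qnorm(0.025) * sg),
      upper = exp(mu + stats::qnorm(0.975) * sg)
    )
    conc[stats::runif(length(conc)) < spec$missing_rate] <- NA
    cytokines <- dplyr::bind_cols(
      tibble::tibble(participant_id = participants$participant_id, batch = batch),
      tibble::as_tibble(stats::setNames(as.data.frame(conc), markers))
    )

    rho_c <- spec$cortisol_bmi_corr
    baseline_cortisol <- tibble::tibble(
      participant_id = participants$participant_id,
      cortisol_baseline = 400 + 80 * (rho_c * lat$bmi_z +
                                        sqrt(1 - rho_c^2) * stats::rnorm(n))
    )

    # salivary cortisol: pre-task responders rise > 2.5 nmol/l from T0 to T1
    t0 <- exp(stats::rnorm(n, log(5), 0.35))
    rise <- ifelse(participants$pretask_responder,
                   2.6 + stats::rexp(n, 1.5),
                   stats::runif(n, -1.2, 2.3))
    t1 <- pmax(t0 + rise, 0.5)
    t2 <- pmax(t0 + stats::rnorm(n, 0, 0.6), 0.5)
    bump <- 2.5 + stats::rexp(n, 0.8)
    t6 <- pmax(t2 + bump * ifelse(participants$pretask_responder, 0.4, 1) +
                 stats::rnorm(n, 0, 0.8), 0.5)
    t8 <- pmax(t2 + 0.3 * bump + stats::rnorm(n, 0, 0.8), 0.5)
    cortisol <- tibble::tibble(
      participant_id = participants$participant_id,
      t0 = t0, t1 = t1, t2 = t2, t6 = t6, t8 = t8
    )

    active <- participants$sex == "female" | !spec$female_specific
    affect <- purrr::map_dfr(c("T3", "T6", "T8"), function(tp) {
      pos_f <- switch(tp, T3 = 0, T6 = -0.9, T8 = -0.35) + stats::rnorm(n, 0, 0.5)
      neg_f <- switch(tp, T3 = 0,
                      T6 = 1.1 + 0.35 * lat$bmi_z * active,
                      T8 = -0.25 + 0.20 * lat$bmi_z * active) +
        stats::rnorm(n, 0, 0.5)
      pos_base <- switch(tp, T3 = 4.1, T6 = 3.4, T8 = 3.8)
      neg_base <- switch(tp, T3 = 1.9, T6 = 2.9, T8 = 1.7)
      items <- vapply(1:15, function(it) {
        if (it <= 5) {
          raw <- pos_base + 0.6 * pos_f + stats::rnorm(n, 0, 0.8)
        } else {
          raw <- neg_base + 0.6 * neg_f + stats::rnorm(n, 0, 0.8)
        }
        pmin(pmax(round(raw), 1), 6)
      }, numeric(n))
      dplyr::bind_cols(
        tibble::tibble(participant_id = participants$participant_id, timepoint = tp),
        tibble::as_tibble(stats::setNames(as.data.frame(items),
                                          sprintf("item_%02d", 1:15)))
      )
    })

    hr_base <- stats::rnorm(n, 70, 7)
    ibi <- purrr::map_dfr(seq_len(n), function(i) {
      purrr::map_dfr(1:15, function(b) {
        hr <- hr_base[i] + c(rep(0, 5), rep(6.7, 5), rep(0.9, 5))[b]
        mean_ibi <- 60 / hr
        n_beats <- max(round(60 / mean_ibi), 10)
        x <- stats::rnorm(n_beats, mean_ibi, 0.04)
        art <- stats::runif(n_beats) < 0.02
        x[art] <- x[art] * sample(c(0.3, 2.2), sum(art), replace = TRUE)
        tibble::tibble(participant_id = participants$participant_id[i],
                       block_index = b, beat = seq_len(n_beats), ibi_s = pmax(x, 0.05))
      })
    })

    if (!is.null(truth)) truth$marker_pathways <- pathways
    list(cytokines = cytokines, detection_limits = limits,
         baseline_cortisol = baseline_cortisol, cortisol = cortisol,
         affect = affect, ibi = ibi, marker_pathways = pathways, truth = truth)
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_participants()],
#' [simulate_ground_truth()], [simulate_timeseries()], and
#' [simulate_biomarkers()] with one spec, atlas, and design.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A [roi_atlas()]; default the full 21-ROI stress atlas.
#' @param design A [task_design()].
#' @return List: `participants`, `truth`, `timeseries`, `nuisance`,
#'   `biomarkers`, `atlas`, `design`, `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), atlas = stress_atlas(),
                            design = task_design()) {
  participants <- simulate_participants(spec)
  truth <- simulate_ground_truth(participants, atlas, design, spec)
  ts <- simulate_timeseries(participants, truth, design, spec)
  bio <- simulate_biomarkers(participants, truth, spec)
  list(participants = participants, truth = bio$truth,
       timeseries = ts$timeseries, nuisance = ts$nuisance,
       biomarkers = bio[setdiff(names(bio), "truth")],
       atlas = atlas, design = design, spec = spec)
}

#' Simulate a cohort at the feature level
#'
#' Bypasses timeseries synthesis and per-edge estimation: features are the
#' ground-truth latent features plus independent Gaussian measurement noise
#' with SD `spec$noise_sd`. Used for prediction-layer studies (permutation
#' calibration, sex-specificity, biomarker attribution) where the estimation
#' stage is exercised separately.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A [roi_atlas()].
#' @param mode `"activation"`, `"fc"`, or `"combined"` feature block.
#' @return List: `participants`, `truth`, `features` (tibble
#'   `participant_id` + labeled feature columns), `biomarkers`.
#' @export
simulate_feature_cohort <- function(spec = cohort_spec(), atlas = stress_atlas(),
                                    mode = c("activation", "fc", "combined")) {
  mode <- match.arg(mode)
  design <- task_design()
  participants <- simulate_participants(spec)
  truth <- simulate_ground_truth(participants, atlas, design, spec)
  feats <- truth_features(truth, atlas)
  keep <- switch(mode,
    activation = grepl("^act_", names(feats)),
    fc = grepl("^fc_", names(feats)),
    combined = rep(TRUE, ncol(feats))
  )
  keep[1] <- TRUE # participant_id
  feats <- feats[, keep, drop = FALSE]
  vals <- as.matrix(feats[, -1, drop = FALSE])
  noisy <- with_seed(spec$seed + 4L, {
    vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd), nrow(vals))
  })
  feats[, -1] <- noisy
  bio <- simulate_biomarkers(participants, truth, spec)
  list(participants = participants, truth = bio$truth, features = feats,
       biomarkers = bio[setdiff(names(bio), "truth")])
}
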