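# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Scaled session layout: same 15-block structure, 200 task volumes.
scaled_design <- function() {
  task_design(block_s = 18, fixation_s = 8, tail_s = 10, rest_volumes = 40)
}

toy_effects <- function(regions = c("reg1", "reg2"), blocks = 6:15) {
  tidyr::expand_grid(region = regions, block_index = blocks) |>
    dplyr::mutate(effect = ifelse(.data$region == regions[1], 1, -1))
}

# 6-ROI cohort with planted effects in both sexes, concatenated and with all
# edge models fitted; reused across estimator and aggregation tests.
small_fitted_cohort <- function() {
  cached("small_fitted", function() {
    spec <- cohort_spec(
      n_female = 5, n_male = 5, seed = 404,
      effect_activation = toy_effects(), female_specific = FALSE,
      noise_sd = 0.5, n_cytokines = 6
    )
    atlas <- toy_atlas(6)
    design <- scaled_design()
    participants <- simulate_participants(spec)
    truth <- simulate_ground_truth(participants, atlas, design, spec)
    ts <- simulate_timeseries(participants, truth, design, spec)
    concat <- concatenate_cohort(ts$timeseries, ts$nuisance, design)
    edges <- fit_all_edges(concat$data, atlas, design)
    list(spec = spec, atlas = atlas, design = design,
         participants = participants, truth = truth,
         concat = concat$data, edges = edges)
  })
}

make_ratings <- function(pos, neg, id = "a", tp = "T3") {
  vals <- as.list(c(pos, neg))
  names(vals) <- sprintf("item_%02d", 1:15)
  dplyr::bind_cols(tibble::tibble(participant_id = id, timepoint = tp),
                   tibble::as_tibble(vals))
}

# Noise-only feature table for prediction-layer tests.
noise_features <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- sprintf("act_reg%d_b%02d", rep(1:4, length.out = p), seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("s%03d", seq_len(n))),
    tibble::as_tibble(X)
  )
}

simple_confounds <- function(n, seed = 2) {
  set.seed(seed)
  tibble::tibble(
    age = stats::rnorm(n, 35, 10),
    sex = rep(c("female", "male"), length.out = n),
    diagnosis = stats::runif(n) < 0.4
  )
}

# 20-seed sex-specificity / attribution study shared by two acceptance
# criteria (one simulation pass, two test blocks).
sex_specific_study <- function() {
  cached("sex_study", function() {
    purrr::map_dfr(1:20, function(s) {
      spec <- cohort_spec(seed = 1000 + s)
      fc <- simulate_feature_cohort(spec)
      p <- fc$participants
      cfg <- prediction_config(outer_folds = 5, inner_folds = 3,
                               n_lambda = 30, seed = s, thresh = 1e-5)
      fit <- nested_cv_elastic_net(fc$features, p$bmi, p[, cfg$confounds], cfg)
      pr <- fit$predictions
      fem <- p$sex == "female"
      tx <- cross_sex_transfer(fc$features, p$bmi, p[, cfg$confounds], p$sex, cfg)
      np <- prepare_cytokines(fc$biomarkers$cytokines, fc$biomarkers$detection_limits)
      mc <- marker_component_regression(np, decompose_outcome(fit), p)
      path <- fc$truth$marker_pathways
      rate <- function(pathway, component, alpha = 0.05) {
        mks <- path$marker[path$pathway == pathway]
        mean(vapply(mks, function(m) {
          mc$p_value[mc$marker == m & mc$component == component & mc$term == m] < alpha
        }, logical(1)))
      }
      tibble::tibble(
        seed = s,
        r_female = stats::cor(pr$predicted_oof[fem], pr$observed[fem]),
        r_male = stats::cor(pr$predicted_oof[!fem], pr$observed[!fem]),
        transfer_female_to_male = tx$transfer$r[tx$transfer$train_sex == "female"],
        brain_pred_rate = rate("brain_mediated", "predicted"),
        brain_resid_rate = rate("brain_mediated", "residual"),
        indep_resid_rate = rate("independent", "residual"),
        indep_pred_rate = rate("independent", "predicted")
      )
    })
  })
}
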