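test_that("single-subject estimates equal direct least squares", {
  co <- small_fitted_cohort()
  one <- co$concat[1, ]
  e <- fit_edge_model(one, "reg1_L", "reg1_R", co$design)
  # independent oracle: rebuild the design by hand and solve with qr
  s <- one$series[[1]]
  tps <- timepoint_labels()
  I17 <- vapply(tps, function(tp) as.numeric(s$timepoint == tp), numeric(nrow(s)))
  x2 <- s$reg1_R - mean(s$reg1_R)
  ev <- co$design$events
  task_rows <- s$segment == "task"
  tt <- s$time_s[task_rows] - min(s$time_s[task_rows])
  motor <- feedback <- rep(0, nrow(s))
  motor[task_rows] <- stresstraj:::convolve_events(
    ev$onset_s[ev$trial_type == "motor_response"],
    ev$duration_s[ev$trial_type == "motor_response"], tt)
  feedback[task_rows] <- stresstraj:::convolve_events(
    ev$onset_s[ev$trial_type == "verbal_feedback"],
    ev$duration_s[ev$trial_type == "verbal_feedback"], tt)
  drift <- vapply(unique(s$segment), function(sg) {
    v <- rep(0, nrow(s)); r <- s$segment == sg
    v[r] <- s$time_s[r] - mean(s$time_s[r]); v
  }, numeric(nrow(s)))
  X <- cbind(1, I17, x2, I17 * x2, motor, feedback, drift)
  beta <- qr.coef(qr(X), s$reg1_L)
  expected <- c(beta[2:18], beta[20:36])
  expect_equal(e$subject$estimate, unname(expected), tolerance = 1e-6)
  expect_equal(e$fixed$estimate, unname(expected), tolerance = 1e-6)
})

test_that("a noiseless planted block effect is estimated exactly", {
  eff <- tibble::tibble(region = "reg1", block_index = 7, effect = 1)
  spec <- cohort_spec(n_female = 2, n_male = 2, seed = 21,
                      effect_activation = eff, female_specific = FALSE,
                      subject_sd = 0, noise_sd = 1e-9, drift_sd = 0,
                      nuisance_leak = 0, offset_sd = 0,
                      motor_scale = 0, feedback_scale = 0)
  atlas <- toy_atlas(4)
  design <- scaled_design()
  p <- simulate_participants(spec)
  truth <- simulate_ground_truth(p, atlas, design, spec, group_profile = c(0, 0, 0))
  ts <- simulate_timeseries(p, truth, design, spec)
  cc <- concatenate_cohort(ts$timeseries, design = design, despike_k = 0)
  # predictor ROI from an unplanted region so the planted boxcar is
  # identified by the activation term alone
  e <- fit_edge_model(cc$data, "reg1_L", "mid1", design)
  lat <- attr(p, "latents")
  est <- e$subject |>
    dplyr::filter(.data$term == "tp_block_07") |>
    dplyr::arrange(match(.data$participant_id, p$participant_id))
  expect_equal(est$estimate, lat$brain_score, tolerance = 1e-4)
  # planted fixed effect = mean of subject effects
  expect_equal(e$fixed$estimate[e$fixed$term == "tp_block_07"],
               mean(lat$brain_score), tolerance = 0.2)
})

test_that("partial pooling shrinks relative to per-subject least squares", {
  co <- small_fitted_cohort()
  e <- fit_edge_model(co$concat, "reg1_L", "mid1", co$design)
  by_term <- e$subject |>
    dplyr::summarise(v_pool = stats::var(.data$estimate),
                     v_ols = stats::var(.data$ols), .by = "term")
  expect_true(all(by_term$v_pool <= by_term$v_ols + 1e-12))
  # per-subject estimates average back to (near) the fixed effect
  avg <- e$subject |> dplyr::summarise(m = mean(.data$estimate), .by = "term")
  cmp <- dplyr::left_join(avg, e$fixed, by = "term")
  expect_lt(max(abs(cmp$m - cmp$estimate)), 0.15)
})

test_that("the REML engine agrees with the two-stage estimator", {
  co <- small_fitted_cohort()
  mom <- fit_edge_model(co$concat, "reg1_L", "reg2_L", co$design)
  reml <- fit_edge_model(co$concat, "reg1_L", "reg2_L", co$design,
                         engine = "reml", re_terms = "activation")
  act_m <- mom$subject[mom$subject$kind == "activation", ]
  act_r <- reml$subject[reml$subject$kind == "activation", ]
  expect_equal(act_m$term, act_r$term)
  expect_gt(stats::cor(act_m$estimate, act_r$estimate), 0.8)
  fx <- dplyr::inner_join(mom$fixed, reml$fixed,
                          by = c("term", "kind", "timepoint")) |>
    dplyr::filter(.data$kind == "activation")
  expect_gt(stats::cor(fx$estimate.x, fx$estimate.y), 0.95)
})

test_that("edge enumeration follows the canonical upper triangle", {
  co <- small_fitted_cohort()
  expect_equal(length(co$edges), 15) # 6*5/2
  expect_equal(purrr::map_chr(co$edges, "roi_a"),
               co$atlas$edges$roi_a)
  atlas3 <- roi_atlas(tibble::tibble(
    roi = c("a", "b", "c"), hemisphere = "M", region = c("a", "b", "c")
  ))
  expect_equal(nrow(atlas3$edges), 3)
  # subject order does not change the estimates
  shuffled <- co$concat[rev(seq_len(nrow(co$concat))), ]
  e1 <- fit_edge_model(co$concat, "mid1", "mid2", co$design)
  e2 <- fit_edge_model(shuffled, "mid1", "mid2", co$design)
  j <- dplyr::inner_join(e1$subject, e2$subject,
                         by = c("participant_id", "term"))
  expect_equal(j$estimate.x, j$estimate.y, tolerance = 1e-10)
})

test_that("aggregation averages dependent-role models by region", {
  co <- small_fitted_cohort()
  act <- aggregate_activation(co$edges, co$atlas)
  expect_equal(ncol(act) - 1, 4 * 15) # 4 regions x 15 blocks
  # brute-force oracle for one region/block cell
  dep_edges <- co$edges[purrr::map_chr(co$edges, "roi_a") %in% c("reg1_L", "reg1_R")]
  byroi <- purrr::map_dfr(dep_edges, function(e) {
    e$subject |>
      dplyr::filter(.data$term == "tp_block_03") |>
      dplyr::mutate(roi = e$roi_a)
  }) |>
    dplyr::summarise(est = mean(.data$estimate), .by = c("participant_id", "roi")) |>
    dplyr::summarise(est = mean(.data$est), .by = "participant_id")
  expect_equal(act$act_reg1_b03[match(byroi$participant_id, act$participant_id)],
               byroi$est, tolerance = 1e-10)
})

test_that("connectivity aggregation averages subnetwork members per timepoint", {
  co <- small_fitted_cohort()
  fcm <- aggregate_connectivity(co$edges, co$atlas)
  expect_equal(ncol(fcm) - 1, dplyr::n_distinct(co$atlas$edges$subnetwork) * 17)
  # singleton-subnetwork oracle via a custom map
  edges_map <- co$atlas$edges
  edges_map$subnetwork <- c(1L, rep(2L, nrow(edges_map) - 1))
  atlas2 <- roi_atlas(co$atlas$rois, subnetworks = edges_map)
  fcm2 <- aggregate_connectivity(co$edges, atlas2)
  e1 <- co$edges[[1]]
  tps <- timepoint_labels()
  for (tp in c(1, 9, 17)) {
    col <- sprintf("fc_net1_t%02d", tp)
    ref <- e1$subject |>
      dplyr::filter(.data$kind == "fc", .data$timepoint == tps[tp])
    expect_equal(fcm2[[col]][match(ref$participant_id, fcm2$participant_id)],
                 ref$estimate, tolerance = 1e-10)
  }
})

test_that("feature assembly produces labeled matrices of the right width", {
  co <- small_fitted_cohort()
  act <- aggregate_activation(co$edges, co$atlas)
  fcm <- aggregate_connectivity(co$edges, co$atlas)
  comb <- assemble_feature_matrix(act, fcm, "combined")
  expect_equal(ncol(comb) - 1, (ncol(act) - 1) + (ncol(fcm) - 1))
  expect_identical(assemble_feature_matrix(act, fcm, "activation"), act)
  expect_identical(assemble_feature_matrix(act, fcm, "fc"), fcm)
  lab <- feature_labels(comb)
  expect_equal(nrow(lab), ncol(comb) - 1)
  expect_false(any(is.na(lab$kind)))
  expect_false(any(duplicated(lab$feature)))
  # every label maps to a unique (kind, unit, timepoint) triple
  expect_false(any(duplicated(lab[c("kind", "unit", "timepoint")])))
  # subject mismatch is a structural error
  expect_error(assemble_feature_matrix(act[-1, ], fcm, "combined"), "subjects")
})

test_that("aggregation is linear in the estimates", {
  co <- small_fitted_cohort()
  scale_est <- function(edges, a) {
    purrr::map(edges, function(e) {
      e$subject$estimate <- a * e$subject$estimate
      e
    })
  }
  act1 <- aggregate_activation(co$edges, co$atlas)
  act2 <- aggregate_activation(scale_est(co$edges, 2), co$atlas)
  expect_equal(as.matrix(act2[-1]), 2 * as.matrix(act1[-1]), tolerance = 1e-10)
})
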