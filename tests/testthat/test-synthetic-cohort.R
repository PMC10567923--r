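test_that("simulated participants reproduce the cohort structure", {
  spec <- cohort_spec(n_female = 1000, n_male = 1000, seed = 7)
  p <- simulate_participants(spec)
  fem <- p[p$sex == "female", ]
  mal <- p[p$sex == "male", ]
  expect_equal(nrow(fem), 1000)
  # sample moments of the truncated draw match the target moments
  expect_lt(abs(mean(fem$bmi) - 23.4), 0.5)
  expect_lt(abs(sd(fem$bmi) - 4.6), 0.5)
  expect_lt(abs(mean(mal$bmi) - 24.0), 0.5)
  expect_lt(abs(sd(mal$bmi) - 2.8), 0.5)
  expect_true(all(fem$bmi >= 17.7 & fem$bmi <= 41.9))
  expect_true(all(mal$bmi >= 18.9 & mal$bmi <= 33.1))
  expect_lt(abs(mean(p$diagnosis) - 0.42), 0.05)
  expect_lt(abs(mean(p$pretask_responder) - 0.16), 0.04)
})

test_that("participant generation is a pure function of spec and seed", {
  spec <- cohort_spec(n_female = 2, n_male = 2, seed = 99)
  p1 <- simulate_participants(spec)
  p2 <- simulate_participants(spec)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4)
  expect_equal(sum(p1$sex == "female"), 2)
  expect_error(cohort_spec(n_female = 1), "counts")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(bmi_female = c(mean = 20, sd = 2, min = 30, max = 25)),
               "min")
})

test_that("female-specific planting leaves males with exactly zero slope", {
  spec <- cohort_spec(n_female = 12, n_male = 12, seed = 31,
                      effect_activation = toy_effects(),
                      female_specific = TRUE, subject_sd = 0)
  atlas <- toy_atlas(6)
  p <- simulate_participants(spec)
  truth <- simulate_ground_truth(p, atlas, scaled_design(), spec)
  males <- p$participant_id[p$sex == "male"]
  dev_m <- truth$activation$deviation[truth$activation$participant_id %in% males]
  expect_true(all(dev_m == 0))
  fem <- p$participant_id[p$sex == "female"]
  planted <- truth$activation |>
    dplyr::filter(.data$participant_id %in% fem, .data$roi == "reg1_L",
                  .data$block_index == 7)
  expect_true(any(planted$deviation != 0))
})

test_that("noiseless construction yields the planted block contrast", {
  eff <- tibble::tibble(region = "reg1", block_index = 7, effect = 1)
  spec <- cohort_spec(n_female = 2, n_male = 2, seed = 5,
                      effect_activation = eff, female_specific = TRUE,
                      subject_sd = 0, noise_sd = 1e-9, drift_sd = 0,
                      nuisance_leak = 0, offset_sd = 0,
                      motor_scale = 0, feedback_scale = 0)
  atlas <- toy_atlas(4)
  design <- scaled_design()
  p <- simulate_participants(spec)
  truth <- simulate_ground_truth(p, atlas, design, spec, group_profile = c(0, 0, 0))
  ts <- simulate_timeseries(p, truth, design, spec)
  lat <- attr(p, "latents")
  for (i in which(p$sex == "female")) {
    s <- ts$timeseries |>
      dplyr::filter(.data$participant_id == p$participant_id[i],
                    .data$segment == "task")
    tt <- s$series[[1]]$time_s
    lab <- stresstraj:::label_task_samples(tt, design)
    x <- s$series[[1]][["reg1_L"]]
    contrast <- mean(x[lab == "block_07"]) - mean(x[lab == "task_fixation"])
    expect_equal(contrast, lat$brain_score[i], tolerance = 1e-6)
  }
})

test_that("per-subject least squares recovers planted activation deviations", {
  co <- small_fitted_cohort()
  design <- co$design
  tb <- design$events[grepl("task$", design$events$trial_type), ]
  rec <- purrr::map_dfr(seq_len(nrow(co$concat)), function(i) {
    s <- co$concat$series[[i]]
    task <- s[s$segment == "task", ]
    tt <- task$time_s - min(task$time_s)
    box <- vapply(seq_len(15), function(b) {
      as.numeric(tt >= tb$onset_s[b] & tt < tb$onset_s[b] + tb$duration_s[b])
    }, numeric(nrow(task)))
    purrr::map_dfr(c("reg1_L", "reg1_R", "reg2_L", "reg2_R"), function(r) {
      cf <- stats::lm.fit(cbind(1, box), task[[r]])$coefficients[-1]
      tibble::tibble(participant_id = co$concat$participant_id[i], roi = r,
                     block_index = 1:15, est = cf)
    })
  })
  # deviations about the cohort mean per roi x block
  rec <- dplyr::mutate(rec, dev = .data$est - stats::ave(.data$est, .data$roi, .data$block_index),
                       .by = character())
  cmp <- dplyr::inner_join(rec, co$truth$activation,
                           by = c("participant_id", "roi", "block_index")) |>
    dplyr::semi_join(
      dplyr::inner_join(co$truth$effect_activation,
                        dplyr::select(co$atlas$rois, "roi", "region"),
                        by = "region", relationship = "many-to-many"),
      by = c("roi", "block_index")
    )
  expect_gt(stats::cor(cmp$dev, cmp$deviation), 0.9)
})

test_that("biomarker generation matches its targets", {
  spec <- cohort_spec(n_female = 600, n_male = 400, seed = 77, n_cytokines = 10)
  p <- simulate_participants(spec)
  bio <- simulate_biomarkers(p, spec = spec)
  # baseline cortisol correlation with BMI within females (the printed
  # association is female-specific; sex pooling attenuates it)
  fem <- p$sex == "female"
  r <- stats::cor(bio$baseline_cortisol$cortisol_baseline[fem], p$bmi[fem])
  expect_lt(abs(r - (-0.27)), 0.08)
  # responders rise strictly more than 2.5 nmol/l from T0 to T1
  rise <- bio$cortisol$t1 - bio$cortisol$t0
  expect_true(all(rise[p$pretask_responder] > 2.5))
  expect_true(all(rise[!p$pretask_responder] <= 2.5))
  # affect ratings stay on the 1..6 scale at all timepoints
  items <- as.matrix(bio$affect[sprintf("item_%02d", 1:15)])
  expect_true(all(items >= 1 & items <= 6))
  expect_setequal(unique(bio$affect$timepoint), c("T3", "T6", "T8"))
  # pathway labels split the non-null markers
  expect_setequal(unique(bio$marker_pathways$pathway),
                  c("brain_mediated", "independent", "null"))
})

test_that("null spec yields null marker associations", {
  spec <- cohort_spec(n_female = 400, n_male = 400, seed = 13, n_cytokines = 6,
                      cytokine_bmi_corr = rep(0, 6), cortisol_bmi_corr = 0,
                      effect_activation = NULL)
  p <- simulate_participants(spec)
  bio <- simulate_biomarkers(p, spec = spec)
  rs <- vapply(sprintf("cyt_%02d", 1:6), function(m) {
    stats::cor(bio$cytokines[[m]], p$bmi, use = "complete.obs")
  }, numeric(1))
  expect_true(all(abs(rs) < 0.1))
  expect_lt(abs(stats::cor(bio$baseline_cortisol$cortisol_baseline, p$bmi)), 0.1)
})

test_that("ground truth round-trips through its text interface", {
  co <- small_fitted_cohort()
  dir <- withr::local_tempdir()
  truth <- co$truth
  truth$marker_pathways <- tibble::tibble(marker = "cyt_01", pathway = "null")
  export_ground_truth(truth, dir)
  back <- read_ground_truth(dir)
  expect_equal(back$activation, truth$activation, tolerance = 1e-12)
  expect_equal(back$fc$coupling, truth$fc$coupling, tolerance = 1e-12)
  expect_equal(back$seed, truth$seed)
  expect_equal(back$marker_pathways, truth$marker_pathways)
  # degenerate: no planted effects still writes valid files
  empty <- truth
  empty$effect_activation <- truth$effect_activation[0, ]
  export_ground_truth(empty, file.path(dir, "empty"))
  back2 <- read_ground_truth(file.path(dir, "empty"))
  expect_equal(nrow(back2$effect_activation), 0)
})
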