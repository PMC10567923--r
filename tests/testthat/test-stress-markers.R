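test_that("affect sums hit their bounds and simple arithmetic", {
  top <- make_ratings(rep(6, 5), rep(1, 10))
  sc <- affect_scores(top)
  expect_equal(sc$positive, 30)
  expect_equal(sc$negative, 10)
  mid <- make_ratings(c(2, 3, 4, 5, 6), rep(3, 10))
  expect_equal(affect_scores(mid)$positive, 20)
  expect_equal(affect_scores(mid)$negative, 30)
  # item order within a scale does not matter
  perm <- make_ratings(c(6, 5, 4, 3, 2), rep(3, 10))
  expect_equal(affect_scores(perm)$positive, 20)
  # missing item propagates to a missing score
  holed <- make_ratings(c(NA, 3, 4, 5, 6), rep(3, 10))
  expect_true(is.na(affect_scores(holed)$positive))
  expect_false(is.na(affect_scores(holed)$negative))
  expect_error(affect_scores(make_ratings(rep(7, 5), rep(1, 10))), "1..6")
})

test_that("affect deltas are differences against the T3 baseline", {
  sc <- dplyr::bind_rows(
    affect_scores(make_ratings(rep(4, 5), c(rep(1, 5), rep(2, 5)), tp = "T3")),
    affect_scores(make_ratings(rep(3, 5), c(rep(2, 5), rep(3, 5)), tp = "T6")),
    affect_scores(make_ratings(rep(4, 5), c(rep(1, 5), rep(2, 5)), tp = "T8"))
  )
  d <- affect_deltas(sc)
  expect_equal(d$delta_neg_t6, (10 + 15) - (5 + 10))
  expect_equal(d$delta_pos_t6, 15 - 20)
  expect_equal(d$delta_neg_t8, 0)
  expect_equal(d$delta_pos_t8, 0)
})

test_that("cortisol deltas and responder classification follow the rules", {
  s <- tibble::tibble(participant_id = letters[1:4],
                      t0 = c(5, 5, 5, 5), t1 = c(7.6, 7.5, 4.0, 8.0),
                      t2 = c(5.0, 5.0, 5.0, 5.0), t6 = c(7.5, 5.0, 6.0, 5.0),
                      t8 = c(6.0, 5.0, 5.5, 5.0))
  cr <- cortisol_response(s)
  expect_equal(cr$delta_cort_t6, c(2.5, 0, 1, 0))
  expect_equal(cr$delta_cort_t8, c(1, 0, 0.5, 0))
  flag <- classify_pre_task_responder(s)
  # 2.6 rise -> responder; exactly 2.5 -> not (strict inequality); fall -> not
  expect_equal(flag$pretask_responder, c(TRUE, FALSE, FALSE, TRUE))
  s$t0[1] <- NA
  expect_true(is.na(classify_pre_task_responder(s)$pretask_responder[1]))
})

test_that("interbeat-interval filtering removes implausible and deviant beats", {
  base <- tibble::tibble(participant_id = "a", block_index = 1L,
                         ibi_s = rep(0.8, 60))
  # range rule
  short <- base; short$ibi_s[10] <- 0.25
  long <- base; long$ibi_s[20] <- 2.5
  expect_false(0.25 %in% filter_ibi(short)$ibi_s)
  expect_false(2.5 %in% filter_ibi(long)$ibi_s)
  # hand-traced 60-beat series: one 1.2 s beat in a steady 0.8 s train
  # deviates 50% from the previous beat, the following beat, and the running
  # mean, so it is removed and all 0.8 s beats are retained
  spike <- base; spike$ibi_s[30] <- 1.2
  out <- filter_ibi(spike)
  expect_equal(nrow(out), 59)
  expect_true(all(out$ibi_s == 0.8))
  report <- attr(out, "report")
  expect_equal(report$n_removed, 1)
  expect_true(report$usable)
  # a 10% deviation stays below the initial 13% threshold
  mild <- base; mild$ibi_s[30] <- 0.88
  expect_equal(nrow(filter_ibi(mild)), 60)
})

test_that("IBI filtering is idempotent and flags unusable blocks", {
  set.seed(6)
  x <- rnorm(120, 0.8, 0.05)
  x[c(15, 60, 100)] <- c(0.2, 1.6, 2.6)
  series <- tibble::tibble(participant_id = "a", block_index = 1L, ibi_s = x)
  once <- filter_ibi(series)
  twice <- filter_ibi(once)
  expect_equal(twice$ibi_s, once$ibi_s)
  expect_equal(attr(twice, "report")$n_removed, 0)
  dead <- tibble::tibble(participant_id = "a", block_index = 2L,
                         ibi_s = c(0.1, 0.2, 2.9))
  rep2 <- attr(filter_ibi(dead), "report")
  expect_false(rep2$usable)
})

test_that("block heart rate and phase contrasts are computed in bpm", {
  const <- tibble::tibble(participant_id = "a", block_index = rep(1:15, each = 20),
                          ibi_s = 0.8)
  hr <- block_heart_rate(const)
  expect_true(all(hr$block_hr$hr_bpm == 75))
  expect_equal(hr$deltas$delta_hr_stress, 0)
  expect_equal(hr$deltas$delta_hr_poststress, 0)
  # prestress 70 bpm, stress 76.7 bpm -> delta 6.7
  two <- tibble::tibble(
    participant_id = "a", block_index = rep(1:15, each = 30),
    ibi_s = rep(c(rep(60 / 70, 5), rep(60 / 76.7, 5), rep(60 / 70, 5)), each = 30)
  )
  d <- block_heart_rate(two)$deltas
  expect_equal(d$delta_hr_stress, 6.7, tolerance = 1e-9)
  expect_equal(d$delta_hr_poststress, 0, tolerance = 1e-9)
})

test_that("filtering before or after splitting at block bounds agrees", {
  set.seed(7)
  x <- rnorm(200, 0.8, 0.04)
  x[c(50, 150)] <- c(1.6, 0.2)
  whole <- tibble::tibble(participant_id = "a", block_index = 1L, ibi_s = x)
  split <- tibble::tibble(participant_id = "a",
                          block_index = rep(1:2, each = 100), ibi_s = x)
  hr_whole <- 60 / mean(filter_ibi(whole)$ibi_s)
  cleaned_split <- filter_ibi(split)
  hr_split <- 60 / mean(cleaned_split$ibi_s)
  expect_equal(hr_whole, hr_split, tolerance = 1e-6)
})

test_that("association models reproduce the closed-form solution on a toy table", {
  toy <- tibble::tibble(
    participant_id = sprintf("t%02d", 1:12),
    bmi = c(20, 22, 24, 26, 28, 30, 21, 23, 25, 27, 29, 31),
    sex = rep(c("female", "male"), each = 6),
    age = c(30, 40, 35, 28, 50, 44, 33, 39, 29, 47, 52, 36),
    diagnosis = rep(c(TRUE, FALSE), 6),
    pretask_responder = rep(c(FALSE, TRUE, FALSE), 4)
  )
  responses <- tibble::tibble(
    participant_id = toy$participant_id,
    delta_neg_t6 = c(2, 4, 7, 9, 12, 15, 1, 2, 2, 3, 4, 4)
  )
  out <- stress_association_models(responses, toy)
  co <- out$coefficients
  # normal-equations oracle
  X <- stats::model.matrix(
    ~ bmi * sex + age + diagnosis + pretask_responder,
    data = dplyr::mutate(toy, sex = factor(sex, levels = c("female", "male")))
  )
  beta <- solve(t(X) %*% X, t(X) %*% responses$delta_neg_t6)
  est <- co$estimate[match(colnames(X), co$term)]
  expect_equal(unname(est), as.vector(beta), tolerance = 1e-8)
  expect_equal(unique(co$n), 12)
})

test_that("planted female-specific affect effects surface in stratified fits", {
  spec <- cohort_spec(n_female = 150, n_male = 120, seed = 7, n_cytokines = 2,
                      female_specific = TRUE)
  p <- simulate_participants(spec)
  bio <- simulate_biomarkers(p, spec = spec)
  resp <- stress_responses(bio$affect, bio$cortisol, bio$ibi)
  fem <- dplyr::filter(p, .data$sex == "female")
  mal <- dplyr::filter(p, .data$sex == "male")
  slope <- function(pp) {
    d <- dplyr::inner_join(resp, pp, by = "participant_id")
    stats::coef(stats::lm(delta_neg_t6 ~ bmi + age, data = d))[["bmi"]]
  }
  expect_gt(slope(fem), 0)
  expect_gt(slope(fem), slope(mal) + 0.1)
  # joint multivariate test over the affect block is reported
  out <- stress_association_models(resp, p)
  expect_false(is.null(out$multivariate))
  expect_true("bmi" %in% out$multivariate$term)
})
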