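#' Specification of a synthetic stress-fMRI cohort
#'
#' Collects every tunable of the synthetic-cohort generator: cohort
#' composition, per-sex BMI distributions, planted trajectory-outcome
#' effects, and peripheral-marker targets. Defaults mirror the reference
#' cohort: 120 females and 70 males, female BMI mean 23.4 (SD 4.6, range
#' 17.7-41.9 kg/m^2), male BMI mean 24.0 (SD 2.8, range 18.9-33.1), 42% with
#' a mood/anxiety diagnosis, 16% pre-task cortisol responders, and a
#' female-specific association between activation trajectories and BMI.
#'
#' The outcome is generated from two independent standard-normal latent
#' scores per subject: a *brain* score that drives the planted trajectory
#' deviations (and brain-mediated markers) and a *residual* score that
#' drives brain-independent markers. Their shares of BMI variance are
#' `bmi_brain_share` and `bmi_resid_share`; with `female_specific = TRUE`
#' the brain share is zero in males, so the planted feature-BMI slope in
#' males is exactly zero.
#'
#' @param n_female,n_male Subjects per sex (each >= 2).
#' @param seed Integer seed; every generator output is a pure function of
#'   (spec, seed).
#' @param bmi_female,bmi_male Named vectors `c(mean, sd, min, max)` in
#'   kg/m^2. The generator moment-matches the *truncated* distribution to
#'   `mean`/`sd`, so sample moments converge to these values.
#' @param diagnosis_rate,pretask_responder_rate,medication_rate Fractions in
#'   \[0, 1\].
#' @param effect_activation Planted activation effects: data frame with
#'   columns `region`, `block_index`, `effect` (feature units per SD of the
#'   brain-linked outcome component). Default plants opposite-signed effects
#'   in the posterior insula versus anterior hippocampus and dACC during the
#'   Stress and PostStress blocks.
#' @param effect_fc Planted connectivity effects: data frame with columns
#'   `roi_a`, `roi_b`, `timepoint` (1-17), `effect`; default none.
#' @param female_specific Plant trajectory effects in females only?
#' @param bmi_brain_share,bmi_resid_share Variance shares of the two latent
#'   scores in the standardized outcome (brain share applies to females
#'   under `female_specific`).
#' @param noise_sd Observation noise SD of the ROI signal (signal units).
#' @param subject_sd SD of non-outcome-related subject deviations of block
#'   effects.
#' @param n_cytokines Panel size.
#' @param cytokine_bmi_corr Target marker-outcome partial correlations:
#'   either a single number recycled over the non-null markers or a vector
#'   of length `n_cytokines` (zeros = null markers). The first half of the
#'   non-null markers is labeled `brain_mediated`, the rest `independent`.
#' @param cortisol_bmi_corr Target correlation of baseline cortisol with
#'   BMI (negative).
#' @param missing_rate Completely-at-random missingness injected into the
#'   cytokine panel.
#' @param n_batches Assay batches for the cytokine panel.
#' @param fd_bmi_corr Correlation between log mean framewise displacement
#'   and the standardized outcome. Default 0: head motion is carried as a
#'   confound of the prediction interface, but the generator leaves it
#'   independent of the outcome so that recovery of planted trajectory
#'   effects is identifiable.
#' @param drift_sd SD of the per-segment linear drift slope (signal units
#'   per second); 0 disables drift.
#' @param nuisance_leak Scale of nuisance-component leakage into ROI
#'   signals; 0 disables leakage.
#' @param baseline_offset,offset_sd Mean and between-segment SD of the raw
#'   intensity baseline, emulating scanner gray-scale offsets that the
#'   concatenation stage must remove.
#' @param motor_scale,feedback_scale Amplitudes of the HRF-convolved motor
#'   response and verbal feedback contributions to every ROI signal.
#' @return A `cohort_spec` object (validated list).
#' @export
cohort_spec <- function(n_female = 120L, n_male = 70L, seed = 20230L,
                        bmi_female = c(mean = 23.4, sd = 4.6, min = 17.7, max = 41.9),
                        bmi_male = c(mean = 24.0, sd = 2.8, min = 18.9, max = 33.1),
                        diagnosis_rate = 0.42,
                        pretask_responder_rate = 0.16,
                        medication_rate = 0.04,
                        effect_activation = default_effect_activation(),
                        effect_fc = NULL,
                        female_specific = TRUE,
                        bmi_brain_share = 0.30,
                        bmi_resid_share = 0.40,
                        noise_sd = 0.5,
                        subject_sd = 0.3,
                        n_cytokines = 42L,
                        cytokine_bmi_corr = 0.3,
                        cortisol_bmi_corr = -0.27,
                        missing_rate = 0.05,
                        n_batches = 4L,
                        fd_bmi_corr = 0,
                        drift_sd = 0.01,
                        nuisance_leak = 0.3,
                        baseline_offset = 600,
                        offset_sd = 5,
                        motor_scale = 0.5,
                        feedback_scale = 0.3) {
  abort_if(drift_sd < 0 || nuisance_leak < 0 || offset_sd < 0,
           "drift_sd, nuisance_leak and offset_sd must be non-negative")
  abort_if(!is_count(n_female, 2) || !is_count(n_male, 2),
           "n_female and n_male must be counts >= 2")
  abort_if(!is_count(seed, 0), "seed must be a non-negative integer")
  for (b in list(bmi_female, bmi_male)) {
    abort_if(!all(c("mean", "sd", "min", "max") %in% names(b)),
             "bmi params need mean, sd, min, max")
    abort_if(b[["min"]] >= b[["max"]], "bmi min must be < max")
    abort_if(b[["sd"]] <= 0, "bmi sd must be positive")
  }
  abort_if(!is_prob(diagnosis_rate) || !is_prob(pretask_responder_rate) ||
             !is_prob(medication_rate) || !is_prob(missing_rate),
           "rates must lie in [0, 1]")
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  abort_if(subject_sd < 0, "subject_sd must be non-negative")
  abort_if(!is_flag(female_specific), "female_specific must be TRUE/FALSE")
  abort_if(!is_prob(bmi_brain_share) || !is_prob(bmi_resid_share) ||
             bmi_brain_share + bmi_resid_share > 1,
           "latent variance shares must be fractions summing to at most 1")
  abort_if(!is_count(n_cytokines, 1), "n_cytokines must be a count >= 1")
  abort_if(abs(cortisol_bmi_corr) >= 1, "cortisol_bmi_corr must be in (-1, 1)")

  if (length(cytokine_bmi_corr) == 1L) {
    n_sig <- min(6L, n_cytokines)
    cytokine_bmi_corr <- c(rep(cytokine_bmi_corr, n_sig),
                           rep(0, n_cytokines - n_sig))
  }
  abort_if(length(cytokine_bmi_corr) != n_cytokines,
           "cytokine_bmi_corr must have length 1 or n_cytokines")
  abort_if(any(abs(cytokine_bmi_corr) >= 1), "marker correlations must be in (-1, 1)")

  effect_activation <- if (is.null(effect_activation)) {
    tibble::tibble(region = character(), block_index = integer(), effect = double())
  } else {
    tibble::as_tibble(effect_activation)
  }
  effect_fc <- if (is.null(effect_fc)) {
    tibble::tibble(roi_a = character(), roi_b = character(),
                   timepoint = integer(), effect = double())
  } else {
    tibble::as_tibble(effect_fc)
  }

  structure(list(
    n_female = as.integer(n_female), n_male = as.integer(n_male),
    seed = as.integer(seed),
    bmi_female = bmi_female, bmi_male = bmi_male,
    diagnosis_rate = diagnosis_rate,
    pretask_responder_rate = pretask_responder_rate,
    medication_rate = medication_rate,
    effect_activation = effect_activation,
    effect_fc = effect_fc,
    female_specific = female_specific,
    bmi_brain_share = bmi_brain_share,
    bmi_resid_share = bmi_resid_share,
    noise_sd = noise_sd, subject_sd = subject_sd,
    n_cytokines = as.integer(n_cytokines),
    cytokine_bmi_corr = cytokine_bmi_corr,
    cortisol_bmi_corr = cortisol_bmi_corr,
    missing_rate = missing_rate,
    n_batches = as.integer(n_batches),
    fd_bmi_corr = fd_bmi_corr,
    drift_sd = drift_sd, nuisance_leak = nuisance_leak,
    baseline_offset = baseline_offset, offset_sd = offset_sd,
    motor_scale = motor_scale, feedback_scale = feedback_scale
  ), class = "cohort_spec")
}

#' Default planted activation effects
#'
#' Opposite-signed trajectory effects during the Stress and PostStress
#' blocks (6-15): lower posterior-insula and posterior-hippocampus
#' activation, higher anterior-hippocampus and dACC activation with a higher
#' brain-linked outcome component.
#'
#' @return Tibble with columns `region`, `block_index`, `effect`.
#' @export
default_effect_activation <- function() {
  tidyr::expand_grid(
    region = c("insula_post", "hippocampus_post", "hippocampus_ant", "dACC"),
    block_index = 6:15
  ) |>
    dplyr::mutate(effect = ifelse(.data$region %in% c("insula_post", "hippocampus_post"),
                                  -1, 1))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d female + %d male, seed %d, %d planted activation effects, %s\n",
    x$n_female, x$n_male, x$seed, nrow(x$effect_activation),
    if (x$female_specific) "female-specific" else "both sexes"
  ))
  invisible(x)
}

# Moment-match a truncated normal: find (mu0, sigma0) such that the normal
# truncated to [lo, hi] has the requested mean and sd.
truncnorm_match <- function(mean, sd, lo, hi) {
  moments <- function(par) {
    mu <- par[1]; sg <- exp(par[2])
    a <- (lo - mu) / sg; b <- (hi - mu) / sg
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (z < 1e-12) return(c(NA, NA))
    d <- (stats::dnorm(a) - stats::dnorm(b)) / z
    m <- mu + sg * d
    v <- sg^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - d^2)
    c(m, sqrt(max(v, 1e-12)))
  }
  obj <- function(par) {
    mo <- moments(par)
    if (anyNA(mo)) return(1e6)
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}
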