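#' Simulate a participants table
#'
#' Draws one row per subject with sex, age, BMI, diagnosis and medication
#' flags, pre-task cortisol responder flag, and log mean framewise
#' displacement. BMI is drawn per sex from a normal distribution whose
#' parameters are moment-matched so that, after truncation to the per-sex
#' range, sample mean and SD converge to the spec's targets. The two latent
#' outcome components (brain-linked and residual scores) are attached as the
#' `"latents"` attribute and consumed by [simulate_ground_truth()] and
#' [simulate_biomarkers()].
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with columns `participant_id`, `sex`, `age`, `bmi`,
#'   `diagnosis`, `medication`, `pretask_responder`, `log_mean_fd`.
#' @examples
#' p <- simulate_participants(cohort_spec(n_female = 20, n_male = 10))
#' table(p$sex)
#' @export
simulate_participants <- function(spec) {
  abort_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  n <- spec$n_female + spec$n_male
  with_seed(spec$seed, {
    sex <- c(rep("female", spec$n_female), rep("male", spec$n_male))
    brain <- stats::rnorm(n)
    resid <- stats::rnorm(n)
    eps <- stats::rnorm(n)

    su <- ifelse(sex == "female" | !spec$female_specific, spec$bmi_brain_share, 0)
    sw <- spec$bmi_resid_share
    z <- sqrt(su) * brain + sqrt(sw) * resid + sqrt(pmax(1 - su - sw, 0)) * eps

    # map the standard-normal composite score through the quantile function
    # of the moment-matched truncated normal (Gaussian copula): the BMI
    # marginal is exactly the truncated normal whose post-truncation moments
    # equal the targets, while the latent scores stay exactly independent
    bmi <- numeric(n)
    for (s in c("female", "male")) {
      par <- if (s == "female") spec$bmi_female else spec$bmi_male
      tm <- truncnorm_match(par[["mean"]], par[["sd"]], par[["min"]], par[["max"]])
      sel <- which(sex == s)
      pa <- stats::pnorm((par[["min"]] - tm$mu) / tm$sigma)
      pb <- stats::pnorm((par[["max"]] - tm$mu) / tm$sigma)
      u01 <- stats::pnorm(z[sel])
      bmi[sel] <- tm$mu + tm$sigma * stats::qnorm(pa + u01 * (pb - pa))
    }

    age <- round(pmin(pmax(stats::rnorm(n, 35, 12.3), 18), 70))
    diagnosis <- stats::runif(n) < spec$diagnosis_rate
    medication <- diagnosis & (stats::runif(n) < spec$medication_rate / max(spec$diagnosis_rate, 1e-9))
    responder <- stats::runif(n) < spec$pretask_responder_rate
    rho_fd <- spec$fd_bmi_corr
    log_mean_fd <- log(0.15) +
      0.35 * (rho_fd * z + sqrt(1 - rho_fd^2) * stats::rnorm(n))

    out <- tibble::tibble(
      participant_id = sprintf("sub-%03d", seq_len(n)),
      sex = sex, age = age, bmi = bmi,
      diagnosis = diagnosis, medication = medication,
      pretask_responder = responder,
      log_mean_fd = log_mean_fd
    )
    attr(out, "latents") <- tibble::tibble(
      participant_id = out$participant_id,
      brain_score = brain, resid_score = resid, bmi_z = z
    )
    out
  })
}

cohort_latents <- function(participants) {
  lat <- attr(participants, "latents")
  abort_if(is.null(lat),
           "participants table lacks the 'latents' attribute; use simulate_participants()")
  lat
}
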