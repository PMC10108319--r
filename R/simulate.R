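# Synthetic meta-analytic data generator and MCAR deletion of SDs.
#
# The generator emulates datasets typical of ecological meta-analyses:
# a true overall effect theta with lognormally-dispersed study-level CVs,
# small within-study sample sizes, study and effect-within-study random
# deviations, and summary statistics (sample mean, sample SD) observed with
# their exact Normal-theory sampling distributions. Heterogeneity is
# parameterised through tau/theta so tau2 = (tau_over_theta * theta)^2,
# split between study and effect level by icc_true.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic dataset generator.
#'
#' @param theta True overall mean lnRR (default 0.3).
#' @param tau_over_theta Heterogeneity ratio tau/theta; 0.01 (low, tau2 =
#'   9e-6 at default theta) or 1 (high, tau2 = 0.09) in the study design.
#' @param icc_true Share of tau2 at the study level, in [0, 1].
#' @param k_studies Number of studies K.
#' @param effects_per_study \code{"poisson"} (Set I: L_i = 1 + Poisson(lambda
#'   - 1) effect sizes per study, mean lambda) or \code{"one"} (Set II: a
#'   single effect size per study).
#' @param lambda Mean number of effects per study under Set I (default 3).
#' @param mean_n Mean within-group sample size; n = 3 + Poisson(mean_n - 3),
#'   shared by an effect's two groups.
#' @param cv_level Typical (median) coefficient of variation of the raw data
#'   (default 0.3).
#' @param cv_heterogeneity SD of the lognormal between-study spread of true
#'   CVs (0.1 = low, 0.75 = high).
#' @param missingness Proportion of studies whose SDs are deleted, in
#'   [0, 0.55] (larger values warn).
#' @param mu2 Baseline (group 2) true mean, default 10.
#' @param seed Optional integer seed.
#' @return Validated list of class \code{sim_config}.
#' @export
sim_config <- function(theta = 0.3,
                       tau_over_theta = 1,
                       icc_true = 0.5,
                       k_studies = 30,
                       effects_per_study = c("poisson", "one"),
                       lambda = 3,
                       mean_n = 5,
                       cv_level = 0.3,
                       cv_heterogeneity = 0.1,
                       missingness = 0,
                       mu2 = 10,
                       seed = NULL) {
  effects_per_study <- match.arg(effects_per_study)
  bad <- function(msg) lnrr_error("config", msg)
  if (!is.finite(theta)) bad("theta must be finite")
  if (!is.finite(tau_over_theta) || tau_over_theta < 0) bad("tau_over_theta must be >= 0")
  if (icc_true < 0 || icc_true > 1) bad("icc_true must be in [0, 1]")
  if (k_studies < 1 || k_studies != round(k_studies)) bad("k_studies must be a positive integer")
  if (lambda < 1) bad("lambda must be >= 1")
  if (mean_n < 3) bad("mean_n must be >= 3")
  if (cv_level <= 0) bad("cv_level must be > 0")
  if (cv_heterogeneity < 0) bad("cv_heterogeneity must be >= 0")
  if (missingness < 0 || missingness > 1) bad("missingness must be in [0, 1]")
  if (missingness > 0.55) {
    lnrr_warning("config", "missingness above 0.55, beyond the range studied")
  }
  if (mu2 <= 0) bad("mu2 must be > 0")
  tau2 <- (tau_over_theta * theta)^2
  structure(list(
    theta = theta, tau_over_theta = tau_over_theta, tau2 = tau2,
    icc_true = icc_true, k_studies = as.integer(k_studies),
    effects_per_study = effects_per_study, lambda = lambda,
    mean_n = mean_n, cv_level = cv_level,
    cv_heterogeneity = cv_heterogeneity,
    missingness = missingness, mu2 = mu2, seed = seed
  ), class = "sim_config")
}

# sample mean and SD of n draws from Normal(mu, sd_true^2), via their exact
# sampling distributions (mean ~ Normal, SD^2 ~ sd^2 chi^2_{n-1}/(n-1));
# means <= 0 are redrawn (lnRR needs ratio-scale data)
draw_summary <- function(mu, sd_true, n) {
  m <- stats::rnorm(length(mu), mu, sd_true / sqrt(n))
  while (any(m <= 0)) {
    i <- m <= 0
    m[i] <- stats::rnorm(sum(i), mu[i], sd_true[i] / sqrt(n[i]))
  }
  s <- sd_true * sqrt(stats::rchisq(length(mu), n - 1) / (n - 1))
  list(mean = m, sd = s)
}

#' Simulate a meta-analytic dataset
#'
#' Draws study effects s_i ~ N(0, icc * tau2), effect deviations u_ij ~
#' N(0, (1 - icc) * tau2), per-study true CVs cv_level * exp(N(0,
#' cv_heterogeneity)) (shared by both groups), per-effect group sample sizes
#' 3 + Poisson(mean_n - 3), and observed group means/SDs from their exact
#' Normal-theory sampling distributions. All records are SD-complete; use
#' \code{\link{impose_missingness}} to delete SDs.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed overriding \code{config$seed}; if both are NULL
#'   the current RNG stream is used.
#' @return An \code{effect_data} data frame with diagnostic columns
#'   \code{true_lnrr} and \code{true_cv}.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- config$k_studies
  L <- if (config$effects_per_study == "poisson") {
    1L + stats::rpois(K, config$lambda - 1)
  } else {
    rep(1L, K)
  }
  study <- rep(seq_len(K), L)
  n_eff <- length(study)

  sigma2_s <- config$icc_true * config$tau2
  sigma2_u <- (1 - config$icc_true) * config$tau2
  s_i <- stats::rnorm(K, 0, sqrt(sigma2_s))
  u_ij <- stats::rnorm(n_eff, 0, sqrt(sigma2_u))
  true_lnrr <- config$theta + s_i[study] + u_ij

  cv_i <- config$cv_level * exp(stats::rnorm(K, 0, config$cv_heterogeneity))
  true_cv <- cv_i[study]

  n <- 3L + stats::rpois(n_eff, config$mean_n - 3)
  mu2 <- rep(config$mu2, n_eff)
  mu1 <- mu2 * exp(true_lnrr)
  g1 <- draw_summary(mu1, true_cv * mu1, n)
  g2 <- draw_summary(mu2, true_cv * mu2, n)

  out <- data.frame(
    study_id = sprintf("S%03d", study),
    effect_id = sprintf("S%03d_e%d", study,
                        as.integer(stats::ave(study, study, FUN = seq_along))),
    m1 = g1$mean, sd1 = g1$sd, n1 = n,
    m2 = g2$mean, sd2 = g2$sd, n2 = n,
    true_lnrr = true_lnrr,
    true_cv = true_cv,
    stringsAsFactors = FALSE
  )
  as_effect_data(out)
}

#' Delete SDs completely at random at the study level
#'
#' Sets both groups' SDs to missing in every effect size of a simple random
#' sample of round(proportion * K) studies, emulating articles that report
#' no variability measure at all.
#'
#' @param data An \code{effect_data} data frame.
#' @param proportion Proportion of studies to delete, in [0, 1]; values
#'   above 0.55 warn (beyond the studied range) but proceed.
#' @param seed Optional seed.
#' @return The dataset with SDs deleted, still \code{effect_data}.
#' @export
impose_missingness <- function(data, proportion, seed = NULL) {
  data <- as_effect_data(data)
  stopifnot(proportion >= 0, proportion <= 1)
  if (proportion > 0.55) {
    lnrr_warning("config", "missingness above 0.55, beyond the range studied")
  }
  if (!is.null(seed)) set.seed(seed)
  studies <- unique(as.character(data$study_id))
  n_del <- round(proportion * length(studies))
  if (n_del > 0) {
    del <- sample(studies, n_del)
    hit <- as.character(data$study_id) %in% del
    data$sd1[hit] <- NA_real_
    data$sd2[hit] <- NA_real_
    data$sd_missing <- is.na(data$sd1) | is.na(data$sd2)
  }
  data
}
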