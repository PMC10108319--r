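# Heterogeneity summaries: the Higgins-Thompson "typical" sampling variance,
# I^2, and the study-level intra-class correlation.

#' Typical (average) sampling variance
#'
#' Higgins-Thompson form: v_bar = (k - 1) * sum(w) / ((sum w)^2 - sum(w^2))
#' with inverse-variance weights w = 1/v. Equals v when all variances are
#' equal, and scales linearly under rescaling of the v's.
#'
#' @param vs Positive sampling variances, length >= 2.
#' @return A list of class \code{typical_variance} with element \code{v_bar}.
#' @export
typical_sampling_variance <- function(vs) {
  if (length(vs) < 2) {
    lnrr_error("single_effect",
               "typical sampling variance needs at least 2 effect sizes")
  }
  if (any(!is.finite(vs) | vs <= 0)) {
    lnrr_error("degenerate_variance", "sampling variances must be finite and > 0")
  }
  w <- 1 / vs
  k <- length(vs)
  structure(list(v_bar = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))),
            class = "typical_variance")
}

#' I-squared heterogeneity statistic
#'
#' Proportion of total variance attributable to heterogeneity rather than
#' sampling error: tau2 / (tau2 + v_bar). Pass total heterogeneity
#' (sigma2_s + sigma2_u) for the multilevel total-I2, or sigma2_s alone for
#' the study-level variant.
#'
#' @param tau2_total Heterogeneity variance, >= 0.
#' @param v_bar Typical sampling variance, >= 0.
#' @return Value in [0, 1].
#' @export
i_squared <- function(tau2_total, v_bar) {
  stopifnot(tau2_total >= 0, v_bar >= 0)
  if (tau2_total == 0 && v_bar == 0) {
    lnrr_error("undefined_heterogeneity",
               "I2 is undefined when tau2 and v_bar are both 0")
  }
  tau2_total / (tau2_total + v_bar)
}

#' Study-level intra-class correlation
#'
#' Share of total heterogeneity sitting between studies:
#' sigma2_s / (sigma2_s + sigma2_u).
#'
#' @param sigma2_s Between-study variance, >= 0.
#' @param sigma2_u Within-study (between-effect) variance, >= 0.
#' @return Value in [0, 1].
#' @export
icc_study <- function(sigma2_s, sigma2_u) {
  stopifnot(sigma2_s >= 0, sigma2_u >= 0)
  if (sigma2_s == 0 && sigma2_u == 0) {
    lnrr_error("undefined_heterogeneity",
               "ICC is undefined when both variance components are 0")
  }
  sigma2_s / (sigma2_s + sigma2_u)
}
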