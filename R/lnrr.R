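# Point estimators and sampling variances for the log response ratio (lnRR).
#
# All functions are vectorised over their numeric arguments and recycle in the
# usual R way. Means must be strictly positive (lnRR is only defined for
# ratio-scale data with a true zero); a missing SD is represented by NA and is
# an error for estimators that need the record's own coefficient of variation.

check_means <- function(...) {
  for (m in list(...)) {
    if (any(!is.finite(m) | m <= 0)) {
      lnrr_error("domain",
        "group means must be finite and > 0 (lnRR requires ratio-scale data)")
    }
  }
  invisible(TRUE)
}

check_sds <- function(...) {
  for (s in list(...)) {
    if (anyNA(s)) {
      lnrr_error("missing_sd", "standard deviation is missing (NA)")
    }
    if (any(s < 0)) {
      lnrr_error("domain", "standard deviations must be >= 0")
    }
  }
  invisible(TRUE)
}

#' Coefficient of variation
#'
#' The ratio of a group's standard deviation to its mean, the building block
#' of all lnRR sampling-variance formulas in this package.
#'
#' @param mean Group mean(s); must be > 0.
#' @param sd Group standard deviation(s); must be >= 0 and not NA.
#' @return Numeric vector of CVs (sd/mean).
#' @examples
#' cv(10, 2)   # 0.2
#' cv(4, 6)    # 1.5, over-dispersed data
#' @export
cv <- function(mean, sd) {
  check_means(mean)
  check_sds(sd)
  sd / mean
}

#' Log response ratio, uncorrected
#'
#' The plain log ratio of two group means, ln(m1/m2).
#'
#' @param m1,m2 Group means; must be > 0.
#' @return lnRR in natural-log units. Antisymmetric under group swap.
#' @export
lnrr_raw <- function(m1, m2) {
  check_means(m1, m2)
  log(m1 / m2)
}

#' Log response ratio with small-sample bias correction
#'
#' Adds the second-order Taylor correction term 0.5 * (CV1^2/n2 - CV2^2/n1)
#' to the raw log ratio, using each group's own coefficient of variation.
#' Note the crossed sample-size indices (group 1's CV is divided by group 2's
#' n): this follows the published form of the correction; with balanced group
#' sizes (n1 = n2), the crossed and uncrossed forms coincide.
#'
#' @param m1,sd1,n1 Mean, SD and sample size of group 1.
#' @param m2,sd2,n2 Mean, SD and sample size of group 2.
#' @return Bias-corrected lnRR.
#' @export
lnrr_corrected <- function(m1, sd1, n1, m2, sd2, n2) {
  check_means(m1, m2)
  check_sds(sd1, sd2)
  cv1 <- sd1 / m1
  cv2 <- sd2 / m2
  log(m1 / m2) + 0.5 * (cv1^2 / n2 - cv2^2 / n1)
}

#' Log response ratio using pooled coefficients of variation
#'
#' As \code{\link{lnrr_corrected}}, but the correction term uses dataset-level
#' weighted-average CVs (see \code{\link{pooled_cv}}) in place of the record's
#' own CVs, so it is computable when the record's SDs are missing. The
#' record's own sample sizes are kept.
#'
#' @param m1,m2 Group means.
#' @param n1,n2 Group sample sizes.
#' @param cv1_bar,cv2_bar Pooled (weighted-average) CVs for groups 1 and 2.
#' @return lnRR point estimate.
#' @export
lnrr_pooled <- function(m1, m2, n1, n2, cv1_bar, cv2_bar) {
  check_means(m1, m2)
  log(m1 / m2) + 0.5 * (cv1_bar^2 / n2 - cv2_bar^2 / n1)
}

#' First-order sampling variance from the record's own CVs
#'
#' CV1^2/n1 + CV2^2/n2, the classical delta-method sampling variance of lnRR.
#' With CV1 = CV2 = 1 this reduces to 1/n-tilde where
#' n-tilde = n1*n2/(n1+n2).
#'
#' @inheritParams lnrr_corrected
#' @return Sampling variance (may be 0 when both SDs are 0; downstream model
#'   fitting rejects zero variances).
#' @export
var_individual_first <- function(m1, sd1, n1, m2, sd2, n2) {
  check_means(m1, m2)
  check_sds(sd1, sd2)
  (sd1 / m1)^2 / n1 + (sd2 / m2)^2 / n2
}

#' Second-order sampling variance from the record's own CVs
#'
#' Adds the quartic correction terms CV1^4/(2 n1^2) + CV2^4/(2 n2^2) to the
#' first-order variance; always >= the first-order value.
#'
#' @inheritParams lnrr_corrected
#' @return Sampling variance.
#' @export
var_individual_second <- function(m1, sd1, n1, m2, sd2, n2) {
  check_means(m1, m2)
  check_sds(sd1, sd2)
  cv1 <- sd1 / m1
  cv2 <- sd2 / m2
  cv1^2 / n1 + cv2^2 / n2 + cv1^4 / (2 * n1^2) + cv2^4 / (2 * n2^2)
}

#' Second-order sampling variance from pooled CVs
#'
#' The pooled-CV analogue of \code{\link{var_individual_second}}: the
#' dataset-level weighted-average CVs stand in for the record's own CVs while
#' the record's own n1, n2 are retained.
#'
#' @inheritParams lnrr_pooled
#' @return Sampling variance.
#' @export
var_pooled_second <- function(n1, n2, cv1_bar, cv2_bar) {
  cv1_bar^2 / n1 + cv2_bar^2 / n2 +
    cv1_bar^4 / (2 * n1^2) + cv2_bar^4 / (2 * n2^2)
}

#' First-order sampling variance from pooled CVs
#'
#' As \code{\link{var_pooled_second}} without the quartic terms. Recommended
#' over the second-order form when many effect sizes fail the Geary normality
#' screen, because it does not lean on the second-order Taylor expansion.
#'
#' @inheritParams lnrr_pooled
#' @return Sampling variance.
#' @export
var_pooled_first <- function(n1, n2, cv1_bar, cv2_bar) {
  cv1_bar^2 / n1 + cv2_bar^2 / n2
}
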