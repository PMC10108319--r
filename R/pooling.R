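# Sample-size-weighted pooling of coefficients of variation across the
# SD-complete part of a dataset. Pooling is two-stage when studies contribute
# several effect sizes: first a weighted-average CV within each study, then a
# weighted average of those study-level CVs across studies (weights are the
# summed group sample sizes). With one effect per study the two stages
# collapse to a single weighted mean. The average of CVs (not of CV^2) is
# pooled and squared downstream; squaring first is far more sensitive to
# outlying CVs from non-normal data.

weighted_two_stage_cv <- function(study, n, cvs) {
  ok <- !is.na(cvs)
  if (!any(ok)) return(list(cv_bar = NA_real_, n_studies = 0L, n_effects = 0L))
  study <- as.character(study[ok])
  n <- n[ok]
  cvs <- cvs[ok]
  within <- rowsum(n * cvs, study) / rowsum(n, study)
  wt <- rowsum(n, study)
  list(
    cv_bar = sum(wt * within) / sum(wt),
    n_studies = length(unique(study)),
    n_effects = sum(ok)
  )
}

#' Pooled (weighted-average) coefficients of variation
#'
#' Computes, separately for each group, the two-stage sample-size-weighted
#' average CV over records that report that group's SD. These pooled CVs are
#' the quantity substituted into the pooled-CV point estimate and variance
#' formulas for records with missing SDs (or, under the all-cases and
#' multiplicative strategies, for every record).
#'
#' A record missing only one group's SD still contributes its available
#' group's CV.
#'
#' @param data An \code{effect_data} data frame.
#' @return An object of class \code{pooled_cv}: a list with \code{cv1_bar},
#'   \code{cv2_bar}, \code{n_studies_used} and \code{n_effects_used} (counts
#'   of fully SD-complete studies/records).
#' @export
pooled_cv <- function(data) {
  data <- as_effect_data(data)
  if (all(data$sd_missing)) {
    lnrr_error("no_complete_records",
               "no records with complete SDs; pooled CVs cannot be estimated")
  }
  cv1 <- ifelse(is.na(data$sd1), NA_real_, data$sd1 / data$m1)
  cv2 <- ifelse(is.na(data$sd2), NA_real_, data$sd2 / data$m2)
  g1 <- weighted_two_stage_cv(data$study_id, data$n1, cv1)
  g2 <- weighted_two_stage_cv(data$study_id, data$n2, cv2)
  complete <- data[!data$sd_missing, , drop = FALSE]
  structure(
    list(
      cv1_bar = g1$cv_bar,
      cv2_bar = g2$cv_bar,
      n_studies_used = length(unique(as.character(complete$study_id))),
      n_effects_used = nrow(complete)
    ),
    class = "pooled_cv"
  )
}

#' @export
print.pooled_cv <- function(x, ...) {
  cat("Pooled coefficients of variation\n")
  cat(sprintf("  group 1: %.6g   group 2: %.6g\n", x$cv1_bar, x$cv2_bar))
  cat(sprintf("  from %d complete effect size(s) in %d study(ies)\n",
              x$n_effects_used, x$n_studies_used))
  invisible(x)
}
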