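# Improved Geary screen for the normality assumption underlying lnRR and its
# Taylor-expansion variances. The per-group criterion is
#   (1/CV) * 4 n^{3/2} / (1 + 4n) >= 3,
# and an effect size passes only if both of its groups pass. The screen is a
# sensitivity-analysis utility: nothing in this package applies it
# implicitly.

#' Improved Geary normality criterion
#'
#' Evaluates (1/CV) * 4 n^(3/2) / (1 + 4n) for one group of an effect size.
#' Values >= 3 indicate the normality assumption behind lnRR's sampling
#' variance is tenable for that group. Over-dispersed data (CV > 1, common
#' for counts) need large n to pass; at CV = 0 the criterion is +Inf.
#'
#' @param cv Coefficient(s) of variation, >= 0.
#' @param n Per-group sample size(s), >= 1.
#' @return The criterion value (vectorised); compare against 3.
#' @export
geary_criterion <- function(cv, n) {
  if (any(cv < 0)) lnrr_error("domain", "cv must be >= 0")
  if (any(n < 1)) lnrr_error("domain", "n must be >= 1")
  ifelse(cv == 0, Inf, (1 / cv) * 4 * n^1.5 / (1 + 4 * n))
}

#' Smallest sample size passing the Geary criterion
#'
#' The smallest integer n for which \code{\link{geary_criterion}(cv, n) >= 3};
#' monotone nondecreasing in cv. At CV = 5 (heavily over-dispersed count
#' data) this is 226 replicates per group.
#'
#' @param cv A single coefficient of variation, > 0.
#' @return Integer sample size.
#' @export
geary_min_n <- function(cv) {
  stopifnot(length(cv) == 1L)
  if (!is.finite(cv) || cv <= 0) lnrr_error("domain", "cv must be > 0")
  # criterion ~ n^{1/2}/cv for large n, so it eventually exceeds 3:
  # bracket by doubling, then binary search for the first passing n.
  hi <- 1L
  while (geary_criterion(cv, hi) < 3) hi <- hi * 2L
  lo <- max(1L, hi %/% 2L)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (geary_criterion(cv, mid) >= 3) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Geary screen over a dataset
#'
#' Applies the improved Geary criterion to both groups of every record.
#' A record passes when both groups pass; records with a missing SD in a
#' group get NA for that group (their CV is unknown) and NA overall.
#'
#' @param data An \code{effect_data} data frame.
#' @return Logical vector, one element per record: TRUE (passes), FALSE
#'   (fails), or NA (not assessable because an SD is missing).
#' @export
geary_screen <- function(data) {
  data <- as_effect_data(data)
  crit <- function(sd, m, n) {
    ifelse(is.na(sd), NA, geary_criterion(ifelse(is.na(sd), 0, sd / m), n) >= 3)
  }
  p1 <- crit(data$sd1, data$m1, data$n1)
  p2 <- crit(data$sd2, data$m2, data$n2)
  p1 & p2
}
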