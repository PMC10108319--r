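# Strategy dispatch: turn a dataset with (possibly) missing SDs into
# per-effect point estimates plus a diagonal variance specification. The six
# strategies:
#
#   reference      no missing SDs allowed; own-CV corrected point + own-CV
#                  second-order variance (the full-data benchmark)
#   complete_case  drop records with missing SDs, then as reference
#   missing_cases  own-CV formulas for complete records, pooled-CV formulas
#                  for missing ones
#   all_cases      pooled-CV variance for *every* record (pooled CVs estimate
#                  sampling variance better than noisy own CVs even when SDs
#                  are reported)
#   multiplicative pooled-CV variance everywhere, entering the model only up
#                  to a proportionality constant phi estimated by REML
#   hybrid         own-CV variance for complete records; phi-scaled pooled-CV
#                  variance for missing ones
#
# Point estimates are shared across missing_cases/all_cases/multiplicative/
# hybrid: bias-corrected own-CV form for complete records, pooled-CV form for
# missing ones. `variance_order = "first"` switches pooled variances to the
# first-order form and pooled-CV points to the raw log ratio, for datasets
# where many effects fail the Geary screen.

strategy_names <- c("reference", "complete_case", "missing_cases",
                    "all_cases", "multiplicative", "hybrid")

#' Apply a missing-SD handling strategy
#'
#' Computes per-effect lnRR point estimates and sampling variances under one
#' of six strategies, together with the mask of variance entries that enter
#' the meta-analytic model only up to the multiplicative parameter phi.
#' Pooled CVs are always estimated from the complete records of the full
#' input dataset (never from a post-filter subset).
#'
#' @param data An \code{effect_data} data frame (see
#'   \code{\link{as_effect_data}}).
#' @param strategy One of \code{"reference"}, \code{"complete_case"},
#'   \code{"missing_cases"}, \code{"all_cases"}, \code{"multiplicative"},
#'   \code{"hybrid"}.
#' @param variance_order \code{"second"} (default) or \code{"first"}; the
#'   first-order option avoids the second-order Taylor terms (and uses the
#'   raw log ratio wherever the pooled-CV point estimate would be used),
#'   advisable when many effects fail \code{\link{geary_screen}}.
#' @param point_pooled_everywhere If TRUE, use the pooled-CV point estimate
#'   for complete records too (the two choices make little difference unless
#'   effects fail the Geary screen).
#' @return A \code{strategy_result}: data frame with columns
#'   \code{study_id}, \code{effect_id}, \code{yi} (point estimate), \code{vi}
#'   (variance value), \code{phi_scaled} (does \code{vi} enter the model as
#'   phi * vi?), plus attributes \code{strategy}, \code{variance_order},
#'   \code{pooled} (the \code{\link{pooled_cv}} object, where used) and
#'   \code{retained} (effect identifiers kept).
#' @export
apply_strategy <- function(data,
                           strategy = c("missing_cases", "all_cases",
                                        "multiplicative", "hybrid",
                                        "reference", "complete_case"),
                           variance_order = c("second", "first"),
                           point_pooled_everywhere = FALSE) {
  strategy <- match.arg(strategy)
  variance_order <- match.arg(variance_order)
  data <- as_effect_data(data)
  if (nrow(data) == 0) lnrr_error("strategy_precondition", "empty dataset")

  if (strategy == "reference" && any(data$sd_missing)) {
    lnrr_error("strategy_precondition",
               "reference strategy requires a dataset with no missing SDs")
  }
  if (strategy == "complete_case" && sum(!data$sd_missing) < 2) {
    lnrr_error("strategy_precondition",
               "complete_case requires at least 2 records with complete SDs")
  }

  pooled <- NULL
  needs_pool <- !(strategy %in% c("reference", "complete_case"))
  if (needs_pool) {
    pooled <- pooled_cv(data)  # errors if no complete records
  }

  kept <- if (strategy == "complete_case") !data$sd_missing else rep(TRUE, nrow(data))
  d <- data[kept, , drop = FALSE]
  miss <- d$sd_missing

  # --- point estimates -----------------------------------------------------
  yi <- numeric(nrow(d))
  own_point <- function(idx) {
    lnrr_corrected(d$m1[idx], d$sd1[idx], d$n1[idx],
                   d$m2[idx], d$sd2[idx], d$n2[idx])
  }
  pool_point <- function(idx) {
    if (variance_order == "first") {
      lnrr_raw(d$m1[idx], d$m2[idx])
    } else {
      lnrr_pooled(d$m1[idx], d$m2[idx], d$n1[idx], d$n2[idx],
                  pooled$cv1_bar, pooled$cv2_bar)
    }
  }
  if (strategy %in% c("reference", "complete_case")) {
    yi <- own_point(seq_len(nrow(d)))
  } else if (point_pooled_everywhere) {
    yi <- pool_point(seq_len(nrow(d)))
  } else {
    if (any(!miss)) yi[!miss] <- own_point(which(!miss))
    if (any(miss)) yi[miss] <- pool_point(which(miss))
  }

  # --- variances and phi mask ----------------------------------------------
  own_var <- function(idx) {
    var_individual_second(d$m1[idx], d$sd1[idx], d$n1[idx],
                          d$m2[idx], d$sd2[idx], d$n2[idx])
  }
  pool_var <- function(idx) {
    f <- if (variance_order == "first") var_pooled_first else var_pooled_second
    f(d$n1[idx], d$n2[idx], pooled$cv1_bar, pooled$cv2_bar)
  }
  all_idx <- seq_len(nrow(d))
  vi <- numeric(nrow(d))
  phi_scaled <- logical(nrow(d))
  if (strategy %in% c("reference", "complete_case")) {
    vi <- own_var(all_idx)
  } else if (strategy == "missing_cases") {
    if (any(!miss)) vi[!miss] <- own_var(which(!miss))
    if (any(miss)) vi[miss] <- pool_var(which(miss))
  } else if (strategy == "all_cases") {
    vi <- pool_var(all_idx)
  } else if (strategy == "multiplicative") {
    vi <- pool_var(all_idx)
    phi_scaled[] <- TRUE
  } else if (strategy == "hybrid") {
    if (any(!miss)) vi[!miss] <- own_var(which(!miss))
    if (any(miss)) {
      vi[miss] <- pool_var(which(miss))
      phi_scaled[miss] <- TRUE
    }
  }

  if (any(vi <= 0)) {
    lnrr_error("degenerate_variance",
      "a sampling variance of 0 was produced (zero CVs); the model's V would be singular")
  }

  out <- data.frame(
    study_id = d$study_id,
    effect_id = d$effect_id,
    yi = yi,
    vi = vi,
    phi_scaled = phi_scaled,
    stringsAsFactors = FALSE
  )
  structure(out,
            strategy = strategy,
            variance_order = variance_order,
            pooled = pooled,
            retained = d$effect_id,
            class = c("strategy_result", "data.frame"))
}
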