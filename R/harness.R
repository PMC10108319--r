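# Evaluation harness: run the missing-SD strategies over replicated
# synthetic datasets and summarise bias of the overall mean, 95% CI
# coverage, log-ratio bias of total heterogeneity and ICC bias.
#
# Replicates are paired across methods: each replicate simulates one dataset
# (and one deleted-SD version of it) that every method analyses, so
# method-vs-method contrasts share the Monte-Carlo noise. The reference
# strategy always sees the pre-deletion dataset.

performance_metrics <- c("median_bias_beta0", "range_bias_beta0", "coverage95",
                         "bias_log_tau2", "bias_icc")

#' Evaluate strategies on replicated synthetic datasets
#'
#' For each replicate: simulate a dataset from \code{config}, delete SDs at
#' the configured study-level proportion, apply each strategy, fit the
#' matching REML model (multilevel for Set I, random-effects for Set II) and
#' record bias in beta0, CI coverage of theta, the log ratio of estimated to
#' true total heterogeneity, and the difference between estimated and true
#' study-level ICC. Failed fits are excluded from the summaries and counted
#' in \code{n_converged}.
#'
#' @param config A \code{\link{sim_config}}; its \code{seed} (if any) seeds
#'   the replicate stream.
#' @param methods Character vector of strategy names (default: reference
#'   plus the four missing-SD strategies).
#' @param n_replicates Number of replicates, >= 1.
#' @param ci_method Passed to \code{\link{reml_fit}}.
#' @param variance_order Passed to \code{\link{apply_strategy}}.
#' @param keep_replicates If TRUE, attach the per-replicate metric table as
#'   attribute \code{"replicates"}.
#' @return A data frame with one row per method: \code{method},
#'   \code{median_bias_beta0}, \code{range_bias_beta0}, \code{coverage95},
#'   \code{bias_log_tau2}, \code{bias_icc}, \code{n_replicates},
#'   \code{n_converged}.
#' @export
run_condition <- function(config,
                          methods = c("reference", "missing_cases", "all_cases",
                                      "multiplicative", "hybrid"),
                          n_replicates = 100,
                          ci_method = "z",
                          variance_order = "second",
                          keep_replicates = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  methods <- match.arg(methods, strategy_names, several.ok = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  levels <- if (config$effects_per_study == "poisson") "ML" else "RE"

  rows <- vector("list", n_replicates * length(methods))
  ri <- 0L
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    full <- simulate_dataset(config, seed = NULL)
    miss <- impose_missingness(full, config$missingness, seed = NULL)
    for (method in methods) {
      dat <- if (method == "reference") full else miss
      fit <- tryCatch({
        sr <- apply_strategy(dat, method, variance_order = variance_order)
        reml_fit(sr, levels = levels, ci_method = ci_method)
      }, error = function(e) NULL)
      ri <- ri + 1L
      rows[[ri]] <- if (is.null(fit) || !fit$converged) {
        data.frame(replicate = r, method = method, converged = FALSE,
                   bias = NA_real_, cover = NA, log_tau2_ratio = NA_real_,
                   icc_bias = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(
          replicate = r, method = method, converged = TRUE,
          bias = fit$beta0 - config$theta,
          cover = fit$ci_low <= config$theta && config$theta <= fit$ci_high,
          log_tau2_ratio = log(fit$tau2_total / config$tau2),
          icc_bias = (if (is.na(fit$icc_s)) NA_real_
                      else fit$icc_s - config$icc_true),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  detail <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(methods, function(method) {
    d <- detail[detail$method == method & detail$converged, , drop = FALSE]
    data.frame(
      method = method,
      median_bias_beta0 = stats::median(d$bias),
      range_bias_beta0 = if (nrow(d) > 0) diff(range(d$bias)) else NA_real_,
      coverage95 = mean(d$cover),
      bias_log_tau2 = stats::median(d$log_tau2_ratio),
      bias_icc = stats::median(d$icc_bias, na.rm = TRUE),
      n_replicates = n_replicates,
      n_converged = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  if (keep_replicates) attr(summ, "replicates") <- detail
  class(summ) <- c("performance_summary", "data.frame")
  summ
}

#' Run a grid of simulation conditions
#'
#' Expands per-condition overrides on top of a base configuration, runs
#' \code{\link{run_condition}} for each, and binds the results with the
#' condition columns attached. Each condition draws its own seed from the
#' master seed so the grid is reproducible as a whole.
#'
#' @param conditions Data frame; each row gives \code{\link{sim_config}}
#'   field overrides (e.g. columns \code{tau_over_theta}, \code{mean_n},
#'   \code{missingness}).
#' @param base Named list of \code{sim_config} arguments shared by all
#'   conditions.
#' @param methods,n_replicates,ci_method,variance_order Passed through to
#'   \code{\link{run_condition}}.
#' @param seed Master seed for the whole grid.
#' @return Data frame: condition columns + the per-method summary rows.
#' @export
run_grid <- function(conditions,
                     base = list(),
                     methods = c("reference", "missing_cases", "all_cases",
                                 "multiplicative", "hybrid"),
                     n_replicates = 100,
                     ci_method = "z",
                     variance_order = "second",
                     seed = NULL) {
  conditions <- as.data.frame(conditions)
  stopifnot(nrow(conditions) >= 1)
  if (!is.null(seed)) set.seed(seed)
  cond_seeds <- sample.int(.Machine$integer.max - 1L, nrow(conditions))
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    over <- as.list(conditions[i, , drop = FALSE])
    cfg <- do.call(sim_config, utils::modifyList(base, c(over, list(seed = cond_seeds[i]))))
    res <- run_condition(cfg, methods = methods, n_replicates = n_replicates,
                         ci_method = ci_method, variance_order = variance_order)
    out[[i]] <- cbind(condition = i, conditions[rep(i, nrow(res)), , drop = FALSE],
                      res, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Reshape grid results to a tidy long table
#'
#' One row per (condition, method, metric), convenient for plotting the
#' distribution of per-condition summaries across methods.
#'
#' @param grid Output of \code{\link{run_grid}}.
#' @return Long-format data frame with columns \code{condition},
#'   \code{method}, \code{metric}, \code{value} (plus the condition
#'   columns).
#' @export
summarize_grid <- function(grid) {
  grid <- as.data.frame(grid)
  id_cols <- setdiff(names(grid), c(performance_metrics, "n_replicates", "n_converged"))
  long <- do.call(rbind, lapply(performance_metrics, function(metric) {
    cbind(grid[id_cols], metric = metric, value = grid[[metric]],
          row.names = NULL)
  }))
  long[order(long$condition, long$method, long$metric), , drop = FALSE]
}
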