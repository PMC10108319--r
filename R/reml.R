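# Restricted maximum likelihood for meta-analytic models of lnRR.
#
# Models (y_ij = effect j in study i, with sampling variance v_ij):
#
#   RE:  y_i  = beta0 + s_i + m_i            s_i ~ N(0, sigma2_s),
#                                            m_i ~ N(0, v_i)
#   ML:  y_ij = beta0 + s_i + u_ij + m_ij    u_ij ~ N(0, sigma2_u)
#
# Any subset of the v entries may enter only up to a proportionality
# constant: Var(m_ij) = phi * v_ij on the phi-scaled entries (the
# weighted-regression assumption behind the multiplicative and hybrid
# strategies). phi is a single scalar shared by all scaled entries and is
# estimated alongside the variance components.
#
# The marginal covariance is block diagonal by study: V_i = sigma2_s * J +
# diag(d_ij) with d_ij = sigma2_u + v'_ij, so each restricted-likelihood
# evaluation is O(k) via the rank-one Woodbury identities
#   log|V_i|     = sum_j log d_ij + log(1 + sigma2_s * a_i),   a_i = sum 1/d_ij
#   1'V_i^-1 1   = a_i / f_i,  1'V_i^-1 y = t_i / f_i,         f_i = 1 + sigma2_s a_i
#   y'V_i^-1 y   = sum y^2/d - (sigma2_s/f_i) t_i^2,           t_i = sum y_j/d_ij
# Variance parameters are optimised on the log scale (floor 1e-10) from
# three dispersed starts, since boundary solutions (tau2-hat = 0) are common
# at low heterogeneity.

block_reml_ll <- function(y, block, d, sigma2_s) {
  inv_d <- 1 / d
  a <- rowsum(inv_d, block, reorder = FALSE)[, 1]
  t1 <- rowsum(y * inv_d, block, reorder = FALSE)[, 1]
  f <- 1 + sigma2_s * a
  W <- sum(a / f)
  U <- sum(t1 / f)
  quad_full <- sum(y^2 * inv_d) - sum((sigma2_s / f) * t1^2)
  beta0 <- U / W
  logdet <- sum(log(d)) + sum(log(f))
  n <- length(y)
  ll <- -0.5 * (logdet + log(W) + (quad_full - U^2 / W) + (n - 1) * log(2 * pi))
  list(ll = ll, beta0 = beta0, W = W)
}

#' REML fit of a meta-analytic model with optional multiplicative variances
#'
#' Fits the random-effects (study level only, rows treated as independent)
#' or multilevel (study + effect-within-study) meta-analytic model by
#' restricted maximum likelihood. Sampling variances are taken as known,
#' except for entries flagged phi-scaled, which enter as phi * v with the
#' scalar phi estimated by the model.
#'
#' @param result A \code{strategy_result} from \code{\link{apply_strategy}},
#'   or any data frame with columns \code{study_id}, \code{yi}, \code{vi}
#'   (and \code{phi_scaled} for masked phi).
#' @param levels \code{"ML"} (multilevel: study and effect-within-study
#'   random effects) or \code{"RE"} (one random effect per row).
#' @param phi_mode \code{"auto"} (default: masked if any \code{phi_scaled}
#'   entry is TRUE, otherwise none), \code{"none"}, \code{"all"}, or
#'   \code{"masked"} (use the \code{phi_scaled} column).
#' @param ci_method \code{"z"} (Wald normal quantile, default) or \code{"t"}
#'   (Student t with k - 1 degrees of freedom, k = number of effects).
#' @param level Confidence level, default 0.95.
#' @param fix Optional named list fixing variance components instead of
#'   estimating them, e.g. \code{list(sigma2_s = 0, sigma2_u = 0)}.
#' @param control List; \code{n_starts} (default 3) and \code{maxit}
#'   (default 500) for the optimiser.
#' @return An object of class \code{lnrr_fit}: a list with elements
#'   \code{beta0}, \code{se_beta0}, \code{ci_low}, \code{ci_high},
#'   \code{sigma2_s}, \code{sigma2_u}, \code{phi} (NA when not estimated),
#'   \code{tau2_total}, \code{icc_s}, \code{i2}, \code{v_bar},
#'   \code{loglik_reml}, \code{converged}, \code{k}, \code{n_studies},
#'   \code{levels}, \code{ci_method}, \code{level}.
#' @export
reml_fit <- function(result,
                     levels = c("ML", "RE"),
                     phi_mode = c("auto", "none", "all", "masked"),
                     ci_method = c("z", "t"),
                     level = 0.95,
                     fix = list(),
                     control = list()) {
  levels <- match.arg(levels)
  phi_mode <- match.arg(phi_mode)
  ci_method <- match.arg(ci_method)
  n_starts <- control$n_starts %||% 3L
  maxit <- control$maxit %||% 500L

  y <- result$yi
  v <- result$vi
  k <- length(y)
  if (k < 2) lnrr_error("single_effect", "at least 2 effect sizes are required")
  if (any(!is.finite(v) | v <= 0)) {
    lnrr_error("degenerate_variance", "all sampling variances must be finite and > 0")
  }

  mask <- switch(phi_mode,
    none = rep(FALSE, k),
    all = rep(TRUE, k),
    masked = ,
    auto = if (!is.null(result$phi_scaled)) as.logical(result$phi_scaled)
           else rep(FALSE, k)
  )
  if (phi_mode == "all") mask <- rep(TRUE, k)
  if (phi_mode == "masked" && is.null(result$phi_scaled)) {
    lnrr_error("strategy_precondition", "phi_mode = 'masked' needs a phi_scaled column")
  }
  est_phi <- any(mask)

  block <- if (levels == "ML") {
    as.integer(factor(as.character(result$study_id),
                      levels = unique(as.character(result$study_id))))
  } else {
    seq_len(k)
  }
  n_studies <- length(unique(as.character(result$study_id)))

  est_s <- is.null(fix$sigma2_s)
  est_u <- levels == "ML" && is.null(fix$sigma2_u)
  fixed_s <- if (est_s) NA_real_ else fix$sigma2_s
  fixed_u <- if (levels == "ML") (if (est_u) NA_real_ else fix$sigma2_u) else 0

  par_names <- c(if (est_s) "log_sigma2_s",
                 if (est_u) "log_sigma2_u",
                 if (est_phi) "log_phi")
  floor_v <- 1e-10

  unpack <- function(par) {
    p <- stats::setNames(as.list(par), par_names)
    list(
      sigma2_s = if (est_s) exp(p$log_sigma2_s) else fixed_s,
      sigma2_u = if (est_u) exp(p$log_sigma2_u) else fixed_u,
      phi = if (est_phi) exp(p$log_phi) else NA_real_
    )
  }

  eval_ll <- function(par) {
    th <- unpack(par)
    vv <- if (est_phi) ifelse(mask, th$phi * v, v) else v
    block_reml_ll(y, block, th$sigma2_u + vv, th$sigma2_s)
  }

  neg_ll <- function(par) {
    r <- eval_ll(par)
    if (!is.finite(r$ll)) 1e10 else -r$ll
  }

  if (length(par_names) == 0) {
    best <- list(par = numeric(0), value = neg_ll(numeric(0)), convergence = 0L)
  } else {
    vy <- max(stats::var(y), 1e-6)
    start_grid <- list(
      c(log_sigma2_s = log(0.5 * vy), log_sigma2_u = log(0.5 * vy), log_phi = 0),
      c(log_sigma2_s = log(0.05 * vy), log_sigma2_u = log(0.05 * vy), log_phi = log(0.2)),
      c(log_sigma2_s = log(1e-8), log_sigma2_u = log(1e-8), log_phi = log(5))
    )[seq_len(min(3L, n_starts))]
    lower <- ifelse(par_names == "log_phi", log(1e-8), log(floor_v))
    upper <- ifelse(par_names == "log_phi", log(1e8), log(1e4 * max(vy, 1)))
    fits <- list()
    for (st in start_grid) {
      par0 <- pmin(pmax(st[par_names], lower), upper)
      opt <- tryCatch(
        stats::optim(par0, neg_ll, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = maxit, factr = 1e3)),
        error = function(e) NULL
      )
      if (!is.null(opt) && is.finite(opt$value)) fits[[length(fits) + 1L]] <- opt
    }
    if (length(fits) == 0) {
      lnrr_error("convergence", "REML optimisation failed from all starts")
    }
    vals <- vapply(fits, `[[`, numeric(1), "value")
    best <- fits[[which.min(vals)]]
    # several starts typically land on the same optimum; call the fit
    # converged if any of them got there with a clean exit code
    clean <- vapply(fits, function(f) f$convergence == 0L, logical(1))
    best$convergence <- if (any(clean & vals <= min(vals) + 1e-6)) 0L else best$convergence
  }

  th <- unpack(best$par)
  at <- eval_ll(best$par)
  # snap floored variance components to an exact zero for reporting
  snap <- function(x) if (is.finite(x) && x <= 2 * 1e-10) 0 else x
  sigma2_s <- snap(th$sigma2_s)
  sigma2_u <- snap(th$sigma2_u)
  phi <- th$phi

  se <- sqrt(1 / at$W)
  tau2_total <- sigma2_s + sigma2_u
  icc_s <- if (tau2_total > 0) sigma2_s / tau2_total else NA_real_
  vv_eff <- if (est_phi) ifelse(mask, phi * v, v) else v
  v_bar <- typical_sampling_variance(vv_eff)$v_bar
  i2 <- tau2_total / (tau2_total + v_bar)

  fit <- structure(list(
    beta0 = at$beta0,
    se_beta0 = se,
    sigma2_s = sigma2_s,
    sigma2_u = sigma2_u,
    phi = phi,
    tau2_total = tau2_total,
    icc_s = icc_s,
    i2 = i2,
    v_bar = v_bar,
    loglik_reml = at$ll,
    converged = best$convergence == 0L,
    k = k,
    n_studies = n_studies,
    levels = levels,
    phi_mode = phi_mode,
    ci_method = ci_method,
    level = level
  ), class = "lnrr_fit")
  ci <- wald_ci(fit, level)
  fit$ci_low <- ci[[1]]
  fit$ci_high <- ci[[2]]
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald confidence interval for the overall mean
#'
#' beta0 +/- q * se, with q the standard normal quantile (\code{ci_method =
#' "z"}) or the Student t quantile with k - 1 degrees of freedom
#' (\code{"t"}).
#'
#' @param fit An \code{lnrr_fit}.
#' @param level Confidence level in (0, 1); defaults to the fit's level.
#' @return Named numeric vector \code{c(low, high)}.
#' @export
wald_ci <- function(fit, level = fit$level) {
  stopifnot(level > 0, level < 1)
  q <- if (fit$ci_method == "t") {
    stats::qt(1 - (1 - level) / 2, df = fit$k - 1)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  c(low = fit$beta0 - q * fit$se_beta0, high = fit$beta0 + q * fit$se_beta0)
}

#' @export
print.lnrr_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Meta-analytic REML fit (%s model%s)\n",
              if (x$levels == "ML") "multilevel" else "random-effects",
              if (is.finite(x$phi) && !is.na(x$phi)) ", multiplicative phi" else ""))
  cat(sprintf("  k = %d effect sizes, %d studies%s\n", x$k, x$n_studies,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  beta0   = %.*g  (SE %.*g, %g%% CI [%.*g, %.*g], %s)\n",
              digits, x$beta0, digits, x$se_beta0, 100 * x$level,
              digits, x$ci_low, digits, x$ci_high, x$ci_method))
  cat(sprintf("  sigma2_s = %.*g   sigma2_u = %.*g   tau2 = %.*g\n",
              digits, x$sigma2_s, digits, x$sigma2_u, digits, x$tau2_total))
  if (!is.na(x$phi)) cat(sprintf("  phi     = %.*g\n", digits, x$phi))
  cat(sprintf("  I2      = %.3f   ICC_s = %s\n", x$i2,
              if (is.na(x$icc_s)) "undefined" else sprintf("%.3f", x$icc_s)))
  invisible(x)
}

#' Flatten a fit to a one-row data frame
#'
#' Convenience serialiser used by the command-line report and the simulation
#' harness.
#'
#' @param fit An \code{lnrr_fit}.
#' @param method Optional label (e.g. the strategy name).
#' @return One-row data frame.
#' @export
fit_to_row <- function(fit, method = NA_character_) {
  data.frame(
    method = method,
    beta0 = fit$beta0, se = fit$se_beta0,
    ci_low = fit$ci_low, ci_high = fit$ci_high,
    sigma2_s = fit$sigma2_s, sigma2_u = fit$sigma2_u,
    phi = fit$phi, tau2_total = fit$tau2_total,
    i2 = fit$i2, icc_s = fit$icc_s,
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
}
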