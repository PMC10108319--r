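# Independent oracles for the REML fitter.
#
# dense_reml_ll builds the full marginal covariance matrix explicitly and
# evaluates the restricted log-likelihood by Cholesky factorisation -- no
# code shared with the package's block/Woodbury implementation.
# oracle_reml maximises it by a coarse grid over the log-variance parameters
# followed by Nelder-Mead refinement from the best grid points.

dense_reml_ll <- function(y, study, v, mask, sigma2_s, sigma2_u, phi = 1) {
  n <- length(y)
  same <- outer(study, study, "==")
  vv <- ifelse(mask, phi * v, v)
  V <- sigma2_s * same + diag(sigma2_u + vv, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  W <- sum(Vi_1)
  beta0 <- sum(Vi_y) / W
  resid <- y - beta0
  Vi_r <- backsolve(R, forwardsolve(t(R), resid))
  ll <- -0.5 * (logdetV + log(W) + sum(resid * Vi_r) + (n - 1) * log(2 * pi))
  attr(ll, "beta0") <- beta0
  ll
}

oracle_reml <- function(y, study, v, mask = rep(FALSE, length(y)),
                        multilevel = TRUE) {
  est_phi <- any(mask)
  if (!multilevel) study <- seq_along(y)
  par_dim <- 1L + as.integer(multilevel) + as.integer(est_phi)
  grid_1d <- log(c(1e-8, 1e-4, 1e-3, 1e-2, 0.05, 0.2, 1))
  # phi grid must reach its boundary: when every entry is scaled, phi and
  # sigma2_u form a near-ridge and the optimum can sit at phi -> 0
  phi_1d <- log(c(1e-8, 1e-3, 0.05, 0.3, 1, 3, 20))
  axes <- c(rep(list(grid_1d), par_dim - as.integer(est_phi)),
            if (est_phi) list(phi_1d))
  grid <- as.matrix(expand.grid(axes))

  evalp <- function(p) {
    s2s <- exp(p[1])
    s2u <- if (multilevel) exp(p[2]) else 0
    phi <- if (est_phi) exp(p[par_dim]) else 1
    dense_reml_ll(y, study, v, mask, s2s, s2u, phi)
  }
  vals <- apply(grid, 1, function(p) as.numeric(evalp(p)))
  best_rows <- order(vals, decreasing = TRUE)[1:5]
  best <- NULL
  for (i in best_rows) {
    opt <- stats::optim(grid[i, ], function(p) -as.numeric(evalp(p)),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ll <- evalp(best$par)
  list(loglik = as.numeric(ll), beta0 = attr(ll, "beta0"), par = best$par)
}

# random small strategy-result-like data frame for oracle comparisons
random_small_dataset <- function(n_effects, n_studies = NULL) {
  if (is.null(n_studies)) n_studies <- sample(2:max(2, n_effects - 1), 1)
  study <- sort(sample(seq_len(n_studies), n_effects, replace = TRUE))
  data.frame(
    study_id = paste0("s", study),
    effect_id = paste0("e", seq_len(n_effects)),
    yi = rnorm(n_effects, 0.3, 0.3),
    vi = runif(n_effects, 0.005, 0.08),
    phi_scaled = FALSE,
    stringsAsFactors = FALSE
  )
}
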