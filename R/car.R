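#' MCMC configuration for the Leroux CAR Poisson model
#'
#' Defaults follow the headline analysis schedule: 3 chains of 520,000
#' iterations each, 20,000 burn-in, thinning every 100, which retains 5,000
#' draws per chain (15,000 in total), with an Inverse-Gamma(1, 0.01) prior
#' on the variance parameter and Uniform(0, 1) on the dependence parameter.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param burn_in burn-in iterations discarded per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param tau2_prior_shape,tau2_prior_scale Inverse-Gamma prior for `tau2`
#'   (density proportional to `x^(-shape-1) exp(-scale/x)`).
#' @param beta_prior_var variance of the diffuse normal prior on the
#'   intercept and coefficients.
#' @param seed base seed; chain `c` runs under `seed + c - 1`.
#' @param fix_rho optional value to hold `rho` fixed (e.g. 0 for independent
#'   random effects); `NULL` samples it.
#' @return a `car_config` list.
#' @export
car_config <- function(n_chains = 3, n_iter = 520000, burn_in = 20000,
                       thin = 100, tau2_prior_shape = 1,
                       tau2_prior_scale = 0.01, beta_prior_var = 1e5,
                       seed = 1L, fix_rho = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if ((n_iter - burn_in) %% thin != 0)
    stop("(n_iter - burn_in) must be divisible by thin", call. = FALSE)
  if (n_chains < 1) stop("need at least one chain", call. = FALSE)
  if (tau2_prior_shape <= 0 || tau2_prior_scale <= 0)
    stop("tau2 prior parameters must be positive", call. = FALSE)
  if (!is.null(fix_rho) && (fix_rho < 0 || fix_rho > 1))
    stop("fix_rho must lie in [0, 1]", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 tau2_prior_shape = tau2_prior_shape,
                 tau2_prior_scale = tau2_prior_scale,
                 beta_prior_var = beta_prior_var,
                 seed = as.integer(seed), fix_rho = fix_rho),
            class = "car_config")
}

#' Retained-draw bookkeeping
#'
#' Iteration indices kept by the sampler: those strictly after the burn-in
#' whose offset from it is a multiple of the thinning interval. With the
#' default schedule each chain retains (520000 - 20000) / 100 = 5000 draws.
#'
#' @param n_iter,burn_in,thin as in [car_config()].
#' @return integer vector of retained iteration numbers.
#' @export
mcmc_retention <- function(n_iter, burn_in, thin) {
  it <- seq_len(n_iter)
  it[it > burn_in & (it - burn_in) %% thin == 0]
}

#' Standardize covariates to mean 0, SD 1
#'
#' Coefficients fitted on the standardized design are log relative risks per
#' standard deviation; the per-column SDs are retained for reporting on the
#' raw scale.
#'
#' @param X covariate matrix or data frame.
#' @return list with `X_std`, `means`, `sds`.
#' @export
standardize_covariates <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  means <- colMeans(X)
  list(X_std = scale(X, center = means, scale = sds)[, , drop = FALSE],
       means = means, sds = sds)
}

#' Log determinant of the Leroux precision structure
#'
#' `log det[rho (D_w - W) + (1 - rho) I] = sum_m log(rho lambda_m + 1 - rho)`
#' using the eigenvalues `lambda_m` of the graph Laplacian `D_w - W`,
#' computed once per graph. Finite for `rho` in `[0, 1)`; `-Inf` at
#' `rho = 1` whenever the Laplacian has a zero eigenvalue (any graph).
#'
#' @param rho dependence parameter in \[0, 1\].
#' @param lambda Laplacian eigenvalues (see [laplacian_eigenvalues()]).
#' @return scalar log determinant.
#' @export
leroux_logdet <- function(rho, lambda) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  terms <- rho * lambda + 1 - rho
  if (any(terms <= 0)) return(-Inf)
  sum(log(terms))
}

#' Eigenvalues of the graph Laplacian `D_w - W`
#'
#' @param W binary adjacency matrix.
#' @return numeric eigenvalues (all >= 0).
#' @export
laplacian_eigenvalues <- function(W) {
  validate_adjacency(W)
  eigen(diag(rowSums(W)) - W, symmetric = TRUE, only.values = TRUE)$values
}

#' Inverse-gamma random draws
#'
#' Draws from the Inverse-Gamma(shape, scale) distribution with density
#' proportional to `x^(-shape-1) exp(-scale/x)` — the same primitive the
#' sampler's conjugate `tau2` update uses, exposed for verification.
#'
#' @param n number of draws.
#' @param shape,scale positive parameters.
#' @return numeric vector of draws.
#' @export
rinvgamma <- function(n, shape, scale) {
  if (shape <= 0 || scale <= 0) stop("parameters must be positive", call. = FALSE)
  rinvgamma_cpp(as.integer(n), shape, scale)
}

#' Fit the Leroux CAR Poisson disease-mapping model
#'
#' Metropolis-within-Gibbs MCMC for
#' `O_i ~ Poisson(E_i exp(alpha + X_i beta + psi_i))` with a Leroux
#' conditional-autoregressive prior on `psi`, Inverse-Gamma prior on `tau2`
#' and Uniform(0, 1) on `rho`. The intercept and coefficients move by
#' adaptive random walks (steps frozen after burn-in), `psi` by single-site
#' random walks against its full conditional, `tau2` by a conjugate Gibbs
#' draw, and `rho` on the logit scale using the precomputed Laplacian
#' spectrum for the determinant. `psi` is recentred to sum zero each
#' iteration with the mean absorbed into the intercept.
#'
#' @param O observed counts.
#' @param E expected deaths (offset), > 0.
#' @param X standardized covariate matrix (see [standardize_covariates()]),
#'   or `NULL` for an intercept-plus-field model.
#' @param W binary adjacency matrix (no isolated areas).
#' @param config a [car_config()].
#' @return object of class `car_fit` holding per-chain retained draws of all
#'   parameters, pointwise log-likelihoods, and acceptance rates.
#' @export
fit_car <- function(O, E, X, W, config = car_config()) {
  stopifnot(inherits(config, "car_config"))
  validate_adjacency(W)
  n <- length(O)
  if (length(E) != n || nrow(W) != n)
    stop("O, E and W dimensions disagree", call. = FALSE)
  if (any(E <= 0)) stop("expected deaths must be positive", call. = FALSE)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  nb <- lapply(seq_len(n), function(i) which(W[i, ] == 1) - 1L)
  wplus <- rowSums(W)
  lambda <- laplacian_eigenvalues(W)
  par_names <- c("alpha", colnames(X), "tau2", "rho")
  alpha0 <- log(sum(O) / sum(E))
  rho0 <- if (is.null(config$fix_rho)) 0.5 else config$fix_rho
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    res <- leroux_mcmc_cpp(as.integer(O), as.numeric(E), X, nb,
                           as.numeric(wplus), lambda,
                           config$n_iter, config$burn_in, config$thin,
                           config$tau2_prior_shape, config$tau2_prior_scale,
                           config$beta_prior_var,
                           alpha0, rep(0, ncol(X)), 0.1, rho0,
                           !is.null(config$fix_rho))
    colnames(res$draws) <- par_names
    names(res$acceptance) <- c("alpha", colnames(X), "psi", "rho")
    chains[[ch]] <- res
  }
  structure(list(chains = chains, par_names = par_names,
                 O = O, E = E, X = X, W = W, config = config),
            class = "car_fit")
}

#' Pool retained draws of the scalar parameters across chains
#'
#' @param fit a `car_fit`.
#' @return matrix (total retained draws) x (parameters).
#' @export
pooled_draws <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "draws"))
}

#' @export
print.car_fit <- function(x, ...) {
  cfg <- x$config
  cat("Leroux CAR Poisson fit:", length(x$O), "areas,",
      ncol(x$X), "covariates\n")
  cat(sprintf("%d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
              cfg$n_chains, cfg$n_iter, cfg$burn_in, cfg$thin,
              cfg$n_chains * (cfg$n_iter - cfg$burn_in) %/% cfg$thin))
  invisible(x)
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` with
#' `lppd = sum_i log(mean_s p(O_i | draw s))` and
#' `p_waic = sum_i var_s(log p(O_i | draw s))`, from a pointwise
#' log-likelihood matrix (draws x observations). The log of the mean
#' likelihood is computed through a log-sum-exp for stability.
#'
#' @param loglik matrix of pointwise log-likelihoods, draws in rows.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 2) warning("p_waic is zero with a single draw", call. = FALSE)
  lppd <- sum(apply(loglik, 2, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }))
  p_waic <- if (S >= 2) sum(apply(loglik, 2, stats::var)) else 0
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) R-hat: with `m` chains of length `n`, within-chain
#' variance `Wv` (mean of the per-chain variances) and between-chain
#' variance `B = n var(chain means)`,
#' `R-hat = sqrt((n - 1) / n + B / (n Wv))`. Values below 1.1 are taken as
#' convergence.
#'
#' @param chains list of equal-length numeric vectors (one per chain).
#' @return scalar R-hat.
#' @export
psrf <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("PSRF needs at least two chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2)
    stop("chains must have equal lengths >= 2", call. = FALSE)
  means <- vapply(chains, mean, 0)
  Wv <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(means)
  if (Wv == 0) return(if (B == 0) 1 else Inf)
  sqrt((n - 1) / n + B / (n * Wv))
}

#' Convergence diagnostics for every scalar parameter of a fit
#'
#' @param fit a `car_fit` with at least two chains.
#' @return named vector of R-hat values (intercept, each coefficient,
#'   `tau2`, and `rho` unless it was held fixed).
#' @export
psrf_all <- function(fit) {
  pars <- fit$par_names
  if (!is.null(fit$config$fix_rho)) pars <- setdiff(pars, "rho")
  vapply(pars, function(p)
    psrf(lapply(fit$chains, function(ch) ch$draws[, p])), 0)
}

#' Posterior summary: relative risks, WAIC, diagnostics, fitted SMRs
#'
#' Relative risks per standard deviation are posterior medians of
#' `exp(beta_k)` with 95% credible intervals (the design having been
#' standardized). Fitted SMRs are posterior medians and intervals of the
#' relative risk `theta_i = exp(alpha + X_i beta + psi_i)`. The residual
#' Moran's I is computed on Pearson-scale residuals
#' `(O_i - E_i theta_hat_i) / sqrt(E_i theta_hat_i)` over the fit's own
#' adjacency.
#'
#' @param fit a `car_fit`.
#' @param moran_seed seed for the Moran permutation test.
#' @return object of class `car_summary`.
#' @export
summarize_car <- function(fit, moran_seed = 1L) {
  draws <- pooled_draws(fit)
  if (nrow(draws) == 0) stop("empty posterior", call. = FALSE)
  covars <- setdiff(fit$par_names, c("alpha", "tau2", "rho"))
  qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  rr <- t(vapply(covars, function(p) qs(exp(draws[, p])), numeric(3)))
  rr_tab <- if (length(covars)) {
    data.frame(term = covars, RR = rr[, 1], lo95 = rr[, 2], hi95 = rr[, 3],
               row.names = NULL)
  } else {
    data.frame(term = character(0), RR = numeric(0), lo95 = numeric(0),
               hi95 = numeric(0))
  }
  # theta draws: alpha + X beta + psi per retained draw
  theta_q <- matrix(0, length(fit$O), 3)
  lin <- do.call(rbind, lapply(fit$chains, function(ch) {
    eta <- ch$draws[, "alpha"] +
      if (length(covars)) ch$draws[, covars, drop = FALSE] %*% t(fit$X) else 0
    eta + ch$psi
  }))
  theta <- exp(lin)
  theta_q <- t(apply(theta, 2, qs))
  smr_tab <- data.frame(area = seq_along(fit$O), smr_median = theta_q[, 1],
                        lo95 = theta_q[, 2], hi95 = theta_q[, 3])
  fitted_mu <- fit$E * theta_q[, 1]
  resid <- (fit$O - fitted_mu) / sqrt(fitted_mu)
  moran <- morans_i(resid, fit$W, seed = moran_seed)
  ll_pooled <- do.call(rbind, lapply(fit$chains, `[[`, "loglik"))
  structure(list(
    rr = rr_tab,
    psrf = psrf_all(fit),
    waic = waic(ll_pooled)$waic,
    waic_by_chain = vapply(fit$chains, function(ch) waic(ch$loglik)$waic, 0),
    moran = moran,
    smr = smr_tab,
    tau2 = qs(draws[, "tau2"]),
    rho = qs(draws[, "rho"]),
    acceptance = lapply(fit$chains, `[[`, "acceptance")
  ), class = "car_summary")
}

#' @export
print.car_summary <- function(x, ...) {
  cat("Leroux CAR Poisson posterior summary\n")
  if (nrow(x$rr)) {
    cat("Relative risk per SD (posterior median, 95% Cr):\n")
    print(transform(x$rr, RR = round(RR, 3), lo95 = round(lo95, 3),
                    hi95 = round(hi95, 3)), row.names = FALSE)
  }
  cat(sprintf("tau2 %.3f (%.3f-%.3f), rho %.3f (%.3f-%.3f)\n",
              x$tau2[1], x$tau2[2], x$tau2[3],
              x$rho[1], x$rho[2], x$rho[3]))
  cat(sprintf("WAIC %.1f (chain 1: %.1f); max R-hat %.3f\n",
              x$waic, x$waic_by_chain[1], max(x$psrf)))
  cat(sprintf("Residual Moran's I %.3f (null %.3f, permutation p %.3f)\n",
              x$moran$I, x$moran$expectation, x$moran$p_value))
  invisible(x)
}
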