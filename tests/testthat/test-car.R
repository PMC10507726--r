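short_cfg <- function(...) car_config(n_chains = 2, n_iter = 3000,
                                      burn_in = 1000, thin = 5, seed = 1,
                                      ...)

test_that("retention bookkeeping is exact", {
  expect_equal(length(mcmc_retention(520000, 20000, 100)), 5000)
  kept <- mcmc_retention(1000, 200, 8)
  expect_equal(kept[1], 208)
  expect_equal(length(kept), 100)
  expect_error(car_config(n_iter = 1000, burn_in = 200, thin = 7),
               "divisible")
  expect_error(car_config(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("covariate standardization is exact and reversible", {
  set.seed(13)
  X <- cbind(a = rnorm(60, 5, 4), b = runif(60))
  s <- standardize_covariates(X)
  expect_equal(unname(colMeans(s$X_std)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s$X_std, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize_covariates(s$X_std)$X_std, s$X_std,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_covariates(cbind(c = rep(2, 10))), "c")
  # reparametrization: coefficients on the standardized scale are sd times
  # the raw-scale coefficients (same fitted model)
  E <- runif(60, 20, 60)
  O <- rpois(60, E * exp(0.05 * (X[, 1] - 5)))
  raw <- suppressWarnings(fit_nb_glm(O, E, X))
  std <- suppressWarnings(fit_nb_glm(O, E, s$X_std))
  expect_equal(unname(std$coefficients[-1]),
               unname(raw$coefficients[-1] * s$sds), tolerance = 1e-6)
})

test_that("Leroux log determinant matches dense-matrix oracles", {
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  lam2 <- laplacian_eigenvalues(W2)
  expect_equal(sort(lam2), c(0, 2))
  expect_equal(leroux_logdet(0.5, lam2), log(0.5) + log(1.5))
  expect_equal(leroux_logdet(0, lam2), 0)
  expect_equal(leroux_logdet(1, lam2), -Inf)
  W <- queen_adjacency(4, 5)
  lam <- laplacian_eigenvalues(W)
  for (rho in c(0, 0.17, 0.5, 0.83, 0.999)) {
    dense <- determinant(leroux_precision(W, rho, 1), logarithm = TRUE)
    expect_lt(abs(leroux_logdet(rho, lam) - as.numeric(dense$modulus)),
              1e-10)
  }
})

test_that("the conjugate update's inverse-gamma primitive is calibrated", {
  # full-conditional example: shape 1 + n/2 with n = 2, scale 0.01 + 4/2
  set.seed(14)
  draws <- rinvgamma(100000, shape = 2, scale = 2.01)
  # quantiles of IG(a, b): b / qgamma(1 - p, a)
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(quantile(draws, p)),
                 2.01 / qgamma(1 - p, 2), tolerance = 0.02)
  }
  expect_error(rinvgamma(10, -1, 1), "positive")
})

test_that("PSRF matches its direct formula and flags divergence", {
  n <- 50
  same <- list(sin(1:n), sin(1:n))
  expect_equal(psrf(same), sqrt((n - 1) / n))
  far <- list(rnorm(n, 0, 0.01), rnorm(n, 100, 0.01))
  expect_gt(psrf(far), 1.1)
  set.seed(15)
  chains <- lapply(1:3, function(i) rnorm(200))
  expect_lt(abs(psrf(chains) - oracle_psrf(chains)), 1e-10)
  expect_error(psrf(list(1:10)), "two chains")
})

test_that("WAIC matches direct arithmetic", {
  ll <- matrix(c(-1.2, -0.8, -1.0, -2.0, -2.2, -1.9), 3, 2)
  w <- waic(ll)
  expect_lt(abs(w$waic - oracle_waic(ll)), 1e-10)
  lppd_hand <- log(mean(exp(ll[, 1]))) + log(mean(exp(ll[, 2])))
  expect_equal(w$lppd, lppd_hand, tolerance = 1e-12)
  expect_warning(w1 <- waic(ll[1, , drop = FALSE]), "single draw")
  expect_equal(w1$waic, -2 * sum(ll[1, ]))
  expect_equal(waic(ll[c(1, 1, 1), ])$waic, w1$waic)
})

test_that("sampler bookkeeping, reproducibility and identifiability hold", {
  d <- sim_lattice(6, generative_truth(0, c(0.2), 0.5, 0.3, seed = 21),
                   seed = 22)
  cfg <- short_cfg()
  fit <- fit_car(d$O, d$E, d$X, d$W, cfg)
  expect_equal(nrow(fit$chains[[1]]$draws),
               length(mcmc_retention(cfg$n_iter, cfg$burn_in, cfg$thin)))
  expect_equal(fit$chains[[1]]$n_retained, 400)
  # sum-to-zero recentring: every retained field draw sums to zero
  expect_lt(max(abs(rowSums(fit$chains[[1]]$psi))), 1e-10)
  # fixed seed gives bit-identical chains
  fit2 <- fit_car(d$O, d$E, d$X, d$W, cfg)
  expect_identical(fit$chains, fit2$chains)
  # rho draws respect the unit interval, tau2 positive
  dr <- pooled_draws(fit)
  expect_true(all(dr[, "rho"] >= 0 & dr[, "rho"] <= 1))
  expect_true(all(dr[, "tau2"] > 0))
})

test_that("posterior summaries are quantile-exact and coherent", {
  d <- sim_lattice(6, generative_truth(0.1, c(0.3), 0.4, 0.2, seed = 23),
                   seed = 24)
  fit <- fit_car(d$O, d$E, d$X, d$W, short_cfg())
  sm <- summarize_car(fit)
  # RR quantiles match a sort-based oracle on the pooled draws
  b <- exp(pooled_draws(fit)[, "x1"])
  expect_equal(sm$rr$RR, unname(quantile(b, 0.5)))
  expect_equal(sm$rr$lo95, unname(quantile(b, 0.025)))
  expect_true(sm$rr$lo95 <= sm$rr$RR & sm$rr$RR <= sm$rr$hi95)
  # model-based SMR median equals the median of the theta draws
  theta1 <- exp(do.call(rbind, lapply(fit$chains, function(ch)
    ch$draws[, "alpha"] + ch$draws[, "x1"] %*% t(fit$X) + ch$psi))[, 1])
  expect_equal(sm$smr$smr_median[1], unname(median(theta1)))
  expect_true(all(sm$smr$lo95 <= sm$smr$smr_median &
                    sm$smr$smr_median <= sm$smr$hi95))
})

test_that("beta draws at zero give unit relative risk", {
  d <- sim_lattice(5, generative_truth(0, c(0), 0.3, 0.2, seed = 25),
                   seed = 26)
  fit <- fit_car(d$O, d$E, d$X, d$W, short_cfg())
  fit$chains <- lapply(fit$chains, function(ch) {
    ch$draws[, "x1"] <- 0; ch
  })
  sm <- summarize_car(fit)
  expect_equal(sm$rr$RR, 1)
  expect_equal(sm$rr$lo95, 1)
  expect_equal(sm$rr$hi95, 1)
})

test_that("with rho fixed at zero the fit matches an exchangeable-effects
           Poisson-lognormal model", {
  skip_if_not_installed("lme4")
  d <- sim_lattice(10, generative_truth(0.2, c(0.25), 0, 0.2, seed = 27),
                   seed = 28)
  cfg <- car_config(n_chains = 2, n_iter = 6000, burn_in = 1000, thin = 5,
                    seed = 2, fix_rho = 0)
  fit <- fit_car(d$O, d$E, d$X, d$W, cfg)
  dr <- pooled_draws(fit)
  df <- data.frame(O = d$O, x = d$X[, 1], id = seq_along(d$O),
                   logE = log(d$E))
  gl <- lme4::glmer(O ~ x + (1 | id) + offset(logE), data = df,
                    family = stats::poisson)
  ct <- coef(summary(gl))
  est <- ct[, "Estimate"]
  se <- ct[, "Std. Error"]
  expect_lt(abs(median(dr[, "alpha"]) - est[1]), 4 * se[1] + 0.05)
  expect_lt(abs(median(dr[, "x1"]) - est[2]), 4 * se[2] + 0.05)
})
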