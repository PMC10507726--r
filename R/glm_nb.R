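#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` comes from the least-squares
#' regression of column `k` on the remaining columns plus an intercept.
#' Perfect collinearity is reported as `Inf`.
#'
#' @param X numeric covariate matrix or data frame (no intercept column).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more rows than covariates", call. = FALSE)
  if (p < 2) return(stats::setNames(rep(1, p), colnames(X)))
  sapply(seq_len(p), function(k) {
    y <- X[, k]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) stop("column ", colnames(X)[k], " has zero variance",
                       call. = FALSE)
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }) |> stats::setNames(colnames(X))
}

#' Iterative VIF-based covariate screening
#'
#' While any VIF exceeds the threshold, removes the covariate with the
#' largest VIF (ties broken by column order) and recomputes. Mirrors the
#' multicollinearity screen applied before the ecological regressions, where
#' compositional industry shares force one share out.
#'
#' @param X covariate matrix or data frame.
#' @param threshold VIF above which a covariate is excluded (default 5).
#' @return list with `X` (retained columns), `removed` (character, in
#'   removal order) and `log` (data frame of each removal with its VIF).
#' @export
screen_covariates <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  removed <- character(0)
  log <- data.frame(step = integer(0), removed = character(0),
                    vif = numeric(0))
  repeat {
    v <- vif(X)
    if (max(v) <= threshold) break
    worst <- names(v)[which.max(v)]   # which.max takes the first on ties
    log <- rbind(log, data.frame(step = length(removed) + 1L,
                                 removed = worst, vif = v[[worst]]))
    removed <- c(removed, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  list(X = X, removed = removed, log = log)
}

#' Non-spatial negative-binomial regression with an offset
#'
#' Fits `O_i ~ NB(r, E_i * theta_i)` with `log theta_i = alpha + X_i beta`
#' and offset `log E_i`, by maximum likelihood (NB2 parametrization,
#' variance `mu + mu^2 / r`). Returns Wald 95% confidence intervals,
#' p-values, the dispersion `r`, Pearson residuals, and the design VIFs.
#'
#' @param O observed counts.
#' @param E expected deaths (offset), > 0.
#' @param X standardized covariate matrix (see [standardize_covariates()]),
#'   or NULL for an intercept-only fit.
#' @return object of class `nb_glm_fit`.
#' @export
fit_nb_glm <- function(O, E, X = NULL) {
  if (any(E <= 0)) stop("offset expected deaths must be positive", call. = FALSE)
  df <- data.frame(O = O, logE = log(E))
  if (!is.null(X)) {
    X <- as.matrix(X)
    df <- cbind(df, as.data.frame(X))
    form <- stats::reformulate(c(colnames(X), "offset(logE)"), response = "O")
  } else {
    form <- O ~ offset(logE)
  }
  fit <- MASS::glm.nb(form, data = df)
  if (!fit$converged) stop("negative-binomial fit did not converge after ",
                           fit$iter, " iterations", call. = FALSE)
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  mu <- stats::fitted(fit)
  r <- fit$theta
  out <- list(
    coefficients = est,
    se = se,
    ci = cbind(lo95 = est - 1.96 * se, hi95 = est + 1.96 * se),
    p_values = 2 * stats::pnorm(-abs(z)),
    dispersion = r,
    residuals = (O - mu) / sqrt(mu + mu^2 / r),
    vif_table = if (!is.null(X) && ncol(X) >= 2) vif(X) else NULL,
    model = fit
  )
  class(out) <- "nb_glm_fit"
  out
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat("Negative-binomial regression (offset log E), dispersion r =",
      format(x$dispersion, digits = 4), "\n")
  tab <- cbind(coef = x$coefficients, x$ci, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation,
#' `I = (n / S0) * (sum_il w_il z_i z_l) / (sum_i z_i^2)` with centred values
#' `z` and `S0 = sum_il w_il`. Significance comes from random permutations of
#' the values over locations (two-sided); the analytic null expectation
#' `-1/(n-1)` is reported alongside.
#'
#' @param values numeric vector with positive variance.
#' @param W binary adjacency matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed permutation seed.
#' @return list with `I`, `expectation`, `p_value`, `n_perm`.
#' @export
morans_i <- function(values, W, n_perm = 999, seed = 1L) {
  validate_adjacency(W)
  n <- length(values)
  stopifnot(nrow(W) == n)
  if (stats::var(values) == 0)
    stop("Moran's I undefined for constant values", call. = FALSE)
  s0 <- sum(W)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * drop(crossprod(zc, W %*% zc)) / sum(zc^2)
  }
  I <- stat(values)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(values)))
  p_hi <- (1 + sum(perm >= I)) / (n_perm + 1)
  p_lo <- (1 + sum(perm <= I)) / (n_perm + 1)
  list(I = I, expectation = -1 / (n - 1),
       p_value = min(1, 2 * min(p_hi, p_lo)), n_perm = n_perm)
}
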