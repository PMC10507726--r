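#' Ground-truth parameters for simulated death counts
#'
#' @param alpha intercept on the log relative-risk scale.
#' @param beta covariate effects (log relative risk per covariate unit).
#' @param rho spatial dependence of the Leroux random field, in \[0, 1\].
#' @param tau2 marginal variance parameter of the random field, > 0.
#' @param seed integer seed.
#' @return a `generative_truth` list.
#' @export
generative_truth <- function(alpha = 0, beta = numeric(0), rho = 0.6,
                             tau2 = 0.25, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (tau2 <= 0) stop("tau2 must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = as.numeric(beta), rho = rho,
                 tau2 = tau2, seed = as.integer(seed)),
            class = "generative_truth")
}

#' Leroux precision matrix
#'
#' `Q(rho, tau2) = (1/tau2) * (rho * (D_w - W) + (1 - rho) * I)` where `D_w`
#' is the diagonal of row sums of the binary adjacency `W`. Interpolates
#' between independence (`rho = 0`) and the intrinsic autoregression
#' (`rho = 1`, singular on any connected graph).
#'
#' @param W binary adjacency matrix.
#' @param rho spatial dependence in \[0, 1\].
#' @param tau2 variance parameter, > 0.
#' @return dense precision matrix.
#' @export
leroux_precision <- function(W, rho, tau2 = 1) {
  validate_adjacency(W)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (tau2 <= 0) stop("tau2 must be positive", call. = FALSE)
  L <- diag(rowSums(W)) - W
  (rho * L + (1 - rho) * diag(nrow(W))) / tau2
}

#' Sample the zero-mean Leroux Gaussian Markov random field
#'
#' Draws exact samples by Cholesky factorization of the precision matrix:
#' with `Q = R'R` (R upper triangular), `psi = R^{-1} z`, `z ~ N(0, I)`, has
#' covariance `Q^{-1}`.
#'
#' @param n number of draws.
#' @param W binary adjacency matrix.
#' @param rho,tau2 field parameters.
#' @return matrix of draws, `n` x `nrow(W)`.
#' @export
sample_leroux <- function(n, W, rho, tau2) {
  Q <- leroux_precision(W, rho, tau2)
  if (rho == 1)
    stop("Leroux precision is singular at rho = 1: the graph Laplacian ",
         "always has a zero eigenvalue, so the intrinsic limit is improper",
         call. = FALSE)
  R <- chol(Q)
  z <- matrix(stats::rnorm(n * nrow(W)), nrow(W), n)
  t(backsolve(R, z))
}

#' Simulate observed death counts from the spatial generative model
#'
#' Draws the spatial random effect `psi` from the Leroux field, then
#' `O_i ~ Poisson(E_i * exp(alpha + X_i beta + psi_i))`.
#'
#' @param E positive expected deaths per area.
#' @param X covariate matrix (or NULL when `truth$beta` is empty).
#' @param W binary adjacency matrix.
#' @param truth a [generative_truth()]; its `seed` is used.
#' @return list with integer counts `O`, the latent `psi`, and the relative
#'   risks `theta`.
#' @export
simulate_deaths <- function(E, X, W, truth) {
  stopifnot(inherits(truth, "generative_truth"))
  if (any(E <= 0)) stop("expected deaths must be positive", call. = FALSE)
  p <- length(truth$beta)
  if (p > 0) {
    X <- as.matrix(X)
    if (ncol(X) != p)
      stop("covariate columns must match length of truth$beta", call. = FALSE)
    if (nrow(X) != length(E)) stop("X rows must match length(E)", call. = FALSE)
  }
  set.seed(truth$seed)
  psi <- drop(sample_leroux(1, W, truth$rho, truth$tau2))
  eta <- truth$alpha + psi
  if (p > 0) eta <- eta + drop(X %*% truth$beta)
  theta <- exp(eta)
  list(O = stats::rpois(length(E), E * theta), psi = psi, theta = theta)
}

#' Split total simulated deaths into sexes
#'
#' Allocates each area's deaths binomially with probability proportional to
#' the sex-specific expected deaths, the natural thinning when the relative
#' risk is shared across sexes.
#'
#' @param O total deaths per area.
#' @param E_men,E_women sex-specific expected deaths.
#' @param seed integer seed.
#' @return data frame (O_men, O_women).
#' @export
split_deaths_by_sex <- function(O, E_men, E_women, seed = 1L) {
  set.seed(seed)
  pm <- E_men / (E_men + E_women)
  O_men <- stats::rbinom(length(O), O, pm)
  data.frame(O_men = O_men, O_women = O - O_men)
}
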