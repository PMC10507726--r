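# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive double loops / direct formulas,
# not the package's vectorized paths.

# worked two-mesh / one-hospital instance: D = {100, 300} at 10 and 20
# minutes from a single hospital with 2 specialists, one municipality
worked_example <- function() {
  list(
    meshes = data.frame(mesh_id = 1:2, mun_id = 1L, x_km = c(0, 0),
                        y_km = c(0, 0), demand = c(100L, 300L)),
    hospitals = data.frame(hospital_id = 1L, x_km = 0, y_km = 0,
                           supply = 2L),
    tt = matrix(c(10, 20), 2, 1)
  )
}

# naive 2SFCA: double loop over meshes and hospitals
brute_2sfca <- function(D, S, tt, beta = 0.07, d0 = 120) {
  n <- length(D); m <- length(S)
  f <- function(d) if (d < d0) exp(-beta * d) else 0
  r <- numeric(m)
  for (j in seq_len(m)) {
    den <- 0
    for (i in seq_len(n)) den <- den + D[i] * f(tt[i, j])
    r[j] <- S[j] / den
  }
  A <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) A[i] <- A[i] + r[j] * f(tt[i, j])
  }
  list(r = r, A = A)
}

# naive Moran's I: explicit double sum
brute_moran <- function(x, W) {
  n <- length(x); z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (l in seq_len(n)) num <- num + W[i, l] * z[i] * z[l]
  (n / sum(W)) * num / sum(z^2)
}

# direct-formula Gelman-Rubin R-hat
oracle_psrf <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  means <- sapply(chains, mean)
  Wv <- mean(sapply(chains, var))
  B <- n * sum((means - mean(means))^2) / (m - 1)
  sqrt((n - 1) / n + B / (n * Wv))
}

# direct-formula WAIC from a loglik matrix (draws x observations)
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  -2 * (lppd - p)
}

# lattice landscape where every hospital reaches every mesh well inside the
# catchment (used for the conservation property)
tight_landscape <- function(seed) {
  lc <- landscape_config(grid_side = 8, block_side = 4,
                         n_hospitals = sample(2:5, 1),
                         mesh_spacing_km = 2, speed_kmh = 60, seed = seed)
  land <- gen_landscape(lc)
  land$tt <- gen_travel_times(land$meshes, land$hospitals, lc)
  land
}

# simulated lattice dataset from the generative model (areas = lattice cells)
sim_lattice <- function(side, truth, seed, p = length(truth$beta)) {
  W <- queen_adjacency(side, side)
  n <- side^2
  set.seed(seed)
  E <- runif(n, 20, 60)
  X <- if (p > 0)
    matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  else NULL
  sim <- simulate_deaths(E, X, W, truth)
  list(W = W, E = E, X = X, O = sim$O, psi = sim$psi)
}
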