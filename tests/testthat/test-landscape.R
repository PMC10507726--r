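test_that("block municipalities get complete queen adjacency on a 2x2 layout", {
  land <- gen_landscape(landscape_config(grid_side = 4, block_side = 2,
                                         n_hospitals = 2, seed = 1))
  expect_equal(length(unique(land$meshes$mun_id)), 4)
  expect_equal(unname(rowSums(land$adjacency)), rep(3, 4))
})

test_that("degenerate and invalid landscape configurations are rejected", {
  expect_error(gen_landscape(landscape_config(grid_side = 2, block_side = 2,
                                              n_hospitals = 1)),
               "at least one adjacency")
  expect_error(landscape_config(grid_side = 10, block_side = 3),
               "multiple of block_side")
  expect_error(landscape_config(n_hospitals = 0), "n_hospitals")
  expect_error(landscape_config(speed_kmh = 0), "speed")
})

test_that("landscape generation is deterministic under a fixed seed", {
  a <- gen_landscape(landscape_config(grid_side = 20, block_side = 4, seed = 7))
  b <- gen_landscape(landscape_config(grid_side = 20, block_side = 4, seed = 7))
  expect_identical(a, b)
})

test_that("adjacency invariants hold across generated landscapes", {
  for (seed in 1:10) {
    land <- gen_landscape(landscape_config(
      grid_side = 12, block_side = sample(c(2, 3, 4), 1),
      n_hospitals = 3, seed = seed))
    W <- land$adjacency
    expect_true(all(W %in% c(0, 1)))
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(rowSums(W) >= 1))
    expect_silent(validate_adjacency(W))
  }
  expect_error(validate_adjacency(matrix(c(0, 1, 1, 1), 2, 2)), "diagonal")
  expect_error(validate_adjacency(diag(0, 3)), "neighbour")
})

test_that("travel times are Euclidean minutes at the configured speed", {
  meshes <- data.frame(x_km = c(0, 30), y_km = c(0, 0))
  hospitals <- data.frame(x_km = 0, y_km = 0)
  tt <- gen_travel_times(meshes, hospitals,
                         landscape_config(speed_kmh = 60))
  expect_equal(dim(tt), c(2, 1))
  expect_equal(tt[1, 1], 0)
  expect_equal(tt[2, 1], 30)
  expect_true(all(is.finite(tt)) && all(tt >= 0))
})

test_that("population tables have 2 sexes x 17 bands and preserve 65+ demand", {
  land <- gen_landscape(landscape_config(grid_side = 8, block_side = 4,
                                         seed = 2))
  pop <- gen_population_table(land$meshes, seed = 5)
  expect_equal(nrow(pop), 4 * 2 * 17)
  expect_setequal(unique(pop$age_band),
                  c(paste(seq(0, 75, 5), seq(4, 79, 5), sep = "-"), "80+"))
  expect_true(all(pop$count >= 0 & pop$count == round(pop$count)))
  eld <- pop[pop$age_band %in% c("65-69", "70-74", "75-79", "80+"), ]
  got <- tapply(eld$count, eld$mun_id, sum)
  want <- tapply(land$meshes$demand, land$meshes$mun_id, sum)
  expect_equal(as.numeric(got), as.numeric(want[names(got)]))
  expect_identical(pop, gen_population_table(land$meshes, seed = 5))
})

test_that("an all-zero municipality yields an all-zero population table", {
  meshes <- data.frame(mesh_id = 1:4, mun_id = rep(1:2, each = 2),
                       x_km = 0, y_km = 0, demand = c(0L, 0L, 5L, 7L))
  pop <- gen_population_table(meshes, seed = 1)
  expect_true(all(pop$count[pop$mun_id == 1] == 0))
})

test_that("reference rates are valid probabilities, nondecreasing in age", {
  rates <- gen_reference_rates(seed = 3)
  expect_true(all(rates$rate >= 0 & rates$rate <= 1))
  for (s in c("men", "women")) {
    r <- rates$rate[rates$sex == s]
    expect_true(all(diff(r) >= 0))
    expect_gte(r[17], r[9])  # 80+ at least the 40-44 rate
  }
  expect_identical(rates, gen_reference_rates(seed = 3))
})

test_that("covariate generator produces compositional industry shares", {
  covs <- gen_covariates(200, seed = 4)
  tot <- covs$primary_share + covs$secondary_share + covs$tertiary_share
  expect_true(all(abs(tot - 100) <= 1.5))  # 3 x uniform(-0.5, 0.5) noise
  expect_true(all(covs$physicians_per10k > 0))
})

test_that("degenerate random effect recovers the Poisson offset mean", {
  W <- queen_adjacency(4, 4)
  E <- rep(c(20, 40), 8)
  sims <- sapply(1:1000, function(k) {
    simulate_deaths(E, NULL, W,
                    generative_truth(0, numeric(0), 0.5, 1e-12, seed = k))$O
  })
  mo <- rowMeans(sims)
  se <- sqrt(E / 1000)
  expect_true(all(abs(mo - E) < 4 * se))
})

test_that("rho = 0 gives i.i.d. fields with variance tau2", {
  W <- queen_adjacency(10, 10)
  set.seed(42)
  psi <- sample_leroux(100, W, rho = 0, tau2 = 0.25)  # 10,000 values
  expect_equal(var(as.vector(psi)), 0.25, tolerance = 0.05)
  expect_lt(abs(mean(psi)), 0.02)
})

test_that("field draws reproduce the analytic Leroux covariance", {
  W <- queen_adjacency(4, 4)
  Q <- leroux_precision(W, rho = 0.6, tau2 = 0.25)
  set.seed(9)
  psi <- sample_leroux(20000, W, rho = 0.6, tau2 = 0.25)
  emp <- cov(psi)
  expect_lt(max(abs(emp - solve(Q))), 0.02)
})

test_that("the intrinsic limit on a connected graph is singular", {
  W <- queen_adjacency(3, 3)
  expect_error(sample_leroux(1, W, rho = 1, tau2 = 1), "singular")
})

test_that("death simulation is bit-reproducible and integer-valued", {
  W <- queen_adjacency(5, 5)
  E <- runif(25, 10, 50)
  X <- matrix(rnorm(50), 25, 2)
  truth <- generative_truth(0.1, c(0.2, -0.1), 0.4, 0.3, seed = 11)
  a <- simulate_deaths(E, X, W, truth)
  b <- simulate_deaths(E, X, W, truth)
  expect_identical(a, b)
  expect_true(all(a$O >= 0 & a$O == round(a$O)))
  expect_error(simulate_deaths(c(-1, E[-1]), X, W, truth), "positive")
  expect_error(simulate_deaths(E, X[, 1, drop = FALSE], W, truth), "match")
})
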