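#' Configuration for a synthetic study landscape
#'
#' Describes a square mesh grid partitioned into square-block municipalities,
#' with hospitals dropped at random mesh locations. The defaults span travel
#' times from a few minutes up to beyond the 120-minute catchment used for
#' accessibility, so that both well-served and under-served municipalities
#' arise, which is the regime the accessibility analysis is about.
#'
#' @param grid_side meshes per side of the square grid.
#' @param block_side meshes per side of one (square) municipality block;
#'   must divide `grid_side`.
#' @param n_hospitals number of hospital sites (distinct mesh locations).
#' @param mesh_spacing_km centre-to-centre mesh spacing in km.
#' @param speed_kmh assumed straight-line travel speed in km/h.
#' @param pop_lognormal_mu,pop_lognormal_sigma log-scale mean and sd of the
#'   per-mesh population aged 65+ (the demand population).
#' @param seed integer seed for reproducibility.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(grid_side = 20, block_side = 4, n_hospitals = 5,
                             mesh_spacing_km = 6, speed_kmh = 40,
                             pop_lognormal_mu = log(50),
                             pop_lognormal_sigma = 1,
                             seed = 1L) {
  if (grid_side < 1 || block_side < 1 || grid_side %% block_side != 0)
    stop("grid_side must be a positive multiple of block_side", call. = FALSE)
  if (n_hospitals < 1 || n_hospitals > grid_side^2)
    stop("n_hospitals must be between 1 and grid_side^2", call. = FALSE)
  if (mesh_spacing_km <= 0) stop("mesh_spacing_km must be positive", call. = FALSE)
  if (speed_kmh <= 0) stop("speed_kmh must be positive", call. = FALSE)
  structure(list(grid_side = as.integer(grid_side),
                 block_side = as.integer(block_side),
                 n_hospitals = as.integer(n_hospitals),
                 mesh_spacing_km = mesh_spacing_km,
                 speed_kmh = speed_kmh,
                 pop_lognormal_mu = pop_lognormal_mu,
                 pop_lognormal_sigma = pop_lognormal_sigma,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Queen-contiguity adjacency matrix of a rectangular lattice
#'
#' Cells sharing an edge or a corner are neighbours. Row/column order is
#' row-major (cell `(r, c)` has index `(r - 1) * ncol + c`).
#'
#' @param nrow,ncol lattice dimensions.
#' @return binary symmetric matrix with zero diagonal.
#' @export
queen_adjacency <- function(nrow, ncol = nrow) {
  n <- nrow * ncol
  if (n < 1) stop("empty lattice", call. = FALSE)
  W <- matrix(0L, n, n)
  idx <- function(r, c) (r - 1L) * ncol + c
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      i <- idx(r, c)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nrow && c2 >= 1 && c2 <= ncol)
          W[i, idx(r2, c2)] <- 1L
      }
    }
  }
  W
}

#' Validate an areal adjacency structure
#'
#' Checks the invariants the spatial model relies on: binary entries,
#' symmetry, zero diagonal, and no isolated areas (every area needs at least
#' one neighbour for the conditional autoregression to be defined on it).
#'
#' @param W candidate adjacency matrix.
#' @return `W` invisibly, or an error.
#' @export
validate_adjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (!all(W %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  if (any(W != t(W))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (any(rowSums(W) < 1))
    stop("every area must have at least one neighbour", call. = FALSE)
  invisible(W)
}

#' Generate a synthetic mesh/hospital landscape
#'
#' Mesh demand populations (persons aged 65+) are drawn log-normal and
#' rounded; municipalities are contiguous square blocks of meshes on a
#' lattice with queen adjacency between blocks; hospitals sit at distinct
#' random meshes with a neurointerventionalist count of `1 + Poisson(2)`.
#'
#' @param config a [landscape_config()].
#' @return list with `meshes` (mesh_id, mun_id, x_km, y_km, demand),
#'   `hospitals` (hospital_id, x_km, y_km, supply), and `adjacency`
#'   (municipality-level queen matrix).
#' @export
gen_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid_side; b <- config$block_side
  nb_side <- g %/% b
  if (nb_side^2 < 2)
    stop("landscape has a single municipality with no neighbour; ",
         "every areal unit must have at least one adjacency", call. = FALSE)
  set.seed(config$seed)
  n_mesh <- g^2
  row <- rep(seq_len(g), each = g)
  col <- rep(seq_len(g), times = g)
  mun_row <- (row - 1L) %/% b + 1L
  mun_col <- (col - 1L) %/% b + 1L
  mun_id <- (mun_row - 1L) * nb_side + mun_col
  demand <- as.integer(round(stats::rlnorm(n_mesh, config$pop_lognormal_mu,
                                           config$pop_lognormal_sigma)))
  meshes <- data.frame(
    mesh_id = seq_len(n_mesh),
    mun_id = mun_id,
    x_km = (col - 0.5) * config$mesh_spacing_km,
    y_km = (row - 0.5) * config$mesh_spacing_km,
    demand = demand
  )
  hosp_mesh <- sample.int(n_mesh, config$n_hospitals)
  hospitals <- data.frame(
    hospital_id = seq_len(config$n_hospitals),
    x_km = meshes$x_km[hosp_mesh],
    y_km = meshes$y_km[hosp_mesh],
    supply = 1L + stats::rpois(config$n_hospitals, 2)
  )
  W <- queen_adjacency(nb_side, nb_side)
  validate_adjacency(W)
  list(meshes = meshes, hospitals = hospitals, adjacency = W)
}

#' Straight-line travel-time matrix
#'
#' Minutes of travel between every mesh and every hospital, from Euclidean
#' distance at a constant speed. Stands in for network travel times; the
#' accessibility functions only require a nonnegative finite matrix.
#'
#' @param meshes,hospitals data frames with `x_km`, `y_km` columns.
#' @param config a [landscape_config()] (supplies `speed_kmh`).
#' @return matrix of minutes, `nrow(meshes)` x `nrow(hospitals)`.
#' @export
gen_travel_times <- function(meshes, hospitals, config = landscape_config()) {
  if (config$speed_kmh <= 0) stop("speed must be positive", call. = FALSE)
  dx <- outer(meshes$x_km, hospitals$x_km, "-")
  dy <- outer(meshes$y_km, hospitals$y_km, "-")
  tt <- 60 * sqrt(dx^2 + dy^2) / config$speed_kmh
  dimnames(tt) <- list(meshes$mesh_id, hospitals$hospital_id)
  tt
}

# age-band labels shared by the population and rate tables
age_bands <- function() {
  c(paste(seq(0, 75, 5), seq(4, 79, 5), sep = "-"), "80+")
}
elderly_bands <- function() c("65-69", "70-74", "75-79", "80+")

#' Generate sex x age-band population tables per municipality
#'
#' Seventeen five-year age bands (0-4 ... 75-79, 80+) by two sexes. The total
#' across the 65+ bands equals the municipality's summed mesh demand exactly
#' (a multinomial split preserves the total); younger bands are filled with a
#' plausible declining-with-age pyramid so the 65+ share is around 30%.
#'
#' @param meshes mesh table with `mun_id` and `demand` columns.
#' @param seed integer seed.
#' @return data frame (mun_id, sex, age_band, count), sexes `"men"`/`"women"`.
#' @export
gen_population_table <- function(meshes, seed = 1L) {
  set.seed(seed)
  bands <- age_bands()
  eb <- elderly_bands()
  demand65 <- tapply(meshes$demand, meshes$mun_id, sum)
  mun_ids <- as.integer(names(demand65))
  # elderly split: men slightly fewer, counts decline with age
  eld_prob <- c(men = 0.45, women = 0.55)
  band_prob <- c(0.35, 0.30, 0.20, 0.15)
  cell_prob <- as.vector(outer(band_prob, eld_prob))  # 8 cells, sums to 1
  out <- vector("list", length(mun_ids))
  young <- setdiff(bands, eb)
  for (k in seq_along(mun_ids)) {
    tot <- demand65[[k]]
    eld <- if (tot > 0) as.vector(stats::rmultinom(1, tot, cell_prob))
           else integer(8)
    # younger bands: scale to elderly total, mild decline with age band index
    base <- if (tot > 0) tot * 2.3 / length(young) else 0
    yw <- stats::rpois(2 * length(young), base * rep(c(0.95, 1.05),
                                                     each = length(young)))
    if (tot == 0) yw <- integer(2 * length(young))
    out[[k]] <- data.frame(
      mun_id = mun_ids[k],
      sex = rep(c("men", "women"), each = length(bands)),
      age_band = rep(bands, 2),
      count = c(yw[seq_along(young)], eld[1:4],
                yw[length(young) + seq_along(young)], eld[5:8])
    )
  }
  do.call(rbind, out)
}

#' Generate national reference mortality rates by sex and age band
#'
#' Stroke-type mortality rises steeply with age; the rates follow an
#' exponential age gradient with a male excess and small multiplicative
#' jitter, forced nondecreasing within sex and clipped to [0, 1].
#'
#' @param seed integer seed.
#' @return data frame (sex, age_band, rate).
#' @export
gen_reference_rates <- function(seed = 1L) {
  set.seed(seed)
  bands <- age_bands()
  mid <- c(seq(2.5, 77.5, 5), 85)
  out <- lapply(c(men = 1.15, women = 0.85), function(mult) {
    r <- 4e-6 * mult * exp(0.085 * mid) *
      exp(stats::rnorm(length(mid), 0, 0.05))
    pmin(cummax(r), 1)
  })
  data.frame(sex = rep(c("men", "women"), each = length(bands)),
             age_band = rep(bands, 2),
             rate = c(out$men, out$women))
}

#' Generate municipality covariates
#'
#' Emulates the covariate structure of the ecological regression: three
#' compositional industry shares (primary/secondary/tertiary) drawn from a
#' Dirichlet and scaled to sum 100, perturbed by independent uniform
#' rounding noise, so they carry the near-exact collinearity that motivates
#' VIF screening; an education share; and medical-resource rates per 10,000
#' population (physicians, hospitals, clinics, emergency hospitals).
#'
#' @param n_mun number of municipalities.
#' @param seed integer seed.
#' @param dirichlet_alpha shape of the industry-share Dirichlet.
#' @param noise_half_width half-width of the uniform rounding noise added to
#'   each share (percentage points).
#' @return data frame with one row per municipality.
#' @export
gen_covariates <- function(n_mun, seed = 1L,
                           dirichlet_alpha = c(2, 5, 13),
                           noise_half_width = 0.5) {
  set.seed(seed)
  sh <- matrix(stats::rgamma(n_mun * 3, shape = rep(dirichlet_alpha,
                                                    each = n_mun)),
               n_mun, 3)
  sh <- 100 * sh / rowSums(sh)
  sh <- sh + matrix(stats::runif(n_mun * 3, -noise_half_width,
                                 noise_half_width), n_mun, 3)
  data.frame(
    mun_id = seq_len(n_mun),
    physicians_per10k = stats::rlnorm(n_mun, log(15), 0.5),
    hospitals_per10k = stats::rlnorm(n_mun, log(0.6), 0.6),
    clinics_per10k = stats::rlnorm(n_mun, log(8), 0.4),
    emergency_per10k = stats::rlnorm(n_mun, log(0.35), 0.7),
    primary_share = sh[, 1],
    secondary_share = sh[, 2],
    tertiary_share = sh[, 3],
    bachelor_share = stats::rlnorm(n_mun, log(15), 0.4)
  )
}
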