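#' Exponential distance-decay weight with catchment cutoff
#'
#' `f(d) = exp(-beta * d)` for `d < d0` and exactly 0 for `d >= d0`. The
#' boundary is excluded: a trip of exactly `d0` minutes gets weight zero.
#'
#' @param d travel time in minutes (vectorized), nonnegative.
#' @param beta friction coefficient per minute (default 0.07).
#' @param d0 catchment threshold in minutes (default 120).
#' @return weights in \[0, 1\].
#' @export
decay_weight <- function(d, beta = 0.07, d0 = 120) {
  if (beta <= 0 || d0 <= 0) stop("beta and d0 must be positive", call. = FALSE)
  if (any(d < 0)) stop("travel time must be nonnegative", call. = FALSE)
  ifelse(d < d0, exp(-beta * d), 0)
}

#' Step 1 of the 2SFCA: demand-to-supply ratio per hospital
#'
#' For hospital `j`, `r_j = S_j / sum_i D_i f(d_ij)` over meshes inside the
#' catchment. Hospitals whose catchment holds no positive weighted demand
#' have an undefined ratio; they are dropped with a warning (the situation of
#' a facility unreachable from any populated mesh).
#'
#' @param meshes mesh table with `demand`.
#' @param hospitals hospital table with `supply`.
#' @param tt travel-time matrix, meshes x hospitals, minutes.
#' @param beta,d0 decay parameters.
#' @return data frame (hospital_id, supply, weighted_demand, ratio); dropped
#'   hospitals carry `ratio = NA`.
#' @export
supply_demand_ratio <- function(meshes, hospitals, tt, beta = 0.07, d0 = 120) {
  stopifnot(nrow(tt) == nrow(meshes), ncol(tt) == nrow(hospitals))
  f <- decay_weight(tt, beta, d0)
  wd <- drop(crossprod(f, meshes$demand))  # sum_i D_i f(d_ij)
  ratio <- ifelse(wd > 0, hospitals$supply / wd, NA_real_)
  if (anyNA(ratio))
    warning(sum(is.na(ratio)), " hospital(s) with empty catchment dropped: ",
            paste(hospitals$hospital_id[is.na(ratio)], collapse = ", "),
            call. = FALSE)
  data.frame(hospital_id = hospitals$hospital_id,
             supply = hospitals$supply,
             weighted_demand = wd,
             ratio = ratio)
}

#' Step 2 of the 2SFCA: accessibility index per mesh
#'
#' `A_i = sum_k r_k f(d_ik)` over hospitals inside the catchment of mesh
#' `i`. Hospitals dropped in step 1 (`ratio = NA`) contribute nothing.
#'
#' @param ratios output of [supply_demand_ratio()].
#' @param tt travel-time matrix, meshes x hospitals.
#' @param beta,d0 decay parameters.
#' @return numeric accessibility index per mesh.
#' @export
accessibility_index <- function(ratios, tt, beta = 0.07, d0 = 120) {
  stopifnot(ncol(tt) == nrow(ratios))
  f <- decay_weight(tt, beta, d0)
  r <- ifelse(is.na(ratios$ratio), 0, ratios$ratio)
  drop(f %*% r)
}

#' Population-weighted spatial accessibility index per municipality
#'
#' Demand-weighted mean of the mesh accessibility index within each
#' municipality; interpretable as providers per person aged 65+.
#' Municipalities with zero total demand get `NA`.
#'
#' @param meshes mesh table with `mun_id` and `demand`.
#' @param A mesh accessibility index from [accessibility_index()].
#' @return data frame (mun_id, pwsai).
#' @export
pwsai <- function(meshes, A) {
  stopifnot(length(A) == nrow(meshes))
  num <- tapply(meshes$demand * A, meshes$mun_id, sum)
  den <- tapply(meshes$demand, meshes$mun_id, sum)
  data.frame(mun_id = as.integer(names(den)),
             pwsai = ifelse(den > 0, num / den, NA_real_),
             row.names = NULL)
}

#' Population-weighted travel time to the nearest hospital, in hours
#'
#' `T_i` is the minimum travel time from mesh `i` over all hospitals (no
#' catchment cutoff: the nearest facility is the nearest even when far);
#' PWTT is its demand-weighted municipal mean converted from minutes to
#' hours. Zero-demand municipalities get `NA`.
#'
#' @param meshes mesh table with `mun_id` and `demand`.
#' @param tt travel-time matrix, meshes x hospitals, minutes.
#' @return data frame (mun_id, pwtt_hours).
#' @export
pwtt <- function(meshes, tt) {
  stopifnot(nrow(tt) == nrow(meshes))
  nearest <- apply(tt, 1, min)
  num <- tapply(meshes$demand * nearest, meshes$mun_id, sum)
  den <- tapply(meshes$demand, meshes$mun_id, sum)
  data.frame(mun_id = as.integer(names(den)),
             pwtt_hours = ifelse(den > 0, (num / den) / 60, NA_real_),
             row.names = NULL)
}

#' Full 2SFCA accessibility computation
#'
#' Runs both steps of the floating catchment method and aggregates to
#' municipalities.
#'
#' @param meshes,hospitals,tt as in [supply_demand_ratio()].
#' @param beta,d0 decay parameters.
#' @return list with `ratios`, `mesh_access` (mesh_id, A) and `municipal`
#'   (mun_id, pwsai, pwtt_hours).
#' @export
compute_accessibility <- function(meshes, hospitals, tt,
                                  beta = 0.07, d0 = 120) {
  ratios <- supply_demand_ratio(meshes, hospitals, tt, beta, d0)
  A <- accessibility_index(ratios, tt, beta, d0)
  municipal <- merge(pwsai(meshes, A), pwtt(meshes, tt), by = "mun_id")
  list(ratios = ratios,
       mesh_access = data.frame(mesh_id = meshes$mesh_id, A = A),
       municipal = municipal[order(municipal$mun_id), ])
}
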