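#' Read and validate a pipeline configuration
#'
#' YAML with a versioned schema; unknown top-level keys are rejected.
#' Recognized sections: `version`, `seed`, `landscape` (arguments of
#' [landscape_config()]), `decay` (`beta`, `d0`), `truth` (arguments of
#' [generative_truth()]), `mcmc` (arguments of [car_config()]), `models`
#' (arguments of [model_specs()]).
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("version", "seed", "landscape", "decay", "truth", "mcmc",
             "models")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  if (is.null(cfg$version) || cfg$version != 1)
    stop("config must declare 'version: 1'", call. = FALSE)
  cfg
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage seeds spawned from the global seed
  (seed * 97L + stage * 1009L) %% 2000000000L
}

write_stage <- function(dir, name, df) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full synthetic pipeline
#'
#' simulate -> accessibility -> standardization -> non-spatial screen ->
#' CAR model suite -> report, writing every stage's tables under `out_dir`
#' together with a manifest recording seeds and file hashes. A stage whose
#' output files already exist is skipped, so deleting only late-stage
#' outputs re-runs just those stages.
#'
#' @param config list from [read_run_config()] or built in code.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg); cat(msg, "\n", file = log_path, append = TRUE)
  }
  have <- function(...) all(file.exists(file.path(out_dir, c(...))))

  lc <- do.call(landscape_config,
                c(config$landscape %||% list(),
                  list(seed = stage_seed(seed, 1L))))
  decay <- config$decay %||% list(beta = 0.07, d0 = 120)

  # stage 1: landscape + tables -----------------------------------------
  if (!have("meshes.csv", "hospitals.csv", "ttmatrix.csv", "adjacency.csv",
            "population.csv", "rates.csv", "covariates.csv")) {
    logf("stage simulate")
    land <- gen_landscape(lc)
    tt <- gen_travel_times(land$meshes, land$hospitals, lc)
    pop <- gen_population_table(land$meshes, seed = stage_seed(seed, 2L))
    rates <- gen_reference_rates(seed = stage_seed(seed, 3L))
    n_mun <- nrow(land$adjacency)
    covs <- gen_covariates(n_mun, seed = stage_seed(seed, 4L))
    write_stage(out_dir, "meshes.csv", land$meshes)
    write_stage(out_dir, "hospitals.csv", land$hospitals)
    tt_long <- data.frame(mesh_id = rep(land$meshes$mesh_id, ncol(tt)),
                          hospital_id = rep(land$hospitals$hospital_id,
                                            each = nrow(tt)),
                          minutes = as.vector(tt))
    write_stage(out_dir, "ttmatrix.csv", tt_long)
    edges <- which(land$adjacency == 1 & upper.tri(land$adjacency),
                   arr.ind = TRUE)
    write_stage(out_dir, "adjacency.csv",
                data.frame(mun_a = edges[, 1], mun_b = edges[, 2]))
    write_stage(out_dir, "population.csv", pop)
    write_stage(out_dir, "rates.csv", rates)
    write_stage(out_dir, "covariates.csv", covs)
  } else logf("stage simulate: cached")

  meshes <- utils::read.csv(file.path(out_dir, "meshes.csv"))
  hospitals <- utils::read.csv(file.path(out_dir, "hospitals.csv"))
  tt_long <- utils::read.csv(file.path(out_dir, "ttmatrix.csv"))
  tt <- matrix(tt_long$minutes, nrow(meshes), nrow(hospitals))
  edges <- utils::read.csv(file.path(out_dir, "adjacency.csv"))
  n_mun <- length(unique(meshes$mun_id))
  W <- matrix(0L, n_mun, n_mun)
  W[cbind(edges$mun_a, edges$mun_b)] <- 1L
  W[cbind(edges$mun_b, edges$mun_a)] <- 1L
  covs <- utils::read.csv(file.path(out_dir, "covariates.csv"))

  # stage 2: accessibility ----------------------------------------------
  if (!have("access.csv", "mesh_access.csv")) {
    logf("stage access")
    acc <- compute_accessibility(meshes, hospitals, tt,
                                 beta = decay$beta, d0 = decay$d0)
    write_stage(out_dir, "access.csv", acc$municipal)
    write_stage(out_dir, "mesh_access.csv", acc$mesh_access)
  } else logf("stage access: cached")
  access <- utils::read.csv(file.path(out_dir, "access.csv"))

  # stage 3: expected deaths + simulated observed deaths ----------------
  if (!have("expected.csv", "deaths.csv", "smr_crude.csv")) {
    logf("stage expected/simulate-deaths")
    pop <- utils::read.csv(file.path(out_dir, "population.csv"))
    rates <- utils::read.csv(file.path(out_dir, "rates.csv"))
    expd <- expected_deaths(pop, rates)
    covs_all <- merge(access, covs, by = "mun_id")
    covs_all <- covs_all[order(covs_all$mun_id), ]
    tcfg <- config$truth %||% list()
    covnames <- tcfg$covariate_names %||% c("pwsai", "secondary_share")
    beta <- as.numeric(tcfg$beta %||% c(-0.1, 0.15))
    Xt <- standardize_covariates(covs_all[, covnames, drop = FALSE])$X_std
    truth <- generative_truth(alpha = tcfg$alpha %||% 0, beta = beta,
                              rho = tcfg$rho %||% 0.6,
                              tau2 = tcfg$tau2 %||% 0.25,
                              seed = stage_seed(seed, 5L))
    sim <- simulate_deaths(expd$E, Xt, W, truth)
    sexes <- split_deaths_by_sex(sim$O, expd$E_men, expd$E_women,
                                 seed = stage_seed(seed, 6L))
    deaths <- data.frame(mun_id = expd$mun_id, O = sim$O,
                         O_men = sexes$O_men, O_women = sexes$O_women)
    write_stage(out_dir, "expected.csv", expd)
    write_stage(out_dir, "deaths.csv", deaths)
    write_stage(out_dir, "smr_crude.csv",
                data.frame(mun_id = expd$mun_id,
                           smr = smr(sim$O, expd$E)))
  } else logf("stage expected: cached")
  expd <- utils::read.csv(file.path(out_dir, "expected.csv"))
  deaths <- utils::read.csv(file.path(out_dir, "deaths.csv"))

  # stage 4: non-spatial screen -----------------------------------------
  covs_all <- merge(access, covs, by = "mun_id")
  covs_all <- covs_all[order(covs_all$mun_id), ]
  covmat <- covs_all[, setdiff(colnames(covs_all), "mun_id")]
  if (!have("nonspatial_fit.csv", "moran.txt")) {
    logf("stage screen/glm")
    scr <- screen_covariates(covmat, threshold = 5)
    Xs <- standardize_covariates(scr$X)$X_std
    nb_fit <- fit_nb_glm(deaths$O, expd$E, Xs)
    mi <- morans_i(nb_fit$residuals, W, seed = stage_seed(seed, 7L))
    tab <- data.frame(term = names(nb_fit$coefficients),
                      coef = nb_fit$coefficients,
                      lo95 = nb_fit$ci[, 1], hi95 = nb_fit$ci[, 2],
                      p = nb_fit$p_values,
                      vif = c(NA, nb_fit$vif_table), row.names = NULL)
    write_stage(out_dir, "nonspatial_fit.csv", tab)
    writeLines(sprintf(
      "Moran's I = %.4f (null expectation %.4f), permutation p = %.4f%s",
      mi$I, mi$expectation, mi$p_value,
      if (length(scr$removed))
        paste0("\nexcluded by VIF > 5: ", paste(scr$removed, collapse = ", "))
      else ""), file.path(out_dir, "moran.txt"))
  } else logf("stage screen: cached")

  # stage 5: CAR model suite ---------------------------------------------
  if (!have("car_fits.csv", "summary.csv", "smr.csv", "waic.txt")) {
    logf("stage fit-car")
    scr <- screen_covariates(covmat, threshold = 5)
    mcfg <- do.call(car_config,
                    c(config$mcmc %||% list(n_iter = 20000, burn_in = 5000,
                                            thin = 10),
                      list(seed = stage_seed(seed, 8L))))
    mspec <- do.call(model_specs, config$models %||% list())
    # drop screened-out covariates from the specs
    mspec$covariates <- lapply(mspec$covariates, intersect,
                               colnames(scr$X))
    suite <- run_model_suite(deaths, expd, covs_all, W, mspec, mcfg)
    write_stage(out_dir, "car_fits.csv", suite$table)
    best <- names(which.min(vapply(suite$fits, `[[`, 0, "waic")))
    bf <- suite$fits[[best]]
    write_stage(out_dir, "summary.csv",
                cbind(bf$rr, psrf = bf$psrf[bf$rr$term]))
    write_stage(out_dir, "smr.csv",
                data.frame(mun_id = expd$mun_id, bf$smr[, -1]))
    writeLines(c(sprintf("best model: %s", best),
                 sprintf("WAIC (pooled) = %.2f", bf$waic),
                 sprintf("WAIC (chain 1) = %.2f", bf$waic_by_chain[1])),
               file.path(out_dir, "waic.txt"))
  } else logf("stage fit-car: cached")

  # stage 6: report, a pure function of the fitted-model table -----------
  if (!have("report.csv")) {
    logf("stage report")
    fits_tab <- utils::read.csv(file.path(out_dir, "car_fits.csv"))
    ord <- order(fits_tab$stratum, fits_tab$model_id)
    write_stage(out_dir, "report.csv", fits_tab[ord, ])
  } else logf("stage report: cached")

  files <- setdiff(list.files(out_dir), c("manifest.json", "run.log"))
  manifest <- list(
    package = "strokeaccess",
    version = as.character(utils::packageVersion("strokeaccess")),
    seed = seed,
    stage_seeds = stats::setNames(as.list(vapply(1:8, stage_seed,
                                                 0L, seed = seed)),
                                  paste0("stage", 1:8)),
    config = config,
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("done")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
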