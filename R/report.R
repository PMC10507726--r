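#' Nested model specifications for the comparison suite
#'
#' Model 1 is the accessibility model (PWSAI, PWTT); Model 2 adds the
#' medical-resource covariates; Model 3 adds the socioeconomic covariates
#' (the full model). Covariate sets must be strictly nested.
#'
#' @param model1,model2,model3 character vectors of covariate names;
#'   `model2`/`model3` are the *additional* columns over the previous model.
#' @param strata subset of `c("total", "men", "women")`.
#' @return data frame of model/stratum specs with a `covariates` list column.
#' @export
model_specs <- function(model1 = c("pwsai", "pwtt_hours"),
                        model2 = c("physicians_per10k", "hospitals_per10k",
                                   "clinics_per10k", "emergency_per10k"),
                        model3 = c("primary_share", "secondary_share",
                                   "bachelor_share"),
                        strata = "total") {
  if (length(model2) == 0 || length(model3) == 0)
    stop("covariate sets must be strictly nested", call. = FALSE)
  sets <- list(`1` = model1, `2` = c(model1, model2),
               `3` = c(model1, model2, model3))
  strata <- match.arg(strata, c("total", "men", "women"), several.ok = TRUE)
  out <- expand.grid(model_id = 1:3, stratum = strata,
                     stringsAsFactors = FALSE)
  out$covariates <- sets[as.character(out$model_id)]
  out
}

#' Run the nested CAR model-comparison suite
#'
#' Fits each model/stratum combination with identical covariates across
#' strata and sex-specific observed and expected deaths, then assembles one
#' table of relative risks, WAIC (pooled and chain 1), convergence
#' diagnostics and residual Moran's I.
#'
#' @param deaths data frame with `O` and optionally `O_men`, `O_women`.
#' @param expected data frame with `E` and optionally `E_men`, `E_women`
#'   (from [expected_deaths()]).
#' @param covariates data frame of (already screened) covariates; columns
#'   referenced by the specs.
#' @param W binary adjacency matrix.
#' @param specs output of [model_specs()].
#' @param config a [car_config()].
#' @return list with `table` (one row per model/stratum/term) and `fits`
#'   (named list of `car_summary` objects).
#' @export
run_model_suite <- function(deaths, expected, covariates, W,
                            specs = model_specs(),
                            config = car_config()) {
  rows <- list(); fits <- list()
  for (s in seq_len(nrow(specs))) {
    mid <- specs$model_id[s]
    str <- specs$stratum[s]
    ocol <- switch(str, total = "O", men = "O_men", women = "O_women")
    ecol <- switch(str, total = "E", men = "E_men", women = "E_women")
    if (is.null(deaths[[ocol]]) || is.null(expected[[ecol]])) {
      message("skipping model ", mid, " stratum ", str,
              ": missing deaths or expectations")
      next
    }
    covs <- specs$covariates[[s]]
    miss <- setdiff(covs, colnames(covariates))
    if (length(miss))
      stop("covariates not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    X <- standardize_covariates(covariates[, covs, drop = FALSE])$X_std
    fit <- fit_car(deaths[[ocol]], expected[[ecol]], X, W, config)
    sm <- summarize_car(fit)
    key <- paste0("model", mid, "_", str)
    fits[[key]] <- sm
    rows[[key]] <- data.frame(
      model_id = mid, stratum = str,
      term = sm$rr$term, RR = sm$rr$RR, lo95 = sm$rr$lo95,
      hi95 = sm$rr$hi95,
      waic = sm$waic, waic_chain1 = sm$waic_by_chain[1],
      moran_resid = sm$moran$I, moran_p = sm$moran$p_value,
      psrf_max = max(sm$psrf), row.names = NULL)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits)
}
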