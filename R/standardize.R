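#' Expected deaths by indirect sex-age standardization
#'
#' `E_i = sum_{s,a} n_{i,s,a} * m_{s,a}`: each municipality's sex x age-band
#' populations multiplied by the national reference rates and summed. Sex-
#' specific expectations are returned for the sex-stratified sub-analysis.
#'
#' @param population data frame (mun_id, sex, age_band, count).
#' @param rates data frame (sex, age_band, rate), rates in \[0, 1\].
#' @return data frame (mun_id, E, E_men, E_women). Municipalities with zero
#'   expected deaths are flagged with a warning (they cannot serve as a
#'   model offset).
#' @export
expected_deaths <- function(population, rates) {
  if (any(rates$rate < 0 | rates$rate > 1))
    stop("reference rates must lie in [0, 1]", call. = FALSE)
  m <- merge(population, rates, by = c("sex", "age_band"))
  if (nrow(m) != nrow(population))
    stop("population strata missing from the rate table", call. = FALSE)
  m$e <- m$count * m$rate
  tot <- tapply(m$e, m$mun_id, sum)
  men <- tapply(m$e[m$sex == "men"], m$mun_id[m$sex == "men"], sum)
  women <- tapply(m$e[m$sex == "women"], m$mun_id[m$sex == "women"], sum)
  out <- data.frame(mun_id = as.integer(names(tot)),
                    E = as.numeric(tot),
                    E_men = as.numeric(men[names(tot)]),
                    E_women = as.numeric(women[names(tot)]),
                    row.names = NULL)
  out <- out[order(out$mun_id), ]
  if (any(out$E == 0))
    warning("municipalities with zero expected deaths: ",
            paste(out$mun_id[out$E == 0], collapse = ", "), call. = FALSE)
  out
}

#' Standardized mortality ratio
#'
#' Observed over expected deaths. Applied to raw counts it gives the crude
#' SMR; applied to posterior draws of fitted deaths it gives the model-based
#' SMR (done by [summarize_car()]).
#'
#' @param observed death count(s).
#' @param expected expected deaths, > 0 (vectorized).
#' @return observed / expected.
#' @export
smr <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected deaths must be positive", call. = FALSE)
  observed / expected
}
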