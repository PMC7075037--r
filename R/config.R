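#' County health statistics
#'
#' Bundles the crude county-wide disease rates that anchor the risk model.
#' Rates are cases per 100,000 residents per year; [convert_rate_to_risk()]
#' turns them into per-person annual baseline risks.
#'
#' @param crude_death_rate CHD deaths per 100,000 per year (> 0).
#' @param crude_hosp_rate CHD hospitalizations per 100,000 per year (> 0).
#' @return An object of class `county_health_config`.
#' @examples
#' county_health_config(187.7, 495)
#' @export
county_health_config <- function(crude_death_rate, crude_hosp_rate) {
  stopifnot(
    is.numeric(crude_death_rate), length(crude_death_rate) == 1,
    is.numeric(crude_hosp_rate), length(crude_hosp_rate) == 1
  )
  if (crude_death_rate <= 0 || crude_hosp_rate <= 0) {
    stop("crude rates must be positive", call. = FALSE)
  }
  structure(
    list(
      crude_death_rate = crude_death_rate,
      crude_hosp_rate = crude_hosp_rate
    ),
    class = "county_health_config"
  )
}

#' Concentration-response effect estimate
#'
#' An effect estimate states the percent change in a health endpoint per
#' fixed increment of long-term exposure, as reported by cohort studies
#' (e.g. a 6% increase in CHD mortality per 0.752 ug/m3 of black carbon).
#'
#' @param endpoint `"mortality"` or `"hospitalization"`.
#' @param pollutant Pollutant name, e.g. `"bc"` or `"no2"`.
#' @param percent_change Percent change in the endpoint per `increment` of
#'   exposure.
#' @param increment Exposure increment in the pollutant's native unit
#'   (> 0).
#' @param ci_low,ci_high Optional lower/upper 95% bounds on
#'   `percent_change`.
#' @return An object of class `effect_estimate`.
#' @examples
#' effect_estimate("mortality", "bc", 6, 0.752)
#' @export
effect_estimate <- function(endpoint = c("mortality", "hospitalization"),
                            pollutant,
                            percent_change,
                            increment,
                            ci_low = NA_real_,
                            ci_high = NA_real_) {
  endpoint <- match.arg(endpoint)
  stopifnot(
    is.character(pollutant), length(pollutant) == 1,
    is.numeric(percent_change), length(percent_change) == 1,
    is.numeric(increment), length(increment) == 1
  )
  if (increment <= 0) stop("increment must be positive", call. = FALSE)
  if (!is.na(ci_low) && !is.na(ci_high) &&
    !(ci_low <= percent_change && percent_change <= ci_high)) {
    stop("require ci_low <= percent_change <= ci_high", call. = FALSE)
  }
  structure(
    list(
      endpoint = endpoint, pollutant = pollutant,
      percent_change = percent_change, increment = increment,
      ci_low = ci_low, ci_high = ci_high
    ),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  ci <- if (!is.na(x$ci_low) || !is.na(x$ci_high)) {
    sprintf(" (95%% CI %s to %s)", format(x$ci_low), format(x$ci_high))
  } else {
    ""
  }
  cat(sprintf(
    "<effect_estimate> %+g%%%s %s per %g unit increment of %s\n",
    x$percent_change, ci, x$endpoint, x$increment, x$pollutant
  ))
  invisible(x)
}

#' Default effect estimates
#'
#' The package's default concentration-response set: 6% CHD mortality and 3%
#' CHD hospitalization per 0.752 ug/m3 of black carbon, and 3% CHD mortality
#' per 4.47 ppb (8.4 ug/m3) of NO2, from a Vancouver cohort study of
#' traffic-related pollutants corrected for co-pollutants. The NO2 /
#' hospitalization pairing is absent because the association did not survive
#' co-pollutant correction in that study (see [tract_risks()]).
#'
#' @return A named list of [effect_estimate()] objects.
#' @export
default_effect_estimates <- function() {
  list(
    bc_mortality = effect_estimate("mortality", "bc", 6, 0.752),
    bc_hospitalization = effect_estimate("hospitalization", "bc", 3, 0.752),
    no2_mortality = effect_estimate("mortality", "no2", 3, 4.47)
  )
}

#' Read a run configuration from YAML
#'
#' A run configuration collects everything a burden run needs besides the
#' tract table: the crude county rates, the effect estimates, and optional
#' generator settings. Missing sections fall back to package defaults.
#'
#' @param path Path to a YAML file with optional keys `rates`
#'   (`crude_death_rate`, `crude_hosp_rate`), `effects` (a list of effect
#'   estimates with fields `endpoint`, `pollutant`, `percent_change`,
#'   `increment`, optional `ci_low`/`ci_high`) and `seed`.
#' @return A list with elements `health`, `effects` and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  health <- if (!is.null(raw$rates)) {
    county_health_config(raw$rates$crude_death_rate, raw$rates$crude_hosp_rate)
  } else {
    county_health_config(187.7, 495)
  }
  effects <- if (!is.null(raw$effects)) {
    lapply(raw$effects, function(e) {
      effect_estimate(
        endpoint = e$endpoint, pollutant = e$pollutant,
        percent_change = e$percent_change, increment = e$increment,
        ci_low = e$ci_low %||% NA_real_, ci_high = e$ci_high %||% NA_real_
      )
    })
  } else {
    default_effect_estimates()
  }
  list(health = health, effects = effects, seed = raw$seed %||% NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
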