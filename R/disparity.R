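#' Partition tracts into exposure quartiles
#'
#' Builds the exposure continuum for one pollutant: tracts are rank-ordered
#' by exposure (ascending, ties broken by `tract_id` for determinism) and
#' cut into four contiguous blocks each holding a quarter of the tracts.
#' When the tract count is not divisible by 4 the larger blocks come first,
#' so 402 tracts give quartile sizes 101, 101, 100, 100.
#'
#' @param tracts A tract table.
#' @param pollutant `"bc"` or `"no2"`.
#' @return A tibble `tract_id`, `exposure`, `quartile` (integer 1-4, 1 =
#'   lowest exposure).
#' @export
assign_quartiles <- function(tracts, pollutant) {
  col <- pollutant_column(pollutant)
  if (!col %in% names(tracts)) {
    stop("tract table lacks exposure column ", col, call. = FALSE)
  }
  n <- nrow(tracts)
  if (n < 4) stop("need at least 4 tracts to form quartiles", call. = FALSE)
  ord <- order(tracts[[col]], tracts$tract_id)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + c(rep(1L, extra), rep(0L, 4L - extra))
  quartile <- integer(n)
  quartile[ord] <- rep(1:4, times = sizes)
  tibble::tibble(
    tract_id = tracts$tract_id,
    exposure = tracts[[col]],
    quartile = quartile
  )
}

#' Relative incidence of EJ tracts across exposure quartiles
#'
#' For quartile i with nEJ_i EJ tracts out of n_i, the relative incidence is
#' \deqn{RI_i = \frac{nEJ_i / n_i}{nEJ_1 / n_1},}
#' the proportion of EJ tracts in quartile i relative to the lowest-exposed
#' quartile, exactly analogous to a relative risk with EJ status standing in
#' for case status. 95% confidence intervals use the Katz log-ratio method:
#' \eqn{\exp(\ln RI \pm 1.96\,SE)} with
#' \eqn{SE^2 = (1-p_1)/(n_1 p_1) + (1-p_i)/(n_i p_i)}.
#'
#' Two significance indicators are returned: `significant` (the quartile's
#' CI excludes 1) and enough information to apply a pairwise CI-overlap rule
#' instead, since the intervals themselves are reported.
#'
#' @param n_ej Integer vector of EJ-tract counts per quartile, quartile 1
#'   first.
#' @param n_tracts Integer vector of total tract counts per quartile.
#' @param conf_level Confidence level; default 0.95.
#' @return A tibble `quartile`, `n_tracts`, `n_ej`, `n_nonej`, `prop_ej`,
#'   `ri`, `ri_ci_low`, `ri_ci_high`, `significant`.
#' @export
relative_incidence <- function(n_ej, n_tracts, conf_level = 0.95) {
  stopifnot(length(n_ej) == length(n_tracts), length(n_ej) >= 2)
  if (any(n_ej < 0) || any(n_tracts <= 0) || any(n_ej > n_tracts)) {
    stop("need 0 <= n_ej <= n_tracts with n_tracts > 0", call. = FALSE)
  }
  if (n_ej[1] == 0) {
    stop(paste(
      "no EJ tracts in the reference (lowest) quartile: the relative",
      "incidence is undefined. Merge quartiles or apply an explicit",
      "continuity correction; none is applied silently."
    ), call. = FALSE)
  }
  p <- n_ej / n_tracts
  ri <- p / p[1]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt((1 - p[1]) / (n_tracts[1] * p[1]) +
    ifelse(n_ej > 0, (1 - p) / (n_tracts * p), NA_real_))
  lo <- exp(log(ri) - z * se)
  hi <- exp(log(ri) + z * se)
  # Reference quartile: RI is exactly 1 by construction, no interval.
  lo[1] <- hi[1] <- 1
  se[1] <- 0
  tibble::tibble(
    quartile = seq_along(n_ej),
    n_tracts = as.integer(n_tracts),
    n_ej = as.integer(n_ej),
    n_nonej = as.integer(n_tracts - n_ej),
    prop_ej = p,
    ri = ri,
    ri_ci_low = lo,
    ri_ci_high = hi,
    significant = c(FALSE, (lo > 1 | hi < 1)[-1])
  )
}

#' Quartile summary for one pollutant
#'
#' Convenience wrapper combining [assign_quartiles()] and
#' [relative_incidence()] with per-quartile exposure and population
#' summaries — the tabular analogue of an EJ-disparity table.
#'
#' @param tracts A tract table with valid `ej_flag`.
#' @param pollutant `"bc"` or `"no2"`.
#' @param conf_level Confidence level for the RI intervals.
#' @return A tibble with one row per quartile: tract and EJ counts,
#'   population totals, exposure min/median/mean/max, and the RI columns of
#'   [relative_incidence()].
#' @export
quartile_summary <- function(tracts, pollutant, conf_level = 0.95) {
  qa <- assign_quartiles(tracts, pollutant)
  tr <- dplyr::left_join(tracts, qa[, c("tract_id", "quartile")],
    by = "tract_id"
  )
  per_q <- tr %>%
    dplyr::group_by(.data$quartile) %>%
    dplyr::summarise(
      n_tracts = dplyr::n(),
      n_ej = sum(.data$ej_flag),
      pop_total = sum(.data$pop_total),
      pop_nonwhite = sum(.data$pop_nonwhite),
      pop_poverty = sum(.data$pop_poverty),
      exposure_min = min(.data[[pollutant_column(pollutant)]]),
      exposure_median = stats::median(.data[[pollutant_column(pollutant)]]),
      exposure_mean = mean(.data[[pollutant_column(pollutant)]]),
      exposure_max = max(.data[[pollutant_column(pollutant)]]),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$quartile)
  ri <- relative_incidence(per_q$n_ej, per_q$n_tracts, conf_level)
  dplyr::left_join(
    per_q,
    ri[, c("quartile", "n_nonej", "prop_ej", "ri", "ri_ci_low",
      "ri_ci_high", "significant")],
    by = "quartile"
  )
}

#' Demographic composition of exposure quartiles
#'
#' Sums populations within each exposure quartile and expresses the
#' non-white minority and below-poverty populations as a percent of the
#' entire population of that quartile, alongside the county-wide reference
#' percentages.
#'
#' @param tracts A tract table.
#' @param quartiles Output of [assign_quartiles()] for the pollutant of
#'   interest.
#' @return A tibble `quartile`, `pop_total`, `pct_nonwhite`, `pct_poverty`,
#'   with county-wide reference percentages attached as attributes
#'   `county_pct_nonwhite` and `county_pct_poverty`.
#' @export
quartile_demographics <- function(tracts, quartiles) {
  tr <- dplyr::left_join(tracts, quartiles[, c("tract_id", "quartile")],
    by = "tract_id"
  )
  if (anyNA(tr$quartile)) {
    stop("quartile assignment does not cover all tracts", call. = FALSE)
  }
  out <- tr %>%
    dplyr::group_by(.data$quartile) %>%
    dplyr::summarise(
      pop_total = sum(.data$pop_total),
      pct_nonwhite = 100 * sum(.data$pop_nonwhite) / sum(.data$pop_total),
      pct_poverty = 100 * sum(.data$pop_poverty) / sum(.data$pop_total),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$quartile)
  if (any(out$pop_total == 0)) {
    warning("quartile(s) with zero population: percentages undefined (NaN)",
      call. = FALSE
    )
  }
  attr(out, "county_pct_nonwhite") <-
    100 * sum(tracts$pop_nonwhite) / sum(tracts$pop_total)
  attr(out, "county_pct_poverty") <-
    100 * sum(tracts$pop_poverty) / sum(tracts$pop_total)
  out
}
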