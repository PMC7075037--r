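#' Environmental-justice designation thresholds
#'
#' The designation used throughout: a tract is EJ-sensitive when at least
#' 30% of its residents are non-white minority and/or at least 20% live
#' below the federal poverty limit. Both comparisons are inclusive (>=).
#'
#' @param minority_threshold Fraction in (0, 1); default 0.30.
#' @param poverty_threshold Fraction in (0, 1); default 0.20.
#' @return An object of class `ej_thresholds`.
#' @export
ej_thresholds <- function(minority_threshold = 0.30, poverty_threshold = 0.20) {
  stopifnot(
    is.numeric(minority_threshold), length(minority_threshold) == 1,
    is.numeric(poverty_threshold), length(poverty_threshold) == 1
  )
  if (minority_threshold <= 0 || minority_threshold >= 1 ||
    poverty_threshold <= 0 || poverty_threshold >= 1) {
    stop("thresholds must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(
      minority_threshold = minority_threshold,
      poverty_threshold = poverty_threshold
    ),
    class = "ej_thresholds"
  )
}

#' Classify tracts as environmental-justice areas
#'
#' Applies the race and poverty thresholds to each tract's demographic
#' fractions and rewrites the `ej_flag` / `ej_criterion` columns. A tract
#' meeting both criteria is labelled `"race_and_poverty"`; meeting neither,
#' `"none"` with `ej_flag = FALSE`.
#'
#' @param tracts A tract table (its existing `ej_flag`/`ej_criterion`
#'   columns, if any, are ignored and replaced).
#' @param thresholds An [ej_thresholds()] object.
#' @return The tract table with updated `ej_flag` and `ej_criterion`.
#' @export
classify_ej <- function(tracts, thresholds = ej_thresholds()) {
  stopifnot(inherits(thresholds, "ej_thresholds"))
  needed <- c("tract_id", "pop_total", "pop_nonwhite", "pop_poverty")
  missing <- setdiff(needed, names(tracts))
  if (length(missing) > 0) {
    stop("classify_ej needs column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  zero <- tracts$tract_id[tracts$pop_total <= 0]
  if (length(zero) > 0) {
    stop("cannot classify tract(s) with zero population: ",
      paste(utils::head(zero, 5), collapse = ", "),
      call. = FALSE
    )
  }
  race <- tracts$pop_nonwhite / tracts$pop_total >= thresholds$minority_threshold
  poverty <- tracts$pop_poverty / tracts$pop_total >= thresholds$poverty_threshold
  criterion <- rep("none", nrow(tracts))
  criterion[race & !poverty] <- "race"
  criterion[!race & poverty] <- "poverty"
  criterion[race & poverty] <- "race_and_poverty"
  tracts$ej_flag <- race | poverty
  tracts$ej_criterion <- criterion
  tibble::as_tibble(tracts)
}

#' Coefficient of variation from an ACS margin of error
#'
#' American Community Survey estimates are published with a 90% margin of
#' error; the implied standard error is `moe / 1.645` and the coefficient of
#' variation, as a percent of the estimate, is `100 * se / estimate`. Tracts
#' with a zero estimate are flagged unreliable (`NA` CV) rather than raising
#' a division error.
#'
#' @param estimate Numeric vector of ACS count estimates (>= 0).
#' @param moe Numeric vector of +/- margins of error (>= 0).
#' @param moe_divisor Normal quantile converting the MOE to a standard
#'   error; default 1.645 (the 90% convention).
#' @return Numeric vector of CV percentages; `NA` where the estimate is 0.
#' @examples
#' cv_percent(100, 16.45) # 10
#' @export
cv_percent <- function(estimate, moe, moe_divisor = 1.645) {
  stopifnot(is.numeric(estimate), is.numeric(moe), moe_divisor > 0)
  if (any(estimate < 0, na.rm = TRUE) || any(moe < 0, na.rm = TRUE)) {
    stop("estimates and margins of error must be non-negative", call. = FALSE)
  }
  out <- 100 * (moe / moe_divisor) / estimate
  unreliable <- !is.na(estimate) & estimate == 0
  if (any(unreliable)) {
    warning(sum(unreliable), " estimate(s) are zero; CV% flagged NA (unreliable)",
      call. = FALSE
    )
    out[unreliable] <- NA_real_
  }
  out
}

#' Combine two ACS vintages of the same estimate
#'
#' Averages two survey vintages of a count estimate and propagates their
#' margins of error as independent: the combined estimate is the arithmetic
#' mean and the combined MOE is `sqrt(moe1^2 + moe2^2) / 2`. If one vintage
#' is missing (`NA`), the available one is returned with a warning.
#'
#' @param estimates Numeric vector of length 2.
#' @param moes Numeric vector of length 2, same units as `estimates`.
#' @return A list with `estimate` and `moe`.
#' @examples
#' combine_acs_vintages(c(100, 200), c(20, 20))
#' @export
combine_acs_vintages <- function(estimates, moes) {
  stopifnot(length(estimates) == 2, length(moes) == 2)
  present <- !is.na(estimates)
  if (!any(present)) {
    stop("both ACS vintages are missing", call. = FALSE)
  }
  if (sum(present) == 1) {
    warning("one ACS vintage missing; falling back to the available estimate",
      call. = FALSE
    )
    return(list(estimate = estimates[present], moe = moes[present]))
  }
  list(
    estimate = mean(estimates),
    moe = sqrt(sum(moes^2)) / 2
  )
}

#' Compare a published EJ listing with an independent validation
#'
#' Cross-tabulates two EJ designations of the same tract universe (for
#' example, a state agency's list against a re-derivation from census data)
#' and reports agreement counts, criterion upgrades/downgrades among tracts
#' EJ in both, and the net difference in total EJ tracts.
#'
#' @param listed,validated Tract tables (or any data frames with
#'   `tract_id`, `ej_flag`, `ej_criterion`) over the same tract set.
#' @return A list with `n_tracts`, `n_agree_flag`, `n_listed_only`,
#'   `n_validated_only`, `net_difference` (validated minus listed EJ
#'   totals), `n_criterion_upgrade`, `n_criterion_downgrade`, and a
#'   `discordant` tibble of per-tract disagreements.
#' @export
compare_designations <- function(listed, validated) {
  for (d in list(listed, validated)) {
    if (!all(c("tract_id", "ej_flag", "ej_criterion") %in% names(d))) {
      stop("designation tables need tract_id, ej_flag, ej_criterion",
        call. = FALSE
      )
    }
  }
  sym_diff <- c(
    setdiff(listed$tract_id, validated$tract_id),
    setdiff(validated$tract_id, listed$tract_id)
  )
  if (length(sym_diff) > 0) {
    stop("tract universes differ; symmetric difference: ",
      paste(utils::head(sort(sym_diff), 10), collapse = ", "),
      call. = FALSE
    )
  }
  v <- validated[match(listed$tract_id, validated$tract_id), ]
  flag_l <- listed$ej_flag
  flag_v <- v$ej_flag

  # Criterion "rank" orders by how many criteria are met.
  crit_rank <- c(none = 0, race = 1, poverty = 1, race_and_poverty = 2)
  both_ej <- flag_l & flag_v
  up <- both_ej & crit_rank[listed$ej_criterion] < crit_rank[v$ej_criterion]
  down <- both_ej & crit_rank[listed$ej_criterion] > crit_rank[v$ej_criterion]

  discordant_idx <- which(flag_l != flag_v |
    listed$ej_criterion != v$ej_criterion)
  discordant <- tibble::tibble(
    tract_id = listed$tract_id[discordant_idx],
    listed_flag = flag_l[discordant_idx],
    validated_flag = flag_v[discordant_idx],
    listed_criterion = listed$ej_criterion[discordant_idx],
    validated_criterion = v$ej_criterion[discordant_idx]
  )
  list(
    n_tracts = nrow(listed),
    n_agree_flag = sum(flag_l == flag_v),
    n_listed_only = sum(flag_l & !flag_v),
    n_validated_only = sum(!flag_l & flag_v),
    net_difference = sum(flag_v) - sum(flag_l),
    n_criterion_upgrade = sum(up),
    n_criterion_downgrade = sum(down),
    discordant = discordant
  )
}
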