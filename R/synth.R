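#' Fit lognormal parameters from a mean and interquartile range
#'
#' Urban long-term exposure surfaces are positive and right-skewed, so the
#' generator uses lognormal marginals matched to the two summary statistics
#' available for the emulated county: the mean and the interquartile range.
#' For LN(mu, sigma), mean = exp(mu + sigma^2/2) and
#' IQR = 2 exp(mu) sinh(z75 sigma) with z75 = qnorm(0.75); the ratio
#' IQR/mean pins sigma (solved numerically), then mu follows.
#'
#' @param mean_value Target mean (> 0).
#' @param iqr_value Target interquartile range (> 0).
#' @return Named numeric vector `meanlog`, `sdlog`.
#' @export
lognormal_from_mean_iqr <- function(mean_value, iqr_value) {
  stopifnot(mean_value > 0, iqr_value > 0)
  z75 <- stats::qnorm(0.75)
  ratio <- iqr_value / mean_value
  g <- function(s) 2 * sinh(z75 * s) * exp(-s^2 / 2)
  # IQR/mean is increasing in sigma up to ~1.07 where it peaks near 0.88;
  # the county-scale ratios used here sit well below that.
  if (ratio >= g(1.05)) {
    stop("IQR/mean ratio too large for a lognormal marginal", call. = FALSE)
  }
  s <- stats::uniroot(function(s) g(s) - ratio, c(1e-8, 1.05), tol = 1e-12)$root
  c(meanlog = log(mean_value) - s^2 / 2, sdlog = s)
}

#' Synthetic-county configuration
#'
#' Calibration targets for [generate_county()]. The defaults emulate the
#' county the analysis was designed around: 402 tracts, ~1.2 M residents,
#' 136 EJ tracts, 18.8% non-white, 13.1% in poverty, black carbon mean
#' 1.05 ug/m3 (IQR 0.22), NO2 mean 4.96 ppb (IQR 2.47), inter-pollutant
#' Spearman correlation 0.58, EJ status skewed toward high exposure, and
#' ACS-style poverty-count coefficients of variation near 33%.
#'
#' @param n_tracts Number of census tracts.
#' @param target_total_pop County population (hit within 1%).
#' @param target_ej_count Exact number of EJ tracts to realize.
#' @param target_nonwhite_frac Population-weighted non-white fraction.
#' @param target_poverty_frac Population-weighted poverty fraction.
#' @param bc_mean,bc_iqr Black-carbon mean and IQR, ug/m3.
#' @param no2_mean,no2_iqr NO2 mean and IQR, ppb.
#' @param pollutant_spearman Target Spearman rank correlation between the
#'   two exposures.
#' @param ej_exposure_skew Non-negative logistic slope linking a tract's
#'   combined exposure rank to its expected minority/poverty fractions;
#'   0 makes EJ status independent of exposure.
#' @param acs_cv_target Target mean CV (fraction, not percent) of the
#'   poverty counts; default 0.33.
#' @param ej_nudge_band Half-width (in fraction points) of the
#'   threshold-adjacent band within which demographic counts may be nudged
#'   to hit `target_ej_count`; default 0.02.
#' @param beta_precision_minority,beta_precision_poverty Base beta-noise
#'   precisions of the tract demographic fractions (re-scaled internally so
#'   the expected EJ count matches the target).
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tracts = 402,
                             target_total_pop = 1.2e6,
                             target_ej_count = 136,
                             target_nonwhite_frac = 0.188,
                             target_poverty_frac = 0.131,
                             bc_mean = 1.05, bc_iqr = 0.22,
                             no2_mean = 4.96, no2_iqr = 2.47,
                             pollutant_spearman = 0.58,
                             ej_exposure_skew = 1.2,
                             acs_cv_target = 0.33,
                             ej_nudge_band = 0.02,
                             beta_precision_minority = 8,
                             beta_precision_poverty = 18,
                             seed = 1) {
  cfg <- list(
    n_tracts = as.integer(n_tracts),
    target_total_pop = target_total_pop,
    target_ej_count = as.integer(target_ej_count),
    target_nonwhite_frac = target_nonwhite_frac,
    target_poverty_frac = target_poverty_frac,
    bc_mean = bc_mean, bc_iqr = bc_iqr,
    no2_mean = no2_mean, no2_iqr = no2_iqr,
    pollutant_spearman = pollutant_spearman,
    ej_exposure_skew = ej_exposure_skew,
    acs_cv_target = acs_cv_target,
    ej_nudge_band = ej_nudge_band,
    beta_precision_minority = beta_precision_minority,
    beta_precision_poverty = beta_precision_poverty,
    seed = as.integer(seed)
  )
  if (cfg$n_tracts < 4) stop("need at least 4 tracts", call. = FALSE)
  if (cfg$target_ej_count > cfg$n_tracts || cfg$target_ej_count < 0) {
    stop("target_ej_count must lie in [0, n_tracts]", call. = FALSE)
  }
  for (fr in c("target_nonwhite_frac", "target_poverty_frac")) {
    if (cfg[[fr]] <= 0 || cfg[[fr]] >= 1) {
      stop(fr, " must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  for (pos in c(
    "target_total_pop", "bc_mean", "bc_iqr", "no2_mean", "no2_iqr",
    "acs_cv_target", "ej_nudge_band",
    "beta_precision_minority", "beta_precision_poverty"
  )) {
    if (cfg[[pos]] <= 0) stop(pos, " must be positive", call. = FALSE)
  }
  if (cfg$ej_exposure_skew < 0) {
    stop("ej_exposure_skew must be non-negative", call. = FALSE)
  }
  if (abs(cfg$pollutant_spearman) >= 1) {
    stop("pollutant_spearman must lie in (-1, 1)", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Expected EJ-tract count given per-tract beta means and precisions:
# P(EJ_i) = 1 - P(minority below)*P(poverty below), noise independent.
expected_ej_count <- function(mu_m, mu_p, phi_m, phi_p, thresholds) {
  p_m <- stats::pbeta(thresholds$minority_threshold,
    mu_m * phi_m, (1 - mu_m) * phi_m,
    lower.tail = FALSE
  )
  p_p <- stats::pbeta(thresholds$poverty_threshold,
    mu_p * phi_p, (1 - mu_p) * phi_p,
    lower.tail = FALSE
  )
  sum(1 - (1 - p_m) * (1 - p_p))
}

# Solve the logistic intercept so the population-weighted mean fraction
# hits its target for the given exposure-rank slope.
solve_intercept <- function(u, w, slope, target) {
  f <- function(a) sum(w * stats::plogis(a + slope * (u - 0.5))) - target
  stats::uniroot(f, c(-12, 12), tol = 1e-10)$root
}

# Nudge the realized EJ count to the target by adjusting demographic counts
# of tracts whose fractions sit within `band` of a threshold. Returns the
# modified table; warns if the band cannot absorb the gap.
nudge_ej_count <- function(tracts, target, thresholds, band) {
  thr_m <- thresholds$minority_threshold
  thr_p <- thresholds$poverty_threshold
  repeat {
    tracts <- classify_ej(tracts, thresholds)
    need <- target - sum(tracts$ej_flag)
    if (need == 0) {
      return(tracts)
    }
    f_m <- tracts$pop_nonwhite / tracts$pop_total
    f_p <- tracts$pop_poverty / tracts$pop_total
    if (need > 0) {
      d_m <- thr_m - f_m
      d_p <- thr_p - f_p
      d_m[tracts$ej_flag | d_m <= 0 | d_m > band] <- NA
      d_p[tracts$ej_flag | d_p <= 0 | d_p > band] <- NA
      d <- pmin(d_m, d_p, na.rm = TRUE)
      d[is.infinite(d)] <- NA
      if (all(is.na(d))) break
      i <- which.min(d)
      if (!is.na(d_m[i]) && (is.na(d_p[i]) || d_m[i] <= d_p[i])) {
        tracts$pop_nonwhite[i] <- ceiling(thr_m * tracts$pop_total[i])
      } else {
        tracts$pop_poverty[i] <- ceiling(thr_p * tracts$pop_total[i])
      }
    } else {
      # Removable only if every satisfied criterion is within the band.
      over_m <- f_m - thr_m
      over_p <- f_p - thr_p
      removable <- tracts$ej_flag &
        (over_m < 0 | over_m < band) &
        (over_p < 0 | over_p < band)
      score <- pmax(ifelse(over_m >= 0, over_m, 0),
        ifelse(over_p >= 0, over_p, 0))
      score[!removable] <- NA
      if (all(is.na(score))) break
      i <- which.min(score)
      if (over_m[i] >= 0) {
        tracts$pop_nonwhite[i] <-
          max(0L, ceiling(thr_m * tracts$pop_total[i]) - 1)
      }
      if (over_p[i] >= 0) {
        tracts$pop_poverty[i] <-
          max(0L, ceiling(thr_p * tracts$pop_total[i]) - 1)
      }
    }
  }
  tracts <- classify_ej(tracts, thresholds)
  warning(sprintf(
    paste0(
      "could not reach target EJ count %d within the +/-%g ",
      "threshold-adjacent band; realized count is %d"
    ),
    target, band, sum(tracts$ej_flag)
  ), call. = FALSE)
  tracts
}

#' Generate a synthetic county of census tracts
#'
#' Draws a full tract table with the statistical structure the burden
#' analysis assumes: lognormal exposure marginals matched to the target
#' means/IQRs and coupled through a Gaussian copula to hit the target
#' Spearman correlation; tract populations that sum to the county total
#' within 1% and thin out toward high exposure; minority and poverty
#' fractions with a logistic dependence on the combined exposure rank
#' (slope `ej_exposure_skew`) plus beta noise, with intercepts solved so
#' the population-weighted fractions hit their targets and the noise
#' precision re-scaled so the expected EJ-tract count equals the target;
#' the realized EJ count is then nudged exactly to target by
#' threshold-adjacent count adjustments, and EJ flags are assigned with
#' [classify_ej()]. Poverty margins of error are drawn so the implied CV%
#' centres on `acs_cv_target`.
#'
#' @param config A [synthetic_config()].
#' @param thresholds An [ej_thresholds()] object.
#' @return A validated tract table (tibble), fully deterministic given
#'   `config$seed`.
#' @export
generate_county <- function(config = synthetic_config(),
                            thresholds = ej_thresholds()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_tracts

  # Exposures: Gaussian copula over lognormal marginals. The Pearson
  # correlation of the latent normals that yields a given Spearman rho is
  # 2 sin(pi * rho / 6) asymptotically; the latent correlation is then
  # fine-tuned against this sample's realized rank correlation so the
  # finite-county Spearman lands on target rather than merely in
  # expectation.
  par_bc <- lognormal_from_mean_iqr(config$bc_mean, config$bc_iqr)
  par_no2 <- lognormal_from_mean_iqr(config$no2_mean, config$no2_iqr)
  rho0 <- 2 * sin(pi * config$pollutant_spearman / 6)
  z1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  realized <- function(r) {
    stats::cor(z1, r * z1 + sqrt(1 - r^2) * e2, method = "spearman")
  }
  grid <- seq(max(-0.99, rho0 - 0.25), min(0.99, rho0 + 0.25), length.out = 501)
  rho <- grid[which.min(abs(vapply(grid, realized, numeric(1)) -
    config$pollutant_spearman))]
  z2 <- rho * z1 + sqrt(1 - rho^2) * e2
  bc <- stats::qlnorm(stats::pnorm(z1), par_bc["meanlog"], par_bc["sdlog"])
  no2 <- stats::qlnorm(stats::pnorm(z2), par_no2["meanlog"], par_no2["sdlog"])

  # Combined exposure rank in (0, 1): drives demographics and population.
  u <- (rank(bc, ties.method = "first") + rank(no2, ties.method = "first")) /
    (2 * (n + 1))

  # Populations: lognormal spread with a linear thinning toward high
  # exposure (the emulated county houses roughly twice as many residents in
  # its least-exposed quartile as in its most-exposed), rescaled to total.
  base_pop <- stats::rlnorm(n, meanlog = 0, sdlog = 0.55) * (1.45 - 0.9 * u)
  pop <- pmax(50L, as.integer(round(
    base_pop * config$target_total_pop / sum(base_pop)
  )))
  w <- pop / sum(pop)

  s <- config$ej_exposure_skew
  a_m <- solve_intercept(u, w, s, config$target_nonwhite_frac)
  a_p <- solve_intercept(u, w, s, config$target_poverty_frac)
  mu_m <- stats::plogis(a_m + s * (u - 0.5))
  mu_p <- stats::plogis(a_p + s * (u - 0.5))

  # Re-scale the beta precisions so the *expected* EJ count equals the
  # target; the realized count then only needs a small nudge.
  count_gap <- function(logmult) {
    expected_ej_count(
      mu_m, mu_p,
      config$beta_precision_minority * exp(logmult),
      config$beta_precision_poverty * exp(logmult),
      thresholds
    ) - config$target_ej_count
  }
  lo <- log(0.15)
  hi <- log(12)
  mult <- if (count_gap(lo) * count_gap(hi) < 0) {
    exp(stats::uniroot(count_gap, c(lo, hi), tol = 1e-8)$root)
  } else {
    1
  }
  phi_m <- config$beta_precision_minority * mult
  phi_p <- config$beta_precision_poverty * mult

  f_m <- stats::rbeta(n, mu_m * phi_m, (1 - mu_m) * phi_m)
  f_p <- stats::rbeta(n, mu_p * phi_p, (1 - mu_p) * phi_p)
  nonwhite <- pmin(pop, round(f_m * pop))
  poverty <- pmin(pop, round(f_p * pop))

  # ACS-style margins of error on the poverty counts: CVs centred on the
  # target with modest tract-to-tract spread.
  cv <- pmin(0.6, pmax(0.12, stats::rnorm(n, config$acs_cv_target, 0.05)))
  moe <- round(1.645 * cv * pmax(poverty, 1))

  tracts <- tibble::tibble(
    tract_id = sprintf("T%04d", seq_len(n)),
    bc_ugm3 = bc,
    no2_ppb = no2,
    pop_total = as.numeric(pop),
    pop_nonwhite = as.numeric(nonwhite),
    pop_poverty = as.numeric(poverty),
    poverty_moe = as.numeric(moe),
    ej_flag = FALSE,
    ej_criterion = "none"
  )
  tracts <- nudge_ej_count(tracts, config$target_ej_count, thresholds,
    config$ej_nudge_band
  )
  validate_tract_table(tracts)
}

# Two-pass box blur used to spatially smooth within-tract exposure noise.
box_blur <- function(m) {
  pad <- function(v) c(v[1], v, v[length(v)])
  blur1 <- function(v) {
    p <- pad(v)
    (p[1:length(v)] + p[2:(length(v) + 1)] + p[3:(length(v) + 2)]) / 3
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

#' Generate a fine exposure grid consistent with a tract table
#'
#' Lays the tracts out as contiguous square blocks of cells on a regular
#' lattice (a deliberately schematic geography) and fills each block with
#' the tract's exposure plus spatially smoothed multiplicative noise, so
#' that [tract_mean_exposure()] recovers the tract exposures to within
#' about 1% (exactly, when `noise_frac = 0`). Blocks beyond the last tract
#' carry the out-of-county sentinel.
#'
#' @param tracts A tract table.
#' @param pollutant `"bc"` or `"no2"`.
#' @param block_cells Edge length of each tract's square block of fine
#'   cells; default 8.
#' @param cell_size Fine cell edge length in metres; default 10.
#' @param noise_frac Relative amplitude of the within-tract noise field;
#'   default 0.015.
#' @param seed RNG seed for the noise field.
#' @return An [exposure_grid()].
#' @export
generate_grid <- function(tracts, pollutant = "bc", block_cells = 8,
                          cell_size = 10, noise_frac = 0.015, seed = 1) {
  col <- pollutant_column(pollutant)
  n <- nrow(tracts)
  if (n == 0) stop("empty tract table", call. = FALSE)
  stopifnot(block_cells >= 1, noise_frac >= 0)
  set.seed(seed)
  nbx <- ceiling(sqrt(n))
  nby <- ceiling(n / nbx)
  nr <- nbx * block_cells
  nc <- nby * block_cells
  vals <- matrix(0, nr, nc)
  mem <- matrix(GRID_SENTINEL, nr, nc)
  for (k in seq_len(n)) {
    bi <- (k - 1) %% nbx
    bj <- (k - 1) %/% nbx
    rows <- bi * block_cells + seq_len(block_cells)
    cols <- bj * block_cells + seq_len(block_cells)
    noise <- matrix(stats::rnorm(block_cells^2), block_cells, block_cells)
    if (block_cells >= 3) noise <- box_blur(noise)
    vals[rows, cols] <- tracts[[col]][k] * (1 + noise_frac * noise)
    mem[rows, cols] <- tracts$tract_id[k]
  }
  exposure_grid(vals, mem, cell_size)
}
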