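bc_mort <- function() effect_estimate("mortality", "bc", 6, 0.752)
R0 <- 0.001877

test_that("population midpoint follows the cumulative-population rule", {
  tr <- make_tracts(bc = c(1, 2, 3), pop = c(100, 100, 100))
  expect_equal(population_midpoint(tr, "bc")$x_mid, 2)

  tr2 <- make_tracts(bc = c(1, 2, 3), pop = c(10, 80, 10))
  # cumulative-sum oracle: first tract reaching half of 100
  cum <- cumsum(c(10, 80, 10))
  expect_equal(
    population_midpoint(tr2, "bc")$x_mid,
    c(1, 2, 3)[which(cum >= 50)[1]]
  )

  single <- make_tracts(bc = 4.2, pop = 500)
  expect_equal(population_midpoint(single, "bc")$x_mid, 4.2)
  expect_error(population_midpoint(make_tracts(bc = numeric(0),
    pop = numeric(0)), "bc"), "empty")
})

test_that("tract risks scale from the midpoint exactly as specified", {
  x_mid <- 1
  tr <- make_tracts(bc = c(1, 1.752), pop = c(100, 200))
  for (mode in c("compound", "linear")) {
    rt <- tract_risks(tr, "bc", R0, bc_mort(), x_mid, scaling = mode)
    # at the midpoint the pollutant-specific component vanishes
    expect_equal(rt$risk_component[1], 0)
    # one full increment above the midpoint: exactly 1.06 x baseline
    expect_equal(rt$total_risk[2], R0 * 1.06)
    # two-tract system: rho' = (0, 0.06 R0), burden = 0.06 R0 * pop2
    expect_equal(rt$risk_rebaselined, c(0, 0.06 * R0))
    expect_equal(rt$burden, c(0, 0.06 * R0 * 200))
  }
})

test_that("excluded pollutant/endpoint pairings need an explicit override", {
  tr <- make_tracts(no2 = c(4, 5, 6), pop = rep(100, 3))
  eff <- effect_estimate("hospitalization", "no2", 3, 4.47)
  expect_error(
    tract_risks(tr, "no2", R0, eff, 5),
    "disabled by default"
  )
  rt <- tract_risks(tr, "no2", R0, eff, 5, allow_excluded_pairings = TRUE)
  expect_s3_class(rt, "risk_table")
  expect_error(
    tract_risks(tr, "no2", R0, bc_mort(), 5),
    "pollutant"
  )
})

test_that("rebaselining and translation invariance hold in both modes", {
  tr <- generate_county(synthetic_config(seed = 8))
  for (mode in c("compound", "linear")) {
    mid <- population_midpoint(tr, "bc")
    rt <- tract_risks(tr, "bc", R0, bc_mort(), mid$x_mid, scaling = mode)
    expect_equal(min(rt$risk_rebaselined), 0)
    # rho' nondecreasing in exposure (strictly increasing for e > 0)
    ord <- order(rt$exposure)
    expect_true(all(diff(rt$risk_rebaselined[ord]) > 0))

    shifted <- tr
    shifted$bc_ugm3 <- tr$bc_ugm3 + 5
    mid_s <- population_midpoint(shifted, "bc")
    expect_identical(mid_s$tract_id, mid$tract_id)
    rt_s <- tract_risks(shifted, "bc", R0, bc_mort(), mid_s$x_mid,
      scaling = mode
    )
    expect_equal(rt_s$risk_rebaselined, rt$risk_rebaselined,
      tolerance = 1e-10
    )
    expect_equal(rt_s$burden, rt$burden, tolerance = 1e-10)
  }
})

test_that("linear-mode burden matches its closed form to machine precision", {
  tr <- generate_county(synthetic_config(seed = 9))
  eff <- bc_mort()
  mid <- population_midpoint(tr, "bc")
  rt <- tract_risks(tr, "bc", R0, eff, mid$x_mid, scaling = "linear")
  closed <- (eff$percent_change / 100) * (R0 / eff$increment) *
    sum(tr$pop_total * (tr$bc_ugm3 - min(tr$bc_ugm3)))
  expect_equal(sum(rt$burden), closed, tolerance = 1e-12)
})

test_that("compound and linear risks agree within 1% over a county span", {
  tr <- generate_county(synthetic_config(seed = 10))
  for (p in c("bc", "no2")) {
    eff <- default_effect_estimates()[[paste0(p, "_mortality")]]
    mid <- population_midpoint(tr, p)
    rc <- tract_risks(tr, p, R0, eff, mid$x_mid, scaling = "compound")
    rl <- tract_risks(tr, p, R0, eff, mid$x_mid, scaling = "linear")
    expect_lt(max(abs(rc$total_risk - rl$total_risk) / rl$total_risk), 0.01)
  }
})

test_that("linear scaling errors when a risk would go non-positive", {
  tr <- make_tracts(bc = c(0.1, 50), pop = c(100, 100))
  eff <- effect_estimate("mortality", "bc", 6, 0.752)
  expect_error(
    tract_risks(tr, "bc", R0, eff, 50, scaling = "linear"),
    "non-positive risk.*T0001"
  )
})

test_that("burden summary splits cases by EJ status correctly", {
  tr <- make_tracts(bc = 1:5, pop = rep(100, 5))
  mid <- population_midpoint(tr, "bc")
  rt <- tract_risks(tr, "bc", R0, bc_mort(), mid$x_mid)
  bs <- burden_summary(rt)
  expect_equal(bs$ej_share, 0) # no EJ tracts
  expect_equal(bs$total_cases, sum(rt$burden))

  # proportionality: constant rho' makes EJ burden share = population share
  flat <- rt
  flat$risk_rebaselined <- 0.001
  flat$burden <- 0.001 * flat$pop_total
  flat$ej_flag <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  flat$pop_total <- c(100, 300, 100, 200, 300)
  flat$burden <- 0.001 * flat$pop_total
  bsf <- burden_summary(flat)
  expect_equal(bsf$ej_share, bsf$ej_pop_share)

  # synthetic skewed county: EJ burden share exceeds EJ population share,
  # totals match the per-tract brute-force sum
  county <- generate_county(synthetic_config(seed = 12))
  midc <- population_midpoint(county, "bc")
  rtc <- tract_risks(county, "bc", R0, bc_mort(), midc$x_mid)
  bsc <- burden_summary(rtc)
  expect_gt(bsc$ej_share, bsc$ej_pop_share)
  expect_equal(bsc$ej_cases + bsc$nonej_cases, bsc$total_cases)
  expect_equal(
    bsc$percent_of_county_cases,
    100 * sum(rtc$burden) / (R0 * sum(county$pop_total))
  )
})

test_that("the D'Agostino-Pearson omnibus statistic matches a reference", {
  # frozen reference values computed with an independent implementation
  # (scipy.stats.normaltest / skewtest / kurtosistest) on this sample
  x <- c(
    2.502383, 2.005824, 1.718852, 2.618286, 1.662848, 3.573606, 2.70974,
    2.443781, 0.695874, 0.360655, 0.761193, 2.815998, 2.40725, 0.553395,
    2.795161, 1.238031, 1.239611, 4.633453, 2.289869, 2.625558, 2.650363,
    0.541429, 2.738324, 8.719103, 0.822505, 3.791293, 4.069339, 4.027513,
    1.406572, 1.705856
  )
  res <- dagostino_pearson_test(x)
  expect_equal(res$statistic, 25.6936488165, tolerance = 1e-9)
  expect_equal(res$p_value, 0.0000026345, tolerance = 1e-4)
  expect_equal(res$z_skewness, 3.7407704380, tolerance = 1e-9)
  expect_equal(res$z_kurtosis, 3.4205679860, tolerance = 1e-9)
  expect_error(dagostino_pearson_test(rnorm(7)), "n >= 8")
})

test_that("EJ risk comparison handles degenerate, exact and skewed cases", {
  # identical groups: U at its null mean, p = 1
  same <- suppressWarnings(
    compare_ej_risks(rep(2, 10), rep(c(TRUE, FALSE), each = 5))
  )
  expect_equal(same$u_statistic, 25 / 2)
  expect_equal(same$p_value, 1)

  # fully separated 3 vs 3: exact two-sided p = 2/20 by enumeration
  sep <- suppressWarnings(
    compare_ej_risks(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  )
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$u_statistic, 9) # all 3x3 pairwise wins

  # both small groups trigger the normality-test warning
  w <- capture_warnings(
    compare_ej_risks(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  )
  expect_length(w, 2)
  expect_match(w, "fewer than 8", all = TRUE)

  # synthetic skewed county, n = (136, 266): EJ stochastically larger
  county <- generate_county(synthetic_config(seed = 13))
  mid <- population_midpoint(county, "no2")
  rt <- tract_risks(county, "no2", R0,
    default_effect_estimates()$no2_mortality, mid$x_mid
  )
  cmp <- compare_ej_risks(rt$risk_rebaselined, rt$ej_flag)
  expect_equal(cmp$ej$n, 136)
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$ej$median, cmp$nonej$median)
})

test_that("sensitivity substitution reproduces independent single runs", {
  tr <- generate_county(synthetic_config(seed = 14))
  base <- effect_estimate("mortality", "no2", 3, 10)
  mid <- population_midpoint(tr, "no2")

  # a single alternative equal to the base run reproduces it
  solo <- sensitivity_substitution(tr, "no2", R0, list(base))
  rt <- tract_risks(tr, "no2", R0, base, mid$x_mid)
  expect_equal(solo$burden_range[["central"]], sum(rt$burden))

  # doubling the percent change under linear scaling doubles the burden
  twice <- effect_estimate("mortality", "no2", 6, 10)
  lin <- sensitivity_substitution(tr, "no2", R0, list(base, twice),
    scaling = "linear"
  )
  expect_equal(lin$runs$total_cases[2], 2 * lin$runs$total_cases[1])

  # hazard-ratio spread 2% / 3% / 5% per 10 ug/m3: ordered burden triple
  alts <- lapply(c(2, 3, 5), function(pc) {
    effect_estimate("mortality", "no2", pc, 10)
  })
  rng <- sensitivity_substitution(tr, "no2", R0, alts)
  expect_true(all(diff(rng$runs$total_cases) > 0))
  singles <- vapply(alts, function(e) {
    sum(tract_risks(tr, "no2", R0, e, mid$x_mid)$burden)
  }, numeric(1))
  expect_equal(rng$runs$total_cases, singles)
  expect_equal(unname(rng$burden_range), sort(singles)[c(1, 2, 3)])

  expect_error(sensitivity_substitution(tr, "no2", R0, list()), "at least one")
  mixed <- list(base, effect_estimate("mortality", "bc", 3, 1))
  expect_error(sensitivity_substitution(tr, "no2", R0, mixed), "share")
})
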