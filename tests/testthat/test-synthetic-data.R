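test_that("the generator is deterministic and hits its calibration targets", {
  cfg <- synthetic_config()
  a <- generate_county(cfg)
  b <- generate_county(cfg)
  expect_identical(a, b)

  expect_equal(nrow(a), 402)
  expect_equal(sum(a$ej_flag), 136)
  expect_equal(mean(a$bc_ugm3), 1.05, tolerance = 0.05)
  expect_equal(mean(a$no2_ppb), 4.96, tolerance = 0.05)
  expect_equal(
    cor(a$bc_ugm3, a$no2_ppb, method = "spearman"), 0.58,
    tolerance = 0.05 / 0.58
  )
  expect_equal(sum(a$pop_total), 1.2e6, tolerance = 0.01)
  # demographic fractions carry beta sampling noise on top of the solved
  # logistic means, so a 10% relative band is the realistic check here
  expect_equal(
    sum(a$pop_nonwhite) / sum(a$pop_total), 0.188,
    tolerance = 0.1
  )
  expect_equal(
    sum(a$pop_poverty) / sum(a$pop_total), 0.131,
    tolerance = 0.1
  )
  # ACS-style CV% of the poverty counts centres near 33%
  cvs <- cv_percent(a$pop_poverty[a$pop_poverty > 0],
    a$poverty_moe[a$pop_poverty > 0])
  expect_equal(mean(cvs), 33, tolerance = 0.1)

  expect_error(
    generate_county(synthetic_config(target_ej_count = 500)),
    "target_ej_count"
  )
})

test_that("EJ status is exposure-independent when the skew is zero", {
  # full-size counties: with ~34 EJ tracts expected per quartile the
  # small-count bias of the ratio estimator stays within a couple percent
  ri4 <- vapply(1:200, function(s) {
    tr <- suppressWarnings(generate_county(synthetic_config(
      ej_exposure_skew = 0, seed = s
    )))
    quartile_summary(tr, "bc")$ri[4]
  }, numeric(1))
  expect_equal(mean(ri4), 1, tolerance = 0.1)
})

test_that("stronger exposure skew raises RI4 and the EJ burden share", {
  stat_at <- function(skew) {
    out <- vapply(1:30, function(s) {
      tr <- suppressWarnings(generate_county(synthetic_config(
        ej_exposure_skew = skew, seed = 1000 + s
      )))
      qs <- quartile_summary(tr, "bc")
      res <- run_burden_analysis(tr, "bc", "mortality")
      c(qs$ri[4], res$burden$ej_share)
    }, numeric(2))
    rowMeans(out)
  }
  low <- stat_at(0)
  mid <- stat_at(0.8)
  high <- stat_at(1.6)
  expect_true(low[1] < mid[1] && mid[1] < high[1])
  expect_true(low[2] < mid[2] && mid[2] < high[2])
})

test_that("generated grids are consistent with the tract table", {
  # EJ status is irrelevant to grid generation; a tiny county may miss the
  # exact EJ target within the nudge band, which warns
  tr <- suppressWarnings(generate_county(synthetic_config(
    n_tracts = 36, target_total_pop = 1e5, target_ej_count = 12, seed = 5
  )))

  exact <- generate_grid(tr, "bc", block_cells = 4, noise_frac = 0, seed = 2)
  rec <- tract_mean_exposure(exact, tr$tract_id)
  expect_equal(rec$excluded, character(0))
  expect_equal(
    rec$means$exposure[match(tr$tract_id, rec$means$tract_id)],
    tr$bc_ugm3
  )

  noisy <- generate_grid(tr, "bc", block_cells = 8, seed = 2)
  recn <- tract_mean_exposure(noisy, tr$tract_id)
  err <- abs(recn$means$exposure[match(tr$tract_id, recn$means$tract_id)] -
    tr$bc_ugm3) / tr$bc_ugm3
  expect_lt(max(err), 0.01)

  # downsample-then-aggregate equals aggregate directly (mean conservation
  # within whole-tract blocks)
  coarse <- downsample_grid(noisy, 4)
  recc <- tract_mean_exposure(coarse, tr$tract_id)
  expect_equal(
    recc$means$exposure[match(tr$tract_id, recc$means$tract_id)],
    recn$means$exposure[match(tr$tract_id, recn$means$tract_id)]
  )

  expect_identical(
    generate_grid(tr, "bc", seed = 3)$values,
    generate_grid(tr, "bc", seed = 3)$values
  )
})

test_that("end-to-end linear-mode burden equals the closed form", {
  tr <- generate_county(synthetic_config(seed = 17))
  r0 <- convert_rate_to_risk(187.7)
  eff <- effect_estimate("mortality", "bc", 6, 0.752)
  mid <- population_midpoint(tr, "bc")
  rt <- tract_risks(tr, "bc", r0, eff, mid$x_mid, scaling = "linear")
  closed <- sum(tr$pop_total * (eff$percent_change / 100) *
    (r0 / eff$increment) * (tr$bc_ugm3 - min(tr$bc_ugm3)))
  expect_equal(sum(rt$burden), closed, tolerance = 1e-12)

  # compound mode stays within the first-order bound of the closed form
  rtc <- tract_risks(tr, "bc", r0, eff, mid$x_mid, scaling = "compound")
  expect_equal(sum(rtc$burden), closed, tolerance = 0.1)
})
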