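test_that("the design-weighted mean reduces to hand-computable cases", {
  d <- survey_design(value = c(1, 2, 3), weight = c(1, 1, 1),
                     stratum = rep(1, 3), psu = c(1, 1, 2))
  expect_equal(weighted_mean_design(d), 2)

  d2 <- survey_design(value = c(0, 4), weight = c(1, 3),
                      stratum = c(1, 1), psu = c(1, 2))
  expect_equal(weighted_mean_design(d2), 3)

  const <- survey_design(value = rep(7.5, 4), weight = c(1, 9, 2, 5),
                         stratum = c(1, 1, 2, 2), psu = c(1, 2, 1, 2))
  expect_equal(weighted_mean_design(const), 7.5)

  empty <- survey_design(value = 1:3, weight = rep(1, 3), stratum = rep(1, 3),
                         psu = 1:3, domain = rep(FALSE, 3))
  expect_error(weighted_mean_design(empty), "no in-domain")
})

test_that("linearized variance matches the hand-worked two-PSU example", {
  # one stratum, PSUs {1,1,1,2,2,2}, w = {1,2,1,1,2,1}, y = 1..6
  # mean = 28/8 = 3.5; PSU residual totals -0.75 and +0.75;
  # v = 2 * (0.75^2 + 0.75^2) = 2.25, se = 1.5, df = 1
  d <- survey_design(value = 1:6, weight = c(1, 2, 1, 1, 2, 1),
                     stratum = rep(1, 6), psu = rep(1:2, each = 3))
  expect_equal(weighted_mean_design(d), 3.5)
  lv <- linearized_variance(d)
  expect_equal(lv$se, 1.5)
  expect_equal(lv$df, 1L)
  est <- svy_estimate(d, level = 0.95)
  tq <- qt(0.975, df = 1)
  expect_equal(est$ci_low, 3.5 - tq * 1.5)
  expect_equal(est$ci_high, 3.5 + tq * 1.5)
})

test_that("equal PSU totals give zero variance and a degenerate interval", {
  d <- survey_design(value = rep(c(1, 3), 4), weight = rep(1, 8),
                     stratum = rep(1:2, each = 4),
                     psu = rep(rep(1:2, each = 2), 2))
  lv <- linearized_variance(d)
  expect_equal(lv$se, 0)
  est <- svy_estimate(d)
  expect_equal(est$ci_low, est$mean)
  expect_equal(est$ci_high, est$mean)
})

test_that("estimates are invariant to rescaling the weights", {
  dat <- random_design_data(5)
  d1 <- survey_design(dat$value, dat$weight, dat$stratum, dat$psu, dat$domain)
  d2 <- survey_design(dat$value, dat$weight * 1000, dat$stratum, dat$psu,
                      dat$domain)
  expect_equal(weighted_mean_design(d1), weighted_mean_design(d2))
  expect_equal(linearized_variance(d1)$se, linearized_variance(d2)$se)
})

test_that("wider confidence levels give wider intervals", {
  dat <- random_design_data(6)
  d <- survey_design(dat$value, dat$weight, dat$stratum, dat$psu, dat$domain)
  e90 <- svy_estimate(d, level = 0.90)
  e99 <- svy_estimate(d, level = 0.99)
  expect_true(e99$ci_high - e99$ci_low > e90$ci_high - e90$ci_low)
  expect_true(e90$ci_low <= e90$mean && e90$mean <= e90$ci_high)
})

test_that("linearized SEs agree with an independent PSU bootstrap", {
  for (seed in c(21, 22, 23)) {
    dat <- random_design_data(seed)
    d <- survey_design(dat$value, dat$weight, dat$stratum, dat$psu, dat$domain)
    lin <- linearized_variance(d)$se
    boot <- boot_se_oracle(dat$value, dat$weight, dat$stratum, dat$psu,
                           dat$domain, reps = 10000L, seed = seed)
    expect_lt(abs(lin - boot) / lin, 0.05)
  }
})

test_that("lonely PSU strata fail by default and centre on request", {
  d <- survey_design(value = c(1, 2, 3, 4), weight = rep(1, 4),
                     stratum = c(1, 1, 2, 2), psu = c(1, 2, 1, 1))
  expect_error(linearized_variance(d), "single PSU")
  lv <- linearized_variance(d, lonely_psu = "centre")
  expect_gte(lv$se, 0)
})

test_that("a single-cycle series equals a direct estimate", {
  pop <- make_survey_population(seed = 9, n_cycles = 1)
  store <- population_store(pop)
  dom <- function(df) df$RIDAGEYR >= 40 & df$RIDAGEYR <= 59
  series <- cycle_series(store, "BMXBMI", "BMX", "DEMO", domain = dom)
  expect_equal(nrow(series), 1L)
  df <- merge(store_get_table(store, "BMX", "raw"),
              store_get_table(store, "DEMO", "raw"), by = "SEQN")
  d <- survey_design(df$BMXBMI, df$WTMEC2YR, df$SDMVSTRA, df$SDMVPSU, dom(df))
  est <- svy_estimate(d)
  expect_equal(series$mean, est$mean)
  expect_equal(series$se, est$se)
  expect_equal(series$df, est$df)
})

test_that("a programmed drift is recovered with covering intervals", {
  pop <- make_survey_population(seed = 31, n_cycles = 3, cycle_drift = 1.5)
  store <- population_store(pop)
  series <- cycle_series(store, "BMXBMI", "BMX", "DEMO",
                         domain = function(df) df$RIDAGEYR >= 40 & df$RIDAGEYR <= 59)
  expect_equal(series$cycle, pop$truth$cycle)
  expect_true(all(diff(series$mean) > 0))
  expect_true(all(series$ci_low <= pop$truth$true_mean &
                    pop$truth$true_mean <= series$ci_high))
})

test_that("per-file weight renames error without an explicit mapping", {
  pop <- make_survey_population(seed = 4, n_cycles = 2)
  store <- population_store(pop)
  # rename the weight variable in the second cycle's file
  demo_b <- store_get_table(store, "DEMO_B", "raw")
  names(demo_b)[names(demo_b) == "WTMEC2YR"] <- "WTSSGL2Y"
  store$raw$DEMO_B <- demo_b
  dom <- function(df) df$RIDAGEYR >= 40 & df$RIDAGEYR <= 59
  expect_error(cycle_series(store, "BMXBMI", "BMX", "DEMO", domain = dom),
               "2001-2002.*WTMEC2YR")
  series <- cycle_series(store, "BMXBMI", "BMX", "DEMO", domain = dom,
                         weight = c(BMX = "WTMEC2YR", BMX_B = "WTSSGL2Y"))
  expect_equal(nrow(series), 2L)
})

test_that("pooling cycles warns about weights and trends, never estimates", {
  expect_warning(rec <- pooled_analysis_guard(c("1999-2000", "2001-2002")),
                 class = "nhanessnap_pooling_warning")
  expect_false(rec$pooled)
  expect_match(rec$message, "reference population")
  rec2 <- pooled_analysis_guard(c("1999-2000", "2001-2002"), acknowledge = TRUE)
  expect_false(rec2$pooled)
  expect_match(rec2$message, "pooled estimates are not computed")
  expect_silent(rec3 <- pooled_analysis_guard("1999-2000"))
  expect_false(rec3$pooled)
})
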