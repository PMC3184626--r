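ref_inputs <- function() {
  list(s = reference_stratum_summary(),
       e = reference_economics(),
       f = reference_unemployment_fractions())
}

test_that("stratum losses reproduce the published worked examples", {
  # male 22-29: 72 x 0.48 x 30/12 x 0.52 x 23,460
  expect_lt(abs(stratum_loss(72, 0.48, 30, 0.52, 23460) - 1054011), 1)
  # male 18-21: 26 x 0.40 x 21/12 x 0.52 x 11,546
  expect_lt(abs(stratum_loss(26, 0.40, 21, 0.52, 11546) - 109271), 1)
  expect_equal(stratum_loss(100, 0, 36, 0.5, 20000), 0)
  expect_error(stratum_loss(10, -0.1, 36, 0.5, 20000), "nonnegative")
})

test_that("pooled per-person losses match the published figures", {
  losses_m <- c(stratum_loss(26, 0.40, 21, 0.52, 11546),
                stratum_loss(72, 0.48, 30, 0.52, 23460))
  expect_lt(abs(per_person_loss(losses_m, c(26, 72)) - 11870), 1)

  losses_f <- c(stratum_loss(150, 0.25, 36, 0.47, 8875),
                stratum_loss(294, 0.43, 26, 0.47, 18508))
  expect_lt(abs(per_person_loss(losses_f, c(150, 294)) - 6423), 5)

  expect_equal(per_person_loss(5000, 10), 500)
  expect_error(per_person_loss(numeric(0), numeric(0)), "patients")
})

test_that("unemployment fraction: t-interval on per-record ratios", {
  # hand-computed t-interval for ratios {0.25, 0.50, 0.75}
  samp <- tibble::tibble(
    sex = rep("male", 3),
    duration_illness_months = c(100, 100, 100),
    duration_unemployment_months = c(25, 50, 75)
  )
  est <- estimate_unemployment_fraction(samp)
  expect_equal(est$mean_fraction, 0.5)
  se <- sd(c(0.25, 0.5, 0.75)) / sqrt(3)          # 0.14434
  expect_equal(est$ci_low, 0.5 - qt(0.975, 2) * se, tolerance = 1e-10)
  expect_equal(est$ci_high, 0.5 + qt(0.975, 2) * se, tolerance = 1e-10)
  expect_equal(qt(0.975, 2), 4.302653, tolerance = 1e-6)

  # degenerate: unemployment equals illness everywhere -> mean 1, zero width
  deg <- tibble::tibble(sex = rep("female", 4),
                        duration_illness_months = c(10, 20, 30, 40),
                        duration_unemployment_months = c(10, 20, 30, 40))
  est_deg <- estimate_unemployment_fraction(deg)
  expect_equal(est_deg$mean_fraction, 1)
  expect_equal(est_deg$ci_low, 1)
  expect_equal(est_deg$ci_high, 1)

  # zero illness duration rejected with a diagnostic
  bad <- dplyr::bind_rows(samp,
                          tibble::tibble(sex = "male",
                                         duration_illness_months = 0,
                                         duration_unemployment_months = 5))
  expect_warning(est_bad <- estimate_unemployment_fraction(bad), "rejected")
  expect_equal(est_bad$n, 3)

  # ratio-of-means alternative
  rom <- estimate_unemployment_fraction(samp, method = "ratio_of_means")
  expect_equal(rom$mean_fraction, 150 / 300)
})

test_that("the cost table reproduces the published subtotals and totals", {
  inp <- ref_inputs()
  ct <- compute_cost_table(inp$s, inp$e, inp$f)

  rel <- function(x, target) abs(x - target) / target
  expect_lt(rel(ct$total$total_loss, 49223672), 0.005)
  expect_lt(rel(ct$total$per_patient, 22684), 0.005)
  m <- ct$by_sex[ct$by_sex$sex == "male", ]
  f <- ct$by_sex[ct$by_sex$sex == "female", ]
  expect_lt(rel(m$total_loss, 22302206), 0.005)
  expect_lt(rel(m$per_patient, 44515), 0.005)
  expect_lt(rel(f$per_patient, 16130), 0.005)

  # conservation at full precision
  expect_equal(sum(ct$strata$loss), ct$total$total_loss)
  expect_equal(ct$by_sex$total_loss,
               tapply(ct$strata$loss, ct$strata$sex, sum)[
                 as.character(ct$by_sex$sex)],
               ignore_attr = TRUE)

  # linearity: doubling every income doubles every loss and total exactly
  e2 <- dplyr::mutate(inp$e, mean_annual_income = 2 * mean_annual_income)
  ct2 <- compute_cost_table(inp$s, e2, inp$f)
  expect_equal(ct2$strata$loss, 2 * ct$strata$loss)
  expect_equal(ct2$total$total_loss, 2 * ct$total$total_loss)

  # all-zero discontinuation gives an all-zero table
  s0 <- dplyr::mutate(inp$s, frac_discontinued = 0)
  ct0 <- compute_cost_table(s0, inp$e, inp$f)
  expect_true(all(ct0$strata$loss == 0))
  expect_equal(ct0$total$total_loss, 0)

  # a stratum without an economics row is an error naming the stratum
  e_miss <- inp$e[!(inp$e$sex == "male" & inp$e$age_band == "30-39"), ]
  expect_error(compute_cost_table(inp$s, e_miss, inp$f), "male 30-39")
})

test_that("every published loss cell reproduces from its own row inputs", {
  inp <- ref_inputs()
  ct <- compute_cost_table(inp$s, inp$e, inp$f)
  published <- c(109271, 1054011, 7444534, 7283684, 5738483, 672223,
                 469266, 2382677, 6162231, 8550786, 7345405, 2011101)
  expect_lt(max(abs(ct$strata$loss - published) / published), 0.0005)
})

test_that("stratum summaries computed from records feed the cost table", {
  co <- simulate_cohort(sim_config(n_patients = 4000), 55)
  smy <- cohort_stratum_summary(co)
  expect_equal(nrow(smy), 12)
  expect_equal(sum(smy$n_patients), 4000)
  expect_true(all(smy$frac_discontinued >= 0 & smy$frac_discontinued <= 1,
                  na.rm = TRUE))

  # excluding "other" from the denominator can only raise the fraction
  smy2 <- cohort_stratum_summary(co, include_other = FALSE)
  expect_true(all(smy2$frac_discontinued >= smy$frac_discontinued, na.rm = TRUE))

  inp <- ref_inputs()
  ct <- compute_cost_table(smy, inp$e, inp$f)
  expect_gt(ct$total$total_loss, 0)
  expect_equal(ct$total$n, 4000)
})
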