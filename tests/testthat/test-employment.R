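test_that("IRLS fit on a 2x2 design equals the closed-form odds ratio", {
  counts <- sex_status_counts()
  dat <- expand_2x2(counts)
  dat$female <- as.integer(dat$x == "female")
  fit <- fit_logistic(discontinued ~ female, dat)
  or_closed <- (counts["female", "discontinued"] * counts["male", "employed"]) /
    (counts["female", "employed"] * counts["male", "discontinued"])
  or_fit <- fit$coefficients$odds_ratio[fit$coefficients$term == "female"]
  expect_equal(or_fit, or_closed, tolerance = 1e-6)
  expect_equal(or_closed, 0.7612844, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("IRLS agrees with the reference GLM fitter on a full model", {
  cfg <- clean_config(n_patients = 4000)
  mf <- prepare_model_frame(score_cohort(simulate_cohort(cfg, 13)))
  mf <- mf[stats::complete.cases(mf), ]
  f <- discontinued ~ age_decade + sex + duration_years + fatigue +
    phys_function + anxiety + depression + pain + centre + year
  fit <- fit_logistic(f, mf)
  ref <- stats::glm(f, family = stats::binomial(), data = mf)
  expect_equal(fit$coefficients$estimate,
               unname(stats::coef(ref)[fit$coefficients$term]),
               tolerance = 1e-6)
  se_ref <- sqrt(diag(stats::vcov(ref)))
  expect_equal(fit$coefficients$std_error,
               unname(se_ref[fit$coefficients$term]), tolerance = 1e-5)
})

test_that("log-likelihood is non-decreasing across IRLS iterations", {
  cfg <- clean_config(n_patients = 1500)
  mf <- prepare_model_frame(score_cohort(simulate_cohort(cfg, 23)))
  fit <- fully_adjusted_model(mf)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
})

test_that("estimates are invariant to record order", {
  cfg <- clean_config(n_patients = 1000)
  mf <- prepare_model_frame(score_cohort(simulate_cohort(cfg, 29)))
  mf <- mf[stats::complete.cases(mf), ]
  fit1 <- fully_adjusted_model(mf)
  fit2 <- fully_adjusted_model(mf[rev(seq_len(nrow(mf))), ])
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("separation and collinearity are flagged, not reported silently", {
  dat <- tibble::tibble(discontinued = rep(c(0L, 1L), each = 20),
                        x = rep(c(0, 1), each = 20))
  expect_warning(fit <- fit_logistic(discontinued ~ x, dat), "separation")
  expect_false(fit$converged)

  dat2 <- tibble::tibble(discontinued = rbinom(50, 1, 0.5),
                         a = rnorm(50))
  dat2$b <- 2 * dat2$a
  expect_error(fit_logistic(discontinued ~ a + b, dat2), "collinear.*b")
})

test_that("coefficients of the generative model are recovered within 3 SE", {
  cfg <- clean_config(n_patients = 20000)
  mf <- prepare_model_frame(score_cohort(simulate_cohort(cfg, 7)))
  fit <- fully_adjusted_model(mf)
  truth <- true_parameters(cfg)$coefficients
  nm <- model_term_map()
  for (term in names(nm)) {
    row <- fit$coefficients[fit$coefficients$term == term, ]
    z <- (row$estimate - truth[[nm[[term]]]]) / row$std_error
    expect_lt(abs(z), 3, label = paste("z-score for", term))
  }
})

test_that("partially-adjusted models isolate the active covariate", {
  # only physical function drives the outcome; other partial ORs stay near 1
  coefs <- c(intercept = 1.4, age_decade = 0, sex_female = 0,
             duration_years = 0, fatigue = 0, phys_function = -0.35,
             anxiety = 0, depression = 0, pain = 0)
  cfg <- clean_config(n_patients = 12000, coefficients = coefs)
  mf <- prepare_model_frame(score_cohort(simulate_cohort(cfg, 17)))
  fits <- partially_adjusted_models(mf)
  or_of <- function(v, term) {
    cf <- fits[[v]]$coefficients
    cf$odds_ratio[cf$term == term]
  }
  expect_lt(or_of("phys_function", "phys_function"), 0.8)
  # inert covariates that are independent of physical function
  for (v in c("age_decade", "duration_years")) {
    expect_lt(abs(log(or_of(v, v))), 0.1)
  }
  # fatigue shares the latent severity with physical function, so its partial
  # association is confounded upward but vanishes under mutual adjustment
  expect_gt(or_of("fatigue", "fatigue"), 1.05)
  full <- fully_adjusted_model(mf)$coefficients
  expect_lt(abs(log(full$odds_ratio[full$term == "fatigue"])), 0.12)
  # determinism across repeated calls
  fits2 <- partially_adjusted_models(mf)
  expect_equal(fits[["fatigue"]]$coefficients, fits2[["fatigue"]]$coefficients)
})

test_that("fully-adjusted model reports the complete-case count", {
  cfg <- sim_config(n_patients = 3000)
  mf <- prepare_model_frame(score_cohort(simulate_cohort(cfg, 19)))
  fit <- fully_adjusted_model(mf)
  expect_equal(fit$n, sum(stats::complete.cases(mf)))
  expect_lt(fit$n, nrow(mf))
})

test_that("group summaries report medians, IQRs and available-case counts", {
  co <- score_cohort(simulate_cohort(sim_config(n_patients = 800), 3))
  smy <- summarize_by_employment(co)

  # available-case n never exceeds group size; percentages sum to 100 per row
  sizes <- table(co$employment_status != "currently_employed")
  expect_true(all(smy$continuous$n_employed <=
                    sum(co$employment_status == "currently_employed", na.rm = TRUE)))
  expect_equal(smy$categorical$pct_employed + smy$categorical$pct_discontinued,
               rep(100, nrow(smy$categorical)))

  # engineered durations reproduce a known median and IQR
  fixed <- tibble::tibble(
    age = rep(40, 5), sex = rep("female", 5),
    employment_status = factor(rep("currently_employed", 5),
                               levels = levels(co$employment_status)),
    duration_illness = c(15, 25, 35, 60, 84),
    chalder_total = NA_real_, sf36pf_total = NA_real_,
    hads_anxiety = NA_real_, hads_depression = NA_real_, vas = NA_real_
  )
  smy2 <- summarize_by_employment(fixed)
  dur <- smy2$continuous[smy2$continuous$variable == "duration_illness", ]
  expect_equal(dur$median_employed, 35)
  expect_equal(dur$q1_employed, 25)
  expect_equal(dur$q3_employed, 60)

  # singleton group: median is the value, IQR degenerate
  one <- fixed[3, ]
  dur1 <- summarize_by_employment(one)$continuous
  dur1 <- dur1[dur1$variable == "duration_illness", ]
  expect_equal(dur1$median_employed, 35)
  expect_equal(dur1$q1_employed, dur1$q3_employed)
})

test_that("association tests match their reference implementations", {
  sex_tab <- sex_status_counts()
  res <- test_association(sex_tab)
  expect_equal(res$p_value,
               stats::chisq.test(sex_tab, correct = FALSE)$p.value)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$p_value, 0.01)

  age_tab <- age_status_counts()
  expect_lt(test_association(age_tab)$p_value, 0.001)

  # identical balanced groups give p = 1
  expect_equal(test_association(cbind(c(50, 50), c(50, 50)))$p_value, 1)

  # trend test equals the reference trend statistic
  tr <- test_association(age_tab, method = "trend")
  ref <- stats::prop.trend.test(age_tab[, 2], rowSums(age_tab))
  expect_equal(tr$p_value, ref$p.value)
  expect_lt(tr$p_value, 0.001)

  # pooled-variance t on a cohort, against the reference
  co <- score_cohort(simulate_cohort(sim_config(n_patients = 500), 37))
  res_t <- test_association(co, "chalder_total")
  keep <- co$employment_status %in% c("currently_employed",
                                      "temporarily_discontinued",
                                      "indefinitely_discontinued")
  g <- co$employment_status[keep] != "currently_employed"
  ref_t <- stats::t.test(co$chalder_total[keep][g], co$chalder_total[keep][!g],
                         var.equal = TRUE)
  expect_equal(res_t$p_value, ref_t$p.value)

  # zero within-group variance directs to an exact alternative
  degenerate <- tibble::tibble(
    employment_status = factor(rep(c("currently_employed",
                                     "indefinitely_discontinued"), each = 4),
                               levels = levels(co$employment_status)),
    score = rep(c(1, 2), each = 4)
  )
  expect_error(test_association(degenerate, "score"), "exact")
})
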