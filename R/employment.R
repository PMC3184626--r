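# Descriptive comparison of employed vs discontinued groups, association
# tests, and logistic regression (partially and fully adjusted) for
# discontinuation of employment.

#' Build the regression model frame from a scored cohort
#'
#' Resolves the 4-category employment status to a binary outcome
#' (`discontinued`: temporary + indefinite pooled = 1, currently employed =
#' 0; "other" and missing excluded), converts age to a linear per-decade term
#' via the age-band midpoint, illness duration to years, and rescales the
#' four inventory totals and the pain rating to 0-10.
#'
#' @param records Scored cohort (see [score_cohort()]).
#' @return Tibble with `discontinued`, `age_decade`, `sex`, `duration_years`,
#'   `fatigue`, `phys_function`, `anxiety`, `depression`, `pain`, `centre`,
#'   `year`.
#' @export
prepare_model_frame <- function(records) {
  records <- dplyr::filter(
    records,
    .data$employment_status %in% c("currently_employed",
                                   "temporarily_discontinued",
                                   "indefinitely_discontinued")
  )
  tibble::tibble(
    discontinued = as.integer(
      records$employment_status != "currently_employed"),
    age_decade = age_band_midpoint(assign_age_band(records$age)) / 10,
    sex = factor(records$sex, levels = SEX_LEVELS),
    duration_years = records$duration_illness / 12,
    fatigue = rescale_for_regression(records$chalder_total, 33),
    phys_function = rescale_for_regression(records$sf36pf_total, 100),
    anxiety = rescale_for_regression(records$hads_anxiety, 21),
    depression = rescale_for_regression(records$hads_depression, 21),
    pain = rescale_for_regression(records$vas, 100),
    centre = factor(records$centre),
    year = factor(records$assessment_year)
  )
}

MODEL_COVARIATES <- c("age_decade", "sex", "duration_years", "fatigue",
                      "phys_function", "anxiety", "depression", "pain")

# Stable Bernoulli log-likelihood at linear predictor eta
bernoulli_loglik <- function(y, eta) {
  sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary outcome. Newton/IRLS updates with step
#' halving (so the log-likelihood is non-decreasing across iterations);
#' convergence when the largest absolute coefficient change falls below
#' `tol` (default 1e-8), capped at `max_iter` iterations. Wald 95% CIs
#' (estimate +/- z * SE) are exponentiated to odds-ratio scale. Separation is
#' flagged as non-convergence with a diagnostic rather than reported
#' silently; a rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param formula Model formula; the response must be 0/1 (or logical).
#' @param data Data frame; rows with missing values in the model variables
#'   are dropped (complete-case analysis) and the count retained is reported.
#' @param level Confidence level (default 0.95).
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return Object of class `logistic_fit`: `$coefficients` (term, estimate,
#'   std_error, odds_ratio, ci_low, ci_high, p_value), `$n`, `$converged`,
#'   `$loglik_trace`, `$formula`.
#' @export
fit_logistic <- function(formula, data, level = 0.95, tol = 1e-8,
                         max_iter = 100L) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  X <- model.matrix(attr(mf, "terms"), mf)

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  p <- ncol(X)
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  ll <- bernoulli_loglik(y, eta)
  trace <- ll
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    step <- beta_new - beta
    # step halving guarantees likelihood ascent
    for (h in 0:20) {
      cand <- beta + step / 2^h
      eta_cand <- drop(X %*% cand)
      ll_cand <- bernoulli_loglik(y, eta_cand)
      if (ll_cand >= ll - 1e-12) break
    }
    delta <- max(abs(cand - beta))
    beta <- cand; eta <- eta_cand; ll <- ll_cand
    trace <- c(trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }

  if (!converged || max(abs(beta)) > 15) {
    converged <- FALSE
    warning("possible complete or quasi-complete separation: ",
            "fit did not converge (max |coef| = ",
            format(max(abs(beta)), digits = 3), ")")
  }

  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  cov_beta <- solve(t(X * w) %*% X)
  se <- sqrt(diag(cov_beta))
  zq <- qnorm(1 - (1 - level) / 2)
  zstat <- beta / se
  beta <- unname(beta); se <- unname(se)
  coef_tbl <- tibble::tibble(
    term = colnames(X),
    estimate = beta,
    std_error = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - zq * se),
    ci_high = exp(beta + zq * se),
    p_value = 2 * pnorm(-abs(zstat))
  )
  structure(
    list(coefficients = coef_tbl, n = nrow(X), converged = converged,
         loglik = ll, loglik_trace = trace, formula = formula,
         level = level),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n,
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(dplyr::mutate(x$coefficients,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4))))
  invisible(x)
}

complete_case_frame <- function(frame, covariates = MODEL_COVARIATES,
                                adjust = c("centre", "year")) {
  cols <- c("discontinued", covariates, adjust)
  frame[complete.cases(frame[, cols]), cols, drop = FALSE]
}

#' Partially-adjusted models: each covariate alone, adjusted for centre and
#' year
#'
#' Every covariate is fitted in its own logistic model together with centre
#' and assessment-year indicators, on the complete-case set for all
#' covariates jointly (so all models share one analysis population).
#'
#' @param frame Model frame from [prepare_model_frame()].
#' @param covariates Covariates to rotate through.
#' @param adjust Adjustment variables included in every model.
#' @return Named list of `logistic_fit` objects, one per covariate.
#' @export
partially_adjusted_models <- function(frame, covariates = MODEL_COVARIATES,
                                      adjust = c("centre", "year")) {
  cc <- complete_case_frame(frame, covariates, adjust)
  fits <- lapply(covariates, function(v) {
    f <- stats::reformulate(c(v, adjust), response = "discontinued")
    fit_logistic(f, cc)
  })
  setNames(fits, covariates)
}

#' Fully-adjusted model: all covariates jointly, plus centre and year
#'
#' @inheritParams partially_adjusted_models
#' @return A single `logistic_fit`; `$n` is the complete-case count.
#' @export
fully_adjusted_model <- function(frame, covariates = MODEL_COVARIATES,
                                 adjust = c("centre", "year")) {
  cc <- complete_case_frame(frame, covariates, adjust)
  f <- stats::reformulate(c(covariates, adjust), response = "discontinued")
  fit_logistic(f, cc)
}

# Descriptive comparison -------------------------------------------------------

#' Compare characteristics of employed and discontinued groups
#'
#' Categorical variables (age band, sex) are tabulated with row-wise
#' percentages across the two groups; continuous variables are summarised as
#' median and interquartile range (25th-75th percentiles, linear
#' interpolation) on available cases per variable.
#'
#' @param records Scored cohort.
#' @return List with `categorical` and `continuous` summary tibbles.
#' @export
summarize_by_employment <- function(records) {
  frame <- dplyr::filter(
    records,
    .data$employment_status %in% c("currently_employed",
                                   "temporarily_discontinued",
                                   "indefinitely_discontinued")
  ) |>
    dplyr::mutate(
      group = factor(ifelse(.data$employment_status == "currently_employed",
                            "employed", "discontinued"),
                     levels = c("employed", "discontinued")),
      age_band = assign_age_band(.data$age)
    )

  cat_one <- function(var) {
    tab <- table(frame[[var]], frame$group)
    tot <- rowSums(tab)
    tibble::tibble(
      variable = var,
      level = rownames(tab),
      n_employed = as.integer(tab[, "employed"]),
      n_discontinued = as.integer(tab[, "discontinued"]),
      pct_employed = unname(ifelse(tot > 0, 100 * tab[, "employed"] / tot,
                                   NA_real_)),
      pct_discontinued = unname(ifelse(tot > 0,
                                       100 * tab[, "discontinued"] / tot,
                                       NA_real_))
    )
  }
  categorical <- dplyr::bind_rows(cat_one("age_band"), cat_one("sex"))

  cont_vars <- c("duration_illness", "chalder_total", "sf36pf_total",
                 "hads_anxiety", "hads_depression", "vas")
  cont_one <- function(var) {
    by_group <- function(g) {
      x <- frame[[var]][frame$group == g]
      x <- x[!is.na(x)]
      if (length(x) == 0) {
        return(c(n = 0, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
      }
      c(n = length(x), median = median(x),
        q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
    }
    e <- by_group("employed"); d <- by_group("discontinued")
    tibble::tibble(
      variable = var,
      n_employed = as.integer(e[["n"]]), median_employed = e[["median"]],
      q1_employed = e[["q1"]], q3_employed = e[["q3"]],
      n_discontinued = as.integer(d[["n"]]),
      median_discontinued = d[["median"]],
      q1_discontinued = d[["q1"]], q3_discontinued = d[["q3"]]
    )
  }
  continuous <- dplyr::bind_rows(lapply(cont_vars, cont_one))
  list(categorical = categorical, continuous = continuous)
}

#' Association of a characteristic with employment group
#'
#' Chi-squared test (no continuity correction) for categorical variables, a
#' pooled-variance two-sample t-test for continuous ones, or a
#' Cochran-Armitage trend test across ordered levels. `x` may also be a
#' pre-tabulated contingency matrix (groups in columns), in which case the
#' chi-squared (or, with `method = "trend"`, trend) test is applied directly.
#'
#' @param x Scored cohort tibble, or a contingency matrix.
#' @param variable Variable name (data-frame input).
#' @param method `"auto"` picks chi-squared for factors and t for numerics.
#' @return Tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
test_association <- function(x, variable = NULL,
                             method = c("auto", "chisq", "t", "trend")) {
  method <- match.arg(method)
  if (is.matrix(x) || is.table(x)) {
    if (method == "trend") {
      successes <- x[, 2]
      totals <- rowSums(x)
      res <- stats::prop.trend.test(successes, totals)
      return(tibble::tibble(method = "cochran_armitage_trend",
                            statistic = unname(res$statistic),
                            df = unname(res$parameter),
                            p_value = res$p.value))
    }
    res <- stats::chisq.test(x, correct = FALSE)
    return(tibble::tibble(method = "chisq",
                          statistic = unname(res$statistic),
                          df = unname(res$parameter), p_value = res$p.value))
  }

  frame <- dplyr::filter(
    x,
    .data$employment_status %in% c("currently_employed",
                                   "temporarily_discontinued",
                                   "indefinitely_discontinued")
  ) |>
    dplyr::mutate(group = .data$employment_status != "currently_employed")
  v <- frame[[variable]]
  if (method == "auto") {
    method <- if (is.numeric(v)) "t" else "chisq"
  }
  if (method == "t") {
    g1 <- v[frame$group & !is.na(v)]
    g0 <- v[!frame$group & !is.na(v)]
    if (sd(g0) == 0 || sd(g1) == 0) {
      stop("zero variance within a group; use an exact test instead")
    }
    res <- stats::t.test(g1, g0, var.equal = TRUE)
    tibble::tibble(method = "t_pooled", statistic = unname(res$statistic),
                   df = unname(res$parameter), p_value = res$p.value)
  } else if (method == "trend") {
    tab <- table(v, frame$group)
    test_association(tab, method = "trend")
  } else {
    tab <- table(v, frame$group)
    test_association(tab)
  }
}
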