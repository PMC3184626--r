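# Human-capital productivity losses: the unemployment-fraction estimator and
# the stratified cost table (losses, pooled per-person losses, subtotals).

#' Estimate the unemployment fraction from an external sample
#'
#' The fraction of the illness period spent out of work, by sex. The default
#' estimator averages the per-record ratios (duration unemployed)/(duration
#' ill) and attaches a t-interval: mean +/- t(n-1, 0.975) * SE. The
#' alternative `"ratio_of_means"` divides the mean unemployment duration by
#' the mean illness duration, with a delta-method interval. Records with zero
#' illness duration are rejected with a diagnostic.
#'
#' @param sample External-sample tibble (see [load_external_sample()]).
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param level Confidence level.
#' @return Tibble with one row per sex: `sex`, `n`, `mean_fraction`,
#'   `ci_low`, `ci_high`, `method`.
#' @export
estimate_unemployment_fraction <- function(sample,
                                           method = c("mean_of_ratios",
                                                      "ratio_of_means"),
                                           level = 0.95) {
  method <- match.arg(method)
  bad <- sample$duration_illness_months <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with zero/negative illness duration rejected")
    sample <- sample[!bad, , drop = FALSE]
  }
  alpha <- 1 - level
  one_sex <- function(dat) {
    n <- nrow(dat)
    if (n < 2) stop("need at least 2 records per sex to estimate the fraction")
    u <- dat$duration_unemployment_months
    i <- dat$duration_illness_months
    if (method == "mean_of_ratios") {
      r <- u / i
      m <- mean(r)
      se <- sd(r) / sqrt(n)
    } else {
      m <- mean(u) / mean(i)
      # delta method for a ratio of means
      v <- (var(u) - 2 * m * stats::cov(u, i) + m^2 * var(i)) / (n * mean(i)^2)
      se <- sqrt(max(v, 0))
    }
    tq <- qt(1 - alpha / 2, df = n - 1)
    tibble::tibble(n = n, mean_fraction = m,
                   ci_low = m - tq * se, ci_high = m + tq * se)
  }
  out <- dplyr::group_by(sample, .data$sex) |>
    dplyr::group_modify(~ one_sex(.x)) |>
    dplyr::ungroup()
  dplyr::mutate(out, method = method)
}

#' Productivity loss of one sex-and-age stratum
#'
#' The human-capital loss accumulated before assessment: the product of the
#' number of patients, the fraction who had discontinued employment, the
#' median illness duration converted to years (12 months per year), the
#' unemployment fraction for that sex, and the stratum's mean annual income.
#' Computed at full floating precision; rounding is a display concern.
#'
#' @param n Patients in the stratum.
#' @param frac Proportion who discontinued employment.
#' @param months Median duration of illness (months).
#' @param fraction Unemployment fraction (duration unemployed / duration
#'   ill) for the stratum's sex.
#' @param income Mean annual income (currency per year).
#' @return Loss in currency units (vectorised).
#' @export
#' @examples
#' stratum_loss(72, 0.48, 30, 0.52, 23460)  # ~1,054,012
stratum_loss <- function(n, frac, months, fraction, income) {
  args <- cbind(n, frac, months, fraction, income)
  if (any(args < 0, na.rm = TRUE)) stop("all inputs must be nonnegative")
  n * frac * (months / 12) * fraction * income
}

#' Per-person loss over a pooled group
#'
#' Total loss divided by total patients across the strata pooled into one
#' reporting group.
#'
#' @param loss Vector of stratum losses.
#' @param n Vector of stratum patient counts.
#' @return Currency per patient.
#' @export
per_person_loss <- function(loss, n) {
  if (length(loss) == 0 || sum(n) == 0) stop("pooled group must contain patients")
  sum(loss) / sum(n)
}

#' Pooled reporting group of an age band
#'
#' The 18-21 band is pooled into 22-29 (reported as 18-29) for per-person
#' losses, access rates and national projection; all other bands stand alone.
#'
#' @param age_band Character/factor vector of band labels.
#' @return Character vector of group labels.
#' @export
pooled_group <- function(age_band) {
  ifelse(as.character(age_band) %in% c("18-21", "22-29"), "18-29",
         as.character(age_band))
}

POOLED_GROUP_LEVELS <- c("18-29", "30-39", "40-49", "50-59", "60-64")

#' Stratified human-capital cost table
#'
#' Joins per-stratum cohort summaries with the economics table and the
#' per-sex unemployment fractions, computes each stratum's productivity loss,
#' pooled per-person losses, per-sex subtotals and the grand total with
#' per-patient averages. All arithmetic is at full precision.
#'
#' @param summaries Tibble with `sex`, `age_band`, `n_patients`,
#'   `frac_discontinued`, `median_illness_months` (one row per stratum), as
#'   from [reference_stratum_summary()] or [cohort_stratum_summary()].
#' @param economics Economics tibble (see [load_economics_table()]).
#' @param fractions Tibble with `sex` and `mean_fraction`, as from
#'   [estimate_unemployment_fraction()] or
#'   [reference_unemployment_fractions()].
#' @return Object of class `cost_table`: `$strata` (per-stratum losses),
#'   `$groups` (pooled per-person losses), `$by_sex` (subtotals), `$total`.
#' @export
compute_cost_table <- function(summaries, economics, fractions) {
  key <- function(tbl) paste(tbl$sex, tbl$age_band)
  missing_econ <- setdiff(key(summaries), key(economics))
  if (length(missing_econ) > 0) {
    stop("no economics row for stratum/strata: ",
         paste(missing_econ, collapse = "; "))
  }
  strata <- dplyr::inner_join(
    summaries,
    dplyr::select(economics, "sex", "age_band", "mean_annual_income"),
    by = c("sex", "age_band")
  ) |>
    dplyr::left_join(dplyr::select(fractions, "sex", "mean_fraction"),
                     by = "sex") |>
    dplyr::mutate(
      loss = stratum_loss(.data$n_patients, .data$frac_discontinued,
                          .data$median_illness_months, .data$mean_fraction,
                          .data$mean_annual_income),
      group = factor(pooled_group(.data$age_band),
                     levels = POOLED_GROUP_LEVELS)
    ) |>
    dplyr::arrange(.data$sex, .data$age_band)

  groups <- dplyr::group_by(strata, .data$sex, .data$group) |>
    dplyr::summarise(
      n = sum(.data$n_patients),
      loss = sum(.data$loss),
      .groups = "drop"
    ) |>
    dplyr::mutate(per_person_loss = .data$loss / .data$n)

  by_sex <- dplyr::group_by(strata, .data$sex) |>
    dplyr::summarise(
      n = sum(.data$n_patients),
      total_loss = sum(.data$loss),
      .groups = "drop"
    ) |>
    dplyr::mutate(per_patient = .data$total_loss / .data$n)

  total <- tibble::tibble(
    n = sum(by_sex$n),
    total_loss = sum(by_sex$total_loss),
    per_patient = sum(by_sex$total_loss) / sum(by_sex$n)
  )

  structure(
    list(strata = strata, groups = groups, by_sex = by_sex, total = total,
         fractions = fractions),
    class = "cost_table"
  )
}

#' @export
print.cost_table <- function(x, ...) {
  cat("Stratified human-capital productivity losses\n")
  show <- dplyr::mutate(x$strata, loss = round(.data$loss))
  print(dplyr::select(show, "sex", "age_band", "n_patients",
                      "frac_discontinued", "median_illness_months", "loss"),
        n = Inf)
  cat("\nSubtotals:\n")
  print(dplyr::mutate(x$by_sex, total_loss = round(.data$total_loss),
                      per_patient = round(.data$per_patient)))
  cat(sprintf("\nTotal loss %s over %d patients (%s per patient)\n",
              format(round(x$total$total_loss), big.mark = ","), x$total$n,
              format(round(x$total$per_patient), big.mark = ",")))
  invisible(x)
}

#' Per-stratum summaries computed from patient records
#'
#' Builds the cost-model inputs from a patient-level cohort: stratum size,
#' fraction discontinued (temporary + indefinite over records with any
#' recorded status; set `include_other = FALSE` to drop "other" from the
#' denominator), and median illness duration on available cases.
#'
#' @param records Patient-record tibble.
#' @param include_other Keep "other" in the discontinuation denominator?
#' @return Tibble in the shape expected by [compute_cost_table()].
#' @export
cohort_stratum_summary <- function(records, include_other = TRUE) {
  records <- dplyr::mutate(records, age_band = assign_age_band(.data$age))
  denom_levels <- c("currently_employed", "temporarily_discontinued",
                    "indefinitely_discontinued",
                    if (include_other) "other")
  dplyr::group_by(records, .data$sex, .data$age_band, .drop = FALSE) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      frac_discontinued = {
        st <- .data$employment_status
        denom <- sum(st %in% denom_levels, na.rm = TRUE)
        num <- sum(st %in% c("temporarily_discontinued",
                             "indefinitely_discontinued"), na.rm = TRUE)
        if (denom > 0) num / denom else NA_real_
      },
      median_illness_months = median(.data$duration_illness, na.rm = TRUE),
      .groups = "drop"
    )
}
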