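# Nationwide extrapolation of the cohort's productivity losses via service
# access rates, plus the two one-way sensitivity analyses.

#' Annual service-access rate per 100,000 population
#'
#' Patients in the group divided by the number of study years, divided by the
#' catchment population, scaled to 100,000. Full precision is carried
#' forward; printed rates are rounded for display only.
#'
#' @param n Patients assessed over the study period.
#' @param years Study duration in years (default 4).
#' @param catchment Catchment population (persons).
#' @return Rate per 100,000 per year (vectorised).
#' @export
#' @examples
#' access_rate(98, 4, 655664)       # ~3.74
#' access_rate(2170, 4, 4701710)    # ~11.54
access_rate <- function(n, years = 4, catchment) {
  if (any(years <= 0)) stop("years must be > 0")
  if (any(catchment <= 0, na.rm = TRUE)) stop("catchment population must be > 0")
  (n / years) / catchment * 1e5
}

pooled_economics <- function(economics) {
  dplyr::mutate(economics,
                group = factor(pooled_group(.data$age_band),
                               levels = POOLED_GROUP_LEVELS)) |>
    dplyr::group_by(.data$sex, .data$group) |>
    dplyr::summarise(
      catchment = sum(.data$pct_population, na.rm = TRUE),
      uk_population = 1000 * sum(.data$uk_population_thousands, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Project cohort losses to nationwide annual productivity costs
#'
#' For each pooled sex-and-age group: the access rate from the group's
#' patient count and catchment population; projected annual patients = rate x
#' UK population / 100,000 (unrounded values carried forward); projected cost
#' = projected patients x the group's per-person loss. Totals by sex and
#' overall are sums of the unrounded group values.
#'
#' @param cost_table A [compute_cost_table()] result.
#' @param economics Economics tibble carrying `pct_population` (catchment)
#'   and `uk_population_thousands`.
#' @param years Study duration in years (default 4).
#' @return Object of class `national_estimate`: `$groups`, `$by_sex`,
#'   `$total` (with `rate`, `projected_patients`, `projected_cost`).
#' @export
national_projection <- function(cost_table, economics, years = 4) {
  econ <- pooled_economics(economics)
  groups <- dplyr::inner_join(cost_table$groups, econ,
                              by = c("sex", "group"))
  unmatched <- dplyr::anti_join(cost_table$groups, econ, by = c("sex", "group"))
  if (nrow(unmatched) > 0) {
    stop("no population figures for group(s): ",
         paste(unmatched$sex, unmatched$group, collapse = "; "))
  }
  groups <- dplyr::mutate(
    groups,
    rate = access_rate(.data$n, years, .data$catchment),
    projected_patients = .data$rate * .data$uk_population / 1e5,
    projected_cost = .data$projected_patients * .data$per_person_loss
  )
  by_sex <- dplyr::group_by(groups, .data$sex) |>
    dplyr::summarise(
      n = sum(.data$n),
      catchment = sum(.data$catchment),
      projected_patients = sum(.data$projected_patients),
      projected_cost = sum(.data$projected_cost),
      .groups = "drop"
    ) |>
    dplyr::mutate(rate = access_rate(.data$n, years, .data$catchment))
  total <- tibble::tibble(
    n = sum(by_sex$n),
    catchment = sum(by_sex$catchment),
    rate = access_rate(sum(by_sex$n), years, sum(by_sex$catchment)),
    projected_patients = sum(by_sex$projected_patients),
    projected_cost = sum(by_sex$projected_cost)
  )
  structure(list(groups = groups, by_sex = by_sex, total = total,
                 years = years),
            class = "national_estimate")
}

#' @export
print.national_estimate <- function(x, ...) {
  cat("Nationwide annual projection (study years =", x$years, ")\n")
  show <- dplyr::mutate(
    x$groups, rate = round(.data$rate, 2),
    projected_patients = round(.data$projected_patients),
    projected_cost = round(.data$projected_cost))
  print(dplyr::select(show, "sex", "group", "n", "rate",
                      "projected_patients", "projected_cost"), n = Inf)
  cat(sprintf(
    "\nOverall: %.2f per 100,000 per year; %s projected patients; cost %s\n",
    x$total$rate, format(round(x$total$projected_patients), big.mark = ","),
    format(round(x$total$projected_cost), big.mark = ",")))
  invisible(x)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' One-way sensitivity analysis of the national cost total
#'
#' Re-runs the whole pipeline (cost table then national projection) twice
#' with one parameter set to the lower and upper bounds of its 95%
#' confidence interval, all else held fixed.
#'
#' * `"unemployment_fraction"`: both sexes' fractions set jointly to their
#'   CI bounds (taken from the `fractions` table's `ci_low`/`ci_high`, or
#'   supplied via `bounds`: a tibble with `sex`, `low`, `high`).
#' * `"discontinued_proportion"`: every stratum's discontinued proportion set
#'   jointly to its Wilson 95% bound, computed from the stratum counts.
#'
#' @param summaries,economics,fractions As for [compute_cost_table()].
#' @param parameter Which parameter to vary.
#' @param bounds Optional per-sex bounds tibble (`sex`, `low`, `high`) for
#'   the unemployment fraction.
#' @param years Study duration in years.
#' @param level Confidence level for the Wilson intervals.
#' @return Object of class `sensitivity_result`: parameter name, the bounds
#'   used, and `base_total`, `low_total`, `high_total` (national annual
#'   cost).
#' @export
sensitivity_one_way <- function(summaries, economics, fractions,
                                parameter = c("unemployment_fraction",
                                              "discontinued_proportion"),
                                bounds = NULL, years = 4, level = 0.95) {
  parameter <- match.arg(parameter)
  run <- function(smy, frac) {
    ct <- compute_cost_table(smy, economics, frac)
    national_projection(ct, economics, years)$total$projected_cost
  }
  base_total <- run(summaries, fractions)

  if (parameter == "unemployment_fraction") {
    if (is.null(bounds)) {
      if (!all(c("ci_low", "ci_high") %in% names(fractions))) {
        stop("fractions table has no ci_low/ci_high; supply `bounds`")
      }
      bounds <- tibble::tibble(sex = fractions$sex,
                               low = fractions$ci_low,
                               high = fractions$ci_high)
    }
    if (any(bounds$low > bounds$high)) stop("bounds must satisfy low <= high")
    if (any(bounds$low < 0 | bounds$high > 1)) {
      stop("fraction bounds must lie in [0, 1]")
    }
    at <- function(side) {
      dplyr::mutate(fractions,
                    mean_fraction = bounds[[side]][match(.data$sex, bounds$sex)])
    }
    low_total <- run(summaries, at("low"))
    high_total <- run(summaries, at("high"))
  } else {
    ci <- t(mapply(function(f, n) wilson_ci(round(f * n), n, level),
                   summaries$frac_discontinued, summaries$n_patients))
    at <- function(col) dplyr::mutate(summaries, frac_discontinued = ci[, col])
    bounds <- tibble::tibble(sex = summaries$sex,
                             age_band = summaries$age_band,
                             low = ci[, "low"], high = ci[, "high"])
    low_total <- run(at("low"), fractions)
    high_total <- run(at("high"), fractions)
  }
  structure(list(parameter = parameter, bounds = bounds,
                 base_total = base_total, low_total = low_total,
                 high_total = high_total),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "One-way sensitivity on %s:\n  base %s, range %s - %s\n",
    x$parameter,
    format(round(x$base_total), big.mark = ","),
    format(round(x$low_total), big.mark = ","),
    format(round(x$high_total), big.mark = ",")))
  invisible(x)
}

#' Write the cost and projection results to files
#'
#' Emits a per-stratum cost table CSV, a pooled-group national projection
#' CSV, an optional sensitivity CSV, a plain-text narrative summary of the
#' headline figures, and a machine-readable JSON of every total. Outputs are
#' deterministic: re-rendering identical inputs yields byte-identical files.
#'
#' @param cost_table A [compute_cost_table()] result.
#' @param national A [national_projection()] result.
#' @param sensitivities Optional list of `sensitivity_result` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(cost_table, national, sensitivities = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  strata_out <- dplyr::mutate(cost_table$strata,
                              loss = round(.data$loss, 2))
  p <- file.path(dir, "cost_table.csv")
  readr::write_csv(strata_out, p, na = ""); paths <- c(paths, p)

  proj_out <- dplyr::mutate(
    national$groups, rate = round(.data$rate, 4),
    projected_patients = round(.data$projected_patients, 2),
    projected_cost = round(.data$projected_cost, 2))
  p <- file.path(dir, "national_projection.csv")
  readr::write_csv(proj_out, p, na = ""); paths <- c(paths, p)

  if (length(sensitivities) > 0) {
    sens_out <- dplyr::bind_rows(lapply(sensitivities, function(s) {
      tibble::tibble(parameter = s$parameter,
                     base_total = round(s$base_total, 2),
                     low_total = round(s$low_total, 2),
                     high_total = round(s$high_total, 2))
    }))
    p <- file.path(dir, "sensitivity.csv")
    readr::write_csv(sens_out, p, na = ""); paths <- c(paths, p)
  }

  fmt <- function(x) format(round(x), big.mark = ",", scientific = FALSE)
  lines <- c(
    "Productivity costs of discontinued employment",
    "",
    sprintf("Cohort: %d patients; total loss %s (%s per patient).",
            cost_table$total$n, fmt(cost_table$total$total_loss),
            fmt(cost_table$total$per_patient)),
    sprintf("By sex: %s.",
            paste(sprintf("%s %s (%s per patient)", cost_table$by_sex$sex,
                          fmt(cost_table$by_sex$total_loss),
                          fmt(cost_table$by_sex$per_patient)),
                  collapse = "; ")),
    sprintf("Overall access rate %.2f per 100,000 per year.", national$total$rate),
    sprintf("Projected %s patients per year nationwide; annual cost %s.",
            fmt(national$total$projected_patients),
            fmt(national$total$projected_cost))
  )
  if (length(sensitivities) > 0) {
    lines <- c(lines, "", "One-way sensitivity analyses:",
               vapply(sensitivities, function(s) {
                 sprintf("  %s: %s - %s", s$parameter, fmt(s$low_total),
                         fmt(s$high_total))
               }, ""))
  }
  p <- file.path(dir, "summary.txt")
  writeLines(lines, p); paths <- c(paths, p)

  res <- list(
    total_loss = cost_table$total$total_loss,
    per_patient_loss = cost_table$total$per_patient,
    overall_access_rate_per_100k = national$total$rate,
    projected_annual_patients = national$total$projected_patients,
    projected_annual_cost = national$total$projected_cost
  )
  if (length(sensitivities) > 0) {
    res$sensitivity <- lapply(sensitivities, function(s) {
      list(parameter = s$parameter, low = s$low_total, high = s$high_total)
    })
  }
  p <- file.path(dir, "results.json")
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
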