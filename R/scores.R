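# Inventory definitions: item count, per-item maximum, attainable grid step.
# Chalder Fatigue 11 items scored 0-3 ("0-3 method"), total 0-33;
# SF-36 physical function 10 items scored 0/5/10, total 0-100;
# HADS anxiety/depression 7 items each scored 0-3, totals 0-21;
# VAS pain is a single 0-100 rating with no item structure.
INVENTORIES <- list(
  chalder = list(n_items = 11L, item_max = 3,  step = 1, scale_max = 33),
  sf36pf  = list(n_items = 10L, item_max = 10, step = 5, scale_max = 100),
  hadsA   = list(n_items = 7L,  item_max = 3,  step = 1, scale_max = 21),
  hadsD   = list(n_items = 7L,  item_max = 3,  step = 1, scale_max = 21)
)

#' Printed scale maxima of the five patient-reported outcomes
#'
#' @return Named numeric vector (chalder 33, sf36pf 100, hads subscales 21,
#'   vas 100).
#' @export
scale_maxima <- function() {
  c(chalder_total = 33, sf36pf_total = 100, hads_anxiety = 21,
    hads_depression = 21, vas = 100)
}

round_half_up <- function(x) floor(x + 0.5)

#' Score one inventory from item responses
#'
#' Applies the missing-item rule used for all four inventories: with no
#' missing items the total is the plain sum; with exactly one missing item an
#' adjusted total is calculated by pro-rating the answered items by
#' `n_items / (n_items - 1)` (equivalent to imputing the mean of the answered
#' items), rounded half-up to the nearest attainable score; with more than one
#' missing item the total is coded as missing.
#'
#' @param items Numeric vector of item responses (NA = unanswered).
#' @param n_items Expected number of items.
#' @param item_max Per-item maximum response.
#' @param step Attainable-score grid step (5 for the SF-36 physical function
#'   subscale, whose items are scored 0/5/10; 1 otherwise).
#' @return The total score, or `NA` if the missing rule fired.
#' @export
#' @examples
#' score_inventory(rep(3, 11), 11, 3)            # 33
#' score_inventory(c(rep(2, 10), NA), 11, 3)     # 22: 20 * 11/10
score_inventory <- function(items, n_items, item_max, step = 1) {
  if (length(items) != n_items) {
    stop("expected ", n_items, " items, got ", length(items))
  }
  bad <- which(!is.na(items) & (items < 0 | items > item_max))
  if (length(bad) > 0) {
    stop("item value out of range [0, ", item_max, "] at index ",
         paste(bad, collapse = ", "))
  }
  n_missing <- sum(is.na(items))
  if (n_missing > 1) return(NA_real_)
  total <- sum(items, na.rm = TRUE)
  if (n_missing == 1) {
    total <- round_half_up(total * n_items / (n_items - 1) / step) * step
  }
  total
}

# Vectorised scoring over an item matrix (rows = patients).
score_inventory_matrix <- function(m, n_items, item_max, step = 1) {
  stopifnot(ncol(m) == n_items)
  if (any(!is.na(m) & (m < 0 | m > item_max))) {
    stop("item value out of range [0, ", item_max, "]")
  }
  n_missing <- rowSums(is.na(m))
  total <- rowSums(m, na.rm = TRUE)
  adj <- round_half_up(total * n_items / (n_items - 1) / step) * step
  out <- ifelse(n_missing == 0, total, ifelse(n_missing == 1, adj, NA_real_))
  out
}

#' Score all five patient-reported outcomes for a cohort
#'
#' Adds `chalder_total`, `sf36pf_total`, `hads_anxiety`, `hads_depression`
#' to a patient table from its item columns (the HADS missing rule is applied
#' per subscale); `vas` passes through unchanged, missing when unanswered.
#'
#' @param records Patient-record tibble with the item columns named as in
#'   [item_columns()].
#' @return The input tibble with four total-score columns appended.
#' @export
score_cohort <- function(records) {
  cols <- item_columns()
  get_matrix <- function(nms) {
    missing_cols <- setdiff(nms, names(records))
    if (length(missing_cols) > 0) {
      stop("missing item column(s): ", paste(missing_cols, collapse = ", "))
    }
    as.matrix(records[, nms])
  }
  records$chalder_total <- score_inventory_matrix(
    get_matrix(cols$chalder), 11L, 3, 1)
  records$sf36pf_total <- score_inventory_matrix(
    get_matrix(cols$sf36pf), 10L, 10, 5)
  records$hads_anxiety <- score_inventory_matrix(
    get_matrix(cols$hadsA), 7L, 3, 1)
  records$hads_depression <- score_inventory_matrix(
    get_matrix(cols$hadsD), 7L, 3, 1)
  records
}

#' Score a single set of item responses
#'
#' @param chalder,sf36pf,hadsA,hadsD Item-response vectors (lengths 11, 10,
#'   7, 7).
#' @param vas Visual-analogue pain rating in \[0, 100\] or `NA`.
#' @return Named list with the five totals (`NA` where the missing rule
#'   fired).
#' @export
score_all <- function(chalder, sf36pf, hadsA, hadsD, vas = NA_real_) {
  if (!is.na(vas) && (vas < 0 || vas > 100)) stop("vas must lie in [0, 100]")
  list(
    chalder_total   = score_inventory(chalder, 11L, 3, 1),
    sf36pf_total    = score_inventory(sf36pf, 10L, 10, 5),
    hads_anxiety    = score_inventory(hadsA, 7L, 3, 1),
    hads_depression = score_inventory(hadsD, 7L, 3, 1),
    vas             = as.numeric(vas)
  )
}

#' Rescale an inventory total to the common 0-10 range
#'
#' Regression coefficients for the different inventories are made comparable
#' by mapping each total linearly onto 0-10: `score * 10 / scale_max`.
#'
#' @param score Total score(s), in `[0, scale_max]`.
#' @param scale_max The inventory's maximum attainable total.
#' @return Rescaled value(s) in \[0, 10\].
#' @export
#' @examples
#' rescale_for_regression(33, 33)   # 10
#' rescale_for_regression(50, 100)  # 5
rescale_for_regression <- function(score, scale_max) {
  if (length(scale_max) != 1 || is.na(scale_max) || scale_max <= 0) {
    stop("scale_max must be a single positive number")
  }
  if (any(!is.na(score) & (score < 0 | score > scale_max))) {
    stop("score outside [0, ", scale_max, "]")
  }
  score * 10 / scale_max
}
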