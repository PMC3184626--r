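# Shared fixtures built in code.

# Published two-by-two of sex by employment group (columns: employed,
# discontinued; rows: female, male) from the descriptive comparison.
sex_status_counts <- function() {
  matrix(c(643, 168, 743, 255), nrow = 2,
         dimnames = list(sex = c("female", "male"),
                         group = c("employed", "discontinued")))
}

# Published age-band by employment group counts.
age_status_counts <- function() {
  cbind(employed = c(59, 153, 265, 202, 119, 13),
        discontinued = c(44, 154, 250, 269, 225, 56))
}

# Expand a contingency table of counts into a minimal scored-cohort tibble
# with a binary employment status, for exercising the regression path.
expand_2x2 <- function(counts) {
  # counts: matrix rows = covariate levels, cols = c(employed, discontinued)
  lev <- rownames(counts)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (j in 1:2) {
      k <- counts[i, j]
      if (k > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          x = lev[i],
          discontinued = rep(j - 1L, k)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# A small well-formed patient table for I/O tests.
tiny_patient_table <- function(n = 3) {
  cfg <- sim_config(n_patients = n)
  simulate_cohort(cfg, 101)
}

# Config with every missingness channel off, for clean recovery studies.
clean_config <- function(...) {
  sim_config(questionnaire_prob = 1, item_miss1_prob = 0, item_miss2_prob = 0,
             duration_missing_prob = 0, status_recorded_prob = 1,
             prob_other = 0, ...)
}

model_term_map <- function() {
  c("(Intercept)" = "intercept", age_decade = "age_decade",
    sexfemale = "sex_female", duration_years = "duration_years",
    fatigue = "fatigue", phys_function = "phys_function",
    anxiety = "anxiety", depression = "depression", pain = "pain")
}
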