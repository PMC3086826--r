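# Record-table builders. Vector arguments are recycled to the id length;
# `pc` is a list of per-person postcode vectors (up to 4 each).

fill_postcodes <- function(df, pc) {
  pc <- rep_len(pc, nrow(df))
  for (k in 1:4) {
    df[[paste0("postcode", k)]] <-
      vapply(pc, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  }
  df
}

make_cohort <- function(study_id,
                        given_name = "ALICE",
                        medicare8 = "12345678",
                        birth_year = 1950, birth_month = 6, birth_day = 15,
                        sex = "F", cob = "AUSTRALIA",
                        pc = list("3000")) {
  n <- length(study_id)
  df <- tibble::tibble(
    study_id = study_id,
    given_name = rep_len(given_name, n),
    medicare8 = rep_len(medicare8, n),
    suffix = derive_suffix(rep_len(given_name, n)),
    birth_year = rep_len(birth_year, n),
    birth_month = rep_len(birth_month, n),
    birth_day = rep_len(birth_day, n),
    sex = rep_len(sex, n),
    country_of_birth = rep_len(cob, n)
  )
  fill_postcodes(df, pc)
}

make_hospital <- function(person_id,
                          medicare8 = "12345678",
                          suffix = "ALI",
                          birth_year = 1950, birth_month = 6, birth_day = 15,
                          sex = "F", cob = "AUSTRALIA",
                          pc = list("3000")) {
  n <- length(person_id)
  df <- tibble::tibble(
    person_id = person_id,
    medicare8 = rep_len(medicare8, n),
    suffix = rep_len(suffix, n),
    birth_year = rep_len(birth_year, n),
    birth_month = rep_len(birth_month, n),
    birth_day = rep_len(birth_day, n),
    sex = rep_len(sex, n),
    country_of_birth = rep_len(cob, n)
  )
  fill_postcodes(df, pc)
}

# hospital table that mirrors a cohort table exactly (true copies)
hospital_copy <- function(cohort, person_id = sub("^S", "H", cohort$study_id)) {
  tibble::tibble(
    person_id = person_id,
    medicare8 = cohort$medicare8,
    suffix = cohort$suffix,
    birth_year = cohort$birth_year,
    birth_month = cohort$birth_month,
    birth_day = cohort$birth_day,
    sex = cohort$sex,
    country_of_birth = cohort$country_of_birth,
    postcode1 = cohort$postcode1,
    postcode2 = cohort$postcode2,
    postcode3 = cohort$postcode3,
    postcode4 = cohort$postcode4
  )
}

# minimal linkage_result for functions that consume results
# (compare_linkage, sensitivity_analysis only touch these fields)
fake_result <- function(links, cohort_ids, label = "fake") {
  structure(
    list(
      links = links,
      cohort_ids = cohort_ids,
      n_cohort = length(cohort_ids),
      unmatched_cohort_ids = setdiff(cohort_ids, links$study_id),
      plan_label = label,
      match_proportion = nrow(links) / length(cohort_ids)
    ),
    class = "linkage_result"
  )
}

# drop the reader's diagnostics attribute for whole-table comparisons
strip_diag <- function(x) {
  attr(x, "diagnostics") <- NULL
  as.data.frame(x)
}

link_set <- function(result) {
  l <- result$links
  sort(paste(l$study_id, l$person_id, l$iteration, sep = "/"))
}

# error model with every rate drawn at random (for fuzzing)
random_error_model <- function() {
  error_model(
    hospital_medicare_missing_rate = runif(1, 0, 0.4),
    cohort_medicare_missing_rate = runif(1, 0, 0.1),
    dob_day_error_rate = runif(1, 0, 0.3),
    dob_gross_error_rate = runif(1, 0, 0.05),
    postcode_change_rate = runif(1, 0, 0.3),
    cob_discrepancy_rate = runif(1, 0, 0.1),
    sex_miscode_rate = runif(1, 0, 0.05),
    suffix_middle_name_rate = runif(1, 0, 0.1),
    family_share_rate = runif(1, 0, 0.3),
    twin_rate = runif(1, 0, 0.05),
    hospital_only_population_multiplier = runif(1, 0, 1.5)
  )
}
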