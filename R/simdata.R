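#' Data-entry error model for synthetic linkage worlds
#'
#' Rates at which the hospital-side copy of a cohort participant is corrupted
#' relative to the roster, emulating the data conditions of a cohort-to-
#' admissions linkage with limited identifiers. Defaults reflect the pilot
#' setting: insurance details present for 100% of the cohort but only ~80% of
#' hospital records; day-of-birth entry errors of 2-10 days and occasional
#' gross year errors of up to 40 years; postcode churn between roster and
#' admission; family members sharing a card number and distinguishable only
#' by the name suffix.
#'
#' @param hospital_medicare_missing_rate Fraction of hospital-side persons
#'   with no insurance number (default 0.20).
#' @param cohort_medicare_missing_rate Fraction of cohort records with no
#'   insurance number (default 0 — fully ascertained at re-interview).
#' @param dob_day_error_rate Fraction of hospital copies whose birth date is
#'   shifted by 2-10 days (sign random).
#' @param dob_gross_error_rate Fraction with a gross birth-year error of 1-40
#'   years (sign random).
#' @param postcode_change_rate Fraction whose hospital-side postcode list
#'   gains a new first postcode (roster postcodes shift down a slot).
#' @param cob_discrepancy_rate Fraction with a discrepant country of birth.
#' @param sex_miscode_rate Fraction with sex miscoded.
#' @param suffix_middle_name_rate Fraction whose hospital-side suffix derives
#'   from a middle name instead of the given name.
#' @param family_share_rate Fraction of cohort members sharing a family card
#'   number with the next member; some sharing pairs also share a 3-letter
#'   name prefix.
#' @param twin_rate Fraction of cohort members that get a hospital-only
#'   demographic "twin" (same birth date, sex, country and postcodes;
#'   different name and card number).
#' @param hospital_only_population_multiplier Ratio of hospital-only
#'   distractor persons to cohort size (default 2).
#' @return An `error_model` list.
#' @export
error_model <- function(hospital_medicare_missing_rate = 0.20,
                        cohort_medicare_missing_rate = 0,
                        dob_day_error_rate = 0.02,
                        dob_gross_error_rate = 0.005,
                        postcode_change_rate = 0.10,
                        cob_discrepancy_rate = 0.01,
                        sex_miscode_rate = 0.005,
                        suffix_middle_name_rate = 0.02,
                        family_share_rate = 0.10,
                        twin_rate = 0.01,
                        hospital_only_population_multiplier = 2) {
  model <- list(
    hospital_medicare_missing_rate = hospital_medicare_missing_rate,
    cohort_medicare_missing_rate = cohort_medicare_missing_rate,
    dob_day_error_rate = dob_day_error_rate,
    dob_gross_error_rate = dob_gross_error_rate,
    postcode_change_rate = postcode_change_rate,
    cob_discrepancy_rate = cob_discrepancy_rate,
    sex_miscode_rate = sex_miscode_rate,
    suffix_middle_name_rate = suffix_middle_name_rate,
    family_share_rate = family_share_rate,
    twin_rate = twin_rate,
    hospital_only_population_multiplier = hospital_only_population_multiplier
  )
  rates <- model[names(model) != "hospital_only_population_multiplier"]
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop("error-model rates must lie in [0, 1]")
  }
  if (model$hospital_only_population_multiplier < 0) {
    stop("hospital_only_population_multiplier must be >= 0")
  }
  structure(model, class = "error_model")
}

#' @return `zero_error_model()`: an [error_model()] with every rate and the
#'   distractor multiplier set to zero — the hospital side is an exact copy
#'   of the cohort.
#' @rdname error_model
#' @export
zero_error_model <- function() {
  error_model(
    hospital_medicare_missing_rate = 0, cohort_medicare_missing_rate = 0,
    dob_day_error_rate = 0, dob_gross_error_rate = 0,
    postcode_change_rate = 0, cob_discrepancy_rate = 0,
    sex_miscode_rate = 0, suffix_middle_name_rate = 0,
    family_share_rate = 0, twin_rate = 0,
    hospital_only_population_multiplier = 0
  )
}

sample_weighted <- function(pool, n, weights = NULL) {
  pool[sample.int(length(pool), n, replace = TRUE, prob = weights)]
}

random_postcodes <- function(n) {
  counts <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  lapply(counts, function(k) sprintf("%04d", sample(3000:3999, k)))
}

set_postcode_slots <- function(df, pcs) {
  for (k in 1:4) {
    df[[paste0("postcode", k)]] <-
      vapply(pcs, function(p) if (length(p) >= k) p[k] else NA_character_, "")
  }
  df
}

# fresh identities (no family structure): demographics + names
gen_people <- function(n, medicare_pool) {
  sex <- sample(c("M", "F"), n, replace = TRUE)
  pick_name <- function(s) {
    ifelse(s == "M",
           sample_weighted(given_names_male, length(s)),
           sample_weighted(given_names_female, length(s)))
  }
  birth_date <- as.Date("1915-01-01") + sample.int(19000, n, replace = TRUE) - 1
  tibble::tibble(
    given_name = pick_name(sex),
    middle_name = pick_name(sex),
    medicare8 = medicare_pool,
    birth_year = as.integer(format(birth_date, "%Y")),
    birth_month = as.integer(format(birth_date, "%m")),
    birth_day = as.integer(format(birth_date, "%d")),
    sex = sex,
    country_of_birth = sample_weighted(country_pool, n, country_weights),
    postcodes = random_postcodes(n)
  )
}

compose_date <- function(year, month, day) {
  # roll invalid day-of-month (e.g. Feb 29 after a year shift) back to the 28th
  d <- parse_iso_date(sprintf("%04d-%02d-%02d", year, month, day))
  bad <- is.na(d)
  if (any(bad)) {
    d[bad] <- parse_iso_date(sprintf("%04d-%02d-28", year[bad], month[bad]))
  }
  d
}

decompose_date <- function(df, d) {
  df$birth_year <- as.integer(format(d, "%Y"))
  df$birth_month <- as.integer(format(d, "%m"))
  df$birth_day <- as.integer(format(d, "%d"))
  df
}

# a name whose 3-letter prefix differs from `avoid`
different_prefix_name <- function(sex, avoid) {
  pool <- if (sex == "M") given_names_male else given_names_female
  pool <- pool[substr(pool, 1, 3) != avoid]
  sample(pool, 1)
}

make_twin_rows <- function(cohort, idx, start_id, medicare_pool) {
  twins <- cohort[idx, c("birth_year", "birth_month", "birth_day", "sex",
                         "country_of_birth", paste0("postcode", 1:4))]
  twins$person_id <- sprintf("T%06d", start_id + seq_along(idx) - 1)
  twins$medicare8 <- medicare_pool
  twins$suffix <- vapply(seq_along(idx), function(i) {
    derive_suffix(different_prefix_name(twins$sex[i], cohort$suffix[idx[i]]))
  }, "")
  twins[c("person_id", "medicare8", "suffix", "birth_year", "birth_month",
          "birth_day", "sex", "country_of_birth", paste0("postcode", 1:4))]
}

#' Generate a paired synthetic cohort/hospital world with known ground truth
#'
#' Builds a cohort roster, a hospital person index containing a corrupted
#' copy of every cohort member (per the [error_model()]) plus demographic
#' twins and hospital-only distractors, an episode table, and the ground
#' truth: the true cohort-to-hospital correspondence and a set of confirmed
#' admissions (one per sampled participant, with medical-record-style date
#' jitter of at most `event_date_jitter` days and occasional missing
#' discharge dates).
#'
#' @param n_cohort Number of cohort participants (>= 1).
#' @param model An [error_model()].
#' @param seed Integer seed; worlds are reproducible for a fixed seed.
#' @param n_events Number of participants given a confirmed admission
#'   (default 5% of the cohort, the pilot's confirmed-event fraction).
#' @param event_date_jitter Maximum +/- days between the confirmed record's
#'   dates and the generating episode (default 2).
#' @return A `linkage_world`: list with `cohort`, `hospital`, `episodes`,
#'   `truth_links` (`study_id`, `person_id`), `truth_events` (confirmed-event
#'   schema of [sensitivity_analysis()]), `model`, `seed`.
#' @export
simulate_linkage_world <- function(n_cohort, model = error_model(), seed,
                                   n_events = max(1, round(0.05 * n_cohort)),
                                   event_date_jitter = 2) {
  stopifnot(n_cohort >= 1, inherits(model, "error_model"),
            n_events <= n_cohort)
  set.seed(seed)

  n_extra <- round(model$hospital_only_population_multiplier * n_cohort)
  # one global card-number pool so family sharing is the only source of
  # duplicate numbers
  medicare_pool <- sprintf(
    "%08d", sample.int(90000000, n_cohort + n_extra + n_cohort) + 9999999
  )

  people <- gen_people(n_cohort, medicare_pool[seq_len(n_cohort)])

  # family card sharing over consecutive pairs; some sharing pairs get
  # colliding 3-letter name prefixes (suffix cannot separate them)
  i <- 1
  while (i < n_cohort) {
    if (runif(1) < model$family_share_rate) {
      people$medicare8[i + 1] <- people$medicare8[i]
      if (runif(1) < 0.3) {
        pair <- collision_name_pairs[[sample.int(
          length(collision_name_pairs), 1
        )]]
        people$given_name[i] <- pair[1]
        people$given_name[i + 1] <- pair[2]
      }
      i <- i + 2
    } else {
      i <- i + 1
    }
  }

  cohort <- tibble::tibble(
    study_id = sprintf("S%05d", seq_len(n_cohort)),
    given_name = people$given_name,
    medicare8 = people$medicare8,
    suffix = derive_suffix(people$given_name),
    birth_year = people$birth_year,
    birth_month = people$birth_month,
    birth_day = people$birth_day,
    sex = people$sex,
    country_of_birth = people$country_of_birth
  )
  cohort <- set_postcode_slots(cohort, people$postcodes)

  # hospital copy of every cohort member, then independent per-record errors
  hosp <- cohort
  hosp$person_id <- sprintf("H%06d", seq_len(n_cohort))
  hit <- function(rate) runif(n_cohort) < rate

  mid <- hit(model$suffix_middle_name_rate)
  hosp$suffix[mid] <- derive_suffix(people$middle_name[mid])

  bd <- compose_date(hosp$birth_year, hosp$birth_month, hosp$birth_day)
  day_err <- hit(model$dob_day_error_rate)
  bd[day_err] <- bd[day_err] +
    sample(c(-1, 1), sum(day_err), replace = TRUE) *
      sample(2:10, sum(day_err), replace = TRUE)
  hosp <- decompose_date(hosp, bd)
  gross <- hit(model$dob_gross_error_rate)
  if (any(gross)) {
    shift <- sample(c(-1, 1), sum(gross), replace = TRUE) *
      sample(1:40, sum(gross), replace = TRUE)
    hosp$birth_year[gross] <- hosp$birth_year[gross] + shift
    d2 <- compose_date(hosp$birth_year[gross], hosp$birth_month[gross],
                       hosp$birth_day[gross])
    hosp[gross, ] <- decompose_date(hosp[gross, ], d2)
  }

  pc_change <- hit(model$postcode_change_rate)
  for (i in which(pc_change)) {
    old <- unlist(hosp[i, paste0("postcode", 1:4)])
    old <- old[!is.na(old)]
    new <- sprintf("%04d", sample(setdiff(3000:3999, as.integer(old)), 1))
    pcs <- utils::head(c(new, old), 4)
    for (k in 1:4) {
      hosp[[paste0("postcode", k)]][i] <-
        if (length(pcs) >= k) pcs[k] else NA_character_
    }
  }

  cobx <- hit(model$cob_discrepancy_rate)
  for (i in which(cobx)) {
    hosp$country_of_birth[i] <-
      sample(setdiff(country_pool, hosp$country_of_birth[i]), 1)
  }
  flip <- hit(model$sex_miscode_rate)
  hosp$sex[flip] <- ifelse(hosp$sex[flip] == "M", "F", "M")
  hosp$medicare8[hit(model$hospital_medicare_missing_rate)] <- NA_character_
  # cohort-side missingness is independent of the hospital's records
  cohort$medicare8[hit(model$cohort_medicare_missing_rate)] <- NA_character_

  hosp$study_id <- NULL
  hosp$given_name <- NULL
  hosp <- hosp[c("person_id", "medicare8", "suffix", "birth_year",
                 "birth_month", "birth_day", "sex", "country_of_birth",
                 paste0("postcode", 1:4))]

  truth_links <- tibble::tibble(
    study_id = cohort$study_id,
    person_id = sprintf("H%06d", seq_len(n_cohort))
  )

  # demographic twins (hospital-only)
  n_twins <- rbinom(1, n_cohort, model$twin_rate)
  if (n_twins > 0) {
    idx <- sample.int(n_cohort, n_twins)
    twin_pool <- medicare_pool[n_cohort + n_extra + seq_len(n_twins)]
    hosp <- dplyr::bind_rows(hosp, make_twin_rows(cohort, idx, 1, twin_pool))
  }

  # hospital-only distractor population
  if (n_extra > 0) {
    extra <- gen_people(n_extra, medicare_pool[n_cohort + seq_len(n_extra)])
    dist <- tibble::tibble(
      person_id = sprintf("D%06d", seq_len(n_extra)),
      medicare8 = extra$medicare8,
      suffix = derive_suffix(extra$given_name),
      birth_year = extra$birth_year,
      birth_month = extra$birth_month,
      birth_day = extra$birth_day,
      sex = extra$sex,
      country_of_birth = extra$country_of_birth
    )
    dist <- set_postcode_slots(dist, extra$postcodes)
    dist$medicare8[runif(n_extra) < model$hospital_medicare_missing_rate] <-
      NA_character_
    hosp <- dplyr::bind_rows(hosp, dist)
  }

  episodes <- gen_episodes(hosp$person_id)

  # confirmed admissions: flag one episode of the participant's true
  # hospital person as AMI/stroke; the confirmed record carries jittered
  # dates and sometimes lacks a discharge date
  ev_idx <- sample.int(n_cohort, n_events)
  ev_pid <- truth_links$person_id[ev_idx]
  ev_eps <- tibble::tibble(
    person_id = ev_pid,
    hospital_name = sample(hospital_pool, n_events, replace = TRUE),
    admission_date = as.Date("1996-07-01") +
      sample.int(4500, n_events, replace = TRUE),
    event_flag = sample(c("AMI", "stroke"), n_events, replace = TRUE)
  )
  ev_eps$discharge_date <- ev_eps$admission_date +
    sample(0:14, n_events, replace = TRUE)
  episodes <- dplyr::bind_rows(
    episodes,
    ev_eps[c("person_id", "hospital_name", "admission_date",
             "discharge_date", "event_flag")]
  )
  jit <- function(n) {
    if (event_date_jitter == 0) rep(0L, n)
    else sample(-event_date_jitter:event_date_jitter, n, replace = TRUE)
  }
  truth_events <- tibble::tibble(
    study_id = truth_links$study_id[ev_idx],
    hospital_name = ev_eps$hospital_name,
    admission_date = ev_eps$admission_date + jit(n_events),
    discharge_date = ev_eps$discharge_date + jit(n_events),
    event_type = ev_eps$event_flag
  )
  truth_events$discharge_date[runif(n_events) < 0.1] <- as.Date(NA)

  structure(
    list(
      cohort = cohort,
      hospital = hosp[sample.int(nrow(hosp)), ],
      episodes = episodes,
      truth_links = truth_links,
      truth_events = truth_events,
      model = model,
      seed = seed
    ),
    class = "linkage_world"
  )
}

gen_episodes <- function(person_ids) {
  k <- rpois(length(person_ids), 1.2)
  pid <- rep(person_ids, k)
  n <- length(pid)
  adm <- as.Date("1996-07-01") + sample.int(4500, n, replace = TRUE)
  tibble::tibble(
    person_id = pid,
    hospital_name = sample(hospital_pool, n, replace = TRUE),
    admission_date = adm,
    discharge_date = adm + sample(0:14, n, replace = TRUE),
    event_flag = "other"
  )
}

#' @export
print.linkage_world <- function(x, ...) {
  cat("<linkage_world> seed", x$seed, "\n")
  cat(sprintf("  cohort %d, hospital persons %d, episodes %d\n",
              nrow(x$cohort), nrow(x$hospital), nrow(x$episodes)))
  cat(sprintf("  truth links %d, confirmed events %d\n",
              nrow(x$truth_links), nrow(x$truth_events)))
  invisible(x)
}

#' Add demographic twins to an existing synthetic world
#'
#' Appends hospital-only persons duplicating randomly chosen cohort members'
#' birth date, sex, country of birth and postcodes, with a different name
#' (different 3-letter prefix) and card number. The ground truth is
#' unchanged: any link to a twin is a false positive. Demographic-only plans
#' are vulnerable to such twins; suffix-bearing plans are not.
#'
#' @param world A `linkage_world`.
#' @param n_twins Number of twins to add (at most the cohort size).
#' @param seed Integer seed.
#' @return The modified `linkage_world`.
#' @export
inject_twins <- function(world, n_twins, seed) {
  stopifnot(inherits(world, "linkage_world"),
            n_twins <= nrow(world$cohort))
  if (n_twins == 0) return(world)
  set.seed(seed)
  idx <- sample.int(nrow(world$cohort), n_twins)
  used <- unique(world$hospital$medicare8)
  pool <- sprintf("%08d", sample.int(90000000, n_twins + length(used)) +
                    9999999)
  pool <- setdiff(pool, used)[seq_len(n_twins)]
  start <- sum(startsWith(world$hospital$person_id, "T")) + 1
  world$hospital <- dplyr::bind_rows(
    world$hospital,
    make_twin_rows(world$cohort, idx, start, pool)
  )
  world
}

#' Write a synthetic world to a directory of delimited files
#'
#' Writes `cohort.csv`, `hospital.csv`, `episodes.csv` in the standard
#' schemas ([record-schemas]) plus `truth_links.csv` and `truth_events.csv`.
#'
#' @param world A `linkage_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "linkage_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(world$cohort, file.path(dir, "cohort.csv"))
  write_hospital(world$hospital, file.path(dir, "hospital.csv"))
  write_episodes(world$episodes, file.path(dir, "episodes.csv"))
  readr::write_csv(world$truth_links, file.path(dir, "truth_links.csv"))
  ev <- world$truth_events
  ev$admission_date <- format(ev$admission_date, "%Y-%m-%d")
  ev$discharge_date <- ifelse(is.na(ev$discharge_date), "",
                              format(ev$discharge_date, "%Y-%m-%d"))
  readr::write_csv(ev, file.path(dir, "truth_events.csv"), na = "")
  invisible(dir)
}
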