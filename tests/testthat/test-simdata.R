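test_that("worlds are reproducible for a fixed seed", {
  a <- simulate_linkage_world(150, error_model(), seed = 8)
  b <- simulate_linkage_world(150, error_model(), seed = 8)
  expect_equal(a$cohort, b$cohort)
  expect_equal(a$hospital, b$hospital)
  expect_equal(a$episodes, b$episodes)
  expect_equal(a$truth_events, b$truth_events)
  c_ <- simulate_linkage_world(150, error_model(), seed = 9)
  expect_false(identical(a$cohort, c_$cohort))
})

test_that("an all-zero model makes the hospital an exact copy of the cohort", {
  w <- simulate_linkage_world(100, zero_error_model(), seed = 1)
  expect_equal(nrow(w$hospital), 100)
  h <- w$hospital[match(w$truth_links$person_id, w$hospital$person_id), ]
  shared <- setdiff(names(h), "person_id")
  expect_equal(as.data.frame(h[shared]),
               as.data.frame(w$cohort[shared]))
  res <- run_plan(w$cohort, w$hospital, plan_v1(), "sec")
  expect_equal(nrow(res$links), 100)
})

test_that("world structure honours the ground-truth invariants", {
  w <- simulate_linkage_world(200, error_model(), seed = 14, n_events = 20)
  expect_equal(anyDuplicated(w$truth_links$study_id), 0L)
  expect_equal(anyDuplicated(w$truth_links$person_id), 0L)
  expect_true(all(w$truth_links$person_id %in% w$hospital$person_id))
  expect_true(all(w$episodes$person_id %in% w$hospital$person_id))
  expect_true(all(w$episodes$discharge_date >= w$episodes$admission_date))
  # every confirmed event has a generating episode on the true person
  for (i in seq_len(nrow(w$truth_events))) {
    e <- w$truth_events[i, ]
    pid <- w$truth_links$person_id[w$truth_links$study_id == e$study_id]
    eps <- w$episodes[w$episodes$person_id == pid, ]
    expect_true(any(episode_matches(e, eps)),
                label = paste("event", e$study_id, "has a source episode"))
  }
})

test_that("empirical corruption fractions recover the configured rates", {
  n <- 2000
  model <- error_model()
  w <- simulate_linkage_world(n, model, seed = 16)
  copies <- w$hospital[match(w$truth_links$person_id, w$hospital$person_id), ]

  check_rate <- function(observed, rate, trials = n) {
    sd3 <- 3 * sqrt(rate * (1 - rate) / trials)
    expect_lt(abs(observed - rate), sd3 + 1e-9)
  }
  check_rate(mean(is.na(copies$medicare8)),
             model$hospital_medicare_missing_rate)
  check_rate(mean(copies$sex != w$cohort$sex), model$sex_miscode_rate)
  check_rate(mean(copies$country_of_birth != w$cohort$country_of_birth),
             model$cob_discrepancy_rate)
  check_rate(mean(copies$postcode1 != w$cohort$postcode1),
             model$postcode_change_rate)
  # day errors move the birth date by 2-10 days (gross errors by years)
  cd <- as.Date(sprintf("%04d-%02d-%02d", w$cohort$birth_year,
                        w$cohort$birth_month, w$cohort$birth_day))
  hd <- as.Date(sprintf("%04d-%02d-%02d", copies$birth_year,
                        copies$birth_month, copies$birth_day))
  diff_days <- abs(as.numeric(hd - cd))
  check_rate(mean(diff_days %in% 2:10), model$dob_day_error_rate)
  expect_equal(nrow(w$hospital),
               n + round(model$hospital_only_population_multiplier * n) +
                 sum(startsWith(w$hospital$person_id, "T")))
})

test_that("twin injection duplicates demographics but never identity fields", {
  w <- simulate_linkage_world(
    60, error_model(twin_rate = 0, hospital_only_population_multiplier = 0),
    seed = 6
  )
  w0 <- inject_twins(w, 0, seed = 1)
  expect_equal(w0$hospital, w$hospital)

  wt <- inject_twins(w, 10, seed = 2)
  expect_equal(nrow(wt$hospital), nrow(w$hospital) + 10)
  expect_equal(wt$truth_links, w$truth_links)  # truth unchanged
  twins <- wt$hospital[startsWith(wt$hospital$person_id, "T"), ]
  demo <- c("birth_year", "birth_month", "birth_day", "sex",
            "country_of_birth", paste0("postcode", 1:4))
  for (i in seq_len(nrow(twins))) {
    src <- which(
      w$cohort$birth_year == twins$birth_year[i] &
        w$cohort$birth_month == twins$birth_month[i] &
        w$cohort$birth_day == twins$birth_day[i] &
        w$cohort$sex == twins$sex[i]
    )
    expect_gte(length(src), 1)
    j <- src[1]
    expect_equal(
      as.data.frame(twins[i, demo]), as.data.frame(w$cohort[j, demo]),
      ignore_attr = TRUE
    )
    # different card number and a different 3-letter name prefix
    expect_false(twins$medicare8[i] %in% w$cohort$medicare8[src])
    expect_false(twins$suffix[i] %in% w$cohort$suffix[src])
  }
  expect_error(inject_twins(w, 1000, seed = 1))
})

test_that("twins degrade the demographic plan but not the suffix-bearing one", {
  # day-of-birth errors knock some true hospital copies off the demographic
  # key; an injected twin then matches in their place under the demographic
  # plan, but its different name suffix excludes it once the suffix is keyed
  model <- error_model(
    dob_day_error_rate = 0.4, hospital_medicare_missing_rate = 0,
    postcode_change_rate = 0, cob_discrepancy_rate = 0,
    sex_miscode_rate = 0, suffix_middle_name_rate = 0,
    dob_gross_error_rate = 0, family_share_rate = 0, twin_rate = 0,
    hospital_only_population_multiplier = 0
  )
  w <- inject_twins(simulate_linkage_world(150, model, seed = 18),
                    n_twins = 80, seed = 19)
  r_v2 <- run_plan(w$cohort, w$hospital, plan_v2(), "sec")
  r_v2s <- run_plan(w$cohort, w$hospital, plan_v2_plus_suffix(), "sec")

  twin_ids <- w$hospital$person_id[startsWith(w$hospital$person_id, "T")]
  false_v2 <- sum(r_v2$links$person_id %in% twin_ids)
  false_v2s <- sum(r_v2s$links$person_id %in% twin_ids)
  expect_gt(false_v2, 0)
  expect_equal(false_v2s, 0)
})
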