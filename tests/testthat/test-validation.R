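ep <- function(person_id, hospital, adm, dis = NA, flag = "other") {
  tibble::tibble(
    person_id = person_id,
    hospital_name = hospital,
    admission_date = as.Date(adm),
    discharge_date = as.Date(dis),
    event_flag = flag
  )
}

ev <- function(study_id, hospital, adm, dis = NA, type = "AMI") {
  tibble::tibble(
    study_id = study_id,
    hospital_name = hospital,
    admission_date = as.Date(adm),
    discharge_date = as.Date(dis),
    event_type = type
  )
}

test_that("episode matching respects hospital name and the ten-day window, inclusive", {
  e <- ev("S1", "Alfred Hospital", "2000-03-10", "2000-03-15")
  expect_true(episode_matches(
    e, ep("H1", "ALFRED HOSPITAL", "2000-03-13", "2000-03-17")
  ))
  # exactly ten days apart is still a match; eleven is not
  expect_true(episode_matches(
    e, ep("H1", "ALFRED HOSPITAL", "2000-03-20", "2000-03-25")
  ))
  expect_false(episode_matches(
    e, ep("H1", "ALFRED HOSPITAL", "2000-03-21", "2000-03-25")
  ))
  expect_false(episode_matches(
    e, ep("H1", "AUSTIN HOSPITAL", "2000-03-10", "2000-03-15")
  ))
  # discharge outside the window fails even when admission agrees
  expect_false(episode_matches(
    e, ep("H1", "ALFRED HOSPITAL", "2000-03-10", "2000-03-28")
  ))
  # a gold record without a discharge date is compared on admission only
  e2 <- ev("S1", "Alfred Hospital", "2000-03-10")
  expect_true(episode_matches(
    e2, ep("H1", "ALFRED HOSPITAL", "2000-03-10", "2000-06-30")
  ))
  # punctuation and case differences in hospital names are immaterial
  e3 <- ev("S1", "St. Vincent's", "2000-03-10")
  expect_true(episode_matches(e3, ep("H1", "ST VINCENT S", "2000-03-10")))
})

test_that("widening the window never loses matches", {
  e <- ev("S1", "Alfred Hospital", "2000-03-10", "2000-03-15")
  eps <- ep(rep("H1", 30), "ALFRED HOSPITAL",
            as.Date("2000-03-10") + seq(-15, 14),
            as.Date("2000-03-15") + seq(-15, 14))
  counts <- vapply(0:20, function(w) sum(episode_matches(e, eps, w)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("sensitivity counts confirmed admissions correctly identified", {
  ids <- sprintf("S%03d", 1:10)
  result <- fake_result(
    tibble::tibble(study_id = ids[1:8],
                   person_id = sprintf("H%03d", 1:8),
                   iteration = 1L, iteration_label = "it"),
    ids
  )
  episodes <- dplyr::bind_rows(
    # persons 1..6 carry an episode matching their confirmed admission
    ep(sprintf("H%03d", 1:6), "ALFRED HOSPITAL", "2001-05-01", "2001-05-04"),
    # persons 7..8 were admitted somewhere else entirely
    ep(sprintf("H%03d", 7:8), "AUSTIN HOSPITAL", "1999-01-01", "1999-01-02"),
    # noise episodes
    ep(sprintf("H%03d", 1:6), "AUSTIN HOSPITAL", "2005-01-01", "2005-01-02")
  )
  events <- ev(ids, "Alfred Hospital", "2001-05-03", "2001-05-06")

  rep <- sensitivity_analysis(events, result, episodes)
  expect_equal(rep$n_confirmed, 10)
  expect_equal(rep$n_linked, 8)
  expect_equal(rep$n_correct, 6)
  expect_equal(rep$n_incorrect, 2)
  expect_equal(rep$sensitivity, 0.6)
  expect_equal(rep$non_matched_rate, 0.2)

  # invariant to event and episode order
  rep2 <- sensitivity_analysis(events[sample.int(10), ], result,
                               episodes[sample.int(nrow(episodes)), ])
  expect_equal(rep2$n_correct, rep$n_correct)

  # all matched
  rep3 <- sensitivity_analysis(events[1:6, ], result, episodes)
  expect_equal(rep3$sensitivity, 1)

  expect_error(
    sensitivity_analysis(ev("S999", "A", "2000-01-01"), result, episodes),
    "outside the cohort"
  )
})

test_that("zero-error synthetic runs have sensitivity 1 against ground truth", {
  w <- simulate_linkage_world(80, zero_error_model(), seed = 4, n_events = 12)
  res <- run_plan(w$cohort, w$hospital, plan_final(), "sec")
  rep <- sensitivity_analysis(w$truth_events, res, w$episodes)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$n_incorrect, 0)
})

test_that("the Wilson interval matches independent evaluations", {
  # against the score-test inversion in stats::prop.test (no correction)
  for (case in list(c(94, 101), c(5, 10), c(1, 8), c(49, 50))) {
    ci <- wilson_ci(case[1], case[2])
    pt <- suppressWarnings(
      prop.test(case[1], case[2], correct = FALSE)$conf.int
    )
    expect_equal(unname(ci), as.numeric(pt), tolerance = 1e-12)
  }
  ci <- wilson_ci(5, 10)
  expect_lt(ci[1], 0.5)
  expect_gt(ci[2], 0.5)

  # boundaries stay in [0, 1]
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  expect_equal(unname(wilson_ci(10, 10)[2]), 1)
  expect_error(wilson_ci(5, 0))

  # agrees with the large-sample normal interval when n is huge
  n <- 1e4
  x <- 7213
  p <- x / n
  z <- qnorm(0.975)
  normal <- c(p - z * sqrt(p * (1 - p) / n), p + z * sqrt(p * (1 - p) / n))
  expect_equal(unname(wilson_ci(x, n)), normal, tolerance = 0.01)

  # exact method is available and close at moderate n
  cp <- wilson_ci(94, 101, method = "clopper-pearson")
  expect_equal(round(unname(cp), 2), c(0.86, 0.97))
})

test_that("ground-truth metrics count planted false matches exactly", {
  truth <- tibble::tibble(study_id = sprintf("S%02d", 1:20),
                          person_id = sprintf("H%02d", 1:20))
  perfect <- fake_result(
    tibble::tibble(study_id = truth$study_id, person_id = truth$person_id,
                   iteration = 1L, iteration_label = "it"),
    truth$study_id
  )
  m <- ground_truth_metrics(perfect, truth)
  expect_equal(m[c("sensitivity", "ppv", "false_match_rate",
                   "missed_match_rate")],
               list(sensitivity = 1, ppv = 1, false_match_rate = 0,
                    missed_match_rate = 0))

  empty <- fake_result(perfect$links[0, ], truth$study_id)
  m0 <- ground_truth_metrics(empty, truth)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$missed_match_rate, 1)
  expect_true(is.na(m0$ppv))

  # 10 links, one deliberately wrong: ppv 0.9
  links <- perfect$links[1:10, ]
  links$person_id[10] <- "H99"
  planted <- fake_result(links, truth$study_id)
  mp <- ground_truth_metrics(planted, truth)
  expect_equal(mp$ppv, 0.9)
  expect_equal(mp$sensitivity, 9 / 20)

  expect_error(
    ground_truth_metrics(perfect, truth[c(1, 1), ]),
    "one-to-one"
  )
})
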