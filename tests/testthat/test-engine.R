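secret <- "unit-test-secret"

test_that("an iteration accepts only key values unique on both sides", {
  spec <- key_spec(c("medicare8", "suffix"))

  co <- make_cohort("A", given_name = "Kim", medicare8 = "11111111")
  ho <- make_hospital("X", suffix = "KIM", medicare8 = "11111111")
  step <- run_iteration(co, ho, spec, secret)
  expect_equal(step$links$study_id, "A")
  expect_equal(step$links$person_id, "X")
  expect_equal(nrow(step$ambiguities), 0)

  # two cohort records share the key: nobody links, everyone is logged
  co2 <- make_cohort(c("A", "B"), given_name = "Kim", medicare8 = "11111111")
  step2 <- run_iteration(co2, ho, spec, secret)
  expect_equal(nrow(step2$links), 0)
  expect_equal(nrow(step2$ambiguities), 3)
  expect_setequal(step2$ambiguities$id, c("A", "B", "X"))
  expect_equal(
    step2$ambiguities$candidates[step2$ambiguities$id == "X"], 2
  )

  # different keys: nothing happens
  ho3 <- make_hospital("X", suffix = "KIM", medicare8 = "22222222")
  step3 <- run_iteration(co, ho3, spec, secret)
  expect_equal(nrow(step3$links), 0)
  expect_equal(nrow(step3$ambiguities), 0)
})

test_that("matched records are removed before later iterations", {
  # A matches X on the full key in iteration 1; B only matches X's key in a
  # later, looser iteration - but X is gone by then
  co <- make_cohort(c("A", "B"), given_name = c("Kim", "Jan"),
                    medicare8 = "11111111", sex = c("F", "F"))
  ho <- make_hospital("X", suffix = "KIM", medicare8 = "11111111")
  plan <- iteration_plan("t", list(
    key_spec(c("medicare8", "suffix"), "tight"),
    key_spec("medicare8", "loose")
  ))
  res <- run_plan(co, ho, plan, secret)
  expect_equal(nrow(res$links), 1)
  expect_equal(res$links$study_id, "A")
  expect_equal(res$links$iteration, 1)
  expect_equal(res$unmatched_cohort_ids, "B")
})

test_that("results are one-to-one, conserve counts, and ignore row order", {
  w <- simulate_linkage_world(120, error_model(), seed = 5)
  res <- run_plan(w$cohort, w$hospital, plan_v1(), secret)

  expect_false(anyDuplicated(res$links$study_id) > 0)
  expect_false(anyDuplicated(res$links$person_id) > 0)
  ic <- res$iteration_counts
  expect_equal(ic$records_remaining,
               res$n_cohort - cumsum(ic$records_linked))
  expect_equal(sum(ic$records_linked) + length(res$unmatched_cohort_ids),
               res$n_cohort)

  # permuting input rows changes nothing (set semantics within an iteration)
  set.seed(1)
  res2 <- run_plan(w$cohort[sample.int(nrow(w$cohort)), ],
                   w$hospital[sample.int(nrow(w$hospital)), ],
                   plan_v1(), secret)
  expect_setequal(link_set(res), link_set(res2))
  expect_equal(res$iteration_counts, res2$iteration_counts)
})

test_that("digest-space matching equals plaintext matching", {
  w <- simulate_linkage_world(100, error_model(), seed = 21)
  rd <- run_plan(w$cohort, w$hospital, plan_v1(), secret, match_on = "digest")
  rp <- run_plan(w$cohort, w$hospital, plan_v1(), secret,
                 match_on = "plaintext")
  expect_equal(link_set(rd), link_set(rp))
  expect_equal(rd$iteration_counts, rp$iteration_counts)
})

test_that("planted day-of-birth errors reproduce the brute-force oracle", {
  w <- simulate_linkage_world(
    50,
    error_model(dob_day_error_rate = 0.3, twin_rate = 0.05,
                hospital_only_population_multiplier = 1),
    seed = 13
  )
  res <- run_plan(w$cohort, w$hospital, plan_v1(), secret)
  oracle <- oracle_run_plan(w$cohort, w$hospital, plan_v1())
  expect_equal(link_set(res), oracle_link_set(oracle))
})

test_that("demographic twins are left ambiguous, not linked, by a demographic key", {
  co <- make_cohort("A", given_name = "Kim")
  # two hospital persons sharing DOB/sex/COB/postcode, different identities
  ho <- make_hospital(c("X", "Y"), suffix = c("KIM", "ZOE"),
                      medicare8 = c("11111111", "22222222"))
  plan <- iteration_plan("demo1", list(plan_v2()$iterations[[1]]))
  res <- run_plan(co, ho, plan, secret)
  expect_equal(nrow(res$links), 0)
  expect_setequal(res$ambiguities$id, c("A", "X", "Y"))
  # the suffix separates them
  res2 <- run_plan(co, ho,
                   iteration_plan("s1", list(plan_v2_plus_suffix()$iterations[[1]])),
                   secret)
  expect_equal(res2$links$person_id, "X")
})

test_that("cumulative links grow monotonically with plan length", {
  w <- simulate_linkage_world(80, error_model(), seed = 31)
  full <- plan_v1()
  prev <- character()
  for (k in seq_along(full$iterations)) {
    pk <- iteration_plan("prefix", full$iterations[seq_len(k)])
    res <- run_plan(w$cohort, w$hospital, pk, secret)
    cur <- sort(paste(res$links$study_id, res$links$person_id, sep = "/"))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("degenerate inputs are rejected", {
  co <- make_cohort(c("A", "A"))
  ho <- make_hospital("X")
  expect_error(run_plan(co, ho, plan_v1(), secret), "not unique")
  expect_error(iteration_plan("empty", list()), "no iterations")
})

test_that("zero-error worlds link fully in the first eligible iteration", {
  w <- simulate_linkage_world(60, zero_error_model(), seed = 2)
  res <- run_plan(w$cohort, w$hospital, plan_v1(), secret)
  expect_equal(nrow(res$links), 60)
  expect_true(all(res$links$iteration == 1))
  expect_equal(
    sort(paste(res$links$study_id, res$links$person_id)),
    sort(paste(w$truth_links$study_id, w$truth_links$person_id))
  )
})
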