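#' Does an admission episode match an independently confirmed event?
#'
#' A confirmed event (from medical-record review) matches a hospital episode
#' when the canonical hospital names are equal and both the admission dates
#' and — where the confirmed record has one — the discharge dates agree
#' within `window_days` calendar days, bounds inclusive.
#'
#' @param event One-row tibble: `hospital_name`, `admission_date`,
#'   `discharge_date` (may be `NA`).
#' @param episode Tibble of episodes ([read_episodes()] schema); may have
#'   any number of rows.
#' @param window_days Non-negative tolerance in days (default 10).
#' @return Logical vector, one element per episode row.
#' @export
episode_matches <- function(event, episode, window_days = 10) {
  stopifnot(window_days >= 0, nrow(event) == 1)
  hosp_ok <- !is.na(episode$hospital_name) &
    episode$hospital_name == canonical_text(event$hospital_name)
  adm_ok <- abs(as.numeric(episode$admission_date - event$admission_date)) <=
    window_days
  dis_ok <- if (is.na(event$discharge_date)) {
    rep(TRUE, nrow(episode))
  } else {
    !is.na(episode$discharge_date) &
      abs(as.numeric(episode$discharge_date - event$discharge_date)) <=
        window_days
  }
  out <- hosp_ok & adm_ok & dis_ok
  out[is.na(out)] <- FALSE
  out
}

#' Gold-standard sensitivity of a linkage run
#'
#' For each confirmed admission (participants whose hospitalization was
#' verified by medical-record review), checks that the participant was linked
#' and that the linked hospital person carries at least one episode matching
#' the confirmed hospital name and dates ([episode_matches()]). Sensitivity
#' is the number of confirmed admissions correctly identified divided by the
#' total number of confirmed admissions, with a 95% confidence interval
#' ([wilson_ci()]).
#'
#' @param events Tibble of confirmed events: `study_id`, `hospital_name`,
#'   `admission_date`, `discharge_date` (`NA` allowed), `event_type`.
#' @param result A `linkage_result` from [run_plan()].
#' @param episodes Tibble of episodes ([read_episodes()] schema).
#' @param window_days Date tolerance in days (default 10).
#' @param ci_method Confidence-interval method passed to [wilson_ci()].
#' @return A `sensitivity_report`: `n_confirmed`, `n_linked` (confirmed
#'   participants linked to any hospital person), `n_correct` (linked with a
#'   matching episode), `n_incorrect = n_linked - n_correct`, `sensitivity =
#'   n_correct / n_confirmed`, `non_matched_rate = n_incorrect /
#'   n_confirmed`, and `ci95` for the sensitivity.
#' @export
sensitivity_analysis <- function(events, result, episodes, window_days = 10,
                                 ci_method = c("wilson", "clopper-pearson")) {
  stopifnot(inherits(result, "linkage_result"))
  ci_method <- match.arg(ci_method)
  unknown <- setdiff(events$study_id, result$cohort_ids)
  if (length(unknown) > 0) {
    stop("confirmed events for participants outside the cohort: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  link_map <- setNames(result$links$person_id, result$links$study_id)
  linked_person <- unname(link_map[events$study_id])

  correct <- vapply(seq_len(nrow(events)), function(i) {
    pid <- linked_person[i]
    if (is.na(pid)) return(FALSE)
    ep <- episodes[episodes$person_id == pid, ]
    if (nrow(ep) == 0) return(FALSE)
    any(episode_matches(events[i, ], ep, window_days))
  }, NA)

  n_confirmed <- nrow(events)
  n_linked <- sum(!is.na(linked_person))
  n_correct <- sum(correct)
  structure(
    list(
      n_confirmed = n_confirmed,
      n_linked = n_linked,
      n_correct = n_correct,
      n_incorrect = n_linked - n_correct,
      sensitivity = n_correct / n_confirmed,
      non_matched_rate = (n_linked - n_correct) / n_confirmed,
      ci95 = wilson_ci(n_correct, n_confirmed, method = ci_method)
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  cat(sprintf("  confirmed admissions          %5d\n", x$n_confirmed))
  cat(sprintf("  participants linked           %5d\n", x$n_linked))
  cat(sprintf("  correctly identified          %5d\n", x$n_correct))
  cat(sprintf("  incorrect matches             %5d\n", x$n_incorrect))
  cat(sprintf("  sensitivity  %d/%d = %.0f%% (95%% CI %.0f%% to %.0f%%)\n",
              x$n_correct, x$n_confirmed, 100 * x$sensitivity,
              100 * x$ci95[1], 100 * x$ci95[2]))
  cat(sprintf("  non-matched rate  %d/%d = %.0f%%\n",
              x$n_incorrect, x$n_confirmed, 100 * x$non_matched_rate))
  invisible(x)
}

#' Confidence interval for a binomial proportion
#'
#' Wilson score interval (default), the standard interval for validation
#' proportions at modest n; optionally the exact Clopper-Pearson interval via
#' [stats::binom.test()].
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return Numeric vector `c(lower, upper)` in `[0, 1]`, bracketing the point
#'   estimate.
#' @examples
#' wilson_ci(94, 101) # ~ (0.86, 0.97)
#' @export
wilson_ci <- function(successes, n, level = 0.95,
                      method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(n > 0, successes >= 0, successes <= n, level > 0, level < 1)
  if (method == "clopper-pearson") {
    ci <- binom.test(successes, n, conf.level = level)$conf.int
    return(c(lower = ci[1], upper = ci[2]))
  }
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(lower = (centre - half) / denom, upper = (centre + half) / denom)
}

#' Ground-truth linkage metrics on synthetic data
#'
#' When the true cohort-to-hospital correspondence is known (synthetic
#' worlds), evaluates a linkage result directly: the kind of
#' specificity-style assessment that is impossible on real de-identified
#' data.
#'
#' @param result A `linkage_result`.
#' @param truth Tibble `study_id`, `person_id` of true pairs; one-to-one.
#' @return List: `sensitivity` (true pairs recovered / true pairs), `ppv`
#'   (true pairs recovered / links made; `NA` when no links),
#'   `false_match_rate` (`1 - ppv`), `missed_match_rate`
#'   (`1 - sensitivity`), plus the counts `n_truth`, `n_links`, `n_correct`.
#' @export
ground_truth_metrics <- function(result, truth) {
  stopifnot(inherits(result, "linkage_result"))
  if (anyDuplicated(truth$study_id) || anyDuplicated(truth$person_id)) {
    stop("truth links must be one-to-one")
  }
  key <- function(s, p) paste(s, p, sep = "\r")
  true_keys <- key(truth$study_id, truth$person_id)
  link_keys <- key(result$links$study_id, result$links$person_id)
  n_correct <- sum(link_keys %in% true_keys)
  n_links <- length(link_keys)
  n_truth <- length(true_keys)
  ppv <- if (n_links == 0) NA_real_ else n_correct / n_links
  list(
    sensitivity = if (n_truth == 0) NA_real_ else n_correct / n_truth,
    ppv = ppv,
    false_match_rate = if (n_links == 0) NA_real_ else 1 - ppv,
    missed_match_rate = if (n_truth == 0) NA_real_ else 1 - n_correct / n_truth,
    n_truth = n_truth,
    n_links = n_links,
    n_correct = n_correct
  )
}
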