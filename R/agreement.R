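#' Agreement between two linkage runs on the same cohort
#'
#' If two linkage algorithms work equally well, each should assign every
#' participant to the same hospital-side person. This classifies each cohort
#' participant into one of five categories — linked to the *same* person by
#' both runs, linked to *different* persons, linked only by run A, only by
#' run B, or unmatched by both — and reports the disagreement fraction:
#' participants assigned to different hospital persons divided by the full
#' cohort size (not the doubly-matched subset).
#'
#' @param result_a,result_b `linkage_result` objects from [run_plan()] over
#'   the same cohort (identical cohort ID sets; anything else is an error).
#' @return An `agreement_report`: counts `same_id`, `different_id`,
#'   `only_in_a`, `only_in_b`, `unmatched_both` (summing to `cohort_size`),
#'   `disagreement_fraction`, and `different_id_pairs` — a tibble
#'   (`study_id`, `person_id_a`, `person_id_b`) for clerical inspection.
#' @export
compare_linkage <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "linkage_result"),
            inherits(result_b, "linkage_result"))
  ids <- result_a$cohort_ids
  if (!setequal(ids, result_b$cohort_ids)) {
    stop("the two results do not derive from the same cohort ",
         "(cohort ID sets differ)")
  }
  n <- length(ids)
  a <- setNames(result_a$links$person_id, result_a$links$study_id)
  b <- setNames(result_b$links$person_id, result_b$links$study_id)
  pa <- unname(a[ids])
  pb <- unname(b[ids])

  in_a <- !is.na(pa)
  in_b <- !is.na(pb)
  same <- in_a & in_b & pa == pb
  diff <- in_a & in_b & pa != pb

  structure(
    list(
      cohort_size = n,
      same_id = sum(same),
      different_id = sum(diff),
      only_in_a = sum(in_a & !in_b),
      only_in_b = sum(!in_a & in_b),
      unmatched_both = sum(!in_a & !in_b),
      disagreement_fraction = sum(diff) / n,
      different_id_pairs = tibble::tibble(
        study_id = ids[diff],
        person_id_a = pa[diff],
        person_id_b = pb[diff]
      ),
      label_a = result_a$plan_label,
      label_b = result_b$plan_label
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>", x$label_a, "vs", x$label_b, "\n")
  cat(sprintf("  cohort size        %6d\n", x$cohort_size))
  cat(sprintf("  same person        %6d\n", x$same_id))
  cat(sprintf("  different persons  %6d\n", x$different_id))
  cat(sprintf("  only in %-9s  %6d\n", x$label_a, x$only_in_a))
  cat(sprintf("  only in %-9s  %6d\n", x$label_b, x$only_in_b))
  cat(sprintf("  unmatched by both  %6d\n", x$unmatched_both))
  cat(sprintf("  disagreement fraction %.1f%%\n",
              100 * x$disagreement_fraction))
  invisible(x)
}

#' Export an agreement report
#'
#' Writes `agreement.json` (the category counts and disagreement fraction)
#' and `different_id_pairs.csv` into `dir`.
#'
#' @param report An `agreement_report` from [compare_linkage()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_agreement_report <- function(report, dir) {
  stopifnot(inherits(report, "agreement_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    report[c("label_a", "label_b", "cohort_size", "same_id", "different_id",
             "only_in_a", "only_in_b", "unmatched_both",
             "disagreement_fraction")],
    file.path(dir, "agreement.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(report$different_id_pairs,
                   file.path(dir, "different_id_pairs.csv"))
  invisible(dir)
}
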