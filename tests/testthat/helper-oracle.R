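# Independent brute-force oracle for the stepwise linkage: compares records
# field by field (no serialization, no digests) and applies the acceptance
# rule per iteration by counting candidates on both sides. Deliberately slow
# and structurally unlike the engine.

oracle_field <- function(records, sel) {
  s <- records$suffix
  na_keep <- function(v) {
    v[is.na(s)] <- NA_character_
    v
  }
  switch(sel,
    suffix_12 = na_keep(substr(s, 1, 2)),
    suffix_23 = na_keep(substr(s, 2, 3)),
    suffix_13 = na_keep(paste0(substr(s, 1, 1), substr(s, 3, 3))),
    as.character(records[[sel]])
  )
}

oracle_run_plan <- function(cohort, hospital, plan) {
  all_links <- list()
  for (it in seq_along(plan$iterations)) {
    sels <- plan$iterations[[it]]$selectors
    if (nrow(cohort) == 0 || nrow(hospital) == 0) break
    cm <- do.call(cbind, lapply(sels, function(s) oracle_field(cohort, s)))
    hm <- do.call(cbind, lapply(sels, function(s) oracle_field(hospital, s)))
    c_ok <- rowSums(is.na(cm)) == 0
    h_ok <- rowSums(is.na(hm)) == 0

    n_c <- nrow(cohort)
    cand <- vector("list", n_c)
    h_hits <- integer(nrow(hospital))
    for (i in which(c_ok)) {
      eq <- h_ok
      for (f in seq_along(sels)) {
        eq <- eq & !is.na(hm[, f]) & hm[, f] == cm[i, f]
      }
      idx <- which(eq)
      cand[[i]] <- idx
      h_hits[idx] <- h_hits[idx] + 1L
    }
    accept <- which(vapply(cand, function(j) {
      length(j) == 1 && h_hits[j] == 1
    }, NA))
    if (length(accept) > 0) {
      all_links[[it]] <- data.frame(
        study_id = cohort$study_id[accept],
        person_id = hospital$person_id[unlist(cand[accept])],
        iteration = it,
        stringsAsFactors = FALSE
      )
      cohort <- cohort[-accept, , drop = FALSE]
      hospital <- hospital[
        !hospital$person_id %in% all_links[[it]]$person_id, , drop = FALSE
      ]
    }
  }
  out <- do.call(rbind, all_links)
  if (is.null(out)) {
    out <- data.frame(study_id = character(), person_id = character(),
                      iteration = integer())
  }
  out
}

oracle_link_set <- function(links) {
  sort(paste(links$study_id, links$person_id, links$iteration, sep = "/"))
}
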