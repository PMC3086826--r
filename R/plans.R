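#' Assemble an ordered iteration plan
#'
#' @param label Plan label.
#' @param iterations List of [key_spec()] objects, in execution order;
#'   labels must be unique.
#' @return An `iteration_plan`.
#' @export
iteration_plan <- function(label, iterations) {
  stopifnot(is.character(label), length(label) == 1)
  if (length(iterations) == 0) stop("plan has no iterations")
  ok <- vapply(iterations, inherits, NA, what = "key_spec")
  if (!all(ok)) stop("iterations must be key_spec objects")
  labels <- vapply(iterations, function(s) s$label, "")
  if (anyDuplicated(labels)) {
    stop("duplicate iteration labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(
    list(label = label, iterations = iterations),
    class = "iteration_plan"
  )
}

#' @export
print.iteration_plan <- function(x, ...) {
  cat("<iteration_plan>", x$label, "-", length(x$iterations), "iterations\n")
  show <- head(seq_along(x$iterations), 8)
  for (i in show) {
    cat(sprintf("  %3d %s\n", i, format(x$iterations[[i]])))
  }
  if (length(x$iterations) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
length.iteration_plan <- function(x) length(x$iterations)

# full demographic selector block in canonical order, minus dropped variables;
# "postcode" names the whole slot sweep. Returns a list of selector vectors:
# one per postcode slot, or a single vector when postcode is dropped.
demographic_sweep <- function(anchors, drop = character()) {
  demo <- c("birth_year", "birth_month", "birth_day", "sex",
            "country_of_birth")
  drop_map <- c(
    birth_year = "birth_year", birth_month = "birth_month",
    birth_day = "birth_day", sex = "sex",
    country_of_birth = "country_of_birth"
  )
  demo <- setdiff(demo, drop_map[intersect(drop, names(drop_map))])
  if ("postcode" %in% drop) {
    list(c(anchors, demo))
  } else {
    lapply(paste0("postcode", 1:4), function(pc) c(anchors, demo, pc))
  }
}

sweep_specs <- function(anchors, anchor_label, drop = character()) {
  sels <- demographic_sweep(anchors, drop)
  drop_tag <- if (length(drop) > 0) {
    paste0(".drop-", paste(sub("^birth_", "", drop), collapse = "+"))
  } else ""
  if ("postcode" %in% drop) {
    list(key_spec(sels[[1]], paste0(anchor_label, drop_tag, ".no-pc")))
  } else {
    lapply(1:4, function(k) {
      key_spec(sels[[k]], paste0(anchor_label, drop_tag, ".pc", k))
    })
  }
}

suffix_variants <- c("suffix_12", "suffix_23", "suffix_13")
variant_tag <- c(suffix_12 = "suf12", suffix_23 = "suf23",
                 suffix_13 = "suf13")
# order in which single variables are relaxed (postcode first, then country,
# sex, then day/month/year of birth)
drop_order <- c("postcode", "country_of_birth", "sex",
                "birth_day", "birth_month", "birth_year")

#' The first published plan: insurance number and name suffix (V1)
#'
#' Ten iterations: card-prefix + full suffix; card-prefix + two-letter suffix
#' variants + sex; card-prefix + birth year + sex; then suffix + full
#' demographics swept over the four postcode slots; finally demographics only
#' on postcode slot 1.
#'
#' @return An [iteration_plan()] labelled `"v1"`.
#' @export
plan_v1 <- function() {
  demo <- c("birth_year", "birth_month", "birth_day", "sex",
            "country_of_birth")
  its <- c(
    list(
      key_spec(c("medicare8", "suffix"), "m8+suf"),
      key_spec(c("medicare8", "suffix_12", "sex"), "m8+suf12+sex"),
      key_spec(c("medicare8", "suffix_23", "sex"), "m8+suf23+sex"),
      key_spec(c("medicare8", "suffix_13", "sex"), "m8+suf13+sex"),
      key_spec(c("medicare8", "birth_year", "sex"), "m8+year+sex")
    ),
    lapply(1:4, function(k) {
      key_spec(c("suffix", demo, paste0("postcode", k)),
               paste0("suf+dob+sex+cob.pc", k))
    }),
    list(key_spec(c(demo, "postcode1"), "dob+sex+cob.pc1"))
  )
  iteration_plan("v1", its)
}

#' The second published plan: demographic variables only (V2)
#'
#' Four iterations of date-of-birth components + sex + country of birth,
#' swept over the four postcode slots. Uses neither the insurance number nor
#' the name suffix.
#'
#' @return An [iteration_plan()] labelled `"v2"`.
#' @export
plan_v2 <- function() {
  iteration_plan("v2", sweep_specs(character(), "dob+sex+cob"))
}

#' The demographic plan augmented with the name suffix
#'
#' [plan_v2()] with the full 3-letter suffix added to every iteration. On
#' hospital sides where demographic "twins" exist (different people sharing
#' date of birth, sex, country of birth and postcode), the added suffix
#' removes false-positive links at the cost of fewer total links.
#'
#' @return An [iteration_plan()] labelled `"v2s"`.
#' @export
plan_v2_plus_suffix <- function() {
  iteration_plan("v2s", sweep_specs("suffix", "suf+dob+sex+cob"))
}

#' The final published three-stage plan
#'
#' Generated from the published relaxation rules rather than a hand-written
#' iteration list:
#'
#' * **Stage A** (card prefix + suffix): the full composite key swept over
#'   the four postcode slots; the sweep repeated under the three two-letter
#'   suffix variants; drop-one relaxations over \{postcode, country of birth,
#'   sex, day, month, year of birth\} (dropping postcode collapses the slot
#'   sweep to a single iteration); the suffix-variant sweeps repeated under
#'   each single dropped variable; and drop-two relaxations over all
#'   2-subsets of the demographic set, with the full suffix. At most two
#'   variables are ever relaxed at once.
#' * **Stage B** (card prefix only): full demographics swept over postcode
#'   slots, then drop-one — catches records whose recorded given names
#'   differ (nicknames, middle names).
#' * **Stage C** (suffix only): full demographics swept over postcode slots —
#'   catches records lacking the insurance number on either side.
#'
#' The first iteration (full key, postcode slot 1) is the most stringent and
#' is assumed to give the most reliable matches; expansion order is
#' deterministic. The generated plan has 174 iterations.
#'
#' @return An [iteration_plan()] labelled `"final"`.
#' @export
plan_final <- function() {
  a_anchor <- c("medicare8", "suffix")
  its <- list()
  add <- function(x) its[[length(its) + 1]] <<- x

  # Stage A: base sweep, then suffix-variant sweeps
  add(sweep_specs(a_anchor, "A.m8+suf"))
  for (v in suffix_variants) {
    add(sweep_specs(c("medicare8", v), paste0("A.m8+", variant_tag[v])))
  }
  # drop-one with full suffix
  for (d in drop_order) {
    add(sweep_specs(a_anchor, "A.m8+suf", drop = d))
  }
  # suffix-variant sweeps under each single dropped variable
  for (d in drop_order) {
    for (v in suffix_variants) {
      add(sweep_specs(c("medicare8", v), paste0("A.m8+", variant_tag[v]),
                      drop = d))
    }
  }
  # drop-two with full suffix, over all 2-subsets in drop order
  for (i in seq_len(length(drop_order) - 1)) {
    for (j in seq(i + 1, length(drop_order))) {
      add(sweep_specs(a_anchor, "A.m8+suf",
                      drop = drop_order[c(i, j)]))
    }
  }
  # Stage B: card prefix only
  add(sweep_specs("medicare8", "B.m8"))
  for (d in drop_order) {
    add(sweep_specs("medicare8", "B.m8", drop = d))
  }
  # Stage C: suffix only
  add(sweep_specs("suffix", "C.suf"))

  iteration_plan("final", unlist(its, recursive = FALSE))
}

#' Resolve a shipped plan by name
#'
#' @param name One of `"v1"`, `"v2"`, `"v2s"`, `"final"`.
#' @return The corresponding [iteration_plan()].
#' @export
shipped_plan <- function(name) {
  switch(name,
    v1 = plan_v1(),
    v2 = plan_v2(),
    v2s = plan_v2_plus_suffix(),
    final = plan_final(),
    stop("unknown plan name: ", name,
         " (expected v1, v2, v2s or final)")
  )
}

#' Read or write an iteration plan as a YAML config
#'
#' The config holds a plan `label` and a list of `iterations`, each with a
#' `label` and a `selectors` list drawn from [key_selectors()]. The shipped
#' plans are expressible in this dialect and round-trip exactly.
#'
#' @param path Path to a YAML plan config.
#' @return [load_plan()] returns an [iteration_plan()]; [save_plan()] returns
#'   `path` invisibly.
#' @export
load_plan <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$label) || is.null(cfg$iterations)) {
    stop("plan config needs 'label' and 'iterations'")
  }
  its <- lapply(cfg$iterations, function(it) {
    if (is.null(it$selectors)) stop("iteration without selectors in ", path)
    label <- if (is.null(it$label)) {
      paste(unlist(it$selectors), collapse = "+")
    } else {
      it$label
    }
    key_spec(unlist(it$selectors), label)
  })
  iteration_plan(cfg$label, its)
}

#' @param plan An [iteration_plan()].
#' @rdname load_plan
#' @export
save_plan <- function(plan, path) {
  stopifnot(inherits(plan, "iteration_plan"))
  cfg <- list(
    label = plan$label,
    iterations = lapply(plan$iterations, function(s) {
      list(label = s$label, selectors = as.list(s$selectors))
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
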