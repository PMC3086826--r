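#' @name record-schemas
#' @title Delimited-file schemas for linkage inputs
#'
#' @description
#' Three delimited tables (UTF-8, header row required, ISO-8601 dates) feed a
#' linkage run:
#'
#' * **Cohort roster** — one row per study participant:
#'   `study_id`, `given_name`, `medicare_number` (raw card number),
#'   `birth_date` (`YYYY-MM-DD`), `sex` (`M`/`F`), `country_of_birth`,
#'   `postcode1`..`postcode4`.
#' * **Hospital person index** — one row per internally-linked hospital-side
#'   person: `person_id`, `medicare8` (already truncated), `suffix`
#'   (3 letters), `birth_year`, `birth_month`, `birth_day`, `sex`,
#'   `country_of_birth`, `postcode1`..`postcode4`.
#' * **Episodes** — one admission per row: `person_id`, `hospital_name`,
#'   `admission_date`, `discharge_date`, `event_flag`
#'   (`AMI`, `stroke` or `other`).
#'
#' Empty strings encode missing values on disk; in memory they are `NA`.
#' A missing field never matches anything: any iteration whose key touches a
#' missing field skips that record. Readers normalize on ingest (suffix
#' derivation, card-number truncation, canonical uppercase country) and reject
#' invalid rows with row-level diagnostics retrievable via
#' [read_diagnostics()]; they fail outright only when a mandatory column is
#' absent.
NULL

cohort_file_cols <- c(
  "study_id", "given_name", "medicare_number", "birth_date", "sex",
  "country_of_birth", "postcode1", "postcode2", "postcode3", "postcode4"
)
hospital_file_cols <- c(
  "person_id", "medicare8", "suffix", "birth_year", "birth_month",
  "birth_day", "sex", "country_of_birth",
  "postcode1", "postcode2", "postcode3", "postcode4"
)
episode_file_cols <- c(
  "person_id", "hospital_name", "admission_date", "discharge_date",
  "event_flag"
)
postcode_cols <- paste0("postcode", 1:4)

read_delim_chr <- function(path, delim) {
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
}

require_cols <- function(raw, needed, path) {
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop(
      "missing mandatory column(s) in ", path, ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

# drop NA/duplicate postcodes per row and shift remaining left, preserving order
compact_postcodes <- function(df) {
  mat <- as.matrix(df[postcode_cols])
  mat[!is.na(mat) & mat == ""] <- NA_character_
  out <- t(apply(mat, 1, function(r) {
    r <- r[!is.na(r)]
    r <- r[!duplicated(r)]
    length(r) <- 4L
    r
  }))
  for (k in 1:4) df[[postcode_cols[k]]] <- out[, k]
  df
}

attach_diagnostics <- function(records, diagnostics) {
  attr(records, "diagnostics") <- diagnostics
  records
}

#' Retrieve row-level diagnostics attached by a reader
#'
#' @param x A tibble returned by [read_cohort()], [read_hospital()] or
#'   [read_episodes()].
#' @return A tibble with columns `row` (1-based data row in the source file),
#'   `id` and `message`, one row per rejected input row. Readers never
#'   silently drop data: rows in = records kept + diagnostics.
#' @export
read_diagnostics <- function(x) {
  d <- attr(x, "diagnostics")
  if (is.null(d)) diagnostics_tbl() else d
}

diagnostics_tbl <- function(row = integer(), id = character(),
                            message = character()) {
  tibble::tibble(row = as.integer(row), id = id, message = message)
}

# combine per-row issue strings into one diagnostic row per rejected record
collect_issues <- function(issues_by_row, ids) {
  bad <- which(lengths(issues_by_row) > 0)
  diagnostics_tbl(
    row = bad,
    id = ids[bad],
    message = vapply(issues_by_row[bad], paste, "", collapse = "; ")
  )
}

#' Read a cohort roster
#'
#' Parses and normalizes the cohort table (see [record-schemas]): the
#' 3-letter suffix is derived from `given_name`, the 8-digit family prefix
#' from `medicare_number`, the birth date split into year/month/day
#' components, and `country_of_birth` canonicalized. Rows with an invalid or
#' missing birth date, an unknown sex code, or a missing/duplicate `study_id`
#' are rejected with a diagnostic ([read_diagnostics()]).
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default `","`).
#' @return Tibble of participant records with columns `study_id`,
#'   `given_name`, `medicare8`, `suffix`, `birth_year`, `birth_month`,
#'   `birth_day`, `sex`, `country_of_birth`, `postcode1`..`postcode4`.
#' @export
read_cohort <- function(path, delim = ",") {
  raw <- read_delim_chr(path, delim)
  require_cols(raw, cohort_file_cols, path)

  rec <- tibble::tibble(
    study_id = blank_na(raw$study_id),
    given_name = blank_na(raw$given_name),
    medicare8 = derive_medicare8(raw$medicare_number),
    suffix = derive_suffix(raw$given_name),
    birth_date = parse_iso_date(raw$birth_date),
    sex = toupper(blank_na(raw$sex)),
    country_of_birth = canonical_text(raw$country_of_birth)
  )
  for (k in postcode_cols) rec[[k]] <- blank_na(raw[[k]])
  rec <- compact_postcodes(rec)

  issues <- record_issues(
    id = rec$study_id, id_field = "study_id",
    date_ok = !is.na(rec$birth_date), sex = rec$sex
  )
  rec$birth_year <- as.integer(format(rec$birth_date, "%Y"))
  rec$birth_month <- as.integer(format(rec$birth_date, "%m"))
  rec$birth_day <- as.integer(format(rec$birth_date, "%d"))
  rec$birth_date <- NULL
  rec <- rec[c(
    "study_id", "given_name", "medicare8", "suffix",
    "birth_year", "birth_month", "birth_day", "sex", "country_of_birth",
    postcode_cols
  )]

  diagnostics <- collect_issues(issues, rec$study_id)
  keep <- lengths(issues) == 0
  attach_diagnostics(rec[keep, ], diagnostics)
}

#' Read a hospital person index
#'
#' Parses and normalizes the de-identified hospital-side person table (see
#' [record-schemas]). `medicare8` and `suffix` are re-normalized on read (a
#' malformed value becomes missing); rows with an invalid birth date, an
#' unknown sex code, or a missing/duplicate `person_id` are rejected with a
#' diagnostic.
#'
#' @inheritParams read_cohort
#' @return Tibble of hospital-person records with columns `person_id`,
#'   `medicare8`, `suffix`, `birth_year`, `birth_month`, `birth_day`, `sex`,
#'   `country_of_birth`, `postcode1`..`postcode4`.
#' @export
read_hospital <- function(path, delim = ",") {
  raw <- read_delim_chr(path, delim)
  require_cols(raw, hospital_file_cols, path)

  rec <- tibble::tibble(
    person_id = blank_na(raw$person_id),
    medicare8 = derive_medicare8(raw$medicare8),
    suffix = derive_suffix(raw$suffix),
    birth_year = suppressWarnings(as.integer(blank_na(raw$birth_year))),
    birth_month = suppressWarnings(as.integer(blank_na(raw$birth_month))),
    birth_day = suppressWarnings(as.integer(blank_na(raw$birth_day))),
    sex = toupper(blank_na(raw$sex)),
    country_of_birth = canonical_text(raw$country_of_birth)
  )
  for (k in postcode_cols) rec[[k]] <- blank_na(raw[[k]])
  rec <- compact_postcodes(rec)

  issues <- record_issues(
    id = rec$person_id, id_field = "person_id",
    date_ok = valid_ymd(rec$birth_year, rec$birth_month, rec$birth_day),
    sex = rec$sex
  )
  diagnostics <- collect_issues(issues, rec$person_id)
  keep <- lengths(issues) == 0
  attach_diagnostics(rec[keep, ], diagnostics)
}

record_issues <- function(id, id_field, date_ok, sex) {
  n <- length(id)
  issues <- vector("list", n)
  add <- function(cond, msg) {
    for (i in which(cond)) issues[[i]] <<- c(issues[[i]], msg)
  }
  add(is.na(id), paste("missing", id_field))
  add(!is.na(id) & duplicated(id), paste("duplicate", id_field))
  add(!date_ok, "invalid or missing birth date")
  add(is.na(sex) | !sex %in% c("M", "F"), "unknown sex code")
  issues
}

#' Read an episode (admissions) table
#'
#' Parses hospital admission episodes (see [record-schemas]). Hospital names
#' are canonicalized for exact comparison. Rows with an unparseable admission
#' or discharge date, a discharge before admission, a missing `person_id`, or
#' an unknown `event_flag` are rejected with a diagnostic. An empty
#' `event_flag` defaults to `"other"`.
#'
#' @inheritParams read_cohort
#' @return Tibble with columns `person_id`, `hospital_name`,
#'   `admission_date`, `discharge_date` (`Date`), `event_flag`.
#' @export
read_episodes <- function(path, delim = ",") {
  raw <- read_delim_chr(path, delim)
  require_cols(raw, episode_file_cols, path)

  rec <- tibble::tibble(
    person_id = blank_na(raw$person_id),
    hospital_name = canonical_text(raw$hospital_name),
    admission_date = parse_iso_date(raw$admission_date),
    discharge_date = parse_iso_date(raw$discharge_date),
    event_flag = dplyr::coalesce(blank_na(raw$event_flag), "other")
  )

  n <- nrow(rec)
  issues <- vector("list", n)
  add <- function(cond, msg) {
    for (i in which(cond)) issues[[i]] <<- c(issues[[i]], msg)
  }
  add(is.na(rec$person_id), "missing person_id")
  add(is.na(rec$admission_date) & !is.na(blank_na(raw$admission_date)),
      "malformed admission_date")
  add(is.na(rec$admission_date) & is.na(blank_na(raw$admission_date)),
      "missing admission_date")
  add(is.na(rec$discharge_date) & !is.na(blank_na(raw$discharge_date)),
      "malformed discharge_date")
  add(!is.na(rec$admission_date) & !is.na(rec$discharge_date) &
        rec$discharge_date < rec$admission_date,
      "discharge before admission")
  add(!rec$event_flag %in% c("AMI", "stroke", "other"), "unknown event_flag")

  diagnostics <- collect_issues(issues, rec$person_id)
  keep <- lengths(issues) == 0
  attach_diagnostics(rec[keep, ], diagnostics)
}

na_blank <- function(x) ifelse(is.na(x), "", as.character(x))

#' Write linkage input tables back to delimited text
#'
#' Inverse of the readers: missing values become empty strings, birth-date
#' components are recomposed to ISO-8601 where the schema stores a full date.
#' A write followed by a read reproduces the in-memory records exactly.
#'
#' @param records Tibble as returned by the corresponding reader.
#' @param path Output file path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, delim = ",") {
  out <- tibble::tibble(
    study_id = na_blank(records$study_id),
    given_name = na_blank(records$given_name),
    medicare_number = na_blank(records$medicare8),
    birth_date = sprintf(
      "%04d-%02d-%02d",
      records$birth_year, records$birth_month, records$birth_day
    ),
    sex = na_blank(records$sex),
    country_of_birth = na_blank(records$country_of_birth)
  )
  for (k in postcode_cols) out[[k]] <- na_blank(records[[k]])
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_hospital <- function(records, path, delim = ",") {
  out <- records
  for (k in names(out)) out[[k]] <- na_blank(out[[k]])
  readr::write_delim(out[hospital_file_cols], path, delim = delim, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_episodes <- function(records, path, delim = ",") {
  out <- tibble::tibble(
    person_id = na_blank(records$person_id),
    hospital_name = na_blank(records$hospital_name),
    admission_date = na_blank(format(records$admission_date, "%Y-%m-%d")),
    discharge_date = na_blank(format(records$discharge_date, "%Y-%m-%d")),
    event_flag = na_blank(records$event_flag)
  )
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
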