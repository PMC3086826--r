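#' Field selectors available to composite linkage keys
#'
#' A key specification names an ordered set of identifying fields. Selectors:
#' `medicare8` (8-digit family card prefix); `suffix` (full 3-letter name
#' suffix) and its two-letter variants `suffix_12`, `suffix_23`, `suffix_13`
#' (first+second, second+third, first+third letters); `birth_year`,
#' `birth_month`, `birth_day`; `sex`; `country_of_birth`; and
#' `postcode1`..`postcode4` (ordered slots of distinct postcodes known for a
#' person — slot *k* is touched only by iterations naming it).
#'
#' @return Character vector of all valid selector names.
#' @export
key_selectors <- function() {
  c(
    "medicare8", "suffix", "suffix_12", "suffix_23", "suffix_13",
    "birth_year", "birth_month", "birth_day", "sex", "country_of_birth",
    paste0("postcode", 1:4)
  )
}

#' Define a composite-key specification
#'
#' @param selectors Character vector of field selectors ([key_selectors()]),
#'   in serialization order; non-empty, no duplicates.
#' @param label Short unique label for the iteration using this key; defaults
#'   to the selectors joined with `+`.
#' @return A `key_spec` object.
#' @examples
#' key_spec(c("medicare8", "suffix"))
#' @export
key_spec <- function(selectors, label = paste(selectors, collapse = "+")) {
  selectors <- as.character(selectors)
  if (length(selectors) == 0) stop("a key spec needs at least one selector")
  unknown <- setdiff(selectors, key_selectors())
  if (length(unknown) > 0) {
    stop("unknown selector(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(selectors)) stop("duplicate selectors in key spec")
  structure(
    list(selectors = selectors, label = as.character(label)),
    class = "key_spec"
  )
}

#' @export
print.key_spec <- function(x, ...) {
  cat("<key_spec>", x$label, ":", paste(x$selectors, collapse = " + "), "\n")
  invisible(x)
}

#' @export
format.key_spec <- function(x, ...) {
  paste0(x$label, " [", paste(x$selectors, collapse = "+"), "]")
}

# value of one selector across a record tibble, as character with NA for missing
selector_values <- function(records, selector) {
  suf <- function(i, j = NULL) {
    s <- records$suffix
    v <- if (is.null(j)) substr(s, i, i) else substr(s, i, j)
    v[is.na(s)] <- NA_character_
    v
  }
  switch(selector,
    suffix_12 = suf(1, 2),
    suffix_23 = suf(2, 3),
    suffix_13 = {
      v <- paste0(suf(1), suf(3))  # paste0 would turn NA into "NANA"
      v[is.na(records$suffix)] <- NA_character_
      v
    },
    as.character(records[[selector]])
  )
}

# serialized composite key per record: selected values joined with KEY_SEP,
# NA if any selected field is missing (a missing field never matches)
serialize_keys <- function(records, spec) {
  stopifnot(inherits(spec, "key_spec"))
  vals <- lapply(spec$selectors, function(s) selector_values(records, s))
  if (any(vapply(vals, function(v) any(grepl(KEY_SEP, v, fixed = TRUE)), NA))) {
    stop("reserved separator '", KEY_SEP, "' found inside a field value; ",
         "normalize inputs before keying")
  }
  any_missing <- Reduce(`|`, lapply(vals, is.na))
  # suffix_13 pastes two substrings; NA suffix propagates via is.na(s) above
  out <- do.call(paste, c(vals, sep = KEY_SEP))
  out[any_missing] <- NA_character_
  out
}

# keyed digest (HMAC-SHA-256, hex) of serialized keys; NA passes through
digest_keys <- function(serialized, secret) {
  if (!nzchar(secret)) stop("secret must be a non-empty string")
  out <- rep(NA_character_, length(serialized))
  ok <- !is.na(serialized)
  if (any(ok)) {
    out[ok] <- as.character(openssl::sha256(serialized[ok], key = secret))
  }
  out
}

#' Build the composite linkage key for one record
#'
#' Serializes the selected fields in order, joined by a reserved separator,
#' and digests the result with a keyed cryptographic digest (HMAC-SHA-256).
#' Comparing digests is equivalent to comparing plaintext keys, but the
#' digest reveals nothing without the run's secret, so two linkage units can
#' exchange digests instead of identifiers.
#'
#' @param record One-row tibble (cohort or hospital schema).
#' @param spec A [key_spec()].
#' @param secret Non-empty secret string shared by the run.
#' @return A `linkage_key` (list with `spec_label`, `serialized`, `digest`),
#'   or `NULL` when any selected field is missing on the record — such a
#'   record is simply ineligible for iterations using this key.
#' @export
build_key <- function(record, spec, secret) {
  stopifnot(nrow(record) == 1)
  ser <- serialize_keys(record, spec)
  if (is.na(ser)) return(NULL)
  structure(
    list(
      spec_label = spec$label,
      serialized = ser,
      digest = digest_keys(ser, secret)
    ),
    class = "linkage_key"
  )
}

#' Compare two linkage keys by digest
#'
#' @param a,b `linkage_key` objects built under the same spec and secret.
#'   Comparing keys from different specs is a programming error and raises.
#' @return `TRUE` iff the digests are identical (equivalently, with
#'   overwhelming probability, the plaintext serializations are equal).
#' @export
digest_equal <- function(a, b) {
  stopifnot(inherits(a, "linkage_key"), inherits(b, "linkage_key"))
  if (!identical(a$spec_label, b$spec_label)) {
    stop("cannot compare keys built under different specs: ",
         a$spec_label, " vs ", b$spec_label)
  }
  identical(a$digest, b$digest)
}
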