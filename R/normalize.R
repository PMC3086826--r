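#' Derive the three-letter name suffix used as a linkage identifier
#'
#' National health-insurance card numbers are unique to a family only;
#' individual family members are distinguished by a suffix comprising the
#' first three letters of the given name. This normalizes a free-text name
#' (uppercase, diacritics transliterated to ASCII, non-alphabetic characters
#' removed) and truncates it to three letters.
#'
#' @param given_name Character vector of given names.
#' @return Character vector of 3-letter uppercase suffixes; `NA` where fewer
#'   than three alphabetic characters remain after normalization.
#' @examples
#' derive_suffix(c("Alison", "Jo", "o'neil"))
#' @export
derive_suffix <- function(given_name) {
  x <- as.character(given_name)
  x <- iconv(enc2utf8(x), from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- toupper(x)
  x <- gsub("[^A-Z]", "", x)
  out <- substr(x, 1, 3)
  out[is.na(x) | nchar(x) < 3] <- NA_character_
  out
}

#' Truncate an insurance card number to its family-level 8-digit prefix
#'
#' Card numbers identify a family; only their first eight digits are stable
#' person-side identifiers, so linkage uses the 8-digit prefix. Separators
#' (spaces, dashes) are removed before truncation.
#'
#' @param card_number Character vector of raw card numbers.
#' @return Character vector of 8-digit strings; `NA` where fewer than eight
#'   digits are present.
#' @examples
#' derive_medicare8(c("1234567890", "1234 56789 0", "1234"))
#' @export
derive_medicare8 <- function(card_number) {
  x <- gsub("[^0-9]", "", as.character(card_number))
  out <- substr(x, 1, 8)
  out[is.na(x) | nchar(x) < 8] <- NA_character_
  out
}

#' Canonicalize free text for exact comparison
#'
#' Uppercases, transliterates diacritics, replaces punctuation with spaces and
#' collapses whitespace. Used for country of birth and hospital names, which
#' are compared as exact canonical strings (no fuzzy matching).
#'
#' @param x Character vector.
#' @return Canonical uppercase character vector; `NA` where empty.
#' @export
canonical_text <- function(x) {
  x <- as.character(x)
  x <- iconv(enc2utf8(x), from = "UTF-8", to = "ASCII//TRANSLIT")
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]+", " ", x)
  x <- trimws(gsub("\\s+", " ", x))
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

# blank -> NA, trim
blank_na <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- NA_character_
  x
}

# strict ISO-8601 date parse: returns Date, NA where invalid
parse_iso_date <- function(x) {
  x <- blank_na(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  # as.Date() rolls some invalid dates; require exact round trip
  bad <- !is.na(d) & format(d, "%Y-%m-%d") != x
  d[bad] <- as.Date(NA)
  d
}

# validity of (year, month, day) triples as calendar dates
valid_ymd <- function(year, month, day) {
  iso <- sprintf("%04d-%02d-%02d", year, month, day)
  iso[is.na(year) | is.na(month) | is.na(day)] <- NA
  d <- parse_iso_date(iso)
  !is.na(d)
}
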