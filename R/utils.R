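#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats setNames
#' @importFrom utils head modifyList
NULL

# Collapse whitespace runs and strip ends; NA-safe.
normalize_ws <- function(x) {
  out <- stringr::str_squish(ifelse(is.na(x), "", x))
  out[is.na(x)] <- NA_character_
  out
}

# Lowercased, whitespace-normalized form used for case-insensitive matching.
normalize_title <- function(x) {
  stringr::str_to_lower(normalize_ws(x))
}

# Strip all blanks then coerce to numeric; returns NA on failure.
coerce_number <- function(x) {
  x <- gsub("[[:space:]]", "", x %||% "")
  suppressWarnings(as.numeric(x))
}

# Serialize a list-column to a compact JSON string (for CSV round-trips).
pack_list_col <- function(col) {
  vapply(col, function(x) {
    jsonlite::toJSON(unname(as.character(x)))
  }, character(1))
}

unpack_list_col <- function(col) {
  lapply(col, function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else as.character(jsonlite::fromJSON(x))
  })
}
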