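#' @name response-tables
#' @title Trial-level response tables
#'
#' @description
#' The package's central data structure is a plain data frame with one row
#' per trial and the columns (in canonical order): `rater_id`, `rater_kind`
#' (`"human"` or `"model"`), `session` (`"test"` or `"retest"`),
#' `presentation` (`"ms50"`, `"ms200"`, `"self_paced"` or `"none"`),
#' `image_condition` (`"isolated"`, `"full"` or `"none"`), `block`,
#' `trial_index`, `stimulus_id`, `true_category`, `response_label`
#' (the raw answer, e.g. a typed word in free naming) and
#' `response_category` (the coded answer: a category label or `"UNKNOWN"`).
#'
#' A valid table has every `true_category` in the experiment's category
#' set, every `response_category` in the set or `"UNKNOWN"`, and no
#' duplicated `(rater_id, session, presentation, image_condition,
#' stimulus_id)` key.
NULL

RESPONSE_COLUMNS <- c("rater_id", "rater_kind", "session", "presentation",
                      "image_condition", "block", "trial_index",
                      "stimulus_id", "true_category", "response_label",
                      "response_category")

RATER_KINDS <- c("human", "model")
SESSIONS <- c("test", "retest")
PRESENTATIONS <- c("ms50", "ms200", "self_paced", "none")
IMAGE_CONDITIONS <- c("isolated", "full", "none")

response_key <- function(records) {
  paste(records$rater_id, records$session, records$presentation,
        records$image_condition, records$stimulus_id, sep = "\r")
}

#' Validate a response table
#'
#' Checks column presence, enum values, category membership and key
#' uniqueness. Row numbers in error messages refer to data rows
#' (the first data row is row 1); when the table came from a CSV file the
#' corresponding file line is the row number plus one (header line).
#'
#' @param records Data frame of trial records (see [response-tables]).
#' @param categories Character vector: the experiment's category set.
#' @return The validated data frame, invisibly, with `block` and
#'   `trial_index` coerced to integer.
#' @export
validate_responses <- function(records, categories) {
  stopifnot(is.data.frame(records), is.character(categories),
            length(categories) >= 2)
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("response table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[RESPONSE_COLUMNS]
  for (col in c("rater_id", "stimulus_id", "true_category",
                "response_label", "response_category"))
    records[[col]] <- as.character(records[[col]])
  records$block <- as.integer(records$block)
  records$trial_index <- as.integer(records$trial_index)
  if (nrow(records) == 0) return(invisible(records))

  check_enum <- function(col, allowed) {
    bad <- which(!records[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("invalid %s %s at row %d (allowed: %s)", col,
                   dQuote(records[[col]][bad[1]]), bad[1],
                   paste(allowed, collapse = ", ")), call. = FALSE)
  }
  check_enum("rater_kind", RATER_KINDS)
  check_enum("session", SESSIONS)
  check_enum("presentation", PRESENTATIONS)
  check_enum("image_condition", IMAGE_CONDITIONS)

  bad <- which(!records$true_category %in% categories)
  if (length(bad))
    stop(sprintf("integrity error: unknown true_category %s at row %d",
                 dQuote(records$true_category[bad[1]]), bad[1]),
         call. = FALSE)
  bad <- which(!records$response_category %in% c(categories, UNKNOWN_LABEL))
  if (length(bad))
    stop(sprintf("integrity error: unknown response_category %s at row %d",
                 dQuote(records$response_category[bad[1]]), bad[1]),
         call. = FALSE)
  bad <- which(is.na(records$block) | records$block < 1 |
                 is.na(records$trial_index) | records$trial_index < 1)
  if (length(bad))
    stop(sprintf("integrity error: non-positive block/trial_index at row %d",
                 bad[1]), call. = FALSE)

  key <- response_key(records)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf(paste0("integrity error: duplicate (rater, session, ",
                        "condition, stimulus) key at row %d (stimulus %s ",
                        "for rater %s)"),
                 dup[1], dQuote(records$stimulus_id[dup[1]]),
                 dQuote(records$rater_id[dup[1]])), call. = FALSE)
  invisible(records)
}

#' Read a response table from CSV
#'
#' Reads a UTF-8, comma-separated trial table with a header row and
#' validates it against a category set. Malformed rows are rejected with
#' messages naming the offending data row.
#'
#' @inheritParams validate_responses
#' @param path Path to the CSV file.
#' @return A validated response data frame in canonical column order.
#' @seealso [write_responses()], [validate_responses()]
#' @export
read_responses <- function(path, categories) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                      check.names = FALSE)
  validate_responses(records, categories)
  records <- records[RESPONSE_COLUMNS]
  records$block <- as.integer(records$block)
  records$trial_index <- as.integer(records$trial_index)
  records
}

#' Write a response table to CSV
#'
#' Writes the canonical column order, UTF-8, with a header row. An empty
#' table yields a header-only file.
#'
#' @param records Response data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(records))
  if (length(missing_cols))
    stop("response table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  write.csv(records[RESPONSE_COLUMNS], path, row.names = FALSE,
            fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Code free-naming answers as categories
#'
#' Maps raw typed answers onto the category set: a case- and
#' whitespace-insensitive exact match to a category wins; otherwise the
#' synonym map is consulted (aliases matched the same way); anything else
#' becomes `"UNKNOWN"`. The function is total and deterministic, and
#' idempotent on coded labels.
#'
#' @param raw Character vector of raw answers.
#' @param synonym_map Named character vector mapping alias -> category
#'   (e.g. `c(telly = "TV")`), or `NULL` for none. All values must belong
#'   to `categories`.
#' @param categories The category set.
#' @return Character vector of category labels or `"UNKNOWN"`, canonical
#'   spelling as given in `categories`.
#' @export
#' @examples
#' normalize_free_response(c(" mug ", "telly", "xylophone"),
#'                         c(telly = "TV"), default_categories())
normalize_free_response <- function(raw, synonym_map = NULL, categories) {
  stopifnot(is.character(categories))
  if (!is.null(synonym_map)) {
    stopifnot(is.character(synonym_map), !is.null(names(synonym_map)))
    bad <- setdiff(synonym_map, categories)
    if (length(bad))
      stop("synonym map targets outside the category set: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  clean <- tolower(trimws(as.character(raw)))
  out <- rep(UNKNOWN_LABEL, length(clean))
  hit <- match(clean, tolower(categories))
  out[!is.na(hit)] <- categories[hit[!is.na(hit)]]
  if (!is.null(synonym_map) && length(synonym_map)) {
    alias <- tolower(trimws(names(synonym_map)))
    rest <- is.na(hit)
    m <- match(clean[rest], alias)
    out[rest][!is.na(m)] <- unname(synonym_map)[m[!is.na(m)]]
  }
  out
}

#' Read a synonym map from a two-column CSV
#'
#' @param path CSV file with columns `alias`, `category`.
#' @return Named character vector alias -> category.
#' @export
read_synonym_map <- function(path) {
  tab <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("alias", "category") %in% names(tab)))
    stop("synonym map needs columns alias, category", call. = FALSE)
  setNames(tab$category, tab$alias)
}
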