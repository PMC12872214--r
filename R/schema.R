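# Record schema shared by every linkage engine.
#
# A patient record carries one opaque id (never a linkage feature; it only
# keys the truth links of a simulation) and ten linkage fields:
#   categorical: sex, nationality, region, coverage, facility
#   date:        dob, ms_first_dx_date
#   set-valued:  other_dx (ICD-10 codes), medications, admissions (dates)
# A blank scalar cell is missing; a blank set cell is the empty set, i.e.
# "no clinical event on record", which is a value, not a gap.

CAT_FIELDS  <- c("sex", "nationality", "region", "coverage", "facility")
DATE_FIELDS <- c("dob", "ms_first_dx_date")
SET_FIELDS  <- c("other_dx", "medications", "admissions")

#' Linkage field names and types
#'
#' @return named character vector mapping each linkage field to its type
#'   (`"categorical"`, `"date"` or `"set"`).
#' @export
linkage_fields <- function() {
  c(setNames(rep("categorical", length(CAT_FIELDS)), CAT_FIELDS),
    setNames(rep("date", length(DATE_FIELDS)), DATE_FIELDS),
    setNames(rep("set", length(SET_FIELDS)), SET_FIELDS))
}

field_type <- function(field) {
  ft <- linkage_fields()
  if (!field %in% names(ft)) stop_("unknown linkage field '%s'", field)
  unname(ft[field])
}

REQUIRED_COLS <- c("record_id", names(linkage_fields()))

# canonical form of one set cell: unique, sorted, no blanks
canon_set <- function(x) {
  if (length(x) == 0) return(character(0))
  sort(unique(x[!is.na(x) & nzchar(x)]))
}

#' Construct a validated two-source-linkage dataset
#'
#' Wraps a data frame of patient records into the container the linkage
#' engines operate on. Dates must be `Date` (or ISO-8601 strings), the
#' set-valued columns list-columns of character vectors (or
#' semicolon-delimited strings). Record ids must be non-empty and unique.
#'
#' @param records data frame with columns `record_id`, `sex`, `dob`,
#'   `nationality`, `region`, `coverage`, `facility`, `ms_first_dx_date`,
#'   `other_dx`, `medications`, `admissions`.
#' @param source single string labelling the source the records came from.
#' @return an `ehr_dataset`: a `data.table` with a `source` attribute.
#' @export
ehr_dataset <- function(records, source) {
  if (!is.character(source) || length(source) != 1L || !nzchar(source))
    stop_("`source` must be a single non-empty string")
  dt <- as.data.table(records)
  missing_cols <- setdiff(REQUIRED_COLS, names(dt))
  if (length(missing_cols))
    stop_("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0L) stop_("a dataset must contain at least one record")
  dt[, record_id := as.character(record_id)]
  if (anyNA(dt$record_id) || any(!nzchar(dt$record_id)))
    stop_("record_id must be non-empty for every row")
  dup <- dt$record_id[duplicated(dt$record_id)]
  if (length(dup))
    stop_("duplicate record_id in source '%s': %s", source, dup[1L])
  for (f in CAT_FIELDS) {
    v <- as.character(dt[[f]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    set(dt, j = f, value = v)
  }
  for (f in DATE_FIELDS) {
    v <- dt[[f]]
    if (!inherits(v, "Date")) v <- parse_iso_dates(as.character(v), f)
    set(dt, j = f, value = v)
  }
  for (f in SET_FIELDS) {
    v <- dt[[f]]
    if (!is.list(v)) v <- split_set_cells(as.character(v))
    set(dt, j = f, value = lapply(v, canon_set))
  }
  setcolorder(dt, REQUIRED_COLS)
  setattr(dt, "source", source)
  setattr(dt, "class", c("ehr_dataset", class(dt)))
  dt[]
}

dataset_source <- function(ds) attr(ds, "source") %||% "?"

#' @export
print.ehr_dataset <- function(x, ...) {
  cat(sprintf("<ehr_dataset> source '%s': %d records\n",
              dataset_source(x), nrow(x)))
  miss <- vapply(names(linkage_fields()), function(f) {
    if (f %in% SET_FIELDS) sum(lengths(x[[f]]) == 0L) else sum(is.na(x[[f]]))
  }, integer(1))
  cat("missing/empty per field:",
      paste(sprintf("%s=%d", names(miss), miss), collapse = " "), "\n")
  invisible(x)
}

# strict ISO parse with row-numbered errors; blank -> NA
parse_iso_dates <- function(x, col) {
  blank <- is.na(x) | !nzchar(x)
  d <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  if (any(!blank)) {
    parsed <- as.Date(x[!blank], format = "%Y-%m-%d")
    # reject e.g. 2023-13-01 and anything not round-tripping to ISO
    ok <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x[!blank]
    if (any(!ok)) {
      bad_row <- which(!blank)[which(!ok)[1L]]
      stop_("column '%s': unparseable date '%s' at row %d",
            col, x[!blank][which(!ok)[1L]], bad_row)
    }
    d[!blank] <- parsed
  }
  d
}

split_set_cells <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) character(0)
    else strsplit(cell, ";", fixed = TRUE)[[1L]]
  })
}
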