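# CSV readers/writers for records, truth links and matched pairs.
#
# Dialect: comma-delimited UTF-8, ISO-8601 dates, semicolon as the
# intra-cell delimiter for set-valued columns. Blank cell = missing for
# scalar columns and empty set for set-valued columns.

#' Read a patient-record CSV into a dataset
#'
#' @param path path to a records CSV with header
#'   `record_id,sex,dob,nationality,region,coverage,facility,ms_first_dx_date,other_dx,medications,admissions`.
#' @param source_label label for the source (conventionally `"A"` or `"B"`).
#' @return an [ehr_dataset()].
#' @export
read_records <- function(path, source_label = "A") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  dt <- fread(path, colClasses = "character", na.strings = NULL,
              encoding = "UTF-8")
  if (!"record_id" %in% names(dt))
    stop_("missing mandatory record_id column in %s", path)
  # admissions elements must themselves be ISO dates
  ds <- ehr_dataset(dt, source_label)
  for (i in seq_len(nrow(ds))) {
    adm <- ds$admissions[[i]]
    if (length(adm)) {
      parsed <- as.Date(adm, format = "%Y-%m-%d")
      if (anyNA(parsed) || any(format(parsed, "%Y-%m-%d") != adm))
        stop_("column 'admissions': unparseable date at row %d", i)
    }
  }
  ds
}

#' Write a dataset back to the records CSV dialect
#'
#' `read_records(write_records(ds))` reproduces every field value,
#' missingness pattern and set membership exactly.
#'
#' @param ds an [ehr_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(ds, path) {
  out <- data.table(record_id = ds$record_id)
  for (f in names(linkage_fields())) {
    v <- ds[[f]]
    col <- switch(field_type(f),
      categorical = fifelse(is.na(v), "", v),
      date = fifelse(is.na(v), "", format(v, "%Y-%m-%d")),
      set = vapply(v, function(s) paste(canon_set(s), collapse = ";"), "")
    )
    set(out, j = f, value = col)
  }
  fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Read / write truth links
#'
#' Truth links are the known one-to-one correspondence between the two
#' sources used to score a simulation; ids appear at most once per side.
#'
#' @param path CSV with columns `record_id_a,record_id_b`.
#' @param truth a two-column data frame of linked id pairs.
#' @return `read_truth`: a `data.table(record_id_a, record_id_b)`.
#' @export
read_truth <- function(path) {
  dt <- fread(path, colClasses = "character")
  validate_truth(dt)
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  truth <- validate_truth(truth)
  fwrite(truth[order(record_id_a, record_id_b)], path, quote = FALSE)
  invisible(path)
}

validate_truth <- function(truth) {
  dt <- as.data.table(truth)[, .(record_id_a = as.character(record_id_a),
                                 record_id_b = as.character(record_id_b))]
  if (anyDuplicated(dt$record_id_a) || anyDuplicated(dt$record_id_b))
    stop_("truth links must be one-to-one: a record id appears twice")
  dt
}

#' Write the matched pairs of a linkage run
#'
#' Rows are sorted by `record_id_a` then `record_id_b`, so re-writing the
#' same result gives a byte-identical file.
#'
#' @param result a `linkage_result` (any engine's output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(result, path) {
  stopifnot(inherits(result, "linkage_result"))
  p <- copy(result$pairs)
  p[, method := result$method]
  if (!"score" %in% names(p)) p[, score := NA_real_]
  setorder(p, record_id_a, record_id_b)
  fwrite(p[, .(record_id_a, record_id_b, method, score)], path, quote = FALSE)
  invisible(path)
}

#' Size of the full comparison universe
#'
#' The confusion-matrix denominator for two-source linkage is the full
#' cross product |A|x|B|; it is returned as a double without materializing
#' any pair.
#'
#' @param dsA,dsB the two datasets.
#' @return |A|*|B| as a double.
#' @export
validate_pair_universe <- function(dsA, dsB) {
  if (nrow(dsA) == 0L || nrow(dsB) == 0L) stop_("datasets must be non-empty")
  as.numeric(nrow(dsA)) * as.numeric(nrow(dsB))
}

#' Read an experiment configuration
#'
#' Loads the YAML config driving the analysis scripts: a `cohort:` section
#' ([cohort_config()] arguments), named deterministic `rules:`,
#' `probabilistic:` criteria (block/compare/threshold/one_to_one) and `ml:`
#' settings. Field names are validated against the record schema.
#'
#' @param path path to a YAML file.
#' @return named list of config sections.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(linkage_fields())
  check_fields <- function(x, where) {
    bad <- setdiff(unlist(x), known)
    if (length(bad))
      stop_("config %s references unknown field(s): %s",
            where, paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$rules)) check_fields(cfg$rules, "rules")
  for (nm in names(cfg$probabilistic %||% list())) {
    check_fields(cfg$probabilistic[[nm]]$block, paste0("probabilistic$", nm, "$block"))
    check_fields(cfg$probabilistic[[nm]]$compare, paste0("probabilistic$", nm, "$compare"))
  }
  if (!is.null(cfg$ml)) check_fields(cfg$ml$fields, "ml$fields")
  cfg
}
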