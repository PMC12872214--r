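# Clone-and-deidentify simulation harness.
#
# Linking a dataset against a deidentified copy of itself makes every true
# match known, so any engine can be scored with a full confusion matrix —
# the validation design applied before touching real data, where no truth
# exists.

# shared constructor for every engine's output
linkage_result <- function(method, pairs, n_candidates, runtime_s) {
  pairs <- as.data.table(pairs)
  if (runtime_s < 0) stop_("runtime must be >= 0")
  structure(list(method = method, pairs = pairs,
                 n_candidates = n_candidates, runtime_s = runtime_s),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> %s: %d matched pairs of %s candidates (%.3fs)\n",
              x$method, nrow(x$pairs), format(x$n_candidates, big.mark = ","),
              x$runtime_s))
  invisible(x)
}

#' Clone and deidentify a dataset
#'
#' The clone keeps every linkage field value-identical to its source record
#' but carries fresh record ids disjoint from the originals; the returned
#' truth links pair each original with its clone.
#'
#' @param ds an [ehr_dataset()].
#' @param id_prefix prefix for the fresh clone ids.
#' @return `list(clone =, truth =)`.
#' @export
clone_deidentify <- function(ds, id_prefix = "C") {
  if (nrow(ds) == 0L) stop_("dataset must be non-empty")
  new_ids <- sprintf("%s%05d", id_prefix, seq_len(nrow(ds)))
  while (any(new_ids %in% ds$record_id)) {
    id_prefix <- paste0(id_prefix, "X")
    new_ids <- sprintf("%s%05d", id_prefix, seq_len(nrow(ds)))
  }
  clone <- copy(as.data.table(ds))
  clone[, record_id := new_ids]
  list(clone = ehr_dataset(clone, paste0(dataset_source(ds), "_clone")),
       truth = data.table(record_id_a = ds$record_id, record_id_b = new_ids))
}

#' Run one linkage method against ground truth
#'
#' Calls `method(dsA, dsB, ...)`, which must return a `linkage_result`,
#' times the engine call (wall clock around the engine only) and computes
#' full confusion metrics over the |A|x|B| universe. An engine error is
#' recorded as a failed run, never silently dropped.
#'
#' @inheritParams match_by_rule
#' @param truth truth links.
#' @param method a linkage callable `function(dsA, dsB, ...)`.
#' @param label optional method label overriding the engine's own.
#' @param ... passed to `method`.
#' @return a `simulation_run`: method label, `linkage_result`,
#'   `confusion_metrics` (or `error` string for a failed run).
#' @export
run_simulation <- function(dsA, dsB, truth, method, label = NULL, ...) {
  truth <- validate_truth(truth)
  universe <- validate_pair_universe(dsA, dsB)
  t0 <- Sys.time()
  res <- tryCatch(method(dsA, dsB, ...), error = function(e) e)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (inherits(res, "error")) {
    return(structure(list(method = label %||% "unknown", result = NULL,
                          metrics = NULL, error = conditionMessage(res)),
                     class = "simulation_run"))
  }
  stopifnot(inherits(res, "linkage_result"))
  if (is.null(res$runtime_s) || is.na(res$runtime_s)) res$runtime_s <- elapsed
  structure(list(method = label %||% res$method, result = res,
                 metrics = confusion_from_pairs(res$pairs, truth, universe),
                 error = NULL),
            class = "simulation_run")
}

#' @export
print.simulation_run <- function(x, ...) {
  if (is.null(x$metrics)) {
    cat(sprintf("<simulation_run> %s FAILED: %s\n", x$method, x$error))
  } else {
    cat(sprintf("<simulation_run> %s\n", x$method))
    print(x$metrics)
  }
  invisible(x)
}

#' Truth-free real-world linkage report
#'
#' When the two sources share no identifier there is no reference standard;
#' methods are compared by the number of matched pairs they declare,
#' reported with the count as a percentage of |B| (one decimal).
#'
#' @inheritParams match_by_rule
#' @param methods named list of linkage callables `function(dsA, dsB)`,
#'   each returning a `linkage_result`.
#' @return `data.table(method, matched_pairs, n_b, pct_of_b)`.
#' @export
real_world_link <- function(dsA, dsB, methods) {
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    stop_("`methods` must be a named list")
  n_b <- nrow(dsB)
  rows <- lapply(names(methods), function(nm) {
    res <- methods[[nm]](dsA, dsB)
    stopifnot(inherits(res, "linkage_result"))
    data.table(method = nm, matched_pairs = nrow(res$pairs), n_b = n_b,
               pct_of_b = match_rate_pct(nrow(res$pairs), n_b))
  })
  rbindlist(rows)
}

#' Match-rate percentage
#'
#' `100 * count / denominator`, half-up at one decimal — the convention of
#' truth-free match-count reporting.
#'
#' @param count matched-pair count.
#' @param denominator reference size (usually |B|).
#' @return percentage at one decimal.
#' @export
match_rate_pct <- function(count, denominator) {
  round_half_up(100 * count / denominator, 1)
}
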