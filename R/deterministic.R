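# Rule-based deterministic linkage: a pair is a match iff it agrees exactly
# on every field of the rule. Missing never agrees with missing. Set-valued
# fields agree on a shared element (default) or on full set equality.
# Matching is a hash join on the composite key, never an all-pairs scan.

#' Define a deterministic linkage rule
#'
#' @param fields character vector of >= 1 linkage field names; a pair
#'   matches iff it agrees on all of them.
#' @param set_semantics agreement semantics for set-valued fields:
#'   `"intersect"` (share at least one element; two empty sets share none)
#'   or `"equal"` (identical sets).
#' @return a `linkage_rule`.
#' @export
linkage_rule <- function(fields, set_semantics = c("intersect", "equal")) {
  set_semantics <- match.arg(set_semantics)
  if (length(fields) < 1L) stop_("a rule needs at least one field")
  unknown <- setdiff(fields, names(linkage_fields()))
  if (length(unknown)) stop_("rule references unknown field '%s'", unknown[1L])
  structure(list(fields = unique(fields), set_semantics = set_semantics),
            class = "linkage_rule")
}

# per-pair agreement bit on one field, vectorized over row indices
agreement_vec <- function(dsA, ia, dsB, ib, field, set_semantics = "intersect") {
  type <- field_type(field)
  if (type == "set") {
    a <- dsA[[field]][ia]; b <- dsB[[field]][ib]
    if (set_semantics == "equal")
      return(as.integer(mapply(identical, a, b)))
    as.integer(mapply(function(x, y) length(intersect(x, y)) > 0L, a, b))
  } else {
    a <- dsA[[field]][ia]; b <- dsB[[field]][ib]
    as.integer(!is.na(a) & !is.na(b) & a == b)
  }
}

# distinct (row-index) pairs agreeing on one field, by hash join
field_pairs <- function(dsA, dsB, field, set_semantics = "intersect") {
  type <- field_type(field)
  if (type == "set") {
    if (set_semantics == "equal") {
      ka <- data.table(ia = seq_len(nrow(dsA)),
                       key_a = vapply(dsA[[field]], paste, "", collapse = ";"))
      kb <- data.table(ib = seq_len(nrow(dsB)),
                       key_a = vapply(dsB[[field]], paste, "", collapse = ";"))
      j <- kb[ka, on = "key_a", allow.cartesian = TRUE, nomatch = NULL]
      return(unique(j[, .(ia, ib)]))
    }
    la <- lengths(dsA[[field]]); lb <- lengths(dsB[[field]])
    ka <- data.table(ia = rep(seq_len(nrow(dsA)), la),
                     key_a = unlist(dsA[[field]], use.names = FALSE))
    kb <- data.table(ib = rep(seq_len(nrow(dsB)), lb),
                     key_a = unlist(dsB[[field]], use.names = FALSE))
    if (nrow(ka) == 0L || nrow(kb) == 0L)
      return(data.table(ia = integer(0), ib = integer(0)))
    j <- kb[ka, on = "key_a", allow.cartesian = TRUE, nomatch = NULL]
    return(unique(j[, .(ia, ib)]))
  }
  va <- as.character(dsA[[field]]); vb <- as.character(dsB[[field]])
  ka <- data.table(ia = seq_len(nrow(dsA)), key_a = va)[!is.na(key_a)]
  kb <- data.table(ib = seq_len(nrow(dsB)), key_a = vb)[!is.na(key_a)]
  kb[ka, on = "key_a", allow.cartesian = TRUE, nomatch = NULL][, .(ia, ib)]
}

#' Link two sources by a deterministic rule
#'
#' Returns exactly the pairs agreeing on every rule field; a pair with a
#' missing value in any rule field is a non-match. The first (rarest) rule
#' field drives a hash join; remaining fields filter the joined pairs.
#'
#' @param dsA,dsB the two [ehr_dataset()]s.
#' @param rule a [linkage_rule()] (or character vector of field names).
#' @return a `linkage_result`: method label, matched-pair table,
#'   candidate-pair count, wall-clock seconds.
#' @export
match_by_rule <- function(dsA, dsB, rule) {
  if (is.character(rule)) rule <- linkage_rule(rule)
  stopifnot(inherits(rule, "linkage_rule"))
  t0 <- Sys.time()
  # drive the join from the cheapest scalar field when available
  est <- vapply(rule$fields, function(f) {
    if (field_type(f) == "set") Inf else candidate_count(dsA, dsB, f)
  }, numeric(1))
  ord <- rule$fields[order(est)]
  pairs <- field_pairs(dsA, dsB, ord[1L], rule$set_semantics)
  n_candidates <- nrow(pairs)
  for (f in ord[-1L]) {
    if (nrow(pairs) == 0L) break
    keep <- agreement_vec(dsA, pairs$ia, dsB, pairs$ib, f, rule$set_semantics) == 1L
    pairs <- pairs[keep]
  }
  out <- data.table(record_id_a = dsA$record_id[pairs$ia],
                    record_id_b = dsB$record_id[pairs$ib])
  setorder(out, record_id_a, record_id_b)
  linkage_result(method = paste0("deterministic:", paste(rule$fields, collapse = "+")),
                 pairs = unique(out), n_candidates = n_candidates,
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Count candidate pairs agreeing on one field
#'
#' For scalar fields this is the frequency-table sum over shared values v
#' of countA(v) * countB(v), computed without materializing pairs. For
#' set-valued fields it is the number of distinct pairs sharing at least
#' one element (or with equal sets, under `"equal"` semantics).
#'
#' @inheritParams match_by_rule
#' @param field one linkage field name.
#' @param set_semantics see [linkage_rule()].
#' @return pair count as a double.
#' @export
candidate_count <- function(dsA, dsB, field, set_semantics = "intersect") {
  type <- field_type(field)
  if (type == "set") return(as.numeric(nrow(field_pairs(dsA, dsB, field, set_semantics))))
  ta <- table(as.character(dsA[[field]]))
  tb <- table(as.character(dsB[[field]]))
  shared <- intersect(names(ta), names(tb))
  sum(as.numeric(ta[shared]) * as.numeric(tb[shared]))
}

#' Single-variable deterministic sweep
#'
#' Evaluates every field as a one-field rule against truth, reporting
#' per-field confusion metrics in percent (two decimals). Counts come from
#' frequency tables plus truth-pair agreement, so the full candidate set of
#' low-cardinality fields (millions of pairs) is never materialized.
#'
#' @inheritParams match_by_rule
#' @param truth truth links (see [read_truth()]).
#' @param fields fields to sweep; defaults to all ten linkage fields.
#' @param set_semantics see [linkage_rule()].
#' @return `data.table` with one row per field: candidate pairs, confusion
#'   counts and percent metrics; the unformatted `confusion_metrics` list is
#'   attached as attribute `"metrics"`.
#' @export
single_variable_sweep <- function(dsA, dsB, truth,
                                  fields = names(linkage_fields()),
                                  set_semantics = "intersect") {
  truth <- validate_truth(truth)
  universe <- validate_pair_universe(dsA, dsB)
  ia <- match(truth$record_id_a, dsA$record_id)
  ib <- match(truth$record_id_b, dsB$record_id)
  if (anyNA(ia) || anyNA(ib)) stop_("truth links reference unknown record ids")
  metrics <- vector("list", length(fields))
  rows <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[k]
    p <- candidate_count(dsA, dsB, f, set_semantics)
    tp <- sum(agreement_vec(dsA, ia, dsB, ib, f, set_semantics))
    m <- confusion_from_counts(tp = tp, fp = p - tp, fn = nrow(truth) - tp,
                               universe = universe)
    metrics[[k]] <- m
    rows[[k]] <- data.table(
      field = f, candidate_pairs = p, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
      accuracy = as_pct(m$accuracy), sensitivity = as_pct(m$sensitivity),
      specificity = as_pct(m$specificity), ppv = as_pct(m$ppv),
      f1 = as_pct(m$f1))
  }
  out <- rbindlist(rows)
  setattr(out, "metrics", setNames(metrics, fields))
  out
}
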