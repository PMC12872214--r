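# Fixture builders and independent brute-force oracles. The oracles
# deliberately re-derive agreement and confusion logic with plain loops and
# set operations, so they never share a code path with the engines they
# check.

library(data.table)

# hand-built dataset from compact column specs; set columns given as
# semicolon-delimited strings
toy_dataset <- function(..., source = "A") {
  cols <- list(...)
  n <- length(cols$record_id)
  defaults <- list(sex = NA_character_, dob = NA_character_,
                   nationality = NA_character_, region = NA_character_,
                   coverage = NA_character_, facility = NA_character_,
                   ms_first_dx_date = NA_character_, other_dx = "",
                   medications = "", admissions = "")
  for (f in names(defaults))
    if (is.null(cols[[f]])) cols[[f]] <- rep(defaults[[f]], n)
  ehr_dataset(as.data.table(cols), source)
}

# clone-simulation bundle from a generated cohort
make_clone_sim <- function(n, seed = 1L, ...) {
  co <- generate_cohort(cohort_config(n_source_a = n, seed = seed, ...))
  cl <- clone_deidentify(co$A)
  list(ds = co$A, clone = cl$clone, truth = cl$truth)
}

# oracle agreement on one field for a single record pair
oracle_agree <- function(dsA, i, dsB, j, field, set_semantics = "intersect") {
  type <- linkage_fields()[[field]]
  a <- dsA[[field]][[i]]; b <- dsB[[field]][[j]]
  if (type == "set") {
    if (set_semantics == "equal") return(identical(sort(a), sort(b)))
    return(length(intersect(a, b)) > 0)
  }
  if (type == "date") return(!is.na(a) && !is.na(b) && a == b)
  !is.na(a) && !is.na(b) && a == b
}

# oracle: all-pairs scan for a deterministic rule
oracle_rule_pairs <- function(dsA, dsB, fields, set_semantics = "intersect") {
  out <- list()
  for (i in seq_len(nrow(dsA))) for (j in seq_len(nrow(dsB))) {
    if (all(vapply(fields, function(f)
      oracle_agree(dsA, i, dsB, j, f, set_semantics), logical(1))))
      out[[length(out) + 1L]] <- c(dsA$record_id[i], dsB$record_id[j])
  }
  if (!length(out))
    return(data.table(record_id_a = character(0), record_id_b = character(0)))
  dt <- as.data.table(do.call(rbind, out))
  setnames(dt, c("record_id_a", "record_id_b"))
  setorder(dt, record_id_a, record_id_b)
  dt
}

# oracle confusion counts from plain set operations
oracle_confusion <- function(predicted, truth, universe) {
  pk <- paste(predicted$record_id_a, predicted$record_id_b)
  tk <- paste(truth$record_id_a, truth$record_id_b)
  tp <- length(intersect(pk, tk))
  list(tp = tp, fp = length(setdiff(pk, tk)), fn = length(setdiff(tk, pk)),
       tn = universe - length(union(pk, tk)))
}

# oracle: exhaustive maximum-total-score one-to-one assignment by
# enumerating subsets recursively (independent of the package's
# branch-and-bound)
oracle_best_assignment <- function(scored) {
  best <- -Inf
  n <- nrow(scored)
  rec <- function(i, ua, ub, tot) {
    if (tot > best) best <<- tot
    if (i > n) return()
    for (j in i:n) {
      a <- scored$record_id_a[j]; b <- scored$record_id_b[j]
      if (!(a %in% ua) && !(b %in% ub))
        rec(j + 1L, c(ua, a), c(ub, b), tot + scored$score[j])
    }
  }
  rec(1L, character(0), character(0), 0)
  best
}

pairs_dt <- function(a, b, score = NULL) {
  dt <- data.table(record_id_a = a, record_id_b = b)
  if (!is.null(score)) dt[, score := score]
  dt
}

expect_same_pairs <- function(got, want) {
  g <- as.data.table(got)[, .(record_id_a, record_id_b)]
  w <- as.data.table(want)[, .(record_id_a, record_id_b)]
  setorder(g, record_id_a, record_id_b)
  setorder(w, record_id_a, record_id_b)
  expect_equal(as.data.frame(g), as.data.frame(w), ignore_attr = TRUE)
}
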