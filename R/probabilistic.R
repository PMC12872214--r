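# Fellegi-Sunter probabilistic linkage.
#
# Candidate pairs come from exact blocking; each pair is reduced to a
# binary agreement vector over the comparison fields. A two-class
# conditional-independence mixture (match / non-match) is fitted to the
# vectors by EM, giving per-field m-probabilities (agreement given a true
# match), u-probabilities (agreement given a non-match) and the mixing
# weight lambda. Pairs are scored by summed log2 likelihood-ratio weights
# and classified by threshold, optionally under a one-to-one constraint
# that links each record at most once.

#' Generate candidate pairs by exact blocking
#'
#' Exactly the pairs agreeing on all block fields (same agreement semantics
#' as the deterministic engine); records missing a block field produce no
#' pairs. For a single block field the pair count equals
#' [candidate_count()].
#'
#' @inheritParams match_by_rule
#' @param block_fields character vector of blocking fields.
#' @param set_semantics see [linkage_rule()].
#' @return `data.table(record_id_a, record_id_b)` of candidate pairs.
#' @export
block_pairs <- function(dsA, dsB, block_fields, set_semantics = "intersect") {
  res <- match_by_rule(dsA, dsB, linkage_rule(block_fields, set_semantics))
  if (nrow(res$pairs) == 0L)
    warning("blocking produced an empty candidate set", call. = FALSE)
  res$pairs
}

#' Build binary comparison vectors for candidate pairs
#'
#' One agreement bit per comparison field and pair; any comparison
#' involving a missing value scores 0 (two missing values never agree).
#'
#' @inheritParams match_by_rule
#' @param pairs candidate pairs, `data.table(record_id_a, record_id_b)`.
#' @param fields comparison fields.
#' @param set_semantics see [linkage_rule()].
#' @return a `comparison_vectors` object: the pair table plus a 0/1 matrix
#'   `gamma` with one column per field.
#' @export
build_comparison_vectors <- function(pairs, dsA, dsB, fields,
                                     set_semantics = "intersect") {
  ia <- match(pairs$record_id_a, dsA$record_id)
  ib <- match(pairs$record_id_b, dsB$record_id)
  if (anyNA(ia) || anyNA(ib)) stop_("pairs reference unknown record ids")
  gamma <- matrix(0L, nrow = nrow(pairs), ncol = length(fields),
                  dimnames = list(NULL, fields))
  for (f in fields)
    gamma[, f] <- agreement_vec(dsA, ia, dsB, ib, f, set_semantics)
  structure(list(pairs = as.data.table(pairs)[, .(record_id_a, record_id_b)],
                 gamma = gamma, fields = fields),
            class = "comparison_vectors")
}

#' Fit the Fellegi-Sunter mixture by expectation-maximization
#'
#' Two-class conditional-independence mixture over binary agreement
#' patterns. E-step: responsibility of the match class for pattern j is
#' `g_j = lambda * prod_k m_k^g_jk (1-m_k)^(1-g_jk) / (that + (1-lambda) *
#' prod_k u_k^g_jk (1-u_k)^(1-g_jk))`. M-step: `lambda = mean(g)`,
#' `m_k = sum(g * gamma_k) / sum(g)`, `u_k = sum((1-g) * gamma_k) /
#' sum(1-g)`. Iterates until the largest absolute parameter change falls
#' below `tol` or `max_iter` is reached; the observed-data log-likelihood
#' is non-decreasing across iterations. Probabilities are clamped to
#' `[1e-6, 1 - 1e-6]`. Label switching is resolved so the class with the
#' higher mean total agreement is "match".
#'
#' @param vectors a [build_comparison_vectors()] result, or a 0/1 matrix.
#' @param m_init,u_init,lambda_init starting values.
#' @param tol convergence tolerance on the parameter vector.
#' @param max_iter iteration cap (warning on hitting it).
#' @return an `fs_model` with `m`, `u`, `lambda`, the log2 agreement and
#'   disagreement weights, iteration count and log-likelihood trace.
#' @export
em_fit <- function(vectors, m_init = 0.9, u_init = 0.1, lambda_init = 0.1,
                   tol = 1e-6, max_iter = 1000L) {
  gamma <- if (inherits(vectors, "comparison_vectors")) vectors$gamma else as.matrix(vectors)
  if (ncol(gamma) < 1L) stop_("at least one comparison field is required")
  storage.mode(gamma) <- "double"
  K <- ncol(gamma)
  # collapse to unique agreement patterns for speed
  key <- apply(gamma, 1L, paste, collapse = "")
  tab <- table(key)
  if (length(tab) < 2L)
    stop_("degenerate comparison data: all agreement vectors are identical")
  pat <- do.call(rbind, strsplit(names(tab), ""))
  storage.mode(pat) <- "double"
  n_pat <- as.numeric(tab)
  N <- sum(n_pat)

  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  m <- clamp(rep(m_init, K)); u <- clamp(rep(u_init, K))
  lambda <- min(max(lambda_init, 1e-6), 1 - 1e-6)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lm <- pat %*% log(m) + (1 - pat) %*% log1p(-m)
    lu <- pat %*% log(u) + (1 - pat) %*% log1p(-u)
    a <- log(lambda) + lm
    b <- log1p(-lambda) + lu
    mx <- pmax(a, b)
    ll <- sum(n_pat * (mx + log(exp(a - mx) + exp(b - mx))))
    loglik <- c(loglik, ll)
    g <- 1 / (1 + exp(b - a))
    lambda_new <- sum(n_pat * g) / N
    wg <- n_pat * g
    wu <- n_pat * (1 - g)
    m_new <- clamp(as.numeric(crossprod(pat, wg)) / sum(wg))
    u_new <- clamp(as.numeric(crossprod(pat, wu)) / sum(wu))
    lambda_new <- min(max(lambda_new, 1e-6), 1 - 1e-6)
    delta <- max(abs(c(m_new - m, u_new - u, lambda_new - lambda)))
    m <- m_new; u <- u_new; lambda <- lambda_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("EM did not converge within %d iterations", max_iter),
            call. = FALSE)
  if (sum(m) < sum(u)) {  # label switch: match class has higher agreement
    tmp <- m; m <- u; u <- tmp
    lambda <- 1 - lambda
  }
  fields <- colnames(gamma) %||% paste0("f", seq_len(K))
  structure(list(
    fields = fields,
    m = setNames(m, fields), u = setNames(u, fields), lambda = lambda,
    w_agree = setNames(log2(m / u), fields),
    w_disagree = setNames(log2((1 - m) / (1 - u)), fields),
    n_iter = iter, converged = converged,
    loglik = loglik[length(loglik)], loglik_trace = loglik),
    class = "fs_model")
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf("<fs_model> lambda = %.4f, %d EM iterations%s\n", x$lambda,
              x$n_iter, if (x$converged) "" else " (not converged)"))
  print(data.table(field = x$fields, m = round(x$m, 4), u = round(x$u, 4),
                   w_agree = round(x$w_agree, 3),
                   w_disagree = round(x$w_disagree, 3)))
  invisible(x)
}

#' Score candidate pairs under a fitted model
#'
#' Total score `S = sum_k [gamma_k * w_agree_k + (1 - gamma_k) *
#' w_disagree_k]` — the summed log2 likelihood ratios across fields.
#'
#' @param vectors a [build_comparison_vectors()] result.
#' @param model an [em_fit()] result fitted on the same fields.
#' @return the pair table with a `score` column.
#' @export
score_pairs <- function(vectors, model) {
  stopifnot(inherits(vectors, "comparison_vectors"), inherits(model, "fs_model"))
  if (!identical(vectors$fields, model$fields))
    stop_("model was fitted on different comparison fields")
  g <- vectors$gamma
  s <- as.numeric(g %*% model$w_agree + (1 - g) %*% model$w_disagree)
  out <- copy(vectors$pairs)
  out[, score := s]
  out[]
}

#' One-to-one assignment of scored pairs
#'
#' Selects pairs in descending score order (ties broken by ascending
#' `(record_id_a, record_id_b)`), skipping any pair whose record is already
#' linked; pairs scoring below `threshold` are excluded. `method = "exact"`
#' solves the maximum-total-score one-to-one assignment by branch-and-bound
#' and is intended as a small-instance oracle (<= ~25 pairs).
#'
#' @param scored `data.table(record_id_a, record_id_b, score)`.
#' @param threshold minimum score retained (default 0: pair more likely a
#'   match than a non-match under the fitted model).
#' @param method `"greedy"` (default) or `"exact"`.
#' @return the selected pair table, sorted by ids.
#' @export
one_to_one_assign <- function(scored, threshold = 0, method = c("greedy", "exact")) {
  method <- match.arg(method)
  s <- as.data.table(scored)[score >= threshold]
  if (nrow(s) == 0L) return(empty_pairs(score = TRUE))
  setorder(s, -score, record_id_a, record_id_b)
  if (method == "greedy") {
    used_a <- character(0); used_b <- character(0)
    keep <- logical(nrow(s))
    ua <- new.env(hash = TRUE); ub <- new.env(hash = TRUE)
    for (i in seq_len(nrow(s))) {
      a <- s$record_id_a[i]; b <- s$record_id_b[i]
      if (is.null(ua[[a]]) && is.null(ub[[b]])) {
        keep[i] <- TRUE; ua[[a]] <- TRUE; ub[[b]] <- TRUE
      }
    }
    out <- s[keep]
  } else {
    out <- s[assign_exact_idx(s)]
  }
  setorder(out, record_id_a, record_id_b)
  out[]
}

# branch-and-bound exact maximum-total-score one-to-one assignment;
# returns selected row indices of `s` (rows pre-sorted descending by score)
assign_exact_idx <- function(s) {
  n <- nrow(s)
  if (n > 40L) stop_("exact assignment is a small-instance oracle (<= 40 pairs)")
  sc <- s$score
  suffix <- rev(cumsum(rev(pmax(sc, 0))))
  best <- list(total = -Inf, sel = integer(0))
  recurse <- function(i, used_a, used_b, total, sel) {
    if (total + (if (i <= n) suffix[i] else 0) <= best$total) return()
    if (i > n) {
      if (total > best$total) best <<- list(total = total, sel = sel)
      return()
    }
    a <- s$record_id_a[i]; b <- s$record_id_b[i]
    if (!(a %in% used_a) && !(b %in% used_b))
      recurse(i + 1L, c(used_a, a), c(used_b, b), total + sc[i], c(sel, i))
    recurse(i + 1L, used_a, used_b, total, sel)
  }
  recurse(1L, character(0), character(0), 0, integer(0))
  best$sel
}

#' End-to-end probabilistic linkage
#'
#' Composition block -> compare -> EM -> score -> classify. Comparison
#' fields must exclude the block fields (within a block they are constant
#' and carry no information, breaking EM identifiability). With
#' `one_to_one = TRUE` the thresholded pairs additionally pass through
#' greedy one-to-one assignment.
#'
#' @inheritParams match_by_rule
#' @param block,compare blocking and comparison field vectors (disjoint).
#' @param threshold score threshold (default 0).
#' @param one_to_one apply the one-to-one constraint (default `TRUE`).
#' @param set_semantics see [linkage_rule()].
#' @return a `linkage_result`; the fitted `fs_model` and candidate count
#'   are attached as `$model` and `$n_candidates`.
#' @export
probabilistic_link <- function(dsA, dsB, block, compare, threshold = 0,
                               one_to_one = TRUE, set_semantics = "intersect") {
  if (length(intersect(block, compare)))
    stop_("comparison fields must exclude block fields: %s",
          paste(intersect(block, compare), collapse = ", "))
  t0 <- Sys.time()
  pairs <- block_pairs(dsA, dsB, block, set_semantics)
  if (nrow(pairs) == 0L) {
    return(linkage_result(method = "probabilistic", pairs = empty_pairs(TRUE),
                          n_candidates = 0,
                          runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  vectors <- build_comparison_vectors(pairs, dsA, dsB, compare, set_semantics)
  model <- em_fit(vectors)
  scored <- score_pairs(vectors, model)
  matched <- if (one_to_one) one_to_one_assign(scored, threshold)
             else { m <- scored[score >= threshold]; setorder(m, record_id_a, record_id_b); m }
  res <- linkage_result(
    method = paste0("probabilistic:", paste(block, collapse = "+"),
                    if (one_to_one) ":1to1" else ":threshold"),
    pairs = matched, n_candidates = nrow(pairs),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res$model <- model
  res
}

#' Write the fitted model report
#'
#' Per-field m- and u-probabilities and the derived log2 weights, as a CSV.
#'
#' @param model an `fs_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(model, path) {
  stopifnot(inherits(model, "fs_model"))
  fwrite(data.table(field = model$fields, m_probability = model$m,
                    u_probability = model$u, w_agree = model$w_agree,
                    w_disagree = model$w_disagree, lambda = model$lambda),
         path, quote = FALSE)
  invisible(path)
}
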