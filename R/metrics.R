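# Confusion-matrix construction and performance metrics.
#
# The universe is the full cross product |A|x|B|; TN is derived
# arithmetically (universe - TP - FP - FN), never by enumeration. Rates
# whose denominator is zero (e.g. PPV with no predicted positives) are
# reported as flagged NA, never as 0 — a fake zero and a fake perfect score
# are equally misleading.

#' F1 score: harmonic mean of sensitivity and PPV
#'
#' `F1 = 2 * Sensitivity * PPV / (Sensitivity + PPV)`; 0 when sensitivity
#' is 0, `NA` when both inputs are undefined.
#'
#' @param sensitivity,ppv proportions in \[0, 1\] (or `NA` when undefined).
#' @return the F1 proportion.
#' @export
f1_score <- function(sensitivity, ppv) {
  if (is.na(sensitivity) && is.na(ppv)) return(NA_real_)
  s <- if (is.na(sensitivity)) 0 else sensitivity
  p <- if (is.na(ppv)) 0 else ppv
  if (s < 0 || s > 1 || p < 0 || p > 1)
    stop_("sensitivity and ppv must lie in [0, 1]")
  if (s + p == 0) return(0)
  2 * s * p / (s + p)
}

#' Wilson score interval for a binomial proportion
#'
#' Behaves at the 0/1 boundaries that perfect linkage produces: the lower
#' bound is exactly 0 at zero successes and the upper bound exactly 1 at
#' full success.
#'
#' @param successes,trials counts with `0 <= successes <= trials`.
#' @param level confidence level (default 0.95).
#' @return `c(lower, upper)`, or flagged `NA`s when `trials` is 0.
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials == 0) return(c(lower = NA_real_, upper = NA_real_))
  if (successes < 0 || successes > trials) stop_("need 0 <= successes <= trials")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Confusion metrics from raw counts
#'
#' `TN = universe - TP - FP - FN`. Sensitivity and PPV carry Wilson 95%
#' intervals.
#'
#' @param tp,fp,fn non-negative counts.
#' @param universe total number of comparison pairs, `>= tp + fp + fn`.
#' @return a `confusion_metrics` list: counts, proportions, CI bounds and
#'   undefined-rate flags.
#' @export
confusion_from_counts <- function(tp, fp, fn, universe) {
  if (min(tp, fp, fn) < 0) stop_("counts must be non-negative")
  tn <- universe - tp - fp - fn
  if (tn < 0) stop_("universe too small for the supplied counts")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(tp, tp + fn)
  ppv <- rate(tp, tp + fp)
  spec <- rate(tn, tn + fp)
  acc <- rate(tp + tn, universe)
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn, universe = universe,
    sensitivity = sens, specificity = spec, ppv = ppv, accuracy = acc,
    f1 = if (is.na(sens) && is.na(ppv)) NA_real_ else
      f1_score(if (is.na(sens)) 0 else sens, if (is.na(ppv)) 0 else ppv),
    ci_sensitivity = wilson_ci(tp, tp + fn),
    ci_ppv = if (tp + fp == 0) c(lower = NA_real_, upper = NA_real_)
             else wilson_ci(tp, tp + fp),
    undefined = c(sensitivity = is.na(sens), ppv = is.na(ppv),
                  specificity = is.na(spec))),
    class = "confusion_metrics")
}

#' Confusion metrics from declared and true pair sets
#'
#' `TP = |predicted intersect truth|`, `FP = |predicted \ truth|`,
#' `FN = |truth \ predicted|`, `TN` arithmetic.
#'
#' @param predicted declared matched pairs
#'   (`data.table(record_id_a, record_id_b)`).
#' @param truth truth links.
#' @param universe comparison-universe size, usually
#'   [validate_pair_universe()].
#' @return a `confusion_metrics` list.
#' @export
confusion_from_pairs <- function(predicted, truth, universe) {
  pred <- unique(as.data.table(predicted)[, .(record_id_a, record_id_b)])
  truth <- validate_truth(truth)
  pk <- pair_key(pred$record_id_a, pred$record_id_b)
  tk <- pair_key(truth$record_id_a, truth$record_id_b)
  tp <- sum(pk %in% tk)
  fp <- nrow(pred) - tp
  fn <- nrow(truth) - tp
  if (universe < length(union(pk, tk)))
    stop_("universe too small: it must cover all predicted and true pairs")
  confusion_from_counts(tp, fp, fn, universe)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> TP %s FP %s FN %s TN %s (universe %s)\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$fn, big.mark = ","), format(x$tn, big.mark = ","),
              format(x$universe, big.mark = ",")))
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("  sensitivity %s  PPV %s  specificity %s  accuracy %s  F1 %s\n",
              fmt(x$sensitivity), fmt(x$ppv), fmt(x$specificity),
              fmt(x$accuracy), fmt(x$f1)))
  invisible(x)
}

#' Tabulate simulation runs
#'
#' One column per run, metric rows in percent rounded half-up to two
#' decimals, plus the unweighted arithmetic mean F1 across runs as
#' attribute `"average_f1"`.
#'
#' @param runs list of `simulation_run` objects.
#' @return `data.table` with a `metric` column and one column per run.
#' @export
report_table <- function(runs) {
  if (length(runs) < 1L) stop_("at least one run is required")
  nm <- vapply(runs, function(r) r$method, "")
  nm <- make.unique(nm)
  tab <- data.table(metric = c("matched_pairs", "candidate_pairs", "accuracy",
                               "sensitivity", "specificity", "ppv", "f1"))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    m <- r$metrics
    col <- if (is.null(m)) rep(NA_real_, 7) else
      c(nrow(r$result$pairs), r$result$n_candidates, as_pct(m$accuracy),
        as_pct(m$sensitivity), as_pct(m$specificity), as_pct(m$ppv),
        as_pct(m$f1))
    set(tab, j = nm[i], value = col)
  }
  f1s <- vapply(runs, function(r)
    if (is.null(r$metrics)) NA_real_ else as_pct(r$metrics$f1), 0)
  setattr(tab, "average_f1", round_half_up(mean(f1s, na.rm = TRUE), 2))
  tab
}

#' Write a metrics CSV for a list of runs
#'
#' Columns: method, tp, fp, fn, tn, accuracy, sensitivity, specificity,
#' ppv, f1, Wilson CI bounds, runtime and matched-pair count; metrics in
#' percent at two decimals.
#'
#' @param runs list of `simulation_run` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(runs, path) {
  rows <- lapply(runs, function(r) {
    m <- r$metrics
    if (is.null(m))
      return(data.table(method = r$method, error = r$error %||% "failed"))
    data.table(
      method = r$method, tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
      accuracy = as_pct(m$accuracy), sensitivity = as_pct(m$sensitivity),
      specificity = as_pct(m$specificity), ppv = as_pct(m$ppv),
      f1 = as_pct(m$f1),
      ci_sens_lo = as_pct(m$ci_sensitivity[["lower"]]),
      ci_sens_hi = as_pct(m$ci_sensitivity[["upper"]]),
      ci_ppv_lo = as_pct(m$ci_ppv[["lower"]]),
      ci_ppv_hi = as_pct(m$ci_ppv[["upper"]]),
      runtime_s = r$result$runtime_s, matched_pairs = nrow(r$result$pairs))
  })
  fwrite(rbindlist(rows, fill = TRUE), path, quote = FALSE)
  invisible(path)
}
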