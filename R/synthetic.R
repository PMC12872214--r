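# Synthetic two-source MS cohort generator.
#
# Stands in for a hospital EHR extract (source A) and its deidentified
# registry representation (source B): B is a corrupted partial copy of A
# under fresh ids, so every true link is known. Category frequencies follow
# truncated geometric distributions whose skew is set per field, which is
# what makes coincidental agreement rates (u-probabilities) differ across
# fields — nationality dominated by one value is nearly uninformative, a
# date of birth nearly unique is highly informative.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the two-source MS cohort the package's experiments are
#' modelled on: 2642 records in source A with 2247 of them (85%)
#' represented in source B, an adult age distribution of mean 34.4 (SD 11)
#' years, a 2016--2023 observation window, a roughly 2:1 sex imbalance and
#' per-field categorical skew spanning near-uninformative (nationality,
#' one dominant value) to moderately informative (region, facility).
#' Corruption and missingness default to zero: the reference simulation
#' design is a clean clone.
#'
#' @param n_source_a number of records in source A (>= 2).
#' @param overlap_fraction fraction of A represented in B, in (0, 1].
#' @param n_b_only number of additional B-only records (no true link).
#' @param corruption named per-field corruption rates in \[0, 1\] (a single
#'   unnamed number is recycled to all linkage fields).
#' @param missingness named per-field rates at which B-side copies lose the
#'   value entirely (scalar fields become missing; set fields become empty).
#' @param categorical_levels named list: number of categories per
#'   categorical field (all >= 2).
#' @param categorical_skew named list: truncated-geometric ratio q per
#'   categorical field; q near 0 concentrates mass on one value, q = 1 is
#'   uniform.
#' @param mean_set_size named mean number of elements for the set-valued
#'   fields; actual sizes are 1 + Poisson(mean - 1), so every record has at
#'   least one event of each kind (the cohort is, by construction, a
#'   diagnosed and treated MS population).
#' @param age_mean,age_sd age distribution (years) used to draw DOBs.
#' @param study_start,study_end observation window for diagnosis and
#'   admission dates.
#' @param reference_date date at which ages are measured.
#' @param unique_profiles if `TRUE`, guarantee no two A records share all
#'   field values (duplicated profiles get their DOB redrawn).
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_source_a = 2642L,
                          overlap_fraction = 2247 / 2642,
                          n_b_only = 0L,
                          corruption = 0,
                          missingness = 0,
                          categorical_levels = list(
                            sex = 2L, nationality = 15L, region = 13L,
                            coverage = 5L, facility = 10L),
                          categorical_skew = list(
                            sex = 0.5, nationality = 0.026, region = 0.41,
                            coverage = 0.53, facility = 0.46),
                          mean_set_size = c(other_dx = 2.5, medications = 3,
                                            admissions = 3),
                          age_mean = 34.4, age_sd = 11,
                          study_start = as.Date("2016-01-01"),
                          study_end = as.Date("2023-12-31"),
                          reference_date = as.Date("2023-06-30"),
                          unique_profiles = TRUE,
                          seed = 1L) {
  fields <- names(linkage_fields())
  expand_rates <- function(r, what) {
    if (is.null(names(r)) && length(r) == 1L) r <- setNames(rep(r, length(fields)), fields)
    full <- setNames(rep(0, length(fields)), fields)
    bad <- setdiff(names(r), fields)
    if (length(bad)) stop_("%s rate for unknown field: %s", what, bad[1L])
    full[names(r)] <- r
    if (any(full < 0 | full > 1)) stop_("%s rates must lie in [0, 1]", what)
    full
  }
  cfg <- list(
    n_source_a = as.integer(n_source_a),
    overlap_fraction = overlap_fraction,
    n_b_only = as.integer(n_b_only),
    corruption = expand_rates(corruption, "corruption"),
    missingness = expand_rates(missingness, "missingness"),
    categorical_levels = categorical_levels,
    categorical_skew = categorical_skew,
    mean_set_size = mean_set_size,
    age_mean = age_mean, age_sd = age_sd,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    reference_date = as.Date(reference_date),
    unique_profiles = isTRUE(unique_profiles),
    seed = as.integer(seed))
  if (cfg$n_source_a < 2L) stop_("n_source_a must be >= 2")
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop_("overlap_fraction must lie in (0, 1]")
  if (any(unlist(categorical_levels) < 2L))
    stop_("categorical cardinalities must be >= 2")
  class(cfg) <- "cohort_config"
  cfg
}

# truncated geometric probabilities p_v proportional to q^(v-1), v = 1..k
tgeom_probs <- function(k, q) {
  if (q >= 1) return(rep(1 / k, k))
  if (q <= 0) q <- 1e-12
  p <- q^(seq_len(k) - 1)
  p / sum(p)
}

# value pools --------------------------------------------------------------

cat_levels <- function(field, k) {
  switch(field,
    sex = c("F", "M")[seq_len(k)],
    nationality = sprintf("NAT%02d", seq_len(k)),
    region = sprintf("REG%02d", seq_len(k)),
    coverage = sprintf("COV%d", seq_len(k)),
    facility = sprintf("FAC%02d", seq_len(k)),
    sprintf("%s%02d", toupper(field), seq_len(k)))
}

# skewed pools of ICD-10-like and medication codes shared by the cohort
icd_pool <- function() {
  chapters <- c("E", "G", "H", "I", "J", "K", "M", "N")
  sprintf("%s%02d.%d", rep(chapters, each = 25),
          rep(10:34, times = length(chapters)),
          rep(0:4, length.out = 200))
}
med_pool <- function() sprintf("MED%03d", 1:150)

sample_sets <- function(n, pool, mean_size, pool_skew = 0.97) {
  probs <- tgeom_probs(length(pool), pool_skew)
  sizes <- 1L + rpois(n, max(mean_size - 1, 0))
  lapply(sizes, function(s)
    canon_set(sample(pool, min(s, length(pool)), prob = probs)))
}

# A-side generation ---------------------------------------------------------

generate_source_a <- function(cfg) {
  n <- cfg$n_source_a
  rec <- data.table(record_id = sprintf("A%05d", seq_len(n)))
  for (f in CAT_FIELDS) {
    k <- cfg$categorical_levels[[f]]
    rec[, (f) := sample(cat_levels(f, k), n, replace = TRUE,
                        prob = tgeom_probs(k, cfg$categorical_skew[[f]]))]
  }
  age_days <- pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 1) * 365.25
  rec[, dob := cfg$reference_date - round(age_days)]
  window <- as.integer(cfg$study_end - cfg$study_start)
  rec[, ms_first_dx_date := cfg$study_start + sample.int(window + 1L, n, replace = TRUE) - 1L]
  adm_dates <- format(cfg$study_start + seq(0L, window, by = 1L), "%Y-%m-%d")
  rec[, other_dx := sample_sets(n, icd_pool(), cfg$mean_set_size[["other_dx"]])]
  rec[, medications := sample_sets(n, med_pool(), cfg$mean_set_size[["medications"]])]
  rec[, admissions := sample_sets(n, adm_dates, cfg$mean_set_size[["admissions"]],
                                  pool_skew = 1)]
  rec
}

profile_key <- function(rec) {
  keys <- lapply(names(linkage_fields()), function(f) {
    if (f %in% SET_FIELDS) vapply(rec[[f]], paste, "", collapse = ";")
    else as.character(rec[[f]])
  })
  do.call(paste, c(keys, sep = "\r"))
}

enforce_unique_profiles <- function(rec, cfg) {
  feasible <- prod(vapply(cfg$categorical_levels, as.numeric, 0)) *
    (as.numeric(cfg$reference_date - cfg$study_start))
  if (feasible < cfg$n_source_a)
    stop_(paste("cannot guarantee unique profiles for n = %d;",
                "increase the categorical cardinalities"), cfg$n_source_a)
  for (attempt in 1:100) {
    dup <- duplicated(profile_key(rec))
    if (!any(dup)) return(rec)
    # DOB is quasi-continuous, so redrawing it resolves clashes quickly
    n_dup <- sum(dup)
    age_days <- pmax(rnorm(n_dup, cfg$age_mean, cfg$age_sd), 1) * 365.25
    rec[dup, dob := cfg$reference_date - round(age_days)]
  }
  stop_("cannot guarantee unique profiles; increase the categorical cardinalities")
}

# corruption ---------------------------------------------------------------

#' Corrupt a copy of one record
#'
#' Applies a list of corruption operations to a single record, leaving all
#' untargeted fields identical. Operations: `set_missing` (scalar missing /
#' set emptied), `swap_category` (different category drawn from the field's
#' frequency distribution), `shift_date_days` (shift by `magnitude` days),
#' `drop_set_element`, `add_set_element`, `typo_edit` (one-character edit
#' on a string-valued field). Uses the RNG state in effect; callers that
#' need reproducibility seed beforehand. The record id may never be
#' targeted — ids are truth keys, not linkage fields.
#'
#' @param record one-row slice of an [ehr_dataset()] (a `data.table`).
#' @param corruptions list of `list(op =, field =, magnitude =)` entries.
#' @param config a [cohort_config()] supplying category frequencies.
#' @return the corrupted one-row `data.table`.
#' @export
corrupt_copy <- function(record, corruptions, config = cohort_config()) {
  rec <- copy(as.data.table(record))
  for (cr in corruptions) {
    f <- cr$field
    if (identical(f, "record_id"))
      stop_("corruption may not target record_id: ids are truth-only")
    if (!f %in% names(linkage_fields())) stop_("unknown field '%s'", f)
    type <- field_type(f)
    val <- rec[[f]]
    new <- switch(cr$op,
      set_missing = if (type == "set") list(character(0)) else
        if (type == "date") as.Date(NA) else NA_character_,
      swap_category = {
        if (type != "categorical") stop_("swap_category needs a categorical field")
        k <- config$categorical_levels[[f]]
        lev <- cat_levels(f, k)
        pr <- tgeom_probs(k, config$categorical_skew[[f]])
        keep <- is.na(val[[1]]) | lev != val[[1]]
        sample(lev[keep], 1L, prob = pr[keep])
      },
      shift_date_days = {
        if (type != "date") stop_("shift_date_days needs a date field")
        mag <- as.integer(cr$magnitude %||% sample(c(-30:-1, 1:30), 1L))
        if (mag == 0L) stop_("shift_date_days magnitude must be >= 1 day")
        val[[1]] + mag
      },
      drop_set_element = {
        s <- val[[1]]
        list(if (length(s) > 1L) canon_set(s[-sample.int(length(s), 1L)]) else s)
      },
      add_set_element = {
        s <- val[[1]]
        pool <- switch(f, other_dx = icd_pool(), medications = med_pool(),
                       admissions = format(config$study_start +
                         sample.int(as.integer(config$study_end - config$study_start) + 1L, 1L) - 1L,
                         "%Y-%m-%d"))
        list(canon_set(c(s, sample(setdiff(pool, s), 1L))))
      },
      typo_edit = {
        if (type != "categorical") stop_("typo_edit applies only to string-valued fields")
        v <- val[[1]]
        if (is.na(v) || !nzchar(v)) v else {
          i <- sample.int(nchar(v), 1L)
          substr(v, i, i) <- sample(c(LETTERS, 0:9), 1L)
          v
        }
      },
      stop_("unknown corruption op '%s'", cr$op))
    set(rec, j = f, value = new)
  }
  rec
}

# draw the stochastic corruption plan for one B-side copy
draw_corruptions <- function(cfg) {
  plan <- list()
  for (f in names(linkage_fields())) {
    u <- runif(1)
    if (u < cfg$missingness[[f]]) {
      plan[[length(plan) + 1L]] <- list(op = "set_missing", field = f)
    } else if (u < cfg$missingness[[f]] + cfg$corruption[[f]]) {
      op <- switch(field_type(f),
        categorical = list(op = "swap_category", field = f),
        date = list(op = "shift_date_days", field = f,
                    magnitude = sample(c(-30:-1, 1:30), 1L)),
        set = list(op = sample(c("drop_set_element", "add_set_element"), 1L),
                   field = f))
      plan[[length(plan) + 1L]] <- op
    }
  }
  plan
}

#' Generate a paired two-source cohort with known truth
#'
#' Source A is drawn from the configured distributions; source B contains a
#' corrupted copy (fresh ids) of a random `overlap_fraction` of A — the
#' truth links — plus optional B-only records. |B overlap| is
#' round-half-up of `overlap_fraction * |A|`. Each B copy gets its own
#' derived RNG stream, so reproducibility does not depend on iteration
#' order.
#'
#' @param config a [cohort_config()].
#' @return `list(A =, B =, truth =)` with two [ehr_dataset()]s and a
#'   truth-link `data.table`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, 1L))
  recA <- generate_source_a(cfg)
  if (cfg$unique_profiles) recA <- enforce_unique_profiles(recA, cfg)
  dsA <- ehr_dataset(recA, "A")

  n_overlap <- as.integer(floor(cfg$overlap_fraction * cfg$n_source_a + 0.5))
  set.seed(derive_seed(cfg$seed, 2L))
  idx <- sort(sample.int(cfg$n_source_a, n_overlap))

  b_rows <- vector("list", n_overlap + cfg$n_b_only)
  for (j in seq_len(n_overlap)) {
    set.seed(derive_seed(cfg$seed, 100L + idx[j]))
    plan <- draw_corruptions(cfg)
    row <- corrupt_copy(recA[idx[j]], plan, cfg)
    set(row, j = "record_id", value = sprintf("B%05d", j))
    b_rows[[j]] <- row
  }
  if (cfg$n_b_only > 0L) {
    set.seed(derive_seed(cfg$seed, 3L))
    extra <- generate_source_a(
      cohort_config(n_source_a = max(cfg$n_b_only, 2L),
                    categorical_levels = cfg$categorical_levels,
                    categorical_skew = cfg$categorical_skew,
                    mean_set_size = cfg$mean_set_size,
                    age_mean = cfg$age_mean, age_sd = cfg$age_sd,
                    study_start = cfg$study_start, study_end = cfg$study_end,
                    reference_date = cfg$reference_date,
                    unique_profiles = FALSE, seed = cfg$seed))
    extra <- extra[seq_len(cfg$n_b_only)]
    extra[, record_id := sprintf("B%05d", n_overlap + .I)]
    for (j in seq_len(cfg$n_b_only)) b_rows[[n_overlap + j]] <- extra[j]
  }
  recB <- rbindlist(b_rows)
  set.seed(derive_seed(cfg$seed, 4L))
  perm <- sample.int(nrow(recB))
  recB <- recB[perm]
  dsB <- ehr_dataset(recB, "B")
  truth <- data.table(record_id_a = recA$record_id[idx],
                      record_id_b = sprintf("B%05d", seq_len(n_overlap)))
  list(A = dsA, B = dsB, truth = validate_truth(truth))
}
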