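# Deterministic engine: hash-join matching equals the all-pairs oracle,
# missing never agrees, conjunctions only shrink the match set, and
# candidate counts from frequency tables equal enumerated pair counts.

test_that("single-field matching equals brute force on the sex toy", {
  A <- toy_dataset(record_id = c("a1", "a2", "a3"), sex = c("M", "M", "F"))
  B <- toy_dataset(record_id = c("b1", "b2", "b3"), sex = c("M", "F", "F"),
                   source = "B")
  res <- match_by_rule(A, B, "sex")
  expect_equal(nrow(res$pairs), 4L)  # 2*1 + 1*2
  expect_same_pairs(res$pairs, oracle_rule_pairs(A, B, "sex"))
})

test_that("a missing value in any rule field makes the pair a non-match", {
  A <- toy_dataset(record_id = c("a1", "a2"), dob = c("1990-01-01", "1991-02-02"))
  B <- toy_dataset(record_id = c("b1", "b2"), dob = c("1990-01-01", NA),
                   source = "B")
  res <- match_by_rule(A, B, "dob")
  expect_same_pairs(res$pairs, pairs_dt("a1", "b1"))
  # missing == missing never agrees
  A2 <- toy_dataset(record_id = "a1", nationality = NA_character_)
  B2 <- toy_dataset(record_id = "b1", nationality = NA_character_, source = "B")
  expect_equal(nrow(match_by_rule(A2, B2, "nationality")$pairs), 0L)
})

test_that("set-valued fields match on shared elements, or equality when configured", {
  A <- toy_dataset(record_id = c("a1", "a2"),
                   other_dx = c("G35;E11.9", "I10"))
  B <- toy_dataset(record_id = c("b1", "b2"),
                   other_dx = c("E11.9;K21", ""), source = "B")
  expect_same_pairs(match_by_rule(A, B, linkage_rule("other_dx"))$pairs,
                    pairs_dt("a1", "b1"))
  # two empty sets share no event and never match under intersection
  B2 <- toy_dataset(record_id = "b1", other_dx = "", source = "B")
  A2 <- toy_dataset(record_id = "a1", other_dx = "")
  expect_equal(nrow(match_by_rule(A2, B2, linkage_rule("other_dx"))$pairs), 0L)
  expect_equal(nrow(match_by_rule(A2, B2,
                                  linkage_rule("other_dx", "equal"))$pairs), 1L)
})

test_that("match_by_rule equals the all-pairs oracle on random cohorts", {
  rules <- list("sex", c("sex", "region"), "other_dx",
                c("dob", "medications"), c("coverage", "facility", "sex"))
  for (seed in c(4, 5)) {
    co <- generate_cohort(cohort_config(n_source_a = 50, seed = seed,
                                        corruption = 0.15, missingness = 0.1,
                                        overlap_fraction = 0.8))
    for (rule in rules) {
      got <- match_by_rule(co$A, co$B, linkage_rule(rule))$pairs
      expect_same_pairs(got, oracle_rule_pairs(co$A, co$B, rule))
    }
  }
})

test_that("conjunctions never enlarge the match set", {
  co <- generate_cohort(cohort_config(n_source_a = 80, seed = 6,
                                      corruption = 0.1, overlap_fraction = 0.9))
  chain <- list("region", c("region", "sex"), c("region", "sex", "coverage"),
                c("region", "sex", "coverage", "dob"))
  sizes <- vapply(chain, function(r) nrow(match_by_rule(co$A, co$B, r)$pairs), 0L)
  expect_true(all(diff(sizes) <= 0))
  # subset relation, not just counts
  p1 <- match_by_rule(co$A, co$B, chain[[1]])$pairs
  p2 <- match_by_rule(co$A, co$B, chain[[2]])$pairs
  expect_true(all(paste(p2$record_id_a, p2$record_id_b) %in%
                  paste(p1$record_id_a, p1$record_id_b)))
})

test_that("candidate_count matches products and enumeration", {
  A <- toy_dataset(record_id = c("a1", "a2", "a3"),
                   coverage = rep("COV1", 3))
  B <- toy_dataset(record_id = sprintf("b%d", 1:4),
                   coverage = rep("COV1", 4), source = "B")
  expect_equal(candidate_count(A, B, "coverage"), 12)
  B2 <- toy_dataset(record_id = "b1", coverage = "COV9", source = "B")
  expect_equal(candidate_count(A, B2, "coverage"), 0)
  co <- generate_cohort(cohort_config(n_source_a = 50, seed = 8,
                                      corruption = 0.1, overlap_fraction = 0.9))
  for (f in names(linkage_fields())) {
    expect_equal(candidate_count(co$A, co$B, f),
                 nrow(match_by_rule(co$A, co$B, linkage_rule(f))$pairs),
                 info = f)
  }
})

test_that("rules referencing unknown fields are rejected", {
  expect_error(linkage_rule("patient_name"), "unknown field")
  expect_error(linkage_rule(character(0)), "at least one field")
})

test_that("single-variable sweep equals brute-force confusion counts", {
  co <- generate_cohort(cohort_config(n_source_a = 30, seed = 9,
                                      corruption = 0.2, missingness = 0.1,
                                      overlap_fraction = 0.85))
  sweep <- single_variable_sweep(co$A, co$B, co$truth)
  universe <- nrow(co$A) * nrow(co$B)
  for (k in seq_len(nrow(sweep))) {
    f <- sweep$field[k]
    pred <- oracle_rule_pairs(co$A, co$B, f)
    oc <- oracle_confusion(pred, co$truth, universe)
    expect_equal(sweep$tp[k], oc$tp, info = f)
    expect_equal(sweep$fp[k], oc$fp, info = f)
    expect_equal(sweep$fn[k], oc$fn, info = f)
    expect_equal(sweep$tn[k], oc$tn, info = f)
  }
})

test_that("every single-field rule has sensitivity 1 on an uncorrupted clone", {
  sim <- make_clone_sim(60, seed = 10)
  sweep <- single_variable_sweep(sim$ds, sim$clone, sim$truth)
  expect_true(all(sweep$sensitivity == 100))
  expect_true(all(sweep$fn == 0L))
})
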