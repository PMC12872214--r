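# ML linkage: bounded similarity features, clean-clone separability for
# all four algorithm families, split arithmetic, permutation null,
# bootstrap behaviour and seeded reproducibility.

test_that("similarity features are bounded and exact on identical records", {
  A <- toy_dataset(record_id = c("a1", "a2"),
                   sex = c("F", "M"), dob = c("1990-01-01", "1990-01-02"),
                   other_dx = c("G35;E11", "G35;I10"))
  feats <- featurize_pairs(pairs_dt("a1", "a1"), A, A,
                           c("sex", "dob", "other_dx"))
  expect_true(all(feats$x == 1))
  f2 <- featurize_pairs(pairs_dt("a1", "a2"), A, A, c("dob", "other_dx"))
  expect_equal(unname(f2$x[1, "dob"]), 0.5)          # 1 / (1 + |1 day|)
  expect_equal(unname(f2$x[1, "other_dx"]), 1 / 3)   # Jaccard {G35,E11} vs {G35,I10}
  # empty vs empty sets are identical; empty vs non-empty fully dissimilar
  B <- toy_dataset(record_id = c("b1", "b2"), other_dx = c("", "G35"),
                   source = "B")
  f3 <- featurize_pairs(pairs_dt(c("b1", "b1"), c("b1", "b2")), B, B, "other_dx")
  expect_equal(as.numeric(f3$x), c(1, 0))
  # property: all features within [0, 1] on a corrupted cohort
  co <- generate_cohort(cohort_config(n_source_a = 60, seed = 24,
                                      corruption = 0.2, missingness = 0.1,
                                      overlap_fraction = 0.9))
  cand <- block_pairs(co$A, co$B, "sex")
  fx <- featurize_pairs(cand, co$A, co$B, names(linkage_fields()))
  expect_true(all(fx$x >= 0 & fx$x <= 1))
})

test_that("edit similarity is a normalized Levenshtein complement", {
  expect_equal(edit_similarity("kitten", "kitten"), 1)
  expect_equal(edit_similarity("abc", "abd"), 2 / 3)
  expect_equal(edit_similarity("abc", NA), 0)
})

test_that("every algorithm family separates a clean unique-profile clone", {
  sim <- make_clone_sim(120, seed = 25)
  # blocking on region keeps plenty of within-block non-matches among the
  # candidates while every truth pair still agrees on it
  for (algo in c("knn", "logistic", "neural_net", "random_forest")) {
    spec <- ml_spec(algo, "similarity_score", seed = 26)
    run <- similarity_score_link(sim$ds, sim$clone, sim$truth, spec,
                                 block_fields = "region")
    expect_equal(run$metrics$f1, 1, info = algo)
  }
})

test_that("classification split arithmetic is exact and metrics recount on the test share", {
  sim <- make_clone_sim(40, seed = 27)   # 1600 labelled pairs, all-pairs mode
  spec <- ml_spec("logistic", "classification", seed = 28)
  run <- classification_link(sim$ds, sim$clone, sim$truth, spec)
  split <- run$result$split
  expect_equal(length(split$train_y), 1200L)
  expect_equal(length(split$test_y), 400L)
  expect_equal(sum(split$test_y), 10L)   # stratified: 25% of the 40 matches
  # metrics equal a brute-force recount over the held-out share
  model_pred <- run$result$pairs
  oc <- oracle_confusion(model_pred,
                         pairs_dt(sim$truth$record_id_a, sim$truth$record_id_b),
                         400)
  expect_equal(run$metrics$tp, oc$tp)
  expect_equal(run$metrics$fp, oc$fp)
  expect_equal(run$metrics$f1, 1)
})

test_that("single-class training labels are a hard error", {
  sim <- make_clone_sim(15, seed = 29)
  feats <- featurize_pairs(sim$truth, sim$ds, sim$clone, c("sex", "region"),
                           sim$truth)
  expect_error(
    similarity_score_link(sim$ds, sim$clone,
                          truth = pairs_dt(character(0), character(0)),
                          spec = ml_spec("logistic"), block_fields = "dob"),
    "one-to-one|single-class")
})

test_that("randomly permuted labels destroy performance down to prevalence", {
  sim <- make_clone_sim(80, seed = 30)
  cand <- block_pairs(sim$ds, sim$clone, "region")
  feats <- featurize_pairs(cand, sim$ds, sim$clone,
                           c("sex", "nationality", "coverage", "facility",
                             "dob", "ms_first_dx_date"), sim$truth)
  set.seed(31)
  y_perm <- sample(feats$label)
  prev <- mean(y_perm)
  model <- linkehr:::fit_pair_model(feats$x, y_perm,
                                    ml_spec("logistic", seed = 32))
  pred <- linkehr:::predict_pair_model(model, feats$x) >= 0.5
  m <- linkehr:::label_confusion(pred, y_perm)
  f1 <- if (is.na(m$f1)) 0 else m$f1
  expect_lt(abs(f1 - prev), 0.2)
  expect_lt(f1, 0.5)
})

test_that("bootstrap collapses at B = 1 and is degenerate on separable data", {
  sim <- make_clone_sim(60, seed = 33)
  spec <- ml_spec("logistic", "classification", bootstrap = 1L, seed = 34)
  run <- classification_link(sim$ds, sim$clone, sim$truth, spec)
  s <- run$result$split
  b1 <- bootstrap_metrics(s$train_x, s$train_y, s$test_x, s$test_y, spec)
  expect_equal(unname(b1$ci["2.5%", ]), unname(b1$mean))
  expect_equal(unname(b1$ci["97.5%", ]), unname(b1$mean))
  spec20 <- ml_spec("logistic", "classification", bootstrap = 20L, seed = 34)
  b20 <- bootstrap_metrics(s$train_x, s$train_y, s$test_x, s$test_y, spec20)
  expect_equal(unname(b20$ci["2.5%", "f1"]), 1)
  expect_equal(unname(b20$ci["97.5%", "f1"]), 1)
})

test_that("seeded runs are reproducible end to end", {
  sim <- make_clone_sim(50, seed = 35, corruption = 0.1)
  for (algo in c("knn", "random_forest")) {
    spec <- ml_spec(algo, "similarity_score", seed = 36)
    r1 <- similarity_score_link(sim$ds, sim$clone, sim$truth, spec, "region")
    r2 <- similarity_score_link(sim$ds, sim$clone, sim$truth, spec, "region")
    expect_equal(as.data.frame(r1$result$pairs),
                 as.data.frame(r2$result$pairs), info = algo)
  }
})
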