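# Fellegi-Sunter engine: blocking counts, hand-computed comparison
# vectors, EM correctness (monotone likelihood, parameter recovery,
# separated-pattern fixed point), closed-form scores, and one-to-one
# assignment against the exhaustive oracle.

test_that("blocking returns exactly the agreeing pairs", {
  A <- toy_dataset(record_id = c("a1", "a2", "a3"),
                   dob = c("1990-01-01", "1990-01-01", "1992-02-02"))
  B <- toy_dataset(record_id = c("b1", "b2", "b3"),
                   dob = c("1990-01-01", "1992-02-02", "1992-02-02"),
                   source = "B")
  p <- block_pairs(A, B, "dob")
  expect_equal(nrow(p), 4L)  # 2*1 + 1*2
  expect_same_pairs(p, oracle_rule_pairs(A, B, "dob"))
  # blocking on two fields is a subset of either alone
  A$sex <- c("F", "M", "F"); B$sex <- c("F", "F", "M")
  p2 <- match_by_rule(A, B, c("dob", "sex"))$pairs
  expect_true(all(paste(p2$record_id_a, p2$record_id_b) %in%
                  paste(p$record_id_a, p$record_id_b)))
})

test_that("comparison vectors equal hand-computed agreement bits", {
  A <- toy_dataset(record_id = c("a1", "a2"),
                   sex = c("F", "M"), region = c("REG01", "REG02"),
                   nationality = c("NAT01", NA), other_dx = c("G35;I10", "E11.9"))
  B <- toy_dataset(record_id = c("b1", "b2"),
                   sex = c("F", "F"), region = c("REG09", "REG02"),
                   nationality = c("NAT01", "NAT02"), other_dx = c("I10", ""),
                   source = "B")
  pairs <- pairs_dt(c("a1", "a1", "a2", "a2", "a1"),
                    c("b1", "b2", "b1", "b2", "b1"))
  cv <- build_comparison_vectors(pairs[1:4], A, B,
                                 c("sex", "region", "nationality", "other_dx"))
  want <- rbind(c(1, 0, 1, 1),   # a1-b1: sex agree, region no, nat agree, dx share I10
                c(1, 0, 0, 0),   # a1-b2: NAT01 vs NAT02; empty dx set never agrees
                c(0, 0, 0, 0),   # a2-b1: missing nationality scores 0
                c(0, 1, 0, 0))   # a2-b2
  dimnames(want) <- list(NULL, c("sex", "region", "nationality", "other_dx"))
  expect_equal(cv$gamma, want)
  # identical records give an all-ones vector
  cv2 <- build_comparison_vectors(pairs_dt("a1", "a1"), A, A,
                                  c("sex", "region", "nationality", "other_dx"))
  expect_true(all(cv2$gamma == 1))
})

simulate_gamma <- function(N, K, lambda, m, u, seed) {
  set.seed(seed)
  z <- runif(N) < lambda
  g <- vapply(seq_len(K), function(k)
    ifelse(z, rbinom(N, 1, m), rbinom(N, 1, u)), numeric(N))
  colnames(g) <- paste0("f", seq_len(K))
  g
}

test_that("EM recovers generating m and u probabilities within 0.02", {
  g <- simulate_gamma(5000, 4, lambda = 0.1, m = 0.95, u = 0.05, seed = 2)
  fit <- em_fit(g)
  expect_true(all(abs(fit$m - 0.95) < 0.02))
  expect_true(all(abs(fit$u - 0.05) < 0.02))
  expect_lt(abs(fit$lambda - 0.1), 0.02)
})

test_that("perfectly separated patterns drive EM to its closed-form fixed point", {
  g <- rbind(matrix(1, 500, 4), matrix(0, 4500, 4))
  colnames(g) <- paste0("f", 1:4)
  fit <- em_fit(g)
  expect_lt(abs(fit$lambda - 0.1), 1e-3)
  expect_true(all(fit$m > 0.999))   # clamped toward 1
  expect_true(all(fit$u < 0.001))   # clamped toward 0
  expect_true(all(fit$w_agree > 0 & fit$w_disagree < 0))
})

test_that("EM log-likelihood is non-decreasing on arbitrary inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- matrix(rbinom(200 * 3, 1, runif(1, 0.2, 0.8)), ncol = 3)
    if (length(unique(apply(g, 1, paste, collapse = ""))) < 2L) next
    fit <- suppressWarnings(em_fit(g))  # slow boundary drift may hit the cap
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("degenerate comparison data is a hard error", {
  g <- matrix(1, 50, 3)
  expect_error(em_fit(g), "degenerate")
})

test_that("scores are summed log2 likelihood-ratio weights", {
  model <- structure(list(fields = "f1", m = c(f1 = 0.9), u = c(f1 = 0.1),
                          lambda = 0.5,
                          w_agree = c(f1 = log2(9)),
                          w_disagree = c(f1 = log2(1 / 9)),
                          n_iter = 1L, converged = TRUE, loglik = 0,
                          loglik_trace = 0), class = "fs_model")
  cv <- structure(list(pairs = pairs_dt(c("a1", "a2"), c("b1", "b2")),
                       gamma = matrix(c(1L, 0L), ncol = 1,
                                      dimnames = list(NULL, "f1")),
                       fields = "f1"), class = "comparison_vectors")
  s <- score_pairs(cv, model)
  expect_equal(s$score, c(log2(9), -log2(9)), tolerance = 1e-12)
  # an uninformative model scores every vector 0
  model0 <- model
  model0$u <- c(f1 = 0.9)
  model0$w_agree <- c(f1 = 0); model0$w_disagree <- c(f1 = 0)
  expect_equal(score_pairs(cv, model0)$score, c(0, 0))
})

test_that("greedy one-to-one assignment follows the stated selection order", {
  scored <- pairs_dt(c("a1", "a1", "a2"), c("b1", "b2", "b2"), c(5, 4, 3))
  got <- one_to_one_assign(scored, threshold = 0)
  expect_same_pairs(got, pairs_dt(c("a1", "a2"), c("b1", "b2")))
  # record-disjoint pairs are all selected
  disj <- pairs_dt(c("a1", "a2", "a3"), c("b1", "b2", "b3"), c(1, 2, 3))
  expect_equal(nrow(one_to_one_assign(disj, 0)), 3L)
  # below threshold -> empty
  expect_equal(nrow(one_to_one_assign(pairs_dt("a1", "b1", -1), 0)), 0L)
})

test_that("greedy equals the exhaustive oracle when the truth pair dominates", {
  # linkage-style instances: diagonal (truth) scores strictly dominate
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:6, 1)
    cand <- CJ(i = 1:n, j = 1:n)[runif(n * n) < 0.6 | i == j]
    sc <- ifelse(cand$i == cand$j, runif(nrow(cand), 5, 10),
                 runif(nrow(cand), -3, 3))
    scored <- pairs_dt(sprintf("a%d", cand$i), sprintf("b%d", cand$j), sc)
    greedy <- one_to_one_assign(scored, threshold = 0)
    exact <- one_to_one_assign(scored, threshold = 0, method = "exact")
    expect_equal(sum(greedy$score), sum(exact$score), tolerance = 1e-9)
    expect_equal(sum(greedy$score),
                 oracle_best_assignment(scored[score >= 0]), tolerance = 1e-9)
  }
})

test_that("with arbitrary scores the greedy deficit is bounded and reported", {
  # greedy maximum-weight matching is a 1/2-approximation; on adversarial
  # score patterns it can fall short of the exhaustive optimum
  deficits <- numeric(0)
  for (seed in 1:15) {
    set.seed(100 + seed)
    n <- sample(3:5, 1)
    cand <- CJ(i = 1:n, j = 1:n)
    scored <- pairs_dt(sprintf("a%d", cand$i), sprintf("b%d", cand$j),
                       runif(nrow(cand), 0, 10))
    greedy_total <- sum(one_to_one_assign(scored, 0)$score)
    best_total <- oracle_best_assignment(scored)
    expect_gte(greedy_total + 1e-9, best_total / 2)
    deficits <- c(deficits, best_total - greedy_total)
  }
  expect_true(all(deficits >= -1e-9))
})

test_that("threshold classification is a superset of one-to-one at the same threshold", {
  sim <- make_clone_sim(150, seed = 13, corruption = 0.1)
  # low match prevalence within sex blocks: EM may drift slowly near the
  # probability clamp and report its iteration cap — expected here
  all_m <- suppressWarnings(
    probabilistic_link(sim$ds, sim$clone, block = "sex",
                       compare = c("dob", "nationality", "region",
                                   "coverage", "facility"),
                       threshold = 0, one_to_one = FALSE))
  oto <- suppressWarnings(
    probabilistic_link(sim$ds, sim$clone, block = "sex",
                       compare = c("dob", "nationality", "region",
                                   "coverage", "facility"),
                       threshold = 0, one_to_one = TRUE))
  expect_true(all(paste(oto$pairs$record_id_a, oto$pairs$record_id_b) %in%
                  paste(all_m$pairs$record_id_a, all_m$pairs$record_id_b)))
})

test_that("end-to-end probabilistic linkage is exact on a clean unique-profile clone", {
  sim <- make_clone_sim(250, seed = 14)
  res <- probabilistic_link(sim$ds, sim$clone, block = "dob",
                            compare = c("sex", "nationality", "coverage",
                                        "facility", "region",
                                        "ms_first_dx_date"))
  m <- confusion_from_pairs(res$pairs, sim$truth,
                            validate_pair_universe(sim$ds, sim$clone))
  expect_equal(m$f1, 1)
  # determinism: EM has no randomness given fixed inputs
  res2 <- probabilistic_link(sim$ds, sim$clone, block = "dob",
                             compare = c("sex", "nationality", "coverage",
                                         "facility", "region",
                                         "ms_first_dx_date"))
  expect_equal(as.data.frame(res$pairs), as.data.frame(res2$pairs))
  # +Inf threshold empties the result
  res3 <- probabilistic_link(sim$ds, sim$clone, block = "dob",
                             compare = c("sex", "region"), threshold = Inf)
  expect_equal(nrow(res3$pairs), 0L)
})

test_that("comparison fields overlapping block fields are rejected", {
  sim <- make_clone_sim(20, seed = 15)
  expect_error(probabilistic_link(sim$ds, sim$clone, block = "dob",
                                  compare = c("dob", "sex")),
               "exclude block fields")
})
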