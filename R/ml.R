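# Machine-learning linkage.
#
# Candidate pairs are turned into similarity features in [0,1]: exact
# agreement for categorical fields, 1/(1+|days|) proximity for dates,
# Jaccard index for set-valued fields (two empty sets are identical and
# score 1). Two modes mirror two study designs: (a) similarity-score
# linkage — block, featurize, train on the labelled candidates, declare the
# predicted positives as matches over the full universe; (b) pair
# classification — label a candidate pair set, split 75/25 stratified by
# label, train on 75% and report metrics on the held-out 25%. Four
# families: k-nearest neighbours, logistic regression, a single-hidden-
# layer neural network, random forest.

#' Normalized edit similarity between two strings
#'
#' `1 - levenshtein(a, b) / max(nchar)`; `NA` input gives 0. Available for
#' string-valued fields; the default record schema's categoricals use exact
#' agreement instead.
#'
#' @param a,b character vectors (recycled).
#' @return similarity in \[0, 1\].
#' @export
edit_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  d <- mapply(function(x, y) {
    if (is.na(x) || is.na(y)) NA_real_ else as.numeric(adist(x, y))
  }, a, b)
  mx <- pmax(nchar(a), nchar(b))
  sim <- ifelse(is.na(d), 0, ifelse(mx == 0, 1, 1 - d / mx))
  unname(pmin(pmax(sim, 0), 1))
}

jaccard_sets <- function(a, b) {
  mapply(function(x, y) {
    la <- length(x); lb <- length(y)
    if (la == 0L && lb == 0L) return(1)
    if (la == 0L || lb == 0L) return(0)
    i <- length(intersect(x, y))
    i / (la + lb - i)
  }, a, b)
}

#' Similarity features for candidate pairs
#'
#' @inheritParams match_by_rule
#' @param pairs candidate pairs `data.table(record_id_a, record_id_b)`.
#' @param fields fields to featurize.
#' @param truth optional truth links; when given, a logical `match` label
#'   is attached.
#' @return a `pair_features` object: the pair table, feature matrix `x`
#'   (one column per field, all values in \[0, 1\]) and optional labels.
#' @export
featurize_pairs <- function(pairs, dsA, dsB, fields, truth = NULL) {
  ia <- match(pairs$record_id_a, dsA$record_id)
  ib <- match(pairs$record_id_b, dsB$record_id)
  if (anyNA(ia) || anyNA(ib)) stop_("pairs reference unknown record ids")
  x <- matrix(0, nrow = nrow(pairs), ncol = length(fields),
              dimnames = list(NULL, fields))
  for (f in fields) {
    type <- field_type(f)
    x[, f] <- switch(type,
      categorical = {
        a <- dsA[[f]][ia]; b <- dsB[[f]][ib]
        as.numeric(!is.na(a) & !is.na(b) & a == b)
      },
      date = {
        a <- dsA[[f]][ia]; b <- dsB[[f]][ib]
        dd <- abs(as.numeric(a) - as.numeric(b))
        ifelse(is.na(dd), 0, 1 / (1 + dd))
      },
      set = jaccard_sets(dsA[[f]][ia], dsB[[f]][ib]))
  }
  label <- NULL
  if (!is.null(truth)) {
    truth <- validate_truth(truth)
    label <- pair_key(pairs$record_id_a, pairs$record_id_b) %in%
      pair_key(truth$record_id_a, truth$record_id_b)
  }
  structure(list(pairs = as.data.table(pairs)[, .(record_id_a, record_id_b)],
                 x = x, label = label, fields = fields),
            class = "pair_features")
}

#' Specification of one ML linkage run
#'
#' Defaults are conventional small-data settings: knn k = 5; L2-regularized
#' logistic regression; one hidden layer of 32 rectifier-free (logistic)
#' units trained for at most 500 epochs; 100-tree random forest. Features
#' are standardized for the scale-sensitive families (knn, logistic,
#' neural net) but not for the forest.
#'
#' @param algorithm one of `"knn"`, `"logistic"`, `"neural_net"`,
#'   `"random_forest"`.
#' @param mode `"similarity_score"` or `"classification"`.
#' @param train_fraction training share of the labelled pairs, in (0, 1).
#' @param bootstrap bootstrap replications (>= 1).
#' @param seed integer seed for splitting, sampling and model fitting.
#' @param knn_k,nn_size,nn_maxit,rf_ntree,logit_decay hyperparameters.
#' @param impact_floor minimum single-feature F1 (threshold 0.5) a field
#'   must reach on the training labels to enter the similarity-score model.
#' @param nonmatch_ratio non-matches sampled per match when the
#'   classification candidate universe is capped (cohorts > 500 records).
#' @return an `ml_spec` list.
#' @export
ml_spec <- function(algorithm = c("knn", "logistic", "neural_net", "random_forest"),
                    mode = c("similarity_score", "classification"),
                    train_fraction = 0.75, bootstrap = 100L, seed = 1L,
                    knn_k = 5L, nn_size = 32L, nn_maxit = 500L,
                    rf_ntree = 100L, logit_decay = 1e-4,
                    impact_floor = 0.2, nonmatch_ratio = 10) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_("train_fraction must lie in (0, 1)")
  if (bootstrap < 1L) stop_("bootstrap replications must be >= 1")
  structure(list(algorithm = algorithm, mode = mode,
                 train_fraction = train_fraction,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 knn_k = knn_k, nn_size = nn_size, nn_maxit = nn_maxit,
                 rf_ntree = rf_ntree, logit_decay = logit_decay,
                 impact_floor = impact_floor, nonmatch_ratio = nonmatch_ratio),
            class = "ml_spec")
}

# fit one pair classifier; x numeric matrix, y logical (TRUE = match)
fit_pair_model <- function(x, y, spec) {
  if (length(unique(y)) < 2L)
    stop_("single-class training labels: cannot fit a pair classifier")
  scaled <- spec$algorithm %in% c("knn", "logistic", "neural_net")
  centre <- scl <- NULL
  if (scaled) {
    centre <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    x <- scale(x, center = centre, scale = scl)
  }
  set.seed(spec$seed)
  fit <- switch(spec$algorithm,
    knn = list(train = x, cl = y),   # lazy learner: store the training set
    logistic = suppressWarnings(
      glm.fit(cbind(1, x), y, family = binomial())),
    neural_net = nnet::nnet(x, matrix(as.numeric(y), ncol = 1),
                            size = spec$nn_size, maxit = spec$nn_maxit,
                            decay = 1e-4, entropy = TRUE, trace = FALSE,
                            MaxNWts = 20000L),
    random_forest = randomForest::randomForest(
      x, factor(y, levels = c(FALSE, TRUE)), ntree = spec$rf_ntree))
  structure(list(spec = spec, fit = fit, centre = centre, scale = scl),
            class = "pair_model")
}

# predicted match probability for new pairs
predict_pair_model <- function(model, x) {
  spec <- model$spec
  if (!is.null(model$centre))
    x <- scale(x, center = model$centre, scale = model$scale)
  switch(spec$algorithm,
    knn = {
      set.seed(spec$seed)
      k <- min(spec$knn_k, nrow(model$fit$train))
      pred <- class::knn(model$fit$train, x,
                         factor(model$fit$cl, levels = c(FALSE, TRUE)),
                         k = k, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "TRUE", pr, 1 - pr)
    },
    logistic = {
      eta <- as.numeric(cbind(1, x) %*% model$fit$coefficients)
      1 / (1 + exp(-eta))
    },
    neural_net = as.numeric(predict(model$fit, x)),
    random_forest = predict(model$fit, x, type = "prob")[, "TRUE"])
}

# single-feature F1 at threshold 0.5 against the labels
feature_impact <- function(x, y) {
  apply(x, 2L, function(v) {
    pred <- v >= 0.5
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    s <- if (tp + fn == 0) 0 else tp / (tp + fn)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1_score(s, p)
  })
}

label_confusion <- function(pred, y, universe = length(y)) {
  confusion_from_counts(tp = sum(pred & y), fp = sum(pred & !y),
                        fn = sum(!pred & y), universe = universe)
}

#' Similarity-score ML linkage
#'
#' Block, featurize, keep the fields whose individual discriminative
#' contribution (single-feature F1 at threshold 0.5) passes
#' `spec$impact_floor`, train on the labelled candidates and declare the
#' predicted positives (probability >= 0.5) as matches; metrics are scored
#' over the full |A|x|B| universe.
#'
#' @inheritParams match_by_rule
#' @param truth truth links (simulation mode requires them for training).
#' @param spec an [ml_spec()].
#' @param block_fields blocking fields for candidate generation.
#' @param fields fields to featurize (default: all except block fields).
#' @return a `simulation_run`; the selected fields and the fitted model are
#'   attached to `$result`.
#' @export
similarity_score_link <- function(dsA, dsB, truth, spec, block_fields,
                                  fields = setdiff(names(linkage_fields()),
                                                   block_fields)) {
  stopifnot(inherits(spec, "ml_spec"))
  t0 <- Sys.time()
  pairs <- block_pairs(dsA, dsB, block_fields)
  feats <- featurize_pairs(pairs, dsA, dsB, fields, truth)
  if (length(unique(feats$label)) < 2L)
    stop_("single-class training labels within the blocked candidates")
  impact <- feature_impact(feats$x, feats$label)
  keep <- names(impact)[impact > spec$impact_floor]
  if (length(keep) == 0L) {
    warning("no field passed the impact floor; keeping all fields",
            call. = FALSE)
    keep <- feats$fields
  }
  model <- fit_pair_model(feats$x[, keep, drop = FALSE], feats$label, spec)
  prob <- predict_pair_model(model, feats$x[, keep, drop = FALSE])
  matched <- feats$pairs[prob >= 0.5]
  matched[, score := prob[prob >= 0.5]]
  setorder(matched, record_id_a, record_id_b)
  res <- linkage_result(
    method = paste0("ml-score:", spec$algorithm), pairs = matched,
    n_candidates = nrow(pairs),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res$selected_fields <- keep
  res$impact <- impact
  res$model <- model
  structure(list(method = res$method, result = res,
                 metrics = confusion_from_pairs(matched, truth,
                                                validate_pair_universe(dsA, dsB)),
                 error = NULL),
            class = "simulation_run")
}

# candidate pairs for classification mode: the full cross product for
# small cohorts, otherwise blocked candidates + truth + sampled non-matches
classification_candidates <- function(dsA, dsB, truth, spec, block_fields) {
  n_a <- nrow(dsA); n_b <- nrow(dsB)
  if (n_a <= 500L && n_b <= 500L) {
    return(CJ(record_id_a = dsA$record_id, record_id_b = dsB$record_id))
  }
  if (is.null(block_fields))
    stop_("cohorts > 500 records need block_fields for classification mode")
  cand <- block_pairs(dsA, dsB, block_fields)
  cand <- unique(rbind(cand, truth[, .(record_id_a, record_id_b)]))
  tk <- pair_key(truth$record_id_a, truth$record_id_b)
  is_match <- pair_key(cand$record_id_a, cand$record_id_b) %in% tk
  n_target <- ceiling(spec$nonmatch_ratio * sum(is_match))
  nonmatch <- cand[!is_match]
  set.seed(derive_seed(spec$seed, 11L))
  if (nrow(nonmatch) > n_target) {
    nonmatch <- nonmatch[sample.int(nrow(nonmatch), n_target)]
  } else {
    # top up with random non-truth pairs from the full universe
    need <- n_target - nrow(nonmatch)
    extra <- data.table(
      record_id_a = sample(dsA$record_id, 2L * need, replace = TRUE),
      record_id_b = sample(dsB$record_id, 2L * need, replace = TRUE))
    extra <- unique(extra)[!pair_key(record_id_a, record_id_b) %in%
                             c(tk, pair_key(nonmatch$record_id_a,
                                            nonmatch$record_id_b))]
    nonmatch <- rbind(nonmatch, utils::head(extra, need))
  }
  rbind(cand[is_match], nonmatch)
}

#' Classification-based ML linkage with a 75/25 split
#'
#' Labels a candidate pair set from truth, splits it stratified by label
#' into training (default 75%) and held-out test (25%) partitions with the
#' spec seed, trains the classifier on the training share and reports
#' confusion metrics on the untouched test share. For cohorts up to 500
#' records per side the candidate set is all |A|x|B| pairs; larger cohorts
#' use blocked candidates plus truth plus non-matches sampled at
#' `spec$nonmatch_ratio` per match.
#'
#' @inheritParams similarity_score_link
#' @param block_fields blocking fields (required above 500 records).
#' @param fields fields to featurize.
#' @return a `simulation_run` whose metrics are computed on the test
#'   partition; `$result$split` carries the train/test features for
#'   [bootstrap_metrics()].
#' @export
classification_link <- function(dsA, dsB, truth, spec, block_fields = NULL,
                                fields = setdiff(names(linkage_fields()),
                                                 block_fields %||% character(0))) {
  stopifnot(inherits(spec, "ml_spec"))
  truth <- validate_truth(truth)
  t0 <- Sys.time()
  cand <- classification_candidates(dsA, dsB, truth, spec, block_fields)
  feats <- featurize_pairs(cand, dsA, dsB, fields, truth)
  y <- feats$label
  set.seed(derive_seed(spec$seed, 12L))
  test_idx <- logical(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    n_test <- round(length(idx) * (1 - spec$train_fraction))
    test_idx[sample(idx, n_test)] <- TRUE
  }
  if (sum(y[test_idx]) == 0L)
    stop_("test split contains zero matches: increase cohort or change seed")
  train_x <- feats$x[!test_idx, , drop = FALSE]
  train_y <- y[!test_idx]
  test_x <- feats$x[test_idx, , drop = FALSE]
  test_y <- y[test_idx]
  model <- fit_pair_model(train_x, train_y, spec)
  pred <- predict_pair_model(model, test_x) >= 0.5
  metrics <- label_confusion(pred, test_y)
  matched <- feats$pairs[which(test_idx)[pred]]
  setorder(matched, record_id_a, record_id_b)
  res <- linkage_result(
    method = paste0("ml-classify:", spec$algorithm), pairs = matched,
    n_candidates = nrow(cand),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res$split <- list(train_x = train_x, train_y = train_y,
                    test_x = test_x, test_y = test_y)
  res$model <- model
  structure(list(method = res$method, result = res, metrics = metrics,
                 error = NULL),
            class = "simulation_run")
}

#' Bootstrap performance estimates over training resamples
#'
#' Resamples the training pairs with replacement `B` times, refits the
#' classifier and re-evaluates on the fixed test partition. Resamples
#' missing a class are redrawn (count reported). Returns the mean and the
#' 2.5/97.5 percentile interval of sensitivity, PPV and F1.
#'
#' @param train_x,train_y training features and logical labels.
#' @param test_x,test_y fixed held-out test features and labels.
#' @param spec an [ml_spec()]; `spec$bootstrap` sets B.
#' @param seed seed for the resampling stream.
#' @return list with `mean`, `ci` (2 x metric matrix), per-replication
#'   `replicates` table and the `redraws` count.
#' @export
bootstrap_metrics <- function(train_x, train_y, test_x, test_y, spec,
                              seed = spec$seed) {
  B <- spec$bootstrap
  n <- length(train_y)
  reps <- matrix(NA_real_, nrow = B, ncol = 3,
                 dimnames = list(NULL, c("sensitivity", "ppv", "f1")))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      set.seed(derive_seed(seed, 1000L + b + 7919L * redraws))
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(train_y[idx])) == 2L) break
      redraws <- redraws + 1L
      if (redraws > 100L * B) stop_("bootstrap cannot draw two-class resamples")
    }
    fit <- fit_pair_model(train_x[idx, , drop = FALSE], train_y[idx], spec)
    pred <- predict_pair_model(fit, test_x) >= 0.5
    m <- label_confusion(pred, test_y)
    reps[b, ] <- c(m$sensitivity, m$ppv, m$f1)
  }
  list(mean = colMeans(reps, na.rm = TRUE),
       ci = apply(reps, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
                  names = TRUE),
       replicates = as.data.table(reps), redraws = redraws)
}
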