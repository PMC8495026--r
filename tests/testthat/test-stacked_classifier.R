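dummy_meta <- function(n, p_female = 0.5, seed = 1) {
  set.seed(seed)
  data.frame(record_id = sprintf("r%05d", seq_len(n)),
             sex = sample(c("female", "male"), n, TRUE,
                          prob = c(p_female, 1 - p_female)),
             age = sample(2:94, n, TRUE),
             stringsAsFactors = FALSE)
}

test_that("stratified folds balance sizes overall and within strata", {
  meta <- dummy_meta(20, seed = 3)
  meta$sex <- rep(c("female", "male"), 10)
  meta$age <- rep(30, 20)
  fa <- stratified_folds(meta, 10, seed = 5)
  expect_equal(fa$fold_sizes, rep(2L, 10))
  tab <- table(meta$sex, fa$assignment$fold)
  expect_true(all(tab == 1))

  big <- dummy_meta(437, seed = 4)
  fb <- stratified_folds(big, 10, seed = 9)
  expect_lte(diff(range(fb$fold_sizes)), 1)
  cell <- table(fb$assignment$stratum, fb$assignment$fold)
  expect_lte(max(apply(cell, 1, function(z) diff(range(z)))), 1)

  expect_identical(stratified_folds(big, 10, seed = 9)$assignment,
                   fb$assignment)
  expect_error(stratified_folds(dummy_meta(5), 10), "exceeds")
})

test_that("k-NN posteriors are neighbour fractions with index tie-breaks", {
  set.seed(2)
  train <- matrix(rnorm(40 * 6), 40, 6)
  fem <- rep(c(TRUE, FALSE), 20)
  q <- matrix(rnorm(6), 1, 6)
  d <- sqrt(colSums((t(train) - as.numeric(q))^2))
  nb <- order(d)[1:20]
  expect_equal(knn_posterior(train, fem, q, k = 20), mean(fem[nb]))
  # query equal to a training row, k = 1
  expect_equal(knn_posterior(train, fem, train[3, ], k = 1), as.numeric(fem[3]))
  # k = train size: the global prevalence
  expect_equal(knn_posterior(train, fem, q, k = 40), mean(fem))
  expect_error(knn_posterior(train, fem, q, k = 41), "k must be")
  expect_error(knn_posterior(train, fem, matrix(0, 1, 5), k = 2), "mismatch")

  # exact distance ties resolved toward the lower training index
  tr <- rbind(c(1, 0), c(-1, 0), c(1, 0))
  expect_equal(knn_posterior(tr, c(TRUE, TRUE, FALSE), c(0, 0), k = 2), 1)
})

test_that("k-NN labels agree with an independent implementation", {
  skip_if_not_installed("class")
  set.seed(6)
  train <- matrix(rnorm(60 * 5), 60, 5)
  fem <- rnorm(60) + train[, 1] > 0
  q <- matrix(rnorm(25 * 5), 25, 5)
  p <- knn_posterior(train, fem, q, k = 7)
  ref <- class::knn(train, q, factor(fem), k = 7, prob = TRUE)
  ref_p <- ifelse(ref == "TRUE", attr(ref, "prob"), 1 - attr(ref, "prob"))
  expect_equal(p, unname(ref_p), tolerance = 1e-12)
})

test_that("stack feature assembly enforces the canonical layout", {
  leads <- c("I", "II", "III", "aVR", "aVL", "aVF",
             "V1", "V2", "V3", "V4", "V5", "V6")
  keys <- posterior_keys(leads)
  expect_length(keys, 720)
  expect_length(posterior_keys("II"), 60)
  set.seed(1)
  post <- matrix(runif(3 * 720), 3, 720, dimnames = list(NULL, sample(keys)))
  subj <- build_stack_features(post, "subject", leads = leads)
  expect_identical(colnames(subj), keys)
  lead_ft <- build_stack_features(post, "lead", lead = "V2")
  expect_length(colnames(lead_ft), 60)
  expect_true(all(startsWith(colnames(lead_ft), "V2|")))
  # permuting insertion order leaves the output identical
  perm <- sample(720)
  expect_identical(build_stack_features(post[, perm], "subject",
                                        leads = leads), subj)
  expect_error(build_stack_features(post[, -1], "subject", leads = leads),
               "missing posterior")
  bad <- post; bad[1, 1] <- 1.5
  expect_error(build_stack_features(bad, "subject", leads = leads),
               "outside")
})

test_that("the stacker separates separable clusters deterministically", {
  set.seed(12)
  x <- rbind(matrix(rnorm(60 * 8, 0), 60, 8), matrix(rnorm(60 * 8, 2.5), 60, 8))
  y <- rep(c(FALSE, TRUE), each = 60)
  st <- train_stacker(x, y, seed = 7)
  expect_equal(mean((predict_stacker(st, x) > 0.5) == y), 1)
  st2 <- train_stacker(x, y, seed = 7)
  expect_identical(predict_stacker(st2, x), predict_stacker(st, x))
  expect_error(train_stacker(x, rep(TRUE, 120), seed = 1), "both classes")
})

test_that("the stacker matches a reference single-hidden-layer fit", {
  skip_if_not_installed("nnet")
  set.seed(30)
  x <- rbind(matrix(rnorm(40 * 4, 0), 40, 4), matrix(rnorm(40 * 4, 3), 40, 4))
  y <- rep(c(FALSE, TRUE), each = 40)
  ours <- predict_stacker(train_stacker(x, y, seed = 2, size = 5), x)
  ref <- nnet::nnet(x = x, y = as.numeric(y), size = 5, decay = 1e-3,
                    entropy = TRUE, maxit = 200, trace = FALSE)
  refp <- as.numeric(stats::predict(ref, x))
  expect_equal((ours > 0.5), (refp > 0.5))
})

test_that("score categories follow the published thresholds", {
  expect_equal(as.character(categorize_score(0.95)), "strong female")
  expect_equal(as.character(categorize_score(0.50)), "indeterminate")
  expect_equal(as.character(categorize_score(0.05)), "strong male")
  # boundary values fall to the less extreme category
  expect_equal(as.character(categorize_score(c(0.1, 0.35, 0.65, 0.9))),
               c("mid male", "indeterminate", "indeterminate", "mid female"))
  expect_error(categorize_score(1.2), "\\[0, 1\\]")
})

test_that("evaluation metrics are consistent with the confusion counts", {
  rep1 <- evaluate_scores(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$sensitivity, 100)
  expect_equal(rep1$specificity, 100)

  male_only <- evaluate_scores(rep(0.49, 5), rep(FALSE, 5))
  expect_equal(male_only$specificity, 100)
  expect_true(is.na(male_only$sensitivity))
  expect_true(is.na(male_only$auc))

  set.seed(14)
  rand <- evaluate_scores(runif(1000), rep(c(TRUE, FALSE), 500))
  expect_equal(rand$auc, 0.5, tolerance = 0.05)
  expect_error(evaluate_scores(numeric(0), logical(0)), "no scores")
})

test_that("our AUC equals the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  sc <- runif(200)
  y <- rnorm(200) + 2 * sc > 1
  ours <- roc_auc(sc, y)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("nested cross-validation recovers class structure without leakage", {
  ft <- small_cohort_features()
  fa <- stratified_folds(ft$meta, 4, seed = 2)
  cv <- nested_cross_validate(ft, fa, k = 3, seed = 3)
  expect_gt(cv$report$accuracy, 85)
  audit <- audit_leakage(cv)
  expect_true(audit$clean)
  expect_equal(nrow(audit$violations), 0)
  # every record is scored exactly once, in its own fold
  expect_false(anyNA(cv$scores$score))
  expect_identical(cv$scores$fold,
                   fold <- fa$assignment$fold[match(cv$scores$record_id,
                                                    fa$assignment$record_id)])
  # a doctored provenance log (test record also used for training) is flagged
  leaked_id <- cv$provenance$record_id[cv$provenance$run == 1 &
                                         cv$provenance$role == "test"][1]
  bad <- rbind(cv$provenance,
               data.frame(run = 1, record_id = leaked_id,
                          role = "base_train"))
  expect_false(audit_leakage(bad)$clean)
})

test_that("classification accuracy grows with the class separation", {
  acc_at <- function(sep) {
    co <- synthesize_cohort(30, 0.5, seed = 555, separation = sep)
    ft <- cohort_features(co, leads = c("II", "V3"),
                          planes = enumerate_planes(c(3, 5)))
    fa <- stratified_folds(ft$meta, 3, seed = 555)
    nested_cross_validate(ft, fa, k = 3, seed = 555,
                          lead_level = FALSE)$report$accuracy
  }
  accs <- vapply(c(0.15, 0.6, 1.0), acc_at, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("the master model scores an unseen cohort in the right direction", {
  ft <- small_cohort_features()
  mm <- train_master_model(ft, k = 3, seed = 5, val_frac = 0.25)
  unseen <- synthesize_cohort(8, 0.5, seed = 404)
  uft <- cohort_features(unseen, leads = c("II", "V3"),
                         planes = enumerate_planes(c(3, 5)))
  sc <- score_cohort(mm, uft)
  expect_equal(nrow(sc), 8)
  truth <- uft$meta$sex == "female"
  expect_gte(mean((sc$score > 0.5) == truth), 0.75)
})
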