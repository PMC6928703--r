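# The two-level rigor classifier: splitting, base learners, boosting,
# voting and evaluation metrics.

# linearly separable toy problem
toy_xy <- function(n = 60, seed = 3) {
  withr::with_seed(seed, {
    y <- rep(c("rigor", "nonrigor"), each = n / 2)
    x1 <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))
    x2 <- rnorm(n)
    list(x = cbind(x1, x2), y = y)
  })
}

test_that("stratified split preserves proportions and the 0.7 default", {
  corpus <- make_synthetic_corpus(
    corpus_spec(n_articles = 100, rigor_fraction = 0.6, seed = 21))
  parts <- split_corpus(corpus, ratio = 0.7, seed = 21)
  expect_equal(nrow(parts$train), 70L)
  tab <- table(parts$train$label)
  expect_lte(abs(tab[["rigor"]] - 42), 1)
  expect_lte(abs(tab[["nonrigor"]] - 28), 1)

  # 0.7 is the default ratio
  expect_equal(nrow(split_corpus(corpus, seed = 21)$train), 70L)
  expect_equal(formals(split_corpus)$ratio, 0.7)

  # determinism
  a <- split_corpus(corpus, seed = 5); b <- split_corpus(corpus, seed = 5)
  expect_identical(a$train$article_id, b$train$article_id)

  single <- corpus; single$label <- "rigor"
  expect_error(split_corpus(single), class = "ebm_validation_error")
})

test_that("every base learner fits and scores probabilities on a toy", {
  toy <- toy_xy()
  for (kind in c("naive_bayes", "decision_tree", "logistic_regression",
                 "glm", "random_forest", "gradient_boosted_trees",
                 "deep_mlp")) {
    fit <- train_base(kind, toy$x, toy$y, seed = 1)
    p <- predict_prob(fit, toy$x)
    expect_length(p, nrow(toy$x))
    expect_true(all(p >= 0 & p <= 1), info = kind)
    expect_gt(mean((p >= 0.5) == (toy$y == "rigor")), 0.9)
  }
  expect_error(train_base("svm_rbf", toy$x, toy$y),
               class = "ebm_config_error")
  expect_error(train_base("deep_mlp", toy$x[0, , drop = FALSE], character(0)),
               class = "ebm_validation_error")
})

test_that("gradient boosted trees separate a separable toy perfectly", {
  toy <- toy_xy()
  fit <- train_base("gradient_boosted_trees", toy$x, toy$y, seed = 1)
  expect_equal(mean((predict_prob(fit, toy$x) >= 0.5) ==
                      (toy$y == "rigor")), 1.0)
})

test_that("the GLM beats the no-information rate on the synthetic corpus", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 2000, seed = 13))
  parts <- split_corpus(corpus, seed = 13)
  tr <- vectorize_corpus(parts$train)
  te <- vectorize_corpus(parts$test, vocabulary = tr$vocabulary)
  fit <- train_base("glm", tr$matrix, parts$train$label, seed = 13)
  acc <- evaluate(fit, te$matrix, parts$test$label)$accuracy
  nir <- max(table(parts$test$label)) / nrow(parts$test)
  expect_gt(acc, nir)
})

test_that("one boosting round reproduces the single base learner", {
  bench <- medium_bench()
  base <- train_base("gradient_boosted_trees", bench$train$matrix,
                     bench$parts$train$label, seed = 11)
  ada1 <- train_adaboost("gradient_boosted_trees", bench$train$matrix,
                         bench$parts$train$label, rounds = 1, seed = 11)
  expect_equal(predict_prob(ada1, bench$test$matrix),
               predict_prob(base, bench$test$matrix), tolerance = 1e-12)
  expect_error(train_adaboost("gradient_boosted_trees", bench$train$matrix,
                              bench$parts$train$label, rounds = 0))
})

test_that("boosting GBT is not worse than plain GBT (paired seeds)", {
  diffs <- vapply(1:5, function(s) {
    bench <- medium_bench(seed = s)
    y <- bench$parts$train$label
    gbt <- train_base("gradient_boosted_trees", bench$train$matrix, y,
                      seed = s)
    ada <- train_adaboost("gradient_boosted_trees", bench$train$matrix, y,
                          rounds = 50, seed = s)
    evaluate(ada, bench$test$matrix, bench$parts$test$label)$accuracy -
      evaluate(gbt, bench$test$matrix, bench$parts$test$label)$accuracy
  }, numeric(1))
  expect_gte(mean(diffs), -0.02)
})

test_that("boosting lifts an underfit perceptron (paired seeds)", {
  weak <- list(hidden = c(4L, 2L), epochs = 10L, lr = 0.1)
  diffs <- vapply(1:5, function(s) {
    bench <- medium_bench(seed = s)
    y <- bench$parts$train$label
    mlp <- train_base("deep_mlp", bench$train$matrix, y, seed = s,
                      params = weak)
    ada <- train_adaboost("deep_mlp", bench$train$matrix, y, rounds = 15,
                          seed = s, params = weak)
    evaluate(ada, bench$test$matrix, bench$parts$test$label)$accuracy -
      evaluate(mlp, bench$test$matrix, bench$parts$test$label)$accuracy
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("the voting ensemble reproduces member consensus", {
  toy <- toy_xy()
  eq <- train_eqrm(toy$x, toy$y,
                   eqrm_spec(stack_members = c("glm", "logistic_regression"),
                             seed = 1))
  mp <- predict_members(eq, toy$x)
  agree <- (mp[, 1] >= 0.5) == (mp[, 2] >= 0.5)
  expect_true(all(agree))   # separable toy: members agree everywhere
  ens <- predict_prob(eq, toy$x) >= 0.5
  expect_equal(ens, mp[, 1] >= 0.5)

  expect_error(train_eqrm(toy$x, toy$y,
                          eqrm_spec(stack_members = "glm")),
               class = "ebm_config_error")
  expect_error(eqrm_spec(stack_members = c("glm", "nonsense")),
               class = "ebm_config_error")
})

test_that("the ensemble is at least as good as members minus vote slack", {
  bench <- medium_bench(seed = 2)
  y <- bench$parts$train$label
  eq <- train_eqrm(bench$train$matrix, y, eqrm_spec(seed = 2))
  acc_ens <- evaluate(eq, bench$test$matrix, bench$parts$test$label)$accuracy
  for (m in names(eq$members)) {
    acc_m <- evaluate(eq$members[[m]], bench$test$matrix,
                      bench$parts$test$label)$accuracy
    expect_gte(acc_ens, acc_m - 0.02)
  }
})

test_that("the stacking combiner fits and scores", {
  bench <- medium_bench(seed = 2)
  eq <- train_eqrm(bench$train$matrix, bench$parts$train$label,
                   eqrm_spec(combiner = "stack", seed = 2))
  rep <- evaluate(eq, bench$test$matrix, bench$parts$test$label)
  expect_gt(rep$accuracy, 0.7)
})

test_that("evaluation metrics match their closed forms", {
  # perfect classifier
  perfect <- eval_report_from_probs(c(0.9, 0.9, 0.1, 0.1),
                                    c("rigor", "rigor", "nonrigor",
                                      "nonrigor"))
  expect_equal(perfect$f_measure, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0L)

  # constant classifier on a balanced set: chance accuracy and AUC
  const <- eval_report_from_probs(rep(0.7, 10),
                                  rep(c("rigor", "nonrigor"), 5))
  expect_equal(const$accuracy, 0.5)
  expect_equal(const$auc, 0.5)

  # hand-built confusion TP=8 FP=2 FN=2 TN=8
  probs <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  labs <- c(rep("rigor", 10), rep("nonrigor", 10))
  rep1 <- eval_report_from_probs(probs, labs)
  expect_equal(rep1$confusion["rigor", "rigor"], 8L)
  expect_equal(rep1$precision, 0.8)
  expect_equal(rep1$f_measure, 0.8)
  expect_equal(rep1$accuracy, 0.8)

  # one-class test set: AUC absent, rest computed
  oneclass <- eval_report_from_probs(c(0.9, 0.2), c("rigor", "rigor"))
  expect_true(is.na(oneclass$auc))
  expect_equal(oneclass$accuracy, 0.5)
})

test_that("rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    probs <- runif(200)
    labs <- ifelse(runif(200) < plogis(3 * (probs - 0.5)), "rigor",
                   "nonrigor")
  })
  got <- eval_report_from_probs(probs, labs)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labs, levels = c("nonrigor", "rigor")),
    predictor = probs, quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("training and evaluation are bit-stable under a fixed seed", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 120, seed = 31))
  b1 <- eqrm_train(corpus, eqrm_spec(seed = 31, rounds = 5))
  b2 <- eqrm_train(corpus, eqrm_spec(seed = 31, rounds = 5))
  expect_identical(glance(b1), glance(b2))
  probe <- make_demo_articles()
  expect_identical(eqrm_classify(b1, probe)$rigor_prob,
                   eqrm_classify(b2, probe)$rigor_prob)
})

test_that("a saved bundle classifies identically after reload", {
  corpus <- make_synthetic_corpus(corpus_spec(n_articles = 120, seed = 17))
  bundle <- eqrm_train(corpus, eqrm_spec(seed = 17, rounds = 5))
  path <- withr::local_tempfile(fileext = ".rds")
  eqrm_save(bundle, path)
  back <- eqrm_load(path)
  probe <- make_demo_articles()
  expect_equal(eqrm_classify(back, probe)$rigor_prob,
               eqrm_classify(bundle, probe)$rigor_prob, tolerance = 1e-12)
})

test_that("association-free shuffles keep counts but kill association", {
  y <- rep(c("rigor", "nonrigor"), c(40, 60))
  s <- shuffle_labels(y, seed = 3)
  expect_equal(as.vector(table(s)), as.vector(table(y)))
  tab <- table(s, y)
  expect_equal(tab["rigor", "rigor"] / 40, tab["rigor", "nonrigor"] / 60)
})

test_that("tidiers expose metrics in broom shapes", {
  repo <- eval_report_from_probs(c(0.9, 0.1), c("rigor", "nonrigor"))
  td <- tidy(repo)
  expect_equal(nrow(td), 5L)
  gl <- glance(repo)
  expect_equal(gl$tp + gl$fp + gl$fn + gl$tn, gl$n_test)
})
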