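test_that("rank-sum AUC equals pairwise counting with half-weight ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "Both classes")
  withr::with_seed(8, {
    for (i in 1:40) {
      n <- sample(10:50, 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties guaranteed
      expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("the rank-sum AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    labels <- rbinom(80, 1, 0.5)
    labels[1:2] <- c(0, 1)
    scores <- round(runif(80), 2)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("ROC curve points trace from (0,0) to (1,1) monotonically", {
  withr::with_seed(10, {
    r <- roc_auc(runif(60), rbinom(60, 1, 0.5))
  })
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("score bands follow the reporting thresholds with closed lower edges", {
  expect_identical(categorize(c(0.60, 0.45, 0.30)),
                   c("positive-high", "positive-low", "negative-high"))
  # boundary semantics: 0.5 and 0.4 both belong to positive-low
  expect_identical(categorize(c(0.5, 0.4, 0.399999, 0.500001)),
                   c("positive-low", "positive-low", "negative-high",
                     "positive-high"))
  expect_error(categorize(1.2), "0, 1")
})

test_that("training cross-validates with a full partition per repeat", {
  fx <- strong_features()
  m <- ep_train(fx$features, "antigen", n_trees = 120, seed = 3,
                freq_model = fx$fm)
  oof <- m$cv$oof
  # each record scored exactly once per repeat
  counts <- table(oof$id, oof$repeat_)
  expect_true(all(counts == 1))
  expect_equal(sort(unique(oof$fold)), 1:5)
  expect_equal(nrow(m$cv$auc_by_fold), 15)
  expect_true(all(m$cv$oof$score >= 0 & m$cv$oof$score <= 1))
  # strongly separated synthetic data is learned well
  expect_gt(m$cv$auc, 0.85)
  # metadata
  expect_identical(m$mtry, 15L)
  g <- glance(m)
  expect_identical(g$mode, "antigen")
  expect_equal(g$cv_auc, m$cv$auc)
})

test_that("training is reproducible under a fixed seed and guards its inputs", {
  fx <- strong_features()
  m1 <- ep_train(fx$features, "antigen", n_trees = 60, seed = 42)
  m2 <- ep_train(fx$features, "antigen", n_trees = 60, seed = 42)
  expect_identical(m1$cv$oof, m2$cv$oof)
  expect_equal(m1$cv$auc, m2$cv$auc)
  p1 <- predict(m1, fx$features)
  p2 <- predict(m2, fx$features)
  expect_identical(p1, p2)

  tiny <- fx$features[1:10, ]
  expect_error(ep_train(tiny, "antigen"), "at least 25")
  unl <- fx$features
  unl$label <- NULL
  expect_error(ep_train(unl, "antigen"), "label")
})

test_that("prediction enforces the bundle's feature schema and flags ranks", {
  fx <- strong_features()
  m <- ep_train(fx$features, "antigen", n_trees = 60, seed = 2,
                freq_model = fx$fm)
  preds <- predict(m, fx$features)
  expect_named(preds, c("id", "score", "category", "rank_warning"))
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_identical(preds$category, categorize(preds$score))
  expect_identical(preds$rank_warning, fx$features$C24 >= 2)

  broken <- fx$features[, setdiff(names(fx$features), "C22")]
  expect_error(predict(m, broken), "Missing: C22")
  extra <- fx$features
  extra$C27 <- 1
  expect_error(predict(m, extra), "Unexpected: C27")
})
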