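# confusion metrics, grid search, the balanced CV protocol, Welch
# comparison, holdout evaluation and prediction

test_that("confusion metrics match the closed-form and oracle values", {
  expect_equal(confusion_metrics(10, 0, 10, 0),
               c(acc = 100, sn = 100, sp = 100, mcc = 100))
  expect_equal(confusion_metrics(5, 5, 5, 5)[["mcc"]], 0)
  m <- confusion_metrics(8, 2, 7, 3)
  expect_equal(m[["acc"]], 75)
  expect_equal(m[["sn"]], 80)
  expect_equal(m[["sp"]], 70)
  expect_equal(m[["mcc"]], 100 * 50 / sqrt(9900))
  expect_error(confusion_metrics(0, 0, 5, 5), "at least one")

  # 1000 random tables against the independent phi-coefficient oracle
  set.seed(19)
  for (i in 1:1000) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    tn <- sample(0:30, 1); fp <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    expect_equal(confusion_metrics(tp, fn, tn, fp),
                 oracle_metrics(tp, fn, tn, fp), tolerance = 1e-12)
  }
})

test_that("grid search picks the best point with deterministic tie-breaks", {
  set.seed(23)
  # linearly separable toy data
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
  y <- rep(c("negative", "positive"), each = 30)
  gs <- grid_search_train(x, y, svm_config(cost = c(1, 10), gamma = c(0.1, 1),
                                           tuning_folds = 3), seed = 1)
  expect_equal(as.character(predict(gs$fit, x)), y)
  gs2 <- grid_search_train(x, y, svm_config(cost = c(1, 10), gamma = c(0.1, 1),
                                            tuning_folds = 3), seed = 1)
  expect_equal(gs$cost, gs2$cost)
  expect_equal(gs$gamma, gs2$gamma)
  # single grid point is taken as-is
  gs1 <- grid_search_train(x, y, svm_config(cost = 4, gamma = 0.25))
  expect_equal(gs1$cost, 4)
  expect_equal(gs1$gamma, 0.25)
  # perfectly tied grid (separable at every point) resolves to the smallest
  # cost, then the smallest gamma
  gs3 <- grid_search_train(x, y, svm_config(cost = c(1, 100),
                                            gamma = c(0.05, 0.5),
                                            tuning_folds = 3), seed = 1)
  expect_equal(gs3$cost, 1)
  expect_equal(gs3$gamma, 0.05)
  expect_error(grid_search_train(matrix(1, 20, 3), y[1:20], fast_svm()),
               "degenerate")
})

test_that("cross-validation is reproducible and aggregates over negative sets", {
  spec <- synthetic_spec(n_positive = 60, n_negative = 240)
  corp <- generate_fragments(spec, seed = 29)
  res <- cross_validate(corp, mask = preset_mask("IG9"),
                        n_negative_sets = 3, folds = 3,
                        config = fast_svm(), seed = 5)
  expect_s3_class(res, "evaluation_result")
  expect_equal(nrow(res$per_fold), 9)
  expect_equal(nrow(res$per_set), 3)
  expect_equal(res$aggregate$metric, c("acc", "sn", "sp", "mcc"))
  # aggregate = mean +/- sd over the per-set fold means
  expect_equal(res$aggregate$mean[res$aggregate$metric == "mcc"],
               mean(res$per_set$mcc))
  expect_equal(res$aggregate$sd[res$aggregate$metric == "acc"],
               sd(res$per_set$acc))
  expect_equal(res$per_set$acc,
               vapply(split(res$per_fold$acc, res$per_fold$set), mean,
                      numeric(1), USE.NAMES = FALSE))

  res2 <- cross_validate(corp, mask = preset_mask("IG9"),
                         n_negative_sets = 3, folds = 3,
                         config = fast_svm(), seed = 5)
  expect_identical(res$per_fold, res2$per_fold)
})

test_that("label-permuted data scores near chance", {
  spec <- synthetic_spec(n_positive = 80, n_negative = 80,
                         motif = motif_spec(p_enrich = 0.05))
  corp <- generate_fragments(spec, seed = 37)
  res <- cross_validate(corp, mask = preset_mask("IG9"), n_negative_sets = 2,
                        folds = 4, config = fast_svm(), seed = 3)
  acc <- res$aggregate$mean[res$aggregate$metric == "acc"]
  mcc <- res$aggregate$mean[res$aggregate$metric == "mcc"]
  expect_gt(acc, 30); expect_lt(acc, 70)
  expect_gt(mcc, -30); expect_lt(mcc, 30)
})

test_that("the training-fold KNN reference leaks nothing from the test fold", {
  spec <- synthetic_spec(n_positive = 40, n_negative = 40)
  corp <- generate_fragments(spec, seed = 41)
  train <- corpus_subset(corp, 1:60)
  test <- corpus_subset(corp, 61:80)
  # query fragments only ever look at the reference, never at each other:
  # encoding a test batch and a sub-batch against the same training
  # reference gives identical rows
  x_te <- assemble_features(test, reference = train, blocks = "KNN")
  x_te_sub <- assemble_features(corpus_subset(test, 1:5), reference = train,
                                blocks = "KNN")
  expect_equal(x_te[1:5, , drop = FALSE], x_te_sub, ignore_attr = TRUE)
  # and changing held-out fragments cannot move training-fold features,
  # because those are encoded against the training fold alone
  x_tr <- assemble_features(train, reference = train, blocks = "KNN")
  mutated <- as.data.frame(test)
  mutated$fragment <- rev(mutated$fragment)
  x_tr2 <- assemble_features(train, reference = train, blocks = "KNN")
  expect_identical(x_tr, x_tr2)

  # within cross_validate every fold records a reference of training size
  res <- cross_validate(corp, mask = preset_mask("IG9"), n_negative_sets = 2,
                        folds = 4, config = fast_svm(), seed = 9)
  expect_true(all(res$per_fold$knn_ref_size == 60))
})

test_that("compare_mcc implements Welch with sane degenerate limits", {
  expect_equal(compare_mcc(c(60, 60, 60), c(60, 60, 60)),
               list(statistic = 0, p_value = 1, df = NA_real_,
                    mean_a = 60, mean_b = 60))
  set.seed(43)
  a <- 60 + rnorm(5, sd = 0.1)
  b <- 40 + rnorm(5, sd = 0.1)
  cmp <- compare_mcc(a, b)
  expect_lt(cmp$p_value, 1e-4)
  # agrees with stats::t.test directly
  ht <- t.test(a, b, var.equal = FALSE)
  expect_equal(cmp$statistic, unname(ht$statistic))
  expect_equal(cmp$p_value, ht$p.value)
  cmp_p <- compare_mcc(a, b, paired = TRUE)
  expect_equal(cmp_p$p_value, t.test(a, b, paired = TRUE)$p.value)
  expect_error(compare_mcc(60, c(40, 41)), "at least two")
})

test_that("training, prediction and holdout evaluation are consistent", {
  spec <- synthetic_spec(n_positive = 80, n_negative = 80,
                         motif = motif_spec(p_enrich = 0.6))
  corp <- generate_fragments(spec, seed = 47)
  model <- train_model(corp, mask = preset_mask("IG9"), config = fast_svm(),
                       seed = 1)
  pred <- predict(model, corp)
  expect_named(pred, c("protein_id", "position", "score", "label"))
  expect_true(all((pred$score > 0) == (pred$label == "positive")))
  # training accuracy is high for a strongly planted motif
  expect_gt(mean(pred$label == corp$label), 0.9)
  # determinism
  expect_identical(pred, predict(model, corp))

  # fresh data from the same generator: performance comparable to training
  hold <- generate_fragments(spec, seed = 48)
  hold <- fragment_corpus(transform(as.data.frame(hold),
                                    protein_id = sub("SYNP", "HOLD",
                                                     protein_id)),
                          window = corpus_window(hold))
  ev <- evaluate_holdout(model, hold)
  expect_gt(ev$aggregate$mean[ev$aggregate$metric == "acc"], 75)

  # disjointness guard and its explicit override
  expect_error(evaluate_holdout(model, corp), "shares")
  ev_train <- evaluate_holdout(model, corp, check_disjoint = FALSE)
  expect_gte(ev_train$aggregate$mean[1], ev$aggregate$mean[1] - 5)

  # window mismatch is a clear error
  w5 <- window_spec(2, 2)
  small <- make_corpus(c("AAKAA"), "positive", w5)
  expect_error(predict(model, small), "window length")
  expect_error(evaluate_holdout(model, corpus_subset(corp, FALSE)), "empty")
})
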