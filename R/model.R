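# RBF-SVM training and the balanced multi-negative-set cross-validation
# protocol, with Acc/Sn/Sp/MCC reporting and Welch comparison of MCC.

#' SVM hyperparameter search configuration
#'
#' RBF kernel throughout; the grids default to the customary coarse
#' powers-of-two search (`C` in `2^-5..2^15`, `gamma` in `2^-15..2^3`, both
#' in x4 steps). A single-point grid skips the inner search entirely.
#'
#' @param cost Candidate values for the penalty parameter `C`.
#' @param gamma Candidate values for the RBF kernel width.
#' @param tuning_folds Inner CV folds used by the grid search (default 5).
#' @return An `svm_config` object.
#' @export
svm_config <- function(cost = 2^seq(-5, 15, by = 2),
                       gamma = 2^seq(-15, 3, by = 2),
                       tuning_folds = 5L) {
  if (!length(cost) || !length(gamma) || any(cost <= 0) || any(gamma <= 0))
    .stopf("`cost` and `gamma` grids must be non-empty and positive")
  structure(list(cost = sort(cost), gamma = sort(gamma),
                 tuning_folds = .assert_scalar_count(tuning_folds,
                                                     "tuning_folds")),
            class = "svm_config")
}

#' Confusion-matrix performance metrics
#'
#' Accuracy, sensitivity (true positive rate), specificity (true negative
#' rate) and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, all
#' reported in percent. MCC is defined as 0 whenever a denominator factor
#' vanishes.
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return Named numeric vector `c(acc, sn, sp, mcc)`, in percent.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) .stopf("confusion counts must be >= 0")
  if (tp + fn == 0 || tn + fp == 0)
    .stopf("need at least one positive and one negative")
  tp <- as.numeric(tp); fn <- as.numeric(fn)
  tn <- as.numeric(tn); fp <- as.numeric(fp)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  c(acc = 100 * (tp + tn) / (tp + tn + fp + fn),
    sn = 100 * tp / (tp + fn),
    sp = 100 * tn / (tn + fp),
    mcc = 100 * mcc)
}

# fit one RBF-SVM (x already encoded; scale=FALSE because all feature blocks
# are constructed in [0, 1])
.fit_svm <- function(x, y, cost, gamma, scale = FALSE) {
  e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
             scale = scale, type = "C-classification")
}

# decision scores oriented so that > 0 means "positive"
.decision_scores <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1L]
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (first != "positive") s <- -s
  list(label = as.character(pr), score = unname(s))
}

#' Grid-search training of the RBF-SVM
#'
#' Evaluates every `(C, gamma)` grid point by stratified inner
#' cross-validation accuracy on the supplied training features, picks the
#' best point (ties resolved toward smaller `C`, then smaller `gamma`), and
#' refits on all the data.
#'
#' @param x Numeric feature matrix.
#' @param y Labels (`"positive"`/`"negative"`), or a factor thereof.
#' @param config An [svm_config()].
#' @param seed Integer seed for the inner fold split.
#' @param scale Standardize features inside the SVM (default `FALSE`: all
#'   encoder blocks already lie in `[0, 1]`).
#' @return List with elements `fit` (the e1071 model), `cost`, `gamma`,
#'   `tuning_accuracy`.
#' @export
grid_search_train <- function(x, y, config = svm_config(), seed = NULL,
                              scale = FALSE) {
  y <- factor(as.character(y), levels = c("negative", "positive"))
  if (any(is.na(y))) .stopf("labels must be 'positive' or 'negative'")
  if (all(apply(x, 2L, function(col) length(unique(col)) == 1L)))
    .stopf("degenerate features: every column is constant")
  if (length(unique(y)) < 2L)
    warning("single-class training data", call. = FALSE)
  else if (abs(sum(y == "positive") - sum(y == "negative")) > 0.1 * length(y))
    warning("training labels are noticeably unbalanced", call. = FALSE)
  grid <- expand.grid(gamma = config$gamma, cost = config$cost)[, 2:1]
  if (nrow(grid) == 1L) {
    best <- c(cost = grid$cost[1L], gamma = grid$gamma[1L])
    best_acc <- NA_real_
  } else {
    fold_of <- with_seed(seed,
                         .stratified_folds(as.character(y),
                                           config$tuning_folds))
    best <- NULL; best_acc <- -Inf
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(config$tuning_folds)) {
        te <- fold_of == f
        fit <- .fit_svm(x[!te, , drop = FALSE], y[!te],
                        grid$cost[g], grid$gamma[g], scale)
        correct <- correct + sum(predict(fit, x[te, , drop = FALSE]) == y[te])
      }
      acc <- correct / length(y)
      if (acc > best_acc) {  # strict: earlier (smaller C, then gamma) wins ties
        best_acc <- acc
        best <- c(cost = grid$cost[g], gamma = grid$gamma[g])
      }
    }
  }
  list(fit = .fit_svm(x, y, best[["cost"]], best[["gamma"]], scale),
       cost = best[["cost"]], gamma = best[["gamma"]],
       tuning_accuracy = best_acc)
}

#' Train a position-specific acetylation-site model
#'
#' Encodes the corpus (which also serves as the KNN reference), grid-search
#' tunes the RBF-SVM, and refits on all data. The returned model carries
#' everything prediction needs: the fitted SVM, the mask, the feature
#' layout, the KNN reference corpus, the similarity matrix, the property
#' index and the seed.
#'
#' @param corpus Labeled `fragment_corpus` (balanced recommended).
#' @param mask A `position_mask` (default: all offsets except center).
#' @param blocks Feature blocks, subset of `c("BE", "KNN", "AASA")`.
#' @param config An [svm_config()].
#' @param knn A [knn_config()].
#' @param sim A `substitution_similarity`.
#' @param index A `property_index`.
#' @param property_scaling Passed to [assemble_features()].
#' @param scale Standardize features inside the SVM.
#' @param seed Integer seed.
#' @return An `ace_model`.
#' @export
train_model <- function(corpus, mask = NULL, blocks = c("BE", "KNN", "AASA"),
                        config = svm_config(), knn = knn_config(),
                        sim = normalize_substitution_matrix(),
                        index = aasa_index(),
                        property_scaling = "minmax", scale = FALSE,
                        seed = NULL) {
  window <- attr(corpus, "window")
  if (is.null(mask)) mask <- .full_mask(window)
  x <- assemble_features(corpus, reference = corpus, mask = mask,
                         blocks = blocks, sim = sim, index = index,
                         config = knn, property_scaling = property_scaling)
  gs <- grid_search_train(x, corpus$label, config = config, seed = seed,
                          scale = scale)
  structure(list(fit = gs$fit, cost = gs$cost, gamma = gs$gamma,
                 mask = mask, blocks = blocks, window = window,
                 layout = attr(x, "layout"), reference = corpus,
                 knn = knn, sim = sim, index = index,
                 property_scaling = property_scaling, scale = scale,
                 seed = seed),
            class = "ace_model")
}

#' @export
print.ace_model <- function(x, ...) {
  cat(sprintf("<ace_model> RBF-SVM (C = %g, gamma = %g), mask %s, blocks %s, %d reference fragments\n",
              x$cost, x$gamma, attr(x$mask, "mask_name"),
              paste(x$blocks, collapse = "+"), nrow(x$reference)))
  invisible(x)
}

#' Predict acetylation labels for new fragments
#'
#' Encodes `newdata` with the model's mask, blocks and stored KNN reference
#' (the full training corpus), and thresholds the SVM decision value at 0.
#'
#' @param object An `ace_model`.
#' @param newdata A `fragment_corpus` with the model's window length.
#' @param ... Unused.
#' @return Data frame `(protein_id, position, score, label)`; `score` is the
#'   decision value, oriented so that positive means predicted acetylation.
#' @export
predict.ace_model <- function(object, newdata, ...) {
  if (window_length(attr(newdata, "window")) != window_length(object$window))
    .stopf("window length of `newdata` (%d) does not match the model (%d)",
           window_length(attr(newdata, "window")),
           window_length(object$window))
  x <- assemble_features(newdata, reference = object$reference,
                         mask = object$mask, blocks = object$blocks,
                         sim = object$sim, index = object$index,
                         config = object$knn,
                         property_scaling = object$property_scaling)
  if (ncol(x) != object$layout$end[nrow(object$layout)])
    .stopf("feature layout mismatch between model and new data")
  sc <- .decision_scores(object$fit, x)
  data.frame(protein_id = newdata$protein_id, position = newdata$position,
             score = sc$score, label = sc$label, stringsAsFactors = FALSE)
}

# build an evaluation_result from a per-(set, fold) metric table
.evaluation_result <- function(per_fold, settings = list()) {
  per_set <- do.call(rbind, lapply(split(per_fold, per_fold$set), function(d) {
    data.frame(set = d$set[1L], acc = mean(d$acc), sn = mean(d$sn),
               sp = mean(d$sp), mcc = mean(d$mcc))
  }))
  rownames(per_set) <- NULL
  aggregate <- data.frame(
    metric = c("acc", "sn", "sp", "mcc"),
    mean = vapply(c("acc", "sn", "sp", "mcc"),
                  function(m) mean(per_set[[m]]), numeric(1)),
    sd = vapply(c("acc", "sn", "sp", "mcc"),
                function(m) stats::sd(per_set[[m]]), numeric(1)))
  rownames(aggregate) <- NULL
  structure(list(per_fold = per_fold, per_set = per_set,
                 aggregate = aggregate, settings = settings),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %d negative set(s) x %d fold(s)\n",
              length(unique(x$per_fold$set)),
              length(unique(x$per_fold$fold))))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-4s %6.2f%% +/- %.2f\n", toupper(agg$metric[i]),
                agg$mean[i], if (is.na(agg$sd[i])) 0 else agg$sd[i]))
  }
  invisible(x)
}

#' Balanced multi-negative-set cross-validation
#'
#' The full evaluation protocol: draw `n_negative_sets` balanced negative
#' sets from the negative pool, and for each set run stratified `folds`-fold
#' cross-validation of the position-specific SVM. Within every fold the KNN
#' reference is the training fold only, and the grid search (when the grid
#' has more than one point) is run inside the training fold, so no
#' information leaks from the test fold. Per-set metrics are the mean over
#' the set's folds; the aggregate is the mean and standard deviation over
#' the sets, so the reported spread tracks negative-set resampling.
#'
#' @param corpus Labeled `fragment_corpus` holding the positives and the
#'   (usually much larger) negative pool.
#' @param mask,blocks,config,knn,sim,index,property_scaling,scale As in
#'   [train_model()].
#' @param n_negative_sets Number of balanced negative sets (default 5).
#' @param folds Cross-validation folds per set (default 10).
#' @param tuning `"per-fold"` (default, leakage-safe) retunes `(C, gamma)`
#'   inside every training fold; `"global"` tunes once per negative set on
#'   that set's full data and reuses the pair across its folds.
#' @param seed Integer seed governing negative-set sampling, fold splits and
#'   the inner grid search.
#' @return An `evaluation_result` with per-fold, per-set and aggregate
#'   (mean +/- sd over sets) Acc/Sn/Sp/MCC.
#' @export
cross_validate <- function(corpus, mask = NULL,
                           blocks = c("BE", "KNN", "AASA"),
                           n_negative_sets = 5L, folds = 10L,
                           config = svm_config(), knn = knn_config(),
                           sim = normalize_substitution_matrix(),
                           index = aasa_index(),
                           property_scaling = "minmax", scale = FALSE,
                           tuning = c("per-fold", "global"), seed = NULL) {
  tuning <- match.arg(tuning)
  folds <- .assert_scalar_count(folds, "folds")
  n_negative_sets <- .assert_scalar_count(n_negative_sets, "n_negative_sets")
  window <- attr(corpus, "window")
  if (is.null(mask)) mask <- .full_mask(window)
  pos <- corpus_subset(corpus, corpus$label == "positive")
  neg <- corpus_subset(corpus, corpus$label == "negative")
  if (nrow(pos) < folds || nrow(neg) < folds)
    .stopf("need at least `folds` fragments of each class")
  with_seed(seed, {
    neg_sets <- sample_balanced_negative_sets(neg, nrow(pos),
                                              n_sets = n_negative_sets,
                                              seed = NULL)
    rows <- list()
    for (s in seq_len(n_negative_sets)) {
      set_corpus <- fragment_corpus(rbind(as.data.frame(pos),
                                          as.data.frame(neg_sets[[s]])),
                                    window = window)
      y <- set_corpus$label
      fold_of <- .stratified_folds(y, folds)
      set_config <- config
      if (tuning == "global" &&
          length(config$cost) * length(config$gamma) > 1L) {
        x_all <- assemble_features(set_corpus, reference = set_corpus,
                                   mask = mask, blocks = blocks, sim = sim,
                                   index = index, config = knn,
                                   property_scaling = property_scaling)
        gs <- grid_search_train(x_all, y, config = config, seed = NULL,
                                scale = scale)
        set_config <- svm_config(cost = gs$cost, gamma = gs$gamma,
                                 tuning_folds = config$tuning_folds)
      }
      for (f in seq_len(folds)) {
        te <- fold_of == f
        train <- corpus_subset(set_corpus, !te)
        test <- corpus_subset(set_corpus, te)
        x_tr <- assemble_features(train, reference = train, mask = mask,
                                  blocks = blocks, sim = sim, index = index,
                                  config = knn,
                                  property_scaling = property_scaling)
        x_te <- assemble_features(test, reference = train, mask = mask,
                                  blocks = blocks, sim = sim, index = index,
                                  config = knn,
                                  property_scaling = property_scaling)
        gs <- grid_search_train(x_tr, train$label, config = set_config,
                                seed = NULL, scale = scale)
        pred <- predict(gs$fit, x_te)
        truth <- factor(test$label, levels = c("negative", "positive"))
        tp <- sum(pred == "positive" & truth == "positive")
        fn <- sum(pred == "negative" & truth == "positive")
        tn <- sum(pred == "negative" & truth == "negative")
        fp <- sum(pred == "positive" & truth == "negative")
        met <- confusion_metrics(tp, fn, tn, fp)
        rows[[length(rows) + 1L]] <-
          data.frame(set = s, fold = f, cost = gs$cost, gamma = gs$gamma,
                     knn_ref_size = nrow(train),
                     tp = tp, fn = fn, tn = tn, fp = fp,
                     acc = met[["acc"]], sn = met[["sn"]], sp = met[["sp"]],
                     mcc = met[["mcc"]])
      }
    }
    .evaluation_result(do.call(rbind, rows),
                       settings = list(mask = mask, blocks = blocks,
                                       n_negative_sets = n_negative_sets,
                                       folds = folds, tuning = tuning,
                                       seed = seed))
  })
}

#' Welch's t-test on per-repetition MCC values
#'
#' Compares the MCC of two evaluated configurations across repetitions
#' (negative sets). The default is Welch's unpaired unequal-variance test;
#' `paired = TRUE` runs a paired t-test on the per-set differences instead.
#'
#' @param a,b `evaluation_result` objects, or numeric vectors of
#'   per-repetition MCC values.
#' @param paired Use a paired t-test (default `FALSE`).
#' @return List with `statistic` (t), `p_value`, `df` and the two means.
#' @export
compare_mcc <- function(a, b, paired = FALSE) {
  va <- if (inherits(a, "evaluation_result")) a$per_set$mcc else as.numeric(a)
  vb <- if (inherits(b, "evaluation_result")) b$per_set$mcc else as.numeric(b)
  if (length(va) < 2L || length(vb) < 2L)
    .stopf("need at least two repetitions per configuration")
  if (stats::var(va) == 0 && stats::var(vb) == 0 &&
      (!paired || length(va) == length(vb))) {
    d <- mean(va) - mean(vb)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p_value = if (d == 0) 1 else 0,
                df = NA_real_, mean_a = mean(va), mean_b = mean(vb)))
  }
  ht <- stats::t.test(va, vb, paired = paired, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(va), mean_b = mean(vb))
}

#' Evaluate a trained model on an independent holdout corpus
#'
#' Single-pass prediction with the model's full training corpus as the KNN
#' reference, followed by confusion metrics.
#'
#' @param model An `ace_model`.
#' @param corpus Labeled holdout `fragment_corpus`.
#' @param check_disjoint Error if a holdout protein also occurs in the
#'   model's training reference (default `TRUE`; disable only for sanity
#'   experiments).
#' @return An `evaluation_result` with a single repetition, plus a
#'   `predictions` element.
#' @export
evaluate_holdout <- function(model, corpus, check_disjoint = TRUE) {
  if (nrow(corpus) == 0L) .stopf("holdout corpus is empty")
  if (check_disjoint) {
    overlap <- intersect(unique(corpus$protein_id),
                         unique(model$reference$protein_id))
    if (length(overlap))
      .stopf("holdout shares %d protein(s) with the training reference",
             length(overlap))
  }
  pred <- predict(model, corpus)
  truth <- factor(corpus$label, levels = c("negative", "positive"))
  tp <- sum(pred$label == "positive" & truth == "positive")
  fn <- sum(pred$label == "negative" & truth == "positive")
  tn <- sum(pred$label == "negative" & truth == "negative")
  fp <- sum(pred$label == "positive" & truth == "negative")
  met <- confusion_metrics(tp, fn, tn, fp)
  out <- .evaluation_result(
    data.frame(set = 1L, fold = 1L, cost = model$cost, gamma = model$gamma,
               tp = tp, fn = fn, tn = tn, fp = fp,
               acc = met[["acc"]], sn = met[["sn"]], sp = met[["sp"]],
               mcc = met[["mcc"]]),
    settings = list(mask = model$mask, blocks = model$blocks,
                    holdout = TRUE))
  out$predictions <- pred
  out
}
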