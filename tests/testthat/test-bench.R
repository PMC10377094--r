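sep_table <- function(n = 200, delta = 6, seed = 1) {
  generate_feature_table(
    synthetic_feature_config(n, 20, 8, effect_size = delta, seed = seed))
}

test_that("rotated splits partition samples with stratified 80/10/10 shares", {
  labs <- factor(rep(c("healthy", "OSCC"), each = 150))
  sp <- split_spec(seed = 4)
  folds <- make_splits(labs, sp)
  expect_length(folds, 3)
  all_idx <- seq_along(labs)
  for (f in folds) {
    expect_setequal(c(f$train, f$validation, f$test), all_idx)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_equal(length(f$train), 240)
    expect_equal(length(f$validation), 30)
    expect_equal(length(f$test), 30)
    # stratification: class shares within one sample of balance
    for (part in f) {
      expect_lte(abs(sum(labs[part] == "OSCC") - length(part) / 2), 1)
    }
  }
  # test partitions are disjoint across folds (rotation)
  expect_length(intersect(folds[[1]]$test, folds[[2]]$test), 0)
  expect_identical(folds, make_splits(labs, sp))  # seed determinism
  expect_false(identical(folds, make_splits(labs, split_spec(seed = 5))))
  expect_error(split_spec(train_fraction = 0.9), "sum to 1")
})

test_that("reference protocol sizes emerge for 3000 balanced samples", {
  labs <- factor(rep(c("healthy", "OSCC"), each = 1500))
  folds <- make_splits(labs, split_spec(seed = 1))
  expect_equal(length(folds[[1]]$train), 2400)
  expect_equal(length(folds[[1]]$validation), 300)
  expect_equal(length(folds[[1]]$test), 300)
})

test_that("every classifier separates well-separated synthetic blobs", {
  ft <- sep_table()
  folds <- make_splits(ft$labels, split_spec(seed = 2))
  f <- folds[[1]]
  tr <- feature_table(ft$features[f$train, ], ft$labels[f$train])
  te <- feature_table(ft$features[f$test, ], ft$labels[f$test])
  for (nm in c("softmax", "dt", "rf", "knn", "svm_linear")) {
    fp <- fit_predict(classifier_spec(nm, seed = 3), tr, te)
    acc <- mean(fp$pred == te$labels)
    expect_equal(acc, 1, info = nm)
    expect_length(fp$scores, nrow(te$features))
  }
  # the gradient-descent softmax variant also separates them
  fp <- fit_predict(classifier_spec("softmax", solver = "sgd", seed = 3),
                    tr, te)
  expect_equal(mean(fp$pred == te$labels), 1)
})

test_that("permuted labels give chance-level accuracy", {
  ft <- sep_table(n = 400, seed = 9)
  perm <- with_seed(11, sample(ft$labels))
  ftp <- feature_table(ft$features, perm)
  folds <- make_splits(ftp$labels, split_spec(seed = 2))
  accs <- vapply(c("softmax", "knn"), function(nm) {
    f <- folds[[1]]
    tr <- feature_table(ftp$features[f$train, ], ftp$labels[f$train])
    te <- feature_table(ftp$features[f$test, ], ftp$labels[f$test])
    mean(fit_predict(classifier_spec(nm, seed = 5), tr, te)$pred ==
           te$labels)
  }, numeric(1))
  expect_true(all(accs >= 0.25 & accs <= 0.75))
})

test_that("1-NN on train = test is perfect (self neighbour)", {
  ft <- sep_table(n = 60, delta = 1, seed = 4)
  fp <- fit_predict(classifier_spec("knn", k = 1, seed = 1), ft, ft)
  expect_equal(mean(fp$pred == ft$labels), 1)
})

test_that("single-class training sets are rejected", {
  ft <- sep_table(n = 40)
  onecls <- feature_table(ft$features[ft$labels == "OSCC", ],
                          ft$labels[ft$labels == "OSCC"])
  expect_error(fit_predict(classifier_spec("dt"), onecls, ft),
               "single class")
})

test_that("the bench reports per-fold confusion matrices that recompute exactly", {
  ft <- sep_table(n = 120, delta = 2, seed = 6)
  bench <- run_bench(ft, c("softmax", "knn"), split_spec(seed = 7))
  expect_named(bench, c("softmax", "knn"))
  for (cv in bench) {
    expect_length(cv$per_fold, 3)
    for (f in cv$per_fold) {
      # metrics always recomputable from the stored confusion matrix
      expect_identical(f$report, cm_metrics(f$cm))
      expect_equal(f$cm$TP + f$cm$FN + f$cm$TN + f$cm$FP, 12)
    }
    accs <- vapply(cv$per_fold, function(f) f$report$AC, numeric(1))
    expect_equal(cv$best_fold, which.max(accs))
    expect_equal(cv$best_report$AC, max(accs))
  }
  tab <- bench_metrics_table(bench)
  expect_equal(nrow(tab), 6)
  expect_equal(names(tab)[3:12],
               c("TP", "FN", "TN", "FP", "AC", "MC", "PR", "SE", "SP", "FS"))
  # determinism end to end
  bench2 <- run_bench(ft, c("softmax", "knn"), split_spec(seed = 7))
  expect_identical(bench_metrics_table(bench2), tab)
})
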