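#' Train/validation/test split specification
#'
#' The reference protocol: 80% training, 10% validation, 10% testing,
#' repeated over 3 folds. A fixed split and k-fold cross-validation are
#' reconciled by rotation: each class's shuffled indices are cut into
#' `1/test_fraction` chunks, and fold `f` takes chunk `f` as test, the
#' next chunk as validation, and the rest as training — so test sets are
#' disjoint across folds and every partition is stratified.
#'
#' @param folds number of rotated folds (default 3).
#' @param train_fraction,validation_fraction,test_fraction partition
#'   fractions summing to 1.
#' @param seed integer seed for the stratified shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(folds = 3L, train_fraction = 0.8,
                       validation_fraction = 0.1, test_fraction = 0.1,
                       seed = 1L) {
  if (abs(train_fraction + validation_fraction + test_fraction - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  structure(list(folds = as.integer(folds),
                 train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Build stratified rotated fold assignments
#'
#' @param labels a label vector or a [feature_table()].
#' @param spec a [split_spec()].
#' @return list of `folds` elements, each with integer index vectors
#'   `train`, `validation`, `test`.
#' @export
make_splits <- function(labels, spec) {
  if (inherits(labels, "feature_table")) labels <- labels$labels
  labels <- as.factor(labels)
  n_chunks <- round(1 / spec$test_fraction)
  chunks_val <- round(spec$validation_fraction * n_chunks)
  by_class <- with_seed(spec$seed, {
    lapply(levels(labels), function(lv) {
      idx <- sample(which(labels == lv))
      chunk <- floor((seq_along(idx) - 1L) * n_chunks / length(idx)) + 1L
      split(idx, chunk)
    })
  })
  out <- lapply(seq_len(spec$folds), function(f) {
    test_c <- (f - 1L) %% n_chunks + 1L
    val_c <- (test_c + seq_len(chunks_val) - 1L) %% n_chunks + 1L
    parts <- list(train = integer(), validation = integer(),
                  test = integer())
    for (cls in by_class) {
      for (ch in seq_len(n_chunks)) {
        dest <- if (ch == test_c) "test" else if (ch %in% val_c) "validation" else "train"
        parts[[dest]] <- c(parts[[dest]], cls[[ch]])
      }
    }
    lapply(parts, sort)
  })
  for (f in out) {
    for (part in f) {
      if (nlevels(labels) == 2 && length(unique(labels[part])) < 2) {
        stop("stratification failed: a class is absent from a partition",
             call. = FALSE)
      }
    }
  }
  out
}

#' Classifier specification
#'
#' The five benchmark classifiers: `softmax` (a single linear layer with
#' softmax output, i.e. penalized multinomial/binomial logistic
#' regression; a plain full-batch gradient-descent solver is available
#' as `solver = "sgd"`), `dt` (CART decision tree), `rf` (100-tree
#' random forest), `knn` (k-nearest neighbours, default k = 5) and
#' `svm_linear` (linear-kernel SVM). Features are standardized with
#' training-fold statistics for `softmax`, `knn` and `svm_linear`; the
#' tree methods see raw features.
#'
#' @param name one of `"softmax"`, `"dt"`, `"rf"`, `"knn"`,
#'   `"svm_linear"`.
#' @param ... hyperparameter overrides: `lambda`/`solver` (softmax),
#'   `ntree` (rf), `k` (knn), `cost` (svm_linear).
#' @param seed integer seed used for any stochastic fitting.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(name, ..., seed = 1L) {
  name <- match.arg(name, c("softmax", "dt", "rf", "knn", "svm_linear"))
  defaults <- switch(name,
    softmax = list(lambda = 1e-4, solver = "glmnet"),
    dt = list(),
    rf = list(ntree = 100L),
    knn = list(k = 5L),
    svm_linear = list(cost = 1))
  hyper <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyper = hyper, seed = as.integer(seed)),
            class = "classifier_spec")
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu, "-"), 2, st$sd, "/")
}

# Full-batch gradient-descent logistic trainer (the "softmax layer"
# solver variant). Returns P(positive class) for the test rows.
sgd_softmax <- function(xtr, ytr, xte, lr = 0.1, epochs = 200L) {
  y <- as.integer(ytr == levels(ytr)[2])
  X <- cbind(1, xtr)
  w <- numeric(ncol(X))
  for (e in seq_len(epochs)) {
    p <- 1 / (1 + exp(-drop(X %*% w)))
    w <- w + lr * drop(crossprod(X, y - p)) / nrow(X)
  }
  1 / (1 + exp(-drop(cbind(1, xte) %*% w)))
}

#' Fit a classifier and predict labels with class scores
#'
#' @param spec a [classifier_spec()].
#' @param train,test [feature_table()] objects (train must contain both
#'   classes).
#' @return list with `pred` (factor over the training levels) and
#'   `scores` (probability of the positive = second level).
#' @export
fit_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"))
  ytr <- droplevels(train$labels)
  if (nlevels(ytr) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  xtr <- train$features
  xte <- test$features
  pos <- levels(ytr)[2]
  if (spec$name %in% c("softmax", "knn", "svm_linear")) {
    st <- standardize_fit(xtr)
    xtr <- standardize_apply(xtr, st)
    xte <- standardize_apply(xte, st)
  }
  scores <- with_seed(spec$seed, switch(spec$name,
    softmax = {
      if (identical(spec$hyper$solver, "sgd")) {
        sgd_softmax(xtr, ytr, xte)
      } else {
        x2 <- if (ncol(xtr) < 2) cbind(xtr, 0) else xtr
        t2 <- if (ncol(xte) < 2) cbind(xte, 0) else xte
        fit <- glmnet::glmnet(x2, ytr, family = "binomial", alpha = 0,
                              lambda = spec$hyper$lambda,
                              standardize = FALSE)
        drop(stats::predict(fit, t2, type = "response"))
      }
    },
    dt = {
      df <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., df, method = "class")
      nd <- data.frame(xte, check.names = TRUE)
      colnames(nd) <- colnames(df)[-1]
      stats::predict(fit, nd, type = "prob")[, pos]
    },
    rf = {
      fit <- randomForest::randomForest(xtr, ytr,
                                        ntree = spec$hyper$ntree)
      stats::predict(fit, xte, type = "prob")[, pos]
    },
    knn = {
      pr <- class::knn(xtr, xte, ytr, k = spec$hyper$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == pos, win, 1 - win)
    },
    svm_linear = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear",
                        cost = spec$hyper$cost, probability = TRUE,
                        scale = FALSE)
      pr <- stats::predict(fit, xte, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    }))
  pred <- factor(ifelse(scores > 0.5, pos, levels(ytr)[1]),
                 levels = levels(ytr))
  # exact 0.5 scores (e.g. kNN vote ties) fall to the negative class
  list(pred = pred, scores = as.numeric(scores))
}

#' Cross-validated classifier bench
#'
#' Runs every classifier over the rotated stratified folds, recording
#' the test-set confusion matrix and metric report per fold; the
#' validation partition is held out untouched (it exists for parity with
#' iterative trainers). The best fold maximizes accuracy; mean and sd
#' across folds are also reported.
#'
#' @param table a [feature_table()].
#' @param specs list of [classifier_spec()] (or character names, given
#'   default hyperparameters).
#' @param split a [split_spec()].
#' @return named list per classifier of `cv_result` objects: `per_fold`
#'   (each with `cm`, `report`, `auc`), `best_fold`, `best_report`,
#'   `summary` data frame.
#' @export
run_bench <- function(table, specs, split = split_spec()) {
  if (is.character(specs)) specs <- lapply(specs, classifier_spec)
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  folds <- make_splits(table$labels, split)
  pos <- levels(table$labels)[2]
  out <- lapply(specs, function(spec) {
    per_fold <- lapply(folds, function(f) {
      tr <- feature_table(table$features[f$train, , drop = FALSE],
                          table$labels[f$train])
      te <- feature_table(table$features[f$test, , drop = FALSE],
                          table$labels[f$test])
      fp <- fit_predict(spec, tr, te)
      cm <- confusion(te$labels, fp$pred, positive = pos)
      list(cm = cm, report = cm_metrics(cm),
           auc = roc_curve(fp$scores, te$labels, positive = pos)$auc)
    })
    acc <- vapply(per_fold, function(f) f$report$AC, numeric(1))
    best <- which.max(acc)
    structure(list(classifier = spec$name, per_fold = per_fold,
                   best_fold = best, best_report = per_fold[[best]]$report,
                   summary = data.frame(fold = seq_along(per_fold),
                                        AC = acc,
                                        AUC = vapply(per_fold, `[[`,
                                                     numeric(1), "auc")),
                   mean_AC = mean(acc), sd_AC = stats::sd(acc)),
              class = "cv_result")
    })
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: best fold %d AC=%.4f (mean %.4f +/- %.4f)\n",
              x$classifier, x$best_fold, x$best_report$AC, x$mean_AC,
              x$sd_AC))
  invisible(x)
}

#' Metrics table shaped like the published benchmarks
#'
#' One row per classifier and fold with the stored confusion counts and
#' the six percent metrics (columns `TP,FN,TN,FP,AC,MC,PR,SE,SP,FS`).
#'
#' @param bench a [run_bench()] result.
#' @return a `data.frame`.
#' @export
bench_metrics_table <- function(bench) {
  do.call(rbind, lapply(bench, function(cv) {
    do.call(rbind, lapply(seq_along(cv$per_fold), function(f) {
      cm <- cv$per_fold[[f]]$cm
      r <- cv$per_fold[[f]]$report
      data.frame(classifier = cv$classifier, fold = f,
                 TP = cm$TP, FN = cm$FN, TN = cm$TN, FP = cm$FP,
                 AC = r$AC, MC = r$MC, PR = r$PR, SE = r$SE, SP = r$SP,
                 FS = r$FS, stringsAsFactors = FALSE)
    }))
  }))
}
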