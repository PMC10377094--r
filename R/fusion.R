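#' Serial concatenation of feature blocks
#'
#' Ordered joining of named vectors into one fused vector with recorded
#' block boundaries, so every input block can be reconstructed exactly.
#'
#' @param blocks non-empty named list of non-empty numeric vectors, in
#'   the order they should appear in the fused vector.
#' @return a `fused_vector`: list with `values` and `block_map`
#'   (`data.frame` of `block`, `start`, `length`).
#' @export
serial_concat <- function(blocks) {
  if (length(blocks) == 0) stop("empty block list", call. = FALSE)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("`blocks` must be a fully named list", call. = FALSE)
  }
  lens <- vapply(blocks, length, integer(1))
  if (any(lens == 0)) stop("all blocks must be non-empty", call. = FALSE)
  block_map <- data.frame(block = names(blocks),
                          start = cumsum(c(1L, utils::head(lens, -1L))),
                          length = as.integer(lens),
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(values = unlist(blocks, use.names = FALSE),
                 block_map = block_map),
            class = "fused_vector")
}

#' @export
print.fused_vector <- function(x, ...) {
  cat(sprintf("<fused_vector> length %d: %s\n", length(x$values),
              paste(sprintf("%s[%d]", x$block_map$block, x$block_map$length),
                    collapse = " + ")))
  invisible(x)
}

#' Recover one block from a fused vector
#' @param fused a [serial_concat()] result.
#' @param block block name.
#' @return the block's numeric values.
#' @export
fused_block <- function(fused, block) {
  b <- fused$block_map[fused$block_map$block == block, , drop = FALSE]
  if (nrow(b) != 1) stop("unknown block: ", block, call. = FALSE)
  fused$values[seq(b$start, length.out = b$length)]
}

#' Tanh ensemble weight of one model
#'
#' A model's weight is the sum of `tanh` over its five performance
#' metrics (accuracy, precision, sensitivity, specificity, F1-score).
#' Metrics arrive on the printed percent scale and are divided by 100
#' before the `tanh`, so the weight lives in `[0, 5 * tanh(1)]` and
#' remains strictly increasing in every metric instead of saturating.
#'
#' @param A numeric vector of the five metrics in `[0, 100]` (extra
#'   elements are rejected).
#' @return scalar weight.
#' @export
ensemble_weight <- function(A) {
  A <- as.numeric(A)
  if (length(A) != 5) {
    stop("expected the five metrics (AC, PR, SE, SP, FS)", call. = FALSE)
  }
  if (any(!is.finite(A)) || any(A < 0 | A > 100)) {
    stop("metrics must lie in [0, 100]", call. = FALSE)
  }
  sum(tanh(A / 100))
}

#' Weighted ensemble of class-probability vectors
#'
#' `ens_j = sum_i w_i p_j(i) / sum_i w_i`: the weight-normalized convex
#' combination of the models' class probabilities, itself a probability
#' vector.
#'
#' @param p matrix of per-model class probabilities (models in rows,
#'   classes in columns; each row sums to 1), or a list of such vectors.
#' @param w non-negative per-model weights with at least one positive
#'   entry (e.g. from [ensemble_weight()]).
#' @return named numeric vector of per-class ensemble scores.
#' @export
ensemble_probability <- function(p, w) {
  if (is.list(p)) p <- do.call(rbind, p)
  p <- as.matrix(p)
  if (length(w) != nrow(p)) {
    stop("one weight per model required", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(w) <= 0) stop("degenerate weights: all zero", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-8)) {
    stop("each model's class probabilities must sum to 1", call. = FALSE)
  }
  as.vector(colSums(w * p) / sum(w))
}

#' Ensemble prediction
#'
#' The class with the maximal ensemble score; ties go to the lower class
#' index (a fixed, documented rule).
#'
#' @param ens per-class ensemble scores (optionally named).
#' @return the winning class: its name if `ens` is named, else its
#'   index.
#' @export
ensemble_predict <- function(ens) {
  if (length(ens) == 0) stop("empty score vector", call. = FALSE)
  j <- which.max(ens)  # which.max returns the first (lowest) maximum
  if (!is.null(names(ens))) names(ens)[j] else j
}

#' Feature-level ensemble of deep blocks
#'
#' Builds the ensemble deep-feature block as the element-wise weighted
#' average of the models' feature vectors (or feature matrices with
#' samples in rows), using the tanh metric weights. The result has the
#' models' common length and is typically reduced afterwards by
#' [select_features()].
#'
#' @param features list of equal-length numeric vectors, or
#'   equal-dimension matrices, one per model.
#' @param metric_tuples list of five-metric vectors (percent scale), one
#'   per model, passed to [ensemble_weight()]; alternatively supply
#'   precomputed `weights`.
#' @param weights optional explicit non-negative weights overriding
#'   `metric_tuples`.
#' @return the weighted-average vector/matrix, with the weights in
#'   attribute `weights`.
#' @export
build_edf <- function(features, metric_tuples = NULL, weights = NULL) {
  if (length(features) < 2) {
    stop("need at least two models to ensemble", call. = FALSE)
  }
  dims <- lapply(features, function(f) dim(f) %||% length(f))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all feature blocks must have identical dimensions", call. = FALSE)
  }
  if (is.null(weights)) {
    if (is.null(metric_tuples) || length(metric_tuples) != length(features)) {
      stop("one metric tuple per model is required", call. = FALSE)
    }
    weights <- vapply(metric_tuples, ensemble_weight, numeric(1))
  }
  if (sum(weights) <= 0) stop("degenerate weights: all zero", call. = FALSE)
  out <- Reduce(`+`, Map(function(f, w) w * f, features, weights)) /
    sum(weights)
  attr(out, "weights") <- weights
  out
}

#' Feature-level ensemble of deep feature tables
#'
#' [build_edf()] applied to the feature matrices of aligned tables.
#'
#' @param tables list of [feature_table()] with identical dimensions and
#'   labels.
#' @inheritParams build_edf
#' @return a [feature_table()] named block `edf`, with the weights in
#'   attribute `weights`.
#' @export
build_edf_table <- function(tables, metric_tuples = NULL, weights = NULL) {
  mats <- lapply(tables, function(t) t$features)
  avg <- build_edf(mats, metric_tuples, weights)
  w <- attr(avg, "weights")
  colnames(avg) <- sprintf("edf_%04d", seq_len(ncol(avg)))
  out <- feature_table(avg, tables[[1]]$labels,
                       data.frame(block = "edf", start = 1L,
                                  length = ncol(avg)))
  attr(out, "weights") <- w
  out
}
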