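#' Labelled feature table
#'
#' The central container passed between pipeline stages: an
#' `n_samples x n_features` numeric matrix with a parallel binary label
#' vector and an optional block map recording which contiguous column
#' ranges came from which feature block (e.g. a deep extractor or the
#' handcrafted descriptors).
#'
#' @param features numeric matrix, one row per sample; column names are
#'   kept and used as feature identifiers.
#' @param labels factor or character vector of length `nrow(features)`
#'   with exactly two levels (by convention `healthy` and `OSCC`).
#' @param blocks optional `data.frame` with columns `block`, `start`,
#'   `length` describing contiguous column ranges. Defaults to a single
#'   block spanning all columns.
#'
#' @return an object of class `feature_table` with elements `features`,
#'   `labels` and `blocks`.
#' @export
feature_table <- function(features, labels, blocks = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%04d", seq_len(ncol(features)))
  }
  labels <- as.factor(labels)
  if (length(labels) != nrow(features)) {
    stop("`labels` must have one entry per row of `features`", call. = FALSE)
  }
  if (nlevels(labels) > 2) {
    stop("feature_table labels must be binary", call. = FALSE)
  }
  if (is.null(blocks)) {
    blocks <- data.frame(block = "all", start = 1L,
                         length = ncol(features),
                         stringsAsFactors = FALSE)
  }
  blocks$start <- as.integer(blocks$start)
  blocks$length <- as.integer(blocks$length)
  if (sum(blocks$length) != ncol(features)) {
    stop("block map does not cover the feature columns exactly",
         call. = FALSE)
  }
  structure(list(features = features, labels = labels, blocks = blocks),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels),
                                 tabulate(x$labels)), collapse = ", "), "\n")
  cat("  blocks:", paste(sprintf("%s[%d]", x$blocks$block, x$blocks$length),
                         collapse = " | "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Extract the columns of one named block
#' @param table a [feature_table()].
#' @param block block name as recorded in the block map.
#' @return a `feature_table` restricted to that block's columns.
#' @export
table_block <- function(table, block) {
  b <- table$blocks[table$blocks$block == block, , drop = FALSE]
  if (nrow(b) == 0) stop("unknown block: ", block, call. = FALSE)
  idx <- unlist(lapply(seq_len(nrow(b)), function(i) {
    seq(b$start[i], length.out = b$length[i])
  }))
  feature_table(table$features[, idx, drop = FALSE], table$labels,
                data.frame(block = block, start = 1L,
                           length = length(idx)))
}

#' Restrict a feature table to selected columns
#' @param table a [feature_table()].
#' @param mask a [selection_mask()] or integer vector of column indices.
#' @param block_name block label for the reduced table.
#' @return a reduced `feature_table`.
#' @export
apply_mask <- function(table, mask, block_name = "selected") {
  idx <- if (inherits(mask, "selection_mask")) mask$indices else as.integer(mask)
  if (any(idx < 1L | idx > ncol(table$features))) {
    stop("mask indices out of range", call. = FALSE)
  }
  feature_table(table$features[, idx, drop = FALSE], table$labels,
                data.frame(block = block_name, start = 1L,
                           length = length(idx)))
}

#' Column-wise fusion of feature tables into one table with a block map
#'
#' Serial (ordered) concatenation at the table level: the fused table's
#' columns are the blocks' columns in the order given, and the block map
#' records each block's boundary so any input block can be reconstructed.
#'
#' @param tables named list of [feature_table()] objects sharing the same
#'   samples (labels must agree element-wise).
#' @return a fused `feature_table`.
#' @export
fuse_tables <- function(tables) {
  if (length(tables) == 0) stop("no tables to fuse", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("`tables` must be a fully named list", call. = FALSE)
  }
  lab <- tables[[1]]$labels
  for (t in tables) {
    if (!identical(as.character(t$labels), as.character(lab))) {
      stop("all tables must carry identical labels", call. = FALSE)
    }
  }
  mats <- lapply(tables, function(t) t$features)
  lens <- vapply(mats, ncol, integer(1))
  blocks <- data.frame(block = names(tables),
                       start = cumsum(c(1L, utils::head(lens, -1L))),
                       length = lens, stringsAsFactors = FALSE,
                       row.names = NULL)
  fused <- do.call(cbind, mats)
  colnames(fused) <- unlist(lapply(names(tables), function(nm) {
    paste0(nm, ".", colnames(tables[[nm]]$features))
  }))
  feature_table(fused, lab, blocks)
}

#' Save / load a feature table
#'
#' Two containers are supported: a plain CSV (first column `label`, block
#' map stored in `#%` comment lines so the round trip keeps metadata) and
#' a compact binary RDS container.
#'
#' @param table a [feature_table()].
#' @param path file path; format inferred from the extension (`.csv` or
#'   `.rds`) unless `format` is given.
#' @param format `"csv"` or `"rds"`.
#' @return `save_feature_table` returns `path` invisibly;
#'   `load_feature_table` returns a `feature_table`.
#' @export
save_feature_table <- function(table, path, format = NULL) {
  format <- format %||% (if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv")
  if (format == "rds") {
    saveRDS(table, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(table$blocks))) {
    writeLines(sprintf("#%% block %s %d %d", table$blocks$block[i],
                       table$blocks$start[i], table$blocks$length[i]), con)
  }
  df <- data.frame(label = as.character(table$labels),
                   table$features, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname save_feature_table
#' @export
load_feature_table <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv")
  if (format == "rds") {
    out <- readRDS(path)
    if (!inherits(out, "feature_table")) {
      stop("file does not contain a feature_table", call. = FALSE)
    }
    return(out)
  }
  lines <- readLines(path)
  meta <- grep("^#% block ", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#%")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) {
    stop("feature-table file has no `label` column; cannot be used for ",
         "classification", call. = FALSE)
  }
  blocks <- NULL
  if (length(meta)) {
    parts <- strsplit(sub("^#% block ", "", meta), " ")
    blocks <- data.frame(
      block = vapply(parts, `[`, "", 1),
      start = as.integer(vapply(parts, `[`, "", 2)),
      length = as.integer(vapply(parts, `[`, "", 3)),
      stringsAsFactors = FALSE)
  }
  feature_table(as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]),
                df$label, blocks)
}
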