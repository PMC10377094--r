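#' Pipeline configuration
#'
#' One configuration drives the whole flow: simulate or ingest images,
#' extract handcrafted and deep features, reduce each block with
#' hummingbird-algorithm selection, fuse per recipe, classify and
#' report.
#'
#' Recipes: `df` (one deep block), `ddf` (two deep blocks serially
#' fused), `edf` (tanh-weighted ensemble of three deep blocks), and each
#' `*_hf` variant appending the handcrafted block. Deep blocks come from
#' `extractors` in order; the handcrafted block is computed whenever the
#' recipe asks for it. `ks` gives the retained dimensions per block
#' (named `deep1`, `deep2`, `deep3`, `edf`, `hf`; `NA` keeps a block
#' unreduced). The defaults are the reference retained dimensions
#' (371/416 for the two deep blocks, 366 for the ensemble block, 103 for
#' the handcrafted block).
#'
#' @param input either a [synthetic_image_config()] together with
#'   `n_per_class`, or a directory path containing images plus
#'   `labels.csv`.
#' @param n_per_class images per class when simulating.
#' @param extractors character vector of registered extractor names (or
#'   list of `feature_extractor` objects).
#' @param recipe one of `df`, `ddf`, `edf`, `df_hf`, `ddf_hf`, `edf_hf`.
#' @param ks named integer vector of retained dimensions.
#' @param classifiers character vector of classifier names for the
#'   bench.
#' @param split a [split_spec()].
#' @param aha_iter iteration budget per selection run.
#' @param seed master seed; every stage derives its own seed from it.
#' @param out_dir optional output directory for artifacts (fused table,
#'   JSON report).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = synthetic_image_config(),
                            n_per_class = 100L,
                            extractors = c("mock", "mock2", "mock3"),
                            recipe = "ddf_hf",
                            ks = c(deep1 = 371L, deep2 = 416L,
                                   deep3 = NA, edf = 366L, hf = 103L),
                            classifiers = c("softmax", "dt", "rf", "knn",
                                            "svm_linear"),
                            split = split_spec(),
                            aha_iter = 100L,
                            seed = 1L,
                            out_dir = NULL) {
  recipe <- match.arg(recipe, c("df", "ddf", "edf", "df_hf", "ddf_hf",
                                "edf_hf"))
  n_deep <- switch(sub("_hf$", "", recipe), df = 1L, ddf = 2L, edf = 3L)
  if (length(extractors) < n_deep) {
    stop("recipe '", recipe, "' needs ", n_deep,
         " deep block(s) but only ", length(extractors),
         " extractor(s) are configured", call. = FALSE)
  }
  structure(list(input = input, n_per_class = as.integer(n_per_class),
                 extractors = extractors, recipe = recipe, ks = ks,
                 classifiers = classifiers, split = split,
                 aha_iter = as.integer(aha_iter), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Expected fused dimension for a recipe given the configured ks and raw
# block widths; checked against the realized block map before any
# classifier runs.
expected_fused_dim <- function(recipe, ks, raw) {
  k_of <- function(name) {
    k <- ks[[name]]
    if (is.null(k) || is.na(k)) raw[[name]] else as.integer(k)
  }
  base <- switch(sub("_hf$", "", recipe),
                 df = k_of("deep1"),
                 ddf = k_of("deep1") + k_of("deep2"),
                 edf = k_of("edf"))
  if (grepl("_hf$", recipe)) base + k_of("hf") else base
}

#' Run the full fusion pipeline
#'
#' Stages: (1) simulate or read the labelled image set; (2) extract the
#' deep block(s) and, if the recipe asks, the 416-length handcrafted
#' block; (3) for the ensemble recipe, score each deep block with a
#' softmax probe on the first fold's validation split to obtain the
#' tanh metric weights and average the blocks; (4) reduce each block to
#' its configured retained dimension with [select_features()]; (5) fuse
#' the blocks serially; (6) run the classifier bench on the fused
#' table; (7) assemble (and optionally write) the run report. The whole
#' run is reproducible from `(config, seed)`.
#'
#' @param cfg a [pipeline_config()].
#' @return a `run_report` list: `config`, `dims`, `masks`,
#'   `ensemble_weights` (edf recipes), `bench`, `fused` (the fused
#'   [feature_table()]), `timings`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  n_deep <- switch(sub("_hf$", "", cfg$recipe), df = 1L, ddf = 2L,
                   edf = 3L)
  want_hf <- grepl("_hf$", cfg$recipe)

  # stage 1: images
  images <- if (is.character(cfg$input)) {
    read_image_dataset(cfg$input)
  } else {
    icfg <- cfg$input
    icfg$seed <- derive_seed(cfg$seed, 1L)
    generate_image_dataset(cfg$n_per_class, icfg)
  }
  tick("images")

  # stage 2: feature blocks
  deep <- lapply(seq_len(n_deep), function(i) {
    ex <- cfg$extractors[[i]]
    extract_deep_features(images, ex)
  })
  names(deep) <- paste0("deep", seq_len(n_deep))
  hf <- if (want_hf) handcrafted_table(images) else NULL
  tick("features")

  # stage 3: ensemble block (edf recipes)
  ensemble_weights <- NULL
  blocks <- deep
  if (n_deep == 3L) {
    probe_split <- cfg$split
    probe_split$seed <- derive_seed(cfg$seed, 5L)
    probe_folds <- make_splits(images$labels, probe_split)
    f1 <- probe_folds[[1]]
    tuples <- lapply(deep, function(tb) {
      tr <- feature_table(tb$features[f1$train, , drop = FALSE],
                          tb$labels[f1$train])
      va <- feature_table(tb$features[f1$validation, , drop = FALSE],
                          tb$labels[f1$validation])
      fp <- fit_predict(classifier_spec("softmax",
                                        seed = derive_seed(cfg$seed, 6L)),
                        tr, va)
      metric_tuple(cm_metrics(confusion(va$labels, fp$pred)))
    })
    edf <- build_edf_table(deep, metric_tuples = tuples)
    ensemble_weights <- attr(edf, "weights")
    blocks <- list(edf = edf)
  }
  if (want_hf) blocks$hf <- hf
  raw_dims <- vapply(blocks, function(b) ncol(b$features), integer(1))

  # recipe arithmetic is checked before any selection or classification
  target_dim <- expected_fused_dim(cfg$recipe, cfg$ks, as.list(raw_dims))
  tick("ensemble")

  # stage 4: per-block reduction
  masks <- list()
  reduced <- lapply(seq_along(blocks), function(i) {
    nm <- names(blocks)[i]
    k <- cfg$ks[[nm]]
    if (is.null(k) || is.na(k)) return(blocks[[i]])
    mask <- select_features(blocks[[i]], as.integer(k),
                            max_iter = cfg$aha_iter,
                            seed = derive_seed(cfg$seed, 10L + i))
    masks[[nm]] <<- mask
    apply_mask(blocks[[i]], mask, block_name = nm)
  })
  names(reduced) <- names(blocks)
  tick("selection")

  # stage 5: serial fusion
  fused <- fuse_tables(reduced)
  if (ncol(fused$features) != target_dim) {
    stop("fused dimension ", ncol(fused$features),
         " does not match the recipe arithmetic (", target_dim, ")",
         call. = FALSE)
  }
  tick("fusion")

  # stage 6: classification bench
  bench_split <- cfg$split
  bench_split$seed <- derive_seed(cfg$seed, 20L)
  specs <- lapply(cfg$classifiers, classifier_spec,
                  seed = derive_seed(cfg$seed, 21L))
  bench <- run_bench(fused, specs, bench_split)
  tick("bench")

  report <- structure(list(
    config = cfg,
    dims = list(blocks = as.list(raw_dims),
                fused = ncol(fused$features),
                block_map = fused$blocks),
    masks = masks,
    ensemble_weights = ensemble_weights,
    bench = bench,
    fused = fused,
    timings = timings), class = "run_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_feature_table(fused, file.path(cfg$out_dir, "fused_features.csv"))
    jsonlite::write_json(report_json(report),
                         file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-serializable view of a run report (timings excluded from the
# reproducibility contract).
report_json <- function(report) {
  list(
    recipe = report$config$recipe,
    seed = report$config$seed,
    n_per_class = report$config$n_per_class,
    ks = as.list(report$config$ks),
    dims = list(blocks = report$dims$blocks, fused = report$dims$fused),
    block_map = report$dims$block_map,
    masks = lapply(report$masks, function(m) {
      list(k = m$k, fitness = m$fitness, indices = m$indices)
    }),
    ensemble_weights = report$ensemble_weights,
    results = lapply(report$bench, function(cv) {
      list(best_fold = cv$best_fold,
           best = report_metrics(cv$best_report),
           mean_AC = cv$mean_AC, sd_AC = cv$sd_AC,
           per_fold = lapply(cv$per_fold, function(f) {
             c(list(TP = f$cm$TP, FN = f$cm$FN, TN = f$cm$TN,
                    FP = f$cm$FP, AUC = f$auc),
               report_metrics(f$report))
           }))
    }),
    versions = list(histofuse = as.character(utils::packageVersion("histofuse")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timings = as.list(report$timings))
}

report_metrics <- function(r) r[c("AC", "MC", "PR", "SE", "SP", "FS")]

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> recipe %s, fused dim %d\n", x$config$recipe,
              x$dims$fused))
  for (cv in x$bench) {
    cat(sprintf("  %-10s best-fold AC %.4f\n", cv$classifier,
                cv$best_report$AC))
  }
  invisible(x)
}
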