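#' Nearest-neighbour image resize
#'
#' Minimal deterministic resize used to honour the extractor contract
#' that every image enters feature extraction at `224 x 224 x 3`.
#'
#' @param img an `h x w x 3` array.
#' @param side target side length in pixels.
#' @return a `side x side x 3` array.
#' @export
resize_image <- function(img, side = 224L) {
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  ri <- pmin(d[1], floor((seq_len(side) - 0.5) * d[1] / side) + 1L)
  ci <- pmin(d[2], floor((seq_len(side) - 0.5) * d[2] / side) + 1L)
  img[ri, ci, , drop = FALSE]
}

# Simple image statistics feeding the mock extractor: 8x8 grid of block
# means, 4x4 grids of horizontal/vertical gradient energy, and a few
# global summaries. Length 102.
image_stats <- function(img) {
  img <- resize_image(img, 224L)
  g <- rgb_to_gray(img)
  grid_means <- function(m, k) {
    ri <- floor((seq_len(nrow(m)) - 1L) * k / nrow(m)) + 1L
    ci <- floor((seq_len(ncol(m)) - 1L) * k / ncol(m)) + 1L
    as.vector(t(vapply(1:k, function(r) {
      vapply(1:k, function(c) mean(m[ri == r, ci == c]), numeric(1))
    }, numeric(k))))
  }
  dx <- abs(g[, -1] - g[, -ncol(g)])
  dy <- abs(g[-1, ] - g[-nrow(g), ])
  c(grid_means(g, 8),
    grid_means(dx, 4), grid_means(dy, 4),
    mean(g), stats::sd(as.vector(g)), stats::median(g),
    mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
}

#' Deterministic mock deep-feature extractor
#'
#' Stands in for a pretrained network's 1000-way output during testing:
#' simple image statistics (block means and gradient-energy summaries)
#' are pushed through a fixed seeded random projection followed by a
#' `tanh` squashing, yielding a length-1000 vector that is a pure
#' function of the image bytes and the extractor seed, and that
#' separates the synthetic texture classes.
#'
#' @param seed integer seed fixing the projection matrix.
#' @param output_length output vector length (1000 to match the
#'   pretrained-network contract).
#' @param name registry name for the extractor.
#' @return a `feature_extractor` object.
#' @export
mock_extractor <- function(seed = 101L, output_length = 1000L,
                           name = "mock") {
  n_stats <- 102L
  proj <- with_seed(seed, {
    matrix(stats::rnorm(output_length * n_stats), output_length, n_stats) /
      sqrt(n_stats)
  })
  fn <- function(img) {
    s <- (image_stats(img) - 128) / 64
    as.vector(tanh(proj %*% s))
  }
  structure(list(name = name, output_length = as.integer(output_length),
                 fn = fn, seed = as.integer(seed)),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %s -> length %d\n", x$name,
              x$output_length))
  invisible(x)
}

.extractor_registry <- new.env(parent = emptyenv())

#' Extractor registry
#'
#' Extractors are addressed by name from configurations and the command
#' line. The package registers deterministic mock extractors (`mock`,
#' `mock2`, `mock3`) at load time. Adapters for pretrained networks
#' (`vgg16`, `vgg19`, `resnet18/50/101`, `densenet201`) are an optional
#' add-on and are not bundled; requesting one raises a lookup error that
#' says so.
#'
#' @param extractor a `feature_extractor` to register.
#' @param name extractor name to look up.
#' @return `get_extractor` returns a `feature_extractor`.
#' @export
register_extractor <- function(extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  assign(extractor$name, extractor, envir = .extractor_registry)
  invisible(extractor)
}

#' @rdname register_extractor
#' @export
get_extractor <- function(name) {
  if (!exists(name, envir = .extractor_registry, inherits = FALSE)) {
    known <- paste(ls(.extractor_registry), collapse = ", ")
    pdl <- c("vgg16", "vgg19", "resnet18", "resnet50", "resnet101",
             "densenet201")
    extra <- if (name %in% pdl) {
      " (pretrained-network adapters are an optional add-on and are not bundled)"
    } else ""
    stop("unknown extractor '", name, "'", extra,
         "; registered: ", known, call. = FALSE)
  }
  get(name, envir = .extractor_registry)
}

.onLoad <- function(libname, pkgname) {
  register_extractor(mock_extractor(101L, name = "mock"))
  register_extractor(mock_extractor(202L, name = "mock2"))
  register_extractor(mock_extractor(303L, name = "mock3"))
}

#' Extract deep features for an image set
#'
#' Applies one registered extractor to every image (after the 224x224x3
#' resize) and assembles the rows into a labelled feature table.
#'
#' @param images a `labeled_image_set`.
#' @param extractor a `feature_extractor` or a registered name.
#' @return a [feature_table()] of `n_images x output_length`.
#' @export
extract_deep_features <- function(images, extractor) {
  if (is.character(extractor)) extractor <- get_extractor(extractor)
  stopifnot(inherits(extractor, "feature_extractor"))
  if (length(images$images) == 0) stop("empty image set", call. = FALSE)
  rows <- t(vapply(images$images, extractor$fn,
                   numeric(extractor$output_length)))
  colnames(rows) <- sprintf("%s_%04d", extractor$name,
                            seq_len(extractor$output_length))
  feature_table(rows, images$labels,
                data.frame(block = extractor$name, start = 1L,
                           length = extractor$output_length))
}
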