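#' Configuration for the synthetic two-class texture generator
#'
#' The generator emulates the texture contrast of H&E histology crops at
#' the level that matters for texture descriptors: dark elliptical blobs
#' (nuclei proxies) scattered over a noisy pink-ish background, with the
#' two classes differing in blob density and blob size. It makes no
#' attempt at visually realistic staining.
#'
#' @param side_px image side in pixels (square output), at least 32.
#' @param blob_density_per_class expected blob count per image for the
#'   `healthy` and `OSCC` classes (Poisson rates), in that order.
#' @param blob_radius_px two-element range of blob semi-axis lengths in
#'   pixels. The `healthy` class draws radii from the lower half of the
#'   range and `OSCC` from the upper half, so the classes differ in both
#'   density and size.
#' @param background_noise_sd standard deviation of the Gaussian pixel
#'   noise added to the background, in 8-bit intensity units.
#' @param seed integer seed; all image content is a pure function of the
#'   configuration, the label and the per-image seed.
#' @return a `synthetic_image_config` list.
#' @export
synthetic_image_config <- function(side_px = 224,
                                   blob_density_per_class = c(healthy = 10, OSCC = 40),
                                   blob_radius_px = c(3, 9),
                                   background_noise_sd = 8,
                                   seed = 1L) {
  if (side_px < 32) stop("side_px must be at least 32", call. = FALSE)
  if (length(blob_density_per_class) != 2 || any(blob_density_per_class < 0)) {
    stop("blob_density_per_class must be two non-negative rates",
         call. = FALSE)
  }
  if (length(blob_radius_px) != 2 || any(blob_radius_px <= 0) ||
      blob_radius_px[1] > blob_radius_px[2]) {
    stop("blob_radius_px must be a positive increasing range", call. = FALSE)
  }
  if (background_noise_sd < 0) {
    stop("background_noise_sd must be non-negative", call. = FALSE)
  }
  names(blob_density_per_class) <- c("healthy", "OSCC")
  structure(list(side_px = as.integer(side_px),
                 blob_density_per_class = blob_density_per_class,
                 blob_radius_px = blob_radius_px,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_image_config")
}

#' Generate one synthetic texture image
#'
#' @param label `"healthy"` or `"OSCC"`.
#' @param cfg a [synthetic_image_config()].
#' @param instance_seed integer seed for this image; the output is
#'   byte-identical for a fixed `(label, cfg, instance_seed)`.
#' @return an 8-bit RGB image as a `side_px x side_px x 3` array of
#'   integers in `[0, 255]`.
#' @export
generate_texture_image <- function(label, cfg, instance_seed) {
  label <- match.arg(label, c("healthy", "OSCC"))
  stopifnot(inherits(cfg, "synthetic_image_config"))
  n <- cfg$side_px
  with_seed(instance_seed, {
    # pink-ish background (eosin-like) with Gaussian pixel noise
    base <- c(228, 186, 205)
    img <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      img[, , ch] <- base[ch] +
        matrix(stats::rnorm(n * n, sd = cfg$background_noise_sd), n, n)
    }

    rate <- cfg$blob_density_per_class[[label]]
    n_blobs <- stats::rpois(1, rate)
    rr <- cfg$blob_radius_px
    mid <- mean(rr)
    rad_range <- if (label == "healthy") c(rr[1], mid) else c(mid, rr[2])

    blob_col <- c(96, 58, 122)  # dark purple (hematoxylin-like)
    if (n_blobs > 0) {
      for (b in seq_len(n_blobs)) {
        cx <- stats::runif(1, 1, n)
        cy <- stats::runif(1, 1, n)
        a <- stats::runif(1, rad_range[1], rad_range[2])
        bb <- stats::runif(1, rad_range[1], rad_range[2])
        th <- stats::runif(1, 0, pi)
        shade <- stats::runif(1, 0.75, 1)
        rmax <- max(a, bb)
        rows <- max(1, floor(cy - rmax)):min(n, ceiling(cy + rmax))
        cols <- max(1, floor(cx - rmax)):min(n, ceiling(cx + rmax))
        dy <- rows - cy
        dx <- cols - cx
        # rotated-ellipse membership on the bounding-box window
        u <- outer(dy, dx, function(y, x) x * cos(th) + y * sin(th))
        v <- outer(dy, dx, function(y, x) -x * sin(th) + y * cos(th))
        inside <- (u / a)^2 + (v / bb)^2 <= 1
        for (ch in 1:3) {
          win <- img[rows, cols, ch]
          win[inside] <- shade * blob_col[ch] + (1 - shade) * win[inside]
          img[rows, cols, ch] <- win
        }
      }
    }
    img <- round(clamp(img, 0, 255))
    storage.mode(img) <- "integer"
    img
  })
}

#' Generate a balanced labelled image set
#'
#' Per-image seeds are derived deterministically from `cfg$seed` and the
#' image index, so the dataset is reproducible and extensible.
#'
#' @param n_per_class images per class (at least 1).
#' @param cfg a [synthetic_image_config()].
#' @return a `labeled_image_set`: list with `images` (list of arrays),
#'   `labels` (factor `healthy`/`OSCC`) and `config`.
#' @export
generate_image_dataset <- function(n_per_class, cfg) {
  if (n_per_class < 1) stop("n_per_class must be at least 1", call. = FALSE)
  labels <- factor(rep(c("healthy", "OSCC"), each = n_per_class),
                   levels = c("healthy", "OSCC"))
  images <- vector("list", 2 * n_per_class)
  for (i in seq_along(labels)) {
    images[[i]] <- generate_texture_image(as.character(labels[i]), cfg,
                                          derive_seed(cfg$seed, i))
  }
  structure(list(images = images, labels = labels, config = cfg),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set> %d images (%s), %dx%d px\n",
              length(x$images),
              paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels)),
                    collapse = ", "),
              dim(x$images[[1]])[1], dim(x$images[[1]])[2]))
  invisible(x)
}

#' Write an image set as PNG files plus a labels CSV
#'
#' @param set a `labeled_image_set`.
#' @param dir output directory (created if needed). Writes
#'   `img_0001.png`, ... and `labels.csv` with columns
#'   `filename,label`.
#' @return the labels data frame, invisibly.
#' @export
write_image_dataset <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("img_%04d.png", seq_along(set$images))
  for (i in seq_along(set$images)) {
    png::writePNG(set$images[[i]] / 255, file.path(dir, files[i]))
  }
  df <- data.frame(filename = files, label = as.character(set$labels),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(df)
}

#' Read an image directory with a labels CSV back into an image set
#'
#' @param dir directory containing PNG images and a `labels.csv` with
#'   columns `filename,label`.
#' @return a `labeled_image_set` (with `config = NULL`).
#' @export
read_image_dataset <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    stop("no labels.csv found in ", dir, call. = FALSE)
  }
  df <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  images <- lapply(df$filename, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("cannot read image file: ", p, call. = FALSE)
    arr <- png::readPNG(p)
    if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
    out <- round(arr[, , 1:3] * 255)
    storage.mode(out) <- "integer"
    out
  })
  structure(list(images = images,
                 labels = factor(df$label, levels = c("healthy", "OSCC")),
                 config = NULL),
            class = "labeled_image_set")
}

#' Configuration for synthetic feature tables with known structure
#'
#' @param n_samples positive even total sample count (balanced classes).
#' @param n_features number of feature columns.
#' @param n_informative number of columns carrying a class-mean shift.
#' @param effect_size standardized mean shift delta: informative columns
#'   have class-mean difference `effect_size * noise_sd`.
#' @param noise_sd within-class standard deviation of every column.
#' @param seed integer seed.
#' @return a `synthetic_feature_config` list.
#' @export
synthetic_feature_config <- function(n_samples, n_features,
                                     n_informative,
                                     effect_size = 2,
                                     noise_sd = 1,
                                     seed = 1L) {
  if (n_samples < 2 || n_samples %% 2 != 0) {
    stop("n_samples must be positive and even", call. = FALSE)
  }
  if (n_informative < 0 || n_informative > n_features) {
    stop("n_informative must lie in [0, n_features]", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be non-negative", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_feature_config")
}

#' Generate a synthetic feature table with known informative columns
#'
#' Balanced binary labels; a seeded random subset of `n_informative`
#' columns receives a between-class mean difference of
#' `effect_size * noise_sd` (half added to the OSCC class, half
#' subtracted from healthy); all remaining columns are pure noise. The
#' informative column indices are recorded in the result's
#' `"informative"` attribute so selection methods can be scored against
#' ground truth.
#'
#' @param cfg a [synthetic_feature_config()].
#' @return a [feature_table()] with attribute `informative` (sorted
#'   integer indices).
#' @export
generate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_feature_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    d <- cfg$n_features
    labels <- factor(rep(c("healthy", "OSCC"), each = n / 2),
                     levels = c("healthy", "OSCC"))
    x <- matrix(stats::rnorm(n * d, sd = cfg$noise_sd), n, d)
    info <- sort(sample.int(d, cfg$n_informative))
    shift <- cfg$effect_size * cfg$noise_sd / 2
    if (length(info)) {
      x[labels == "OSCC", info] <- x[labels == "OSCC", info] + shift
      x[labels == "healthy", info] <- x[labels == "healthy", info] - shift
    }
    colnames(x) <- sprintf("f%04d", seq_len(d))
    out <- feature_table(x, labels,
                         data.frame(block = "synthetic", start = 1L,
                                    length = d))
    attr(out, "informative") <- info
    out
  })
}
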