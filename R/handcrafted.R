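#' Convert an RGB image to grayscale intensities
#'
#' Single documented conversion applied once at module entry: ITU-R 601
#' luma weights `0.299 R + 0.587 G + 0.114 B` on the 0-255 scale.
#'
#' @param img an `h x w x 3` array (0-255) or an already-gray matrix.
#' @return a numeric matrix of intensities in `[0, 255]`.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img * 1.0)
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    stop("expected an RGB array or a gray matrix", call. = FALSE)
  }
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Uniform-pattern lookup: 8-bit circular codes with at most two 0/1
# transitions get their own bin (58 of them, in increasing code order);
# everything else falls into the catch-all 59th bin.
uniform_lbp_bins <- function() {
  transitions <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }
  codes <- 0:255
  uniform <- codes[vapply(codes, transitions, integer(1)) <= 2]
  map <- rep.int(59L, 256)
  map[uniform + 1L] <- seq_along(uniform)
  map
}
.lbp_bin_map <- uniform_lbp_bins()

# Raw 8-neighbour radius-1 codes for all interior pixels, vectorized via
# shifted submatrices. Neighbour order: clockwise from the top-left
# corner; a bit is set when neighbour >= centre.
lbp_code_matrix <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr < 3 || nc < 3) stop("image must be at least 3x3", call. = FALSE)
  centre <- gray[2:(nr - 1), 2:(nc - 1)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, nr - 2, nc - 2)
  for (p in seq_along(offs)) {
    dr <- offs[[p]][1]; dc <- offs[[p]][2]
    nb <- gray[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
    code <- code + bitwShiftL(as.integer(nb >= centre), p - 1L)
  }
  code
}

#' Weighted uniform LBP histogram
#'
#' Standard uniform local binary patterns (8 neighbours, radius 1) on an
#' intensity-rescaled copy of the image: the weight `W` in 1..4
#' multiplies the grayscale intensities, clipped to `[0, 255]`, before
#' code extraction, so larger weights progressively saturate bright
#' texture. The 59 bins are the 58 uniform patterns plus one catch-all,
#' normalized to unit sum over the interior pixels.
#'
#' @param img RGB array or gray matrix.
#' @param weight integer in `{1, 2, 3, 4}`.
#' @param rescale strategy hook mapping `(gray, weight)` to the image the
#'   codes are computed on; the default is `clamp(weight * gray, 0, 255)`.
#' @return a named numeric vector of 59 frequencies summing to 1, with
#'   class `lbp_histogram` and attribute `weight`.
#' @export
weighted_lbp <- function(img, weight,
                         rescale = function(gray, w) clamp(w * gray, 0, 255)) {
  if (length(weight) != 1 || !(weight %in% 1:4)) {
    stop("weight must be one of 1, 2, 3, 4", call. = FALSE)
  }
  gray <- rescale(rgb_to_gray(img), weight)
  bins <- .lbp_bin_map[lbp_code_matrix(gray) + 1L]
  h <- tabulate(bins, nbins = 59L)
  h <- h / sum(h)
  names(h) <- sprintf("lbp_w%d_%02d", weight, 1:59)
  structure(h, class = "lbp_histogram", weight = as.integer(weight))
}

#' Concatenated weighted-LBP block (length 236)
#'
#' The four weighted histograms at W = 1, 2, 3, 4 in that order:
#' `4 x 59 = 236` values.
#'
#' @inheritParams weighted_lbp
#' @return named numeric vector of length 236.
#' @export
lbp_block <- function(img) {
  gray <- rgb_to_gray(img)
  unlist(lapply(1:4, function(w) unclass(weighted_lbp(gray, w))))
}

#' One-level 2-D Haar wavelet decomposition
#'
#' Orthonormal Haar analysis (low = `(a+b)/sqrt(2)`, high =
#' `(a-b)/sqrt(2)`), first along rows then along columns, giving four
#' half-resolution subbands. Odd trailing rows/columns are trimmed. The
#' orthonormal normalization makes energy conservation (Parseval) exact:
#' the summed squared coefficients of the four subbands equal the squared
#' norm of the (trimmed) input.
#'
#' @param img RGB array or gray matrix; grayscale side must be >= 2.
#' @return list with matrices `approximate`, `vertical` (high-pass along
#'   the horizontal axis: responds to vertical edges), `horizontal` and
#'   `diagonal`.
#' @export
dwt_decompose <- function(img) {
  g <- rgb_to_gray(img)
  if (nrow(g) < 2 || ncol(g) < 2) {
    stop("image too small for a wavelet level (need side >= 2)",
         call. = FALSE)
  }
  g <- g[seq_len(nrow(g) %/% 2 * 2), seq_len(ncol(g) %/% 2 * 2), drop = FALSE]
  s2 <- sqrt(2)
  odd_c <- seq(1, ncol(g), by = 2); evn_c <- odd_c + 1
  lo <- (g[, odd_c, drop = FALSE] + g[, evn_c, drop = FALSE]) / s2
  hi <- (g[, odd_c, drop = FALSE] - g[, evn_c, drop = FALSE]) / s2
  odd_r <- seq(1, nrow(g), by = 2); evn_r <- odd_r + 1
  col_pass <- function(m) {
    list(lo = (m[odd_r, , drop = FALSE] + m[evn_r, , drop = FALSE]) / s2,
         hi = (m[odd_r, , drop = FALSE] - m[evn_r, , drop = FALSE]) / s2)
  }
  L <- col_pass(lo); H <- col_pass(hi)
  list(approximate = L$lo,   # low-low
       vertical    = H$lo,   # high-pass along columns (vertical edges)
       horizontal  = L$hi,   # high-pass along rows (horizontal edges)
       diagonal    = H$hi)
}

#' 45-value subband descriptor
#'
#' Partitions a subband into a 9 x 5 grid of near-equal contiguous
#' blocks and records the mean absolute coefficient per block,
#' row-major: a deterministic, resolution-independent 45-number summary.
#'
#' @param band a subband coefficient matrix.
#' @return numeric vector of length 45.
#' @export
subband_descriptor <- function(band) {
  ri <- floor((seq_len(nrow(band)) - 1L) * 9 / nrow(band)) + 1L
  ci <- floor((seq_len(ncol(band)) - 1L) * 5 / ncol(band)) + 1L
  out <- numeric(45)
  k <- 0L
  a <- abs(band)
  for (r in 1:9) {
    for (c in 1:5) {
      k <- k + 1L
      out[k] <- mean(a[ri == r, ci == c, drop = FALSE])
    }
  }
  out
}

#' Wavelet descriptor block (length 180)
#'
#' The 45-value descriptor of each Haar subband, concatenated in the
#' order approximate, vertical, horizontal, diagonal: `4 x 45 = 180`.
#'
#' @inheritParams dwt_decompose
#' @return named numeric vector of length 180.
#' @export
dwt_block <- function(img) {
  sb <- dwt_decompose(img)
  out <- unlist(lapply(c("approximate", "vertical", "horizontal", "diagonal"),
                       function(nm) {
                         v <- subband_descriptor(sb[[nm]])
                         names(v) <- sprintf("dwt_%s_%02d", nm, 1:45)
                         v
                       }))
  out
}

#' Full handcrafted descriptor (length 416)
#'
#' Concatenation of the weighted-LBP block (236) and the wavelet block
#' (180), with recorded block boundaries.
#'
#' @inheritParams weighted_lbp
#' @return a `handcrafted_vector`: list with `full` (length-416 named
#'   vector), `lbp` (236), `dwt` (180) and `blocks` (boundary map).
#' @export
handcrafted_vector <- function(img) {
  gray <- rgb_to_gray(img)
  lbp <- lbp_block(gray)
  dwt <- dwt_block(gray)
  structure(list(full = c(lbp, dwt), lbp = lbp, dwt = dwt,
                 blocks = data.frame(block = c("lbp", "dwt"),
                                     start = c(1L, 237L),
                                     length = c(236L, 180L))),
            class = "handcrafted_vector")
}

#' Handcrafted feature table for an image set
#'
#' @param images a `labeled_image_set`.
#' @return a [feature_table()] with 416 columns and blocks `lbp` / `dwt`.
#' @export
handcrafted_table <- function(images) {
  rows <- t(vapply(images$images,
                   function(im) handcrafted_vector(im)$full,
                   numeric(416)))
  feature_table(rows, images$labels,
                data.frame(block = c("lbp", "dwt"), start = c(1L, 237L),
                           length = c(236L, 180L)))
}
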