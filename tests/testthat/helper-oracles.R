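# Independent oracles used across the suite. These deliberately use
# naive per-element computations so they share no code with the
# vectorized implementations they check.

# Per-pixel uniform LBP histogram by explicit loops: 8 neighbours,
# radius 1, clockwise from the top-left corner, bit set when
# neighbour >= centre; uniform codes (<= 2 circular transitions) get
# their own bin in increasing code order, the rest the 59th bin.
brute_lbp_histogram <- function(gray) {
  is_uniform <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)]) <= 2
  }
  uniform_codes <- Filter(is_uniform, 0:255)
  offsets <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                  c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  counts <- numeric(59)
  for (r in 2:(nrow(gray) - 1)) {
    for (c in 2:(ncol(gray) - 1)) {
      code <- 0
      for (p in seq_along(offsets)) {
        nb <- gray[r + offsets[[p]][1], c + offsets[[p]][2]]
        if (nb >= gray[r, c]) code <- code + 2^(p - 1)
      }
      bin <- if (code %in% uniform_codes) match(code, uniform_codes) else 59
      counts[bin] <- counts[bin] + 1
    }
  }
  counts / sum(counts)
}

# AUC as the exhaustive pairwise concordance probability (ties = 1/2).
brute_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + if (scores[i] > scores[j]) 1 else
        if (scores[i] == scores[j]) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Centroid distance recomputed directly from first principles.
brute_cd <- function(features, labels, idx) {
  g2 <- labels == levels(labels)[2]
  d2 <- 0
  for (j in idx) {
    x <- features[, j]
    n1 <- sum(!g2); n2 <- sum(g2)
    s_pool <- sqrt(((n1 - 1) * var(x[!g2]) + (n2 - 1) * var(x[g2])) /
                     (n1 + n2 - 2))
    if (s_pool > 0) {
      d2 <- d2 + ((mean(x[g2]) - mean(x[!g2])) / s_pool)^2
    }
  }
  sqrt(d2)
}

# Small-image config shared by image-based tests.
tiny_image_cfg <- function(seed = 7, side = 48) {
  synthetic_image_config(side_px = side, seed = seed)
}

random_gray <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}
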