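test_that("serial concatenation records exact block boundaries", {
  f <- serial_concat(list(vgg = rnorm(371), densenet = rnorm(416)))
  expect_length(f$values, 787)
  expect_equal(f$block_map$start, c(1L, 372L))
  f2 <- serial_concat(list(ddf = rnorm(787), hf = rnorm(103)))
  expect_length(f2$values, 890)
  # single block is the identity
  v <- rnorm(12)
  f3 <- serial_concat(list(only = v))
  expect_equal(f3$values, v)
  expect_error(serial_concat(list()), "empty")
  expect_error(serial_concat(list(a = numeric(0))), "non-empty")
  # block reconstruction is exact
  a <- rnorm(5); b <- rnorm(9)
  f4 <- serial_concat(list(a = a, b = b))
  expect_equal(fused_block(f4, "a"), a)
  expect_equal(fused_block(f4, "b"), b)
})

test_that("tanh ensemble weights hit their closed forms and monotonicity", {
  expect_equal(ensemble_weight(c(0, 0, 0, 0, 0)), 0)
  expect_equal(ensemble_weight(rep(100, 5)), 5 * tanh(1))
  expect_equal(5 * tanh(1), 3.8079708, tolerance = 1e-7)
  w0 <- ensemble_weight(c(90, 80, 70, 60, 50))
  w1 <- ensemble_weight(c(90, 80, 75, 60, 50))
  expect_gt(w1, w0)
  expect_error(ensemble_weight(c(101, 0, 0, 0, 0)), "0, 100")
  expect_error(ensemble_weight(c(1, 2, 3)), "five")
})

test_that("ensemble probabilities are weight-normalized convex combinations", {
  p <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  # hand-computed example, w = (1, 1, 2):
  # class 1: (0.9 + 0.6 + 2 * 0.2) / 4 = 0.475; class 2: 0.525
  expect_equal(ensemble_probability(p, c(1, 1, 2)), c(0.475, 0.525))
  # equal weights reduce to the arithmetic mean
  expect_equal(ensemble_probability(p, c(1, 1, 1)), colMeans(p))
  # single-model weight reduces to that model
  expect_equal(ensemble_probability(p, c(0, 1, 0)), p[2, ])
  # output is a probability vector
  ens <- ensemble_probability(p, c(0.3, 1.2, 0.7))
  expect_true(all(ens >= 0))
  expect_equal(sum(ens), 1)
  # permutation equivariance in (model, weight) pairs
  perm <- c(3, 1, 2)
  expect_equal(ensemble_probability(p[perm, ], c(1, 1, 2)[perm]),
               ensemble_probability(p, c(1, 1, 2)))
  expect_error(ensemble_probability(p, c(0, 0, 0)), "degenerate")
  expect_error(ensemble_probability(rbind(c(0.5, 0.2)), 1), "sum to 1")
})

test_that("ensemble prediction takes the argmax with a lower-index tie rule", {
  expect_equal(ensemble_predict(c(0.475, 0.525)), 2)
  expect_equal(ensemble_predict(c(healthy = 0.6, OSCC = 0.4)), "healthy")
  expect_equal(ensemble_predict(c(0.5, 0.5)), 1)
  # unanimous models survive any positive weighting
  p <- rbind(c(0.8, 0.2), c(0.7, 0.3), c(0.9, 0.1))
  for (w in list(c(1, 1, 1), c(3, 0.2, 1))) {
    expect_equal(ensemble_predict(ensemble_probability(p, w)), 1)
  }
  expect_error(ensemble_predict(numeric(0)), "empty")
})

test_that("feature-level ensemble averages blocks by tanh weights", {
  v <- rnorm(100)
  same <- list(v, v, v)
  tup <- list(rep(95, 5), rep(90, 5), rep(99, 5))
  expect_equal(build_edf(same, tup), v, ignore_attr = TRUE)
  # equal weights give the plain element-wise mean
  vs <- list(rnorm(50), rnorm(50), rnorm(50))
  eq <- build_edf(vs, list(rep(90, 5), rep(90, 5), rep(90, 5)))
  expect_equal(as.vector(eq), (vs[[1]] + vs[[2]] + vs[[3]]) / 3)
  # explicit weights follow the weighted-mean formula
  wavg <- build_edf(vs, weights = c(2, 1, 1))
  expect_equal(as.vector(wavg), (2 * vs[[1]] + vs[[2]] + vs[[3]]) / 4)
  expect_error(build_edf(list(rnorm(5), rnorm(6)), tup[1:2]), "identical")
  expect_error(build_edf(vs, tup[1:2]), "one metric tuple")
})

test_that("table-level fusion preserves labels and reconstructs blocks", {
  labs <- rep(c("healthy", "OSCC"), each = 10)
  t1 <- feature_table(matrix(rnorm(200), 20), labs,
                      data.frame(block = "b1", start = 1, length = 10))
  t2 <- feature_table(matrix(rnorm(100), 20), labs,
                      data.frame(block = "b2", start = 1, length = 5))
  fused <- fuse_tables(list(b1 = t1, b2 = t2))
  expect_equal(ncol(fused$features), 15)
  expect_equal(fused$blocks$block, c("b1", "b2"))
  back <- table_block(fused, "b2")
  expect_equal(unname(back$features), unname(t2$features))
  t3 <- feature_table(matrix(1, 20, 2), rev(labs))
  expect_error(fuse_tables(list(a = t1, b = t3)), "identical labels")
})
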