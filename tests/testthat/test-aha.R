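quadratic_1d <- function(x) -(x[1] - 3)^2
sphere <- function(x) -sum(x^2)

test_that("swarm initialization fills the box with a zeroed visit table", {
  cfg <- aha_config(n_birds = 25, dim = 10, lower = -1, upper = 2,
                    max_iter = 10, seed = 1)
  st <- with_seed(1, initialize_swarm(cfg, sphere))
  expect_equal(dim(st$positions), c(25L, 10L))
  expect_equal(dim(st$visit_table), c(25L, 25L))
  expect_true(all(st$positions >= -1 & st$positions <= 2))
  expect_true(all(is.na(diag(st$visit_table))))
  expect_true(all(st$visit_table[upper.tri(st$visit_table)] == 0))
  expect_equal(st$best_fitness, max(st$fitness))
  # degenerate box shrinks all positions onto the lower bound
  eps <- 1e-12
  cfg2 <- aha_config(dim = 3, lower = 5, upper = 5 + eps, max_iter = 1,
                     seed = 1)
  st2 <- with_seed(1, initialize_swarm(cfg2, sphere))
  expect_true(all(abs(st2$positions - 5) <= eps))
  expect_error(aha_config(dim = 2, lower = 0, upper = Inf), "finite")
  expect_error(aha_config(dim = 2, lower = 1, upper = 1), "strictly")
  expect_error(aha_config(n_birds = 1, dim = 2, lower = 0, upper = 1),
               "n_birds")
})

test_that("direction masks obey the axial/diagonal/omnidirectional contracts", {
  set.seed(1)
  for (i in 1:200) {
    dv <- sample_direction(8)
    ones <- sum(dv$D)
    expect_true(all(dv$D %in% c(0, 1)))
    switch(dv$mode,
           axial = expect_equal(ones, 1),
           diagonal = expect_true(ones >= 2 && ones <= 7),
           omnidirectional = expect_equal(ones, 8))
  }
  # d = 1: axial and omnidirectional coincide
  expect_equal(sample_direction(1, "axial")$D, 1)
  expect_equal(sample_direction(1, "omnidirectional")$D, 1)
  expect_equal(sample_direction(5, "omnidirectional")$D, rep(1, 5))
  # axial coordinate choice is uniform (chi-square over many draws)
  set.seed(2)
  picks <- replicate(10000, which(sample_direction(5, "axial")$D == 1))
  expect_gt(stats::chisq.test(tabulate(picks, 5))$p.value, 0.001)
})

test_that("guided foraging moves to the target at a = 0 and accepts greedily", {
  cfg <- aha_config(n_birds = 3, dim = 4, lower = -5, upper = 5,
                    max_iter = 10, seed = 3)
  st <- with_seed(3, initialize_swarm(cfg, sphere))
  omni <- sample_direction(4, "omnidirectional")
  tar <- histofuse:::choose_target(st, 1)
  st1 <- with_seed(4, guided_forage(st, 1, sphere, a = 0, direction = omni))
  # candidate was exactly X_tar; accepted only if strictly better
  if (st$fitness[tar] > st$fitness[1]) {
    expect_equal(st1$positions[1, ], st$positions[tar, ])
  } else {
    expect_equal(st1$positions[1, ], st$positions[1, ])
  }
  # a worse candidate never displaces the incumbent
  st2 <- with_seed(5, guided_forage(st, 2, function(x) sphere(x) - 1e6))
  expect_equal(st2$positions[2, ], st$positions[2, ])
  expect_equal(st2$fitness[2], st$fitness[2])
  # visit bookkeeping: +1 toward others, reset toward the target
  expect_equal(st1$visit_table[1, tar], 0)
  others <- setdiff(1:3, c(1, tar))
  expect_true(all(st1$visit_table[1, others] ==
                    st$visit_table[1, others] + 1))
})

test_that("territorial foraging is a no-op at b = 0 and at the origin", {
  cfg <- aha_config(n_birds = 2, dim = 3, lower = -5, upper = 5,
                    max_iter = 10, seed = 6)
  st <- with_seed(6, initialize_swarm(cfg, sphere))
  st1 <- with_seed(7, territorial_forage(st, 1, sphere, b = 0))
  expect_equal(st1$positions[1, ], st$positions[1, ])
  # X_i = 0: candidate equals X_i regardless of b (multiplicative form)
  st$positions[1, ] <- c(0, 0, 0)
  st$fitness[1] <- sphere(c(0, 0, 0))
  st2 <- with_seed(8, territorial_forage(st, 1, sphere, b = 2.7))
  expect_equal(st2$positions[1, ], c(0, 0, 0))
})

test_that("migration re-seeds the worst source inside the box, keeping the best", {
  cfg <- aha_config(n_birds = 2, dim = 2, lower = -4, upper = 4,
                    max_iter = 10, seed = 9)
  st <- with_seed(9, initialize_swarm(cfg, sphere))
  st$positions[1, ] <- c(0, 0); st$fitness[1] <- 0       # at optimum
  st$positions[2, ] <- c(3, 3); st$fitness[2] <- -18     # worst
  st$best_position <- c(0, 0); st$best_fitness <- 0
  st1 <- with_seed(10, migration_forage(st, sphere))
  expect_equal(st1$positions[1, ], c(0, 0))  # optimum untouched
  expect_false(identical(st1$positions[2, ], c(3, 3)))
  expect_true(all(st1$positions[2, ] >= -4 & st1$positions[2, ] <= 4))
  expect_equal(st1$best_fitness, 0)
})

test_that("the optimizer finds 1-D and 2-D closed-form optima across seeds", {
  best1 <- vapply(1:10, function(s) {
    run_aha(quadratic_1d, aha_config(dim = 1, lower = 0, upper = 10,
                                     max_iter = 200, seed = s))$best_position
  }, numeric(1))
  expect_true(sum(abs(best1 - 3) <= 0.05) >= 9)

  best2 <- vapply(1:10, function(s) {
    run_aha(sphere, aha_config(dim = 2, lower = -5, upper = 5,
                               max_iter = 500, seed = s))$best_fitness
  }, numeric(1))
  expect_true(sum(best2 >= -1e-2) >= 9)
})

test_that("traces are monotone and invariants hold for every seed", {
  for (s in 1:6) {
    cfg <- aha_config(n_birds = 8, dim = 3, lower = -2, upper = 2,
                      max_iter = 60, seed = s)
    res <- run_aha(sphere, cfg)
    expect_false(is.unsorted(res$trace))
    expect_equal(res$best_fitness, max(res$trace))
    expect_true(all(res$state$positions >= -2 &
                      res$state$positions <= 2))
    vt <- res$state$visit_table
    expect_true(all(is.na(diag(vt))))
    expect_true(all(vt[row(vt) != col(vt)] >= 0))
    expect_lte(res$evaluations, (cfg$max_iter + 1) * cfg$n_birds +
                 cfg$max_iter %/% cfg$migration_period)
    expect_identical(res$trace,
                     run_aha(sphere, cfg)$trace)  # seed determinism
  }
  expect_error(run_aha(function(x) NaN,
                       aha_config(dim = 1, lower = 0, upper = 1,
                                  max_iter = 2, seed = 1)),
               "non-finite")
})

test_that("cd_fitness equals the brute-force centroid distance", {
  ft <- generate_feature_table(
    synthetic_feature_config(200, 30, 5, effect_size = 2, seed = 13))
  full <- seq_len(30)
  expect_equal(cd_fitness(ft, full), brute_cd(ft$features, ft$labels, full))
  some <- c(2, 9, 17)
  expect_equal(cd_fitness(ft, some), brute_cd(ft$features, ft$labels, some))
  expect_equal(cd_fitness(ft, integer(0)), 0)
  # identical class means give 0 (constant features)
  const <- feature_table(matrix(1, 40, 3),
                         rep(c("healthy", "OSCC"), each = 20))
  expect_equal(cd_fitness(const, 1:3), 0)
  # a single column scores its own standardized gap
  one <- feature_table(matrix(c(rnorm(50), rnorm(50) + 1.5), ncol = 1),
                       rep(c("healthy", "OSCC"), each = 50))
  expect_equal(cd_fitness(one, 1),
               brute_cd(one$features, one$labels, 1))
})

test_that("select_features returns exactly k columns and the full-mask shortcut", {
  ft <- generate_feature_table(
    synthetic_feature_config(100, 40, 5, effect_size = 3, seed = 17))
  m <- select_features(ft, 7, max_iter = 50, seed = 1)
  expect_s3_class(m, "selection_mask")
  expect_equal(m$k, 7)
  expect_length(m$indices, 7)
  full <- select_features(ft, 40)
  expect_equal(full$indices, 1:40)
  expect_equal(full$fitness, cd_fitness(ft, 1:40))
  expect_error(select_features(ft, 0), "k must")
  expect_error(select_features(ft, 41), "k must")
})

test_that("selection recovers planted informative columns", {
  ft <- generate_feature_table(
    synthetic_feature_config(400, 100, 10, effect_size = 2, seed = 108))
  m <- select_features(ft, 10, max_iter = 300, seed = 8)
  expect_gte(length(intersect(m$indices, attr(ft, "informative"))), 8)
})
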