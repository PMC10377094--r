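#' Artificial Hummingbird Algorithm configuration
#'
#' The AHA is a population metaheuristic in which each "hummingbird"
#' holds a candidate solution (a "food source") and forages by three
#' moves: guided foraging toward a target source chosen through a visit
#' table, territorial foraging around its own source, and migration of
#' the worst source to a fresh uniform draw. Direction of movement is
#' masked by axial, diagonal or omnidirectional flight patterns. The
#' algorithm maximizes the objective.
#'
#' @param n_birds population size (default 25).
#' @param dim search-space dimension.
#' @param lower,upper bound vectors (scalars are recycled); must satisfy
#'   `lower < upper` elementwise and be finite.
#' @param max_iter iteration budget (the field default for long runs is
#'   2500; pick per problem).
#' @param migration_period run a migration step every this many
#'   iterations; defaults to `2 * n_birds`.
#' @param seed integer seed; all randomness in one run flows from it.
#' @return an `aha_config` list.
#' @export
aha_config <- function(n_birds = 25L, dim, lower, upper,
                       max_iter = 500L, migration_period = NULL,
                       seed = NULL) {
  if (n_birds < 2) stop("n_birds must be at least 2", call. = FALSE)
  lower <- rep_len(as.double(lower), dim)
  upper <- rep_len(as.double(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite (bounded box required)", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("lower must be strictly below upper elementwise", call. = FALSE)
  }
  migration_period <- migration_period %||% (2L * n_birds)
  structure(list(n_birds = as.integer(n_birds), dim = as.integer(dim),
                 lower = lower, upper = upper,
                 max_iter = as.integer(max_iter),
                 migration_period = as.integer(migration_period),
                 seed = seed),
            class = "aha_config")
}

#' Initialize the swarm
#'
#' Positions are drawn uniformly in the bound box; the visit table
#' starts at zero off the diagonal (the diagonal is never consulted);
#' the objective is evaluated once per bird.
#'
#' @param cfg an [aha_config()].
#' @param objective function mapping a position vector to a finite
#'   scalar; maximized.
#' @return a `swarm_state` list with `positions`, `fitness`,
#'   `visit_table`, `best_position`, `best_fitness`, `evaluations`.
#' @export
initialize_swarm <- function(cfg, objective) {
  n <- cfg$n_birds; d <- cfg$dim
  X <- matrix(stats::runif(n * d), n, d)
  X <- sweep(sweep(X, 2, cfg$upper - cfg$lower, "*"), 2, cfg$lower, "+")
  fit <- apply(X, 1, function(x) eval_objective(objective, x))
  VT <- matrix(0, n, n)
  diag(VT) <- NA_real_
  b <- which.max(fit)
  structure(list(positions = X, fitness = fit, visit_table = VT,
                 best_position = X[b, ], best_fitness = fit[b],
                 evaluations = n),
            class = "swarm_state", lower = cfg$lower, upper = cfg$upper)
}

eval_objective <- function(objective, x, bird = NULL) {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f)) {
    stop("objective returned a non-finite value",
         if (!is.null(bird)) paste0(" for bird ", bird), call. = FALSE)
  }
  f
}

#' Sample a flight-direction mask
#'
#' Returns a 0/1 indicator over coordinates: axial flight sets exactly
#' one coordinate, omnidirectional flight sets all of them, and diagonal
#' flight sets a random subset of size between 2 and `d - 1`. The flight
#' pattern is drawn uniformly over the three modes; in dimensions where
#' diagonal flight is degenerate (`d <= 2`) it collapses to
#' omnidirectional, and for `d = 1` axial and omnidirectional coincide.
#'
#' @param d dimension.
#' @param mode optionally force `"axial"`, `"diagonal"` or
#'   `"omnidirectional"` instead of drawing the mode at random.
#' @return a `direction_vector`: list with `D` (0/1 vector) and `mode`.
#' @export
sample_direction <- function(d, mode = NULL) {
  if (d < 1) stop("d must be at least 1", call. = FALSE)
  if (is.null(mode)) {
    r <- stats::runif(1)
    mode <- if (r < 1 / 3) "axial" else if (r < 2 / 3) "diagonal" else "omnidirectional"
  }
  mode <- match.arg(mode, c("axial", "diagonal", "omnidirectional"))
  if (mode == "diagonal" && d <= 2) mode <- "omnidirectional"
  if (mode == "axial" && d == 1) mode <- "omnidirectional"
  D <- numeric(d)
  if (mode == "axial") {
    D[sample.int(d, 1)] <- 1
  } else if (mode == "diagonal") {
    # two-stage draw: a random upper limit ceil(r*(d-2)) + 1, then k
    # uniform up to it, which biases diagonal flights toward small
    # coordinate subsets
    up <- min(d - 1, ceiling(stats::runif(1) * (d - 2)) + 1)
    k <- if (up <= 2) 2L else sample(2:up, 1)
    D[sample.int(d, k)] <- 1
  } else {
    D[] <- 1
  }
  structure(list(D = D, mode = mode), class = "direction_vector")
}

# Guided-foraging target for bird i: the source with the highest visit
# count; ties broken by higher fitness, then lower index.
choose_target <- function(state, i) {
  visits <- state$visit_table[i, ]
  visits[i] <- -Inf
  cand <- which(visits == max(visits, na.rm = TRUE))
  if (length(cand) > 1) {
    cand <- cand[state$fitness[cand] == max(state$fitness[cand])]
  }
  cand[1]
}

# Visit bookkeeping after bird i forages: one more "iteration since
# visit" toward every other source, and a reset toward the source just
# visited (if any).
bump_visits <- function(state, i, visited = NULL) {
  state$visit_table[i, -i] <- state$visit_table[i, -i] + 1
  if (!is.null(visited)) state$visit_table[i, visited] <- 0
  state
}

# When bird i replaces its food source, every other bird's visit counter
# toward i jumps to its row maximum + 1: freshly improved sources become
# the highest-priority guided-foraging targets, which is how good
# solutions propagate through the swarm.
mark_improved <- function(state, i) {
  for (j in seq_len(nrow(state$visit_table))[-i]) {
    state$visit_table[j, i] <-
      max(state$visit_table[j, -j], na.rm = TRUE) + 1
  }
  state
}

# Bound handling: out-of-bound coordinates are re-drawn uniformly inside
# the box rather than clamped. Hard clamping parks coordinates exactly on
# the bounds, which are absorbing states for the multiplicative
# territorial move (a coordinate at 0 can never leave) and create rank
# ties at the upper bound that the strict greedy acceptance can never
# break; uniform resampling keeps positions in the box while preserving
# exploration.
keep_in_box <- function(x, lower, upper) {
  out <- x < lower | x > upper
  if (any(out)) {
    x[out] <- lower[out] + stats::runif(sum(out)) * (upper[out] - lower[out])
  }
  x
}

accept_if_better <- function(state, i, candidate, objective) {
  candidate <- keep_in_box(candidate, attr(state, "lower"),
                           attr(state, "upper"))
  f <- eval_objective(objective, candidate, bird = i)
  state$evaluations <- state$evaluations + 1L
  if (f > state$fitness[i]) {
    state$positions[i, ] <- candidate
    state$fitness[i] <- f
    if (f > state$best_fitness) {
      state$best_fitness <- f
      state$best_position <- candidate
    }
    state <- mark_improved(state, i)
  }
  state
}

#' Guided foraging step
#'
#' Bird `i` flies toward the target source `X_tar` picked from its visit
#' table: the candidate is
#' `V = X_tar + a * D * (X_i - X_tar)` with guiding factor
#' `a ~ N(0, 1)` and flight mask `D`. The move is accepted only if it
#' improves bird `i`'s fitness (greedy acceptance), and the visit table
#' is updated regardless.
#'
#' @param state a `swarm_state` (as produced inside [run_aha()]).
#' @param i bird index.
#' @param objective the objective function.
#' @param a,direction optional overrides of the random guiding factor
#'   and flight mask (used in tests).
#' @return the updated `swarm_state`.
#' @export
guided_forage <- function(state, i, objective, a = NULL, direction = NULL) {
  tar <- choose_target(state, i)
  d <- ncol(state$positions)
  a <- a %||% stats::rnorm(d)
  D <- (direction %||% sample_direction(d))$D
  xi <- state$positions[i, ]
  xt <- state$positions[tar, ]
  cand <- xt + a * D * (xi - xt)
  state <- accept_if_better(state, i, cand, objective)
  bump_visits(state, i, visited = tar)
}

#' Territorial foraging step
#'
#' Bird `i` explores around its own source:
#' `V = X_i + b * D * X_i` with territorial factor `b ~ N(0, 1)`,
#' greedy acceptance, bounds re-enforced.
#'
#' @inheritParams guided_forage
#' @param b optional override of the territorial factor.
#' @return the updated `swarm_state`.
#' @export
territorial_forage <- function(state, i, objective, b = NULL,
                               direction = NULL) {
  d <- ncol(state$positions)
  b <- b %||% stats::rnorm(d)
  D <- (direction %||% sample_direction(d))$D
  xi <- state$positions[i, ]
  cand <- xi + b * D * xi
  state <- accept_if_better(state, i, cand, objective)
  bump_visits(state, i)
}

#' Migration step
#'
#' The worst-fitness source is abandoned: that bird is re-seeded
#' uniformly in the bound box and its visit-table row and column are
#' reset. The best-so-far record is untouched.
#'
#' @inheritParams guided_forage
#' @return the updated `swarm_state`.
#' @export
migration_forage <- function(state, objective) {
  w <- which.min(state$fitness)
  lower <- attr(state, "lower"); upper <- attr(state, "upper")
  state$positions[w, ] <- lower + stats::runif(length(lower)) * (upper - lower)
  state$fitness[w] <- eval_objective(objective, state$positions[w, ], bird = w)
  state$evaluations <- state$evaluations + 1L
  state$visit_table[w, -w] <- 0
  state <- mark_improved(state, w)  # fresh source: make it a priority target
  if (state$fitness[w] > state$best_fitness) {
    state$best_fitness <- state$fitness[w]
    state$best_position <- state$positions[w, ]
  }
  state
}

#' Run the Artificial Hummingbird Algorithm
#'
#' Maximizes `objective` over the bound box of `cfg`. Each iteration,
#' every bird performs guided foraging with probability 1/2 and
#' territorial foraging otherwise; every `migration_period` iterations
#' the worst source migrates. Greedy acceptance plus best-so-far
#' bookkeeping make the returned trace monotone non-decreasing.
#'
#' @param objective function of a `dim`-length vector returning a finite
#'   scalar to maximize.
#' @param cfg an [aha_config()].
#' @return an `aha_result`: list with `best_position`, `best_fitness`,
#'   `trace` (per-iteration best fitness), `evaluations`, and the final
#'   `state`.
#' @export
run_aha <- function(objective, cfg) {
  stopifnot(inherits(cfg, "aha_config"))
  with_seed(cfg$seed, {
    state <- initialize_swarm(cfg, objective)
    trace <- numeric(cfg$max_iter)
    for (t in seq_len(cfg$max_iter)) {
      for (i in seq_len(cfg$n_birds)) {
        state <- if (stats::runif(1) < 0.5) {
          guided_forage(state, i, objective)
        } else {
          territorial_forage(state, i, objective)
        }
      }
      if (t %% cfg$migration_period == 0) {
        state <- migration_forage(state, objective)
      }
      trace[t] <- state$best_fitness
    }
    structure(list(best_position = state$best_position,
                   best_fitness = state$best_fitness,
                   trace = trace, evaluations = state$evaluations,
                   state = state),
              class = "aha_result")
  })
}

#' @export
print.aha_result <- function(x, ...) {
  cat(sprintf("<aha_result> best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  invisible(x)
}

# Per-column standardized class-mean gaps: (mean_OSCC - mean_healthy)
# divided by the pooled within-class standard deviation. Columns with
# zero pooled spread contribute a zero gap.
standardized_gaps <- function(table) {
  x <- table$features
  g2 <- table$labels == levels(table$labels)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  if (n1 == 0 || n2 == 0) {
    stop("feature table must contain both classes", call. = FALSE)
  }
  m1 <- colMeans(x[!g2, , drop = FALSE])
  m2 <- colMeans(x[g2, , drop = FALSE])
  v1 <- if (n1 > 1) apply(x[!g2, , drop = FALSE], 2, stats::var) else 0
  v2 <- if (n2 > 1) apply(x[g2, , drop = FALSE], 2, stats::var) else 0
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / max(n1 + n2 - 2, 1))
  gap <- (m2 - m1) / pooled
  gap[!is.finite(gap)] <- 0
  gap
}

#' Cartesian-distance fitness of a feature subset
#'
#' The selection wrapper's objective: the Euclidean (Cartesian) distance
#' between the two class-centroid vectors restricted to the selected
#' columns, computed on per-column standardized features (pooled
#' within-class standard deviation), so a single column with
#' standardized gap `delta` scores exactly `delta`. An empty mask scores
#' 0 by convention.
#'
#' @param table a [feature_table()] containing both classes.
#' @param mask a [selection_mask()], integer index vector, or logical
#'   indicator over columns.
#' @return a non-negative scalar.
#' @export
cd_fitness <- function(table, mask) {
  idx <- if (inherits(mask, "selection_mask")) {
    mask$indices
  } else if (is.logical(mask)) {
    which(mask)
  } else {
    as.integer(mask)
  }
  if (length(idx) == 0) return(0)
  gaps <- standardized_gaps(table)
  sqrt(sum(gaps[idx]^2))
}

#' Selection mask
#'
#' @param indices selected column indices (stored sorted).
#' @param n_features total number of columns in the parent table.
#' @param fitness optional Cartesian-distance fitness of the selection.
#' @return a `selection_mask` list.
#' @export
selection_mask <- function(indices, n_features, fitness = NA_real_) {
  structure(list(indices = sort(as.integer(indices)),
                 k = length(indices),
                 n_features = as.integer(n_features),
                 fitness = fitness),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> %d of %d columns, CD fitness %.4f\n",
              x$k, x$n_features, x$fitness))
  invisible(x)
}

#' AHA-based feature selection with Cartesian-distance fitness
#'
#' Wraps [run_aha()] around a continuous relaxation of subset selection:
#' each bird holds a score vector in `[0, 1]^d`, a candidate subset is
#' the `k` highest-scoring coordinates (so the retained count is exactly
#' `k` by construction), and the fitness is the standardized
#' class-centroid distance over that subset. The per-column gaps are
#' precomputed once, which makes each fitness evaluation O(d log d).
#'
#' @param table a [feature_table()] with both classes present.
#' @param k number of columns to retain, in `[1, n_features]`.
#' @param cfg optional [aha_config()]; defaults to 25 birds over
#'   `[0, 1]^d`. `dim`, `lower` and `upper` are forced to match the
#'   table.
#' @param max_iter,seed convenience overrides applied to the default
#'   configuration.
#' @return a [selection_mask()] with the AHA convergence trace in
#'   attribute `trace`.
#' @export
select_features <- function(table, k, cfg = NULL, max_iter = 300L,
                            seed = NULL) {
  d <- ncol(table$features)
  if (k < 1 || k > d) {
    stop("k must lie in [1, n_features]", call. = FALSE)
  }
  gaps2 <- standardized_gaps(table)^2
  if (k == d) {
    return(selection_mask(seq_len(d), d, fitness = sqrt(sum(gaps2))))
  }
  if (is.null(cfg)) {
    cfg <- aha_config(n_birds = 25L, dim = d, lower = 0, upper = 1,
                      max_iter = max_iter, seed = seed)
  } else {
    cfg$dim <- d
    cfg$lower <- rep_len(0, d)
    cfg$upper <- rep_len(1, d)
    if (!is.null(seed)) cfg$seed <- seed
  }
  objective <- function(pos) {
    sqrt(sum(gaps2[order(pos, decreasing = TRUE)[seq_len(k)]]))
  }
  res <- run_aha(objective, cfg)
  idx <- order(res$best_position, decreasing = TRUE)[seq_len(k)]
  out <- selection_mask(idx, d, fitness = res$best_fitness)
  attr(out, "trace") <- res$trace
  out
}
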