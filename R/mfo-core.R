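# Continuous Moth-Flame Optimization (MFO).
#
# Moths are search agents; flames are an elitist, sorted memory of the best
# positions seen so far. Each iteration every moth flies a logarithmic spiral
# around a flame, the flame count shrinks linearly so the swarm concentrates
# on the best flame by the final iteration, and the flame archive is rebuilt
# as the best N of (previous flames, current moths), which guarantees the
# best-so-far fitness never degrades.

#' Define a box-bounded search space
#'
#' @param lower,upper Numeric vectors of equal length giving per-dimension
#'   bounds. Scalars are recycled against the other argument.
#' @param dims Optional dimensionality; required when both bounds are scalar.
#' @return An object of class `mfo_search_space` with fields `dims`, `lower`,
#'   `upper`.
#' @examples
#' mfo_search_space(-10, 10, dims = 5)
#' @export
mfo_search_space <- function(lower, upper, dims = NULL) {
  if (is.null(dims)) dims <- max(length(lower), length(upper))
  stopifnot(dims >= 1)
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("search-space bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("each lower bound must be strictly below its upper bound", call. = FALSE)
  }
  structure(list(dims = dims, lower = lower, upper = upper),
            class = "mfo_search_space")
}

#' MFO run configuration
#'
#' @param n_moths Population size N (>= 2).
#' @param max_iterations Iteration budget T (>= 1).
#' @param spiral_b Logarithmic-spiral shape constant b; default 1.
#' @param seed Integer seed; the whole run consumes a single seeded stream,
#'   so identical `(config, space)` pairs reproduce bit-identical results.
#' @return An object of class `mfo_config`.
#' @export
mfo_config <- function(n_moths = 20, max_iterations = 100, spiral_b = 1,
                       seed = 1L) {
  stopifnot(n_moths >= 2, max_iterations >= 1, is.finite(spiral_b))
  structure(list(n_moths = as.integer(n_moths),
                 max_iterations = as.integer(max_iterations),
                 spiral_b = as.numeric(spiral_b),
                 seed = as.integer(seed)),
            class = "mfo_config")
}

#' Initialize a moth population uniformly inside the bounds
#'
#' Each coordinate is `rand * (upper - lower) + lower`, with uniform draws
#' taken from the current RNG stream in moth-major order (moth 1 dimension
#' 1..D, then moth 2, ...).
#'
#' @param space An [mfo_search_space()].
#' @param n Number of moths (>= 2).
#' @return List with `positions` (n x D matrix) and `fitness`
#'   (length-n vector of `NA`, not yet evaluated).
#' @export
mfo_init_population <- function(space, n) {
  stopifnot(inherits(space, "mfo_search_space"), n >= 2)
  d <- space$dims
  u <- matrix(stats::runif(n * d), nrow = n, ncol = d, byrow = TRUE)
  pos <- sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
  list(positions = pos, fitness = rep(NA_real_, n))
}

# round-half-away-from-zero; base round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Number of active flames at an iteration
#'
#' The flame count shrinks linearly from N at the first iteration to exactly 1
#' at the last: `round(N - t * (N - 1) / T)`, rounding halves away from zero
#' and clamping at 1.
#'
#' @param t Iteration index in `1..t_max`.
#' @param n Population size N.
#' @param t_max Iteration budget T.
#' @return Integer flame count in `[1, N]`.
#' @examples
#' mfo_flame_count(1, 10, 100)  # 10
#' mfo_flame_count(50, 10, 100) # 6
#' mfo_flame_count(100, 10, 100) # 1
#' @export
mfo_flame_count <- function(t, n, t_max) {
  stopifnot(n >= 2)
  if (t < 1 || t > t_max) {
    stop("iteration index t must lie in [1, t_max]", call. = FALSE)
  }
  r <- round_half_away(n - t * (n - 1) / t_max)
  as.integer(min(max(r, 1), n))
}

#' Construct the flame archive for an iteration
#'
#' At `t = 1` the flames are the moths sorted ascending by fitness. For
#' `t > 1` the previous flames and the freshly evaluated moths are pooled
#' (2N candidates) and the best N are retained, sorted ascending. Sorting is
#' stable, so ties keep first-seen order, and the best fitness can never
#' increase between iterations (elitism).
#'
#' @param flames Previous archive (list with `flames`, `flame_fitness`) or
#'   `NULL` at the first iteration.
#' @param moths Evaluated population (list with `positions`, `fitness`).
#' @param t Iteration index.
#' @return List with `flames` (N x D matrix, best first) and `flame_fitness`.
#' @export
mfo_construct_flames <- function(flames, moths, t) {
  fit <- moths$fitness
  if (anyNA(fit) || !all(is.finite(fit))) {
    stop("moth fitness contains NA/NaN; evaluate the population first",
         call. = FALSE)
  }
  n <- length(fit)
  if (t == 1 || is.null(flames)) {
    ord <- order(fit)
    return(list(flames = moths$positions[ord, , drop = FALSE],
                flame_fitness = fit[ord]))
  }
  dual_pop <- rbind(flames$flames, moths$positions)
  dual_fit <- c(flames$flame_fitness, fit)
  ord <- order(dual_fit)[seq_len(n)]
  list(flames = dual_pop[ord, , drop = FALSE], flame_fitness = dual_fit[ord])
}

#' Spiral coefficients for an iteration
#'
#' Computes the adaptive lower bound `a = -1 + t * (-1 / t_max)` (so `a`
#' moves from near -1 to -2 over the run) and draws one spiral parameter
#' `k = (a - 1) * rand + 1`, so `k` spans `[a, 1]`.
#'
#' @param t Iteration index; `t_max` the budget; `b` the spiral constant.
#' @return List with `a`, `k`, `b`.
#' @export
mfo_spiral_terms <- function(t, t_max, b = 1) {
  if (t < 1 || t > t_max) {
    stop("iteration index t must lie in [1, t_max]", call. = FALSE)
  }
  a <- -1 + t * (-1 / t_max)
  k <- (a - 1) * stats::runif(1) + 1
  list(a = a, k = k, b = b)
}

# One spiral flight of the whole population. k is drawn per moth per
# dimension (moth-major order, matching the documented stream contract).
# Moth i <= r spirals around flame i; moth i > r around flame r.
mfo_update_positions <- function(moths, flames, r, t, cfg, space) {
  n <- nrow(moths$positions)
  d <- ncol(moths$positions)
  if (r > nrow(flames$flames)) {
    stop("flame count exceeds the number of flames", call. = FALSE)
  }
  a <- -1 + t * (-1 / cfg$max_iterations)
  k <- matrix((a - 1) * stats::runif(n * d) + 1, nrow = n, ncol = d,
              byrow = TRUE)
  target_idx <- pmin(seq_len(n), r)
  target <- flames$flames[target_idx, , drop = FALSE]
  dist <- abs(target - moths$positions)
  newpos <- dist * exp(cfg$spiral_b * k) * cos(2 * pi * k) + target
  newpos <- pmin(pmax(newpos, matrix(space$lower, n, d, byrow = TRUE)),
                 matrix(space$upper, n, d, byrow = TRUE))
  list(positions = newpos, fitness = rep(NA_real_, n))
}

#' Run Moth-Flame Optimization
#'
#' Minimizes `objective` over a box-bounded space. Each iteration evaluates
#' the population, folds it into the elitist flame archive, shrinks the
#' active flame count, and moves every moth along a logarithmic spiral
#' around its flame. The best flame fitness is recorded per iteration and is
#' non-increasing by construction.
#'
#' @param objective Function mapping a position vector to a finite scalar to
#'   minimize. To maximize a score, pass its negation.
#' @param space An [mfo_search_space()].
#' @param config An [mfo_config()].
#' @return An object of class `mfo_result` with `best_position`,
#'   `best_fitness`, `trace` (per-iteration best flame fitness),
#'   `n_evaluations`, and a `config` echo. Use [tidy()][generics::tidy] for
#'   the trace as a tibble and `autoplot()` for a convergence plot.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- mfo_optimize(sphere, mfo_search_space(-10, 10, dims = 2),
#'                     mfo_config(n_moths = 10, max_iterations = 50, seed = 1))
#' res$best_fitness
#' @export
mfo_optimize <- function(objective, space, config = mfo_config()) {
  stopifnot(inherits(space, "mfo_search_space"), inherits(config, "mfo_config"))
  n <- config$n_moths
  t_max <- config$max_iterations
  trace <- numeric(t_max)
  n_eval <- 0L
  withr::with_seed(config$seed, {
    moths <- mfo_init_population(space, n)
    flames <- NULL
    for (t in seq_len(t_max)) {
      fit <- vapply(seq_len(n), function(i) {
        v <- tryCatch(objective(moths$positions[i, ]), error = function(e) {
          stop(sprintf("objective failed at iteration %d, moth %d: %s",
                       t, i, conditionMessage(e)), call. = FALSE)
        })
        as.numeric(v)
      }, numeric(1))
      n_eval <- n_eval + n
      moths$fitness <- fit
      flames <- mfo_construct_flames(flames, moths, t)
      trace[t] <- flames$flame_fitness[1]
      r <- mfo_flame_count(t, n, t_max)
      moths <- mfo_update_positions(moths, flames, r, t, config, space)
    }
    structure(list(best_position = as.numeric(flames$flames[1, ]),
                   best_fitness = flames$flame_fitness[1],
                   trace = trace,
                   n_evaluations = n_eval,
                   config = config,
                   space = space),
              class = "mfo_result")
  })
}

#' @export
print.mfo_result <- function(x, ...) {
  cat("<mfo_result>\n")
  cat(sprintf("  dims: %d  moths: %d  iterations: %d  seed: %d\n",
              x$space$dims, x$config$n_moths, x$config$max_iterations,
              x$config$seed))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the convergence trace of an MFO run
#'
#' @param x An `mfo_result`.
#' @param ... Unused.
#' @return Tibble with columns `iteration` and `best_fitness`.
#' @method tidy mfo_result
#' @export
tidy.mfo_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), best_fitness = x$trace)
}

#' One-row summary of an MFO run
#'
#' @param x An `mfo_result`.
#' @param ... Unused.
#' @method glance mfo_result
#' @export
glance.mfo_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 iterations = x$config$max_iterations,
                 n_moths = x$config$n_moths,
                 n_evaluations = x$n_evaluations,
                 seed = x$config$seed)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Convergence plot for an MFO run
#'
#' @param object An `mfo_result`.
#' @param ... Unused.
#' @method autoplot mfo_result
#' @export
autoplot.mfo_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Best flame fitness",
                  title = "MFO convergence") +
    ggplot2::theme_minimal()
}
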