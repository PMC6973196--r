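#' Hyperparameter search space for each kernel model
#'
#' Builds the bounded, scale-annotated search space the swarm explores.
#' Dimensions per model:
#' \describe{
#'   \item{linear}{`log2C` (D = 1)}
#'   \item{gaussian}{`log2C, log2gamma` (D = 2)}
#'   \item{polynomial}{`log2C, log2eta, delta, d` (D = 4)}
#'   \item{lgp}{`log2C, beta1, beta2, beta3, log2gamma, log2eta, delta, d` (D = 8)}
#' }
#' Bounds: `-5 <= log2C <= 15`, `-15 <= log2gamma, log2eta <= 3`,
#' `0 <= delta <= 5`, `2 <= d <= 5`, each beta raw in `[0, 1]` and decoded
#' jointly onto the simplex.
#'
#' @param model_kind One of `"linear"`, `"polynomial"`, `"gaussian"`,
#'   `"lgp"` (single-letter aliases `"L"`, `"P"`, `"G"`, `"LGP"` accepted).
#' @return A `search_space`: data frame with columns `name`, `lower`,
#'   `upper`, `scale` (one of `linear`, `log2`, `integer`, `simplex`), plus
#'   attribute `model_kind`.
#' @export
build_search_space <- function(model_kind) {
  kind <- switch(toupper(model_kind),
    L = , LINEAR = "linear",
    P = , POLYNOMIAL = "polynomial",
    G = , GAUSSIAN = "gaussian",
    LGP = "lgp",
    stop(sprintf("unknown model kind '%s'", model_kind))
  )
  dim_row <- function(name, lower, upper, scale) {
    data.frame(name = name, lower = lower, upper = upper, scale = scale)
  }
  log2C <- dim_row("log2C", -5, 15, "log2")
  log2gamma <- dim_row("log2gamma", -15, 3, "log2")
  log2eta <- dim_row("log2eta", -15, 3, "log2")
  delta <- dim_row("delta", 0, 5, "linear")
  d <- dim_row("d", 2, 5, "integer")
  betas <- do.call(rbind, lapply(1:3, function(i) {
    dim_row(paste0("beta", i), 0, 1, "simplex")
  }))
  space <- switch(kind,
    linear = log2C,
    gaussian = rbind(log2C, log2gamma),
    polynomial = rbind(log2C, log2eta, delta, d),
    lgp = rbind(log2C, betas, log2gamma, log2eta, delta, d)
  )
  rownames(space) <- NULL
  structure(space, model_kind = kind, class = c("search_space", "data.frame"))
}

#' Decode a raw particle position into SVM parameters
#'
#' Applies each dimension's scale: `log2` dimensions are exponentiated
#' (`value = 2^raw`), `integer` dimensions rounded to the nearest in-range
#' integer, and the simplex group is renormalized to sum to 1.
#'
#' @param space A `search_space`.
#' @param raw Numeric vector of raw positions, within bounds.
#' @return List with `C` (penalty) and `params` (a [kernel_params()]).
#' @export
decode_position <- function(space, raw) {
  if (length(raw) != nrow(space)) {
    stop(sprintf("position has %d dims, space has %d", length(raw), nrow(space)))
  }
  if (any(raw < space$lower - 1e-9) || any(raw > space$upper + 1e-9)) {
    stop("raw position out of bounds; clamp before decoding")
  }
  kind <- attr(space, "model_kind")
  val <- function(nm) raw[match(nm, space$name)]
  C <- 2^val("log2C")
  params <- switch(kind,
    linear = kernel_params("linear"),
    gaussian = kernel_params("gaussian", gamma = 2^val("log2gamma")),
    polynomial = kernel_params("polynomial",
      eta = 2^val("log2eta"), delta = val("delta"),
      degree = pmin(5, pmax(2, round(val("d"))))
    ),
    lgp = {
      b <- raw[space$scale == "simplex"]
      if (sum(b) < 1e-6) stop("degenerate simplex group (sum ~ 0)")
      kernel_params("lgp",
        beta = b / sum(b),
        gamma = 2^val("log2gamma"),
        eta = 2^val("log2eta"), delta = val("delta"),
        degree = pmin(5, pmax(2, round(val("d"))))
      )
    }
  )
  list(C = C, params = params)
}

#' Swarm configuration
#'
#' Canonical particle-swarm settings: swarm size defaults to 10 x D
#' (a standard heuristic for population sizing), inertia weight `w = 1`,
#' cognitive and social learning factors `c1 = c2 = 2`, 50 iterations.
#'
#' @param D Search-space dimension (used for the default swarm size).
#' @param n_particles Swarm size; default `10 * D`.
#' @param max_iters Number of velocity/position updates, default 50.
#' @param w Inertia weight, default 1.
#' @param c1,c2 Cognitive and social learning factors, default 2.
#' @param seed Integer seed for initialization and the stochastic updates.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(D, n_particles = 10 * D, max_iters = 50,
                         w = 1, c1 = 2, c2 = 2, seed = 1) {
  stopifnot(n_particles >= 2, max_iters >= 1)
  structure(
    list(n_particles = as.integer(n_particles), max_iters = as.integer(max_iters),
         w = w, c1 = c1, c2 = c2, seed = as.integer(seed)),
    class = "swarm_config"
  )
}

#' Particle swarm optimization over a search space
#'
#' Maximizes `fitness` with the canonical update
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, `x <- x + v`,
#' followed by clamping to the bounds. Velocities are clamped per dimension
#' to half the bound width (with `w = 1` an unclamped swarm can diverge);
#' a position component hitting a bound has its velocity zeroed. Positions
#' start uniform in the bounds with zero velocities. A particle whose
#' simplex group collapses below 1e-6 total mass has those components
#' re-drawn uniformly. Fitness evaluating to `NaN` is treated as `-Inf`
#' with a warning. Every particle is evaluated at initialization and at
#' every iteration, so the total number of evaluations is
#' `n_particles * (max_iters + 1)`.
#'
#' @param space A `search_space`.
#' @param fitness Function of `(C, params)` returning a scalar to maximize;
#'   must be deterministic in its arguments (fix CV folds beforehand).
#' @param config A [swarm_config()].
#' @return List with `best_C`, `best_params`, `best_fitness`,
#'   `best_position` (raw), `history` (gbest fitness after initialization
#'   and after each iteration; non-decreasing), and `n_evals`.
#' @export
pso_optimize <- function(space, fitness, config) {
  D <- nrow(space)
  lo <- space$lower
  hi <- space$upper
  width <- hi - lo
  vmax <- 0.5 * width
  simplex <- space$scale == "simplex"
  n <- config$n_particles

  evaluate <- function(pos) {
    dec <- decode_position(space, pos)
    f <- fitness(dec$C, dec$params)
    if (is.na(f) || is.nan(f)) {
      warning("fitness returned NaN; treating as -Inf")
      f <- -Inf
    }
    f
  }

  withr::with_seed(config$seed, {
    X <- matrix(runif(n * D, rep(lo, each = n), rep(hi, each = n)), n, D)
    if (any(simplex)) {
      bad <- rowSums(X[, simplex, drop = FALSE]) < 1e-6
      X[bad, simplex] <- runif(sum(bad) * sum(simplex))
    }
    V <- matrix(0, n, D)
    fit_vals <- apply(X, 1, evaluate)
    pbest <- X
    pbest_fit <- fit_vals
    g <- which.max(pbest_fit)
    gbest <- pbest[g, ]
    gbest_fit <- pbest_fit[g]
    history <- numeric(config$max_iters + 1)
    history[1] <- gbest_fit
    n_evals <- n

    for (iter in seq_len(config$max_iters)) {
      r1 <- matrix(runif(n * D), n, D)
      r2 <- matrix(runif(n * D), n, D)
      V <- config$w * V +
        config$c1 * r1 * (pbest - X) +
        config$c2 * r2 * (sweep(-X, 2, gbest, "+"))
      V <- pmin(pmax(V, rep(-vmax, each = n)), rep(vmax, each = n))
      X <- X + V
      lo_hit <- sweep(X, 2, lo, "<")
      hi_hit <- sweep(X, 2, hi, ">")
      X <- pmin(pmax(X, rep(lo, each = n)), rep(hi, each = n))
      V[lo_hit | hi_hit] <- 0
      if (any(simplex)) {
        bad <- rowSums(X[, simplex, drop = FALSE]) < 1e-6
        if (any(bad)) X[bad, simplex] <- runif(sum(bad) * sum(simplex))
      }
      fit_vals <- apply(X, 1, evaluate)
      n_evals <- n_evals + n
      improved <- fit_vals > pbest_fit
      pbest[improved, ] <- X[improved, , drop = FALSE]
      pbest_fit[improved] <- fit_vals[improved]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest <- pbest[g, ]
        gbest_fit <- pbest_fit[g]
      }
      history[iter + 1] <- gbest_fit
    }

    dec <- decode_position(space, gbest)
    list(
      best_C = dec$C,
      best_params = dec$params,
      best_fitness = gbest_fit,
      best_position = gbest,
      history = history,
      n_evals = n_evals
    )
  })
}
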