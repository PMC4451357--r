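# Particle swarm optimization.
#
# Standard global-best PSO with inertia w and cognitive/social weights
# c1/c2, positions clamped to the box and velocities to the box span. Used
# to tune kernel hyperparameters (fitness = mean inner-CV accuracy, with C
# and sigma searched on a log2 scale), but exposed as a generic minimizer so
# it can be validated on analytic test functions.

#' PSO configuration
#'
#' @param swarm number of particles (>= 2).
#' @param iterations iteration budget (>= 1).
#' @param w inertia weight.
#' @param c1,c2 cognitive and social acceleration weights. The defaults
#'   (w = 0.729, c1 = c2 = 1.49445) are Clerc's constriction values.
#' @param seed RNG seed.
#' @return an object of class `pso_config`.
#' @export
pso_config <- function(swarm = 20L, iterations = 50L, w = 0.729,
                       c1 = 1.49445, c2 = 1.49445, seed = 1L) {
  check_scalar_number(swarm, "swarm", lower = 2, integer = TRUE)
  check_scalar_number(iterations, "iterations", lower = 1, integer = TRUE)
  check_scalar_number(w, "w")
  check_scalar_number(c1, "c1"); check_scalar_number(c2, "c2")
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(swarm = as.integer(swarm), iterations = as.integer(iterations),
                 w = w, c1 = c1, c2 = c2, seed = as.integer(seed)),
            class = "pso_config")
}

#' Minimize a function over a box by particle swarm
#'
#' @param fn objective taking a numeric vector, returning a scalar to
#'   minimize.
#' @param lower,upper finite box bounds (equal length, ordered).
#' @param config a [pso_config()].
#' @return list with `par` (global best position), `value`, and `trace`
#'   (best value after each iteration; non-increasing).
#' @export
pso_optimize <- function(fn, lower, upper, config = pso_config()) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!length(lower) || length(lower) != length(upper))
    stop_eb("lower and upper must be nonempty and of equal length")
  if (!all(is.finite(c(lower, upper))) || any(lower > upper))
    stop_eb("bounds must be finite with lower <= upper")
  d <- length(lower)
  span <- upper - lower

  restore <- push_seed(config$seed)
  on.exit(restore())

  pos <- matrix(stats::runif(config$swarm * d, lower, upper),
                nrow = config$swarm, byrow = TRUE)
  vel <- matrix(stats::runif(config$swarm * d, -span, span),
                nrow = config$swarm, byrow = TRUE) * 0.1
  pbest <- pos
  pbest_val <- apply(pos, 1L, fn)
  g <- which.min(pbest_val)
  gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
  trace <- numeric(config$iterations)

  for (it in seq_len(config$iterations)) {
    r1 <- matrix(stats::runif(config$swarm * d), nrow = config$swarm)
    r2 <- matrix(stats::runif(config$swarm * d), nrow = config$swarm)
    vel <- config$w * vel +
      config$c1 * r1 * (pbest - pos) +
      config$c2 * r2 * (matrix(gbest, config$swarm, d, byrow = TRUE) - pos)
    vmax <- matrix(span, config$swarm, d, byrow = TRUE)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lower, config$swarm, d, byrow = TRUE)),
                matrix(upper, config$swarm, d, byrow = TRUE))
    vals <- apply(pos, 1L, fn)
    improved <- vals < pbest_val
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- vals[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
    }
    trace[it] <- gbest_val
  }
  list(par = gbest, value = gbest_val, trace = trace)
}

#' Tune kernel hyperparameters by PSO
#'
#' Fitness of a candidate is its mean stratified inner-CV accuracy of an
#' SMO-trained SVM on the supplied data (PSO minimizes 1 - accuracy). Search
#' space per kernel: `C` on log2 in [-5, 15]; additionally `sigma` on log2
#' in [-15, 3] (rbf) or `offset` in [0, 10] and `degree` in [2, 5] (rounded;
#' pol).
#'
#' @param x,y training features and 0/1 labels.
#' @param kind kernel kind.
#' @param config a [pso_config()].
#' @param inner_folds folds of the tuning CV (default 5).
#' @return the tuned [kernel_spec()], with attributes `fitness` (best mean
#'   inner-CV accuracy) and `trace`.
#' @export
pso_tune <- function(x, y, kind = c("linear", "rbf", "pol"),
                     config = pso_config(), inner_folds = 5L) {
  kind <- match.arg(kind)
  x <- as.matrix(x); y <- as.integer(y)
  bounds <- switch(kind,
    linear = list(lower = -5, upper = 15),
    rbf    = list(lower = c(-5, -15), upper = c(15, 3)),
    pol    = list(lower = c(-5, 0, 2), upper = c(15, 10, 5)))
  par_to_spec <- function(p) {
    switch(kind,
      linear = kernel_spec("linear", C = 2^p[1L]),
      rbf    = kernel_spec("rbf", C = 2^p[1L], sigma = 2^p[2L]),
      pol    = kernel_spec("pol", C = 2^p[1L], offset = p[2L],
                           degree = round(p[3L])))
  }
  folds <- stratified_folds(y, k = inner_folds, seed = config$seed)
  fit <- function(p) {
    spec <- par_to_spec(p)
    acc <- vapply(seq_along(folds), function(f) {
      te <- folds[[f]]; tr <- setdiff(seq_along(y), te)
      m <- train_svm_smo(x[tr, , drop = FALSE], y[tr], spec,
                         max_passes = 5L, max_iter = 200L)
      mean(predict(m, x[te, , drop = FALSE]) == y[te])
    }, numeric(1L))
    1 - mean(acc)
  }
  res <- pso_optimize(fit, bounds$lower, bounds$upper, config)
  spec <- par_to_spec(res$par)
  attr(spec, "fitness") <- 1 - res$value
  attr(spec, "trace") <- 1 - res$trace
  spec
}
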