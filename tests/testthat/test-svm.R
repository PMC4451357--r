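# Kernels, SMO training, prediction, PSO, cross-validation.

test_that("kernel evaluations match their closed forms", {
  rbf <- kernel_spec("rbf", sigma = 1)
  expect_equal(kernel_eval(rbf, c(1, 2), c(1, 2)), 1)
  expect_equal(kernel_eval(rbf, c(1, 0), c(0, 0)), exp(-1))
  rbf2 <- kernel_spec("rbf", sigma = 2)
  expect_equal(kernel_eval(rbf2, c(3, 0), c(0, 4)), exp(-25 / 4))
  pol <- kernel_spec("pol", degree = 1, offset = 0)
  lin <- kernel_spec("linear")
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(kernel_eval(pol, x, y), kernel_eval(lin, x, y))
  pol3 <- kernel_spec("pol", degree = 3, offset = 2)
  expect_equal(kernel_eval(pol3, x, y), (sum(x * y) + 2)^3)
  expect_error(kernel_eval(lin, 1:3, 1:4), "dimension")
})

test_that("Gram matrices are symmetric, elementwise-consistent, and rbf is PSD in (0,1]", {
  set.seed(51)
  X <- matrix(rnorm(8 * 3), 8, 3)
  for (spec in list(kernel_spec("linear"), kernel_spec("rbf", sigma = 1.3),
                    kernel_spec("pol", degree = 2, offset = 1))) {
    G <- kernel_matrix(spec, X)
    expect_equal(G, t(G), tolerance = 1e-12)
    expect_equal(G[2, 5], kernel_eval(spec, X[2, ], X[5, ]), tolerance = 1e-12)
  }
  Gr <- kernel_matrix(kernel_spec("rbf", sigma = 1.3), X)
  expect_true(all(Gr > 0 & Gr <= 1))
  expect_gt(min(eigen(Gr, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("symmetric separable pair: boundary at zero, both points support vectors", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c(0L, 1L)
  m <- train_svm_smo(x, y, kernel_spec("linear", C = 1e3), scale = FALSE)
  expect_equal(nrow(m$sv_x), 2L)
  expect_equal(decision_values(m, matrix(0)), 0, tolerance = 1e-6)
  expect_equal(predict(m, x), y)
  expect_gt(decision_values(m, matrix(2)), 0)
  expect_lt(decision_values(m, matrix(-2)), 0)
})

test_that("SMO reaches the QP-oracle dual optimum and satisfies the dual constraints", {
  set.seed(52)
  x <- rbind(matrix(rnorm(3 * 2, mean = -1.2), ncol = 2),
             matrix(rnorm(3 * 2, mean = 1.2), ncol = 2))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  ys <- ifelse(y == 1L, 1, -1)
  for (spec in list(kernel_spec("linear", C = 2),
                    kernel_spec("rbf", C = 2, sigma = 2),
                    kernel_spec("pol", C = 2, degree = 2, offset = 1))) {
    m <- train_svm_smo(x, y, spec, tol = 1e-4, max_passes = 50,
                       max_iter = 5000, scale = FALSE)
    K <- kernel_matrix(spec, x)
    oracle <- qp_svm_oracle(K, ys, spec$C)
    expect_equal(m$dual_objective, oracle$objective, tolerance = 1e-4)
    expect_equal(dual_objective(K, ys, m$alpha), m$dual_objective,
                 tolerance = 1e-10)
    expect_lt(abs(sum(m$alpha * ys)), 1e-6)
    expect_true(all(m$alpha >= -1e-12 & m$alpha <= spec$C + 1e-12))
  }
})

test_that("prediction is label-antisymmetric and stable under duplicated non-support points", {
  set.seed(53)
  x <- rbind(matrix(rnorm(8 * 2, mean = -2), ncol = 2),
             matrix(rnorm(8 * 2, mean = 2), ncol = 2))
  y <- rep(c(0L, 1L), each = 8)
  spec <- kernel_spec("linear", C = 10)
  m <- train_svm_smo(x, y, spec, tol = 1e-4, max_passes = 30,
                     max_iter = 5000, scale = FALSE)
  expect_equal(predict(m, x), y)              # separable training set
  m_flip <- train_svm_smo(x, 1L - y, spec, tol = 1e-4, max_passes = 30,
                          max_iter = 5000, scale = FALSE)
  xt <- rbind(matrix(rnorm(5 * 2, mean = -2), ncol = 2),
              matrix(rnorm(5 * 2, mean = 2), ncol = 2))
  expect_equal(predict(m_flip, xt), 1L - predict(m, xt))
  # duplicating an interior (non-support) point leaves the (unique) decision
  # function unchanged up to solver tolerance
  far <- which(m$alpha < 1e-8)[1]
  x2 <- rbind(x, x[far, ]); y2 <- c(y, y[far])
  m_dup <- train_svm_smo(x2, y2, spec, tol = 1e-4, max_passes = 30,
                         max_iter = 5000, scale = FALSE)
  expect_equal(decision_values(m_dup, xt), decision_values(m, xt),
               tolerance = 0.05)
  expect_equal(predict(m_dup, xt), predict(m, xt))
  expect_error(train_svm_smo(cbind(c(1, NA)), c(0L, 1L)), "non-finite")
})

test_that("PSO: constant surface, sphere benchmark, determinism", {
  cfg <- pso_config(swarm = 20, iterations = 100, seed = 2)
  flat <- pso_optimize(function(p) 4.2, c(-1, -1), c(1, 1),
                       pso_config(swarm = 5, iterations = 5, seed = 1))
  expect_equal(flat$value, 4.2)
  expect_true(all(flat$par >= -1 & flat$par <= 1))
  sph <- pso_optimize(function(p) sum(p^2), c(-5, -5), c(5, 5), cfg)
  expect_lt(sph$value, 1e-3)
  expect_true(all(diff(sph$trace) <= 0))      # best-so-far never worsens
  sph2 <- pso_optimize(function(p) sum(p^2), c(-5, -5), c(5, 5), cfg)
  expect_identical(sph$par, sph2$par)
  expect_error(pso_optimize(function(p) 0, numeric(0), numeric(0)), "nonempty")
})

test_that("pso_tune returns an in-bounds spec of the requested family, deterministically", {
  set.seed(54)
  x <- rbind(matrix(rnorm(12 * 2, mean = -1.5), ncol = 2),
             matrix(rnorm(12 * 2, mean = 1.5), ncol = 2))
  y <- rep(c(0L, 1L), each = 12)
  cfg <- pso_config(swarm = 4, iterations = 3, seed = 7)
  s1 <- pso_tune(x, y, "rbf", cfg, inner_folds = 3)
  s2 <- pso_tune(x, y, "rbf", cfg, inner_folds = 3)
  expect_identical(unclass(s1)[c("C", "sigma")], unclass(s2)[c("C", "sigma")])
  expect_true(s1$C >= 2^-5 && s1$C <= 2^15)
  expect_true(s1$sigma >= 2^-15 && s1$sigma <= 2^3)
  expect_gte(attr(s1, "fitness"), 0.5)        # trivially separable data
  sp <- pso_tune(x, y, "pol", cfg, inner_folds = 3)
  expect_true(sp$degree %in% 2:5)
})

test_that("confusion metrics match their definitions", {
  m <- confusion_metrics(c(TP = 25, FP = 8, TN = 90, FN = 3))
  expect_equal(unname(round(m * 100, 2)),
               c(91.27, 89.29, 91.84, 75.76))
  # accuracy * N = TP + TN identity on random counts
  set.seed(55)
  for (i in 1:5) {
    cts <- c(TP = sample(0:50, 1), FP = sample(1:50, 1),
             TN = sample(1:50, 1), FN = sample(1:50, 1))
    mm <- confusion_metrics(cts)
    expect_equal(mm[["accuracy"]] * sum(cts), cts[["TP"]] + cts[["TN"]])
  }
})

test_that("stratified folds partition the data and keep both classes per fold", {
  y <- rep(c(0L, 1L), c(20, 8))
  folds <- stratified_folds(y, k = 4, seed = 3)
  expect_equal(sort(unlist(folds)), 1:28)
  for (f in folds) {
    expect_equal(sum(y[f] == 1L), 2L)
    expect_equal(sum(y[f] == 0L), 5L)
  }
  expect_error(stratified_folds(y, k = 10), "cannot stratify")
})

test_that("cross-validation: perfect separation gives 100% +/- 0 and runs are reproducible", {
  set.seed(56)
  x <- cbind(c(rnorm(20, -4), rnorm(10, 4)), rnorm(30))
  y <- rep(c(0L, 1L), c(20, 10))
  cv <- cross_validate(x, y, kernel_spec("linear", C = 10), k = 5, reps = 3,
                       seed = 11)
  expect_equal(cv$summary$mean, rep(100, 4))
  expect_equal(cv$summary$sd, rep(0, 4))
  expect_true(all(rowSums(cv$counts) == 30))
  cv2 <- cross_validate(x, y, kernel_spec("linear", C = 10), k = 5, reps = 1,
                        seed = 11)
  cv3 <- cross_validate(x, y, kernel_spec("linear", C = 10), k = 5, reps = 1,
                        seed = 11)
  expect_identical(cv2$counts, cv3$counts)
  expect_identical(cv2$metrics, cv3$metrics)
})

test_that("tuned cross-validation modes run at toy scale", {
  set.seed(57)
  x <- cbind(c(rnorm(12, -3), rnorm(12, 3)), rnorm(24))
  y <- rep(c(0L, 1L), each = 12)
  cfg <- pso_config(swarm = 8, iterations = 4, seed = 5)
  cv_once <- cross_validate(x, y, kernel_spec("rbf"), k = 3, reps = 1,
                            seed = 1, tune = "once", pso = cfg,
                            inner_folds = 3)
  expect_gte(cv_once$summary$mean[1], 80)
  cfg_small <- pso_config(swarm = 3, iterations = 2, seed = 5)
  cv_nested <- cross_validate(x, y, kernel_spec("linear"), k = 3, reps = 1,
                              seed = 1, tune = "nested", pso = cfg_small,
                              inner_folds = 3)
  expect_gte(cv_nested$summary$mean[1], 80)
})
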