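# Independent oracles and shared fixtures. Everything here is deliberately
# implemented by a different route than the package code it checks.

# Projected-gradient solver for the SVM dual:
#   max  sum(a) - 1/2 a' (yy' * K) a   s.t. 0 <= a <= C, sum(a * y) = 0
# Exact projection onto the box-hyperplane intersection by bisection on the
# dual multiplier. Only meant for tiny problems (<= 8 points).
qp_svm_oracle <- function(K, y, C, iters = 200000L) {
  n <- length(y)
  Q <- (y %o% y) * K
  L <- max(abs(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  step <- 1 / L
  project <- function(a) {
    f <- function(nu) sum(y * pmin(pmax(a - nu * y, 0), C))
    lo <- -1e6; hi <- 1e6
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a - ((lo + hi) / 2) * y, 0), C)
  }
  a <- project(rep(C / 2, n))
  for (i in seq_len(iters)) {
    g <- 1 - Q %*% a
    a_new <- project(a + step * as.vector(g))
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  list(alpha = a, objective = sum(a) - 0.5 * sum(a * (Q %*% a)))
}

dual_objective <- function(K, y, alpha) {
  sum(alpha) - 0.5 * sum(alpha * (((y %o% y) * K) %*% alpha))
}

# principal angles between the column spaces of two matrices
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(sv, -1), 1))
}

# small phantom cohort shared across tests
tiny_phantom <- function(shape = c(20, 20, 20), n_nc = 8, n_ad = 6,
                         noise_sd = 2, seed = 42, magnitudes = NULL) {
  regions <- default_test_regions(shape, magnitudes)
  generate_phantom(phantom_config(shape = shape, n_nc = n_nc, n_ad = n_ad,
                                  effect_regions = regions,
                                  noise_sd = noise_sd, seed = seed))
}

default_test_regions <- function(shape, magnitudes = NULL) {
  if (is.null(magnitudes)) magnitudes <- c(-40, -30)
  ctr <- floor((shape + 1) / 2)
  list(
    list(center = ctr, radius = 3, magnitude = magnitudes[1L]),
    list(center = ctr + c(2, 1, -1), radius = 2, magnitude = magnitudes[2L])
  )
}

# hand-built eigenbrain_set wrapping arbitrary loading vectors (columns)
fake_eset <- function(U, height, width, key_index = 1L) {
  structure(
    list(U = as.matrix(U), eigvals = rev(seq_len(ncol(as.matrix(U)))),
         scores = matrix(0, 2L, ncol(as.matrix(U))),
         mu = NULL, sigma = NULL, constant = NULL,
         height = height, width = width, key_index = key_index,
         labels = NULL, n_subjects = 2L),
    class = "eigenbrain_set"
  )
}
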