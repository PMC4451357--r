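# Eigenbrain decomposition of a key-slice stack.
#
# Each subject's H x W slice is vectorized to an A-vector (column-major, R's
# native layout; reshape is the exact inverse). The N x A matrix is
# standardized per voxel (attribute) across subjects, and PCA is computed via
# the small-sample trick: instead of eigendecomposing the A x A covariance
#   C = Z' Z / (N - 1)
# we decompose the N x N matrix
#   C' = Z Z' / (N - 1)
# whose nonzero eigenvalues coincide with those of C; the eigenbrains are the
# unit-normalized back-projections Z' w of the eigenvectors w of C'. Because
# standardized columns sum to zero, at most N - 1 eigenvalues are nonzero.

#' Standardize a key-slice stack per voxel
#'
#' Vectorizes each subject's slice and standardizes every voxel column to
#' sample mean 0 and sample SD 1 (denominator N - 1) across subjects.
#' Constant voxels (SD 0, e.g. background) become all-zero columns and are
#' flagged.
#'
#' @param stack a `slice_stack` (from [extract_slices()]), or an N x A
#'   numeric matrix of already-vectorized images.
#' @param axis standardize per `"voxel"` (default, the eigenface convention)
#'   or per `"sample"` (each subject's slice centered/scaled by its own
#'   statistics).
#' @return a `standardized_stack`: list with `Z` (N x A), `mu`, `sigma`,
#'   `constant` (logical mask of zero-variance voxels), image height/width,
#'   key-slice index, labels.
#' @export
standardize_stack <- function(stack, axis = c("voxel", "sample")) {
  axis <- match.arg(axis)
  if (inherits(stack, "slice_stack")) {
    d <- dim(stack$images)
    n <- d[1L]; h <- d[2L]; w <- d[3L]
    X <- matrix(stack$images, nrow = n)  # column-major flatten of H x W
    key_index <- stack$key_index
    labels <- stack$labels
  } else if (is.matrix(stack)) {
    X <- stack
    n <- nrow(X); h <- ncol(X); w <- 1L
    key_index <- NA_integer_
    labels <- NULL
  } else stop_eb("stack must be a slice_stack or a matrix")
  if (n < 2L) stop_eb("standardization needs at least 2 subjects")

  if (axis == "sample") {
    mu_s <- rowMeans(X)
    sd_s <- apply(X, 1L, stats::sd)
    sd_s[sd_s == 0] <- 1
    Z <- (X - mu_s) / sd_s
    mu <- mu_s; sigma <- sd_s
    constant <- rep(FALSE, ncol(X))
  } else {
    mu <- colMeans(X)
    sigma <- col_sds(X)
    constant <- sigma == 0
    denom <- ifelse(constant, 1, sigma)
    Z <- sweep(sweep(X, 2L, mu), 2L, denom, `/`)
    if (any(constant)) Z[, constant] <- 0
  }

  structure(
    list(Z = Z, mu = mu, sigma = sigma, constant = constant,
         height = h, width = w, key_index = key_index, labels = labels,
         standardize_axis = axis),
    class = "standardized_stack"
  )
}

#' Compute eigenbrains via the small-sample covariance trick
#'
#' Eigendecomposes `Z Z' / (N - 1)` (N x N), back-projects eigenvectors to
#' voxel space, unit-normalizes them, and fixes each sign so the
#' largest-magnitude loading is positive. Components with eigenvalue below
#' `tol` times the leading eigenvalue are dropped. Subject scores are the
#' projections `Z U`; each score column has mean 0 and sample variance equal
#' to its eigenvalue.
#'
#' @param zstack a `standardized_stack` (or any N x A matrix with centered
#'   columns).
#' @param n_eig optional cap on the number of retained components.
#' @param tol relative eigenvalue cutoff (default 1e-10).
#' @return an `eigenbrain_set`: `U` (A x n_eig), `eigvals`, `scores`
#'   (N x n_eig), standardization stats, image geometry, key-slice index.
#' @export
compute_eigenbrains <- function(zstack, n_eig = NULL, tol = 1e-10) {
  if (inherits(zstack, "standardized_stack")) {
    Z <- zstack$Z
    geom <- zstack
  } else if (is.matrix(zstack)) {
    Z <- zstack
    geom <- list(mu = NULL, sigma = NULL, constant = NULL,
                 height = ncol(Z), width = 1L, key_index = NA_integer_,
                 labels = NULL)
  } else stop_eb("zstack must be a standardized_stack or a matrix")
  n <- nrow(Z)
  if (n < 2L) stop_eb("eigenbrain decomposition needs at least 2 subjects")

  Cp <- tcrossprod(Z) / (n - 1)
  ed <- eigen(Cp, symmetric = TRUE)
  lam <- ed$values
  lam[lam < 0] <- 0
  if (max(lam) <= 0) {
    warning("degenerate all-zero stack: no eigenbrains retained")
    keep <- integer(0L)
  } else {
    keep <- which(lam > tol * max(lam))
  }
  if (!is.null(n_eig)) keep <- keep[seq_len(min(length(keep), n_eig))]

  if (length(keep) == 0L) {
    U <- matrix(numeric(0L), nrow = ncol(Z), ncol = 0L)
    scores <- matrix(numeric(0L), nrow = n, ncol = 0L)
    lam_keep <- numeric(0L)
  } else {
    W <- ed$vectors[, keep, drop = FALSE]
    U <- crossprod(Z, W)                       # A x k back-projection
    nrm <- sqrt(colSums(U^2))
    U <- sweep(U, 2L, nrm, `/`)
    # deterministic sign: largest-|loading| voxel is positive
    for (j in seq_len(ncol(U))) {
      piv <- which.max(abs(U[, j]))
      if (U[piv, j] < 0) U[, j] <- -U[, j]
    }
    scores <- Z %*% U
    lam_keep <- lam[keep]
  }

  structure(
    list(U = U, eigvals = lam_keep, scores = scores,
         mu = geom$mu, sigma = geom$sigma, constant = geom$constant,
         height = geom$height, width = geom$width,
         key_index = geom$key_index, labels = geom$labels,
         n_subjects = n),
    class = "eigenbrain_set"
  )
}

#' @export
print.eigenbrain_set <- function(x, ...) {
  cat(sprintf("eigenbrain_set: %d eigenbrains (%dx%d image, %d subjects, key slice %s)\n",
              length(x$eigvals), x$height, x$width, x$n_subjects,
              ifelse(is.na(x$key_index), "?", x$key_index)))
  if (length(x$eigvals))
    cat("  leading eigenvalues:",
        paste(signif(utils::head(x$eigvals, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Reshape an eigenbrain vector back to image form
#'
#' @param eset an `eigenbrain_set`.
#' @param i eigenbrain index (1-based, by decreasing eigenvalue).
#' @return an H x W numeric matrix; `matrix <-> vector` round-trips exactly.
#' @export
reshape_eigenbrain <- function(eset, i) {
  if (!inherits(eset, "eigenbrain_set")) stop_eb("eset must be an eigenbrain_set")
  check_scalar_number(i, "i", lower = 1, integer = TRUE)
  if (i > ncol(eset$U))
    stop_eb("eigenbrain index ", i, " out of range 1..", ncol(eset$U))
  matrix(eset$U[, i], nrow = eset$height, ncol = eset$width)
}

#' Run the eigenbrain decomposition on every key slice
#'
#' Convenience wrapper: standardize + decompose each stack of a
#' `slice_stack_set`, all subjects pooled (both classes), before any
#' cross-validation split.
#'
#' @param stacks a `slice_stack_set` from [extract_slices()].
#' @inheritParams standardize_stack
#' @inheritParams compute_eigenbrains
#' @return list of `eigenbrain_set`, one per key slice.
#' @export
eigenbrains_per_slice <- function(stacks, axis = "voxel", n_eig = NULL,
                                  tol = 1e-10) {
  if (!inherits(stacks, "slice_stack_set"))
    stop_eb("stacks must be a slice_stack_set")
  lapply(stacks, function(s)
    compute_eigenbrains(standardize_stack(s, axis = axis),
                        n_eig = n_eig, tol = tol))
}
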