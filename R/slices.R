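# Coronal key-slice selection by inter-class variance (ICV).
#
# For each coronal slice k the ICV is
#   v(k) = || mu_AD(k) - mu_NC(k) ||^2
# the squared Euclidean norm of the difference between the class-mean images
# of that slice. Slices with v(k) at least a fraction (default 50%) of the
# maximum are candidates; the kept key slices are every `undersample`-th
# candidate (default every 10th), anchored at the smallest candidate index.

slice_plane <- function(vol, axis, k) {
  switch(axis, vol[k, , ], vol[, k, ], vol[, , k])
}

assign_plane <- function(vol, axis, k, plane) {
  switch(axis,
         vol[k, , ] <- plane,
         vol[, k, ] <- plane,
         vol[, , k] <- plane)
  vol
}

#' Inter-class variance profile over coronal slices
#'
#' Computes, per coronal slice, the squared Euclidean norm (optionally the
#' plain norm) of the difference between the AD and NC mean images.
#'
#' @param data a `labeled_volume_set` with both classes present.
#' @param axis coronal axis; defaults to the one recorded in `data`.
#' @param norm `"squared"` (default) for the squared Euclidean norm,
#'   `"plain"` for the unsquared norm. The 50%-of-max selection rule is
#'   sensitive to this choice.
#' @return an `icv_profile`: data.frame with `slice` (1-based index) and
#'   `icv`, plus the axis and norm as attributes.
#' @export
compute_icv <- function(data, axis = NULL, norm = c("squared", "plain")) {
  norm <- match.arg(norm)
  if (!inherits(data, "labeled_volume_set"))
    stop_eb("data must be a labeled_volume_set")
  axis <- as.integer(axis %||% data$coronal_axis)
  check_scalar_number(axis, "axis", lower = 1, upper = 3, integer = TRUE)
  if (length(unique(data$labels)) < 2L)
    stop_eb("ICV needs both classes; only one label present")

  nc <- which(data$labels == 0L)
  ad <- which(data$labels == 1L)
  mean_vol <- function(idx) Reduce(`+`, data$volumes[idx]) / length(idx)
  dmean <- mean_vol(ad) - mean_vol(nc)

  n_slices <- data$shape[axis]
  v <- vapply(seq_len(n_slices), function(k) {
    sum(slice_plane(dmean, axis, k)^2)
  }, numeric(1L))
  if (norm == "plain") v <- sqrt(v)

  structure(data.frame(slice = seq_len(n_slices), icv = v),
            class = c("icv_profile", "data.frame"),
            axis = axis, norm = norm)
}

#' Select key slices from an ICV profile
#'
#' Candidates are slices whose ICV reaches `fraction` of the maximum; the
#' returned key slices are the candidates whose offset from the smallest
#' candidate is a multiple of `undersample`, in increasing order.
#'
#' @param profile an `icv_profile` from [compute_icv()].
#' @param fraction threshold as a fraction of the maximum ICV, in (0, 1].
#' @param undersample keep every `undersample`-th candidate slice.
#' @return a `key_slice_selection`: list with `key_indices` (1-based),
#'   `candidates`, `fraction`, `undersample`, `threshold`, `axis`.
#' @export
select_key_slices <- function(profile, fraction = 0.5, undersample = 10L) {
  if (!inherits(profile, "icv_profile")) stop_eb("profile must be an icv_profile")
  check_scalar_number(fraction, "fraction", lower = 1e-12, upper = 1)
  check_scalar_number(undersample, "undersample", lower = 1, integer = TRUE)
  v <- profile$icv
  if (length(v) == 0L) stop_eb("empty ICV profile")
  vmax <- max(v)
  if (vmax <= 0)
    stop_eb("all-zero ICV profile: threshold is degenerate (no class contrast)")
  candidates <- which(v >= fraction * vmax)
  anchor <- min(candidates)
  keep <- candidates[(candidates - anchor) %% undersample == 0L]
  structure(
    list(key_indices = keep, candidates = candidates,
         fraction = fraction, undersample = as.integer(undersample),
         threshold = fraction * vmax, axis = attr(profile, "axis")),
    class = "key_slice_selection"
  )
}

#' @export
print.key_slice_selection <- function(x, ...) {
  cat(sprintf("key_slice_selection: %d key slices (axis %d): %s\n",
              length(x$key_indices), x$axis,
              paste(x$key_indices, collapse = ", ")))
  invisible(x)
}

#' Extract per-slice image stacks for the selected key slices
#'
#' Pulls, for each key slice, the N coronal planes (one per subject) into an
#' `N x H x W` array. Subject order and intensities are preserved.
#'
#' @param data a `labeled_volume_set`.
#' @param selection a `key_slice_selection`, or an integer vector of 1-based
#'   slice indices.
#' @return a `slice_stack_set`: list of `slice_stack` objects, each holding
#'   `images` (N x H x W), `key_index`, `axis`, `subject_ids`, `labels`.
#' @export
extract_slices <- function(data, selection) {
  if (!inherits(data, "labeled_volume_set"))
    stop_eb("data must be a labeled_volume_set")
  if (inherits(selection, "key_slice_selection")) {
    idx <- selection$key_indices
    axis <- selection$axis
  } else {
    idx <- as.integer(selection)
    axis <- data$coronal_axis
  }
  n_slices <- data$shape[axis]
  if (any(idx < 1L | idx > n_slices))
    stop_eb("slice index out of range 1..", n_slices, ": ",
            paste(idx[idx < 1L | idx > n_slices], collapse = ", "))

  n <- length(data$volumes)
  hw <- dim(slice_plane(data$volumes[[1L]], axis, 1L))
  stacks <- lapply(idx, function(k) {
    imgs <- array(NA_real_, dim = c(n, hw))
    for (i in seq_len(n)) imgs[i, , ] <- slice_plane(data$volumes[[i]], axis, k)
    structure(list(images = imgs, key_index = k, axis = axis,
                   subject_ids = data$subject_ids, labels = data$labels),
              class = "slice_stack")
  })
  structure(stacks, class = "slice_stack_set")
}
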