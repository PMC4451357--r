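# Discriminant-voxel detection from the most important eigenbrain.
#
# Four-stage procedure per key slice: (1) take the MIE, (2) absolute value
# of its loadings (signs are arbitrary), (3) highlight pixels strictly above
# the 0.98 quantile of |loading| (linear-interpolation quantile, so ~2% of
# the population is kept), (4) optionally aggregate highlighted voxels
# against an integer label volume (atlas stand-in). Quantiles are computed
# per slice; an optional mask restricts the quantile population (e.g. to
# brain voxels).

#' Detect discriminant voxels by quantile thresholding of the MIE
#'
#' @param eigen_sets list of `eigenbrain_set`, one per key slice.
#' @param mie_index eigenbrain index to threshold (from [select_mie()]).
#' @param quantile quantile of `|loading|` above which a pixel is
#'   highlighted (strict inequality), in (0, 1). Default 0.98.
#' @param mask optional logical H x W matrix restricting the quantile
#'   population and the highlighted set (e.g. a brain mask).
#' @return a `region_map`: per key slice the threshold, highlighted pixel
#'   coordinates (`row`, `col`, 1-based) and count; the coronal axis and key
#'   indices as fields.
#' @export
detect_regions <- function(eigen_sets, mie_index, quantile = 0.98,
                           mask = NULL) {
  if (quantile <= 0 || quantile >= 1)
    stop_eb("quantile must be inside (0, 1), got ", quantile)
  check_scalar_number(mie_index, "mie_index", lower = 1, integer = TRUE)
  slices <- lapply(eigen_sets, function(es) {
    img <- abs(reshape_eigenbrain(es, mie_index))
    keep <- if (is.null(mask)) rep(TRUE, length(img)) else {
      if (!identical(dim(mask), dim(img)))
        stop_eb("mask shape does not match the eigenbrain image")
      as.vector(mask)
    }
    thr <- stats::quantile(img[keep], probs = quantile, names = FALSE,
                           type = 7)
    hi <- which(img > thr & matrix(keep, nrow(img), ncol(img)))
    coords <- arrayInd(hi, dim(img))
    list(key_index = es$key_index, threshold = thr,
         coords = data.frame(row = coords[, 1L], col = coords[, 2L],
                             value = img[hi]),
         count = length(hi), population = sum(keep))
  })
  structure(list(slices = slices,
                 key_indices = vapply(slices, `[[`, numeric(1L), "key_index"),
                 quantile = quantile, mie_index = as.integer(mie_index)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: MIE %d, quantile %.3f, %d key slices, %d voxels highlighted\n",
              x$mie_index, x$quantile,
              length(x$slices), sum(vapply(x$slices, `[[`, numeric(1L), "count"))))
  invisible(x)
}

# 3D voxel coordinates (subject space) of all highlighted pixels: the slice
# index is re-inserted on the coronal axis.
region_voxels <- function(map, axis) {
  out <- lapply(map$slices, function(s) {
    if (!nrow(s$coords)) return(NULL)
    k <- rep(s$key_index, nrow(s$coords))
    switch(axis,
           cbind(k, s$coords$row, s$coords$col),
           cbind(s$coords$row, k, s$coords$col),
           cbind(s$coords$row, s$coords$col, k))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- matrix(integer(0L), ncol = 3L)
  colnames(out) <- c("i", "j", "k")
  out
}

#' Aggregate highlighted voxels against a label volume
#'
#' Stand-in for an anatomical-atlas lookup: counts highlighted voxels per
#' integer label of a user-supplied label volume (0 = background, excluded).
#'
#' @param map a `region_map`.
#' @param label_volume integer 3D array in the same voxel grid as the data.
#' @param axis coronal axis used when the map was built.
#' @return data.frame (`label_table`) with `label` and `n_voxels`, sorted by
#'   decreasing count.
#' @export
map_labels <- function(map, label_volume, axis = 2L) {
  if (!is.array(label_volume) || length(dim(label_volume)) != 3L)
    stop_eb("label_volume must be a 3D array")
  vox <- region_voxels(map, axis)
  if (nrow(vox) &&
      (max(vox[, 1L]) > dim(label_volume)[1L] ||
       max(vox[, 2L]) > dim(label_volume)[2L] ||
       max(vox[, 3L]) > dim(label_volume)[3L]))
    stop_eb("label volume shape does not cover the highlighted voxels")
  if (!nrow(vox))
    return(structure(data.frame(label = integer(0L), n_voxels = integer(0L)),
                     class = c("label_table", "data.frame")))
  labs <- label_volume[vox]
  labs <- labs[labs != 0]
  tab <- sort(table(labs), decreasing = TRUE)
  structure(data.frame(label = as.integer(names(tab)),
                       n_voxels = as.integer(tab)),
            class = c("label_table", "data.frame"))
}

#' Overlap between highlighted voxels and a ground-truth effect mask
#'
#' Recovery score against phantom truth, restricted to the key slices the
#' map examined (voxels of the truth mask on other slices are out of reach
#' of a slice-based detector and are excluded from recall).
#'
#' @param map a `region_map`.
#' @param truth a `phantom_truth` (or logical 3D array).
#' @param axis coronal axis.
#' @return list with `dice`, `recall`, `precision`, `n_highlighted`,
#'   `n_truth` (truth voxels within the examined key slices).
#' @export
overlap_score <- function(map, truth, axis = 2L) {
  mask <- if (inherits(truth, "phantom_truth")) truth$effect_mask else truth
  if (!is.array(mask)) stop_eb("truth must be a phantom_truth or 3D array")
  if (!any(mask)) stop_eb("empty truth mask")
  vox <- region_voxels(map, axis)
  in_slices <- array(FALSE, dim = dim(mask))
  for (k in map$key_indices)
    in_slices <- assign_plane(in_slices, axis, k, TRUE)
  truth_k <- mask & in_slices
  n_truth <- sum(truth_k)
  hit <- if (nrow(vox)) sum(truth_k[vox]) else 0L
  n_hi <- nrow(vox)
  list(dice = if (n_hi + n_truth > 0) 2 * hit / (n_hi + n_truth) else NaN,
       recall = if (n_truth > 0) hit / n_truth else NaN,
       precision = if (n_hi > 0) hit / n_hi else NaN,
       n_highlighted = n_hi, n_truth = n_truth)
}
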