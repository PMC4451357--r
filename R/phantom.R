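# Synthetic brain phantom.
#
# The generator emulates what the downstream pipeline assumes about its
# input: co-registered, brain-masked volumes in a common voxel grid, two
# diagnostic classes whose expected intensities differ inside a few compact
# regions, and i.i.d. per-voxel acquisition noise. The shared template is a
# smooth ellipsoid ("brain") with a bright outer shell ("cortex") and a dark
# interior cavity ("ventricles"); AD subjects receive additive mean shifts in
# the configured effect regions, mimicking cortical atrophy, ventricular
# enlargement and hippocampal shrinkage. No anatomical realism is attempted.

#' Phantom generator configuration
#'
#' Describes the synthetic cohort: voxel grid, class sizes, effect regions
#' (spheres in which the AD class mean is shifted), and the noise level.
#'
#' @param shape integer vector of 3 positive voxel extents.
#' @param n_nc,n_ad subject counts per class (each at least 2). Defaults are
#'   the reference cohort sizes: 98 controls, 28 AD.
#' @param effect_regions list of effect regions, each a list with `center`
#'   (3 voxel coordinates), `radius` (voxels) and `magnitude` (additive
#'   intensity shift applied to the AD class). `NULL` picks three default
#'   regions scaled to `shape`: a cortex-shell patch (-25), a periventricular
#'   sphere (-35) and a hippocampus-analog sphere (-30).
#' @param noise_sd SD of the i.i.d. Gaussian voxel noise (intensity units).
#' @param coronal_axis which array axis plays the coronal (slice) direction.
#' @param seed RNG seed making the cohort reproducible.
#' @return an object of class `phantom_config`.
#' @examples
#' cfg <- phantom_config(shape = c(24, 24, 24), n_nc = 6, n_ad = 4)
#' @export
phantom_config <- function(shape = c(64L, 64L, 64L),
                           n_nc = 98L, n_ad = 28L,
                           effect_regions = NULL,
                           noise_sd = 5,
                           coronal_axis = 2L,
                           seed = 1L) {
  if (length(shape) != 3L || any(shape < 4L) || any(shape != round(shape)))
    stop_eb("shape must be 3 integers >= 4")
  shape <- as.integer(shape)
  check_scalar_number(n_nc, "n_nc", lower = 2, integer = TRUE)
  check_scalar_number(n_ad, "n_ad", lower = 2, integer = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(coronal_axis, "coronal_axis", lower = 1, upper = 3,
                      integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)

  if (is.null(effect_regions))
    effect_regions <- default_effect_regions(shape)
  for (r in effect_regions) {
    if (!all(c("center", "radius", "magnitude") %in% names(r)))
      stop_eb("each effect region needs center, radius, magnitude")
    if (length(r$center) != 3L)
      stop_eb("effect region center must have 3 coordinates")
    if (r$radius <= 0)
      stop_eb("effect region radius must be positive")
    if (any(r$center - r$radius < 1) || any(r$center + r$radius > shape))
      stop_eb("effect region (center ", paste(r$center, collapse = ","),
              ", radius ", r$radius, ") does not fit inside shape")
  }

  structure(
    list(shape = shape, n_nc = as.integer(n_nc), n_ad = as.integer(n_ad),
         effect_regions = effect_regions, noise_sd = noise_sd,
         coronal_axis = as.integer(coronal_axis), seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Three AD-effect spheres placed relative to the grid: one on the cortical
# shell, one next to the ventricle cavity, one low-posterior (hippocampus
# analog). Magnitudes are strong relative to the default noise_sd = 5 so the
# injected contrast dominates single-voxel noise.
default_effect_regions <- function(shape) {
  c0 <- (shape + 1) / 2
  r_eff <- max(2L, round(min(shape) / 10))
  list(
    list(center = round(c0 + c(0.30, 0.05, 0.05) * shape),
         radius = r_eff, magnitude = -25),
    list(center = round(c0 + c(0.00, 0.00, 0.12) * shape),
         radius = r_eff, magnitude = -35),
    list(center = round(c0 + c(-0.15, 0.10, -0.22) * shape),
         radius = r_eff, magnitude = -30)
  )
}

# squared normalized ellipsoid coordinate for every voxel; vectorized
ellipsoid_field <- function(shape, semi_axes) {
  gx <- (seq_len(shape[1L]) - (shape[1L] + 1) / 2) / semi_axes[1L]
  gy <- (seq_len(shape[2L]) - (shape[2L] + 1) / 2) / semi_axes[2L]
  gz <- (seq_len(shape[3L]) - (shape[3L] + 1) / 2) / semi_axes[3L]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

sphere_mask <- function(shape, center, radius) {
  dx <- seq_len(shape[1L]) - center[1L]
  dy <- seq_len(shape[2L]) - center[2L]
  dz <- seq_len(shape[3L]) - center[3L]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= radius^2
}

# Shared template: tissue 100 inside the brain ellipsoid, cortex shell 130,
# ventricle cavity 30, background 0.
phantom_template <- function(shape) {
  r2 <- ellipsoid_field(shape, 0.42 * shape)
  vol <- array(0, dim = shape)
  vol[r2 <= 1] <- 100
  vol[r2 <= 1 & r2 > 0.72] <- 130
  vent <- ellipsoid_field(shape, c(0.10, 0.22, 0.14) * shape)
  vol[vent <= 1] <- 30
  vol
}

#' Generate a synthetic labeled cohort of brain-like volumes
#'
#' Draws `n_nc + n_ad` volumes from a shared smooth template plus i.i.d.
#' Gaussian noise; AD subjects (label 1) additionally receive the configured
#' additive mean shifts inside each effect region. The ground-truth effect
#' mask is the union of all regions with nonzero magnitude.
#'
#' @param config a [phantom_config()].
#' @return a list with components
#'   \describe{
#'     \item{data}{a `labeled_volume_set`: `volumes` (list of 3D arrays),
#'       `labels` (0 = NC, 1 = AD), `subject_ids`, `coronal_axis`.}
#'     \item{truth}{a `phantom_truth`: logical `effect_mask` array plus the
#'       region list.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(24, 24, 24),
#'                                       n_nc = 6, n_ad = 4))
#' table(ph$data$labels)
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    config <- do.call(phantom_config, config)
  shape <- config$shape
  n <- config$n_nc + config$n_ad

  template <- phantom_template(shape)
  effect <- array(0, dim = shape)
  mask <- array(FALSE, dim = shape)
  for (r in config$effect_regions) {
    if (r$magnitude == 0) next
    sm <- sphere_mask(shape, r$center, r$radius)
    effect[sm] <- effect[sm] + r$magnitude
    mask <- mask | sm
  }

  labels <- c(rep(0L, config$n_nc), rep(1L, config$n_ad))
  subject_ids <- sprintf("sub-%03d", seq_len(n))

  restore <- push_seed(config$seed)
  on.exit(restore())
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    v <- template + array(stats::rnorm(prod(shape), sd = config$noise_sd),
                          dim = shape)
    if (labels[i] == 1L) v <- v + effect
    volumes[[i]] <- v
  }

  data <- labeled_volume_set(volumes, labels, subject_ids,
                             coronal_axis = config$coronal_axis)
  truth <- structure(list(effect_mask = mask,
                          effect_regions = config$effect_regions),
                     class = "phantom_truth")
  list(data = data, truth = truth)
}

# Scoped RNG: set a seed without clobbering the caller's stream.
push_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Construct a labeled volume set
#'
#' Container pairing co-registered subject volumes with binary diagnosis
#' labels (0 = NC, 1 = AD). All volumes must share one shape and both classes
#' must be represented.
#'
#' @param volumes list of 3D numeric arrays, one per subject.
#' @param labels integer vector in \{0, 1\}.
#' @param subject_ids character vector; defaults to `sub-001`, ...
#' @param coronal_axis which array axis is coronal.
#' @return an object of class `labeled_volume_set`.
#' @export
labeled_volume_set <- function(volumes, labels, subject_ids = NULL,
                               coronal_axis = 2L) {
  if (!is.list(volumes) || length(volumes) < 2L)
    stop_eb("volumes must be a list of at least 2 arrays")
  shapes <- vapply(volumes, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_eb("all volumes must share one shape; got: ",
            paste(unique(shapes), collapse = ", "))
  labels <- as.integer(labels)
  if (length(labels) != length(volumes) || !all(labels %in% c(0L, 1L)))
    stop_eb("labels must be one 0/1 value per volume")
  if (length(unique(labels)) != 2L)
    stop_eb("both classes (0 = NC, 1 = AD) must be present")
  subject_ids <- subject_ids %||% sprintf("sub-%03d", seq_along(volumes))
  if (anyDuplicated(subject_ids)) stop_eb("subject_ids must be unique")
  structure(
    list(volumes = volumes, labels = labels,
         subject_ids = as.character(subject_ids),
         coronal_axis = as.integer(coronal_axis),
         shape = dim(volumes[[1L]])),
    class = "labeled_volume_set"
  )
}

#' @export
print.labeled_volume_set <- function(x, ...) {
  cat(sprintf("labeled_volume_set: %d subjects (%d NC, %d AD), grid %s, coronal axis %d\n",
              length(x$volumes), sum(x$labels == 0L), sum(x$labels == 1L),
              paste(x$shape, collapse = "x"), x$coronal_axis))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d effect voxels in %d regions\n",
              sum(x$effect_mask), length(x$effect_regions)))
  invisible(x)
}
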