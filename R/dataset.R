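# Dataset round-trip: a directory of per-subject NIfTI volumes plus a labels
# CSV (subject_id, cdr, label). CDR 0 maps to NC (label 0), CDR 1 to AD
# (label 1); any other CDR value is rejected explicitly — intermediate
# severities are outside the binary contrast this pipeline models.

#' Write a labeled volume set to disk
#'
#' One uncompressed `.nii` per subject (named by subject id) plus
#' `labels.csv` with columns `subject_id`, `cdr`, `label`.
#'
#' @param data a `labeled_volume_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (!inherits(data, "labeled_volume_set"))
    stop_eb("data must be a labeled_volume_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(data$volumes))
    write_nifti(data$volumes[[i]],
                file.path(dir, paste0(data$subject_ids[i], ".nii")))
  utils::write.csv(
    data.frame(subject_id = data$subject_ids, cdr = data$labels,
               label = data$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a labeled volume set from disk
#'
#' Matches volumes to labels by subject id (CSV row order is irrelevant).
#' The CSV needs `subject_id` plus either `label` (0/1) or `cdr` (0 -> NC,
#' 1 -> AD; other values are rejected).
#'
#' @param volumes_path directory containing one `.nii` per subject.
#' @param labels_path labels CSV; defaults to `labels.csv` inside
#'   `volumes_path`.
#' @param coronal_axis which array axis is coronal.
#' @return a `labeled_volume_set` ordered as in the CSV.
#' @export
read_dataset <- function(volumes_path,
                         labels_path = file.path(volumes_path, "labels.csv"),
                         coronal_axis = 2L) {
  if (!dir.exists(volumes_path)) stop_eb("volumes directory not found: ", volumes_path)
  if (!file.exists(labels_path)) stop_eb("labels CSV not found: ", labels_path)
  tab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab))
    stop_eb("labels CSV must have a subject_id column")
  if ("label" %in% names(tab)) {
    labels <- as.numeric(tab$label)
  } else if ("cdr" %in% names(tab)) {
    labels <- as.numeric(tab$cdr)
  } else stop_eb("labels CSV must have a label or cdr column")
  bad <- !labels %in% c(0, 1)
  if (any(bad))
    stop_eb("unsupported CDR/label values (only 0 = NC and 1 = AD are accepted) for: ",
            paste(tab$subject_id[bad], collapse = ", "))

  files <- file.path(volumes_path, paste0(tab$subject_id, ".nii"))
  missing <- !file.exists(files)
  if (any(missing))
    stop_eb("no volume file for subject(s): ",
            paste(tab$subject_id[missing], collapse = ", "))
  volumes <- lapply(files, read_nifti)
  labeled_volume_set(volumes, as.integer(labels), tab$subject_id,
                     coronal_axis = coronal_axis)
}
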