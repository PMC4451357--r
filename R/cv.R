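# Repeated stratified k-fold cross-validation.
#
# Each repetition draws a fresh stratified partition (every fold carries an
# approximately proportional share of both classes — with 28 positives among
# 126 subjects, unstratified folds can lose the AD class entirely). Fold
# confusion counts are summed per repetition; accuracy, sensitivity,
# specificity and precision are aggregated as mean +/- SD over repetitions.
# AD (label 1) is the positive class: a correctly identified AD case is a
# true positive.

# k index sets, each holding ~1/k of every class; reproducible by seed
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (k < 2L) stop_eb("k must be at least 2")
  if (min(table(y)) < k)
    stop_eb("cannot stratify ", k, " folds: smallest class has ",
            min(table(y)), " subjects")
  restore <- push_seed(seed)
  on.exit(restore())
  folds <- vector("list", k)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    grp <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == 1L & pred == 1L),
    FP = sum(truth == 0L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FN = sum(truth == 1L & pred == 0L))
}

#' Classification metrics from confusion counts
#'
#' @param counts named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return named vector: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, each in `[0, 1]` (`NaN` where the denominator is 0).
#' @examples
#' confusion_metrics(c(TP = 25, FP = 8, TN = 90, FN = 3))
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = tp / (tp + fp))
}

#' Repeated stratified k-fold cross-validation of the kernel SVM
#'
#' @param x N x p feature matrix.
#' @param y 0/1 labels (1 = AD).
#' @param spec a [kernel_spec()]; with `tune != "none"` only its `kind` is
#'   used as the kernel family.
#' @param k folds per repetition (default 10).
#' @param reps repetitions (default 50).
#' @param seed base seed; repetition r partitions with `seed + r`.
#' @param tune `"none"` (use `spec` as given), `"once"` (PSO-tune on the
#'   full data set before CV; fast, but the tuning sees the test folds) or
#'   `"nested"` (re-tune inside every training fold; leakage-free, slow).
#' @param pso a [pso_config()] used when tuning.
#' @param inner_folds folds of the tuning CV.
#' @return a `cv_report`: per-repetition confusion counts, per-repetition
#'   metrics, and `summary` (mean and SD of each metric, in percent).
#' @export
cross_validate <- function(x, y, spec = kernel_spec(), k = 10L, reps = 50L,
                           seed = 1L, tune = c("none", "once", "nested"),
                           pso = pso_config(), inner_folds = 5L) {
  tune <- match.arg(tune)
  x <- as.matrix(x); y <- as.integer(y)
  if (nrow(x) < k) stop_eb("need at least k subjects")
  check_scalar_number(reps, "reps", lower = 1, integer = TRUE)

  if (tune == "once") {
    spec <- pso_tune(x, y, kind = spec$kind, config = pso,
                     inner_folds = inner_folds)
  }

  per_rep_counts <- matrix(0L, nrow = reps, ncol = 4L,
                           dimnames = list(NULL, c("TP", "FP", "TN", "FN")))
  for (r in seq_len(reps)) {
    folds <- stratified_folds(y, k = k, seed = seed + r)
    counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (f in seq_len(k)) {
      te <- folds[[f]]; tr <- setdiff(seq_len(nrow(x)), te)
      fold_spec <- if (tune == "nested") {
        pso_in <- pso; pso_in$seed <- pso$seed + 1000L * r + f
        pso_tune(x[tr, , drop = FALSE], y[tr], kind = spec$kind,
                 config = pso_in, inner_folds = inner_folds)
      } else spec
      m <- train_svm_smo(x[tr, , drop = FALSE], y[tr], fold_spec)
      pred <- predict(m, x[te, , drop = FALSE])
      counts <- counts + confusion_counts(y[te], pred)
    }
    per_rep_counts[r, ] <- counts
  }

  per_rep_metrics <- t(apply(per_rep_counts, 1L, confusion_metrics))
  mu <- colMeans(per_rep_metrics) * 100
  sd_ <- if (reps > 1L) apply(per_rep_metrics, 2L, stats::sd) * 100
         else rep(0, 4L)
  structure(
    list(counts = per_rep_counts, metrics = per_rep_metrics,
         summary = data.frame(metric = names(mu), mean = unname(mu),
                              sd = unname(sd_)),
         k = as.integer(k), reps = as.integer(reps), seed = as.integer(seed),
         spec = spec, tune = tune),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d x %d-fold CV, %s kernel (tune = %s)\n",
              x$reps, x$k, x$spec$kind, x$tune))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}
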