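# Most-important-eigenbrain (MIE) selection by Welch's t-test.
#
# Per key slice and eigenbrain index, the per-subject projection scores of
# the two diagnostic groups are compared with Welch's unequal-variance
# two-sample t-test (two-sided, Welch-Satterthwaite degrees of freedom). The
# MIE is the smallest eigenbrain index whose scores differ significantly
# (p < alpha) on EVERY key slice; its per-slice scores become the
# classification features (one feature per key slice).

#' Welch's two-sample t-test from summary statistics
#'
#' The unequal-variance location test:
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided Student-t
#' p-value. SDs use the sample (n - 1) convention.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_ttest(-3.36, 20.01, 98, 11.75, 27.91, 28)$p  # ~0.011
#' @export
welch_ttest <- function(m1, s1, n1, m2, s2, n2) {
  check_scalar_number(n1, "n1", lower = 2, integer = TRUE)
  check_scalar_number(n2, "n2", lower = 2, integer = TRUE)
  if (s1 < 0 || s2 < 0) stop_eb("SDs must be nonnegative")
  se1 <- s1^2 / n1
  se2 <- s2^2 / n2
  se <- se1 + se2
  if (se == 0) stop_eb("zero pooled standard error: both groups are constant")
  t <- (m1 - m2) / sqrt(se)
  df <- se^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p)
}

#' Welch's t-test from raw samples
#'
#' Computes the group summaries (mean, sample SD) and delegates to
#' [welch_ttest()]; exactly equivalent to the summary-statistic form.
#'
#' @param x,y numeric sample vectors (each length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_ttest_samples <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_eb("each sample needs at least 2 observations")
  welch_ttest(mean(x), stats::sd(x), length(x),
              mean(y), stats::sd(y), length(y))
}

#' Welch-test table for eigenbrain scores
#'
#' For every key slice and each of the first `max_rank` eigenbrains, tests
#' NC vs AD subject scores. The layout mirrors the usual reporting table:
#' per-group mean and SD, t, df, p.
#'
#' @param eigen_sets list of `eigenbrain_set` (one per key slice).
#' @param labels 0/1 diagnosis labels aligned with the score rows; defaults
#'   to the labels carried by the eigenbrain sets.
#' @param max_rank test at most this many leading eigenbrains (default 6).
#' @return data.frame of class `wtt_result` with columns `slice`, `eig`,
#'   `nc_mean`, `nc_sd`, `ad_mean`, `ad_sd`, `t`, `df`, `p`.
#' @export
wtt_table <- function(eigen_sets, labels = NULL, max_rank = 6L) {
  if (!length(eigen_sets)) stop_eb("need at least one key slice")
  check_scalar_number(max_rank, "max_rank", lower = 1, integer = TRUE)
  rows <- list()
  for (es in eigen_sets) {
    lab <- labels %||% es$labels
    if (is.null(lab)) stop_eb("labels are required (none stored in the eigenbrain set)")
    lab <- as.integer(lab)
    if (length(unique(lab)) < 2L) stop_eb("both classes must be present")
    k <- min(max_rank, ncol(es$scores))
    for (i in seq_len(k)) {
      sc <- es$scores[, i]
      nc <- sc[lab == 0L]; ad <- sc[lab == 1L]
      wt <- welch_ttest_samples(nc, ad)
      rows[[length(rows) + 1L]] <- data.frame(
        slice = es$key_index, eig = i,
        nc_mean = mean(nc), nc_sd = stats::sd(nc),
        ad_mean = mean(ad), ad_sd = stats::sd(ad),
        t = wt$t, df = wt$df, p = wt$p
      )
    }
  }
  structure(do.call(rbind, rows), class = c("wtt_result", "data.frame"))
}

#' Select the most important eigenbrain
#'
#' The MIE is the smallest eigenbrain index with Welch p < `alpha` on every
#' key slice. Ties break toward the smaller index (earlier components carry
#' more variance). If no index passes on all slices the error carries the
#' full test table in its condition data.
#'
#' @inheritParams wtt_table
#' @param alpha significance level (default 0.05, i.e. the 95% confidence
#'   level).
#' @param bonferroni apply a Bonferroni correction over
#'   `max_rank * n_slices` tests before thresholding (off by default).
#' @return list with `mie_index` and the `wtt_result` table.
#' @export
select_mie <- function(eigen_sets, labels = NULL, alpha = 0.05,
                       max_rank = 6L, bonferroni = FALSE) {
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1)
  wtt <- wtt_table(eigen_sets, labels = labels, max_rank = max_rank)
  select_mie_from_wtt(wtt, alpha = alpha, bonferroni = bonferroni)
}

# selection given a precomputed test table (also used for external summary
# tables, e.g. published group statistics)
select_mie_from_wtt <- function(wtt, alpha = 0.05, bonferroni = FALSE) {
  thr <- if (bonferroni) alpha / nrow(wtt) else alpha
  n_slices <- length(unique(wtt$slice))
  passing <- vapply(sort(unique(wtt$eig)), function(i) {
    sub <- wtt[wtt$eig == i, ]
    nrow(sub) == n_slices && all(sub$p < thr)
  }, logical(1L))
  idx <- sort(unique(wtt$eig))[passing]
  if (!length(idx))
    stop_eb("no eigenbrain index is significant on every key slice at alpha = ",
            thr, class = "eb_no_mie", data = wtt)
  list(mie_index = min(idx), wtt = wtt)
}

#' Reference eigenbrain-score group summaries (OASIS cohort)
#'
#' The published per-slice, per-eigenbrain group means and SDs of subject
#' scores for the 98-NC / 28-AD OASIS-derived cohort (coronal slices 60-150
#' in steps of 10, eigenbrain indices 1-6), shipped as package data. Useful
#' as a worked example: recomputing Welch's t-test from these summaries
#' identifies eigenbrain 1 as the only index significant on every slice.
#'
#' @return data.frame with `slice`, `eig`, `nc_mean`, `nc_sd`, `ad_mean`,
#'   `ad_sd`, `n_nc`, `n_ad`, `p_printed` (the two-decimal published
#'   p-value).
#' @export
reference_wtt_summary <- function() {
  path <- system.file("extdata", "oasis_wtt_summary.csv",
                      package = "eigenbrain", mustWork = TRUE)
  utils::read.csv(path)
}

#' Welch-test table from group summary statistics
#'
#' Builds a `wtt_result` (as produced by [wtt_table()]) from per-cell group
#' means/SDs instead of raw scores, e.g. from [reference_wtt_summary()];
#' feed the result to [select_mie_from_summary()].
#'
#' @param tab data.frame with columns `slice`, `eig`, `nc_mean`, `nc_sd`,
#'   `ad_mean`, `ad_sd`, `n_nc`, `n_ad`.
#' @return a `wtt_result` data.frame.
#' @export
wtt_from_summary <- function(tab) {
  need <- c("slice", "eig", "nc_mean", "nc_sd", "ad_mean", "ad_sd",
            "n_nc", "n_ad")
  if (!all(need %in% names(tab)))
    stop_eb("summary table must have columns: ", paste(need, collapse = ", "))
  res <- lapply(seq_len(nrow(tab)), function(i) {
    wt <- welch_ttest(tab$nc_mean[i], tab$nc_sd[i], tab$n_nc[i],
                      tab$ad_mean[i], tab$ad_sd[i], tab$n_ad[i])
    data.frame(slice = tab$slice[i], eig = tab$eig[i],
               nc_mean = tab$nc_mean[i], nc_sd = tab$nc_sd[i],
               ad_mean = tab$ad_mean[i], ad_sd = tab$ad_sd[i],
               t = wt$t, df = wt$df, p = wt$p)
  })
  structure(do.call(rbind, res), class = c("wtt_result", "data.frame"))
}

#' Select the MIE from a precomputed summary table
#'
#' @param tab summary data.frame (see [wtt_from_summary()]).
#' @inheritParams select_mie
#' @return list with `mie_index` and the recomputed `wtt_result`.
#' @export
select_mie_from_summary <- function(tab, alpha = 0.05, bonferroni = FALSE) {
  select_mie_from_wtt(wtt_from_summary(tab), alpha = alpha,
                      bonferroni = bonferroni)
}

#' Assemble the classification feature matrix
#'
#' One feature per key slice: each subject's projection score on the MIE of
#' that slice. Rows follow the subject order of the input volumes.
#'
#' @param eigen_sets list of `eigenbrain_set`.
#' @param mie_index eigenbrain index to take from every slice.
#' @return N x n_key_slices numeric matrix; columns named `slice<k>`,
#'   attribute `mie_index` records the selected component.
#' @export
build_features <- function(eigen_sets, mie_index) {
  check_scalar_number(mie_index, "mie_index", lower = 1, integer = TRUE)
  if (!length(eigen_sets)) stop_eb("need at least one key slice")
  cols <- lapply(eigen_sets, function(es) {
    if (mie_index > ncol(es$scores))
      stop_eb("eigenbrain index ", mie_index, " missing for key slice ",
              es$key_index)
    es$scores[, mie_index]
  })
  f <- do.call(cbind, cols)
  colnames(f) <- paste0("slice", vapply(eigen_sets, function(e) e$key_index,
                                        numeric(1L)))
  attr(f, "mie_index") <- as.integer(mie_index)
  f
}
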