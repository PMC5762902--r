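#' ROC-area criterion for one feature
#'
#' Area between the empirical ROC curve and the random-classifier diagonal:
#' the empirical AUC of in-segment versus out-segment intensities (computed
#' from the Mann-Whitney pair statistic, ties counted 1/2) folded around
#' chance, `|AUC - 0.5|`. The criterion is two-sided, so features depleted
#' in-segment score as highly as enriched ones, and it is invariant under
#' strictly monotone transforms of the intensities.
#'
#' @param values_in,values_out Non-empty numeric samples.
#' @return A score in `[0, 0.5]`.
#' @export
roc_area_criterion <- function(values_in, values_out) {
  n1 <- length(values_in); n2 <- length(values_out)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(values_in, values_out), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  abs(auc - 0.5)
}

#' Pooled-variance t criterion for one feature
#'
#' Absolute two-sample t statistic with pooled variance. Degenerate inputs
#' are ranked sensibly: zero pooled variance with equal means scores 0,
#' zero pooled variance with unequal means scores `Inf` (perfectly
#' separated constants rank first).
#'
#' @param values_a,values_b Numeric samples with at least 2 values each.
#' @return A non-negative score (possibly `Inf`).
#' @export
ttest_criterion <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values")
  ma <- mean(values_a); mb <- mean(values_b)
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    return(if (ma == mb) 0 else Inf)
  }
  abs(ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Rank m/z features by a discrimination criterion
#'
#' Evaluates the chosen criterion for every feature of a labeled pixel-by-
#' feature matrix and returns the top `n` (default 10) as a
#' [ranked_features()] tibble. Ties are broken by ascending m/z; the
#' direction records whether the feature is enriched (`"up"`) or depleted
#' (`"down"`) in the positive class. No multiple-testing correction is
#' applied: this is a ranking, not a test.
#'
#' @param matrix Numeric pixel-by-feature intensity matrix.
#' @param mz_axis m/z value per feature column.
#' @param labels Logical (or 0/1) vector per pixel: TRUE = in-segment /
#'   case class. Both classes must be non-empty.
#' @param criterion `"roc"` or `"ttest"`.
#' @param n Number of features to return (default 10); capped at the
#'   feature count with a warning.
#' @param segment_id Segment index recorded in the output.
#' @return A [ranked_features()] tibble with `n` rows.
#' @export
rank_features <- function(matrix, mz_axis, labels, criterion = c("roc", "ttest"),
                          n = 10, segment_id = 1L) {
  criterion <- match.arg(criterion)
  labels <- as.logical(labels)
  stopifnot(nrow(matrix) == length(labels), ncol(matrix) == length(mz_axis))
  if (!any(labels) || all(labels)) stop("both classes must be non-empty")
  f <- if (criterion == "roc") roc_area_criterion else ttest_criterion
  scores <- vapply(seq_len(ncol(matrix)), function(j) {
    f(matrix[labels, j], matrix[!labels, j])
  }, numeric(1))
  if (n > length(scores)) {
    warning(sprintf("requested %d features but only %d exist; returning all",
                    n, length(scores)))
    n <- length(scores)
  }
  ord <- order(-scores, mz_axis)[seq_len(n)]
  dirs <- ifelse(
    colMeans(matrix[labels, ord, drop = FALSE]) >=
      colMeans(matrix[!labels, ord, drop = FALSE]),
    "up", "down"
  )
  ranked_features(mz_axis[ord], scores[ord], dirs, segment_id)
}

#' Segment-wise comparison of two cohorts
#'
#' Pools the pixels carrying segment label `idx` from each cohort's binned
#' dataset(s) and ranks the features separating cohort A from cohort B with
#' the pooled t criterion — the substructure-wise case/control comparison.
#' All datasets must share one binned m/z axis.
#'
#' @param ds_a,ds_b Lists of binned continuous-mode [msi_dataset()]s (one
#'   per section) for the two cohorts.
#' @param segs_a,segs_b Matching lists of [segment_map()]s on the same grids.
#' @param idx Segment index to compare within.
#' @param n Number of features to return (default 10).
#' @return A [ranked_features()] tibble; `direction` is relative to cohort A.
#' @export
segmentwise_group_compare <- function(ds_a, ds_b, segs_a, segs_b, idx,
                                      n = 10) {
  if (inherits(ds_a, "msi_dataset")) ds_a <- list(ds_a)
  if (inherits(ds_b, "msi_dataset")) ds_b <- list(ds_b)
  if (inherits(segs_a, "segment_map")) segs_a <- list(segs_a)
  if (inherits(segs_b, "segment_map")) segs_b <- list(segs_b)
  pool <- function(dss, segs, cohort) {
    stopifnot(length(dss) == length(segs))
    rows <- list()
    for (i in seq_along(dss)) {
      ds <- dss[[i]]; seg <- segs[[i]]
      stopifnot(ds$mode == "continuous")
      lab <- as.integer(t(seg$labels))[ds$pixel_idx + 1L]
      hit <- lab == as.integer(idx)
      if (!any(hit)) {
        stop(sprintf("segment %d is empty in cohort %s section '%s'",
                     idx, cohort, ds$section_id))
      }
      rows[[i]] <- ds$intensities[hit, , drop = FALSE]
    }
    do.call(rbind, rows)
  }
  axis <- ds_a[[1]]$mz_axis
  for (ds in c(ds_a, ds_b)) {
    if (length(ds$mz_axis) != length(axis) ||
        (length(axis) && max(abs(ds$mz_axis - axis)) > 1e-9)) {
      stop("all datasets must share one binned m/z axis")
    }
  }
  a <- pool(ds_a, segs_a, "A")
  b <- pool(ds_b, segs_b, "B")
  rank_features(rbind(a, b), axis,
                labels = c(rep(TRUE, nrow(a)), rep(FALSE, nrow(b))),
                criterion = "ttest", n = n, segment_id = idx)
}

#' Rank features for every segment of a map
#'
#' Convenience wrapper running [rank_features()] once per segment of a
#' segment map against a binned dataset on the same grid (in-segment versus
#' all other on-tissue pixels, ROC criterion by default).
#'
#' @param ds A binned continuous-mode [msi_dataset()].
#' @param seg A [segment_map()] on the dataset's grid.
#' @param criterion `"roc"` or `"ttest"`.
#' @param n Features per segment (default 10).
#' @return A single tibble with all segments' tables stacked.
#' @export
rank_segments <- function(ds, seg, criterion = "roc", n = 10) {
  stopifnot(inherits(ds, "msi_dataset"), ds$mode == "continuous",
            inherits(seg, "segment_map"))
  if (!grid_equal(ds$grid, seg$grid)) stop("dataset and map must share a grid")
  lab <- as.integer(t(seg$labels))[ds$pixel_idx + 1L]
  present <- sort(unique(lab[lab > 0L]))
  on <- lab > 0L
  out <- lapply(present, function(ix) {
    rank_features(ds$intensities[on, , drop = FALSE], ds$mz_axis,
                  labels = lab[on] == ix, criterion = criterion, n = n,
                  segment_id = ix)
  })
  dplyr::bind_rows(out)
}
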