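#' Derivative log ratio (DLR) of an array
#'
#' The sample standard deviation of successive probe log2 differences, the
#' standard probe-to-probe noise metric for aCGH arrays.  Probes must be in
#' genomic order.  DLR is translation-invariant and scales linearly with
#' the profile.
#'
#' @param profile Numeric vector of per-probe log2 ratios in genomic order.
#' @return The DLR (non-negative scalar).
#' @export
compute_dlr <- function(profile) {
  profile <- profile[!is.na(profile)]
  if (length(profile) < 3L) stop("DLR needs at least 3 probes", call. = FALSE)
  stats::sd(diff(profile))
}

.qc_report <- function(stage, threshold, excluded, n_before) {
  list(stage = stage, threshold = threshold,
       excluded = excluded, n_before = n_before,
       n_after = n_before - length(excluded))
}

#' Array-level QC filters
#'
#' Three array filters applied in the study's order, each a single pass
#' (thresholds are computed once and not re-derived after exclusion):
#'
#' * `filter_arrays_dlr()`: retain arrays with DLR strictly below
#'   `threshold` (default 0.3).
#' * `filter_arrays_variance()`: exclude arrays whose intra-array probe
#'   log2 variance is >= mean + 1 SD of the per-array variances.
#' * `filter_arrays_mean()`: exclude arrays whose intra-array mean log2 is
#'   >= 2 SD from the grand mean (two-sided).
#'
#' When the spread of the criterion statistic is exactly zero the filter
#' excludes nothing (outlier removal, not literal thresholding).  All SDs
#' are sample (n-1) standard deviations.
#'
#' @param log2mat Probes x samples numeric matrix.
#' @param threshold DLR cutoff (arrays with DLR >= threshold are excluded).
#' @return List with `log2` (retained columns) and `report` (stage name,
#'   threshold used, excluded sample ids, counts before/after).
#' @export
filter_arrays_dlr <- function(log2mat, threshold = 0.3) {
  dlr <- apply(log2mat, 2, compute_dlr)
  excl <- colnames(log2mat)[dlr >= threshold]
  list(log2 = log2mat[, setdiff(colnames(log2mat), excl), drop = FALSE],
       stats = dlr,
       report = .qc_report("dlr", threshold, excl, ncol(log2mat)))
}

#' @rdname filter_arrays_dlr
#' @export
filter_arrays_variance <- function(log2mat) {
  if (ncol(log2mat) < 2L) stop("need at least 2 arrays", call. = FALSE)
  v <- apply(log2mat, 2, stats::var, na.rm = TRUE)
  s <- .sd0(v)
  thr <- mean(v) + s
  excl <- if (s == 0) character(0) else colnames(log2mat)[v >= thr]
  list(log2 = log2mat[, setdiff(colnames(log2mat), excl), drop = FALSE],
       stats = v,
       report = .qc_report("array_variance", thr, excl, ncol(log2mat)))
}

#' @rdname filter_arrays_dlr
#' @export
filter_arrays_mean <- function(log2mat) {
  if (ncol(log2mat) < 2L) stop("need at least 2 arrays", call. = FALSE)
  m <- colMeans(log2mat, na.rm = TRUE)
  s <- .sd0(m)
  excl <- if (s == 0) character(0) else
    colnames(log2mat)[abs(m - mean(m)) >= 2 * s]
  list(log2 = log2mat[, setdiff(colnames(log2mat), excl), drop = FALSE],
       stats = m,
       report = .qc_report("array_mean", 2 * s, excl, ncol(log2mat)))
}

#' Probe-level interarray variance filter
#'
#' Computes each probe's variance across arrays and excludes probes whose
#' variance is >= mean + 1 SD of the per-probe variances.  Applied to the
#' post-DLR array set, before the remaining array filters feed downstream
#' calling.  With a single array the filter is a no-op (with a warning):
#' interarray variance is undefined.
#'
#' @param log2mat Probes x samples numeric matrix.
#' @return List with `log2` (retained rows), `retained_probes`, and
#'   `report`.
#' @export
filter_probes_variance <- function(log2mat) {
  if (ncol(log2mat) < 2L) {
    warning("single array: interarray probe variance undefined, no probes removed")
    return(list(log2 = log2mat, retained_probes = rownames(log2mat),
                report = .qc_report("probe_variance", NA_real_,
                                    character(0), nrow(log2mat))))
  }
  v <- apply(log2mat, 1, stats::var, na.rm = TRUE)
  s <- .sd0(v)
  thr <- mean(v) + s
  excl <- if (s == 0) character(0) else rownames(log2mat)[v >= thr]
  keep <- setdiff(rownames(log2mat), excl)
  list(log2 = log2mat[keep, , drop = FALSE], retained_probes = keep,
       report = .qc_report("probe_variance", thr, excl, nrow(log2mat)))
}

#' Exclude samples with outlying CNV counts
#'
#' Deletion and duplication counts are computed per sample (samples with
#' no calls count zero) and samples exceeding mean + 5 SD in either count
#' are excluded, evaluated once (not iterated).
#'
#' @param calls CNV call `data.frame`.
#' @param sample_ids Character vector of all samples in the call set's
#'   cohort (so zero-call samples enter the mean).
#' @param n_sd Number of SDs over the mean (default 5).
#' @return List with `calls` (calls of retained samples), `retained`
#'   sample ids, and `report`.
#' @export
filter_samples_cnv_count <- function(calls, sample_ids, n_sd = 5) {
  .check_calls(calls)
  cnt <- function(type) {
    tab <- table(factor(calls$sample_id[calls$type == type],
                        levels = sample_ids))
    as.numeric(tab)
  }
  dels <- cnt("deletion"); dups <- cnt("duplication")
  lim <- function(x) {
    s <- .sd0(x)
    if (s == 0) Inf else mean(x) + n_sd * s
  }
  excl <- sample_ids[dels > lim(dels) | dups > lim(dups)]
  retained <- setdiff(sample_ids, excl)
  list(calls = calls[calls$sample_id %in% retained, , drop = FALSE],
       retained = retained,
       report = .qc_report("cnv_count", c(deletions = lim(dels),
                                          duplications = lim(dups)),
                           excl, length(sample_ids)))
}

#' Run the array- and probe-level QC cascade
#'
#' Applies DLR, probe-variance, array-variance and array-mean filters in
#' that order (the probe filter acts on the post-DLR array set).  The
#' CNV-count sample filter runs after calling and is not part of this
#' cascade.
#'
#' @param log2mat Probes x samples matrix.
#' @param dlr_threshold DLR cutoff.
#' @param order Character vector of stage names; the default mirrors the
#'   study's published order.
#' @return List with `log2` (filtered matrix) and `reports` (per stage).
#' @export
run_array_qc <- function(log2mat, dlr_threshold = 0.3,
                         order = c("dlr", "probe_variance",
                                   "array_variance", "array_mean")) {
  reports <- list()
  for (stage in order) {
    res <- switch(stage,
      dlr = filter_arrays_dlr(log2mat, dlr_threshold),
      probe_variance = filter_probes_variance(log2mat),
      array_variance = filter_arrays_variance(log2mat),
      array_mean = filter_arrays_mean(log2mat),
      stop("unknown QC stage: ", stage))
    log2mat <- res$log2
    reports[[stage]] <- res$report
  }
  list(log2 = log2mat, reports = reports)
}
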