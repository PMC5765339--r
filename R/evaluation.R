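#' Score called CNVs against simulator ground truth
#'
#' Matches calls to truth records of the same sample and type under the
#' reciprocal-overlap criterion (both fractions >= `ro_threshold`).
#' Precision is the fraction of calls matching some truth record; recall
#' the fraction of truth records matched by some call.  Truth records of
#' samples outside `sample_ids` (e.g. QC-excluded arrays) are ignored, as
#' are calls from such samples.
#'
#' @param calls CNV call `data.frame`.
#' @param truth Truth `data.frame` from [simulate_cohort()].
#' @param sample_ids Samples in scope (default: samples present in calls).
#' @param ro_threshold Reciprocal-overlap threshold (default 0.5).
#' @return List with `precision`, `recall`, `n_calls`, `n_truth`,
#'   `matched_calls`, `matched_truth`.
#' @export
score_recovery <- function(calls, truth, sample_ids = unique(calls$sample_id),
                           ro_threshold = 0.5) {
  calls <- calls[calls$sample_id %in% sample_ids, , drop = FALSE]
  truth <- truth[truth$sample_id %in% sample_ids, , drop = FALSE]
  match_one <- function(s1, e1, s2, e2) {
    ov <- .overlap_len(s1, e1, s2, e2)
    ov / (e1 - s1) >= ro_threshold & ov / (e2 - s2) >= ro_threshold
  }
  call_hit <- vapply(seq_len(nrow(calls)), function(i) {
    tt <- truth[truth$sample_id == calls$sample_id[i] &
                  truth$type == calls$type[i], , drop = FALSE]
    nrow(tt) > 0 && any(match_one(calls$start[i], calls$end[i],
                                  tt$start, tt$end))
  }, TRUE)
  truth_hit <- vapply(seq_len(nrow(truth)), function(i) {
    cc <- calls[calls$sample_id == truth$sample_id[i] &
                  calls$type == truth$type[i], , drop = FALSE]
    nrow(cc) > 0 && any(match_one(truth$start[i], truth$end[i],
                                  cc$start, cc$end))
  }, TRUE)
  list(precision = if (nrow(calls)) mean(call_hit) else NA_real_,
       recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
       n_calls = nrow(calls), n_truth = nrow(truth),
       matched_calls = sum(call_hit), matched_truth = sum(truth_hit))
}
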