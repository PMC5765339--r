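#' Post-call filter parameters
#'
#' @param max_cnv_size Calls at least this long (bp) are removed
#'   (default 1 Mb).
#' @param excluded_regions Two-column matrix/data.frame of 0-based
#'   half-open intervals; calls with either breakpoint inside any of them
#'   are removed.  Default: the reference sample's deletion
#'   (chr21:45,555,257-45,615,042) and the poorly mapped p-arm /
#'   pericentromeric region chr21:0-15,400,000.
#' @param min_catalog_size Smallest catalog variant used for validation
#'   (default 1798 bp, the platform's detection floor).
#' @param reciprocal_overlap_threshold Reciprocal-overlap fraction for
#'   catalog matches and region clustering (default 0.5).
#' @param rare_frequency_cutoff Region frequency below which a variant is
#'   "rare" (default 0.01).
#' @return A `filter_params` list.
#' @export
filter_params <- function(max_cnv_size = 1e6,
                          excluded_regions = rbind(
                            c(45555256, 45615042),
                            c(0, 15400000)),
                          min_catalog_size = 1798,
                          reciprocal_overlap_threshold = 0.5,
                          rare_frequency_cutoff = 0.01) {
  stopifnot(max_cnv_size > 0, min_catalog_size > 0,
            reciprocal_overlap_threshold > 0,
            reciprocal_overlap_threshold <= 1)
  structure(list(max_cnv_size = max_cnv_size,
                 excluded_regions = as.matrix(excluded_regions),
                 min_catalog_size = min_catalog_size,
                 reciprocal_overlap_threshold = reciprocal_overlap_threshold,
                 rare_frequency_cutoff = rare_frequency_cutoff),
            class = "filter_params")
}

# is either breakpoint of [s,e) inside any excluded region? vectorized
.breakpoint_in_region <- function(start, end, regions) {
  hit <- rep(FALSE, length(start))
  for (r in seq_len(nrow(regions))) {
    rs <- regions[r, 1]; re <- regions[r, 2]
    hit <- hit | (start >= rs & start < re) | (end > rs & end <= re)
  }
  hit
}

#' Apply post-call filters
#'
#' Removes, in order: (1) calls of size >= `max_cnv_size`; (2) calls with
#' either breakpoint inside an excluded region; (3) samples whose CNV
#' counts are outliers (> 5 SD over the mean deletion or duplication
#' count; delegated to [filter_samples_cnv_count()]).  The returned log
#' conserves counts: removed per rule plus survivors equals the input.
#'
#' @param calls CNV call `data.frame`.
#' @param params A [filter_params()].
#' @param sample_ids All samples in the cohort (for the count filter).
#' @return List with `calls` (survivors) and `log` (`data.frame` of
#'   per-rule removed counts by type).
#' @export
apply_call_filters <- function(calls, params = filter_params(),
                               sample_ids = unique(calls$sample_id)) {
  .check_calls(calls)
  log_rows <- list()
  note <- function(rule, removed) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      rule = rule,
      removed_deletions = sum(removed$type == "deletion"),
      removed_duplications = sum(removed$type == "duplication"),
      stringsAsFactors = FALSE)
  }
  big <- (calls$end - calls$start) >= params$max_cnv_size
  note("max_size", calls[big, , drop = FALSE])
  calls <- calls[!big, , drop = FALSE]

  inreg <- .breakpoint_in_region(calls$start, calls$end,
                                 params$excluded_regions)
  note("excluded_region", calls[inreg, , drop = FALSE])
  calls <- calls[!inreg, , drop = FALSE]

  cc <- filter_samples_cnv_count(calls, sample_ids)
  note("cnv_count_outlier",
       calls[!calls$sample_id %in% cc$retained, , drop = FALSE])
  calls <- cc$calls
  rownames(calls) <- NULL
  list(calls = calls, log = do.call(rbind, log_rows),
       retained_samples = cc$retained)
}

#' Reciprocal overlap of two intervals
#'
#' Overlap length divided by each interval's own length; a pair "matches"
#' at threshold t when both fractions are >= t.  Symmetric up to swapping
#' the tuple.
#'
#' @param a,b Numeric length-2 intervals (0-based half-open), same
#'   chromosome.
#' @return Named numeric: `frac_a`, `frac_b`.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a[2] <= a[1] || b[2] <= b[1]) {
    stop("zero-length interval", call. = FALSE)
  }
  ov <- .overlap_len(a[1], a[2], b[1], b[2])
  c(frac_a = ov / (a[2] - a[1]), frac_b = ov / (b[2] - b[1]))
}

#' Validate calls against a catalog of known variants
#'
#' Flags each call that has >= 50% (configurable) reciprocal overlap with
#' a catalog variant of the same type (`multiallelic` catalog entries
#' match either type), after dropping catalog entries below the platform's
#' detection floor.  Summarizes the flagged fraction by call type.
#'
#' @param calls CNV call `data.frame`.
#' @param catalog Catalog `data.frame` (see [read_catalog()]).
#' @param params A [filter_params()].
#' @return List with `calls` (input plus logical `in_catalog`) and
#'   `summary` (`type`, `n`, `in_catalog`, `fraction`).
#' @export
annotate_dgv <- function(calls, catalog, params = filter_params()) {
  .check_calls(calls)
  cat_ok <- catalog[(catalog$end - catalog$start) >= params$min_catalog_size, ,
                    drop = FALSE]
  thr <- params$reciprocal_overlap_threshold
  flag <- rep(FALSE, nrow(calls))
  if (nrow(calls) && nrow(cat_ok)) {
    hits <- IRanges::findOverlaps(.as_iranges(calls), .as_iranges(cat_ok))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    type_ok <- cat_ok$svtype[si] == "multiallelic" |
      cat_ok$svtype[si] == calls$type[qi]
    ov <- .overlap_len(calls$start[qi], calls$end[qi],
                       cat_ok$start[si], cat_ok$end[si])
    ro <- type_ok &
      ov / (calls$end[qi] - calls$start[qi]) >= thr &
      ov / (cat_ok$end[si] - cat_ok$start[si]) >= thr
    flag[unique(qi[ro])] <- TRUE
  }
  calls$in_catalog <- flag
  summ <- do.call(rbind, lapply(c("deletion", "duplication"), function(tp) {
    n <- sum(calls$type == tp)
    k <- sum(calls$type == tp & calls$in_catalog)
    data.frame(type = tp, n = n, in_catalog = k,
               fraction = if (n) k / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, summary = summ)
}

# single-linkage union-find clustering of same-type calls under the
# reciprocal-overlap relation
.cluster_regions <- function(calls, thr) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  if (n > 1) {
    ir <- .as_iranges(calls)
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi < si & calls$type[qi] == calls$type[si]
    qi <- qi[keep]; si <- si[keep]
    if (length(qi)) {
      ov <- .overlap_len(calls$start[qi], calls$end[qi],
                         calls$start[si], calls$end[si])
      ro <- ov / (calls$end[qi] - calls$start[qi]) >= thr &
        ov / (calls$end[si] - calls$start[si]) >= thr
      for (k in which(ro)) unite(qi[k], si[k])
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Collapse calls into regions and classify frequency
#'
#' Same-type calls are clustered by single-linkage under the 50%
#' reciprocal-overlap relation; each region's frequency is its carrier
#' count (a sample counts once regardless of call multiplicity) divided by
#' the cohort size, and regions below `rare_frequency_cutoff` are labelled
#' rare.
#'
#' @param calls CNV call `data.frame`.
#' @param cohort_size Number of samples screened.
#' @param params A [filter_params()].
#' @return List with `calls` (input plus `region_id`) and `regions`
#'   (`region_id`, `type`, `start`, `end`, `carriers`, `frequency`,
#'   `rare`).
#' @export
classify_frequency <- function(calls, cohort_size, params = filter_params()) {
  if (cohort_size < 1) stop("empty cohort", call. = FALSE)
  .check_calls(calls)
  if (!nrow(calls)) {
    calls$region_id <- character(0)
    return(list(calls = calls,
                regions = data.frame(region_id = character(), type = character(),
                                     start = numeric(), end = numeric(),
                                     carriers = integer(), frequency = numeric(),
                                     rare = logical(), stringsAsFactors = FALSE)))
  }
  comp <- .cluster_regions(calls, params$reciprocal_overlap_threshold)
  ids <- match(comp, sort(unique(comp)))
  calls$region_id <- sprintf("R%03d", ids)
  regions <- do.call(rbind, lapply(split(seq_len(nrow(calls)), calls$region_id),
    function(idx) {
      data.frame(region_id = calls$region_id[idx[1]],
                 type = calls$type[idx[1]],
                 start = min(calls$start[idx]), end = max(calls$end[idx]),
                 carriers = length(unique(calls$sample_id[idx])),
                 stringsAsFactors = FALSE)
    }))
  regions$frequency <- regions$carriers / cohort_size
  regions$rare <- regions$frequency < params$rare_frequency_cutoff
  rownames(regions) <- NULL
  list(calls = calls, regions = regions)
}
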