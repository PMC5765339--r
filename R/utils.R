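# Internal helpers shared across modules.  All intervals 0-based half-open.

# overlap length of [s1,e1) and [s2,e2); vectorized
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# any-overlap predicate on half-open intervals
.overlaps <- function(s1, e1, s2, e2) {
  pmin(e1, e2) > pmax(s1, s2)
}

# IRanges view of a 0-based half-open interval data.frame (same chromosome
# assumed by callers; chr21-only designs keep this simple)
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# sample SD guarded for length-1 input
.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

# empty CNV call table with canonical columns
.empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(), type = character(),
             n_probes = integer(), mean_log2 = numeric(),
             callers = character(), stringsAsFactors = FALSE)
}

.check_calls <- function(calls) {
  .stopifnot_cols(calls, c("sample_id", "chrom", "start", "end", "type",
                           "n_probes", "mean_log2"), "CNV call table")
  if (nrow(calls) && !all(calls$type %in% c("deletion", "duplication"))) {
    stop("CNV type must be 'deletion' or 'duplication'", call. = FALSE)
  }
  invisible(calls)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# derive a reproducible child seed (< 2^31) from a parent seed and stage tag
.child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}
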