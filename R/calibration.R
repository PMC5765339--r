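#' Trisomy-aware frequency bounds for a called deletion
#'
#' On a trisomic background a called deletion can represent one, two, or
#' (in principle) all three of the three expected copies, so `d` calls
#' among `S` samples (3S chromosomes) bound the chromosome-level variant
#' frequency by `lower = d / (3S)` (every call is a single lost copy) and
#' `upper = d / S` (every call is a full loss).  The bounds are kept as
#' exact integer rationals; `lower = upper / 3` holds exactly.
#'
#' @param d Number of times the variant was called (one call per sample
#'   per region).
#' @param n_samples Number of samples `S` screened.
#' @return A `freq_band` list: `d`, `n_samples`, `lower`, `upper`, and the
#'   exact rationals `lower_num`/`lower_den`, `upper_num`/`upper_den`.
#' @export
freq_bounds <- function(d, n_samples) {
  d <- as.integer(d); n_samples <- as.integer(n_samples)
  if (d < 0) stop("d must be non-negative", call. = FALSE)
  if (d > n_samples) stop("d cannot exceed the number of samples", call. = FALSE)
  structure(list(d = d, n_samples = n_samples,
                 lower_num = d, lower_den = 3L * n_samples,
                 upper_num = d, upper_den = n_samples,
                 lower = d / (3 * n_samples), upper = d / n_samples),
            class = "freq_band")
}

#' Reference-deletion detection fraction
#'
#' The hybridization reference carries a known deletion, so every
#' non-carrier test sample should show a duplication call over that
#' interval.  Returns the fraction of the given samples with at least one
#' duplication call overlapping the interval by >= 1 bp.
#'
#' @param calls CNV call `data.frame`.
#' @param sample_ids Non-carrier test samples to evaluate.
#' @param interval Numeric length-2, the reference deletion (0-based
#'   half-open; default chr21:45,555,257-45,615,042).
#' @return Fraction in `[0, 1]`.
#' @export
reference_deletion_detection <- function(calls, sample_ids,
                                         interval = c(45555256, 45615042)) {
  if (!length(sample_ids)) stop("empty cohort", call. = FALSE)
  hits <- calls[calls$type == "duplication" &
                  .overlaps(calls$start, calls$end, interval[1], interval[2]), ]
  mean(sample_ids %in% hits$sample_id)
}

# one-call-per-sample carrier count for a catalog variant at >= 50%
# reciprocal overlap with a same-type call
.catalog_carrier_count <- function(calls, variant, ro_threshold = 0.5) {
  same <- calls[calls$type == variant$svtype, , drop = FALSE]
  if (!nrow(same)) return(0L)
  ov <- .overlap_len(same$start, same$end, variant$start, variant$end)
  hit <- ov / (same$end - same$start) >= ro_threshold &
    ov / (variant$end - variant$start) >= ro_threshold
  length(unique(same$sample_id[hit]))
}

#' Heuristic calibration of the elimination threshold Tm
#'
#' Sweeps `Tm` over 4.5-20.5 by half steps; at each value the cohort is
#' called (segmentation + shift caller + concordance) and evaluated on two
#' criteria: (1) a duplication overlapping the reference-deletion interval
#' is detected in at least `detection_min` of the test samples, and
#' (2) every designated calibration variant's catalog frequency falls
#' inside its trisomy frequency band `[d/(3S), d/S]`, where `d` is the
#' number of samples with a concordant same-type call at >= 50% reciprocal
#' overlap.  For a calibration variant recorded in a specific population,
#' `d` and `S` are computed within that population's samples, as the
#' catalog frequency is population-specific.  The selected Tm is the
#' largest value satisfying both (most conservative).  Detection is
#' non-increasing in Tm on fixed data.
#'
#' @param log2mat QC-passed probes x samples matrix.
#' @param design Probe design aligned to `log2mat` rows.
#' @param catalog Variant catalog; rows with `calibration = TRUE` and size
#'   >= `min_catalog_size` are the bracketing requirement.
#' @param params A [seg_params()]; its `t_threshold` is ignored in favor
#'   of the grid.
#' @param tm_grid Numeric grid of thresholds (default `seq(4.5, 20.5, 0.5)`,
#'   33 values).
#' @param detection_min Required reference-deletion detection fraction
#'   (default 0.8).
#' @param ref_interval Reference-deletion interval (0-based half-open).
#' @param min_catalog_size Smallest catalog variant considered detectable
#'   (default 1798 bp).
#' @param adm2_z Score floor for the shift caller.
#' @param populations Optional character vector of population labels named
#'   by sample id; required when a calibration variant is
#'   population-specific.
#' @return A `calibration_result` list: `grid` (per-Tm `data.frame` with
#'   `tm`, `detection`, `all_bracketed`, `qualifies`), `per_variant`
#'   (per-Tm, per-variant `d`, bounds and bracket flag), `selected_tm`
#'   (NA on failure), `status` (`"ok"`/`"failed"`), and `calls` at the
#'   selected Tm.
#' @export
sweep_tm <- function(log2mat, design, catalog, params = seg_params(),
                     tm_grid = seq(4.5, 20.5, by = 0.5),
                     detection_min = 0.8,
                     ref_interval = c(45555256, 45615042),
                     min_catalog_size = 1798, adm2_z = 5,
                     populations = NULL) {
  stopifnot(nrow(log2mat) == nrow(design))
  cal <- catalog[catalog$calibration &
                   (catalog$end - catalog$start) >= min_catalog_size, ,
                 drop = FALSE]
  if (nrow(cal) && any(cal$population != "ALL") && is.null(populations)) {
    stop("population-specific calibration variants need `populations`",
         call. = FALSE)
  }
  for (k in seq_len(nrow(cal))) {
    cov <- sum(.overlaps(design$start, design$end, cal$start[k], cal$end[k]))
    if (cov < params$min_seg_len) {
      stop(sprintf("calibration variant %s covered by %d < %d probes",
                   cal$variant_id[k], cov, params$min_seg_len), call. = FALSE)
    }
  }
  samples <- colnames(log2mat)
  S <- length(samples)
  states <- lapply(samples, function(sid) {
    y <- gc_correct(center_profile(log2mat[, sid]), design)
    .sweep_sample_state(y, design, params, adm2_z)
  })
  names(states) <- samples

  grid_rows <- vector("list", length(tm_grid))
  pv_rows <- vector("list", length(tm_grid))
  calls_by_tm <- vector("list", length(tm_grid))
  for (ti in seq_along(tm_grid)) {
    tm <- tm_grid[ti]
    calls <- do.call(rbind, lapply(samples, function(sid) {
      .sweep_sample_calls_at_tm(states[[sid]], tm, design, params, sid)
    }))
    calls_by_tm[[ti]] <- calls
    det <- reference_deletion_detection(calls, samples, ref_interval)
    if (nrow(cal)) {
      pv <- do.call(rbind, lapply(seq_len(nrow(cal)), function(k) {
        pop <- cal$population[k]
        eval_samples <- if (pop == "ALL") samples
                        else samples[populations[samples] == pop]
        if (!length(eval_samples)) {
          stop(sprintf("no samples from population '%s' for variant %s",
                       pop, cal$variant_id[k]), call. = FALSE)
        }
        sub <- calls[calls$sample_id %in% eval_samples, , drop = FALSE]
        d <- .catalog_carrier_count(sub, cal[k, ])
        fb <- freq_bounds(d, length(eval_samples))
        data.frame(tm = tm, variant_id = cal$variant_id[k],
                   population = pop, frequency = cal$frequency[k], d = d,
                   n_samples = length(eval_samples),
                   lower = fb$lower, upper = fb$upper,
                   bracketed = fb$lower <= cal$frequency[k] &
                     cal$frequency[k] <= fb$upper,
                   stringsAsFactors = FALSE)
      }))
    } else {
      pv <- NULL
    }
    all_br <- is.null(pv) || all(pv$bracketed)
    grid_rows[[ti]] <- data.frame(tm = tm, detection = det,
                                  all_bracketed = all_br,
                                  qualifies = det >= detection_min & all_br)
    pv_rows[[ti]] <- pv
  }
  grid <- do.call(rbind, grid_rows)
  ok <- grid$tm[grid$qualifies]
  selected <- if (length(ok)) max(ok) else NA_real_
  structure(list(
    grid = grid, per_variant = do.call(rbind, pv_rows),
    selected_tm = selected,
    status = if (is.na(selected)) "failed" else "ok",
    calls = if (is.na(selected)) NULL else
      calls_by_tm[[which(tm_grid == selected)]]),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Tm sweep over %d values: status %s, selected Tm = %s\n",
              nrow(x$grid), x$status, format(x$selected_tm)))
  invisible(x)
}
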