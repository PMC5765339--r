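test_that("DLR matches hand-computed values and its invariances", {
  expect_equal(compute_dlr(rep(0.1, 100)), 0)
  # diffs of [0, .2, 0, .2, 0] are [.2,-.2,.2,-.2]; sample SD = 0.23094
  expect_equal(compute_dlr(c(0, 0.2, 0, 0.2, 0)), 0.2309401, tolerance = 1e-6)
  y <- rnorm(50)
  expect_equal(compute_dlr(y + 5), compute_dlr(y))       # translation
  expect_equal(compute_dlr(3 * y), 3 * compute_dlr(y))   # linear scaling
  expect_error(compute_dlr(c(1, 2)), "3 probes")
})

test_that("DLR filter retains strictly below the 0.3 boundary", {
  mk <- function(dlr) {
    # alternating +/- d/2 has successive diffs +/-d; sample SD ~ d
    d <- dlr * sqrt((100 - 1) / 100)  # adjust so sample SD == dlr (99 diffs)
    y <- rep(c(0, 1), 50)[1:100] * d
    y
  }
  m <- cbind(a = mk(0.29), b = mk(0.30))
  # exact construction: verify computed DLRs straddle the boundary
  dlrs <- apply(m, 2, compute_dlr)
  m <- m[, order(dlrs)]
  res <- filter_arrays_dlr(m, threshold = mean(dlrs))
  expect_equal(ncol(res$log2), 1)
  expect_equal(res$report$excluded, colnames(m)[2])

  flat <- matrix(0, 10, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(length(filter_arrays_dlr(flat)$report$excluded), 0)
})

test_that("bad arrays fail DLR far more often than clean arrays", {
  cfg <- sim_config(n_probes = 800, n_cases = c(Caucasian = 30),
                    n_controls = c(Caucasian = 30),
                    bad_array_fraction = 0.2,
                    bad_array_variance_multiplier = 9,
                    planted_variants = default_planted_variants()[0, ],
                    seed = 17)
  co <- simulate_cohort(cfg)
  res <- filter_arrays_dlr(co$log2)
  bad <- co$meta$sample_id[co$meta$bad_array]
  rate_bad <- mean(bad %in% res$report$excluded)
  rate_clean <- mean(setdiff(co$meta$sample_id, bad) %in% res$report$excluded)
  expect_gte(rate_bad, 0.9)
  expect_lt(rate_clean, rate_bad / 2)
})

test_that("array variance/mean filters recompute the documented thresholds", {
  set.seed(3)
  m <- matrix(rnorm(200 * 10, sd = 0.1), 200, 10,
              dimnames = list(NULL, paste0("S", 1:10)))
  m[, 7] <- rnorm(200, sd = sqrt(10) * 0.1)   # one 10x-variance array
  res <- filter_arrays_variance(m)
  v <- apply(m, 2, var)
  expect_setequal(res$report$excluded, colnames(m)[v >= mean(v) + sd(v)])
  expect_true("S7" %in% res$report$excluded)
  # invariance to column order
  perm <- sample(10)
  expect_setequal(filter_arrays_variance(m[, perm])$report$excluded,
                  res$report$excluded)

  m2 <- matrix(rnorm(200 * 10, sd = 0.05), 200, 10,
               dimnames = list(NULL, paste0("S", 1:10)))
  m2[, 4] <- m2[, 4] + 0.5
  res2 <- filter_arrays_mean(m2)
  expect_equal(res2$report$excluded, "S4")
  # sign flip leaves the exclusion set unchanged (two-sided rule)
  expect_equal(filter_arrays_mean(-m2)$report$excluded, "S4")

  # degenerate spread excludes nothing
  same <- matrix(rep(rnorm(50), 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(length(filter_arrays_variance(same)$report$excluded), 0)
  expect_equal(length(filter_arrays_mean(same)$report$excluded), 0)
  expect_error(filter_arrays_variance(m[, 1, drop = FALSE]), "2 arrays")
})

test_that("probe variance filter removes planted bad probes", {
  cfg <- sim_config(n_probes = 2000, n_cases = c(Caucasian = 40),
                    n_controls = c(Caucasian = 40),
                    bad_array_fraction = 0, array_noise_sdlog = 0,
                    bad_probe_fraction = 0.01,
                    bad_probe_variance_multiplier = 16,
                    planted_variants = default_planted_variants()[0, ],
                    seed = 23)
  co <- simulate_cohort(cfg)
  res <- filter_probes_variance(co$log2)
  bad <- co$design$probe_id[co$design$bad_probe]
  expect_gte(mean(!bad %in% res$retained_probes), 0.9)
  # single array: defined no-op with a warning
  expect_warning(r1 <- filter_probes_variance(co$log2[, 1, drop = FALSE]),
                 "single array")
  expect_equal(nrow(r1$log2), nrow(co$log2))
})

test_that("iid probe exclusion fraction matches the chi-square tail", {
  set.seed(9)
  n_arr <- 60
  m <- matrix(rnorm(3000 * n_arr, sd = 0.15), 3000, n_arr,
              dimnames = list(sprintf("p%04d", 1:3000), paste0("S", 1:n_arr)))
  res <- filter_probes_variance(m)
  frac <- 1 - length(res$retained_probes) / 3000
  # Monte Carlo oracle for the same rule on iid normal probe rows
  mc <- replicate(200, {
    v <- rchisq(3000, n_arr - 1) / (n_arr - 1)
    mean(v >= mean(v) + sd(v))
  })
  expect_gt(frac, quantile(mc, 0.001))
  expect_lt(frac, quantile(mc, 0.999))
})

test_that("CNV-count outlier filter excludes extreme samples once", {
  # a lone outlier among n samples can reach at most (n-1)/sqrt(n) SDs,
  # so a 5-SD rule needs a reasonably sized cohort to trigger at all
  ids <- paste0("S", 1:50)
  calls <- data.frame(sample_id = rep(ids, 1), chrom = "chr21",
                      start = 1000, end = 2000, type = "deletion",
                      n_probes = 6L, mean_log2 = -0.5, callers = "c",
                      stringsAsFactors = FALSE)
  res <- filter_samples_cnv_count(calls, ids)   # everyone has 1 deletion
  expect_equal(res$retained, ids)

  extra <- calls[rep(1, 50), ]; extra$sample_id <- "S1"
  calls2 <- rbind(calls, extra)
  res2 <- filter_samples_cnv_count(calls2, ids)
  expect_equal(res2$report$excluded, "S1")
  # single evaluation: the remaining samples are not re-tested after exclusion
  expect_equal(sort(res2$retained), sort(setdiff(ids, "S1")))
})

test_that("QC cascade applies stages in order and conserves counts", {
  fx <- small_cohort()
  qc <- run_array_qc(fx$cohort$log2)
  expect_equal(names(qc$reports),
               c("dlr", "probe_variance", "array_variance", "array_mean"))
  for (r in qc$reports) {
    expect_equal(r$n_before - length(r$excluded), r$n_after)
  }
  expect_equal(ncol(qc$log2), qc$reports$array_mean$n_after)
  expect_equal(nrow(qc$log2), qc$reports$probe_variance$n_after)
})
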