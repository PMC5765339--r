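# Shared fixtures and independent oracles.  Heavy fixtures are cached per
# test session.

.fixture_env <- new.env(parent = emptyenv())

# small, fast cohort for module-level tests: 40 arrays, 1200 probes,
# no bad arrays/probes so planted effects are the only structure
small_cohort <- function(seed = 11, ...) {
  key <- paste0("small", seed, paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_probes = 1200,
                      n_cases = c(Caucasian = 10, AfricanAmerican = 10),
                      n_controls = c(Caucasian = 10, AfricanAmerican = 10),
                      bad_array_fraction = 0, bad_probe_fraction = 0,
                      array_noise_sdlog = 0, seed = seed, ...)
    .fixture_env[[key]] <- list(config = cfg, cohort = simulate_cohort(cfg))
  }
  .fixture_env[[key]]
}

# the full default study-condition cohort, QC'd, swept over Tm, and called
# at Tm = 8; shared by the calibration/recovery acceptance checks
default_study_fixture <- function(seed = 20240917) {
  if (is.null(.fixture_env$default_study)) {
    cfg <- sim_config(seed = seed)
    cohort <- simulate_cohort(cfg)
    qc <- run_array_qc(cohort$log2)
    design <- cohort$design[match(rownames(qc$log2), cohort$design$probe_id), ]
    catalog <- simulate_catalog(cfg)
    pops <- setNames(cohort$meta$population, cohort$meta$sample_id)
    sweep <- sweep_tm(qc$log2, design, catalog, seg_params(),
                      populations = pops)
    calls8 <- call_cnvs(qc$log2, design, seg_params(t_threshold = 8))
    .fixture_env$default_study <- list(
      config = cfg, cohort = cohort, qc = qc, design = design,
      catalog = catalog, sweep = sweep, calls8 = calls8)
  }
  .fixture_env$default_study
}

# ---- independent oracles -------------------------------------------------

# exact one-sided Fisher tail by direct binomial-coefficient summation
oracle_fisher_p <- function(a, n1, c_, n2, direction = "cases") {
  K <- a + c_
  js <- max(0, K - n2):min(n1, K)
  logp <- lchoose(n1, js) + lchoose(n2, K - js) - lchoose(n1 + n2, K)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  if (direction == "cases") sum(p[js >= a]) else sum(p[js <= a])
}

# HWE exact p by full enumeration of heterozygote counts via log-factorials
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(hom_min) - lfactorial(hom_maj) -
      lfactorial(h) + h * log(2) +
      lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n_Aa)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# minimum residual sum of squares over all partitions of y with exactly k
# breakpoints (dynamic programming over segment ends)
oracle_dp_rss <- function(y, k) {
  n <- length(y)
  S <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {           # probes i..j, 1-based inclusive
    (S2[j + 1] - S2[i]) - (S[j + 1] - S[i])^2 / (j - i + 1)
  }
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in i:n) cost[i, j] <- sse(i, j)
  # dp[m, j]: best RSS for first j probes split into m segments
  dp <- matrix(Inf, k + 1, n)
  dp[1, ] <- cost[1, ]
  if (k > 0) {
    for (m in 2:(k + 1)) {
      for (j in m:n) {
        dp[m, j] <- min(dp[m - 1, (m - 1):(j - 1)] + cost[m:j, j])
      }
    }
  }
  dp[k + 1, n]
}

rss_of_segments <- function(y, seg) {
  sum(vapply(seq_len(nrow(seg)), function(i) {
    v <- y[seg$i_start[i]:seg$i_end[i]]
    sum((v - mean(v))^2)
  }, 0))
}

# simple per-sample burden-metric generator (counts Poisson, sizes
# exponential in kb) for calibration/power properties of the permutation
# kernel
sim_burden_metric <- function(n, lambda = 1, mean_kb = 20) {
  k <- stats::rpois(n, lambda)
  vapply(k, function(x) sum(stats::rexp(x, 1 / mean_kb)), 0)
}

expect_lossless_tsv <- function(write_fn, read_fn, obj, ...) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fn(obj, path, ...)
  obj2 <- read_fn(path)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_fn(obj2, path2, ...)
  expect_identical(readLines(path), readLines(path2))
  invisible(obj2)
}
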