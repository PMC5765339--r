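test_that("noise-free cohort reproduces the analytic copy-ratio shifts", {
  cfg <- sim_config(n_probes = 400, noise_sd = 1e-12,
                    n_cases = c(Caucasian = 2), n_controls = c(Caucasian = 2),
                    bad_array_fraction = 0, bad_probe_fraction = 0,
                    array_noise_sdlog = 0, array_offset_sd = 0,
                    planted_variants = default_planted_variants()[0, ],
                    seed = 5)
  co <- simulate_cohort(cfg)
  rdi <- cfg$reference_deletion_interval
  inside <- co$design$start < rdi[2] & co$design$end > rdi[1]
  expect_true(any(inside))
  # outside the reference deletion every probe reads 0; inside, +log2(3/2)
  expect_equal(max(abs(co$log2[!inside, ])), 0, tolerance = 1e-6)
  expect_equal(unname(co$log2[inside, 1]), rep(log2(3 / 2), sum(inside)),
               tolerance = 1e-6)

  # a planted deletion sits at log2(2/3) in carriers
  pv <- data.frame(id = "d1", start = 20000000, end = 21000000,
                   type = "deletion", frequency = 0.999, population = "ALL",
                   case_enrichment = 1, in_catalog = TRUE, calibration = FALSE,
                   stringsAsFactors = FALSE)
  cfg2 <- sim_config(n_probes = 400, noise_sd = 1e-12,
                     n_cases = c(Caucasian = 2), n_controls = c(Caucasian = 2),
                     bad_array_fraction = 0, bad_probe_fraction = 0,
                     array_noise_sdlog = 0, array_offset_sd = 0,
                     planted_variants = pv, seed = 5)
  co2 <- simulate_cohort(cfg2)
  expect_equal(nrow(co2$truth), 4)  # freq ~1 => everyone carries it
  din <- co2$design$start < pv$end & co2$design$end > pv$start
  expect_equal(mean(co2$log2[din, 1]), log2(2 / 3), tolerance = 1e-6)
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 300, n_cases = c(Caucasian = 3),
                    n_controls = c(Caucasian = 3), seed = 99)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$log2, b$log2)
  expect_identical(a$truth, b$truth)
  g1 <- simulate_genotypes(c(A = 5, B = 5), 50, fst = 0.1, seed = 4)
  g2 <- simulate_genotypes(c(A = 5, B = 5), 50, fst = 0.1, seed = 4)
  expect_identical(g1$dosage, g2$dosage)
})

test_that("simulator validates planted variants and genotype fst", {
  pv <- default_planted_variants()
  pv$frequency[1] <- 1.5
  expect_error(sim_config(planted_variants = pv), "frequency")
  pv <- default_planted_variants()
  pv$start[1] <- 1e6; pv$end[1] <- 2e6  # outside 15.4-47 Mb probe territory
  expect_error(simulate_cohort(sim_config(n_probes = 300, planted_variants = pv)),
               "outside the probe territory")
  expect_error(simulate_genotypes(c(A = 5, B = 5), 10, fst = 0), "fst")
  expect_error(simulate_genotypes(c(A = 5, B = 5), 10, fst = 0.7), "fst")
})

test_that("segment means inside planted variants match the analytic shift", {
  # noise sd 0.15, >= 10-probe variants: mean within 3*sd/sqrt(n) nearly always
  pv <- data.frame(id = c("d1", "u1", "d2"),
                   start = c(20000000, 28000000, 36000000),
                   end = c(20400000, 28400000, 36400000),
                   type = c("deletion", "duplication", "deletion"),
                   frequency = c(0.3, 0.3, 0.3), population = "ALL",
                   case_enrichment = 1, in_catalog = TRUE,
                   calibration = FALSE, stringsAsFactors = FALSE)
  cfg <- sim_config(n_probes = 1200, n_cases = c(Caucasian = 15),
                    n_controls = c(Caucasian = 15), bad_array_fraction = 0,
                    bad_probe_fraction = 0, array_noise_sdlog = 0,
                    planted_variants = pv, seed = 61)
  co <- simulate_cohort(cfg)
  ok <- 0L; tot <- 0L
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    idx <- co$design$start < tr$end & co$design$end > tr$start
    if (sum(idx) < 10) next
    mu <- if (tr$type == "deletion") log2(2 / 3) else log2(4 / 3)
    dev <- abs(mean(co$log2[idx, tr$sample_id]) - mu)
    tot <- tot + 1L
    if (dev < 3 * 0.15 / sqrt(sum(idx))) ok <- ok + 1L
  }
  expect_gt(tot, 20)
  expect_gte(ok / tot, 0.95)
})

test_that("empirical carrier frequency converges to the trisomic carrier probability", {
  pv <- data.frame(id = "d1", start = 20000000, end = 21000000,
                   type = "deletion", frequency = 0.2, population = "ALL",
                   case_enrichment = 1, in_catalog = TRUE, calibration = FALSE,
                   stringsAsFactors = FALSE)
  cfg <- sim_config(n_probes = 300, n_cases = c(Caucasian = 250),
                    n_controls = c(Caucasian = 250), planted_variants = pv,
                    bad_array_fraction = 0, seed = 31)
  co <- simulate_cohort(cfg)
  p_carrier <- 1 - (1 - 0.2)^3   # three chromosomes at allele frequency 0.2
  obs <- nrow(co$truth) / 500
  ci <- stats::binom.test(nrow(co$truth), 500, p_carrier)$p.value
  expect_gt(ci, 0.001)
  expect_lt(abs(obs - p_carrier), 0.06)
})

test_that("Balding-Nichols genotypes separate populations in PCA at fst 0.1", {
  g <- simulate_genotypes(c(A = 50, B = 50), 2000, fst = 0.1, seed = 8)
  pca <- pca_stratify(g$dosage, n_components = 2)
  pc1 <- pca$eigenvectors[, 1]
  expect_true(max(pc1[g$population == "A"]) < min(pc1[g$population == "B"]) ||
              max(pc1[g$population == "B"]) < min(pc1[g$population == "A"]))
})

test_that("gene models tile the design and degenerate cases behave", {
  fx <- small_cohort()
  gm <- simulate_gene_models(fx$cohort$design, n_genes = 10, seed = 2)
  expect_equal(nrow(gm$genes), 10)
  # every exon covers at least one probe
  for (i in seq_len(nrow(gm$exons))) {
    expect_true(any(fx$cohort$design$start < gm$exons$end[i] &
                    fx$cohort$design$end > gm$exons$start[i]))
  }
  # single gene spanning the whole design intersects any call
  gm1 <- simulate_gene_models(fx$cohort$design, n_genes = 1,
                              exons_per_gene = 2, seed = 2)
  expect_equal(gm1$genes$tx_start, min(fx$cohort$design$start))
  expect_equal(gm1$genes$tx_end, max(fx$cohort$design$end))
  gm0 <- simulate_gene_models(fx$cohort$design, n_genes = 0, seed = 2)
  expect_equal(nrow(gm0$genes), 0)
  expect_error(simulate_gene_models(fx$cohort$design, n_genes = 1e6),
               "territory")
  expect_identical(simulate_gene_models(fx$cohort$design, 5, seed = 1),
                   simulate_gene_models(fx$cohort$design, 5, seed = 1))
})

test_that("the catalog records planted in_catalog variants and avoids others", {
  fx <- small_cohort()
  catalog <- simulate_catalog(fx$config)
  pv <- fx$config$planted_variants
  expect_setequal(paste0("cat_", pv$id[pv$in_catalog]),
                  catalog$variant_id[grepl("^cat_", catalog$variant_id)])
  bg <- catalog[grepl("^bg", catalog$variant_id), ]
  for (i in seq_len(nrow(bg))) {
    expect_false(any(bg$start[i] < pv$end & bg$end[i] > pv$start))
  }
})
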