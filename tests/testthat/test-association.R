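mk_genes <- function() {
  gm <- list(
    genes = data.frame(gene_symbol = c("G1", "G2"), chrom = "chr21",
                       strand = "+", tx_start = c(1000, 9000),
                       tx_end = c(5000, 12000), stringsAsFactors = FALSE),
    exons = data.frame(gene_symbol = c("G1", "G1", "G2"),
                       start = c(1000, 4000, 9000),
                       end = c(1500, 4500, 9500), stringsAsFactors = FALSE))
  class(gm) <- "gene_models"
  gm
}

cnv <- function(s, e, type, sid = "S1") {
  data.frame(sample_id = sid, chrom = "chr21", start = s, end = e,
             type = type, n_probes = 8L,
             mean_log2 = ifelse(type == "deletion", -0.5, 0.4),
             callers = "c", stringsAsFactors = FALSE)
}

test_that("reduced-to-disomy membership follows the exon/breakpoint rules", {
  genes <- mk_genes()
  calls <- rbind(
    cnv(900, 2000, "deletion"),          # covers exon -> in
    cnv(1600, 3900, "deletion"),         # intron-only -> out
    cnv(4200, 8000, "duplication"),      # breakpoint inside exon -> in
    cnv(500, 6000, "duplication"),       # envelopes G1, intergenic bps -> out
    cnv(2000, 3000, "duplication"))      # intronic dup, no exon bp -> out
  set <- build_reduced_to_disomy_set(calls, genes)
  expect_equal(set$calls$start, c(900, 4200))
  # the enveloping duplication belongs to the full-gene set instead
  fg <- build_full_gene_duplication_set(calls, genes)
  expect_equal(fg$calls$start, 500)
})

test_that("full-gene duplication containment is inclusive and call-level", {
  genes <- mk_genes()
  exact <- cnv(1000, 5000, "duplication")     # equals G1 span
  expect_equal(nrow(build_full_gene_duplication_set(exact, genes)$calls), 1)
  half <- cnv(1000, 3000, "duplication")
  expect_equal(nrow(build_full_gene_duplication_set(half, genes)$calls), 0)
  both <- cnv(500, 13000, "duplication")      # covers G1 and G2: counted once
  expect_equal(nrow(build_full_gene_duplication_set(both, genes)$calls), 1)
})

test_that("one-sided Fisher reproduces the duplication-burden worked example", {
  f <- fisher_one_sided(5, 174, 1, 181, "cases")
  expect_equal(round(f$odds_ratio, 1), 5.3)
  expect_equal(round(f$one_sided_p, 2), 0.10)
  expect_equal(round(f$ci_95[1], 2), 0.75)
  expect_true(is.infinite(f$ci_95[2]))
})

test_that("Fisher handles nulls, zero margins and matches the oracle", {
  f <- fisher_one_sided(2, 10, 2, 10, "cases")
  expect_equal(f$odds_ratio, 1)
  expect_gt(f$one_sided_p, 0.5)
  fz <- fisher_one_sided(3, 10, 0, 10, "cases")
  expect_true(fz$or_undefined)
  expect_true(is.na(fz$odds_ratio))
  expect_lte(fz$one_sided_p, 1)
  set.seed(40)
  for (r in 1:100) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    dir <- sample(c("cases", "controls"), 1)
    expect_equal(fisher_one_sided(a, n1, c_, n2, dir, conf_int = FALSE)$one_sided_p,
                 oracle_fisher_p(a, n1, c_, n2, dir), tolerance = 1e-10)
  }
})

test_that("burden p-values respect the (k+1)/(B+1) floor and tie behavior", {
  x <- rep(1, 20)
  is_case <- rep(c(TRUE, FALSE), 10)
  r <- perm_mean_test(x, is_case, "cases", n_permutations = 500, seed = 3)
  expect_gte(r$empirical_p, 0.5)          # identical groups
  expect_gt(r$empirical_p, 0)             # never exactly 0
  expect_error(perm_mean_test(x, rep(TRUE, 20), "cases"), "empty")
  # determinism
  y <- rnorm(20)
  expect_identical(perm_mean_test(y, is_case, "cases", 200, seed = 7),
                   perm_mean_test(y, is_case, "cases", 200, seed = 7))
})

test_that("3-vs-3 burden p matches the exhaustive permutation oracle", {
  set.seed(44)
  for (r in 1:10) {
    x <- round(rnorm(6), 2)
    is_case <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    obs <- mean(x[1:3]) - mean(x[4:6])
    combos <- combn(6, 3)
    stats <- apply(combos, 2, function(ii) mean(x[ii]) - mean(x[-ii]))
    p_exact <- mean(stats >= obs - 1e-12)
    B <- 4000
    p_mc <- perm_mean_test(x, is_case, "cases", B, seed = r)$empirical_p
    se <- sqrt(p_exact * (1 - p_exact) / B)
    expect_lt(abs(p_mc - p_exact), 2 * se + 2 / B)
  }
})

test_that("burden_test computes RATE/KBTOT/GRATE on calls", {
  meta <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                     phenotype = c("case", "case", "control", "control"),
                     stringsAsFactors = FALSE)
  calls <- rbind(cnv(1000, 5000, "deletion", "S1"),
                 cnv(9000, 12000, "deletion", "S1"),
                 cnv(1000, 3000, "deletion", "S3"))
  bm <- burden_metrics(calls, meta$sample_id, mk_genes())
  expect_equal(bm$RATE, c(2, 0, 1, 0))
  expect_equal(bm$KBTOT, c(7, 0, 2, 0))
  expect_equal(bm$GRATE, c(2, 0, 1, 0))
  bt <- burden_test(calls, meta, "KBTOT", "cases", n_permutations = 200,
                    seed = 2)
  expect_equal(bt$mean_case, 3.5)
  expect_equal(bt$mean_control, 1)
  expect_error(burden_test(calls, meta, "GRATE", "cases"), "gene models")
})

test_that("region association matches hypergeometric enumeration", {
  meta <- data.frame(sample_id = paste0("S", 1:20),
                     phenotype = rep(c("case", "control"), each = 10),
                     stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(paste0("S", 1:10), function(s)
    cnv(1000000, 1050000, "duplication", s)))
  res <- region_association(calls, meta, n_permutations = 20000, seed = 5)
  expect_equal(res$case_carriers, 10)
  expect_equal(res$control_carriers, 0)
  # exact one-sided p: all 10 carriers in cases = 1 / C(20,10)
  p_exact <- 1 / choose(20, 10)
  expect_lt(abs(res$empirical_p - p_exact), 3e-3)
  # balanced region: p near 1
  calls2 <- do.call(rbind, lapply(paste0("S", c(1:5, 11:15)), function(s)
    cnv(1000000, 1050000, "duplication", s)))
  res2 <- region_association(calls2, meta, n_permutations = 2000, seed = 5)
  expect_gt(res2$empirical_p, 0.5)
  expect_equal(nrow(region_association(calls[0, ], meta, 100, 1)), 0)
})

test_that("gene association tests carrier excess per gene", {
  meta <- data.frame(sample_id = paste0("S", 1:20),
                     phenotype = rep(c("case", "control"), each = 10),
                     stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(paste0("S", 1:5), function(s)
    cnv(1000, 2000, "duplication", s)))
  res <- gene_association(calls, mk_genes(), meta, n_permutations = 20000,
                          seed = 9)
  expect_equal(res$gene_symbol, "G1")       # G2 untouched: omitted
  expect_equal(res$case_carriers, 5)
  p_exact <- choose(15, 5) / choose(20, 10)  # P(all 5 carriers are cases)
  expect_lt(abs(res$empirical_p - p_exact), 0.01)
  genes_bad <- mk_genes()
  genes_bad$genes$gene_symbol <- c("G1", "G1")
  expect_error(gene_association(calls, genes_bad, meta), "duplicate")
})

test_that("Mann-Whitney agrees with wilcox.test and full separation is 1/C(n1+n2,n1)", {
  set.seed(50)
  # tie-free exact path against the independent wilcox.test oracle
  for (r in 1:30) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- mann_whitney_one_sided(x, y, "greater")
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # full separation
  x <- 10 + (1:5); y <- 1:5
  expect_equal(mann_whitney_one_sided(x, y, "greater")$p,
               1 / choose(10, 5), tolerance = 1e-12)
  # identical distributions: p >= 0.5
  expect_gte(mann_whitney_one_sided(y, y, "greater")$p, 0.5)
  # tie correction: with ties present, the approximation stays a proper p
  x <- sample(1:3, 8, replace = TRUE); y <- sample(1:3, 8, replace = TRUE)
  p_tied <- mann_whitney_one_sided(x, y, "greater", exact_max = 0)$p
  expect_gt(p_tied, 0); expect_lte(p_tied, 1)
})

test_that("probe-ratio replication test flags a planted dosage difference", {
  set.seed(60)
  probes <- paste0("probe", 1:3)
  ref <- setNames(c(100, 120, 90), probes)
  ctrl <- matrix(rpois(3 * 8, lambda = rep(c(100, 120, 90), 8)), nrow = 3,
                 dimnames = list(probes, paste0("C", 1:8)))
  case <- matrix(rpois(3 * 8, lambda = rep(c(100, 120, 90), 8)), nrow = 3,
                 dimnames = list(probes, paste0("A", 1:8)))
  case["probe2", ] <- rpois(8, 120 * 2 / 3)     # deletion-like drop in cases
  res <- nanostring_ratio_test(case, ctrl, ref, direction = "less")
  expect_equal(res$method, rep("exact_enumeration", 3))
  expect_lt(res$one_sided_p[2], 0.05)
  expect_gt(min(res$one_sided_p[c(1, 3)]), 0.05)
  expect_error(nanostring_ratio_test(case, ctrl, setNames(c(100, 0, 90),
                                                          probes)),
               "zero reference")
})
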