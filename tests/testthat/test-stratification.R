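test_that("HWE exact test matches enumeration and known cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)        # monomorphic
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)       # total het deficit
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
  expect_error(hwe_exact_test(-1, 2, 3), "negative")
  # random triples against the log-factorial enumeration oracle
  set.seed(12)
  for (r in 1:200) {
    n <- sample(3:50, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c_ <- n - a - b
    expect_equal(hwe_exact_test(a, b, c_), oracle_hwe_p(a, b, c_),
                 tolerance = 1e-9,
                 info = sprintf("(%d,%d,%d)", a, b, c_))
  }
})

test_that("SNP QC drops by missingness, HWE and MAF at the stated boundaries", {
  set.seed(21)
  n <- 100
  good <- rbinom(n, 2, 0.3)
  miss11 <- good; miss11[1:11] <- NA                  # 11% missing -> drop
  miss10 <- good; miss10[1:10] <- NA                  # 10% -> keep
  hwe_bad <- c(rep(0L, 50), rep(2L, 50))              # het deficit
  maf5 <- c(rep(1L, 10), rep(0L, 90))                 # MAF exactly 0.05 -> drop
  d <- cbind(good = good, miss11 = miss11, miss10 = miss10,
             hwe_bad = hwe_bad, maf5 = maf5)
  res <- snp_qc(d)
  expect_setequal(res$retained, c("good", "miss10"))
  expect_equal(res$report$dropped, c(1, 1, 1))
})

test_that("SNPs simulated under HWE almost never fail the HWE filter", {
  set.seed(22)
  d <- sapply(runif(2000, 0.1, 0.9), function(p) rbinom(200, 2, p))
  p <- apply(d, 2, function(g) hwe_exact_test(sum(g == 0), sum(g == 1),
                                              sum(g == 2)))
  expect_lte(sum(p < 1e-6), 1)
})

test_that("LD pruning removes correlated SNPs and keeps independent ones", {
  set.seed(30)
  n <- 80
  base <- rbinom(n, 2, 0.4)
  d <- cbind(a = base, b = base,                         # duplicated column
             c = rbinom(n, 2, 0.4), e = rbinom(n, 2, 0.4))
  map <- data.frame(snp_id = c("a", "b", "c", "e"),
                    pos = c(1000, 2000, 3000, 4000))
  kept <- ld_prune(d, map)
  expect_true("a" %in% kept)       # later duplicate removed
  expect_false("b" %in% kept)
  expect_true(all(c("c", "e") %in% kept))

  # independent SNPs (r2 < 0.2) are all retained
  set.seed(31)
  ind <- sapply(1:20, function(i) rbinom(200, 2, 0.5))
  colnames(ind) <- paste0("s", 1:20)
  map2 <- data.frame(snp_id = colnames(ind), pos = seq(1000, by = 2000,
                                                       length.out = 20))
  expect_equal(ld_prune(ind, map2), colnames(ind))
  expect_error(ld_prune(ind, map2[rev(seq_len(20)), ]), "sorted")
})

test_that("small-instance pruning matches a global greedy oracle", {
  set.seed(33)
  n <- 60
  d <- matrix(NA_integer_, n, 20)
  d[, 1] <- rbinom(n, 2, 0.5)
  for (j in 2:20) {
    # chain of correlation so pruning decisions cascade
    copy <- runif(1) < 0.4
    d[, j] <- if (copy) d[, j - 1] else rbinom(n, 2, 0.5)
  }
  colnames(d) <- sprintf("s%02d", 1:20)
  map <- data.frame(snp_id = colnames(d), pos = seq(100, by = 100,
                                                    length.out = 20))
  # all SNPs sit in one 50 kb window, so the window rule reduces to the
  # global greedy rule: repeatedly drop the later SNP of the first
  # offending pair
  keep <- rep(TRUE, 20)
  repeat {
    done <- TRUE
    for (i in 1:19) {
      if (!keep[i]) next
      for (j in (i + 1):20) {
        if (!keep[j]) next
        r2 <- suppressWarnings(cor(d[, i], d[, j]))^2
        if (!is.na(r2) && r2 > 0.2) { keep[j] <- FALSE; done <- FALSE }
      }
    }
    if (done) break
  }
  expect_setequal(ld_prune(d, map), colnames(d)[keep])
})

test_that("PCA eigenvectors are orthonormal and conserve variance", {
  g <- simulate_genotypes(c(A = 30, B = 30), 500, fst = 0.1, seed = 14)
  pca <- pca_stratify(g$dosage, n_components = 5)
  ev <- pca$eigenvectors
  expect_equal(crossprod(ev), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_true(all(pca$eigenvalues >= -1e-10))
  expect_equal(sum(pca$eigenvalues), pca$total_variance,
               tolerance = 1e-8 * pca$total_variance)
  # permutation equivariance
  perm <- sample(nrow(g$dosage))
  pca2 <- pca_stratify(g$dosage[perm, ], n_components = 2)
  expect_equal(abs(pca2$eigenvectors[, 1]),
               abs(pca$eigenvectors[perm, 1]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(pca_stratify(g$dosage[1:3, ], n_components = 5), "fewer samples")
  expect_error(pca_stratify(matrix(1L, 10, 4)), "zero variance")
})

test_that("symmetric-mode outlier flags are invariant to eigenvector sign", {
  g <- simulate_genotypes(c(A = 40, B = 10), 800, fst = 0.15, seed = 19)
  pca <- pca_stratify(g$dosage, 2)
  cut <- quantile(abs(pca$eigenvectors[, 1]), 0.8)
  out1 <- pca_stratify(g$dosage, 2, cutoff = cut, mode = "symmetric")$outliers
  flipped <- pca_stratify(-g$dosage + 2L, 2, cutoff = cut,
                          mode = "symmetric")$outliers
  # sign conventions may differ between runs; the symmetric rule is stable
  expect_setequal(out1, flipped)
})

test_that("two-round stratification flags per-population PC1 outliers", {
  g <- simulate_genotypes(c(Caucasian = 40, AfricanAmerican = 40), 1500,
                          fst = 0.1, seed = 25)
  st <- stratify_cohort(g$dosage, g$population,
                        round2_cutoffs = list(Caucasian = -0.9,
                                              AfricanAmerican = -0.9))
  # extreme cutoffs flag nobody; PC1 of round 1 separates the populations
  expect_equal(length(st$removed), 0)
  pc1 <- st$round1$eigenvectors[, 1]
  expect_true(max(pc1[g$population == "Caucasian"]) <
                min(pc1[g$population == "AfricanAmerican"]) ||
              max(pc1[g$population == "AfricanAmerican"]) <
                min(pc1[g$population == "Caucasian"]))
})
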