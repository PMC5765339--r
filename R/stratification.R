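#' Genotype QC parameters
#'
#' @param max_missingness SNPs with missingness above this are dropped
#'   (default 0.10).
#' @param hwe_alpha SNPs with Hardy-Weinberg exact p below this are
#'   dropped (default 1e-6).
#' @param min_maf SNPs with minor allele frequency at or below this are
#'   dropped (default 0.05; only MAF > 0.05 is kept).
#' @param prune_window LD-pruning window in bp (default 50,000).
#' @param prune_step Window advance in SNPs (default 5).
#' @param max_r2 Genotypic correlation r^2 above which one SNP of a pair
#'   is pruned (default 0.2).
#' @param n_components Number of principal components (default 5).
#' @return A `geno_qc_params` list.
#' @export
geno_qc_params <- function(max_missingness = 0.10, hwe_alpha = 1e-6,
                           min_maf = 0.05, prune_window = 50000,
                           prune_step = 5, max_r2 = 0.2, n_components = 5) {
  stopifnot(max_missingness > 0, max_missingness < 1, prune_window > 0,
            min_maf > 0, min_maf < 1, max_r2 > 0, max_r2 < 1)
  structure(list(max_missingness = max_missingness, hwe_alpha = hwe_alpha,
                 min_maf = min_maf, prune_window = prune_window,
                 prune_step = prune_step, max_r2 = max_r2,
                 n_components = n_components),
            class = "geno_qc_params")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value
#' is the sum of probabilities of all heterozygote counts (same parity)
#' that are no more probable than the observed one.  Probabilities follow
#' the standard recurrence on the number of heterozygotes, evaluated
#' stably from the distribution mode.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all-zero genotype counts", call. = FALSE)
  n_minor <- 2L * n_aa + n_Aa
  n_minor <- min(n_minor, 2L * n - n_minor)
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_hom_minor(h) * n_hom_major(h) / ((h+2)(h+1))
  # walk up from the smallest heterozygote count in log space
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1L]
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - (h + n_minor) / 2
    logp[i] <- logp[i - 1L] +
      log(4 * hom_minor * hom_major) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("heterozygote count has impossible parity", call. = FALSE)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' SNP quality control
#'
#' Drops SNPs with missingness above `max_missingness`, then SNPs failing
#' the Hardy-Weinberg exact test at `hwe_alpha`, then SNPs with MAF at or
#' below `min_maf`, in that order.
#'
#' @param dosage Samples x SNPs minor-allele dosage matrix (0/1/2/NA).
#' @param params A [geno_qc_params()].
#' @return List with `dosage` (retained columns), `retained` SNP ids, and
#'   `report` (per-rule drop counts).
#' @export
snp_qc <- function(dosage, params = geno_qc_params()) {
  miss <- colMeans(is.na(dosage))
  keep1 <- miss <= params$max_missingness
  d1 <- dosage[, keep1, drop = FALSE]
  hwe_p <- apply(d1, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep2 <- hwe_p >= params$hwe_alpha
  d2 <- d1[, keep2, drop = FALSE]
  maf <- apply(d2, 2, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  keep3 <- maf > params$min_maf
  d3 <- d2[, keep3, drop = FALSE]
  list(dosage = d3, retained = colnames(d3),
       report = data.frame(
         rule = c("missingness", "hwe", "maf"),
         dropped = c(sum(!keep1), sum(!keep2), sum(!keep3))))
}

# genotypic correlation r^2 on pairwise-complete dosages
.r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  r <- suppressWarnings(stats::cor(x[ok], y[ok]))
  if (is.na(r)) 0 else r^2
}

#' LD pruning by pairwise r-squared in sliding windows
#'
#' Windows of `prune_window` bp advance by `prune_step` SNPs; within each
#' window any pair with genotypic r^2 above `max_r2` loses its later
#' (by position) SNP.  Passes repeat until no window changes.
#'
#' @param dosage Samples x SNPs dosage matrix.
#' @param map `data.frame` with `snp_id` and `pos`, sorted by position.
#' @param params A [geno_qc_params()].
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(dosage, map, params = geno_qc_params()) {
  map <- map[map$snp_id %in% colnames(dosage), , drop = FALSE]
  if (is.unsorted(map$pos)) stop("map is not sorted by position", call. = FALSE)
  keep <- setNames(rep(TRUE, nrow(map)), map$snp_id)
  pos <- map$pos
  n <- nrow(map)
  repeat {
    changed <- FALSE
    s <- 1L
    while (s <= n) {
      in_win <- which(keep & pos >= pos[s] & pos < pos[s] + params$prune_window)
      in_win <- in_win[in_win >= s]
      if (length(in_win) > 1) {
        i <- 1L
        while (i < length(in_win)) {
          j <- i + 1L
          while (j <= length(in_win)) {
            a <- in_win[i]; b <- in_win[j]
            if (.r2(dosage[, map$snp_id[a]], dosage[, map$snp_id[b]]) >
                params$max_r2) {
              keep[b] <- FALSE
              changed <- TRUE
              in_win <- in_win[-j]
            } else j <- j + 1L
          }
          i <- i + 1L
        }
      }
      s <- s + params$prune_step
    }
    if (!changed) break
  }
  map$snp_id[keep]
}

#' Principal component analysis of standardized dosages
#'
#' Each SNP is centered by twice its allele frequency and scaled by
#' `sqrt(2 p (1-p))`; missing dosages are mean-imputed (zero after
#' centering).  Eigen-decomposition of the sample-by-sample covariance of
#' the standardized matrix yields orthonormal sample eigenvectors with
#' non-increasing, non-negative eigenvalues.  Optionally flags outliers on
#' PC1, either one-sided (`PC1 <= cutoff`, matching how visually flagged
#' outliers are usually encoded) or symmetric (`|PC1| >= |cutoff|`, immune
#' to the arbitrary sign of an eigenvector).
#'
#' @param dosage Samples x SNPs dosage matrix (QC'd and pruned).
#' @param n_components Number of components to return.
#' @param cutoff Optional PC1 outlier cutoff.
#' @param mode `"signed"` or `"symmetric"`.
#' @return A `pca_result` list: `eigenvectors` (samples x n_components),
#'   `eigenvalues` (all), `total_variance` (trace of the covariance), and
#'   `outliers` (sample ids, when a cutoff is given).
#' @export
pca_stratify <- function(dosage, n_components = 5, cutoff = NULL,
                         mode = c("signed", "symmetric")) {
  mode <- match.arg(mode)
  n <- nrow(dosage)
  if (n < n_components) stop("fewer samples than components", call. = FALSE)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  v <- apply(dosage, 2, stats::var, na.rm = TRUE)
  ok <- p > 0 & p < 1 & !is.na(p) & !is.na(v) & v > 0
  if (!any(ok)) stop("all SNPs have zero variance", call. = FALSE)
  x <- dosage[, ok, drop = FALSE]
  p <- p[ok]
  x <- sweep(x, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  K <- tcrossprod(x) / ncol(x)
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors[, seq_len(n_components), drop = FALSE]
  rownames(vecs) <- rownames(dosage)
  colnames(vecs) <- paste0("PC", seq_len(n_components))
  outliers <- NULL
  if (!is.null(cutoff)) {
    flag <- if (mode == "signed") vecs[, 1] <= cutoff
            else abs(vecs[, 1]) >= abs(cutoff)
    outliers <- rownames(vecs)[flag]
  }
  structure(list(eigenvectors = vecs, eigenvalues = vals,
                 total_variance = sum(diag(K)), outliers = outliers),
            class = "pca_result")
}

#' Two-round stratification with PC1 outlier removal
#'
#' Round 1 runs PCA on the full cohort (separating self-identified
#' populations along PC1); round 2 reruns PCA within each population and
#' flags PC1 outliers at the per-population cutoffs.  Cutoffs are
#' data-dependent in practice, so they are parameters, not constants.
#'
#' @param dosage Samples x SNPs dosage matrix (post [snp_qc()] and
#'   [ld_prune()]).
#' @param population Character vector of population labels per sample.
#' @param params A [geno_qc_params()].
#' @param round2_cutoffs Named numeric of per-population PC1 cutoffs.
#' @param mode Outlier mode, see [pca_stratify()].
#' @return List with `round1` (pca_result), `round2` (per-population
#'   pca_result), and `removed` (sample ids flagged in round 2).
#' @export
stratify_cohort <- function(dosage, population, params = geno_qc_params(),
                            round2_cutoffs = NULL,
                            mode = c("signed", "symmetric")) {
  mode <- match.arg(mode)
  round1 <- pca_stratify(dosage, params$n_components)
  pops <- unique(population)
  round2 <- list(); removed <- character(0)
  for (p in pops) {
    idx <- population == p
    if (sum(idx) < params$n_components) next
    cutoff <- round2_cutoffs[[p]]
    r2 <- pca_stratify(dosage[idx, , drop = FALSE], params$n_components,
                       cutoff = cutoff, mode = mode)
    round2[[p]] <- r2
    removed <- c(removed, r2$outliers)
  }
  list(round1 = round1, round2 = round2, removed = removed)
}
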