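#' Default planted variants for the simulated cohort
#'
#' Four chromosome-21 variants emulating the structure the study design
#' needs: a common deletion restricted to the African American population
#' and used for frequency-band calibration (chromosome-level frequency
#' 0.227, mirroring a common African-ancestry 1000 Genomes deletion), a
#' lower-frequency Caucasian deletion (0.064, mirroring its
#' European-ancestry counterpart), a rare case-enriched duplication, and a
#' rare control-enriched deletion.  `frequency` is the per-chromosome
#' (allele) frequency; on a trisomic background the per-sample carrier
#' probability is `1 - (1 - frequency)^3`.  Keeping the common variants
#' population-restricted also keeps their probes' interarray variance
#' below the probe-QC cutoff, as in real mixed cohorts.
#'
#' @return `data.frame` with columns `id`, `start`, `end`, `type`,
#'   `frequency`, `population`, `case_enrichment`, `in_catalog`,
#'   `calibration` (coordinates 0-based half-open).
#' @export
default_planted_variants <- function() {
  data.frame(
    id = c("common_del_cal", "common_del_low", "risk_dup", "protective_del"),
    start = c(33000000, 24000000, 38380000, 28000000),
    end   = c(33120000, 24075000, 38810000, 28070000),
    type  = c("deletion", "deletion", "duplication", "deletion"),
    frequency = c(0.227, 0.064, 0.010, 0.020),
    population = c("AfricanAmerican", "Caucasian", "ALL", "ALL"),
    case_enrichment = c(1, 1, 3, 1/3),
    in_catalog = c(TRUE, TRUE, FALSE, TRUE),
    calibration = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every knob of the trisomic aCGH cohort simulator.  Defaults are
#' a desk-scale rendering of the study design: 250 arrays in two
#' self-identified populations, probe noise SD 0.15 log2 units, 5% noisy
#' ("bad") arrays at 9x variance, 0.5% noisy probes at 49x variance (the
#' heavy-tailed probe population that motivates the probe-variance QC
#' cut), per-array mean offsets N(0, 0.01^2), and a reference sample
#' carrying a deletion at chr21:45,555,257-45,615,042 that surfaces as a
#' +log2(3/2) duplication signal in every non-carrier test sample.
#'
#' @param n_probes Number of chr21 probes (a scaled-down rendering of the
#'   52,944-probe design; spacing scales accordingly).
#' @param region Numeric length-2, simulated probe territory in bp
#'   (0-based half-open).
#' @param probe_length Probe footprint in bp.
#' @param n_cases,n_controls Named integer vectors of per-population counts.
#' @param noise_sd Per-probe Gaussian noise SD in log2 units.
#' @param bad_array_fraction,bad_array_variance_multiplier Fraction of
#'   arrays with inflated variance, and the variance multiplier.
#' @param bad_probe_fraction,bad_probe_variance_multiplier Fraction of
#'   probes with inflated variance across all arrays, and the multiplier.
#' @param array_noise_sdlog Continuous per-array hybridization-quality
#'   heterogeneity: each array's noise SD is multiplied by a lognormal
#'   factor with this log-SD (default 0.2).  Without it the clean-array
#'   variance distribution is unrealistically tight and the array-variance
#'   QC cut would preferentially discard arrays that merely carry a real
#'   CNV.
#' @param array_offset_sd SD of per-array mean log2 offsets.
#' @param gc_slope Linear GC bias: added log2 per unit (gc - mean gc);
#'   default 0.
#' @param planted_variants `data.frame` as in [default_planted_variants()].
#' @param reference_deletion_interval Numeric length-2, the reference
#'   sample's deletion (0-based half-open).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 4500,
                       region = c(15400000, 47000000),
                       probe_length = 60,
                       n_cases = c(Caucasian = 72, AfricanAmerican = 48),
                       n_controls = c(Caucasian = 78, AfricanAmerican = 52),
                       noise_sd = 0.15,
                       bad_array_fraction = 0.05,
                       bad_array_variance_multiplier = 9,
                       bad_probe_fraction = 0.005,
                       bad_probe_variance_multiplier = 49,
                       array_noise_sdlog = 0.2,
                       array_offset_sd = 0.01,
                       gc_slope = 0,
                       planted_variants = default_planted_variants(),
                       reference_deletion_interval = c(45555256, 45615042),
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), region = region,
              probe_length = probe_length,
              n_cases = n_cases, n_controls = n_controls,
              noise_sd = noise_sd,
              bad_array_fraction = bad_array_fraction,
              bad_array_variance_multiplier = bad_array_variance_multiplier,
              bad_probe_fraction = bad_probe_fraction,
              bad_probe_variance_multiplier = bad_probe_variance_multiplier,
              array_noise_sdlog = array_noise_sdlog,
              array_offset_sd = array_offset_sd,
              gc_slope = gc_slope,
              planted_variants = planted_variants,
              reference_deletion_interval = reference_deletion_interval,
              seed = as.integer(seed))
  stopifnot(cfg$noise_sd > 0,
            cfg$bad_array_fraction >= 0, cfg$bad_array_fraction <= 1,
            cfg$bad_probe_fraction >= 0, cfg$bad_probe_fraction <= 1)
  if (nrow(planted_variants)) {
    if (any(planted_variants$frequency > 1 | planted_variants$frequency < 0)) {
      stop("planted variant frequency outside [0,1]", call. = FALSE)
    }
    pv <- planted_variants[order(planted_variants$start), ]
    if (nrow(pv) > 1 && any(pv$start[-1] < pv$end[-nrow(pv)])) {
      stop("planted variants may not overlap one another", call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the probe design
#'
#' Probes are laid on a jittered grid across the configured territory so
#' the median spacing equals span / n_probes; GC fraction of the 2 kb
#' window around each probe is drawn Uniform(0.3, 0.7).
#'
#' @param config A [sim_config()].
#' @return Probe design `data.frame` (0-based half-open, sorted), with a
#'   simulator annotation column `bad_probe`.
#' @export
simulate_probe_design <- function(config) {
  set.seed(.child_seed(config$seed, "design"))
  n <- config$n_probes
  span <- diff(config$region)
  spacing <- span / n
  centers <- config$region[1] + (seq_len(n) - 0.5) * spacing +
    runif(n, -0.3, 0.3) * spacing
  start <- round(centers - config$probe_length / 2)
  design <- data.frame(
    probe_id = sprintf("p%05d", seq_len(n)),
    chrom = "chr21",
    start = start, end = start + config$probe_length,
    gc_fraction = round(runif(n, 0.3, 0.7), 4),
    is_backbone = FALSE,
    bad_probe = runif(n) < config$bad_probe_fraction,
    stringsAsFactors = FALSE)
  design[order(design$start), ]
}

#' Simulate a trisomic aCGH cohort with ground truth
#'
#' Per probe the signal is `log2(test_copies / ref_copies)` plus Gaussian
#' noise and a per-array offset.  Reference copies are 2 inside the
#' reference sample's deletion and 3 elsewhere; test copies are 3 except
#' inside planted variants carried by the sample (2 for deletions, 4 for
#' duplications).  Noisy ("bad") arrays and probes get inflated noise SD.
#' A truth record is emitted for every planted variant a sample carries.
#'
#' @param config A [sim_config()].
#' @return A `tri_cohort` list: `design` (probe table), `log2`
#'   (probes x samples matrix), `meta` (sample table with `sample_id`,
#'   `phenotype`, `population`, `sex`, and simulator annotation
#'   `bad_array`), and `truth` (`sample_id`, `chrom`, `start`, `end`,
#'   `type`, `copies`).
#' @export
simulate_cohort <- function(config) {
  design <- simulate_probe_design(config)
  set.seed(.child_seed(config$seed, "cohort"))
  pv <- config$planted_variants
  lo <- min(design$start); hi <- max(design$end)
  if (nrow(pv) && (any(pv$start < lo) || any(pv$end > hi))) {
    stop("planted variant outside the probe territory", call. = FALSE)
  }
  rdi <- config$reference_deletion_interval
  if (sum(.overlaps(design$start, design$end, rdi[1], rdi[2])) < 1) {
    stop("reference deletion interval contains no probes", call. = FALSE)
  }

  pops <- union(names(config$n_cases), names(config$n_controls))
  meta <- do.call(rbind, lapply(pops, function(p) {
    nc <- config$n_cases[[p]] %||% 0L
    nn <- config$n_controls[[p]] %||% 0L
    data.frame(phenotype = rep(c("case", "control"), c(nc, nn)),
               population = p, stringsAsFactors = FALSE)
  }))
  n_samp <- nrow(meta)
  meta$sample_id <- sprintf("S%03d", seq_len(n_samp))
  meta$sex <- sample(c("M", "F"), n_samp, replace = TRUE)
  meta$bad_array <- runif(n_samp) < config$bad_array_fraction
  meta <- meta[, c("sample_id", "phenotype", "population", "sex", "bad_array")]

  # copy-number template: reference copies per probe
  ref_copies <- ifelse(.overlaps(design$start, design$end, rdi[1], rdi[2]), 2, 3)

  # carrier draws per planted variant (allele frequency on 3 chromosomes)
  carrier <- matrix(FALSE, nrow = n_samp, ncol = nrow(pv))
  if (nrow(pv)) {
    for (k in seq_len(nrow(pv))) {
      f <- rep(pv$frequency[k], n_samp)
      f[meta$phenotype == "case"] <- pmin(pv$frequency[k] * pv$case_enrichment[k], 0.99)
      if (pv$population[k] != "ALL") f[meta$population != pv$population[k]] <- 0
      p_carrier <- 1 - (1 - f)^3
      carrier[, k] <- runif(n_samp) < p_carrier
    }
  }

  probe_sd <- config$noise_sd *
    ifelse(design$bad_probe, sqrt(config$bad_probe_variance_multiplier), 1)
  array_sd_fac <- ifelse(meta$bad_array,
                         sqrt(config$bad_array_variance_multiplier), 1) *
    exp(rnorm(n_samp, 0, config$array_noise_sdlog))
  array_offset <- rnorm(n_samp, 0, config$array_offset_sd)
  gc_term <- config$gc_slope * (design$gc_fraction - mean(design$gc_fraction))

  log2mat <- matrix(0, nrow = nrow(design), ncol = n_samp,
                    dimnames = list(design$probe_id, meta$sample_id))
  truth_rows <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    test_copies <- rep(3, nrow(design))
    carried <- which(carrier[j, ])
    for (k in carried) {
      idx <- .overlaps(design$start, design$end, pv$start[k], pv$end[k])
      test_copies[idx] <- if (pv$type[k] == "deletion") 2 else 4
    }
    mu <- log2(test_copies / ref_copies) + array_offset[j] + gc_term
    log2mat[, j] <- mu + rnorm(nrow(design), 0, probe_sd * array_sd_fac[j])
    if (length(carried)) {
      truth_rows[[j]] <- data.frame(
        sample_id = meta$sample_id[j], chrom = "chr21",
        start = pv$start[carried], end = pv$end[carried],
        type = pv$type[carried],
        copies = ifelse(pv$type[carried] == "deletion", 2L, 4L),
        variant_id = pv$id[carried], stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth)) {
    truth <- data.frame(sample_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        type = character(), copies = integer(),
                        variant_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(design = design, log2 = log2mat, meta = meta,
                 truth = truth, config = config),
            class = "tri_cohort")
}

#' @export
print.tri_cohort <- function(x, ...) {
  cat(sprintf("tri_cohort: %d probes x %d arrays (%d cases / %d controls), %d truth records\n",
              nrow(x$design), nrow(x$meta),
              sum(x$meta$phenotype == "case"),
              sum(x$meta$phenotype == "control"), nrow(x$truth)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate two-population SNP genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each
#' population's frequency is Beta(p(1-fst)/fst, (1-p)(1-fst)/fst); diploid
#' genotypes are Binomial(2, population frequency).
#'
#' @param n_per_pop Named integer vector of samples per population.
#' @param n_snps Number of independent SNPs.
#' @param fst Divergence parameter in (0, 0.5].
#' @param seed Integer seed.
#' @param missing_rate Fraction of genotype calls set missing (default 0).
#' @return List with `dosage` (samples x SNPs), `map` (chrom/snp_id/cm/pos),
#'   and `population` (character vector per sample).
#' @export
simulate_genotypes <- function(n_per_pop, n_snps, fst, seed = 1L,
                               missing_rate = 0) {
  if (fst <= 0) stop("fst must be > 0", call. = FALSE)
  if (fst > 0.5) stop("fst must be <= 0.5", call. = FALSE)
  set.seed(.child_seed(seed, "genotypes"))
  pops <- names(n_per_pop)
  if (is.null(pops)) pops <- paste0("pop", seq_along(n_per_pop))
  p_anc <- runif(n_snps, 0.05, 0.95)
  shape <- (1 - fst) / fst
  pop_freq <- vapply(seq_along(n_per_pop), function(i) {
    rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
  }, numeric(n_snps))
  dosage <- do.call(rbind, lapply(seq_along(n_per_pop), function(i) {
    matrix(rbinom(n_per_pop[i] * n_snps, 2, rep(pop_freq[, i], each = n_per_pop[i])),
           nrow = n_per_pop[i], ncol = n_snps)
  }))
  if (missing_rate > 0) {
    dosage[matrix(runif(length(dosage)) < missing_rate, nrow(dosage))] <- NA_integer_
  }
  population <- rep(pops, n_per_pop)
  pos <- sort(sample.int(48000000, n_snps))
  map <- data.frame(chrom = "21", snp_id = sprintf("snp%06d", seq_len(n_snps)),
                    cm = 0, pos = pos, stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  colnames(dosage) <- map$snp_id
  list(dosage = dosage, map = map, population = population)
}

#' Simulate gene models tiling the probe territory
#'
#' The probe axis is divided into `n_genes` contiguous blocks; each gene
#' spans its block's probes and carries `exons_per_gene` exons, each
#' covering at least one probe.
#'
#' @param design Probe design `data.frame`.
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene.
#' @param seed Integer seed.
#' @return A `gene_models` object (see [read_gene_models()]).
#' @export
simulate_gene_models <- function(design, n_genes = 150, exons_per_gene = 4,
                                 seed = 1L) {
  if (nrow(design) == 0) stop("empty probe design", call. = FALSE)
  if (n_genes < 1) {
    gm <- list(genes = data.frame(gene_symbol = character(), chrom = character(),
                                  strand = character(), tx_start = numeric(),
                                  tx_end = numeric(), stringsAsFactors = FALSE),
               exons = data.frame(gene_symbol = character(), start = numeric(),
                                  end = numeric(), stringsAsFactors = FALSE))
    class(gm) <- "gene_models"
    return(gm)
  }
  if (n_genes * exons_per_gene > nrow(design)) {
    stop("n_genes exceeds the available probe territory", call. = FALSE)
  }
  set.seed(.child_seed(seed, "genes"))
  n <- nrow(design)
  bounds <- floor(seq(0, n, length.out = n_genes + 1))
  genes <- vector("list", n_genes); exons <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    idx <- (bounds[g] + 1L):bounds[g + 1L]
    tx_start <- design$start[idx[1]]
    tx_end <- design$end[idx[length(idx)]]
    sym <- sprintf("GENE%03d", g)
    strand <- sample(c("+", "-"), 1)
    ex_idx <- idx[unique(floor(seq(1, length(idx), length.out = exons_per_gene)))]
    ex_start <- pmax(design$start[ex_idx] - 200, tx_start)
    ex_end <- pmin(design$end[ex_idx] + 200, tx_end)
    keep <- c(TRUE, ex_start[-1] >= ex_end[-length(ex_end)])
    genes[[g]] <- data.frame(gene_symbol = sym, chrom = "chr21",
                             strand = strand, tx_start = tx_start,
                             tx_end = tx_end, stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_symbol = sym, start = ex_start[keep],
                             end = ex_end[keep], stringsAsFactors = FALSE)
  }
  gm <- list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
  class(gm) <- "gene_models"
  validate_gene_models(gm)
}

#' Simulate a DGV-like variant catalog
#'
#' Emits one entry per planted variant flagged `in_catalog`, carrying its
#' configured chromosome-level frequency and calibration designation, plus
#' background entries placed away from all planted variants and the
#' reference deletion.
#'
#' @param config A [sim_config()].
#' @param n_background Number of background catalog entries.
#' @return Catalog `data.frame` (see [read_catalog()]).
#' @export
simulate_catalog <- function(config, n_background = 30) {
  set.seed(.child_seed(config$seed, "catalog"))
  pv <- config$planted_variants
  planted <- pv[pv$in_catalog, , drop = FALSE]
  cat_pl <- data.frame(
    variant_id = paste0("cat_", planted$id), chrom = "chr21",
    start = planted$start, end = planted$end,
    svtype = planted$type, population = planted$population,
    frequency = planted$frequency, calibration = planted$calibration,
    stringsAsFactors = FALSE)
  avoid <- rbind(pv[, c("start", "end")],
                 data.frame(start = config$reference_deletion_interval[1],
                            end = config$reference_deletion_interval[2]))
  bg <- list(); tries <- 0
  while (length(bg) < n_background && tries < 50 * n_background) {
    tries <- tries + 1
    size <- round(exp(runif(1, log(1798), log(120000))))
    s <- round(runif(1, config$region[1], config$region[2] - size))
    if (any(.overlaps(s, s + size, avoid$start, avoid$end))) next
    bg[[length(bg) + 1L]] <- data.frame(
      variant_id = sprintf("bg%04d", length(bg) + 1L), chrom = "chr21",
      start = s, end = s + size,
      svtype = sample(c("deletion", "duplication", "multiallelic"), 1),
      population = "ALL", frequency = round(runif(1, 0.001, 0.05), 4),
      calibration = FALSE, stringsAsFactors = FALSE)
  }
  rbind(cat_pl, do.call(rbind, bg))
}
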