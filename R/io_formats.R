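#' Read a probe design table
#'
#' Reads the tab-separated probe design (columns `probe_id`, `chrom`,
#' `start`, `end`, `gc_fraction`, `is_backbone`).  On disk coordinates are
#' 1-based inclusive; in memory they become 0-based half-open.  Probes are
#' sorted by (chrom, start) on load.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` with columns `probe_id`, `chrom`, `start`, `end`,
#'   `gc_fraction`, `is_backbone`; 0-based half-open coordinates.
#' @export
read_probe_design <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  .stopifnot_cols(df, c("probe_id", "chrom", "start", "end"), "probe design")
  start <- suppressWarnings(as.numeric(df$start))
  end   <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed coordinate in probe design at line %d",
                 bad[1] + 1L), call. = FALSE)  # +1 for the header line
  }
  if (any(end < start)) {
    stop(sprintf("end < start in probe design at line %d",
                 which(end < start)[1] + 1L), call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in probe design: ",
         df$probe_id[duplicated(df$probe_id)][1], call. = FALSE)
  }
  out <- data.frame(
    probe_id = df$probe_id, chrom = df$chrom,
    start = start - 1, end = end,
    gc_fraction = if ("gc_fraction" %in% names(df)) as.numeric(df$gc_fraction) else NA_real_,
    is_backbone = if ("is_backbone" %in% names(df)) as.logical(as.integer(df$is_backbone)) else FALSE,
    stringsAsFactors = FALSE)
  if (any(!is.na(out$gc_fraction) & (out$gc_fraction < 0 | out$gc_fraction > 1))) {
    stop("gc_fraction outside [0,1]", call. = FALSE)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a probe design table
#'
#' Inverse of [read_probe_design()]; emits 1-based inclusive coordinates.
#'
#' @param design Probe design `data.frame` (0-based half-open).
#' @param path Output path.
#' @export
write_probe_design <- function(design, path) {
  out <- data.frame(
    probe_id = design$probe_id, chrom = design$chrom,
    start = format(design$start + 1, scientific = FALSE, trim = TRUE),
    end = format(design$end, scientific = FALSE, trim = TRUE),
    gc_fraction = sprintf("%.4f", design$gc_fraction),
    is_backbone = as.integer(design$is_backbone),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probes-by-samples log2 ratio matrix
#'
#' The matrix is stored as TSV with probe ids in the first column and one
#' column per sample.
#'
#' @param path File path.
#' @return Numeric matrix, rownames = probe ids, colnames = sample ids.
#' @export
read_log2_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_log2_matrix
#' @param mat Numeric matrix (probes x samples).
#' @export
write_log2_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.PLINK_TYPE <- c(deletion = 1L, duplication = 3L)

#' Write CNV calls to PLINK .cnv or BED
#'
#' In the `plink_cnv` dialect the columns are
#' `FID IID CHR BP1 BP2 TYPE SCORE SITES` with 1-based inclusive
#' coordinates and TYPE 1 = deletion (two of three copies),
#' TYPE 3 = duplication (four of three copies) relative to the trisomic
#' baseline of three copies; a leading `#` comment line declares the
#' baseline.  The `bed` dialect emits 0-based half-open `chrom start end
#' name score` rows.
#'
#' @param calls CNV call `data.frame` (see [consensus_calls()]).
#' @param path Output path.
#' @param dialect `"plink_cnv"` or `"bed"`.
#' @export
write_cnv_calls <- function(calls, path, dialect = c("plink_cnv", "bed")) {
  dialect <- match.arg(dialect)
  .check_calls(calls)
  if (nrow(calls) && any(calls$n_probes < 1)) {
    stop("call with zero probes cannot be written", call. = FALSE)
  }
  if (dialect == "plink_cnv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# baseline: trisomic (TYPE 1 = loss to 2 of 3 copies, TYPE 3 = gain to 4 of 3 copies)", con)
    writeLines("FID\tIID\tCHR\tBP1\tBP2\tTYPE\tSCORE\tSITES", con)
    if (nrow(calls)) {
      lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%d\t%.4f\t%d",
                       calls$sample_id, calls$sample_id,
                       sub("^chr", "", calls$chrom),
                       format(calls$start + 1, scientific = FALSE, trim = TRUE),
                       format(calls$end, scientific = FALSE, trim = TRUE),
                       .PLINK_TYPE[calls$type], calls$mean_log2, calls$n_probes)
      writeLines(lines, con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(calls)) {
      lines <- sprintf("%s\t%s\t%s\t%s;%s\t%.4f",
                       calls$chrom,
                       format(calls$start, scientific = FALSE, trim = TRUE),
                       format(calls$end, scientific = FALSE, trim = TRUE),
                       calls$sample_id, calls$type, calls$mean_log2)
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read CNV calls from a PLINK .cnv file
#'
#' Inverse of [write_cnv_calls()] for the `plink_cnv` dialect; `#` comment
#' lines are skipped, coordinates become 0-based half-open.
#'
#' @param path Path to a `.cnv` file.
#' @return CNV call `data.frame`.
#' @export
read_cnv_calls <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  .stopifnot_cols(df, c("IID", "CHR", "BP1", "BP2", "TYPE", "SCORE", "SITES"),
                  "PLINK .cnv")
  if (!nrow(df)) return(.empty_calls())
  type <- names(.PLINK_TYPE)[match(df$TYPE, .PLINK_TYPE)]
  if (anyNA(type)) stop("unknown TYPE code in .cnv (expect 1 or 3)", call. = FALSE)
  data.frame(sample_id = as.character(df$IID),
             chrom = paste0("chr", df$CHR),
             start = df$BP1 - 1, end = as.numeric(df$BP2),
             type = type, n_probes = as.integer(df$SITES),
             mean_log2 = df$SCORE, callers = "file",
             stringsAsFactors = FALSE)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses a biallelic `.ped`/`.map` pair into a samples-by-SNPs matrix of
#' minor-allele dosages (0/1/2, `NA` for missing "0 0").  The minor allele
#' is the less frequent observed allele; frequency ties are broken by
#' taking the lexicographically later allele as minor.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A list with `dosage` (samples x SNPs integer matrix), `map`
#'   (`data.frame`: `chrom`, `snp_id`, `cm`, `pos`), and `fam`
#'   (`data.frame`: `fid`, `iid`, `sex`, `phenotype`).
#' @export
read_genotypes <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos"))
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(ped_lines)]
  toks <- strsplit(ped_lines, "[ \t]+")
  n_field <- lengths(toks)
  if (length(unique(n_field)) > 1L) stop("ragged .ped rows", call. = FALSE)
  n_snp <- (n_field[1] - 6L) / 2L
  if (n_snp != nrow(map)) {
    stop(sprintf(".map lists %d SNPs but .ped carries %d genotype columns",
                 nrow(map), n_snp), call. = FALSE)
  }
  tok <- do.call(rbind, toks)
  fam <- data.frame(fid = tok[, 1], iid = tok[, 2],
                    sex = tok[, 5], phenotype = tok[, 6],
                    stringsAsFactors = FALSE)
  a1 <- tok[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  dosage <- matrix(NA_integer_, nrow = nrow(tok), ncol = n_snp,
                   dimnames = list(fam$iid, map$snp_id))
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    if (!length(obs)) next
    tab <- table(obs)
    alleles <- names(tab)
    if (length(alleles) > 2L) {
      stop(sprintf("SNP %s is not biallelic", map$snp_id[j]), call. = FALSE)
    }
    minor <- if (length(alleles) == 1L) {
      alleles  # monomorphic: dosage counts the single allele (all 2s)
    } else if (tab[1] == tab[2]) {
      sort(alleles)[2]  # tie: lexicographically later allele is minor
    } else {
      alleles[which.min(tab)]
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == minor) + (a2[, j] == minor)
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  list(dosage = dosage, map = map, fam = fam)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param dosage Samples x SNPs matrix of minor-allele dosage (0/1/2/NA).
#' @param map `data.frame` with `chrom`, `snp_id`, `cm`, `pos`.
#' @param fam `data.frame` with `fid`, `iid`, `sex`, `phenotype`.
#' @param ped_path,map_path Output paths.
#' @param alleles Length-2 character vector, major then minor allele symbol.
#' @export
write_genotypes <- function(dosage, map, fam, ped_path, map_path,
                            alleles = c("A", "G")) {
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  gt <- matrix("", nrow = nrow(dosage), ncol = 2L * ncol(dosage))
  a1 <- matrix(alleles[1], nrow(dosage), ncol(dosage))
  a2 <- a1
  a1[dosage >= 1] <- alleles[2]
  a2[dosage == 2] <- alleles[2]
  a1[is.na(dosage)] <- "0"; a2[is.na(dosage)] <- "0"
  gt[, seq(1, ncol(gt), 2)] <- a1
  gt[, seq(2, ncol(gt), 2)] <- a2
  out <- cbind(fam$fid, fam$iid, "0", "0", fam$sex, fam$phenotype, gt)
  write.table(out, ped_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

#' Read / write a sample table (.fam)
#'
#' PLINK `.fam` with phenotype 2 = case (DS+AVSD), 1 = control (DS+NH).
#' The population label is carried in the FID column.
#'
#' @param path File path.
#' @return `data.frame` with `sample_id`, `phenotype` (`"case"`/`"control"`),
#'   `population`, `sex`.
#' @export
read_fam <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  data.frame(sample_id = df$iid,
             phenotype = ifelse(df$pheno == 2, "case", "control"),
             population = df$fid,
             sex = ifelse(df$sex == 1, "M", "F"),
             stringsAsFactors = FALSE)
}

#' @rdname read_fam
#' @param meta Sample metadata `data.frame` as returned by [simulate_cohort()].
#' @export
write_fam <- function(meta, path) {
  out <- data.frame(fid = meta$population, iid = meta$sample_id,
                    pat = 0L, mat = 0L,
                    sex = ifelse(meta$sex == "M", 1L, 2L),
                    pheno = ifelse(meta$phenotype == "case", 2L, 1L))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write refFlat-style gene models
#'
#' Tab-separated columns `gene_symbol`, `chrom`, `strand`, `tx_start`,
#' `tx_end`, `exon_starts`, `exon_ends` (comma-separated lists), 0-based
#' half-open on disk as in UCSC tables.  Strand is parsed but ignored by
#' interval intersection (CNVs are strandless).
#'
#' @param path File path.
#' @return A `gene_models` list with `$genes` (`gene_symbol`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`) and `$exons` (`gene_symbol`, `start`,
#'   `end`), one row per exon, sorted and non-overlapping within a gene.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .stopifnot_cols(df, c("gene_symbol", "chrom", "strand", "tx_start",
                        "tx_end", "exon_starts", "exon_ends"), "gene table")
  ex <- lapply(seq_len(nrow(df)), function(i) {
    s <- as.numeric(strsplit(df$exon_starts[i], ",")[[1]])
    e <- as.numeric(strsplit(df$exon_ends[i], ",")[[1]])
    data.frame(gene_symbol = df$gene_symbol[i], start = s, end = e,
               stringsAsFactors = FALSE)
  })
  gm <- list(genes = df[, c("gene_symbol", "chrom", "strand",
                            "tx_start", "tx_end")],
             exons = do.call(rbind, ex))
  class(gm) <- "gene_models"
  validate_gene_models(gm)
}

#' @rdname read_gene_models
#' @param gm A `gene_models` object.
#' @export
write_gene_models <- function(gm, path) {
  exs <- split(gm$exons, gm$exons$gene_symbol)
  g <- gm$genes
  fmt <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  out <- data.frame(
    gene_symbol = g$gene_symbol, chrom = g$chrom, strand = g$strand,
    tx_start = format(g$tx_start, scientific = FALSE, trim = TRUE),
    tx_end = format(g$tx_end, scientific = FALSE, trim = TRUE),
    exon_starts = vapply(g$gene_symbol, function(s) fmt(exs[[s]]$start), ""),
    exon_ends = vapply(g$gene_symbol, function(s) fmt(exs[[s]]$end), ""),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a gene_models object
#'
#' Checks exon ordering, containment in the transcript span, and unique
#' gene symbols.
#'
#' @param gm A `gene_models` list.
#' @return `gm`, invisibly validated.
#' @export
validate_gene_models <- function(gm) {
  if (anyDuplicated(gm$genes$gene_symbol)) {
    stop("duplicate gene symbols in gene models", call. = FALSE)
  }
  for (s in gm$genes$gene_symbol) {
    g <- gm$genes[gm$genes$gene_symbol == s, ]
    e <- gm$exons[gm$exons$gene_symbol == s, ]
    if (is.unsorted(e$start, strictly = TRUE) ||
        any(e$start[-1] < e$end[-nrow(e)])) {
      stop("exons of ", s, " are unsorted or overlapping", call. = FALSE)
    }
    if (any(e$start < g$tx_start) || any(e$end > g$tx_end)) {
      stop("exon of ", s, " outside its transcript span", call. = FALSE)
    }
  }
  gm
}

#' Read / write a structural-variant catalog
#'
#' Tab-separated catalog of known variants (1000 Genomes / DGV style):
#' `variant_id`, `chrom`, `start`, `end` (1-based inclusive on disk),
#' `svtype` (`deletion`/`duplication`/`multiallelic`), `population`,
#' `frequency`, and optional `calibration` flag.
#'
#' @param path File path.
#' @return `data.frame` with 0-based half-open coordinates.
#' @export
read_catalog <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .stopifnot_cols(df, c("variant_id", "chrom", "start", "end", "svtype",
                        "population", "frequency"), "variant catalog")
  df$start <- df$start - 1
  if (any(df$end - df$start < 1)) stop("catalog variant of length < 1 bp", call. = FALSE)
  if (any(df$frequency < 0 | df$frequency > 1)) {
    stop("catalog frequency outside [0,1]", call. = FALSE)
  }
  if (!"calibration" %in% names(df)) df$calibration <- FALSE
  df$calibration <- as.logical(df$calibration)
  df
}

#' @rdname read_catalog
#' @param catalog Catalog `data.frame` (0-based half-open).
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  out$frequency <- sprintf("%.4f", catalog$frequency)
  out$calibration <- as.integer(catalog$calibration)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write simulator truth records
#'
#' @param path File path.
#' @return `data.frame` with `sample_id`, `chrom`, `start`, `end`, `type`,
#'   `copies` (0-based half-open in memory, 1-based on disk).
#' @export
read_truth <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$start <- df$start - 1
  df
}

#' @rdname read_truth
#' @param truth Truth `data.frame`.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
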