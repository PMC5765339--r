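#' Pipeline configuration
#'
#' Collects every stage's parameters plus a global seed that is fanned
#' out to per-stage child seeds (documented derivation: seed * 1009 plus
#' a stage-name hash, modulo 2^31 - 1), so stages can be re-run in
#' isolation.  `paper_mode` switches the permutation count to one million
#' and pins Tm = 8, MinSegLen = 6 — the full-scale analysis settings —
#' at a corresponding runtime cost.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Global integer seed.
#' @param sim A [sim_config()]; its seed is overridden by the global seed.
#' @param dlr_threshold Array DLR cutoff.
#' @param calibrate Run the Tm sweep (default TRUE); when FALSE the
#'   configured `tm` is used directly.
#' @param tm Elimination threshold used when `calibrate = FALSE`.
#' @param min_seg_len Minimum probes per CNV.
#' @param adm2_z Shift-caller score floor.
#' @param n_permutations Permutations for burden/association tests.
#' @param genotypes List with `n_snps` and `fst` for the stratification
#'   stage's simulated genome-wide SNPs.
#' @param stratify Run the stratification stage (default TRUE).
#' @param paper_mode Use full-scale analysis settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = NULL,
                            dlr_threshold = 0.3, calibrate = TRUE, tm = 8,
                            min_seg_len = 6, adm2_z = 5,
                            n_permutations = 10000,
                            genotypes = list(n_snps = 2000, fst = 0.1),
                            stratify = TRUE, paper_mode = FALSE) {
  if (paper_mode) {
    n_permutations <- 1e6
    tm <- 8
    min_seg_len <- 6
  }
  if (is.null(sim)) sim <- sim_config(seed = .child_seed(seed, "simulate"))
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 dlr_threshold = dlr_threshold, calibrate = calibrate,
                 tm = tm, min_seg_len = min_seg_len, adm2_z = adm2_z,
                 n_permutations = n_permutations, genotypes = genotypes,
                 stratify = stratify, paper_mode = paper_mode),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a `sim`
#' block maps onto [sim_config()] arguments (planted variants given as a
#' list of records).
#'
#' @param path YAML file.
#' @param outdir Output directory (overrides any `outdir` in the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$planted_variants)) {
      y$sim$planted_variants <- do.call(rbind, lapply(y$sim$planted_variants,
        function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(pipeline_config, y)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages execute in order: simulate, array/probe QC, calibrate (optional
#' Tm sweep), call, filter + catalog validation, stratify, associate.
#' Every artifact is written under `config$outdir` along with a manifest
#' recording the package version, seeds, selected Tm, stage status and
#' md5 hashes of all outputs; a stage failure aborts with a stage-named
#' error after writing the partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`cohort`,
#'   `qc`, `calibration`, `calls`, `filtered`, `stratification`,
#'   `association`, `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("tri21cnv")),
                   seed = config$seed, paper_mode = config$paper_mode,
                   stages = list())
  results <- list()
  finish_manifest <- function() {
    files <- list.files(config$outdir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$files <<- as.list(tools::md5sum(files))
    names(manifest$files) <<- basename(files)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      finish_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  # --- simulate -------------------------------------------------------
  cohort <- stage("simulate", {
    cohort <- simulate_cohort(config$sim)
    write_probe_design(cohort$design, out("probes.tsv"))
    write_log2_matrix(cohort$log2, out("log2.tsv"))
    write_truth(cohort$truth, out("truth.tsv"))
    write_fam(cohort$meta, out("cohort.fam"))
    catalog <- simulate_catalog(config$sim)
    write_catalog(catalog, out("catalog.tsv"))
    genes <- simulate_gene_models(cohort$design,
                                  seed = .child_seed(config$seed, "genes"))
    write_gene_models(genes, out("genes.tsv"))
    cohort$catalog <- catalog
    cohort$genes <- genes
    cohort
  })
  results$cohort <- cohort

  # --- QC -------------------------------------------------------------
  qc <- stage("qc", {
    qc <- run_array_qc(cohort$log2, config$dlr_threshold)
    rep_df <- do.call(rbind, lapply(qc$reports, function(r) {
      data.frame(stage = r$stage, n_before = r$n_before, n_after = r$n_after,
                 excluded = paste(r$excluded, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(rep_df, out("qc_report.tsv"))
    qc
  })
  results$qc <- qc
  design_qc <- cohort$design[match(rownames(qc$log2), cohort$design$probe_id), ]
  params <- seg_params(t_threshold = config$tm,
                       min_seg_len = config$min_seg_len)

  # --- calibrate + call ----------------------------------------------
  if (config$calibrate) {
    calib <- stage("calibrate", {
      cal <- sweep_tm(qc$log2, design_qc, cohort$catalog, params,
                      ref_interval = config$sim$reference_deletion_interval,
                      adm2_z = config$adm2_z,
                      populations = setNames(cohort$meta$population,
                                             cohort$meta$sample_id))
      .write_tsv(cal$grid, out("calibration.tsv"))
      if (cal$status != "ok") stop("no Tm satisfies both calibration criteria")
      cal
    })
    results$calibration <- calib
    manifest$selected_tm <- calib$selected_tm
    calls <- calib$calls
  } else {
    calls <- stage("call", {
      call_cnvs(qc$log2, design_qc, params, adm2_z = config$adm2_z)
    })
  }
  stage("write_calls", {
    write_cnv_calls(calls, out("calls.cnv"), "plink_cnv")
    write_cnv_calls(calls, out("calls.bed"), "bed")
  })
  results$calls <- calls

  # --- filter ---------------------------------------------------------
  filtered <- stage("filter", {
    fp <- filter_params(excluded_regions = rbind(
      config$sim$reference_deletion_interval, c(0, 15400000)))
    fl <- apply_call_filters(calls, fp, colnames(qc$log2))
    ann <- annotate_dgv(fl$calls, cohort$catalog, fp)
    freq <- classify_frequency(ann$calls, length(fl$retained_samples), fp)
    .write_tsv(fl$log, out("filter_log.tsv"))
    write_cnv_calls(freq$calls[, names(.empty_calls())], out("filtered.cnv"),
                    "plink_cnv")
    .write_tsv(freq$regions, out("regions.tsv"))
    list(calls = freq$calls, regions = freq$regions, log = fl$log,
         dgv_summary = ann$summary, params = fp,
         retained_samples = fl$retained_samples)
  })
  results$filtered <- filtered

  # --- stratify -------------------------------------------------------
  meta <- cohort$meta[cohort$meta$sample_id %in% filtered$retained_samples, ]
  if (config$stratify) {
    strat <- stage("stratify", {
      pops <- table(meta$population)
      g <- simulate_genotypes(setNames(as.integer(pops), names(pops)),
                              n_snps = config$genotypes$n_snps,
                              fst = config$genotypes$fst,
                              seed = .child_seed(config$seed, "stratify"))
      rownames(g$dosage) <- meta$sample_id[order(meta$population)]
      meta_sorted <- meta[order(meta$population), ]
      write_genotypes(g$dosage, g$map,
                      data.frame(fid = meta_sorted$population,
                                 iid = meta_sorted$sample_id,
                                 sex = ifelse(meta_sorted$sex == "M", 1L, 2L),
                                 phenotype = ifelse(meta_sorted$phenotype == "case",
                                                    2L, 1L)),
                      out("genotypes.ped"), out("genotypes.map"))
      qcd <- snp_qc(g$dosage)
      pruned <- ld_prune(qcd$dosage, g$map)
      st <- stratify_cohort(qcd$dosage[, pruned, drop = FALSE],
                            meta$population[order(meta$population)])
      ev <- data.frame(sample_id = rownames(st$round1$eigenvectors),
                       st$round1$eigenvectors)
      .write_tsv(ev, out("pca.tsv"))
      st
    })
    results$stratification <- strat
    meta <- meta[!meta$sample_id %in% strat$removed, ]
  }

  # --- associate ------------------------------------------------------
  assoc <- stage("associate", {
    calls_a <- filtered$calls[filtered$calls$sample_id %in% meta$sample_id, ]
    dels <- calls_a[calls_a$type == "deletion", ]
    dups <- calls_a[calls_a$type == "duplication", ]
    burden <- do.call(rbind, lapply(
      list(list(calls = dels, dir = "controls", set = "deletions"),
           list(calls = dups, dir = "cases", set = "duplications")),
      function(h) {
        do.call(rbind, lapply(c("RATE", "KBTOT", "GRATE"), function(m) {
          bt <- burden_test(h$calls, meta, m, h$dir,
                            n_permutations = config$n_permutations,
                            seed = .child_seed(config$seed, paste0(h$set, m)),
                            genes = cohort$genes)
          data.frame(set = h$set, metric = m, mean_case = bt$mean_case,
                     mean_control = bt$mean_control, direction = h$dir,
                     empirical_p = bt$empirical_p, stringsAsFactors = FALSE)
        }))
      }))
    .write_tsv(burden, out("burden.tsv"))

    carriers <- function(set_calls) {
      ids <- unique(set_calls$sample_id)
      c(case = sum(meta$phenotype == "case" & meta$sample_id %in% ids),
        control = sum(meta$phenotype == "control" & meta$sample_id %in% ids))
    }
    fg <- build_full_gene_duplication_set(dups, cohort$genes)
    rd <- build_reduced_to_disomy_set(calls_a, cohort$genes)
    cf <- carriers(fg$calls); cr <- carriers(rd$calls)
    n_case <- sum(meta$phenotype == "case")
    n_control <- sum(meta$phenotype == "control")
    f1 <- fisher_one_sided(cf["case"], n_case, cf["control"], n_control, "cases")
    f2 <- fisher_one_sided(cr["case"], n_case, cr["control"], n_control, "controls")
    fisher_df <- data.frame(
      set = c("full_gene_duplication", "reduced_to_disomy"),
      case_carriers = c(cf["case"], cr["case"]),
      control_carriers = c(cf["control"], cr["control"]),
      direction = c("cases", "controls"),
      odds_ratio = c(f1$odds_ratio, f2$odds_ratio),
      one_sided_p = c(f1$one_sided_p, f2$one_sided_p),
      stringsAsFactors = FALSE)
    .write_tsv(fisher_df, out("fisher.tsv"))

    regions <- region_association(calls_a, meta,
                                  n_permutations = config$n_permutations,
                                  seed = .child_seed(config$seed, "regions"))
    .write_tsv(regions, out("region_association.tsv"))
    genes_assoc <- gene_association(calls_a, cohort$genes, meta,
                                    n_permutations = config$n_permutations,
                                    seed = .child_seed(config$seed, "geneassoc"))
    .write_tsv(genes_assoc, out("gene_association.tsv"))
    list(burden = burden, fisher = fisher_df, regions = regions,
         genes = genes_assoc)
  })
  results$association <- assoc

  finish_manifest()
  results$manifest <- manifest
  invisible(results)
}
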