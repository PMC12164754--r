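#' Pipeline configuration
#'
#' Collects the paths and tunables of the full workflow. Defaults are the
#' study thresholds: in-frame reads of 29--33 nt, pausing scores from genes
#' with more than 10 reads, |FC| >= 1.5 with padj < 0.05 for differential
#' calls, and VIP >= 1 with FC >= 2 or <= 0.5 for the metabolite screen.
#'
#' @param dir directory holding the input files (the [make_demo()] layout).
#' @param out_dir directory for result tables (created if missing).
#' @param length_range in-frame footprint length window (nt).
#' @param min_support minimum reads per length for offset detection.
#' @param min_reads pausing-score gene inclusion threshold (strictly more
#'   than this many interior reads).
#' @param fc_threshold linear fold-change threshold for DE/DTEG/quadrants.
#' @param alpha BH-adjusted significance level.
#' @param vip_threshold,fc_hi,fc_lo metabolite screen gates.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, out_dir = file.path(dir, "results"),
                            length_range = c(29L, 33L), min_support = 500,
                            min_reads = 10, fc_threshold = 1.5,
                            alpha = 0.05, vip_threshold = 1,
                            fc_hi = 2, fc_lo = 0.5) {
  structure(list(dir = dir, out_dir = out_dir,
                 length_range = length_range, min_support = min_support,
                 min_reads = min_reads, fc_threshold = fc_threshold,
                 alpha = alpha, vip_threshold = vip_threshold,
                 fc_hi = fc_hi, fc_lo = fc_lo),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(unlist(config)), unlist(config), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

write_result_csv <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ribopause %s config_hash=%s",
                     as.character(packageVersion("ribopause")),
                     config_hash(config)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a demo-layout dataset
#'
#' Stage order: ingest -> offsets -> in-frame filter -> pausing ->
#' counting -> differential TE -> nine-quadrant, plus polysome P/M and the
#' metabolite screen when their inputs are present. Each stage's output is
#' a CSV/JSON under `config$out_dir`; every table carries a header comment
#' with the package version and a hash of the configuration, and a
#' `provenance.json` records parameters and input checksums. Reruns with
#' the same inputs and config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  d <- config$dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  tx <- stage("ingest", read_transcriptome(
    file.path(d, "transcriptome.fa"), file.path(d, "cds_table.tsv")))
  aln <- stage("ingest", list(
    WT = read_alignments(file.path(d, "wt_footprints.tsv"), "tsv", tx),
    mutant = read_alignments(file.path(d, "mut_footprints.tsv"), "tsv", tx)))

  offs <- stage("offsets", lapply(aln, detect_psite_offsets, tx,
                                  min_support = config$min_support))
  write_offsets_json(offs$WT, file.path(config$out_dir, "offsets_wt.json"))
  write_offsets_json(offs$mutant,
                     file.path(config$out_dir, "offsets_mut.json"))

  filt <- stage("filter", mapply(function(a, o) {
    filter_inframe(a, o, tx, length_range = config$length_range)
  }, aln, offs, SIMPLIFY = FALSE))
  peri <- do.call(rbind, lapply(names(aln), function(cn) {
    cbind(condition = cn, periodicity(aln[[cn]], offs[[cn]], tx))
  }))
  write_result_csv(peri, file.path(config$out_dir, "periodicity.csv"),
                   config)

  pause <- stage("pausing", {
    per_site <- lapply(c(A = "A", P = "P", E = "E"), function(s) {
      sc <- lapply(names(filt), function(cn) {
        occ <- codon_occupancy(filt[[cn]], offs[[cn]], tx, site = s)
        pausing_scores(occ, tx, min_reads = config$min_reads)
      })
      names(sc) <- names(filt)
      cmp <- pausing_comparison(sc$mutant, sc$WT)
      cbind(site = s, cmp)
    })
    do.call(rbind, per_site)
  })
  write_result_csv(pause, file.path(config$out_dir, "pausing_scores.csv"),
                   config)

  te_res <- NULL
  if (file.exists(file.path(d, "rna_counts.tsv"))) {
    te_res <- stage("te", {
      rna <- as.matrix(read.table(file.path(d, "rna_counts.tsv"),
                                  header = TRUE, sep = "\t",
                                  row.names = 1, check.names = FALSE))
      rpf <- as.matrix(read.table(file.path(d, "rpf_counts.tsv"),
                                  header = TRUE, sep = "\t",
                                  row.names = 1, check.names = FALSE))
      samples <- read.csv(file.path(d, "samples.csv"))
      cond <- factor(samples$condition[match(colnames(rna),
                                             samples$sample)],
                     levels = c("WT", "mutant"))
      differential_te(rpf, rna, cond,
                      fc_threshold = config$fc_threshold,
                      alpha = config$alpha)
    })
    write_result_csv(te_res, file.path(config$out_dir, "dteg.csv"), config)
    quad <- as.data.frame(table(te_res$quadrant, useNA = "ifany"))
    names(quad) <- c("class", "n_genes")
    write_result_csv(quad, file.path(config$out_dir,
                                     "quadrant_counts.csv"), config)
  }

  poly <- NULL
  if (file.exists(file.path(d, "trace_wt.tsv"))) {
    poly <- stage("polysome", {
      ratios <- vapply(c(WT = "trace_wt.tsv", mutant = "trace_mut.tsv"),
                       function(f) {
                         tr <- read_polysome_trace(file.path(d, f))
                         pm_ratio(tr)
                       }, numeric(1))
      data.frame(condition = names(ratios), pm_ratio = unname(ratios))
    })
    write_result_csv(poly, file.path(config$out_dir, "pm_ratios.csv"),
                     config)
  }

  screen <- NULL
  if (file.exists(file.path(d, "metabolites.csv"))) {
    screen <- stage("metscreen", {
      met <- read.csv(file.path(d, "metabolites.csv"), row.names = 1,
                      check.names = FALSE)
      group <- factor(sub("_[0-9]+$", "", colnames(met)),
                      levels = c("group1", "group2"))
      differential_metabolites(as.matrix(met), group,
                               vip_threshold = config$vip_threshold,
                               fc_hi = config$fc_hi, fc_lo = config$fc_lo)
    })
    write_result_csv(screen, file.path(config$out_dir,
                                       "metabolite_screen.csv"), config)
  }

  inputs <- list.files(d, full.names = TRUE)
  inputs <- inputs[!dir.exists(inputs)]
  prov <- list(
    tool = "ribopause",
    version = as.character(packageVersion("ribopause")),
    config = unclass(config),
    config_hash = config_hash(config),
    input_md5 = as.list(tools::md5sum(sort(inputs)))
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(transcriptome = tx, offsets = offs, periodicity = peri,
                 filtered = filt, pausing = pause, te = te_res,
                 polysome = poly, metabolites = screen))
}

#' Build the packaged synthetic WT-vs-mutant demonstration dataset
#'
#' Writes a complete two-condition dataset to `dir`: a transcriptome
#' (FASTA + CDS table), footprint alignments for a wild type with uniform
#' codon dwell and a mutant with all six serine codons dwelling 2x longer,
#' paired RNA/RPF count matrices in which 40% of genes have TE reduced by
#' 30% (plus small strongly shifted sets so the translational-only
#' nine-quadrant classes are populated), polysome traces whose true P/M
#' ratio drops from 1.5 (WT) to 0.6 (mutant), and a 500-metabolite table
#' with 20 differentials including a "serine" metabolite at fold change 0.2
#' (an 80% reduction). Ground truth is written as `ground_truth.json`.
#'
#' @param dir output directory (created).
#' @param seed integer master seed; every file is byte-identical given the
#'   same seed.
#' @param n_genes transcriptome size.
#' @param read_depth expected footprints per gene and condition.
#' @param n_count_genes genes in the count experiment.
#' @param n_rep replicates per condition and assay.
#' @return invisible list with the config, file paths and ground truth.
#' @export
make_demo <- function(dir, seed = 1L, n_genes = 500L, read_depth = 2000,
                      n_count_genes = 2000L, n_rep = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser2 <- setNames(rep(2, 6), SERINE_CODONS)
  cfg_wt <- sim_config(n_genes = n_genes, read_depth = read_depth,
                       seed = seed)
  cfg_mut <- sim_config(n_genes = n_genes, read_depth = read_depth,
                        dwell_multipliers = ser2, seed = seed)
  tx <- simulate_transcriptome(cfg_wt)
  write_transcriptome_fasta(tx, file.path(dir, "transcriptome.fa"))
  write_cds_table(tx, file.path(dir, "cds_table.tsv"))
  fp_wt <- simulate_footprints(tx, cfg_wt, "WT", seed = seed + 1L)
  fp_mut <- simulate_footprints(tx, cfg_mut, "mutant", seed = seed + 2L)
  write_alignments_tsv(fp_wt$alignments, file.path(dir, "wt_footprints.tsv"))
  write_alignments_tsv(fp_mut$alignments,
                       file.path(dir, "mut_footprints.tsv"))

  # TE effects: 40% of genes reduced 30% (global repression), plus 2.5%
  # strongly down / 2.5% strongly up to populate classes S8 / S2
  te_eff <- with_seed(seed + 3L, {
    eff <- numeric(n_count_genes)
    n40 <- round(0.4 * n_count_genes)
    pick <- sample.int(n_count_genes, n40 + round(0.05 * n_count_genes))
    eff[pick[seq_len(n40)]] <- log2(0.7)
    strong <- pick[-seq_len(n40)]
    half <- length(strong) %/% 2L
    eff[strong[seq_len(half)]] <- -1.5
    eff[strong[-seq_len(half)]] <- 1.5
    eff
  })
  cx <- simulate_count_experiment(n_count_genes, n_rep, dispersion = 0.05,
                                  te_effect = te_eff, seed = seed + 4L)
  write.table(cx$rna, file.path(dir, "rna_counts.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(cx$rpf, file.path(dir, "rpf_counts.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  samples <- data.frame(
    sample = c(colnames(cx$rna), colnames(cx$rpf)),
    condition = rep(as.character(cx$condition), 2L),
    assay = rep(c("RNA", "RPF"), each = length(cx$condition)),
    replicate = rep(rep(seq_len(n_rep), 2L), 2L)
  )
  write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE)

  peaks_wt <- data.frame(center = c(1, 2, 3.2, 5.5),
                         width = c(0.15, 0.15, 0.2, 0.6),
                         area = c(0.6, 0.9, 2, 3))
  peaks_mut <- peaks_wt
  peaks_mut$area <- c(0.6, 0.9, 2, 1.2)
  tr_wt <- simulate_polysome_trace(peaks_wt, noise_sd = 0.001,
                                   seed = seed + 5L,
                                   positions = seq(0, 8, length.out = 2001))
  tr_mut <- simulate_polysome_trace(peaks_mut, noise_sd = 0.001,
                                    seed = seed + 6L,
                                    positions = seq(0, 8, length.out = 2001))
  write_polysome_trace(tr_wt, file.path(dir, "trace_wt.tsv"))
  write_polysome_trace(tr_mut, file.path(dir, "trace_mut.tsv"))

  met_eff <- with_seed(seed + 7L, {
    e <- setNames(sample(c(-2, 2), 20L, replace = TRUE),
                  c("serine", sprintf("diffmet%02d", 1:19)))
    e["serine"] <- log2(0.2)  # 80% reduction
    e
  })
  met <- simulate_metabolome(500L, 20L, log2_effect = met_eff,
                             n_rep = n_rep, seed = seed + 8L)
  write.csv(as.data.frame(met$intensity),
            file.path(dir, "metabolites.csv"))

  truth <- list(
    seed = seed,
    dwell_multipliers_mutant = as.list(ser2),
    expected_reads_wt = fp_wt$truth$expected_reads,
    true_offsets = as.list(cfg_wt$true_offsets),
    te_log2fc = cx$truth$te_log2fc,
    depth_factors = as.list(cx$truth$depth),
    pm_true = list(WT = 3 / 2, mutant = 1.2 / 2),
    metabolite_log2_effects = as.list(met$truth$log2_effect[
      met$truth$differential])
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, config = cfg_wt, config_mut = cfg_mut,
                 transcriptome = tx, counts = cx, metabolome = met,
                 truth = truth))
}
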