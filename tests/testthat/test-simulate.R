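test_that("simulated CDSs are well-formed and deterministic", {
  cfg <- sim_config(n_genes = 30, cds_codon_range = c(20, 40), seed = 11)
  tx <- simulate_transcriptome(cfg)
  cds <- cds_sequence(tx)
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  stops <- c("TAA", "TAG", "TGA")
  expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) %in% stops))
  internal <- vapply(cds, function(s) {
    cod <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    any(cod %in% stops)
  }, logical(1))
  expect_false(any(internal))
  expect_equal(unname(nchar(cds)), 3 * (tx$n_codons + 1))

  # forced length: 20 codons -> 60 nt of sense CDS plus the stop
  one <- simulate_transcriptome(sim_config(n_genes = 1,
                                           cds_codon_range = c(20, 20),
                                           seed = 2))
  expect_equal(unname(nchar(cds_sequence(one))), 63)

  # byte-identical FASTA under a fixed seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_transcriptome_fasta(simulate_transcriptome(cfg), f1)
  write_transcriptome_fasta(simulate_transcriptome(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  tx3 <- simulate_transcriptome(sim_config(n_genes = 30,
                                           cds_codon_range = c(20, 40),
                                           seed = 12))
  expect_false(identical(tx$sequence, tx3$sequence))
})

test_that("uniform codon usage is recovered within binomial error", {
  cfg <- sim_config(n_genes = 200, cds_codon_range = c(100, 200), seed = 5)
  tx <- simulate_transcriptome(cfg)
  cds <- cds_sequence(tx)
  body <- unlist(lapply(cds, function(s) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cod[-c(1, length(cod))]  # drop fixed ATG and stop
  }))
  n <- length(body)
  obs <- table(factor(body, levels = ribopause:::sense_codons()))
  se <- sqrt(n * (1 / 61) * (60 / 61))
  z <- (as.numeric(obs) - n / 61) / se
  expect_lt(max(abs(z)), 3.5)
  expect_gte(sum(abs(z) < 3), 58)
})

test_that("footprint placement follows the offset rule and conserves reads", {
  cfg <- sim_config(n_genes = 5, read_depth = 2000, seed = 7,
                    length_weights = c(`30` = 1),
                    true_offsets = c(`30` = 12L), start_peak = 1)
  tx <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg, "WT", seed = 8)
  aln <- fp$alignments
  expect_equal(nrow(aln), fp$truth$n_signal + fp$truth$n_noise)
  expect_equal(fp$truth$n_noise, 0)
  idx <- match(aln$transcript_id, tx$transcript_id)
  # 5' end is offset + 3 = 15 nt upstream of the A-site codon start
  a <- (aln$five_prime - tx$cds_start[idx] + 15) / 3
  expect_true(all(a == floor(a)))
  expect_true(all(a >= 1 & a <= tx$n_codons[idx] - 1))
  # no read extends past its transcript
  expect_true(all(aln$five_prime >= 0))
  expect_true(all(aln$five_prime + aln$length <=
                    nchar(tx$sequence)[idx]))
  # determinism
  fp2 <- simulate_footprints(tx, cfg, "WT", seed = 8)
  expect_identical(fp$alignments, fp2$alignments)
})

test_that("uniform dwell gives flat per-codon occupancy (chi-square)", {
  cfg <- sim_config(n_genes = 1, cds_codon_range = c(200, 200),
                    read_depth = 1e4, seed = 3,
                    length_weights = c(`30` = 1),
                    true_offsets = c(`30` = 12L), start_peak = 1,
                    expression_sdlog = 0)
  tx <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg, "WT", seed = 4)
  off <- offset_table(c(`30` = 12L))
  occ <- codon_occupancy(fp$alignments, off, tx, "A")
  counts <- numeric(tx$n_codons)
  counts[occ$codon + 1] <- occ$count
  counts <- counts[2:tx$n_codons]  # A-sites are sampled on codons 1..n-1
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("injected 3x serine dwell is visible in raw A-site density", {
  mult <- setNames(rep(3, 6), serine_codons)
  cfg <- sim_config(n_genes = 10, read_depth = 1e4, seed = 21,
                    dwell_multipliers = mult, start_peak = 1,
                    expression_sdlog = 0)
  tx <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg, "mut", seed = 22)
  off <- offset_table(cfg$true_offsets)
  fl <- quiet(filter_inframe(fp$alignments, off, tx))
  occ <- codon_occupancy(fl, off, tx, "A")
  # direct counting oracle: mean reads per A-site position, serine vs not
  cds <- cds_sequence(tx)
  idx <- match(occ$transcript_id, tx$transcript_id)
  cod <- substr(cds[idx], 3 * occ$codon + 1, 3 * occ$codon + 3)
  n_pos_ser <- sum(unlist(lapply(seq_len(nrow(tx)), function(i) {
    cods <- substring(cds[i], seq(4, 3 * (tx$n_codons[i] - 1) + 1, 3),
                      seq(6, 3 * (tx$n_codons[i] - 1) + 3, 3))
    sum(cods %in% serine_codons)
  })))
  n_pos_all <- sum(tx$n_codons - 1)
  ser_rate <- sum(occ$count[cod %in% serine_codons]) / n_pos_ser
  other_rate <- sum(occ$count[!cod %in% serine_codons]) /
    (n_pos_all - n_pos_ser)
  expect_equal(ser_rate / other_rate, 3, tolerance = 0.1)
})

test_that("count experiment encodes TE effects and the Poisson limit", {
  # a TE effect is identifiable relative to unaffected genes (shared
  # normalization absorbs any transcriptome-wide shift), so perturb a subset
  eff <- c(rep(-1, 100), rep(0, 300))
  cx <- simulate_count_experiment(400, 3, dispersion = 0.05,
                                  te_effect = eff, seed = 31,
                                  depth_sdlog = 0)
  te <- compute_te(cx$rpf, cx$rna, cx$condition)
  lr <- log2(te$te_mutant / te$te_WT)
  # the affected-vs-background contrast recovers the injected -1;
  # (median-of-ratios shifts both groups by a common offset)
  expect_equal(mean(lr[1:100], na.rm = TRUE) -
                 mean(lr[101:400], na.rm = TRUE), -1, tolerance = 0.1)

  # dispersion -> 0: sample variance approaches the mean
  cx0 <- simulate_count_experiment(2000, 3, dispersion = 1e-6,
                                   te_effect = 0, seed = 32,
                                   depth_sdlog = 0)
  m <- rowMeans(cx0$rna[, 1:3])
  v <- apply(cx0$rna[, 1:3], 1, var)
  expect_equal(mean(v / m), 1, tolerance = 0.05)

  expect_error(simulate_count_experiment(10, 1, 0.1), "n_rep")
  expect_error(simulate_count_experiment(10, 3, 0), "dispersion")
})

test_that("polysome trace integrates to its specified areas", {
  tr <- simulate_polysome_trace(data.frame(center = 5, width = 0.3,
                                           area = 2),
                                baseline = 0.1, noise_sd = 0)
  y <- tr$a254 - 0.1
  area <- sum(diff(tr$position) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(area, 2, tolerance = 0.001)

  flat <- simulate_polysome_trace(data.frame(center = numeric(0),
                                             width = numeric(0),
                                             area = numeric(0)),
                                  baseline = 0.07)
  expect_true(all(flat$a254 == 0.07))
  expect_error(simulate_polysome_trace(
    data.frame(center = c(2, 1), width = c(.1, .1), area = c(1, 1))),
    "strictly increasing")
  expect_warning(simulate_polysome_trace(
    data.frame(center = c(1, 1.05), width = c(.2, .2), area = c(1, 1))),
    "ambiguous")
})

test_that("metabolome simulation records truth and honours null settings", {
  met <- simulate_metabolome(300, 0, log2_effect = 2, n_rep = 3, seed = 41)
  fc <- met_fold_change(met$intensity, met$group)
  expect_equal(sum(fc >= 2 | fc <= 0.5), 0)

  met2 <- simulate_metabolome(300, 15, log2_effect = 2, n_rep = 3,
                              seed = 42)
  expect_equal(sum(met2$truth$differential), 15)
  expect_identical(
    simulate_metabolome(50, 5, 2, 3, seed = 9)$intensity,
    simulate_metabolome(50, 5, 2, 3, seed = 9)$intensity)

  # duplicated groups give fold change exactly 1
  x <- met$intensity[, 1:3]
  dup <- cbind(x, x)
  fc1 <- met_fold_change(dup, factor(rep(c("g1", "g2"), each = 3)))
  expect_true(all(fc1 == 1))
})
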