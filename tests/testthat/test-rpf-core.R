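make_tsv <- function(aln) {
  f <- tempfile(fileext = ".tsv")
  write_alignments_tsv(aln, f)
  f
}

test_that("TSV ingestion validates references and coordinates", {
  tx <- hand_tx(make_cds(30))
  aln <- data.frame(transcript_id = "g01",
                    five_prime = c(0L, 10L, 50L), length = 30L)
  got <- read_alignments(make_tsv(aln), "tsv", tx)
  expect_equal(nrow(got), 3)

  bad_ref <- rbind(aln, data.frame(transcript_id = "nope",
                                   five_prime = 0L, length = 30L))
  expect_error(read_alignments(make_tsv(bad_ref), "tsv", tx),
               "unresolvable reference")

  # g01 transcript is 30 + 93 + 30 = 153 nt; a read at 140+30 overhangs
  over <- rbind(aln, data.frame(transcript_id = "g01",
                                five_prime = 140L, length = 30L))
  expect_message(got2 <- read_alignments(make_tsv(over), "tsv", tx),
                 "overhanging")
  expect_equal(nrow(got2), 3)

  empty <- data.frame(transcript_id = character(0),
                      five_prime = integer(0), length = integer(0))
  expect_error(read_alignments(make_tsv(empty), "tsv", tx), "no alignments")
})

test_that("BAM ingestion drops secondary records", {
  skip_if_not_installed("Rsamtools")
  tx <- hand_tx(make_cds(30))
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", tx$transcript_id,
                   nchar(tx$sequence)))
  rec <- function(id, flag, pos) {
    sprintf("%s\t%d\tg01\t%d\t255\t30M\t*\t0\t0\t%s\t*", id, flag, pos,
            substr(tx$sequence[1], pos, pos + 29))
  }
  writeLines(c(hdr, vapply(1:9, function(i) rec(paste0("r", i), 0L, i),
                           character(1)),
               rec("r10", 256L, 1L)), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  expect_message(aln <- read_alignments(bam, "bam", tx), "dropped 1")
  expect_equal(nrow(aln), 9)
  expect_equal(aln$five_prime, 0:8)  # BAM 1-based -> internal 0-based
  expect_true(all(aln$length == 30))
})

test_that("length distribution counts every read", {
  tx <- hand_tx(make_cds(30))
  aln <- data.frame(transcript_id = "g01", five_prime = 0:4, length = 30L)
  expect_equal(length_distribution(aln), c(`30` = 5L))
  expect_error(length_distribution(aln[0, ]), "empty")

  cfg <- sim_config(n_genes = 5, read_depth = 2000, seed = 13,
                    length_weights = c(`29` = 0.5, `31` = 0.5),
                    true_offsets = c(`29` = 12L, `31` = 12L))
  fp <- simulate_footprints(simulate_transcriptome(cfg), cfg, "WT")
  ld <- length_distribution(fp$alignments)
  expect_equal(sum(ld), nrow(fp$alignments))
  n <- sum(ld)
  se <- sqrt(n * 0.25)
  expect_true(all(abs(ld - n / 2) < 3 * se))
})

test_that("offset detection recovers simulator truth exactly (seed sweep)", {
  for (seed in c(1, 7, 101)) {
    cfg <- sim_config(n_genes = 15, read_depth = 4000, seed = seed)
    tx <- simulate_transcriptome(cfg)
    fp <- simulate_footprints(tx, cfg, "WT", seed = seed + 1)
    off <- detect_psite_offsets(fp$alignments, tx, min_support = 500)
    expected <- cfg$true_offsets[as.character(off$length)]
    expect_equal(setNames(off$offset, off$length),
                 setNames(as.integer(expected), off$length))
    ld <- length_distribution(fp$alignments)
    covered <- names(ld)[ld >= 500]
    expect_setequal(as.character(off$length), covered)
  }
})

test_that("offset ties break toward the smaller offset, support gates apply", {
  tx <- hand_tx(make_cds(60))
  # equal piles at metagene positions -13 and -10 for 30-mers
  aln <- data.frame(
    transcript_id = "g01",
    five_prime = rep(c(30L - 13L, 30L - 10L), each = 600),
    length = 30L)
  expect_message(off <- detect_psite_offsets(aln, tx, min_support = 500),
                 "tie")
  expect_equal(off$offset, 10L)

  # below min_support the length is omitted; with nothing left it errors
  few <- aln[seq_len(499), ]
  expect_error(detect_psite_offsets(few, tx, min_support = 500),
               "insufficient data")

  # no annotated start codons
  tx_na <- tx; tx_na$cds_start <- NA_integer_
  expect_error(detect_psite_offsets(aln, tx_na, min_support = 500),
               "no annotated start")
})

test_that("frame fractions are exact on ideal data and mix with noise", {
  cfg <- sim_config(n_genes = 10, read_depth = 3000, seed = 17)
  tx <- simulate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg, "WT", seed = 18)
  off <- detect_psite_offsets(fp$alignments, tx)
  per <- periodicity(fp$alignments, off, tx)
  expect_equal(per$frame0, rep(1, nrow(per)))
  expect_equal(per$frame0 + per$frame1 + per$frame2, rep(1, nrow(per)),
               tolerance = 1e-12)

  cfg_n <- sim_config(n_genes = 10, read_depth = 5000, seed = 17,
                      noise_frac_offtarget = 0.3)
  fp_n <- simulate_footprints(tx, cfg_n, "WT", seed = 19)
  per_n <- periodicity(fp_n$alignments, offset_table(cfg$true_offsets), tx)
  pooled <- sum(per_n$frame0 * per_n$n_reads) / sum(per_n$n_reads)
  # mixture arithmetic: 0.7 in frame + a third of the uniform 0.3
  se <- sqrt(0.8 * 0.2 / sum(per_n$n_reads))
  expect_equal(pooled, 0.8, tolerance = 5 * se / 0.8)

  # invariance under read order permutation
  perm <- fp_n$alignments[rev(seq_len(nrow(fp_n$alignments))), ]
  per_p <- periodicity(perm, offset_table(cfg$true_offsets), tx)
  expect_equal(per_n, per_p)
})

test_that("in-frame filter keeps frame-0 reads of 29-33 nt and is idempotent", {
  tx <- hand_tx(make_cds(60))
  off <- offset_table(c(`28` = 12L, `30` = 12L))
  aln <- data.frame(
    transcript_id = "g01",
    five_prime = c(30L - 12L,      # length 30, frame 0 -> kept
                   30L - 12L + 1L, # length 30, frame 1 -> dropped
                   30L - 12L,      # length 28, frame 0 but out of range
                   30L - 12L + 3L),# length 30, frame 0 -> kept
    length = c(30L, 30L, 28L, 30L))
  kept <- quiet(filter_inframe(aln, off, tx))
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$length == 30))
  # subset of the input, and idempotent
  expect_true(nrow(merge(kept, aln)) == nrow(kept))
  expect_equal(quiet(filter_inframe(kept, off, tx)), kept)
  # zero retained is an error
  bad <- aln[2, , drop = FALSE]
  expect_error(quiet(filter_inframe(bad, off, tx)), "zero reads")
  # lengths in range but without offsets are dropped with a message
  off29 <- offset_table(c(`30` = 12L))
  aln29 <- rbind(aln, data.frame(transcript_id = "g01",
                                 five_prime = 18L, length = 29L))
  expect_message(filter_inframe(aln29, off29, tx), "without detected")
})
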