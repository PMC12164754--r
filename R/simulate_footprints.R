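#' Simulate ribosome footprints with codon-resolved dwell
#'
#' Emits transcriptome-space footprint alignments under an A-site-anchored
#' occupancy model: a read whose A-site covers codon `c` of gene `g` is drawn
#' with probability proportional to `expression[g] * dwell_multipliers[c]`
#' (times `start_peak` at the first A-site codon, the initiation pile-up).
#' Read length is sampled from `length_weights` and the 5' end placed at
#' `A-site codon start - (true_offset[length] + 3)` nt, so the read is exactly
#' in frame 0 under the true offsets. A `noise_frac_offtarget` fraction of
#' reads is instead placed uniformly at random on the transcriptome.
#'
#' @param transcriptome a [simulate_transcriptome()] result.
#' @param config the [sim_config()] used to build it (dwell multipliers,
#'   length weights, offsets, depth and noise fraction are taken from here).
#' @param condition_label label stored with the output (e.g. `"WT"`).
#' @param seed RNG seed for this draw; defaults to `config$seed`. Use distinct
#'   seeds per condition so conditions are independent draws.
#' @return list with `alignments` (data.frame `transcript_id`, `five_prime`
#'   0-based, `length`), `condition`, and `truth` (per-gene expected read
#'   counts, dwell map, signal/noise split).
#' @export
simulate_footprints <- function(transcriptome, config,
                                condition_label = "WT",
                                seed = config$seed) {
  config <- validate_sim_config(config)
  tx <- transcriptome
  max_len <- max(as.integer(names(config$length_weights)))
  tlen <- nchar(tx$sequence)
  short <- tlen < max_len
  if (any(short)) {
    warning(sum(short), " transcript(s) shorter than max read length ",
            max_len, " skipped: ",
            paste(tx$transcript_id[short], collapse = ", "))
    tx <- tx[!short, , drop = FALSE]
    tlen <- tlen[!short]
  }
  if (!nrow(tx)) stop("no transcripts long enough to carry footprints")

  with_seed(seed, {
    ## Per-position sampling weights: one row per candidate A-site codon.
    ## A-site codons run 1 .. n_codons-1 (0-based; codon 0 is the start codon
    ## and can only sit in the P-site).
    n_pos <- tx$n_codons - 1L
    gene_idx <- rep.int(seq_len(nrow(tx)), n_pos)
    a_codon <- unlist(lapply(n_pos, seq_len), use.names = FALSE)  # 1..n-1
    cds <- cds_sequence(tx)
    codon_at <- substr(cds[gene_idx],
                       3L * a_codon + 1L, 3L * a_codon + 3L)
    dwell <- rep(1, length(codon_at))
    if (length(config$dwell_multipliers)) {
      hit <- match(codon_at, names(config$dwell_multipliers))
      dwell[!is.na(hit)] <- config$dwell_multipliers[hit[!is.na(hit)]]
    }
    w <- tx$expression[gene_idx] * dwell
    w[a_codon == 1L] <- w[a_codon == 1L] * config$start_peak

    n_total <- rpois(1L, nrow(tx) * config$read_depth)
    n_noise <- rbinom(1L, n_total, config$noise_frac_offtarget)
    n_signal <- n_total - n_noise

    lens <- as.integer(names(config$length_weights))
    sig_pos <- sample.int(length(w), n_signal, replace = TRUE, prob = w)
    sig_len <- lens[sample.int(length(lens), n_signal, replace = TRUE,
                               prob = config$length_weights)]
    off <- lookup(config$true_offsets, as.character(sig_len), "read length")
    five_prime <- tx$cds_start[gene_idx[sig_pos]] +
      3L * a_codon[sig_pos] - (off + 3L)

    aln <- data.frame(
      transcript_id = tx$transcript_id[gene_idx[sig_pos]],
      five_prime = as.integer(five_prime),
      length = sig_len,
      stringsAsFactors = FALSE
    )

    if (n_noise > 0L) {
      ng <- sample.int(nrow(tx), n_noise, replace = TRUE)
      nl <- lens[sample.int(length(lens), n_noise, replace = TRUE,
                            prob = config$length_weights)]
      npos <- floor(runif(n_noise) * (tlen[ng] - nl + 1L))
      aln <- rbind(aln, data.frame(
        transcript_id = tx$transcript_id[ng],
        five_prime = as.integer(npos),
        length = nl,
        stringsAsFactors = FALSE
      ))
    }

    stopifnot(all(aln$five_prime >= 0L),
              all(aln$five_prime + aln$length <=
                    tlen[match(aln$transcript_id, tx$transcript_id)]))

    expected_reads <- tapply(w, factor(gene_idx, levels = seq_len(nrow(tx))),
                             sum)
    expected_reads <- n_signal * expected_reads / sum(w)
    list(
      alignments = aln,
      condition = condition_label,
      truth = list(
        expected_reads = setNames(as.numeric(expected_reads),
                                  tx$transcript_id),
        dwell_multipliers = config$dwell_multipliers,
        true_offsets = config$true_offsets,
        n_signal = n_signal,
        n_noise = n_noise
      )
    )
  })
}

#' Write / read the TSV footprint alignment dialect
#'
#' Three tab-separated columns with header:
#' `transcript_id`, `five_prime` (0-based transcript coordinate of the read
#' 5' end), `length` (nt).
#'
#' @param alignments alignment data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(alignments, path) {
  write.table(alignments[, c("transcript_id", "five_prime", "length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
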