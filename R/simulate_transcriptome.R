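#' Simulate a coding transcriptome
#'
#' Draws `n_genes` transcripts, each a 5' UTR + CDS + 3' UTR. Every CDS begins
#' ATG, ends with exactly one stop codon, has length divisible by 3 and no
#' internal stops; internal codons are drawn i.i.d. from the configured codon
#' usage (uniform over the 61 sense codons by default). A log-normal true
#' expression rate (mean 1) is drawn per gene and recorded — it is shared by
#' every downstream `simulate_footprints()` call on this transcriptome so that
#' conditions differ only in dwell, not in expression.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `transcriptome` with columns
#'   `transcript_id`, `sequence` (full transcript), `cds_start` (0-based
#'   offset of the A of ATG), `n_codons` (sense codons, stop excluded),
#'   `expression` (true relative expression, mean 1).
#' @seealso [write_transcriptome_fasta()], [write_cds_table()]
#' @export
simulate_transcriptome <- function(config) {
  config <- validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_genes
    usage <- config$codon_usage
    codons <- sense_codons()
    if (is.null(usage)) {
      usage <- setNames(rep(1 / length(codons), length(codons)), codons)
    }
    usage <- usage[codons]
    lens_avail <- seq(config$cds_codon_range[1], config$cds_codon_range[2])
    n_codons <- lens_avail[sample.int(length(lens_avail), n,
                                      replace = TRUE)]
    stops <- stop_codons()
    seqs <- vapply(n_codons, function(nc) {
      body <- sample(codons, nc - 1L, replace = TRUE, prob = usage)
      utr5 <- paste(sample(c("A", "C", "G", "T"), config$utr_len[1],
                           replace = TRUE), collapse = "")
      utr3 <- paste(sample(c("A", "C", "G", "T"), config$utr_len[2],
                           replace = TRUE), collapse = "")
      paste0(utr5, "ATG", paste(body, collapse = ""),
             sample(stops, 1L), utr3)
    }, character(1))
    expression <- rlnorm(n, meanlog = -config$expression_sdlog^2 / 2,
                         sdlog = config$expression_sdlog)
    tx <- data.frame(
      transcript_id = sprintf("tx%04d", seq_len(n)),
      sequence = seqs,
      cds_start = config$utr_len[1],
      n_codons = n_codons,
      expression = expression,
      stringsAsFactors = FALSE
    )
    class(tx) <- c("transcriptome", "data.frame")
    tx
  })
}

#' CDS sequence (including the stop codon) of each transcript
#' @param tx a `transcriptome`.
#' @return character vector named by transcript id.
#' @export
cds_sequence <- function(tx) {
  setNames(substr(tx$sequence, tx$cds_start + 1L,
                  tx$cds_start + 3L * (tx$n_codons + 1L)),
           tx$transcript_id)
}

#' Write transcript sequences as FASTA
#' @param tx a `transcriptome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(tx, path) {
  ss <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$transcript_id))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Write / read the 3-column CDS annotation table
#'
#' Plain TSV with columns `transcript_id`, `cds_start`, `cds_end`
#' (1-based inclusive, stop codon included). Internally the package is
#' 0-based half-open; the 1-based convention applies only at this file
#' boundary.
#'
#' @param tx a `transcriptome`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cds_table <- function(tx, path) {
  df <- data.frame(transcript_id = tx$transcript_id,
                   cds_start = tx$cds_start + 1L,
                   cds_end = tx$cds_start + 3L * (tx$n_codons + 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cds_table
#' @param fasta FASTA of transcript sequences matching the table.
#' @return for `read_transcriptome`, a `transcriptome` data.frame
#'   (without true expression, which only the simulator knows).
#' @export
read_transcriptome <- function(fasta, path) {
  ann <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "cds_start", "cds_end") %in% names(ann)))
  ss <- Biostrings::readDNAStringSet(fasta)
  idx <- match(ann$transcript_id, names(ss))
  if (anyNA(idx)) {
    stop("annotation references transcripts absent from FASTA: ",
         paste(ann$transcript_id[is.na(idx)], collapse = ", "))
  }
  tx <- data.frame(
    transcript_id = ann$transcript_id,
    sequence = as.character(ss[idx]),
    cds_start = ann$cds_start - 1L,
    n_codons = (ann$cds_end - ann$cds_start + 1L) %/% 3L - 1L,
    expression = NA_real_,
    stringsAsFactors = FALSE
  )
  validate_transcriptome(tx)
  class(tx) <- c("transcriptome", "data.frame")
  tx
}

validate_transcriptome <- function(tx) {
  cds <- substr(tx$sequence, tx$cds_start + 1L,
                tx$cds_start + 3L * (tx$n_codons + 1L))
  if (any(nchar(cds) %% 3 != 0)) stop("CDS length not divisible by 3")
  if (any(substr(cds, 1, 3) != "ATG")) stop("CDS must begin with ATG")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (any(!last %in% stop_codons())) stop("CDS must end with a stop codon")
  invisible(tx)
}
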