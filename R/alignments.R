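#' Read footprint alignments (TSV dialect or BAM)
#'
#' TSV is the three-column dialect written by [write_alignments_tsv()]
#' (`transcript_id`, `five_prime` 0-based, `length`). BAM must carry
#' transcript-space references; secondary, supplementary and unmapped records
#' are dropped (their count is reported via `message()`), matching the
#' uniquely-mapped-reads-only convention. Reads whose reference is absent
#' from the annotation are a hard error; reads overhanging their transcript
#' are rejected with their coordinates logged.
#'
#' @param path alignment file.
#' @param format `"tsv"` or `"bam"` (BAM requires the Rsamtools package).
#' @param transcriptome annotation ([simulate_transcriptome()] or
#'   [read_transcriptome()]) the references must resolve against.
#' @return data.frame with columns `transcript_id`, `five_prime`, `length`.
#' @export
read_alignments <- function(path, format = c("tsv", "bam"), transcriptome) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "tsv") {
    aln <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("transcript_id", "five_prime", "length")
    if (!all(need %in% names(aln))) {
      stop("TSV alignments need columns: ", paste(need, collapse = ", "))
    }
    aln <- aln[, need]
    dropped <- 0L
  } else {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package")
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("rname", "pos", "qwidth"))
    rec <- Rsamtools::scanBam(path, param = p)[[1]]
    total <- Rsamtools::countBam(path)$records
    dropped <- total - length(rec$pos)
    aln <- data.frame(transcript_id = as.character(rec$rname),
                      five_prime = rec$pos - 1L,
                      length = rec$qwidth,
                      stringsAsFactors = FALSE)
  }
  if (!nrow(aln)) stop("no alignments in ", path)
  if (dropped > 0L) {
    message("dropped ", dropped,
            " secondary/supplementary/unmapped record(s)")
  }
  idx <- match(aln$transcript_id, transcriptome$transcript_id)
  if (anyNA(idx)) {
    stop("unresolvable reference name(s): ",
         paste(unique(aln$transcript_id[is.na(idx)]), collapse = ", "))
  }
  tlen <- nchar(transcriptome$sequence)[idx]
  bad <- aln$five_prime < 0L | aln$five_prime + aln$length > tlen
  if (any(bad)) {
    ex <- utils::head(which(bad), 5L)
    message("rejected ", sum(bad), " read(s) overhanging transcript ends, ",
            "e.g. ", paste(sprintf("%s:%d+%d", aln$transcript_id[ex],
                                   aln$five_prime[ex], aln$length[ex]),
                           collapse = ", "))
    aln <- aln[!bad, , drop = FALSE]
  }
  if (!nrow(aln)) stop("no alignments left after coordinate filtering")
  rownames(aln) <- NULL
  aln
}

#' Footprint length distribution
#'
#' @param alignments alignment data.frame.
#' @return named integer vector, read length -> count; counts sum to the
#'   number of input alignments.
#' @export
length_distribution <- function(alignments) {
  if (!nrow(alignments)) stop("empty alignment collection")
  tab <- table(alignments$length)
  setNames(as.integer(tab), names(tab))
}
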