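# Shared fixture builders: everything is generated in code at test time.

# Transcriptome built by hand from CDS strings (each must end in a stop).
hand_tx <- function(cds, utr5 = 30L, utr3 = 30L, ids = NULL) {
  ids <- ids %||% sprintf("g%02d", seq_along(cds))
  pad <- function(n) vapply(n, function(k)
    paste(rep("C", k), collapse = ""), character(1))
  tx <- data.frame(
    transcript_id = ids,
    sequence = paste0(pad(rep(utr5, length(cds))), cds,
                      pad(rep(utr3, length(cds)))),
    cds_start = utr5,
    n_codons = nchar(cds) %/% 3L - 1L,
    expression = 1,
    stringsAsFactors = FALSE
  )
  class(tx) <- c("transcriptome", "data.frame")
  tx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Codon occupancy table assembled directly from per-gene count vectors
# (counts[i] is the occupancy of 0-based codon i-1).
hand_occupancy <- function(tx, counts_by_gene, site = "A") {
  rows <- lapply(names(counts_by_gene), function(id) {
    cnt <- counts_by_gene[[id]]
    nz <- which(cnt > 0)
    data.frame(transcript_id = id, codon = nz - 1L, count = cnt[nz],
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, rows)
  structure(occ, class = c("codon_occupancy", "data.frame"),
            site = site, discarded = 0L)
}

# A CDS of n sense codons: ATG, then `body` codons recycled, then a stop.
make_cds <- function(n, body = c("GCT", "GAA", "CTG", "AAA")) {
  stopifnot(n >= 2)
  paste0("ATG", paste(rep_len(body, n - 1L), collapse = ""), "TAA")
}

serine_codons <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
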