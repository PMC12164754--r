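#' Infer 5'-to-P-site offsets from a start-codon metagene
#'
#' For each read length with at least `min_support` reads, builds the
#' metagene histogram of 5'-end positions relative to the annotated start
#' codon over `window` and takes the offset as minus the arg-max position,
#' with the search restricted to `search` (default 10--15 nt, one codon's
#' room either side of the canonical 12--13 nt, preventing off-by-one-codon
#' captures). Reads with the P-site on the start codon pile up at position
#' `-offset`, so the arg-max identifies the offset. Ties break toward the
#' smaller offset and are logged.
#'
#' @param alignments alignment data.frame.
#' @param transcriptome annotation providing `cds_start` per transcript.
#' @param min_support minimum reads per length; lengths below are omitted.
#' @param search integer length-2 vector, inclusive offset search window (nt).
#' @param window metagene window relative to the start codon.
#' @return data.frame of class `offset_table` with columns `length`,
#'   `offset`, `n_reads`.
#' @export
detect_psite_offsets <- function(alignments, transcriptome,
                                 min_support = 500,
                                 search = c(10L, 15L),
                                 window = c(-40L, 20L)) {
  idx <- match(alignments$transcript_id, transcriptome$transcript_id)
  if (anyNA(idx)) stop("alignments reference unknown transcripts")
  if (all(is.na(transcriptome$cds_start))) {
    stop("transcriptome provides no annotated start codons")
  }
  rel <- alignments$five_prime - transcriptome$cds_start[idx]
  lens <- sort(unique(alignments$length))
  lens <- lens[lens >= 26L & lens <= 36L]
  out <- lapply(lens, function(L) {
    sel <- alignments$length == L
    n <- sum(sel)
    if (n < min_support) return(NULL)
    r <- rel[sel]
    r <- r[r >= window[1] & r <= window[2]]
    cand <- seq(-search[2], -search[1])          # positions -15 .. -10
    counts <- vapply(cand, function(p) sum(r == p), integer(1))
    if (all(counts == 0L)) return(NULL)
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      # smaller offset = candidate position closer to 0 (later in `cand`)
      message("offset tie for length ", L, " at positions ",
              paste(cand[best], collapse = ", "),
              "; choosing the smaller offset")
      best <- max(best)
    }
    data.frame(length = L, offset = -cand[best], n_reads = n)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    stop("insufficient data for offset detection (no length reached ",
         min_support, " supporting reads)")
  }
  class(out) <- c("offset_table", "data.frame")
  out
}

#' Build an offset table by hand
#' @param offsets named vector, read length -> offset (nt).
#' @param n_reads optional support counts.
#' @return an `offset_table`.
#' @export
offset_table <- function(offsets, n_reads = NA_integer_) {
  out <- data.frame(length = as.integer(names(offsets)),
                    offset = as.integer(offsets),
                    n_reads = n_reads)
  class(out) <- c("offset_table", "data.frame")
  out
}

#' Write an offset table as JSON (`{"30": 12, ...}`)
#' @param offsets an `offset_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_offsets_json <- function(offsets, path) {
  jsonlite::write_json(as.list(setNames(offsets$offset,
                                        offsets$length)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

offset_for <- function(offsets, lengths) {
  offsets$offset[match(lengths, offsets$length)]
}

#' Reading-frame composition per read length
#'
#' Frame of a read is `(five_prime + offset - cds_start) mod 3`; frame 0
#' means the inferred P-site is in the annotated reading frame. Lengths
#' without an offset are skipped.
#'
#' @param alignments alignment data.frame.
#' @param offsets an `offset_table`.
#' @param transcriptome annotation.
#' @return data.frame with `length`, `frame0`, `frame1`, `frame2`
#'   (fractions summing to 1 per length) and `n_reads`.
#' @export
periodicity <- function(alignments, offsets, transcriptome) {
  off <- offset_for(offsets, alignments$length)
  keep <- !is.na(off)
  aln <- alignments[keep, , drop = FALSE]
  off <- off[keep]
  if (!nrow(aln)) stop("no alignments with known offsets")
  idx <- match(aln$transcript_id, transcriptome$transcript_id)
  frame <- (aln$five_prime + off - transcriptome$cds_start[idx]) %% 3L
  tab <- table(factor(aln$length), factor(frame, levels = 0:2))
  frac <- tab / rowSums(tab)
  data.frame(length = as.integer(rownames(tab)),
             frame0 = as.numeric(frac[, "0"]),
             frame1 = as.numeric(frac[, "1"]),
             frame2 = as.numeric(frac[, "2"]),
             n_reads = as.integer(rowSums(tab)))
}

#' Keep in-frame reads in the analysis length range
#'
#' Retains reads whose length lies in `length_range` (29--33 nt by default)
#' and whose frame, under the inferred offsets, is 0. Lengths without
#' offsets are dropped and logged; the retention fraction is logged.
#'
#' @inheritParams periodicity
#' @param length_range inclusive read-length window.
#' @return filtered alignment data.frame (a subset of the input rows).
#' @export
filter_inframe <- function(alignments, offsets, transcriptome,
                           length_range = c(29L, 33L)) {
  in_len <- alignments$length >= length_range[1] &
    alignments$length <= length_range[2]
  off <- offset_for(offsets, alignments$length)
  no_off <- in_len & is.na(off)
  if (any(no_off)) {
    message("dropping ", sum(no_off), " read(s) of length(s) ",
            paste(sort(unique(alignments$length[no_off])), collapse = ", "),
            " without detected offsets")
  }
  idx <- match(alignments$transcript_id, transcriptome$transcript_id)
  frame <- (alignments$five_prime + off -
              transcriptome$cds_start[idx]) %% 3L
  keep <- in_len & !is.na(frame) & frame == 0L
  out <- alignments[keep, , drop = FALSE]
  if (!nrow(out)) stop("zero reads retained by in-frame filtering")
  message(sprintf("retained %d/%d reads (%.1f%%) in frame 0, lengths %d-%d",
                  nrow(out), nrow(alignments),
                  100 * nrow(out) / nrow(alignments),
                  length_range[1], length_range[2]))
  rownames(out) <- NULL
  out
}
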