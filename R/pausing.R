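#' Per-codon ribosome occupancy at the A, P or E site
#'
#' Maps each (already in-frame-filtered) read to the codon its chosen
#' ribosomal site covers: P-site codon `(five_prime + offset - cds_start)/3`,
#' A-site one codon downstream, E-site one upstream. Reads whose site codon
#' falls outside `[0, n_codons)` (e.g. an E-site before the start codon) are
#' discarded and counted.
#'
#' @param alignments in-frame filtered alignment data.frame.
#' @param offsets an `offset_table`.
#' @param transcriptome annotation.
#' @param site `"A"`, `"P"` or `"E"`.
#' @return data.frame of class `codon_occupancy` with columns
#'   `transcript_id`, `codon` (0-based codon index), `count`; attribute
#'   `discarded` holds the out-of-CDS read count, attribute `site` the site.
#' @export
codon_occupancy <- function(alignments, offsets, transcriptome,
                            site = c("A", "P", "E")) {
  site <- match.arg(site)
  off <- offset_for(offsets, alignments$length)
  if (anyNA(off)) stop("offsets missing for some read lengths; filter first")
  idx <- match(alignments$transcript_id, transcriptome$transcript_id)
  rel <- alignments$five_prime + off - transcriptome$cds_start[idx]
  if (any(rel %% 3L != 0L)) {
    stop("out-of-frame reads present; run filter_inframe() first")
  }
  p_codon <- rel %/% 3L
  codon <- p_codon + switch(site, A = 1L, P = 0L, E = -1L)
  ok <- codon >= 0L & codon < transcriptome$n_codons[idx]
  # tabulate on a (gene, codon) key: linear time in the number of reads
  K <- max(transcriptome$n_codons)
  key <- (idx[ok] - 1L) * K + codon[ok] + 1L
  counts <- tabulate(key, nbins = nrow(transcriptome) * K)
  nz <- which(counts > 0L)
  occ <- data.frame(
    transcript_id = transcriptome$transcript_id[(nz - 1L) %/% K + 1L],
    codon = (nz - 1L) %% K,
    count = counts[nz],
    stringsAsFactors = FALSE
  )
  structure(occ, class = c("codon_occupancy", "data.frame"),
            site = site, discarded = sum(!ok))
}

#' Codon pausing scores
#'
#' For each gene with strictly more than `min_reads` site-assigned reads on
#' its interior codons (the first `edge_exclusion[1]` and last
#' `edge_exclusion[2]` codons are excluded to avoid initiation/termination
#' piles), each interior codon position's occupancy is normalized by the
#' gene's mean occupancy per interior codon. The pausing score of a codon is
#' then either the mean of these normalized densities over every interior
#' position encoding it across genes (`method = "gene_normalized"`, the
#' default) or the ratio of pooled counts to pooled expected counts
#' (`method = "pooled"`, provided for sensitivity analysis). A score of 1
#' means average elongation speed; > 1 means pausing.
#'
#' @param occupancy a [codon_occupancy()] result (single condition, single
#'   site).
#' @param transcriptome annotation (codon identities come from its CDS).
#' @param min_reads genes are retained only if interior read count is
#'   strictly greater than this (default 10).
#' @param edge_exclusion integer length-2: codons excluded at the start and
#'   end of each CDS.
#' @param method scoring convention, see above.
#' @return data.frame of class `codon_score_set`, one row per sense codon:
#'   `codon`, `amino_acid`, `score` (NA for codons with no scoreable
#'   occurrence), `n_occurrences`; attributes `site`, `n_genes`, `method`.
#' @export
pausing_scores <- function(occupancy, transcriptome, min_reads = 10,
                           edge_exclusion = c(15L, 5L),
                           method = c("gene_normalized", "pooled")) {
  method <- match.arg(method)
  site <- attr(occupancy, "site")
  tx <- transcriptome[match(unique(occupancy$transcript_id),
                            transcriptome$transcript_id), , drop = FALSE]
  codons61 <- sense_codons()
  sum_d <- setNames(numeric(length(codons61)), codons61)
  sum_e <- sum_d          # pooled expected counts (method = "pooled")
  pool_counts <- sum_d    # pooled observed counts (method = "pooled")
  n_occ <- setNames(integer(length(codons61)), codons61)
  cds <- cds_sequence(tx)
  occ_by_gene <- split(occupancy[c("codon", "count")],
                       occupancy$transcript_id)
  n_genes <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(tx))) {
    nc <- tx$n_codons[i]
    lo <- edge_exclusion[1]                 # first interior codon (0-based)
    hi <- nc - edge_exclusion[2] - 1L       # last interior codon
    if (hi < lo) next
    counts <- numeric(nc)
    og <- occ_by_gene[[tx$transcript_id[i]]]
    if (!is.null(og)) counts[og$codon + 1L] <- og$count
    interior <- (lo:hi) + 1L
    total <- sum(counts[interior])
    if (total <= min_reads) next
    m <- total / length(interior)
    if (m == 0) { skipped <- skipped + 1L; next }
    dens <- counts[interior] / m
    cod <- substring(cds[i], 3L * (lo:hi) + 1L, 3L * (lo:hi) + 3L)
    keep <- cod %in% codons61
    agg_d <- tapply(dens[keep], cod[keep], sum)
    agg_n <- tapply(rep(1L, sum(keep)), cod[keep], sum)
    sum_d[names(agg_d)] <- sum_d[names(agg_d)] + agg_d
    n_occ[names(agg_n)] <- n_occ[names(agg_n)] + agg_n
    if (method == "pooled") {
      agg_c <- tapply(counts[interior][keep], cod[keep], sum)
      sum_e[names(agg_n)] <- sum_e[names(agg_n)] + agg_n * m
      pool_counts[names(agg_c)] <- pool_counts[names(agg_c)] + agg_c
    }
    n_genes <- n_genes + 1L
  }
  if (n_genes == 0L) stop("zero genes retained for pausing scores")
  if (skipped > 0L) {
    message(skipped, " gene(s) skipped with zero interior occupancy")
  }
  score <- if (method == "gene_normalized") {
    ifelse(n_occ > 0L, sum_d / n_occ, NA_real_)
  } else {
    ifelse(n_occ > 0L, pool_counts / sum_e, NA_real_)
  }
  out <- data.frame(codon = codons61,
                    amino_acid = codon_to_aa(codons61),
                    score = as.numeric(score),
                    n_occurrences = as.integer(n_occ),
                    stringsAsFactors = FALSE)
  structure(out, class = c("codon_score_set", "data.frame"),
            site = site, n_genes = n_genes, method = method)
}

#' Compare pausing scores between two conditions
#'
#' Per-codon score ratio `score_a / score_b`. Because per-gene mean
#' normalization makes the 61 scores compositional (raising one codon's
#' dwell mechanically depresses all others), the ratios are additionally
#' centered on their median codon ratio (`centered_ratio`) — the
#' median-of-ratios assumption that most codons are unaffected — so that an
#' injected k-fold dwell change is read off directly. Serine's six codons
#' are flagged.
#'
#' @param scores_a,scores_b two [pausing_scores()] results from the same
#'   ribosomal site (e.g. mutant and WT).
#' @param center logical; add the median-centered ratio column (default).
#' @return data.frame: `codon`, `amino_acid`, `score_a`, `score_b`, `ratio`,
#'   `centered_ratio` (if `center`), `is_serine`. Codons with `score_b` 0 or
#'   NA get NA ratios.
#' @export
pausing_comparison <- function(scores_a, scores_b, center = TRUE) {
  if (!identical(attr(scores_a, "site"), attr(scores_b, "site"))) {
    stop("pausing score sets come from different ribosomal sites")
  }
  stopifnot(identical(scores_a$codon, scores_b$codon))
  ratio <- ifelse(!is.na(scores_b$score) & scores_b$score > 0,
                  scores_a$score / scores_b$score, NA_real_)
  out <- data.frame(codon = scores_a$codon,
                    amino_acid = scores_a$amino_acid,
                    score_a = scores_a$score,
                    score_b = scores_b$score,
                    ratio = ratio,
                    stringsAsFactors = FALSE)
  if (center) {
    out$centered_ratio <- ratio / median(ratio, na.rm = TRUE)
  }
  out$is_serine <- out$codon %in% SERINE_CODONS
  out
}

#' Amino-acid composition of a CDS
#'
#' @param cds_sequence a CDS nucleotide string (trailing stop codon allowed;
#'   internal stops are an error).
#' @return named numeric vector of amino-acid fractions (stop excluded),
#'   summing to 1, over the amino acids present.
#' @export
aa_composition <- function(cds_sequence) {
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_sequence))), "")[[1]]
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in CDS")
  if (!length(aa)) stop("empty CDS")
  tab <- table(aa)
  setNames(as.numeric(tab) / length(aa), names(tab))
}
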