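#' Gene-level read counting
#'
#' Tallies one count per read against its transcript (for RPFs, pass the
#' in-frame filtered alignments so the count reflects P-site-assigned
#' footprints). Reads on transcripts absent from the annotation are
#' unassigned and logged.
#'
#' @param alignments alignment data.frame.
#' @param transcriptome annotation.
#' @return named integer vector of counts, one per annotated transcript
#'   (zeros included); total equals the number of assigned reads.
#' @export
count_genes <- function(alignments, transcriptome) {
  idx <- match(alignments$transcript_id, transcriptome$transcript_id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " read(s) unassigned to annotated transcripts")
    idx <- idx[!is.na(idx)]
  }
  setNames(tabulate(idx, nbins = nrow(transcriptome)),
           transcriptome$transcript_id)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with nonzero
#' counts in every sample) of the ratio of its count to the gene's geometric
#' mean across samples; factors are rescaled to geometric mean 1, so equal
#' columns give factors of exactly 1.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has nonzero counts in all samples")
  lc <- log(counts[pos, , drop = FALSE])
  lgm <- rowMeans(lc)
  lsf <- apply(lc - lgm, 2L, median)
  exp(lsf - mean(lsf))
}

# Method-of-moments NB dispersion per gene, shrunk toward a mean-dispersion
# trend. `group` defines the cells of the full design so genuine effects do
# not inflate the estimate. Shrinkage: precision-weighted average with the
# trend in linear space (prior weight `prior_df` pseudo-replicates), then a
# floor. With many genes sharing a dispersion regime the trend dominates,
# which is what keeps the likelihood-ratio test calibrated at n = 3.
estimate_dispersions <- function(counts, sf, group, prior_df = 20,
                                 floor = 1e-8) {
  q <- sweep(as.matrix(counts), 2L, sf, `/`)
  groups <- split(seq_len(ncol(q)), group)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (!length(groups)) stop("dispersion estimation needs >= 2 replicates")
  num <- matrix(0, nrow(q), length(groups))
  den <- num
  wts <- numeric(length(groups))
  for (k in seq_along(groups)) {
    cols <- groups[[k]]
    m <- rowMeans(q[, cols, drop = FALSE])
    v <- apply(q[, cols, drop = FALSE], 1L, var)
    cinv <- mean(1 / sf[cols])     # Var(K/s) ~ mu/s + alpha mu^2
    num[, k] <- (v - m * cinv) * (length(cols) - 1L)
    den[, k] <- m^2 * (length(cols) - 1L)
    wts[k] <- length(cols) - 1L
  }
  raw <- rowSums(num) / pmax(rowSums(den), .Machine$double.eps)
  raw <- pmax(raw, 0)
  mu_all <- rowMeans(q)
  # mean-dispersion trend: loess of the (positive) raw estimates on log mean
  use <- raw > 1e-6 & mu_all > 0
  trend <- rep(median(raw[use], na.rm = TRUE), nrow(q))
  if (sum(use) >= 50L) {
    td <- data.frame(lmu = log(mu_all[use]), ldisp = log(raw[use]))
    fit <- suppressWarnings(
      loess(ldisp ~ lmu, data = td, span = 0.75, degree = 1L,
            family = "symmetric"))
    pred <- predict(fit, newdata = data.frame(
      lmu = log(pmax(mu_all, min(mu_all[use])))))
    # loess of log-dispersion is biased low by Jensen; correct with the mean
    # residual offset on the natural scale
    adj <- mean(raw[use] / exp(predict(fit)), na.rm = TRUE)
    ok <- is.finite(pred)
    trend[ok] <- exp(pred[ok]) * adj
  }
  d <- sum(wts)
  disp <- (d * raw + prior_df * trend) / (d + prior_df)
  pmax(disp, floor)
}

nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Per-gene negative-binomial likelihood-ratio test
#'
#' Fits each gene with a NB GLM (log link, offsets = log size factors,
#' per-gene dispersion estimated by method-of-moments with trend shrinkage
#' and a floor of 1e-8, then held fixed) under a full and a nested reduced
#' design, and tests twice the log-likelihood difference against a
#' chi-square with df equal to the difference in design rank.
#'
#' @param counts genes x samples count matrix.
#' @param design_full,design_reduced model matrices (reduced must be nested
#'   in full).
#' @param sf size factors; computed from `counts` if `NULL`.
#' @param dispersions per-gene dispersions; estimated if `NULL`.
#' @return data.frame: `gene`, `log2fc` (last full-design coefficient, in
#'   log2 units), `stat`, `df`, `p` (NA for non-converged genes, flagged in
#'   `converged`).
#' @export
nb_lrt <- function(counts, design_full, design_reduced, sf = NULL,
                   dispersions = NULL) {
  counts <- as.matrix(counts)
  qrf <- qr(design_full)
  qrr <- qr(design_reduced)
  # nesting: every reduced column must lie in the span of the full design
  resid_r <- qr.resid(qrf, design_reduced)
  if (max(abs(resid_r)) > 1e-8 || qrr$rank >= qrf$rank) {
    stop("designs are not nested (reduced must be a sub-model of full)")
  }
  df_test <- qrf$rank - qrr$rank
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) {
    group <- apply(design_full, 1L, paste, collapse = "/")
    dispersions <- estimate_dispersions(counts, sf, group)
  }
  off <- log(sf)
  n <- nrow(counts)
  out <- data.frame(gene = rownames(counts) %||% as.character(seq_len(n)),
                    log2fc = NA_real_, stat = NA_real_,
                    df = df_test, p = NA_real_, converged = FALSE)
  for (g in seq_len(n)) {
    y <- counts[g, ]
    fam <- MASS::negative.binomial(theta = 1 / dispersions[g])
    fit <- tryCatch({
      ff <- suppressWarnings(
        stats::glm.fit(design_full, y, family = fam, offset = off))
      fr <- suppressWarnings(
        stats::glm.fit(design_reduced, y, family = fam, offset = off))
      list(ff = ff, fr = fr)
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$ff$converged || !fit$fr$converged) next
    ll_f <- nb_loglik(y, fit$ff$fitted.values, dispersions[g])
    ll_r <- nb_loglik(y, fit$fr$fitted.values, dispersions[g])
    stat <- max(0, 2 * (ll_f - ll_r))
    out$log2fc[g] <- fit$ff$coefficients[ncol(design_full)] / log(2)
    out$stat[g] <- stat
    out$p[g] <- pchisq(stat, df = df_test, lower.tail = FALSE)
    out$converged[g] <- TRUE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-condition differential expression for one assay
#'
#' NB LRT of `~ condition` against `~ 1`; fold changes are ratios of
#' size-factor-normalized condition means (condition 2 over condition 1).
#' Genes are called up if `log2FC >= log2(fc_threshold)` and
#' `padj < alpha` (BH), down symmetrically. The threshold is applied on the
#' linear scale: FC 1.49 is never called, whatever its p-value.
#'
#' @param counts genes x samples matrix (one assay).
#' @param condition length-`ncol(counts)` factor with exactly 2 levels;
#'   fold changes are level 2 vs level 1.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param alpha BH-adjusted significance threshold.
#' @return data.frame: `gene`, `baseMean`, `log2fc`, `p`, `padj`,
#'   `call` (`"up"`, `"down"`, `"ns"`).
#' @export
differential_expression <- function(counts, condition, fc_threshold = 1.5,
                                    alpha = 0.05) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  full <- model.matrix(~condition)
  red <- full[, 1L, drop = FALSE]
  res <- nb_lrt(counts, full, red, sf = sf)
  q <- sweep(counts, 2L, sf, `/`)
  m1 <- rowMeans(q[, condition == levels(condition)[1], drop = FALSE])
  m2 <- rowMeans(q[, condition == levels(condition)[2], drop = FALSE])
  res$baseMean <- rowMeans(q)
  res$log2fc <- ifelse(m1 > 0 & m2 > 0, log2(m2 / m1), NA_real_)
  res$padj <- p.adjust(res$p, method = "BH")
  thr <- log2(fc_threshold)
  res$call <- ifelse(is.na(res$log2fc) | is.na(res$padj), "ns",
                     ifelse(res$log2fc >= thr & res$padj < alpha, "up",
                            ifelse(res$log2fc <= -thr & res$padj < alpha,
                                   "down", "ns")))
  res[c("gene", "baseMean", "log2fc", "stat", "df", "p", "padj",
        "converged", "call")]
}

#' Per-gene, per-condition translation efficiency
#'
#' TE = normalized mean RPF / normalized mean RNA, with size factors
#' computed jointly over the RNA and RPF samples (shared normalization).
#' Genes with zero RNA mean in a condition get NA TE (flagged, never fed to
#' the eCDF).
#'
#' @param rpf,rna genes x samples count matrices over the same genes, with
#'   columns in the same condition order.
#' @param condition factor for the columns of each matrix.
#' @param sf optional shared size factors for `cbind(rna, rpf)`.
#' @return data.frame: `gene`, `te_<level1>`, `te_<level2>`, `log2fc_te`.
#' @export
compute_te <- function(rpf, rna, condition, sf = NULL) {
  rpf <- as.matrix(rpf); rna <- as.matrix(rna)
  if (!identical(rownames(rpf), rownames(rna))) {
    common <- intersect(rownames(rpf), rownames(rna))
    if (!length(common)) stop("RPF and RNA gene sets are disjoint")
    rpf <- rpf[common, , drop = FALSE]
    rna <- rna[common, , drop = FALSE]
  }
  condition <- droplevels(as.factor(condition))
  if (is.null(sf)) sf <- size_factors(cbind(rna, rpf))
  sf_rna <- sf[seq_len(ncol(rna))]
  sf_rpf <- sf[ncol(rna) + seq_len(ncol(rpf))]
  qr_ <- sweep(rna, 2L, sf_rna, `/`)
  qp <- sweep(rpf, 2L, sf_rpf, `/`)
  te <- sapply(levels(condition), function(lv) {
    mr <- rowMeans(qr_[, condition == lv, drop = FALSE])
    mp <- rowMeans(qp[, condition == lv, drop = FALSE])
    ifelse(mr > 0, mp / mr, NA_real_)
  })
  out <- data.frame(gene = rownames(rpf), te, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("te_", levels(condition))
  out$log2fc_te <- log2(out[[3]] / out[[2]])
  rownames(out) <- NULL
  out
}

#' Differential translation efficiency (interaction LRT)
#'
#' Tests, per gene, the condition-by-assay interaction in the NB GLM
#' `~ condition + assay + condition:assay` against the additive reduced
#' model, over the combined RNA + RPF count matrix with shared size
#' factors. A gene is a differential-TE gene (DTEG) if
#' `|log2FC_TE| >= log2(fc_threshold)` and BH-adjusted `p < alpha`.
#' Fold changes are plug-in ratios of normalized condition means, so
#' `log2FC_TE = log2FC_RPF - log2FC_mRNA` holds exactly; the nine-quadrant
#' class of each gene (fold-change axes only) is included.
#'
#' @inheritParams compute_te
#' @param fc_threshold linear TE fold-change threshold (default 1.5).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return data.frame with per-gene `log2fc_mrna`, `log2fc_rpf`,
#'   `te_<cond1>`, `te_<cond2>`, `log2fc_te`, `p`, `padj`, `quadrant`,
#'   `dteg`.
#' @export
differential_te <- function(rpf, rna, condition, fc_threshold = 1.5,
                            alpha = 0.05) {
  rpf <- as.matrix(rpf); rna <- as.matrix(rna)
  stopifnot(identical(rownames(rpf), rownames(rna)),
            ncol(rpf) == length(condition),
            ncol(rna) == length(condition))
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  if (min(table(condition)) < 2L) stop(">= 2 replicates per cell required")
  keep <- rowSums(rna) + rowSums(rpf) > 0
  rna <- rna[keep, , drop = FALSE]
  rpf <- rpf[keep, , drop = FALSE]
  combined <- cbind(rna, rpf)
  cond2 <- factor(rep(as.character(condition), 2L),
                  levels = levels(condition))
  assay <- factor(rep(c("RNA", "RPF"), c(ncol(rna), ncol(rpf))),
                  levels = c("RNA", "RPF"))
  sf <- size_factors(combined)
  full <- model.matrix(~ cond2 + assay + cond2:assay)
  red <- model.matrix(~ cond2 + assay)
  res <- nb_lrt(combined, full, red, sf = sf)

  te <- compute_te(rpf, rna, condition, sf = sf)
  qn <- sweep(rna, 2L, sf[seq_len(ncol(rna))], `/`)
  qp <- sweep(rpf, 2L, sf[ncol(rna) + seq_len(ncol(rpf))], `/`)
  lv <- levels(condition)
  mfun <- function(q, lvl) rowMeans(q[, condition == lvl, drop = FALSE])
  l2 <- function(a, b) ifelse(a > 0 & b > 0, log2(b / a), NA_real_)
  out <- data.frame(
    gene = rownames(rna),
    log2fc_mrna = l2(mfun(qn, lv[1]), mfun(qn, lv[2])),
    log2fc_rpf = l2(mfun(qp, lv[1]), mfun(qp, lv[2])),
    stringsAsFactors = FALSE
  )
  out[[paste0("te_", lv[1])]] <- te[[paste0("te_", lv[1])]]
  out[[paste0("te_", lv[2])]] <- te[[paste0("te_", lv[2])]]
  out$log2fc_te <- out$log2fc_rpf - out$log2fc_mrna
  out$p <- res$p
  out$padj <- p.adjust(res$p, method = "BH")
  out$quadrant <- nine_quadrant(out$log2fc_mrna, out$log2fc_rpf,
                                fc_threshold)
  thr <- log2(fc_threshold)
  out$dteg <- !is.na(out$log2fc_te) & !is.na(out$padj) &
    abs(out$log2fc_te) >= thr & out$padj < alpha
  out
}

#' TE eCDF comparison between conditions
#'
#' Empirical CDFs of log2 TE per condition and the two-sample
#' Kolmogorov-Smirnov test. A global TE reduction in the second condition
#' shifts its curve left.
#'
#' @param te_a,te_b per-gene TE values for the two conditions (NA/zero
#'   dropped); at least 50 defined values each.
#' @return list with `ecdf_a`, `ecdf_b` (functions over log2 TE), `D`, `p`.
#' @export
te_ecdf <- function(te_a, te_b) {
  a <- log2(te_a[!is.na(te_a) & te_a > 0])
  b <- log2(te_b[!is.na(te_b) & te_b > 0])
  if (length(a) < 50L || length(b) < 50L) {
    stop("need >= 50 genes with defined TE in both conditions")
  }
  ks <- suppressWarnings(ks.test(a, b))
  list(ecdf_a = ecdf(a), ecdf_b = ecdf(b),
       D = unname(ks$statistic), p = ks$p.value)
}

#' Nine-quadrant transcriptome/translatome classification
#'
#' Joint classification of genes by mRNA and RPF fold-change state
#' (down / unchanged / up, using `|FC| >= fc_threshold` on the linear
#' scale; the boundary |FC| exactly at the threshold counts as changed).
#' Classes: S1 mRNA-down/RPF-up, S2 unchanged/up, S3 up/up, S4
#' down/unchanged, S5 unchanged/unchanged, S6 up/unchanged, S7 down/down,
#' S8 unchanged/down, S9 up/down.
#'
#' @param log2fc_mrna,log2fc_rpf per-gene log2 fold changes.
#' @param fc_threshold linear threshold (default 1.5).
#' @return factor with levels S1..S9 (NA where a fold change is NA).
#' @export
nine_quadrant <- function(log2fc_mrna, log2fc_rpf, fc_threshold = 1.5) {
  thr <- log2(fc_threshold)
  state <- function(x) ifelse(x <= -thr, 1L, ifelse(x >= thr, 3L, 2L))
  m <- state(log2fc_mrna)   # 1 down, 2 unchanged, 3 up
  r <- state(log2fc_rpf)
  cls <- ifelse(is.na(m) | is.na(r), NA_character_,
                paste0("S", (3L - r) * 3L + m))
  factor(cls, levels = paste0("S", 1:9))
}
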