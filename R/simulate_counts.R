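#' Simulate a paired RNA / RPF count experiment
#'
#' Negative-binomial counts for two assays (RNA, RPF) in two conditions with
#' `n_rep` replicates each. Gene baseline means are log-normal around
#' `base_mean`; the RPF mean is the RNA mean times a per-gene translation
#' efficiency; condition 2 perturbs mRNA level by `rna_effect` and TE by
#' `te_effect` (both log2 fold changes). Per-sample sequencing-depth
#' multipliers are drawn log-normally and recorded, so size-factor recovery
#' can be checked against truth.
#'
#' @param n_genes number of genes.
#' @param n_rep_per_condition replicates per condition (>= 2).
#' @param dispersion NB dispersion alpha (> 0); `Var = mu + alpha * mu^2`.
#' @param te_effect per-gene log2 TE fold change in condition 2 (scalar or
#'   length-`n_genes` vector).
#' @param seed RNG seed.
#' @param rna_effect per-gene log2 mRNA fold change in condition 2.
#' @param base_mean median baseline RNA mean count.
#' @param mean_sdlog log-sd of the baseline mean spread.
#' @param te_sdlog log-sd of the per-gene baseline TE (centered on 1).
#' @param depth_sdlog log-sd of per-sample depth multipliers (0 = equal depth).
#' @return list with `rna` and `rpf` (genes x 2*n_rep integer matrices),
#'   `condition` (factor, aligned with the columns of both matrices), and
#'   `truth` (means, effects, TE, depth multipliers).
#' @export
simulate_count_experiment <- function(n_genes, n_rep_per_condition,
                                      dispersion, te_effect = 0,
                                      seed = 1L, rna_effect = 0,
                                      base_mean = 500, mean_sdlog = 1,
                                      te_sdlog = 0.25, depth_sdlog = 0.15) {
  if (n_rep_per_condition < 2L) stop("n_rep_per_condition must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  te_effect <- rep_len(te_effect, n_genes)
  rna_effect <- rep_len(rna_effect, n_genes)
  with_seed(seed, {
    nr <- n_rep_per_condition
    mu0 <- rlnorm(n_genes, meanlog = log(base_mean), sdlog = mean_sdlog)
    te0 <- rlnorm(n_genes, meanlog = -te_sdlog^2 / 2, sdlog = te_sdlog)
    depth <- rlnorm(4L * nr, meanlog = 0, sdlog = depth_sdlog)

    cond <- factor(rep(c("WT", "mutant"), each = nr),
                   levels = c("WT", "mutant"))
    rna_mu <- cbind(matrix(mu0, n_genes, nr),
                    matrix(mu0 * 2^rna_effect, n_genes, nr))
    rpf_mu <- cbind(matrix(mu0 * te0, n_genes, nr),
                    matrix(mu0 * te0 * 2^(rna_effect + te_effect),
                           n_genes, nr))
    rna_mu <- sweep(rna_mu, 2L, depth[seq_len(2L * nr)], `*`)
    rpf_mu <- sweep(rpf_mu, 2L, depth[2L * nr + seq_len(2L * nr)], `*`)

    draw <- function(mu) {
      m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                  nrow = n_genes)
      rownames(m) <- sprintf("gene%05d", seq_len(n_genes))
      m
    }
    rna <- draw(rna_mu)
    rpf <- draw(rpf_mu)
    colnames(rna) <- paste0("RNA_", cond, "_", rep(seq_len(nr), 2L))
    colnames(rpf) <- paste0("RPF_", cond, "_", rep(seq_len(nr), 2L))
    list(rna = rna, rpf = rpf, condition = cond,
         truth = list(base_mean = mu0, te = te0,
                      rna_log2fc = rna_effect, te_log2fc = te_effect,
                      dispersion = dispersion,
                      depth = setNames(depth, c(colnames(rna),
                                                colnames(rpf)))))
  })
}
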