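#' Simulate a metabolite intensity table
#'
#' Log-normal intensities for two groups with `n_rep` replicates each;
#' `n_diff` metabolites are shifted in group 2 by `log2_effect` (scalar with
#' random signs, or a named signed vector, one entry per differential
#' metabolite — names become metabolite ids). Truth flags and directions are
#' recorded.
#'
#' @param n_metabolites number of metabolites.
#' @param n_diff number of differential metabolites (<= n_metabolites).
#' @param log2_effect scalar magnitude (signs drawn at random) or signed
#'   vector of length `n_diff`.
#' @param n_rep replicates per group (>= 3 for the screen's PLS-DA).
#' @param seed RNG seed.
#' @param cv within-group coefficient of variation of intensities.
#' @param base_sdlog log-sd of metabolite baseline abundances.
#' @return list with `intensity` (metabolites x samples), `group` (factor),
#'   `truth` (`differential` logical, `log2_effect` per metabolite).
#' @export
simulate_metabolome <- function(n_metabolites, n_diff, log2_effect = 2,
                                n_rep = 3, seed = 1L, cv = 0.2,
                                base_sdlog = 1) {
  if (n_diff > n_metabolites) stop("n_diff must be <= n_metabolites")
  if (n_rep < 2L) stop("n_rep must be >= 2")
  with_seed(seed, {
    ids <- sprintf("met%04d", seq_len(n_metabolites))
    eff <- numeric(n_metabolites)
    if (n_diff > 0L) {
      which_diff <- sample.int(n_metabolites, n_diff)
      if (length(log2_effect) == 1L && is.null(names(log2_effect))) {
        signs <- sample(c(-1, 1), n_diff, replace = TRUE)
        eff[which_diff] <- signs * abs(log2_effect)
      } else {
        stopifnot(length(log2_effect) == n_diff)
        eff[which_diff] <- log2_effect
        if (!is.null(names(log2_effect))) {
          ids[which_diff] <- names(log2_effect)
        }
      }
    }
    base <- rlnorm(n_metabolites, meanlog = log(1e6), sdlog = base_sdlog)
    sdlog <- sqrt(log(1 + cv^2))
    g <- factor(rep(c("group1", "group2"), each = n_rep),
                levels = c("group1", "group2"))
    mu <- cbind(matrix(base, n_metabolites, n_rep),
                matrix(base * 2^eff, n_metabolites, n_rep))
    x <- matrix(rlnorm(length(mu), meanlog = log(mu) - sdlog^2 / 2,
                       sdlog = sdlog), nrow = n_metabolites)
    rownames(x) <- ids
    colnames(x) <- paste0(g, "_", rep(seq_len(n_rep), 2L))
    list(intensity = x, group = g,
         truth = list(differential = eff != 0,
                      log2_effect = setNames(eff, ids)))
  })
}
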