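#' Simulation configuration for the footprint generator
#'
#' Bundles and validates every tunable of the synthetic ribosome-profiling
#' generator. Defaults encode the study conditions the downstream analyses
#' assume: footprint lengths 26--36 nt peaking at 30 nt (plant 80S monosome
#' footprint mode), 5'-to-P-site offsets of 12 nt for lengths up to 31 and
#' 13 nt for 32 nt and longer, and uniform codon dwell.
#'
#' @param n_genes number of coding transcripts to simulate.
#' @param cds_codon_range integer length-2 vector, inclusive range of CDS
#'   lengths in codons (excluding the stop codon). Lower bound must be >= 20
#'   so that edge-codon exclusion leaves scoreable positions.
#' @param read_depth expected footprints per gene (the per-gene Poisson mean;
#'   total expected reads are `n_genes * read_depth`).
#' @param length_weights named numeric vector mapping read length (nt, within
#'   26--36) to sampling probability; must sum to 1.
#' @param true_offsets named integer vector mapping read length to the true
#'   5'-to-P-site offset in nt; must cover every length in `length_weights`.
#' @param dwell_multipliers named positive numeric vector mapping codons to
#'   relative A-site dwell time; codons absent from the map have dwell 1.
#' @param noise_frac_offtarget fraction of reads placed uniformly at random on
#'   the transcriptome (out-of-frame background).
#' @param seed integer RNG seed; all `simulate_*` output is byte-identical
#'   given the same seed.
#' @param utr_len integer length-2 vector: 5' and 3' UTR lengths in nt flanking
#'   the CDS on each simulated transcript.
#' @param expression_sdlog standard deviation (log scale) of the log-normal
#'   per-gene expression rates (mean 1).
#' @param start_peak positional dwell multiplier applied at the first A-site
#'   codon, emulating the canonical initiation pile-up at the start codon.
#' @param codon_usage optional named probability vector over the 61 sense
#'   codons; defaults to uniform usage.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       cds_codon_range = c(150, 450),
                       read_depth = 1000,
                       length_weights = c(`28` = 0.08, `29` = 0.17,
                                          `30` = 0.30, `31` = 0.20,
                                          `32` = 0.15, `33` = 0.10),
                       true_offsets = default_offsets(),
                       dwell_multipliers = numeric(0),
                       noise_frac_offtarget = 0,
                       seed = 1L,
                       utr_len = c(30L, 30L),
                       expression_sdlog = 0.75,
                       start_peak = 3,
                       codon_usage = NULL) {
  cfg <- list(n_genes = as.integer(n_genes),
              cds_codon_range = as.integer(cds_codon_range),
              read_depth = read_depth,
              length_weights = length_weights,
              true_offsets = true_offsets,
              dwell_multipliers = dwell_multipliers,
              noise_frac_offtarget = noise_frac_offtarget,
              seed = as.integer(seed),
              utr_len = as.integer(utr_len),
              expression_sdlog = expression_sdlog,
              start_peak = start_peak,
              codon_usage = codon_usage)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default 5'-to-P-site offsets per read length
#'
#' 12 nt for lengths 26--31 and 13 nt for 32--36, the field convention for
#' 80S footprints; fully overridable in [sim_config()].
#' @return named integer vector, length -> offset (nt).
#' @export
default_offsets <- function() {
  setNames(c(rep(12L, 6), rep(13L, 5)), as.character(26:36))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (length(cfg$cds_codon_range) != 2L ||
      cfg$cds_codon_range[1] > cfg$cds_codon_range[2] ||
      cfg$cds_codon_range[1] < 2L) {
    stop("cds_codon_range infeasible", call. = FALSE)
  }
  if (cfg$cds_codon_range[1] < 20L) {
    stop("cds_codon_range lower bound must be >= 20 ",
         "(room for excluded edge codons)", call. = FALSE)
  }
  lw <- cfg$length_weights
  if (is.null(names(lw)) || abs(sum(lw) - 1) > 1e-9 || any(lw < 0)) {
    stop("length_weights must be named, non-negative and sum to 1",
         call. = FALSE)
  }
  lens <- as.integer(names(lw))
  if (any(lens < 26L | lens > 36L)) {
    stop("length_weights lengths must lie in [26, 36]", call. = FALSE)
  }
  if (!all(names(lw) %in% names(cfg$true_offsets))) {
    stop("true_offsets must cover every length in length_weights",
         call. = FALSE)
  }
  dm <- cfg$dwell_multipliers
  if (length(dm)) {
    if (any(dm <= 0)) stop("all dwell_multipliers must be > 0", call. = FALSE)
    bad <- setdiff(names(dm), sense_codons())
    if (length(bad)) {
      stop("dwell_multiplier keys must be sense codons; offending: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (cfg$noise_frac_offtarget < 0 || cfg$noise_frac_offtarget >= 1) {
    stop("noise_frac_offtarget must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(cfg$codon_usage)) {
    cu <- cfg$codon_usage
    if (!setequal(names(cu), sense_codons()) || abs(sum(cu) - 1) > 1e-9) {
      stop("codon_usage must be a probability vector over the 61 sense codons",
           call. = FALSE)
    }
  }
  if (cfg$start_peak <= 0) stop("start_peak must be > 0", call. = FALSE)
  cfg
}
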