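# ribopause

Codon-resolution analysis of translational repression for a two-condition
(wild-type vs mutant) design, built for the situation where an amino-acid
deficiency is suspected of slowing elongation at specific codons and
depressing translation genome-wide. It is aimed at people analysing
ribosome profiling (Ribo-seq) together with RNA-seq, polysome profiles
and metabolite panels — and at anyone who wants those estimators
exercised against a generator with known ground truth.

## What it computes

**Footprint geometry.** For each read length *L*, the 5′→P-site offset is
inferred as the arg-max of the start-codon metagene within 10–15 nt;
reads of 29–33 nt whose P-site frame `(five_prime + offset − cds_start) mod 3`
is 0 are kept for analysis.

**Codon pausing.** With interior codon counts *x<sub>i</sub>* of a gene
(first 15 / last 5 codons excluded, genes with > 10 reads only), the
pausing score of codon *c* is the mean of *x<sub>i</sub>* / (gene mean)
over all interior positions encoding *c*, across genes; > 1 means slow
decoding. Between conditions, per-codon score ratios are centred on their
median (most codons are assumed unaffected), so an injected *k*-fold
dwell change is recovered as *k* at the A-site and ≈ 1 at the P/E sites.

**Translation efficiency.** TE = normalized RPF / normalized RNA
(median-of-ratios size factors over the combined matrix). Differential TE
is the per-gene negative-binomial likelihood-ratio test of the
`condition × assay` interaction (`~ condition + assay + condition:assay`
vs the additive model), dispersion by method-of-moments with
trend shrinkage; a gene is a DTEG when |FC<sub>TE</sub>| ≥ 1.5 and
BH-adjusted p < 0.05. Genes are also placed in the nine-quadrant
transcriptome/translatome grid (S1 = mRNA-down/RPF-up … S5 = centre …
S9 = mRNA-up/RPF-down, |FC| ≥ 1.5 per axis), and TE distributions are
compared by eCDF + two-sample Kolmogorov–Smirnov.

**Polysome profiles.** Traces are segmented into 40S / 60S / monosome /
polysome peaks; P/M is the ratio of trapezoidal baseline-subtracted
areas. Per-fraction transcript values are reported as percent of input.

**Metabolite screen.** Two-component PLS-DA (NIPALS, log2 + autoscaling)
gives VIP scores with mean(VIP²) = 1; a metabolite is differential when
VIP ≥ 1 and its raw-mean fold change is ≥ 2 or ≤ 0.5.

**Synthetic data.** `simulate_transcriptome()`, `simulate_footprints()`
(A-site-anchored dwell model with per-length offsets and 3-nt
periodicity), `simulate_count_experiment()` (NB counts with condition and
TE effects), `simulate_polysome_trace()` (Gaussian peaks with known
areas) and `simulate_metabolome()` (log-normal with flagged
differentials) generate every input with recorded truth; `make_demo()`
writes a complete WT-vs-mutant dataset to disk.

## Worked example

Inject a 2× dwell on the six serine codons and recover it from raw
footprints:

```r
library(ribopause)

ser2 <- setNames(rep(2, 6), c("TCT","TCC","TCA","TCG","AGT","AGC"))
cfg_wt  <- sim_config(n_genes = 10, read_depth = 2e4, seed = 1)
cfg_mut <- sim_config(n_genes = 10, read_depth = 2e4, seed = 1,
                      dwell_multipliers = ser2)
tx <- simulate_transcriptome(cfg_wt)

score <- function(cfg, seed) {
  fp  <- simulate_footprints(tx, cfg, seed = seed)
  off <- detect_psite_offsets(fp$alignments, tx)
  fl  <- filter_inframe(fp$alignments, off, tx)
  pausing_scores(codon_occupancy(fl, off, tx, site = "A"), tx)
}
cmp <- pausing_comparison(score(cfg_mut, seed = 3), score(cfg_wt, seed = 2))
aggregate(centered_ratio ~ is_serine, cmp, mean)
#> retained 183780/199569 reads (92.1%) in frame 0, lengths 29-33
#> retained 183654/199598 reads (92.0%) in frame 0, lengths 29-33
#>   is_serine centered_ratio
#> 1     FALSE       1.001581
#> 2      TRUE       1.959254
```

The six serine codons come back at ≈ 2.0, every other codon at ≈ 1.0 —
the injected elongation defect, read off from simulated reads alone.

## Analysis workflow

The `analysis/` scripts run the full study on the packaged synthetic
demo, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # demo dataset + ground truth
Rscript analysis/02_offsets_filtering.R # lengths, offsets, periodicity
Rscript analysis/03_pausing.R           # A/P/E pausing comparison
Rscript analysis/04_te_quadrants.R      # DTEGs, TE eCDF, nine quadrants
Rscript analysis/05_polysome.R          # P/M ratios, fraction example
Rscript analysis/06_metabolites.R       # VIP + FC screen vs truth
```

Each script prints what it found (e.g. `03` reports the serine A-site
ratio with P/E unaffected; `05` reports the WT and mutant P/M ratios
against their true areas).

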