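---
title: "Quantifying translational repression at codon resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translational repression at codon resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

# Scope and model

`ribopause` quantifies translational repression in a two-condition
(wild-type versus mutant) design from four complementary readouts:

1. **Ribosome footprints** (Ribo-seq) at codon resolution — where on each
   mRNA ribosomes sit, and whether specific codons (here: the six serine
   codons) are decoded more slowly in the mutant;
2. **Paired RNA/RPF counts** — whether per-gene translation efficiency
   (TE = footprint abundance / mRNA abundance) changes between conditions;
3. **Polysome absorbance profiles** — the bulk polysome-to-monosome (P/M)
   ratio as a global engagement measure;
4. **Metabolite intensity tables** — which metabolites discriminate the
   two genotypes under the standard VIP >= 1 and FC >= 2 (or <= 0.5) rule.

Every stage is exercised end to end on synthetic data whose generating
parameters are recorded, so each estimate can be compared with its own
ground truth.

# The footprint generator

A transcript is a 5' UTR (30 nt), a CDS that starts ATG and ends in a
single stop, and a 3' UTR (30 nt). Internal codons are drawn i.i.d. from a
configurable codon usage (uniform over the 61 sense codons by default).
Footprints are **A-site anchored**: a read whose A-site covers codon $c$
of gene $g$ is emitted with probability proportional to
$\mathrm{expression}_g \times \mathrm{dwell}(c)$. This is the simplest
generative model in which slow decoding at a codon (a dwell multiplier
$k > 1$) raises A-site occupancy there by a factor $k$, while P- and
E-site signals arise only through codon adjacency — exactly the
asymmetry the A-site/P-site/E-site comparison is meant to detect.

Given a sampled A-site codon and a read length $L$ drawn from
`length_weights`, the 5' end is placed at
$\text{A-site start} - (\mathrm{offset}(L) + 3)$ nt, so every signal read
is in frame 0 under the true offsets. Defaults: lengths 28--33 nt peaking
at 30 nt (the 80S monosome footprint mode in plants), offsets 12 nt for
lengths up to 31 nt and 13 nt above — the field's convention; both fully
overridable. A `noise_frac_offtarget` fraction of reads is placed
uniformly at random, giving the out-of-frame background used to test the
periodicity and filtering stages.

Two deliberate additions beyond the minimal dwell model:

* **Initiation pile-up** (`start_peak`, default 3x at the first A-site
  codon). Real start-codon metagenes are dominated by the initiation
  peak; without it, the metagene arg-max cannot distinguish offsets that
  are congruent modulo 3 (e.g. 13 nt versus 10 nt for 32-mers) because
  successive codons pile at 3-nt spacing. The pile-up sits inside the
  excluded edge region, so pausing scores never see it.
* **Per-gene expression** is drawn once per transcriptome (log-normal,
  mean 1, `expression_sdlog = 0.75`, a moderate spread typical of
  moderately expressed mRNA populations) and shared by all conditions,
  so condition contrasts reflect dwell and not expression resampling.

What the generator does **not** emulate: sequencing errors, ligation/
nuclease sequence biases, uneven gene-body coverage, multi-mapping, or
genome-space splicing. Passing tests therefore demonstrate correctness of
the estimators under the stated stochastic model, not robustness to
protocol artefacts of real libraries.

# Offsets, frames and filtering

`detect_psite_offsets()` builds, per read length, the histogram of 5'
ends relative to annotated start codons and returns minus the arg-max
position, searched within 10--15 nt. The window spans one codon either
side of the canonical 12--13 nt and prevents captures one codon off; ties
break deterministically toward the smaller offset and are logged. Lengths
with fewer than `min_support = 500` reads are omitted — below that the
arg-max becomes noise-driven. Whether offsets should be per-length or
global is exposed rather than hard-coded: the table is per-length, and a
constant table can be supplied through `offset_table()`.

`filter_inframe()` retains reads of 29--33 nt whose inferred P-site falls
in frame 0. The filtered set is a subset of its input and the filter is
idempotent; downstream counting uses only these reads.

Coordinates are 0-based half-open everywhere inside the package; 1-based
inclusive coordinates appear only in the on-disk CDS table, which is the
convention annotation formats use.

# Pausing scores

For each gene with **strictly more than** `min_reads = 10` reads on its
interior codons, each interior codon's count is divided by the gene's
mean count per interior codon ("normalized density"). The pausing score
of a codon is the mean normalized density over all interior positions
encoding it, across genes. The first 15 and last 5 codons of each CDS are
excluded (initiation and termination piles); both the exclusion and the
threshold are configurable. A pooled variant (total counts over total
expectation) is available behind `method = "pooled"` for sensitivity
analysis; the two agree under uniform dwell.

**Compositionality and the centered ratio.** Because densities are
normalized to the gene mean, the 61 scores are compositional: raising
serine dwell by $k$ multiplies serine scores by
$k/(1 + f_\mathrm{Ser}(k-1))$ and *all other* codons by
$1/(1 + f_\mathrm{Ser}(k-1))$, where $f_\mathrm{Ser}$ is the serine codon
frequency. A between-condition score ratio is therefore identifiable only
up to a global factor. `pausing_comparison()` resolves this the same way
median-of-ratios normalization resolves sequencing depth: assuming most
codons are unaffected, it rescales ratios by their median
(`centered_ratio`), after which an injected $k$-fold dwell change reads
off directly as $k$ and unaffected codons sit at 1. Raw ratios are kept
alongside for inspection.

# Differential translation efficiency

Counting is per gene (P-site-assigned footprints for RPF libraries).
Normalization is median-of-ratios over the **combined** RNA + RPF matrix,
scaled to geometric mean 1; TE is the ratio of normalized mean RPF to
normalized mean RNA per condition.

The differential test fits, per gene, a negative-binomial GLM (log link,
log size factors as offsets) under
`~ condition + assay + condition:assay` and its additive reduction, and
refers twice the log-likelihood difference to $\chi^2_1$ — the
interaction term is precisely the TE change. Dispersion is estimated per
gene by method of moments within design cells (so real effects do not
inflate it), then shrunk toward a loess mean--dispersion trend with a
prior weight of 20 pseudo-replicates and floored at $10^{-8}$. The
shrinkage is what keeps the test calibrated at $n = 3$: the raw
method-of-moments estimate is far too noisy at that depth, and plugging
it in unshrunk makes the LRT anticonservative. As dispersion approaches
zero the fit coincides with a Poisson GLM, which the tests verify against
`stats::glm` directly.

Fold changes reported alongside the test are plug-in ratios of
normalized condition means, so the identity
$\log_2\mathrm{FC}_{TE} = \log_2\mathrm{FC}_{RPF} -
\log_2\mathrm{FC}_{mRNA}$ holds exactly. A gene is a DTEG when
$|\mathrm{FC}_{TE}| \ge 1.5$ **and** BH-adjusted $p < 0.05$; the
fold-change gate is applied on the linear scale, so FC 1.49 is never
called regardless of significance.

**Identifiability caveat.** Shared normalization absorbs any
transcriptome-wide multiplicative TE shift: a truly uniform 30% reduction
is indistinguishable from an RPF depth difference. TE effects are
identifiable *relative to unaffected genes*, which is why the synthetic
repression pattern places the 30% reduction in 40% of genes and why the
tests assert affected-versus-background contrasts. The TE eCDF comparison
(`te_ecdf()`, two-sample Kolmogorov--Smirnov on log2 TE) operates on the
TE vectors after this normalization and should be read the same way.

The nine-quadrant classification uses fold-change state only
(down / unchanged / up on each of the mRNA and RPF axes, threshold
$|\mathrm{FC}| \ge 1.5$ with the boundary counting as changed): S1 is
mRNA-down/RPF-up, S5 the double-unchanged centre, S9 mRNA-up/RPF-down.
Requiring significance as well is a stricter variant the caller can apply
by intersecting with `padj`; the classification itself stays descriptive.
Genes with an undefined fold change (a zero condition mean) get class NA
rather than being silently binned.

# Polysome profiles

Traces are segmented by local maxima on a lightly smoothed signal
(running mean over 1% of grid points — extrema location only; areas are
always integrated on the raw trace), with maxima closer than 2% of the
span merged in favour of the taller. The baseline is the trace's 5th
percentile, a robust stand-in for the flat inter-peak absorbance floor;
it is configurable because gradient hardware differs. With the canonical
four peaks, the monosome region spans the valleys around the third peak
and the polysome region runs from the monosome/polysome valley to the
trace end. P/M is the ratio of trapezoidal baseline-subtracted areas —
area-under-curve semantics, no peak-model fitting, matching how such
traces are quantified from image analysis in practice. On noise-free
synthetic traces with well-separated peaks the ratio matches the analytic
value within 1%; strongly overlapping peaks (centers closer than one
width) are flagged at simulation time because no boundary placement is
then unambiguous.

Per-transcript distributions across gradient fractions are reported as
percent of the input sample, with monosome and polysome group sums.

# Metabolite screen

Intensities are log2-transformed and autoscaled, and a two-component
PLS-DA is fitted by NIPALS against the group indicator. VIP for
metabolite $j$ is
$\sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$
with unit-norm weight vectors, so mean(VIP²) = 1 algebraically — the
tests assert this identity on every fitted model and cross-check the
values against an independent PLS-DA implementation. Fold change is
computed on raw (unlogged) group means, matching the linear-scale
FC >= 2 / <= 0.5 phrasing of the screening rule; zeros are imputed to
half the smallest observed intensity before averaging. A metabolite is
differential only when both gates pass. OPLS-DA would yield slightly
different VIP values; plain PLS-DA with unit-variance scaling was chosen
as the most reproducible default, and the cutoff sensitivity to that
choice is confined to metabolites with VIP near 1.

# Numerical choices and degenerate inputs

* Offset ties: smaller offset, logged. Lengths outside 26--36 nt are
  never assigned offsets.
* Reads whose A/P/E-site codon falls outside the CDS are discarded and
  counted, not clamped.
* Genes whose interior occupancy is zero after edge exclusion are
  skipped with a message; a run in which no gene survives is an error,
  not an empty result.
* `size_factors()` requires at least one gene with nonzero counts in all
  samples; all-zero genes are dropped before normalization.
* Non-converged GLM fits yield `p = NA` and are flagged, never silently
  dropped.
* PLS-DA reduces the component count to the data rank with a warning;
  zero-variance metabolites are dropped with a message.
* All simulators accept a seed and are byte-reproducible given it; the
  session RNG state is saved and restored around every draw.

# Problem sizes

The shipped demonstration uses a 500-gene transcriptome at 2,000
footprints per gene and condition, a 2,000-gene count experiment at
$n = 3$ with dispersion 0.05, 500 metabolites with 20 differentials, and
2,001-point traces. The test-suite and verification runs use the same
conditions at 10--20 genes and $10^5$ footprints per gene where codon
statistics are the target (about $10^6$ reads per condition, which puts
the Monte-Carlo standard error of a codon score, roughly
$\sqrt{61/N}$, near 0.008). These sizes were chosen so every stage's
estimate sits well inside its tolerance under the generating model.

# Known limitations

* The pausing score is reported per codon, not per codon pair; dipeptide
  and collision (disome) effects are out of scope.
* The NB machinery is intentionally compact: no Cox--Reid adjustment, no
  outlier refitting. It is calibrated at the simulated depths, not a
  drop-in replacement for mature DE frameworks on real data.
* Metagene offset detection presumes annotated start codons; transcripts
  without one contribute nothing to offset inference.
* The monosome/polysome boundary on real gradients with shoulder peaks
  (e.g. a 60S shoulder on the 80S peak) may need the user-supplied
  landmark override rather than automatic segmentation.
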