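---
title: "ssdripr: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssdripr: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the statistical model
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## The assay and the analysis problem

ssDRIP-seq immunoprecipitates RNA:DNA hybrids with the S9.6 antibody and
builds libraries that preserve the identity of the DNA strand carrying the
hybrid. Two controls structure the whole analysis:

* **RNase H treatment** degrades RNA inside hybrids, so RNase-H-treated
  libraries estimate everything in the signal that is *not* an R-loop
  (chromatin accessibility, mappability, library artifacts). The total
  R-loop call tests DRIP coverage against this control.
* **The opposite strand** of the same library is the natural control for
  strand specificity: a *stranded* R-loop shows significant enrichment of
  one strand over the other, an *unstranded* R-loop (hybrids on both
  strands) does not.

All coordinates in the package are 0-based half-open (BED convention)
internally; 1-based coordinates appear only in display. Fragments — not
reads — are the unit of input: paired ends are assumed merged upstream, and
"coverage" everywhere means fragment-bases per bin, which makes coverage
conservation exactly testable (the binned total equals the clipped fragment
lengths).

## The window caller

The caller scores sliding windows of width $w$ (default 200 bp, step
$w/2$) on each chromosome. The observed statistic is the window's treatment
fragment count, estimated as fragment-bases in the window divided by the
mean treatment fragment length and rounded; this keeps the Poisson unit
"fragments in window" even when fragments straddle window edges.

The background is the *local lambda*:

$$\lambda = \max(\lambda_{bg}, \lambda_{1k}, \lambda_{5k}, \lambda_{10k})
  + \text{pseudocount}$$

where $\lambda_L$ converts control fragment-bases in a window of size $L$
centered on the test window's midpoint into expected treatment-scale
fragments, $\text{bases}/\bar\ell \cdot (w/L) \cdot r$, with $\bar\ell$ the
mean fragment length and $r = N_t/N_c$ the treatment/control depth ratio;
$\lambda_{bg}$ is the genome-wide control rate. Taking the maximum over
nested windows guards against locally elevated background being mistaken
for enrichment. The pseudocount (default 0.5) keeps the test defined where
the control is empty.

The p-value is the Poisson upper tail $P(X \ge t)$, computed in log space
(`stats::ppois(lower.tail = FALSE)`); q-values are Benjamini–Hochberg over
*all* tested windows. Narrow peaks link windows at $q \le 0.05$ across gaps
$\le w$; broad peaks link windows at $q \le 0.10$ across gaps $\le 4w$;
touching windows always merge, peaks shorter than $w$ are dropped, and each
peak carries its minimum window q. Numerical detail: local windows are
evaluated on the step-size bin grid; with the default step (100 bp) every
local half-window (500/2500/5000 bp) is grid-aligned, so the binned sums
equal the exact interval sums.

Two deliberate departures from read-pileup callers: windows replace the
shifted-read pileup model (the scientific content here is the control
design, not pileup heuristics, and windows make every number auditable),
and the control is always rescaled to treatment depth by $r$ regardless of
direction (scaling larger-to-smaller only is a pileup-caller convention the
window model does not need).

## Consensus and classification

Per-replicate peaks qualify for consensus support at $q \le 0.001$ in either
the narrow or broad call. Qualifying peaks from all replicates are
union-merged; a merged region is retained when qualifying peaks from at
least 3 distinct replicates overlap it by $\ge$ 1 bp. The 1 bp overlap rule
is the convention of the standard interval toolkits; merging is union (not
intersection) because the consensus is a presence filter followed by a
merge.

Strand enrichment re-runs the same caller per DRIP replicate with the plus
strand as treatment and the minus strand as control, and vice versa; the
same $(\ge 3, q \le 0.001)$ consensus filter is applied per strand. A
consensus R-loop is **stranded** when exactly one strand's enrichment
passes; when *both* strands pass independently the loop is classified
**unstranded** — "strand-specific" must mean one strand dominates, and a
region enriched on both strands against each other is the signature of
hybrids on both strands. RNase-H samples never enter strand classification.
Whether strand peaks should be consensus-filtered per sample or pooled
first was an open choice; per-sample consensus was adopted for symmetry
with the total call.

## Annotation

Feature windows are oriented: promoter/TSS is $[-2.5\,\text{kb},
+0.5\,\text{kb}]$ around the TSS and downstream is $[-0.5\,\text{kb},
+2.5\,\text{kb}]$ around the gene end, both in gene orientation and clipped
at chromosome boundaries. Overlaps resolve by the fixed priority
promoter > exon > intron > downstream > pseudogene > intergenic, giving a
partition of the genome; without an exon table, gene bodies are labelled
intron. Each R-loop gets the single label at its midpoint, so observed
counts sum to the class size and observed/expected ratios are comparable
across features. Expected counts are analytic (class size × genome fraction
of the feature) and the CI comes from resampling midpoints uniformly —
no GC or mappability correction is attempted.

Expression strata are tertiles over genes with expression > 1 (CPM-like
floor); the low/mid/high cut-offs are not externally defined, so tertiles
are the neutral choice. Gene overlap flags use the gene span extended by
the promoter and downstream windows (equivalently ±2.5 kb).

## Metaprofiles

`signal_matrix()` centers a window of $\pm$`flank` (default 2.5 kb, 100
bins) on each R-loop midpoint — consensus regions have no summit after
merging, so the midpoint is the only defensible center — and computes
length-weighted means of the piecewise-constant track per bin via an exact
cumulative integral. Windows running past chromosome ends are zero-padded
and still counted, keeping `n_used` stable. No per-row normalization is
applied: profiles are in the track's own units. Flank and bin count are
parameters because the plotted window size is a presentation choice, not a
modelled quantity.

## PCA QC

The QC mirrors the replicate check of the assay: coverage in 500 bp bins,
both strands concatenated (chromosomes in genome order, plus block then
minus block), each bin standardized to zero mean and unit variance across
samples (constant bins dropped; a matrix with no varying bin is an error),
PCA by SVD with samples as observations. "Scaled" is interpreted as
per-feature standardization — the default of R's `scale()` — since no
further detail is available. The reported flag is sign-invariant: DRIP and
RNase-H samples separate when their PC1 values form disjoint ranges.
Whether the original analysis concatenated strands or collapsed them is
unknown; concatenation was adopted as it preserves the strand structure the
assay exists to measure.

## Fisher set enrichment

`build_table()` forms the 2×2 table of two id sets over a stated universe;
`fisher_enrichment()` computes the hypergeometric upper tail (one-sided,
"greater", the default — the question is enrichment) in log space, exact
and finite for universes up to $10^6$. The worked example in the acceptance
suite reconstructs the only printed counts available — 15 of 30
two-assay-supported interactors among 67 high-confidence R-loop proteins in
a universe of 1534 retina-expressed RBPs, table (15, 15, 52, 1452) — which
yields $p = 7.5\times10^{-14}$. The published headline value is
$2\times10^{-13}$; no table assembled from the printed counts reproduces it
at one significant figure (the nearest, with an overlap of 14, gives
$2.9\times10^{-13}$). The corresponding acceptance check is therefore
expected to fail and is kept failing rather than loosened: the
reconstruction, not the test, is the uncertain quantity.

## The synthetic generator: what it emulates

`simulate_cohort()` generates the stated world: 4 DRIP replicates + 4
RNase-H controls over a 5 Mb two-chromosome genome, 200 non-overlapping
genes with log-normal lengths (median ~8 kb — desk-scale, about half the
mammalian median so that a 5 Mb genome holds a realistic gene density) and
zero-inflated log-normal expression; 50 stranded + 50 unstranded planted
R-loops of 0.5–2 kb; fragments of Normal(250, 50) bp truncated to
[50, 500]; background 0.02 fragments/bp/strand, i.e. ~2×10⁵ fragments per
sample (the real depth is unstated; this desk-scale default is flagged as
arbitrary). Background fragments are uniform Poisson per strand and
identical in law between DRIP and RNase-H samples; inside a planted loop,
DRIP samples receive extra fragments with expectation
$(\text{fold}-1)\times$ the two-strand background, all on the truth strand
for stranded loops and split 50/50 for unstranded loops. Consequently the
*combined-strand* in-loop coverage is fold × background for both classes —
matching the observation that DRIP coverage is similar for stranded and
unstranded R-loops — while the strand asymmetry differs sharply between
classes, which is exactly what the classifier consumes. Sample $i$ uses
seed $+ i\cdot10007$, making replicates reproducible yet independent.

The generator does **not** emulate: sequence (no FASTA/FASTQ, no GC or
mappability structure), PCR duplicates, aligner artifacts, fragment-length
differences between conditions, biological replicate variability beyond
Poisson sampling, or template/non-template strand biology (the truth strand
*is* defined as the enriched strand). A green recovery test therefore
establishes that the caller/classifier correctly inverts the stated
generative model at realistic depth — not that it is robust to the
non-uniform backgrounds of real genomes, which is precisely what the
RNase-H and opposite-strand controls are designed to absorb.

Placement biases (`tss_stranded_tts_unstranded`, `long_genes`) exist to
test the annotation stages against planted structure: stranded loops near
TSSs ([−2 kb, +2 kb]), unstranded loops downstream of gene ends ([0,
+5 kb] past the TTS), or loops preferentially on the longest gene tertile.

## Degenerate inputs and numerical choices

* Empty treatment: warning and an empty peak set. Empty control: allowed
  only with a positive pseudocount.
* Strand "." in fragment input is an error — the assay is strand-resolved
  by construction.
* Genome shorter than one window: error.
* Zero-variance coverage bins are dropped before PCA; an all-constant
  matrix is an error ("degenerate matrix").
* BH is `stats::p.adjust(method = "BH")`; Poisson and hypergeometric tails
  are the log-space `stats` implementations; each is contract-tested
  against an independent oracle (direct term summation, naive $O(m^2)$
  step-up, full enumeration) rather than re-derived.
* Window linking treats touching windows (gap 0) as one peak, always.

## Known limitations

* The published genomic counts (4,677 R-loops; 3,352 unstranded; 1,328
  stranded) depend on the deposited mouse retina data and genome and are
  not reproducible at desk scale; validation is property-based
  (recovery, FDR, calibration, determinism) on synthetic cohorts.
* The caller has no fragment-size estimation, duplicate modelling or
  control-free mode; inputs are assumed filtered.
* Observed/expected enrichment assumes uniform placement as the null;
  regions of low mappability will inflate intergenic expectation on real
  data.
* The two-sided Fisher option sums point probabilities with the customary
  $1+10^{-7}$ tolerance factor and can differ from other conventions in
  ties.
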