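---
title: "Cross-platform transcriptome concordance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform transcriptome concordance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordia)
```

## The problem

Two-channel DNA microarrays and RNA sequencing both quantify transcript
abundance, but they rest on different physics (competitive hybridization of
two dye-labelled cDNA pools vs. counting of sequenced fragments) and
different normalization conventions. When the same two-state contrast — here
a proliferative ("PRO") versus serum-starved quiescent ("QUI") fibroblast
design — is measured on both platforms, how well do the per-probe fold
changes (FC, always QUI/PRO) agree? `concordia` implements the complete
analysis chain needed to answer that question on any dataset of this shape,
together with a synthetic-data generator so that every stage can be verified
against a known ground truth.

The chain is: two-channel array processing (crosstalk correction, MA-LOWESS
normalization, fold changes, geometric-mean combination across replicate
arrays, artificial dye swapping); RNA-seq feature-probe quantification (RPKM
with a pseudocount, read-level replicate pooling); a deterministic
sequence-plus-Ensembl-ID mapping between the two probe spaces; a statistical
core (three correlation measures, Fisher's z, a permutation test for top-k
list overlap with an exact hypergeometric oracle, FC-threshold concordance);
and qRT-PCR arbitration via the 2^-ddCT method against a panel of normalizer
genes.

## The synthetic study design

`simulation_config()` fixes the conditions of the emulated study. The
defaults describe a scaled-down but structurally faithful version of a
two-platform fibroblast experiment:

* **Genome and annotation.** 500 transcripts of 200–2000 bp on 3
  chromosomes, embedded in random intergenic spacer; coordinates 1-based
  inclusive, forward strand, alphabet A/C/G/T only (no Ns) so substring
  semantics stay unambiguous. Ten transcripts are splice-like variants
  sharing a leading exon block with another transcript, which is what makes
  multi-candidate probe mapping a real phenomenon rather than an edge case.
* **Array probes.** 600 probes of 70 bp. Most are verbatim substrings of a
  transcript; 10% are decoys (random genome-absent sequence, no IDs — never
  mappable, so unmapped-probe handling is always exercised); 5% are
  point-mutated away from the genome but keep their source transcript's
  Ensembl-style ID, so they can only map through the ID fallback. A few
  exact probes carry a spurious extra ID or no ID at all.
* **Expression.** Baseline log2 abundance is Normal(4, 2) — a deliberately
  heavy-tailed, microarray/RNA-seq-like dynamic range. Exactly
  `n_genes_changed = 100` transcripts change, with random sign and magnitude
  `log2(5) + Exp(1)`, i.e. at least fivefold, the regime in which platform
  agreement is expected to be best. All other transcripts have log2 FC
  exactly 0, which also supplies valid qPCR normalizer genes.
* **Array measurement.** Per channel,
  `intensity = scale * abundance * dye_bias * exp(eps)` with
  `eps ~ N(0, array_noise_sd^2)` (default sd 0.5 on the natural-log scale),
  followed by symmetric crosstalk mixing
  `observed_A = clean_A + alpha * clean_B` (default alpha 0.05) — the
  simplest invertible model of fluorophore leakage, since published
  correction procedures for this chemistry are not specified in enough
  detail to copy. A dye bias of 1.5 on Cy5 gives the LOWESS stage real work.
  Decoy probes receive background-only signal. Dye orientation ("qui-cy5"
  vs. "qui-cy3") is metadata, never an intensity relabeling, so raw files
  stay immutable under artificial dye swaps.
* **RNA-seq measurement.** Expected count proportional to abundance times
  probe length, scaled to the replicate's library size (default 5x10^5
  reads per replicate, four replicates PRO1/PRO2/QUI1/QUI2), drawn
  negative-binomially with dispersion 0.05 (Poisson as dispersion goes to
  0). Counts are simulated per probe, not per read: read alignment is out
  of scope and the analysis begins at per-probe quantities.
* **qPCR.** `CT = 30 - log2(abundance) + N(0, 0.15^2)` cycles, three
  technical replicates per gene and state; a slope of -1 cycles per log2
  unit corresponds to 100% amplification efficiency, matching the
  2^-ddCT assumption used downstream.

No published noise magnitudes exist for either platform in this design, so
the defaults were chosen once to give realistic correlation regimes
(replicate reproducibility high, cross-platform agreement moderate) rather
than to match any particular dataset; they are not tuned afterwards.
Everything is a pure function of `(config, seed)`: identical seeds give
byte-identical outputs, including written FASTA/TSV files.

What the generator does **not** emulate: image-level artefacts and spot
morphology, print-tip or spatial effects, intensity-dependent (curved) dye
bias, GC/length biases of library preparation, splice-isoform read
ambiguity, or dendrimer-labelling chemistry. Passing tests therefore
demonstrate correctness of the computational chain under the stated model,
not robustness to every artefact of real slides and sequencers.

## Numerical and algorithmic choices

**Crosstalk correction** inverts the mixing model exactly:
`clean_A = (obs_A - alpha * obs_B) / (1 - alpha^2)`. `alpha >= 0.5` is
rejected (by policy, well before the algebraic singularity at 1), and
negative unmixed intensities are floored at `1e-6` and flagged rather than
dropped.

**MA-LOWESS** uses `stats::lowess` — Cleveland's tricube-weighted local
regression — with span 0.3 and 3 robustness iterations, interpolated back
onto the observed A values; `M` is recentred by the fitted trend and the
channels are reconstructed holding A fixed (A is preserved to machine
precision). Fewer than 10 retained probes is an error: the curve would be
underdetermined. One property worth stating explicitly: a LOWESS smoother is
*not* a projection, so normalization is not exactly idempotent — a second
application moves log-ratios again, by roughly an order of magnitude less
than the first pass removed. The tests assert exactly that contraction
behaviour rather than a fictitious fixed point.

**RPKM and the compositional constant.** RPKM is
`1e9 * count / (length * total_reads)`, with the library total taken as the
reads assigned to probes (an explicit `total_reads` override exists for
genome-wide totals). A pseudocount of 0.05 is added to the *normalized*
values, per the convention the pipeline follows, before any ratio or log.
Because RPKM divides by the realized per-million total, a genuine shift in
total RNA between states displaces every probe's log2 FC by the same
constant `log2(S_pro / S_qui)` with `S = sum(abundance x length)`. This is
an intrinsic property of per-million normalization (the reason TMM and
median-ratio normalizations exist), not an implementation artefact: in a
noise-free simulation the RNA-seq log2 FCs equal the ground truth *plus*
that closed-form constant, and the test suite verifies exactly this.
Correlation- and rank-based comparisons are unaffected by a global shift.
Replicate pooling sums raw reads and totals and renormalizes — read-level
pooling, not averaging of RPKMs.

**Probe mapping** restricts sequence candidates to feature probes on the
array probe's recorded chromosome, then requires verbatim contiguous
substring containment (70-mers are treated as exact; hybridization makes a
general non-contiguous subsequence reading biologically meaningless).
Reverse-complement matching is on by default — array probes may be antisense
to the reference — with a flag for strict forward-only semantics. Conflict
resolution is fully deterministic: a unique sequence candidate wins; among
several, one sharing an Ensembl ID with the probe is preferred; otherwise
the lexicographically smallest feature-probe id is taken and the assignment
is flagged ambiguous (a reproducible stand-in for an arbitrary pick). With
no sequence candidate the probe's Ensembl IDs are tried in sorted order,
case-sensitively, stopping at the first hit. The implementation is verified
against a naive all-pairs brute-force oracle on 100x100 designs containing
decoys, splice-variant multi-matches and ID-fallback cases, and is invariant
to input row order.

**Top-k overlap test.** Lists are ranked by FC with lexicographic
(C-locale) tie-breaks on probe id. The null draws two independent k-subsets
of the mapped universe without replacement, 10,000 trials by default, and
the p-value is the *proportion* of trials with overlap at or above the
observed one — so an observed overlap of 0 always gives p = 1. The exact
null is Hypergeometric(N, k, k); `overlap_exact_pvalue()` computes the tail
with log-binomials and doubles as the oracle for the Monte-Carlo path (the
two are compared across a grid in the tests, and the package's closed form
is itself cross-checked against `stats::phyper`). The universe defaults to
the unique mapped feature probes; the array-side fold changes are projected
into that space by geometric-mean aggregation over the array probes mapped
to each feature probe, so both lists live in one id space.

**Correlations and their comparison.** Three measures everywhere: Pearson
on raw values, Pearson on log2 values, Spearman with average ranks. Values
must be strictly positive (the log must apply) and zero-variance input is an
error, not an NA. Fisher's z comparison uses the independent-samples form
`z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided
normal p-value; when the two correlations share a vector (both platforms
against the same qPCR panel) this form ignores that dependence, which is
stated here rather than silently corrected. No multiple-testing adjustment
is applied anywhere in the pipeline.

**qPCR.** Technical replicates are averaged at the CT stage, per gene and
state, before any difference is taken. The per-normalizer fold change is
`2^-ddCT`; the per-gene value is the *arithmetic* mean over the normalizer
panel (the geometric mean — averaging on the log scale — is available as an
option, since that is the other defensible convention). A gene measured by
several array probes gets the geometric mean of probe FCs. Platform
closeness is adjudicated on the log2 scale with ties declared below 1e-12.

## Reporting conventions

Mapping summaries report the mapped fraction to the nearest integer percent
and the used-feature-probe fraction to one decimal; threshold concordance
reports one decimal. These match how such tables are conventionally printed
and are applied at the reporting boundary only — internal computation keeps
full precision.

## Problem sizes

The packaged demonstration configuration (`default_run_config()`) uses 500
transcripts, 600 array probes across four arrays (two dye-swapped), four
RNA-seq replicates of 5x10^5 expected reads, and 20 qPCR genes with four
normalizers; a full run completes in well under a minute on one CPU. The
test suite works at 50–150 transcripts with 10^4 permutation trials and a
10-seed noise sweep, sizes chosen so the whole suite runs in a few tens of
seconds while keeping Monte-Carlo bounds sharp enough to detect real
defects.

## Worked example

```{r example, eval = FALSE}
cfg_path <- tempfile(fileext = ".cfg")
default_run_config(cfg_path, seed = 1L)
res <- run_full_analysis(cfg_path, outdir = tempfile("run-"))

res$mapping_summary$percent_mapped     # 90: all non-decoy probes map
res$tables$table3                      # cross-platform correlations
res$tables$table4                      # top-k overlaps with empirical p
res$qpcr$n_rnaseq_closer               # genes where RNA-seq is closer to qPCR
```

## Known limitations

* The crosstalk model is single-coefficient and symmetric; scanner-specific
  asymmetric leakage would need a 2x2 mixing matrix.
* RPKM is the only count normalization offered, by design; the pipeline
  characterizes that method rather than replacing it with TMM/median-ratio
  alternatives.
* The Fisher-z comparison assumes independent samples (see above).
* Amplification-efficiency correction for qPCR (slopes other than -1 per
  log2 unit are simulated but not efficiency-corrected downstream) is out
  of scope.
* Real-data ingestion is limited to the documented plain-text formats
  (FASTA, TSV); platform-native image or scanner files are not parsed.
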