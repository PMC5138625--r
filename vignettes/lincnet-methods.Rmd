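---
title: "lincnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincnet)
```

# What the package computes

`lincnet` implements the downstream half of a lincRNA discovery study: it
starts from a merged transcript catalog (GTF), a reference annotation (GTF),
transcript sequences (FASTA) and FPKM expression panels, and produces a
lincRNA call set, tissue-specificity scores, neighbour-gene cis-correlation
summaries, a signed weighted co-expression network with stage-specific
modules and kME-ranked hub genes, and Fisher-exact term enrichment. A
synthetic-data generator plants ground truth for all of these so the whole
chain is testable without external downloads.

# The lincRNA funnel

Candidate lincRNAs are filtered in five fixed stages:

1. **Known-transcript removal.** A catalog transcript is "known" when its
   intron chain is identical to a reference transcript on the same
   chromosome and strand; terminal-exon extensions do not rescue a
   transcript from this rule. A transcript that is not an intron-chain match
   but shares at least one exonic base with a reference exon *on the same
   strand* is removed as an exonic overlap. Antisense overlap is deliberately
   not treated as "known": such transcripts survive this stage and are
   instead caught by the strand-agnostic distance rule below. For single-exon
   transcripts intron chains are degenerate, so a single-exon transcript is
   "known" only when it exactly matches a single-exon reference transcript.
2. **Multi-exon rule:** spliced structure with at least 2 exons. The source
   material is internally inconsistent here ("at least 2" in one place,
   "more than 2" in another); we follow "at least 2", consistent with the
   stated removal of unspliced transcripts and with reported mean exon
   counts near 3.
3. **Minimum length:** spliced length (sum of exon widths, not genomic span)
   of at least 200 nt.
4. **Minimum distance:** the transcript's genomic span must lie at least
   500 bp from every annotated gene locus, strand-agnostic, where a gene
   locus is the union span of its transcripts. Locus-level (not exon-level)
   distance is used because the rule is about intergenic placement.
5. **Coding potential:** transcripts with coding probability at or above the
   decision threshold (default 0.5) are removed.

The order is part of the contract: each transcript's verdict records the
first failing stage, and the per-stage input/passed/removed counts satisfy
`input = passed + removed` and `passed(k) = input(k+1)` by construction
(enforced by the `FilterReport` validity method).

# The coding-potential model

External coding-potential callers are replaced by an internal scorer over
the classic feature set:

* **Longest ORF** (nt): longest ATG-initiated, stop-terminated open frame on
  the three sense frames, stop codon included; ORFs containing N are
  skipped.
* **ORF coverage:** ORF length / spliced length.
* **Fickett TESTCODE score:** the published position and composition
  parameter tables and weights, embedded verbatim; position parameters are
  max/(min+1) base counts over the three codon phases.
* **Hexamer usage log-likelihood ratio:** mean per-hexamer
  log(f~coding~/f~noncoding~), with the table trained from user-supplied (or
  simulated) coding/noncoding sets with pseudocounts. Hexamers are counted
  in frame (step 3) inside the longest ORF when one of at least 6 nt exists,
  else by sliding window over the whole sequence.

A logistic regression combines the four features; the fitted model and its
threshold travel with every report. On the synthetic study conditions the
classes are separable nearly perfectly (a design choice — see below), so the
logistic fit saturates; this is expected and harmless for ranking and
thresholding.

# Tissue specificity and cis correlation

Detection breadth counts conditions whose mean FPKM strictly exceeds 0.1.
The specificity score of a feature is `1 - JSdist(p, e_t)` maximized over
conditions `t`, where `p` is the vector of `log10(FPKM + 1)` condition means
normalized to sum 1, `e_t` is the unit vector of condition `t`, and `JSdist`
is the square root of the Jensen-Shannon divergence with base-2 entropy.
Replicates are averaged to condition level first (the source is silent on
replicate handling; averaging is the standard choice). All-zero features are
reported as missing rather than scored 0, so summaries are not diluted by
undetected features.

Neighbour pairs are feature pairs whose gene-body gap is strictly below
10 kb, strand ignored (orientation is reported, not filtered). Pair
correlation is Pearson on `log2(FPKM + 0.05)` across samples. The random
null draws unordered feature pairs uniformly without replacement, excludes
genuine neighbour pairs, and is seeded; the sampling restores the caller's
RNG state. TSS-distance profiles bin pairs strictly below a 4 kb window into
400 nt bins. qPCR quantification uses 2^-ddCt^ with a designated calibrator.

# The co-expression network

Pretreatment drops genes with maximum FPKM below 0.05, keeps the top 75% by
log-scale variance, and transforms to `log2(FPKM + 1)`. The signed adjacency
is `((1 + cor)/2)^beta`; the orchestrated pipeline uses the canonical signed
power beta = 13, and `pickSoftThreshold()` can select the power as the
smallest reaching a scale-free fit R^2 of 0.9. The scale-free index bins
connectivity into 10 equal-width bins and regresses log10(frequency) on
log10(mean k), signing R^2 by the slope; equal-occupancy binning would make
the frequencies constant by construction and the fit meaningless, so the
standard equal-width scheme is used.

The topological overlap is the unsigned weighted TOM,
`t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
`l_ij = sum_u a_iu a_uj`, diagonal 1. Modules are branches of the
average-linkage dendrogram of `1 - TOM` under a static cut at a quantile of
the merge heights, with branches below the minimum size left unassigned.
The default cut quantile is 0.90: on planted-module data the merge-height
distribution is sharply bimodal (within-module merges low, noise joins near
the top), and a cut at the 0.99 quantile would sit above the noise joins and
sweep unstructured genes into the last surviving branches; 0.90 cuts inside
the gap. Both the quantile and the minimum module size (default 30; the
synthetic panel uses 10, matching its 50-gene modules) are configurable.

Module eigengenes are first principal components of the standardized module
expression (unit norm over samples), sign-oriented so the correlation with
the module mean profile is non-negative. Modules whose eigengenes correlate
above 0.7 are merged iteratively, highest pair first, recomputing eigengenes
after every merge; the procedure is a deterministic fixpoint. Stage
association correlates each eigengene with a one-hot stage indicator per
sample; p-values are two-sided Student t with n-2 degrees of freedom, and a
module is stage-specific when r > 0.7 and p < 1e-4 (raw, uncorrected — the
thresholds are conventionally applied to raw p). kME is the correlation of
a gene's profile with a module eigengene; hubs are the top members by kME
(default 100), ranked descending with ties broken by gene id.

# Enrichment

Term enrichment is a one-sided (greater) Fisher exact test — the
hypergeometric tail P(X >= k) — of a module's genes against a background
universe, the preprocessed expressed set by default. Benjamini-Hochberg
adjustment is applied within each term category and can be disabled. No
ontology propagation is performed; the annotation is a flat term-to-gene
table.

# The synthetic study conditions

The generator's defaults define the conditions under which the pipeline is
exercised and scored:

* **Genome and annotation:** 30 multi-exon genes (4-9 exons, 120-400 bp
  exons, 0.5-3 kb introns) on 3 chromosomes, separated by 12-40 kb
  intergenic gaps; a random genome with designed coding sequence written
  into gene exons.
* **Catalog (180 transcripts):** 30 intron-chain copies of reference
  transcripts with extended terminal exons; 30 same-strand exonic-overlap
  novels; 35 true lincRNAs (2-4 exons, >= 200 nt, >= 500 bp from genes,
  noncoding); 30 intergenic coding transcripts (planted ORFs of 300-900 nt
  with codon-usage-biased hexamers); and decoys failing exactly one stage
  each: 20 single-exon, 15 below 200 nt, 20 placed 100-480 bp from a gene.
  Noncoding sequences are uniform random with chance ORFs longer than
  150 nt interrupted by stop codons; this cap, against the 300 nt coding
  floor, makes the planted funnel deterministic so its counts can be checked
  exactly.
* **Tissue panel:** 8 tissues, one library per tissue (mirroring one
  published data set per tissue). 40% of free lincRNAs and 10% of free
  mRNAs are single-tissue specific (high FPKM in one tissue, < 0.1
  elsewhere); 15 lincRNAs are planted as cis neighbours of gene TSSs at
  bimodal anchor distances (about 0.6-0.9 kb and 2.5-3.4 kb) with target
  expression correlation rho = 0.9 on the log2 scale. Because every called
  lincRNA is at least 500 bp from any gene, TSS distances below ~0.5 kb
  cannot occur among surviving pairs in this design.
* **Stage panel:** 6 developmental stages x 2 replicates (replicate counts
  are not specified by the source study; 2 is a deliberate, configurable
  minimum that keeps correlation p-values defined), 4 modules x 50 genes
  plus 100 noise genes. Module genes follow a pulse profile — log2
  expression 6 at the module's stage, 1 elsewhere — plus Gaussian noise of
  sd 0.5; the 10% of genes designated hubs get one fifth of that noise, so
  kME ranks them at the top. Noise genes are independent with sd 1.2.

What the generator does **not** emulate: read-level sampling noise,
alignment and assembly artifacts, batch effects, length-dependent FPKM
biases, overlapping gene structures, or realistic codon usage of any
particular species. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure, not performance on
real libraries.

# Numerical choices and degenerate inputs

* Coordinates are held in `GRanges` (1-based, closed), the Bioconductor
  convention; GTF I/O goes through `rtracklayer`.
* Entropy is base 2 throughout; `JSdist` is the square root of the JS
  divergence, so single-condition expression scores exactly 1.
* Strict inequalities follow the stated rules: detection is FPKM > 0.1,
  neighbour gap < 10 kb, TSS window < 4 kb, merge correlation > 0.7, stage
  rule r > 0.7 and p < 1e-4; the funnel keeps length >= 200 and
  distance >= 500.
* Zero-variance genes abort adjacency construction by name (they must be
  removed in pretreatment); zero-variance pair members are flagged, not
  silently dropped; all-zero specificity features are missing, not 0.
* Problem sizes used by the test suite and acceptance script — a 180
  transcript catalog, 1000 held-out coding/noncoding sequences, 20 seeds
  for module recovery, 100 seeds for the cis ordering — were chosen so each
  check exercises the full code path at desk scale.
* Randomized helpers (`randomPairNull`, all simulators) take explicit seeds
  and restore the caller's RNG state; a fixed configuration reproduces every
  output byte-identically.

# Known limitations

* The coding model is only as good as its training sets; with the synthetic
  generator the classes are nearly separable and the logistic fit saturates.
  For real data, supply realistic coding/noncoding training FASTAs.
* The module detector is a static-cut variant of dendrogram branch cutting;
  it does not implement the adaptive branch-shape analysis of the hybrid
  dynamic tree cut, and very unequal module sizes may require adjusting the
  cut quantile.
* Scale-free topology is not guaranteed on small modular designs: with a
  few equal-size dense modules the connectivity distribution is bimodal and
  no power reaches the fit target — `pickSoftThreshold()` then warns and
  returns the best fit. The orchestrated pipeline uses the fixed canonical
  power 13.
* Enrichment treats terms as flat sets (no GO graph propagation), matching
  a plain Fisher/DAVID-style analysis.
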