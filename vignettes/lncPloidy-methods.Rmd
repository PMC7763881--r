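---
title: "lncPloidy: models, parameters and design choices"
author: "lncPloidy maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{lncPloidy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science inside `lncPloidy`: what each stage
computes, which parameters matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open and a choice had to be made. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The analysis

The package studies long non-coding RNAs across an allopolyploidization
series: two diploid parents (CC and HH), their interspecific F1 hybrid,
and a derived allotetraploid (S14), each with three replicates. Two
questions drive the design: which transcripts are credible lncRNAs, and
how does their expression move relative to the additive expectation (the
mid-parent value, MPV) at the two key transitions — hybridization
(parents to F1) and genome doubling (MPV/F1 to S14).

## Identification cascade

Four filters, applied in order, each recorded in an audit table so every
removal is attributable:

1. **Novelty.** Class codes against the reference annotation. Only
   `u` (no overlap with any reference transcript span), `i` (span
   contained in a reference intron, no exonic overlap with any reference
   transcript; containment is strand-blind) and `x` (≥ 1 bp exon–exon
   overlap on the opposite strand) are novel; transcripts with an
   identical intron chain are known; every other overlap is discarded.
   Novel transcripts must reach 200 nt of *spliced* length — "length"
   throughout the package means exonic length, which is how assembled
   transcript lengths are conventionally reported. The inclusive
   boundary (200 nt passes) follows the usual "no less than 200 bp"
   convention.
2. **Coding potential.** The internal scorer follows the CPAT recipe:
   longest forward-strand ORF (ATG to stop, three frames; assembled
   transcripts are already stranded, so the reverse strand is not
   searched), ORF coverage, the Fickett TESTCODE statistic with the
   published position/content lookup tables hard-coded, and the mean
   log-ratio of in-frame hexamer frequencies under a coding vs a
   noncoding model (add-one smoothing). A logistic regression (IRLS via
   `glm`) turns the four features into a probability. Because the
   pipeline has no curated noncoding training set, the model trains on
   the annotation at hand: reference mRNAs with CDS as the coding class,
   and length-matched draws from intergenic space as the noncoding
   class. The consensus rule is a strict intersection: noncoding only if
   *every* supplied score is strictly below its threshold (internal
   probability < 0.36; optional external CPC2/PLEK/CNCI tables at < 0).
   A probability of exactly 0.36 is coding.
3. **Structure.** At least two exons — single-exon models are too often
   assembly artifacts.
4. **Expression.** Maximum across the four group-mean TPMs > 0.3. The
   choice of *which* sample the threshold applies to was open; the
   maximum over group means is the permissive reading under which
   species-specific lncRNAs (expressed in one parent only) survive,
   which the downstream analysis requires.

Surviving transcripts collapse to genes by shared gene id; gene counts
are member sums and the gene length is the longest member's spliced
length (mirroring the convention of comparing longest transcripts).

## Positional classes and the sense category

Positional classification runs against the coding annotation
*independently* of the earlier class-code filter: sense (≥ 1 bp exonic
overlap, same strand) > antisense (opposite strand) > intronic (span in
an intron, no exonic overlap) > intergenic. Among several qualifying
coding genes the largest exonic overlap decides, ties to the smaller
gene id.

Strict u/i/x extraction cannot, by itself, produce same-strand "sense"
lncRNAs, yet sense lncRNAs are a substantial category in real
annotations. The package resolves this tension explicitly: a transcript
can carry an opposite-strand exonic overlap with one gene (class `x`,
so it survives extraction) *and* a same-strand exonic overlap with a
second, overlapping gene (so it classifies as sense). The synthetic
generator plants its sense lncRNAs at exactly such convergent
overlapping gene pairs, which keeps both the extraction contract and the
category table satisfiable. This is a documented modelling choice, not a
claim about how any particular study derived its categories.

## TE overlap, subgenomes, collinearity

A lncRNA is TE-derived when some single TE interval overlaps its exons
by ≥ 10 bp (strand-blind, the BEDTools-intersect convention).
Subgenomes are read off the chromosome name (H/C prefix; anything else
is unplaced). Homoeologous lncRNA pairs are found in two stages that
mirror the usual BLASTn + MCScanX practice at desk scale: reciprocal
best matches by shared 11-mer Jaccard similarity (threshold 0.2), then
chaining matches on a chromosome pair into blocks where the partner
positions are monotone in either orientation with rank gaps ≤ 25,
keeping blocks of ≥ 4 anchors (the `-s 4` convention). The k-mer
similarity replaces alignment: it is deterministic, fast, and adequate
for detecting homologous sequences at the few-percent divergence the
generator plants; it is *not* a substitute for alignment at high
divergence.

## Expression, MPV, and the NB test

TPM is computed within the pipeline from counts and spliced lengths;
each sample sums to one million by construction. Replicate QC reports
mean pairwise Pearson correlation on log2(TPM + 1).

MPV pseudo-replicates pair parental replicates by index:
`MPV_i = (CC_i + HH_i) / 2`, rounded half-up for counts. The replicate
construction for MPV-based testing was an open choice; index pairing
preserves three pseudo-replicates for the count-based test rather than
collapsing the parents to a single average.

The differential test is a deliberately compact NB Wald test, not a GLM
framework: median-of-ratios size factors; per-feature method-of-moments
dispersion pooled over both groups; a mean–dispersion trend
`a + b/mean` fitted by least squares; the per-feature estimate averaged
with the trend (weight 0.5) and **floored at the trend**. The floor is
the package's own calibration choice: with three replicates per side the
moments estimate is extremely noisy and its downward excursions inflate
the Wald statistic; treating below-trend estimates as noise keeps the
seeded-null type-I error near nominal (the acceptance suite measures
this). When group means nearly coincide, the `1/mean` regressor is
uninformative and the pooled mean dispersion is used instead. Fold
changes use a 0.5 pseudo-count; p-values are two-sided normal; BH
correction excludes features with zero counts in both groups. Calls
require both `padj < 1e-4` and `|log2FC| > 2`. Species-specific
expression (strictly zero counts on one side, > 0.3 TPM on the other)
bypasses the Wald p — the standard error is undefined with zeros — and
is merged into the DE calls as its own kind of differential expression.
Numeric equality with DESeq2 is explicitly not claimed; DESeq2's
median-of-ratios implementation serves as an independent cross-check for
the size factors in the test suite.

Additivity classification is the progeny-vs-MPV call: non-additive up or
down when the DE thresholds are met, additive otherwise.

## Trend profiles

Model profiles are all unit-change trajectories over the ordered triple
(MPV, F1, S14) with per-step changes in {-2..2}: 25 profiles, numbered
lexicographically from the most negative, the flat profile at id 12.
(25 is below the common 50-profile default, so no greedy profile
subselection is needed.) Genes are assigned by maximal Pearson
correlation between their difference-from-start series of mean
log2(TPM + 1) and the profile values; zero-variance genes go to the flat
profile; ties resolve to the lowest id. Correlation is scale-invariant,
so proportional profiles (e.g. (+1,+1) and (+2,+2)) are equivalence
classes for assignment and the lower id absorbs them — a property
inherited from correlation-based profile matching generally, covered by
the test suite. Significance: each permutation round independently
shuffles every gene's three values and reassigns; the expected fraction
per profile is the mean over rounds; the p-value is the binomial upper
tail at the observed count; BH across profiles at 0.05. Significant
profiles cluster by single linkage at value-correlation ≥ 0.7. The
number of clusters is an output, not a constant: a presentation grouping
such as "seven bins" is one realization, not a contract.

## Cis targets and enrichment

Potential targets are coding genes whose span lies within 100 kb of the
lncRNA span (span-to-span gaps, 0 when overlapping, signed by position
on the forward axis; whether the window should anchor at the TSS was
open, and span-to-span is the choice). Pair correlation uses
log2(TPM + 1) over **all 12 samples** with the two-sided t-test on
n - 2 = 10 degrees of freedom at p < 0.05. The 12-sample choice matters:
the critical |r| at 10 df is about 0.576, consistent with reported
passing correlations starting around 0.6, whereas correlating 4 group
means (2 df) would demand |r| above 0.95. Enrichment is the upper-tail
hypergeometric test per GO term over a plain gene-to-term table (no
ontology-graph propagation), BH-corrected, with the top 10 terms below
p = 0.05 flagged.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every acceptance property is measured.

**What it emulates.** A 19-chromosome, two-subgenome genome (12 H + 7 C,
2 Mb per chromosome, AT-rich background); coding genes with real ORFs
(ATG..stop, 300-750 nt, drawn from a fixed biased codon usage that gives
coding sequence a distinctive in-frame hexamer signature) split into
2-4 exons; planted lncRNAs in the four positional categories at roughly
the category proportions of real lncRNA annotations (intergenic
largest, intronic smallest); decoys that the cascade must remove
(ORF-carrying novels, single-exon models, barely expressed models at
0.05 TPM); TE intervals, 77% of lncRNA genes receiving one overlapping
their first exon by well over 10 bp, the rest placed in intergenic gaps
with a configurable midpoint bias; homoeologous gene and intergenic
lncRNA pairs planted in identical relative order on paired H/C
chromosomes (collinear by construction, sequences copied with 3% point
mutations); and extra isoforms for a subset of lncRNA genes so the
gene collapse is exercised.

Counts are NB with dispersion 0.05 around expected values proportional
to true TPM times transcript length (transcript-quantification
semantics), scaled to library sizes of about 2 million. Group means
carry the planted structure: 4% of lncRNAs species-specific (exact zero
in one parent), 8% parent-different (|log2FC| in 2.5-4), 22.1%
non-additive in F1 (88.9% of them up), 2.1% non-additive in S14 — the
non-additivity rates and the up-share are the reported study-scale
rates, reproduced as generator defaults. Effect sizes are drawn above
the |log2FC| = 2 call threshold (uniform 2.5-4) so that planted truth
and callable signal coincide. Trend-profile truth is derived from the
planted means, not drawn separately. A subset of DE lncRNAs is coupled
to its nearest coding gene (scaled means, hence correlated expression),
and those genes carry a marker GO term so target prediction and
enrichment have a recoverable signal. Group means are expressed on a
true TPM scale (each group sums to one million), which makes the
0.3-TPM filter and the 0.05-TPM decoys mean what they say.

Every artifact derives from one master seed through per-artifact
sub-streams, so regenerating counts never perturbs the genome, and the
same seed reproduces byte-identical files.

**What it does not emulate.** No read-level simulation (no FASTQ, no
mapping ambiguity or positional bias), no assembly errors (reference
copies are exact, so the known-transcript match is never fuzzy), no TE
sequence realism beyond interval placement, no expression correlation
structure beyond the planted lncRNA-target couplings, and mutation-only
sequence divergence between homoeologs (no indels). Passing tests
therefore demonstrate that the algorithms implement their contracts and
recover planted structure under clean conditions; they do not
demonstrate robustness to assembly noise, mapping artifacts, or high
sequence divergence.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GTF convention); BED is
  converted on read/write. Adjacent inclusive intervals overlap by 0.
* Reported percentages round to one decimal and ratios to two, using
  R's IEC-60559 `round` (half to even), which reproduces conventional
  reported values such as 9.62 for 77:8.
* Zero-variance series: replicate-correlation pairs are dropped from
  the mean; correlation pairs fail; zero-variance trend series go to
  the flat profile.
* All-zero samples abort TPM normalization with an error naming the
  samples; transcripts present in the annotation but absent from the
  counts abort identification with the missing ids.
* Problem sizes: the default generator produces about 1,870 assembled
  transcripts over 38 Mb and 12 samples; the acceptance simulations use
  1,000-feature NB matrices and 400-gene profile sets. These sizes were
  chosen as the smallest at which the binomial/recovery margins in the
  acceptance properties are comfortably away from their thresholds.

# Known limitations

* The NB test is intentionally minimal: no GLM covariates, no MAP
  dispersion estimation, no independent filtering, no shrunken fold
  changes. It is validated by simulation against its own contracts.
* The k-mer collinearity stage assumes low divergence between
  homoeologs; diverged pairs need a real aligner upstream, whose scores
  can be supplied in place of the internal similarity.
* GO enrichment treats terms as flat labels; without ontology
  propagation, parent terms are only as annotated.
* Correlation-based profile assignment cannot separate proportional
  profiles; interpret profile ids up to positive scaling.
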