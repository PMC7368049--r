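---
title: "Insulator occupancy at heterochromatic promoters: models and methods"
author: "hetinsul"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insulator occupancy at heterochromatic promoters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetinsul)
```

## The scientific problem

Pericentric heterochromatin in *Drosophila* — marked by H3K9me3 and HP1a —
is a transcriptionally repressive environment, yet it harbours dozens of
protein-coding genes that remain active, and gene loci have repeatedly
relocated between euchromatin and heterochromatin during *Drosophila*
evolution. One candidate explanation is that such genes carry intrinsic
insulation: binding sites for insulator proteins (BEAF-32, GAF, dCTCF, and
the co-localizing replication-element factor Dref) near their promoters
that shield the nucleosome-free promoter region from the surrounding
repressive chromatin.

`hetinsul` implements the quantitative skeleton of that analysis: domain
delineation from chromatin marks, an activity filter, promoter occupancy
and direct/indirect binding calls, association of occupancy with
differential expression under BEAF-32 disruption, and the comparative
promoter/selection toolkit (ortholog chaining, TSS inference, TN93
distances, NG86 dN/dS). Everything operates on standard file formats
(GFF3, narrowPeak/BED6, bedGraph, FASTA, TSV) and a synthetic toy genome
with planted ground truth exercises the pipeline end to end.

## Coordinate and data model

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
is converted at the boundary, BED-family formats are native. One convention
everywhere prevents off-by-one drift, and the interval-overlap predicate is
the half-open one: `[0,10)` does not touch `[10,20)`.

The TSS of a gene is the 5'-most transcript start across isoforms. Genes
with two promoters a few hundred bp apart are real, but a deterministic
convention is required; 5'-most is ours and is applied identically
everywhere.

## Fold enrichment and enrichment matrices

Signal tracks are fixed-bin vectors (default 200 bp, the promoter-window
scale). Fold enrichment is `(treat + c)/(input + c)` per bin with
pseudocount `c = 1` in RPM units. Input-normalization conventions rarely
fix a pseudocount; 1 RPM is small against real coverage yet regularizes
empty bins. `fold_enrichment()` deliberately refuses to run
without an input track — occupancy medians are defined in fold-enrichment
units, and silently falling back to raw signal would change their meaning.

TSS-anchored matrices (`tss_matrix()`) extract strand-oriented windows
(e.g. 2 kb either side of the TSS; 10 kb upstream / 2 kb downstream for
the extended BEAF-32 view), with minus-strand rows reversed so columns
always read 5' to 3' and out-of-chromosome bins set to 0.

## Border delineation

A euchromatin–heterochromatin border described only qualitatively — a
gradual rise of H3K9me3/HP1a enrichment toward the centromere — is not a
formula, so the package operationalizes it:

1. aggregate the fold-enrichment track into `window_bp` windows (default
   10 kb, mean over bins);
2. smooth with a running median of width `smooth_k` (default 5) to kill
   isolated spikes;
3. scan from the telomeric end toward the pericentric end; the border is
   the telomere-facing boundary of the first window where smoothed FE
   reaches `threshold` (default 2.0, midway between the simulated
   euchromatic level 1 and heterochromatic level 4) and stays there for
   `min_run` consecutive windows (default 10, i.e. 100 kb of sustained
   enrichment — a domain, not a peak).

All four knobs are exposed. Ties: a TSS exactly at the border is assigned
to heterochromatin — arbitrary but fixed. Whether the H3K9me3 and HP1a
borders should be intersected or unioned is a free choice;
`combine_borders()` defaults to the outermost (most telomeric) call, i.e.
the larger heterochromatin extent, with `h3k9me3_only` and `innermost` as
alternatives. The dot chromosome 4 bypasses border logic entirely and is
treated as wholly heterochromatic. The border is monotone under the
threshold: raising it can only shrink heterochromatin (a property test).

## Activity and occupancy calls

A gene is *active* when (i) at least one called RNA Pol II peak overlaps
its strand-oriented ±2 kb TSS window — peak calls carry the significance,
so "significant Pol II enrichment" is delegated to the peak caller — and
(ii) its expression is at least 10 RPM (`rpm = count / library_size x 1e6`).
Only protein-coding genes are considered.

Occupancy requires ≥ 1 bp overlap between a peak and the 200-nt upstream
promoter window (no minimum overlap fraction is stated anywhere, so none is
imposed). The per-gene enrichment value is the maximum `signalValue` among
overlapping peaks; the distance to TSS uses that peak's summit, or midpoint
when no summit is recorded. For poorly annotated genomes an *extended*
strand-aware window (10 kb upstream, 2 kb downstream) replaces the promoter
window.

Direct versus indirect binding: the full sequence of the best peak is
scanned for the factor's consensus (CGATA for BEAF-32; TATCGATA for Dref —
note CGATA is contained in the Dref consensus, and TATCGATA is its own
reverse complement) as exact IUPAC matches on both strands. A match makes
the binding direct. The scan covers the peak's full sequence, not just the
slice inside the promoter window: a peak overlapping the promoter is
classified by everything it spans. Genes occupied by Dref without the
canonical motif are reported rather than dropped.

`mann_whitney()` follows a fixed contract: the statistic is U of the first
sample (ties counted one half); exact mode uses the null U distribution
(full enumeration of labelings under ties), the approximation uses the
tie-corrected variance with a continuity correction, and `auto` goes exact
when `n1 + n2 <= 20` with no ties. Exact mode is checked against
brute-force enumeration in the tests; the approximation against
`stats::wilcox.test`.

## DEG association

The differential-expression table is consumed, not fitted — the upstream
negative-binomial model is out of scope. Filtering keeps `P <= 0.05`
(unadjusted, as is typical for exploratory DEG screens; a BH flag exists
but is off by default) and `>= 1 log10 CPM`. DEGs are assigned to the `2^3` occupancy
subsets of {BEAF-32, dCTCF, GAF} and rolled up to four display groups (one,
two, three factors, none); direction trends are compared pairwise with a
two-sided Fisher exact test. DEGs absent from the occupancy annotation are
excluded from the groups and counted separately — occupancy annotation is
often incomplete for real gene sets, and an explicit count keeps the
bookkeeping honest rather than silently shrinking the totals.

## Comparative promoters and selection

*Hit chaining.* Alignment hits (12-column tabular format) with
`E <= 1e-80` are chained into ortholog loci: same subject chromosome and
strand, collinear query order, inter-block gap at most `max_intron`
(default 50 kb — adjacency alone does not bound the gap, so the default is
explicit; sensitivity to this knob should be reported, not resolved, and it
is exposed). E-value thresholds are significance bounds: a hit qualifies
when `evalue <= 1e-80`.
Blocks become exons; inter-block sequence is intronic; reciprocal best-hit
validation accepts a locus whose top back-hit overlaps the original gene.

*TSS inference.* Among 5'UTR hits with `E <= 1e-60`, on the right strand,
whose 3' end lies within 600 nt of the annotated CDS start, the TSS is the
5'-most mapped nucleotide. Hits slightly overlapping the CDS are accepted
(gap clamped at 0): real 5'UTR alignments frequently run into the start
codon, and only the upper distance bound is meaningful.

*Promoter motif maps* anchor offsets at the TSS placed at the right end of
each sequence, so offsets are invariant under distal padding and comparable
across species. The promoter window length is per-gene configurable (the
*Myb* promoter is shortened to 100 bp when a MITE insertion sits 92 bp
upstream of the TSS in one lineage).

*TN93.* The Tamura–Nei (1993) distance is computed in closed form with a
gamma rate-variation correction (shape 1 by default, matching the original
MEGA setting) after complete deletion (every column containing a non-ACGT
symbol in either sequence is removed). Base frequencies are pooled
empirical frequencies of the retained columns. Saturation (log-domain
violation) is flagged as an infinite distance rather than an error. The
implementation is verified against an independently coded formula oracle
and against `ape::dist.dna`.

*dN/dS.* Maximum-likelihood codeml estimation is the field standard; the
package implements Nei–Gojobori (1986) counting as the transparent
desk-scale alternative. Site counts average the synonymous fraction over both sequences;
stop-codon-creating changes count as nonsynonymous. Multi-hit codons
average over all minimal mutational pathways, excluding pathways through
premature stop codons (falling back to all pathways when every one is
blocked). Proportions are Jukes–Cantor corrected; `p >= 3/4` flags the
rate infinite, and dN/dS is reported absent (never 0/0) when `dS = 0`.
Agreement with ML estimates is approximate, but the kind of conclusion the
method is used for here — dN/dS well below 1, purifying selection — is a
bound that is robust to the estimator.

The TN93 sequence generator (`simulate_tn93_pair()`) uses the closed-form
transition probabilities with per-site gamma rates matching the estimator's
correction; tests verify the transition matrix against a matrix-exponential
of the generator and require < 10% relative RMSE of recovered distances at
d = 0.05, 0.2 and 0.5.

## The synthetic stated world

`sim_config()` fixes the world the tests probe: two 1-Mb arms with borders
at 600 kb (pericentric right) and 400 kb (pericentric left), a 120-kb
wholly heterochromatic dot chromosome, 200 non-overlapping genes (45% per
arm, 10% on the dot), euchromatic FE 1 and heterochromatic FE 4 with
Gaussian noise sd 0.5 per 200-bp bin, 80% of genes expressed at 15–300 RPM
(the rest below 5 RPM, straddling the 10 RPM cut), BEAF-32 on 90% of
heterochromatic and 35% of euchromatic promoters with 84% direct binding,
GAF at roughly half on both sides, dCTCF enriched pericentric, Dref only
where BEAF-32 binds, and direct/indirect peak signals drawn from shifted
lognormals with medians 11 and 5 so the group comparison has planted
power. These values were chosen once to be realistic for this system and
are fixed, not tuned.

Genes are kept 15 kb clear of the true borders (repeat-dense boundary
zones carry few genes in reality, and it keeps location accuracy a test of
the border call rather than of gene placement luck). Activity truth is
derived from the emitted Pol II peaks under the same ±2 kb rule the
classifier uses, so a neighbour's peak counts for both. Motifs are
physically written into the FASTA inside direct peaks — classification is
tested against real sequence, not bookkeeping — and chance motif matches
are scrubbed out of indirect peaks (mutating a base outside any planted
motif, re-scanning until clean). `audit_bundle()` re-reads the emitted
files and fails loudly if any planted fact does not hold.

What a green recovery test establishes: the pipeline's rules reproduce the
planted world near-perfectly under the stated noise. What it does not:
realistic read-level noise, peak-caller artefacts, repeat-driven
mappability gaps, isoform complexity, or biological coupling between
chromatin state and expression — peaks and tables are simulated directly,
as the pipeline consumes peak calls by design.

## Numerical and degenerate-input choices

* Rasterization of bedGraph intervals is a coverage-length-weighted mean
  over the full bin width (uncovered bp count as zero), conserving total
  mass; records beyond the chromosome are clipped with a warning.
* Arms shorter than `min_run` windows yield an absent border with a
  warning; an absent border means an entirely euchromatic arm.
* `region_score()` on an interval overlapping no bins is an error, not 0.
* Exact Mann–Whitney with ties falls back to explicit enumeration and
  refuses when the labeling count exceeds 2e6.
* A Fisher table with a zero margin has P = 1.
* Identical sequences give TN93 distance 0 and NG86 `dN = dS = 0` with the
  ratio reported absent.

## Known limitations

* The border operationalization is one of many consistent with a "gradual
  increase"; its four knobs matter near shallow boundaries, which is why
  they are exposed and the monotonicity property is tested.
* NG86 is a counting estimator; for strong rate heterogeneity across sites
  or codons it diverges from ML codeml values.
* Occupancy uses called peaks as given; no re-calling, no signal-level
  occupancy model.
* The Venn/grouping logic assumes one occupancy record per gene x factor;
  multi-promoter genes are collapsed to the single conventional TSS.
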