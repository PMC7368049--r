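# hetinsul

Insulator-protein occupancy at heterochromatic gene promoters in *Drosophila*.

Dozens of essential *Drosophila* genes live inside pericentric
heterochromatin — a repeat-rich, H3K9me3/HP1a-marked environment that
normally silences transcription — yet stay active. `hetinsul` implements a
reusable, fully testable pipeline for the analyses that connect this activity
to insulator proteins (BEAF-32, GAF, dCTCF, and the co-localizing factor
Dref):

* **Chromatin domains** — delineate the euchromatin–heterochromatin border
  per chromosome arm from input-normalized H3K9me3/HP1a fold enrichment
  (FE = (treat + c)/(input + c) per fixed bin), as the outermost window where
  smoothed FE first reaches a threshold and stays there for a sustained run;
  the dot chromosome 4 is treated as entirely heterochromatic.
* **Active gene calls** — a heterochromatic gene is *active* when an RNA
  Pol II peak overlaps its ±2 kb TSS window and its expression is ≥ 10 RPM.
* **Promoter occupancy** — a factor occupies a gene when a called peak
  overlaps the 200-nt upstream promoter window; binding is *direct* when the
  peak sequence carries the consensus motif (CGATA for BEAF-32, TATCGATA for
  Dref, scanned on both strands), *indirect* otherwise. Occupancy
  combinations (Venn counts), group medians and Mann–Whitney U comparisons
  are produced.
* **DEG association** — a differential-expression table is filtered at
  P ≤ 0.05 and ≥ 1 log10 CPM, grouped by promoter occupancy (one / two /
  three insulators / none) and tested for direction trends with Fisher's
  exact test.
* **Comparative promoters and selection** — tabular alignment hits are
  chained into ortholog loci (same strand, collinear, E ≤ 1e-80), TSSs
  inferred from 5'UTR hits (E ≤ 1e-60, within 600 nt of the CDS), promoter
  motif maps anchored at the TSS, and divergence quantified with Tamura–Nei
  (1993) distances (gamma shape 1, complete deletion) and Nei–Gojobori
  (1986) dN/dS on codon alignments.
* **Synthetic data** — a seeded generator plants a toy genome with known
  borders, gene activity, occupancy, motifs and DEG effects, so every stage
  is testable end to end without downloads; an audit pass re-reads its own
  files and verifies the planted truth.

## Worked example

```r
library(hetinsul)

dir <- tempfile()
simulate_bundle(sim_config(seed = 1), dir)   # toy genome + all inputs
audit_bundle(dir)                            # generator self-check
report <- run_pipeline(bundle_config(dir))
print(report)
```

```
hetinsul pipeline report
  genes: 200 (90 het / 110 eu); active het: 62
  BEAF-32 on active het promoters: 56 (47 direct)
  direct vs indirect medians: direct=11.937, indirect=4.551; P = 9.99e-06
  DEG: 46 significant (46 grouped + 0 unannotated)
```

Reading: of 200 simulated genes, 90 fall pericentric of the recovered
borders; 62 heterochromatic genes pass the Pol II + 10 RPM activity filter;
BEAF-32 occupies 56 of their promoters, 47 directly (peak carries CGATA).
Direct peaks are ~2.5-fold more enriched than indirect ones (medians ≈ 12
vs ≈ 4.6), a planted shift the Mann–Whitney U test detects at P ≈ 1e-5.
`report$venn`, `report$occupancy` and `report$deg_trends` hold the full
tables; `run_pipeline(..., out_dir = ...)` writes them as TSV/JSON.

Single steps are exported on their own: `read_gff()`, `read_peaks()`,
`read_bedgraph()`, `fold_enrichment()`, `tss_matrix()`,
`delineate_border()`, `promoter_window()`, `scan_motif()`,
`call_occupancy()`, `classify_binding()`, `mann_whitney()`, `chain_hits()`,
`infer_tss()`, `back_translate()`, `tn93_distance()`, `ng86_dnds()`,
`filter_deg()`, `fisher_exact_2x2()`, and more — see the help pages and the
methods vignette (`vignettes/heterochromatic-promoter-insulators.Rmd`).

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch against
the installed package: it simulates the default stated world at the given
seed, audits the bundle, executes every stage, scores recovery against the
planted truth, and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
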