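---
title: "Differential methylation across aging and regeneration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation across aging and regeneration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenmeth)
```

## The analysis problem

Whole-genome bisulfite sequencing (WGBS) tabulates, for every CpG in a
tissue sample, how many reads carried a methylated cytosine out of the
total covering reads. Because each liver sample pools millions of cells,
the per-CpG methylated fraction β is a continuous quantity in [0, 1] even
though methylation is binary per cell. regenmeth implements the full
downstream analysis for a two-factor design — age (2, 8, 16 months) by
regeneration time after 70% partial hepatectomy (0, 1, 2, 4 days) — in
which each *contrast* compares two condition groups of biological
replicates: three aging contrasts (A8:A2, A16:A8, A16:A2) and three
regeneration contrasts (R1:R0, R2:R0, R4:R0, all against the pre-surgery
baseline of young livers).

## DMC and DMR model

Replicates of a group are pooled by summing counts per CpG, so the pooled
fraction is the coverage-weighted mean of the replicate fractions. A CpG
is **tested** only if its pooled coverage reaches `min_coverage` (default
3 reads) in *both* groups. It is a **differentially methylated cytosine
(DMC)** when

* its methylation difference Δβ = β_test − β_ref satisfies |Δβ| > 0.2
  (strict), and
* the two-sided Fisher exact p on the pooled 2×2 count table is < 0.05
  (strict).

Both inequalities are strict by design; p-values are deliberately left
unadjusted for multiplicity (the region-level clustering step is the
effective error control, and `call_dmcs()` notes this once per run). An
optional **credible** statistic replaces |Δβ| by the lower endpoint of the
central 95% posterior interval of |β_test − β_ref| under independent
Jeffreys Beta(m + ½, u + ½) posteriors, capped at the raw pooled
difference so that it only ever *discounts* sampling noise. This is a
deliberately simple stand-in for hierarchical beta-binomial credible
differences: it penalises low-coverage sites without modelling replicate
dispersion, which is out of scope here.

A **differentially methylated region (DMR)** is assembled per direction
from the DMC list: every run of ≥ 3 consecutive same-direction DMCs whose
positional span is at most 300 bp (inclusive; equivalent to a 300-bp
window slid at 1-nt steps) seeds a region, seeds sharing any DMC merge
transitively, and the merged component spans its outermost DMCs. An
intervening opposite-direction DMC does not break a run, because hyper-
and hypo-catalogs are independent sets. The assembler is verified against
a brute-force window-enumeration oracle on thousands of random instances.

## Cross-contrast classification

All shared-region logic uses a single overlap rule: at least
`min_overlap_bp` (default 1) shared base pairs, on half-open intervals, so
abutting regions do not overlap.

* **Temporal categories** (early = A8:A2 vs late = A16:A8): an early DMR
  is *inverse* if any opposite-direction late DMR overlaps it,
  *progressive* if only same-direction late DMRs do, else *early single*;
  unmatched late DMRs are *late single*. Inverse takes precedence over
  progressive when both kinds of partner exist — the categories must be
  exclusive and the inverse pattern is the phenomenon of interest; the
  partner list retains the full evidence either way.
* **Cross records** (regeneration × aging): every overlapping pair is
  labelled *synchronous* (equal directions) or *inverse*. The label
  depends only on direction equality, so flipping every direction label
  leaves it invariant.
* **Venn accounting** (three same-direction catalogs): records are
  clustered into overlap-connected components and all quantities are
  counted over components, so a DMR overlapping two DMRs of another
  catalog is not double-counted; pairwise intersection counts include the
  triple, which makes the three-set inclusion–exclusion identity
  `union = ΣS − ΣP + T` exact by construction.

## Genomic annotation

`derive_region_tracks()` builds the hotspot vocabulary from refFlat-like
gene models: transcript and extended spans, first/all exons and introns,
`Genf` (first-exon start to second-exon start), promoter and TSS/TTS
flanks (`Prom1k`, `TSSup1k`, `TSSdn1k`, `TTS1k`, …), the central 60% of
the transcript (`Center30ct`, boundaries rounded toward the centre), a
7-kb upstream window (`TSS-7k`), exonic UTRs when CDS coordinates are
present (empty with a warning otherwise), plus pass-through repeat (rmsk
and per-class) and CpG-island tracks. Everything upstream/downstream is
strand-aware: the TSS of a `-` gene is `tx_end` and upstream means larger
coordinates. Windows clip to `[0, chromosome length)` when sizes are
supplied (synthetic genomes always supply them); without sizes they clip
at 0 with a warning. Hotspot membership is by ≥ 1 bp overlap and classes
are not mutually exclusive, so percentages need not sum to 100.

DMR-to-gene mapping uses the strand-aware promoter window −7 kb/+3 kb
around the TSS and the gene body `[tx_start, tx_end)`; each gene-model row
is treated independently and gene-level counts deduplicate by `gene_id`.

## DEG integration

DEG classification is inclusive (q ≤ 0.05, fold change ≥ 2), with
Benjamini–Hochberg q computed over all raw p only when the table carries
no q column (a supplied q is trusted as-is, matching how upstream
differential-expression output is consumed). Linkage keeps only the
coherent pairs — promoter hypo-DMR with an up-DEG, promoter hyper-DMR with
a down-DEG (`zone_filter` can add gene bodies). A **flip gene** is a DEG
whose promoter carries an early-aging DMR synchronous with its expression
direction *and* a mid-to-late-aging DMR inverse to it; the flip set equals
the gene-level intersection of a synchronous early-linkage pass and an
inverse late-linkage pass, which the tests assert as a set identity.

## The synthetic generator

`simulate_methylomes()` emulates the statistical shape of the study so
that every stage can be tested end-to-end with known truth:

* irregular background CpG positions (uniform without replacement) with
  U-shaped Beta(0.7, 0.25) baselines — mean 0.737, matching a ~74% global
  methylation level — clipped to [0.02, 0.98];
* per-sample coverage Poisson (or negative binomial) around 10×, with
  zero-coverage sites absent from that sample's table, and binomial
  methylated counts; four replicates per condition;
* planted differential regions as CpG-dense clusters of 8–14 CpGs within
  ≤ 280 bp. Real DMRs sit in locally CpG-dense sequence (island-like
  density; reported example DMRs span tens to a few hundred bp), and a
  per-CpG power analysis at these conditions (pooled 40 vs 40 reads,
  Δβ = 0.3) gives 0.71–0.87 detection probability per CpG, so 8+ CpG
  clusters make a planted region recoverable with high probability while
  5-CpG clusters would not be;
* aging shifts accumulate along the A2 → A8 → A16 chain, so each temporal
  category produces exactly its intended contrast signature (e.g. an
  early-single region shifts both A8 and A16 and therefore also appears
  in A16:A2 — recorded as such in the truth table);
* planted baselines are drawn uniformly from the interval that keeps
  every shifted value inside [0.05, 0.95], so clipping never erodes a
  planted effect;
* flip genes are inverse-category loci placed wholly inside the
  strand-aware promoter window with ≥ 20 bp margin; background gene
  promoters are kept clear of planted loci by interval reservation so the
  linkage truth is exact;
* the DEG table carries planted concordant, flip and discordant genes
  with small p, and null genes with Uniform(0, 1) p, exercising the BH
  path.

What the generator does **not** emulate: replicate-level biological
dispersion beyond binomial sampling, chromatin-domain autocorrelation,
non-CpG methylation, and realistic repeat/CGI placement (random
intervals). Passing recovery tests therefore demonstrate correctness of
the calling and classification logic under the stated noise model, not
calibration on real livers.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally; CpG inputs are 1-based
  and converted on read; reports restore 1-based inclusive positions.
* Minus-strand CpG records merge into the paired plus-strand cytosine
  (position − 1) by summing counts — one record per CpG dyad. This is a
  package convention (symmetric-CpG pooling), not inherited from any
  upstream caller.
* The credible bound is computed by fixed-grid quadrature (2001 points)
  plus root-finding to 1e-8; ties at the Fisher test use the standard
  two-sided rule (sum of table probabilities ≤ the observed one).
* Chromosome names compare as exact strings; no "chr" normalisation.
* The reference synthetic study used by the test suite and the acceptance
  script is 2 chromosomes × 5 Mb, ~30,000 background CpGs, 146 planted
  regions across all six contrasts, and 92 genes — small enough to run
  the full pipeline in well under a minute while every planted category
  is represented tens of times.

## A worked example

```{r example, eval = FALSE}
library(regenmeth)
cfg <- pipeline_config(simulation = sim_config(seed = 101))
run <- run_pipeline(cfg, out_dir = "run1")
run$recovery$per_contrast
run$summary$temporal_counts
run$flip_genes
```

## Known limitations

* Pooled counts feed the per-CpG test; replicate dispersion enters only
  through the optional credible statistic. A full hierarchical
  beta-binomial model is explicitly out of scope.
* DMC p-values are raw; genome-wide error control at the DMC level is not
  attempted.
* Venn accounting over components means a component that chains across
  many records counts once; set "sizes" are component counts, which is
  what makes inclusion–exclusion exact but can differ from raw record
  counts when records within one catalog overlap records of another
  asymmetrically.
* The temporal precedence rule (inverse over progressive) is a
  documented convention for the rare DMR overlapping late partners of
  both directions.
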