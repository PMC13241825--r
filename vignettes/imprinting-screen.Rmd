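---
title: "Methods: screening uniparental methylomes and transcriptomes for imprinted genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening uniparental methylomes and transcriptomes for imprinted genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniprint)
library(data.table)
```

## The screening model

Uniparental human embryonic stem cells carry two copies of a single
parental genome, so parent-of-origin epigenetic asymmetries that are
averaged out in biparental material appear at full amplitude: a
paternally methylated promoter approaches 100% methylation in
androgenetic (AG) cells and 0% in parthenogenetic (PG) cells, and a
maternally expressed gene (MEG) is overexpressed in PG relative to AG
cells.  The screen therefore rests on three independent, combinable
signals per gene:

* a **promoter DMR**: a difference in pooled CpG methylation inside the
  TSS ± 500 bp window between AG and PG samples, with direction
  (AG-hyper = paternal, PG-hyper = maternal);
* **imprinted-like expression**: a significant AG-versus-PG expression
  difference among expressed genes, signed as MEG-like or PEG-like;
* **allelic-ratio support**: monoallelic or partially monoallelic SNP
  expression in independent (biparental) material, with isoform-level
  resolution where transcript-tagged records exist.

A gene is a **tier-1** candidate when the first two signals co-occur
concordantly (paternal DMR with MEG-like expression, maternal with
PEG-like — the silenced allele is the methylated one).  Because imprinted
genes cluster under shared control regions, a **tier-2** search relaxes
the requirement to either signal alone within 500 kb of a tier-1 anchor
TSS.  ASE and germline evidence annotate candidates but never gate them:
they come from different biological material and unmatched coverage, so
requiring them would couple sensitivity to external data availability.

Finally, the **germline scan** asks whether candidate-cluster methylation
differences originate in the gametes: 1-kb tiles across the cluster
region (anchors ± 200 kb) are tested sperm-versus-oocyte by exact
permutation, and significant tiles are checked for concordant
persistence in the uniparental cells.  Promoter DMRs lacking germline
support are classified *secondary* — established after fertilisation,
downstream of some other control element.

## Statistical choices

**Promoter test unit.**  With four samples per group, a per-sample
Wilcoxon rank-sum test has a minimum two-sided p of 2/70 ≈ 0.029 and can
never survive BH correction over thousands of promoters.  The default
(`test_mode = "cpg_level"`) therefore pools per-sample per-CpG
methylation levels within the window and applies a two-sided
Mann–Whitney test to the AG versus PG pools; with ~10 informative CpGs
per promoter and four samples per group this yields ~40 observations per
pool and genome-wide-correctable p-values.  The per-sample mode is
retained as an option and the mode used is recorded in the output.  Ties
are handled by midranks with the continuity-corrected normal
approximation (the behaviour of `stats::wilcox.test`); the exact
distribution is used when the sample configuration permits it.

**Effect-size gate.**  CpG-level pooling can make trivially small
differences significant at high coverage, so reported DMR calls also
require |AG − PG| ≥ 25 percentage points (`dmr_min_delta_pp`).  The gate
is configurable and logged; 25 pp is small enough to keep partially
eroded imprints (full amplitude would be ~100 pp, culture-driven loss of
imprinting commonly halves it) and large enough to exclude
coverage-driven micro-deltas.

**Expression engine.**  Counts are TMM-normalised (trimmed mean of
M-values, 30%/5% trims, weighted by delta-method variances) and compared
with a conditional negative-binomial exact test on depth-equalised group
sums.  The per-gene dispersion is max(common, 0.5·tagwise + 0.5·common),
where the tagwise value is a method-of-moments estimate and the common
value a trimmed mean across informative genes — deliberately
conservative at n = 4 per group, where tagwise moments are noisy.  At
dispersion zero the test reduces exactly to the conditional Poisson
(binomial) test, which the test suite checks in closed form.  Log2 fold
changes use a prior count of 0.5 so zero-containing genes stay finite.
Classifications (MEG-like/PEG-like), not p-values, are the comparable
output of this stage; an externally produced DE table with columns
(gene_id, log2fc_pg_over_ag, p_value) can be injected into
`classify_imprinted_expression()` unchanged.

**Expressed universe.**  A gene is expressed at a stage when TPM > 1 in
at least two samples of that stage, approximating count-based
independent filtering; the promoter-DMR FDR family is restricted to this
universe, matching the biology (an unexpressed promoter's methylation
is uninterpretable for imprinting) and improving power.

**Allelic-ratio boundaries.**  Ratio < 0.15 is monoallelic (strict, so
0.15 itself is partial); 0.15–0.3 inclusive is partially monoallelic;
"more than 5 reads" is implemented as total ≥ 6, and stringent mode
requires ≥ 20.  Per-gene summaries report the strongest class over
qualifying records plus a discordance flag rather than guessing a rule
for disagreeing SNPs.  The isoform-specific flag requires the
monoallelic/biallelic contrast between transcripts *within one cell
type*, since tissue-specific imprinting across cell types would
otherwise masquerade as isoform-specific.

**Permutation convention.**  The observed assignment is counted in both
numerator and denominator, so p ≥ 1/N (conservative standard).  All
label assignments are enumerated when C(nA+nB, nA) ≤ `perm_max_exact`
(default 20 000); beyond that, 10 000 Monte-Carlo draws with an add-one
correction.  With the realistic gamete panel of 4 sperm versus 3
oocytes, N = 35 and the minimum attainable p is 1/35 ≈ 0.0286 — **no
single window can clear BH at 0.05 over any universe larger than one
window**.  The scan therefore reports both the (usually empty) BH-gated
set and a *nominal* putative set (unadjusted p ≤ 0.05 with the delta
gate) over the covered-window universe, and records the universe size.
This limitation is a property of the design, not of the implementation;
persistence in uniparental cells (4v4, minimum p 2/70, tested per
window rather than as a family) provides the corroborating evidence.

**1-Mb window.**  "A 1-Mb window around the TSS" is read as total width
1 Mb, i.e. a 500-kb radius (`cluster_radius_bp`); the radius is
configurable to 1 Mb since the phrase is ambiguous, and the value used
is part of the run manifest.

**Dyad merging.**  Opposite-strand CpG calls at a dyad are merged by
count summing on ingest (CpG methylation is symmetric; merging raises
per-dyad coverage).  This is configurable (`merge_strands`) and recorded
on the sample object; forward-strand CpG starts are never adjacent, so
runs of adjacent positions are paired greedily from the left.

**Coordinates.**  All internal coordinates are 0-based half-open;
Bismark-style 1-based inputs are converted on ingest and back on output.
Methylation is a fraction internally and percent (0–100) at every
reporting boundary.  QC's "normal" band 30–70% is inclusive at both
ends.  DMRs without sufficient coverage are excluded from the QC
denominator rather than counted as failures, which avoids penalising
RRBS dropout; a sample with no assessable registry DMR raises an error
rather than passing silently.  The registry gate applies to biparental
(reference) samples only — uniparental samples legitimately sit at the
extremes of known imprinted DMRs, which is the signal, not an artefact.

## What the generator emulates — and what it does not

`simulate_study()` produces a complete seeded study: promoter CpG tables
with beta-binomial counts (per-locus mixture baseline shared across
origins at null promoters; origin-split levels 0.5 ± delta/2 at planted
DMRs; negative-binomial depth, mean 30×, size 4), negative-binomial
counts (planted 4-fold MEGs/PEGs at base mean 100, dispersion 0.1,
±30% library-depth variation), binomial ASE records (leakage 0.05 at
monoallelic loci, 0.5 at biallelic; isoform-specific genes get one
transcript of each), and sperm/oocyte methylomes over a sparsely
covered scan region with planted oocyte-methylated windows, two of
three persisting into the uniparental cells.  The default scenario —
2000 genes over 4 chromosomes, 20 paternal promoter DMRs at 60 pp,
20 MEGs and 20 PEGs, a chromosome-1 cluster of 5 stringent genes with 3
expression-only neighbours, 4 AG versus 4 PG ESC samples plus 2
biparental, 4 sperm versus 3 oocytes, 30 covered scan windows — is the
study design the analysis stages are validated against; the test suite
measures planted-DMR sensitivity/FDR, expression recovery, and exact
tier recovery over 20 seeded replicates of it.

Deliberately not emulated: read-level artefacts (mapping bias,
bisulfite conversion failure, PCR duplicates), CpG-density-correlated
coverage, linked methylation along reads, isoform-level quantification
from reads, cell-line-specific copy-number effects, and culture-drift
aberrations beyond the planted patterns.  Passing tests therefore show
the statistical machinery is correct and well-calibrated under the
generative assumptions — not that real RRBS/RNA-seq artefacts are
handled; on real data the QC stage and the configurable gates are the
defence.

## Degenerate inputs and tie-breaks

Regions with fewer than `min_cpgs_per_region` (3) informative CpGs
(coverage ≥ `min_cov_per_cpg` = 5) yield "no data", a value, never an
error.  Genes with fewer than two informative samples in either group
are skipped with a logged reason.  All-zero genes test at p = 1 with
log2fc 0.  Empty candidate sets write header-only tables.  A gene near
several tier-1 anchors records its nearest anchor.  Monte-Carlo
permutation is seeded through the run configuration; at default panel
sizes every permutation test in the pipeline is exact, so a run is a
deterministic function of (inputs, configuration, seed) — the
determinism check in the acceptance script asserts byte-identical
candidate tables across repeated runs.

## Known limitations

* The NB exact test is not a GLM: batch terms or paired designs are out
  of scope (inject an external DE table instead).
* The germline scan's FDR statement is bounded by the gamete panel size
  (see above); with ≤ 7 gamete samples the nominal set plus persistence
  is the only workable readout.
* The shipped known-DMR registry carries approximate locus-level
  coordinates for demonstration and QC; serious use should supply a
  curated registry (BED6+2: name, origin).
* Biparental samples are used as a QC reference and reporting baseline
  only; allele deconvolution in biparental material is not attempted.
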