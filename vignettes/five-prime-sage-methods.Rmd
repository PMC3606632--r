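---
title: "5'-SAGE tag profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{5'-SAGE tag profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagetag)
```

# The method

5'-Serial Analysis of Gene Expression (5'-SAGE) reads out the first
15-20 bases of each mRNA. Each sequenced unit is a *ditag*: two 5' tags
ligated tail-to-tail between adapters, ~100 bp in total, well matched to
short pyrosequencing reads. Because a 5' tag starts at the transcript's
first base, its genome-mapped position is simultaneously an expression
count and a transcription start site (TSS) observation. `sagetag`
implements the complete digital-profiling chain for a two-condition
design -- here labelled `Myc` (vegetative mycelium) and `S1-Pri` (stage 1
primordium), the two developmental stages of the fruiting-body
transition in the model mushroom *Coprinopsis cinerea* that motivated
the pipeline:

1. **Extraction** -- Phred-based read filtering, ditag splitting by exact
   adapter/linker match, collapsing to tag counts, singleton removal.
2. **Mapping** -- exact (mismatch-free) matching of every distinct tag to
   both genome strands, with multiplicity classes (unique / 2-4 / 5-10 /
   >=11 matches / unmapped). Only uniquely mapped tags go further.
3. **Annotation** -- classification of each tag position against gene
   models into sense/antisense x 5'-UTR/CDS/3'-UTR categories, and
   per-gene TSS catalogues with preferred sites.
4. **Expression and testing** -- tags per 100,000 (tphk) per gene, and a
   pairwise Fisher exact test per gene between the two libraries.
5. **Enrichment** -- one-sided hypergeometric domain enrichment of DEG
   sets, and lineage-specificity classification from tabular homology
   reports.
6. **Validation** -- Pearson agreement of log2 ratios across platforms
   (5'-SAGE, microarray, real-time RT-PCR).

A synthetic-data module generates toy genomes, gene models and read sets
with known ground truth, so that every stage is testable offline and the
statistical procedures can be calibrated.

# Models and conventions

## Coordinates

All coordinates are 1-based inclusive. A tag's reported position is its
5'-end base *in transcript orientation*: the leftmost base of a
plus-strand hit and the rightmost base of a minus-strand hit. With this
convention the mapped position of a 5' tag *is* its candidate TSS, and
minus-strand genes use mirrored offset arithmetic.

## Promoter and UTR windows

Gene models carry translation coordinates only, so UTRs are operational
windows: the putative 5'-UTR is the 500 bases immediately upstream of
the start codon (offsets -500..-1) and the putative 3'-UTR the 500 bases
downstream of the stop codon (+1..+500). Windows are clipped at
chromosome ends and keep their category. A tag 501 bases upstream of the
only nearby gene is `unclassified`.

When a position falls inside windows of several genes the category
priority is `utr5_sense > cds_sense > utr3_sense` followed by the same
order for antisense, with the nearest start codon as the final
tie-breaker. Assigning each tag to exactly one gene keeps the seven
categories an exact partition of the uniquely mapped total -- every
summary percentage column sums to 100. The alternative (crediting both
genes) would break this conservation property, which the tests rely on.

## Expression unit and test

Expression of a gene is the occurrence sum of its `utr5_sense` tags
divided by the library denominator, times 100,000 (tphk). The
denominator is the *uniquely genome-mapped* occurrence total of the
stage: the phrase "all genome-mapped tags" is ambiguous between this and
the total valid tags, and the unique total is the one consistent with
barring multi-mapped tags from every other step; it is configurable.

Differential expression uses the two-sided Fisher exact test on the
table `(count_myc, total_myc - count_myc; count_pri, total_pri -
count_pri)` at unadjusted p < 0.05. Two-sidedness follows the
minimum-likelihood rule: the p-value sums all hypergeometric point
probabilities not exceeding the observed one (relative tie tolerance
1e-7). Optional Benjamini-Hochberg adjustment is provided but off by
default, matching the unadjusted convention of the original analysis.
No dispersion-modelling framework is used on purpose: the artifact
reproduces the classical digital-SAGE procedure, not a modern count
model, and with single libraries per stage there is no replicate
dispersion to estimate.

## The zero-replacement log2 ratio

Log2 ratios are formed on tphk values after replacing exact zeros by
`pseudo_tphk = 1.0`. This convention is reverse-engineered from the
published per-gene tables: genes silent in one stage print ratios equal
to `log2(tphk/1)` (for instance 879.2 vs 0.0 prints 9.78, and 0.0 vs
620.5 prints -9.28), which pins the zero-replacement value at 1.0 tphk.
For rows with small nonzero minority counts the printed ratios are
consistent with computation from unrounded tphk, so only zero-count rows
are treated as exact references.

```{r}
log2_ratio(879.2, 0.0)   # printed as 9.78
log2_ratio(0.0, 620.5)   # printed as -9.28
```

## Enrichment and lineage rules

Domain enrichment is one-sided (over-representation), per domain, on
ORF-level presence/absence -- an ORF carrying a domain twice counts
once. Assignments are pre-filtered at e < 1e-20, the threshold used for
conserved-domain assignment. DEG sets must be subsets of the ORF
universe; violations are reported by name.

Lineage classification consumes per-species best e-values from
12-column tabular homology reports. Hits with e > 1e-2 are discarded as
dissimilar; e < 1e-10 indicates homology. A DEG is
`basidiomycete_unique` when at least two fruiting-body-forming species
show homologs and no outgroup species has any hit at e <= 1e-2;
`species_unique` when no species shows a homolog; otherwise `neither`.
Any outgroup hit at e <= 1e-2 forces `neither` even without strong
homology anywhere -- weak broad conservation is evidence against
lineage-specificity. The query genome is excluded from the reports, so
self-hits never count.

## Cross-platform validation

Pearson correlation on log2 ratios, complete-case per platform pair,
with at least 3 pairs required. Pearson (not Spearman) is used because
the quantities are already log-scaled fold changes and the reference
analysis reports product-moment-style correlations. The 18-gene panel
(5'-SAGE, microarray, real-time RT-PCR columns) ships with the package
so the stage runs offline. Note that Pearson on the panel columns
yields 0.958 (SAGE~qPCR) and 0.793 (SAGE~microarray), whereas the
published footer alongside those columns states 0.936 and 0.792 --
values not recoverable from the printed (rounded) columns under any
correlation variant we tried, presumably computed on unrounded data.
The package reports what the shipped panel actually gives.

# The synthetic-data generator

The generator stands in for the deposited reads and the 37.5 Mb genome
assembly at desk scale. Its defaults define the study conditions used by
the tests:

* **Genome**: 3 chromosomes x 35 kb, GC 0.5, 30 genes of 0.9-2.1 kb with
  at least 1.1 kb between gene spans -- the gene density of a compact
  fungal genome (one gene per ~3 kb). The 1.1 kb minimum spacing also
  guarantees that one genomic position can carry at most one gene's
  window, making error-free round-trips exact. Every gene's
  [start-500, stop+500] window lies inside its chromosome; infeasible
  packings fail with an explicit error. An optional
  `duplicated_region_fraction` copies a segment over gene-free ground to
  create genuine multi-mapping tags.
* **Expression truth**: log-normal baseline abundances (sdlog 1.2, the
  heavy-tailed shape typical of digital tag libraries); a third of genes
  differentially expressed with linear folds 3-8, mirroring the
  reported "almost one-third" DEG prevalence and the predominance of
  >3-fold changes. DEGs are built in up/down pairs sharing a baseline
  and a fold, so both stages' expected shares sum to exactly 1, non-DEG
  genes keep exactly equal shares, and each DEG's realised log2 fold
  equals its drawn fold (an odd DEG is balanced by shifting baseline
  mass within one pair, preserving every ratio).
* **TSS profiles**: one or two sites per gene, the primary within 200 bp
  upstream of the start codon (where most observed TSSs concentrate),
  the secondary anywhere in the 500 bp window, with primary weight
  0.55-0.85 -- "an array of TSSs with one or two preferred sites".
* **Reads**: two libraries of unequal depth (default 2,000 and 3,000
  ditags, emulating the 107k/146k-tag asymmetry of the source libraries
  at reduced scale); each read packages two tags
  (`adapter5 + tag + linker + revcomp(tag) + adapter3`, ~100 bp); tag
  length uniform 15-20 bp; per-base substitution errors at a
  configurable rate applied to tag bases; constant Q40 qualities except
  a degraded-read fraction (default 2%) at Q8 to exercise the filter.
  The internal ditag orientation (second tag reverse-complemented after
  a fixed linker) and the adapter sequences are modelling choices: the
  library chemistry does not prescribe readable adapter sequences, and
  tail-to-tail blunt ligation is the simplest geometry consistent with
  it. Antisense tags (default 15% of a gene's tags) are drawn uniformly
  from the gene body on the opposite strand.

## What the generator does not emulate

No splice junctions (junction-spanning tags, a minor unmapped class in
real data, never arise), no strain-difference mismatches, no PCR or
sequence-composition bias, no RNA secondary structure. Unmapped tags
arise only from sequencing errors, and multi-mapping only from
configured duplications. Consequently the synthetic mapping-class
percentages are far cleaner than the ~80% unique / 7% multi / 11%
unmapped split of real libraries, and passing round-trip tests shows the
bookkeeping is exact -- not that the pipeline handles every artefact of
real pyrosequencing data.

A further honest observation from the toy runs: uniformly placed
antisense tags rarely recur at the same position, so the singleton
filter removes almost all of them. Real antisense transcription shows
positional preference (recurrent antisense tags at the same coordinate
in both libraries); modelling antisense TSS profiles would be needed to
emulate the reported double-digit antisense percentages after singleton
removal.

# Numerical and procedural choices

* Singleton tags are removed per library after collapsing and before
  mapping; the original description lists the filter with extraction and
  does not order it relative to mapping, so the order here is a
  documented choice, not an inference about the authors' intent.
* Quality thresholds default to mean >= 20 and min >= 10; no published
  cutoff exists.
* Mapping is hash-table lookup (per tag length, both strands) -- exact
  matching at toy scale needs no suffix structures; the contract is
  exact-match completeness, verified against a naive full-scan oracle.
* Mapping-class percentages are occurrence-weighted (a tag seen 12 times
  contributes 12), which makes classes sum exactly to the library total;
  whether the reference percentages were occurrence- or tag-weighted is
  not stated.
* Tags containing N are invalid at extraction (`bad_tag_length`): exact
  matching cannot place them.
* "Preferred TSS" is operationalised as: the top-count site always, plus
  the runner-up when its count is at least half the top count; ties
  rank deterministically by coordinate.
* Fisher p-values use `dhyper` sums; the test suite checks them against
  exhaustive binomial-coefficient enumeration for all tables with
  margins up to 60 (at 1e-9) and against `stats::fisher.test` on random
  tables.
* Degenerate Fisher tables (any zero margin) return p = 1.
* DEG direction is decided by the count proportions, not the sign of the
  pseudo-count log2 ratio, so a direction is defined even when both tphk
  values are tiny.

# Calibration results the tests compute

The acceptance suite simulates the study conditions at these sizes
(chosen to keep the whole suite fast while leaving thousands of tests
per calibration): a null design with 2,500 equally expressed genes at
50,000/75,000-tag depths for the type-I check (empirical false-positive
fraction must stay <= 0.06 at unadjusted p < 0.05; the discrete Fisher
test is conservative, so the observed fraction sits well below the
nominal 5%), and a 500-gene design with 30% DEGs at a fixed 8-fold for
power (>= 90% detection among DEGs with expected up-stage counts >= 30)
and ratio recovery (median absolute log2 error < 0.35 among DEGs with
expected counts >= 50). The round-trip suite runs the full read-level
chain (two libraries, 1,200/1,800 ditags, error-free) and demands exact
multiset recovery of emitted tags, unique mapping to recorded origins,
and exact category/class partitions.

# Known limitations

* Exact-match mapping only; a single sequencing error unmaps a tag
  (real analyses accept this -- it biases against error-rich tags).
* Two libraries without replicates: the Fisher test treats tag sampling
  as the only noise source, as in the classical SAGE literature.
* The GO/KEGG annotation layers of the original study depend on external
  services and are out of scope; enrichment here covers domain tables
  and homology reports supplied as files.
* With very short toy genomes there is a small chance that a random
  15-mer recurs by chance and turns an emitted tag into a multi-mapper;
  the default 105 kb genome keeps the expectation of such collisions
  well below one tag per run.

# Reproducing the analysis

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` ... `07_validation.R`) that run the chain on the
default synthetic study and write their tables under `results/run/`;
`scripts/acceptance.R` recomputes the published reference quantities.
The same flow is available programmatically:

```{r, eval = FALSE}
cfg <- default_run_config("results/pipeline_demo", seed = 1)
manifest <- run_pipeline(cfg)
```
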