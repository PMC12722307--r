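---
title: "Classifying substrain variants and selecting RCC markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying substrain variants and selecting RCC markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(substrainr)
```

## The problem

Two colonies of the same inbred strain maintained by different vendors drift
apart only through spontaneous mutations that reach fixation. Comparing
whole-genome variant calls between such substrains therefore produces two
very different signals. First, a large set of variants *shared* by both
substrains relative to the reference genome — the legacy of their common
ancestor — which should be almost entirely homozygous if the lines are fully
inbred. Second, a small set of *substrain-unique* variants, the raw material
for mapping phenotypic differences between the substrains in a
reduced-complexity cross (RCC). An RCC needs a genome-wide panel of markers
that are homozygous for opposite alleles in the two parents, so the final
step is to thin the unique SNPs to one reliable marker per genomic window.

`substrainr` implements this downstream analysis. Upstream read alignment
and variant calling are out of scope: the package consumes the joint
small-variant VCF, the SV VCF, the soft-masked reference FASTA, per-base
depth tracks and an exclusion BED that such a pipeline produces.

## Classification model

Every jointly called record is assigned exactly one category, which makes
the classification a partition and lets the counts be audited end to end:

* **shared** — both samples carry the identical non-reference genotype
  (allele order and phasing are normalised first, so `1/0` equals `0/1`);
* **unique_A** / **unique_B** — the carrier is non-reference while the
  other sample is homozygous reference at the same jointly called site;
* **discordant_other** — both non-reference but different (e.g. `1/1` vs
  `1/2`); these are reported rather than silently merged into "unique",
  because neither the shared nor the unique definition covers them;
* **discarded** — failed a filter, with the reason retained
  (`excluded_region`, `qual`, `filter`, `low_gq`, `missing_genotype`,
  `hom_ref_both`).

Filters are applied in a documented order (excluded region → joint QUAL →
SV FILTER) so the first reported reason is deterministic. Small variants
are filtered on the joint quality score and per-sample genotype quality;
VCF FILTER is ignored for them. Structural variants carry no GQ in typical
long-read pipelines, so `FILTER = PASS` stands in for the genotype-quality
requirement.

Two threshold subtleties are deliberate and configurable
(`classification_config()`):

* QUAL must *exceed* 30 (strict), and GQ on shared variants must exceed 30;
* GQ on strain-unique variants (and marker candidates) passes at
  *exactly* 30 (inclusive ≥ 30).

The source descriptions of these rules use both phrasings ("exceeding 30"
vs "≥ 30"); we adopt the strict reading for the shared set, where the
cost of a false positive is low, and the inclusive reading for the unique
set, whose published selection rule is stated with "≥". Both appear in the
configuration so either convention can be forced. A missing GQ always fails
a GQ threshold — quality is never imputed.

Multi-allelic records are never split into biallelic rows: the rules above
operate on genotype identity, which is well defined on the full genotype
tuple. SNP/indel classing follows common caller usage: SNP iff the
reference and all *called* alternate alleles have length 1 and are not
symbolic; symbolic alleles are SVs only when the record carries `SVTYPE`.

**Divergent-base accounting.** Each non-discarded variant affects
`affected_bases()` ≥ 1 positions: 1 for a SNP, the largest ref/alt length
difference over called alleles for an indel, and `|SVLEN|` for an SV
(unresolvable SV lengths count as 1, with a warning). The divergent-site and
divergent-base totals sum these over the strain-unique categories.

**Homozygosity.** Per category the homozygosity percentage is
`homozygous / total × 100`, with "homozygous" judged on the carrier
genotype. The heterozygous share of shared variants is the complementary
inbreeding diagnostic.

## Coverage statistics

Depth arrives as bedGraph-like interval tracks (0-based half-open, the
format's convention). All statistics are position-weighted with no
sampling, so they are invariant under interval refinement — splitting an
interval in two changes nothing, which is also tested as a property. The
median is the lower median for even position counts and the SD is the
population (denominator *n*) standard deviation, both computed on weighted
intervals without per-base expansion. Coverage bins are integer-depth bins
zero = 0x, low = 1–10x, medium = 11–30x, high ≥ 31x; the boundaries are
exposed in `coverage_bins()` because the two published phrasings of the
bins ("<10x" vs "≤10x") disagree and we follow the procedural (Methods)
wording. The genome-wide summary is defined as the summary of the
concatenated track and is tested to be exactly that.

## Impact triage

SnpEff's `ANN` field is parsed into (allele, effect, impact, gene,
transcript) entries; the severity order is HIGH > MODERATE > LOW >
MODIFIER, and a record with no annotation defaults to MODIFIER. A variant
contributes to exactly one (category, max-impact) cell. Because one variant
can hit several genes at its top impact, the reports list one row per
(variant, gene) and the cell counts carry *both* tallies — distinct
variants and distinct genes. The effect table for substrain-specific
variants counts each variant once under its single most severe effect, with
ties broken by ANN order (the published effect totals are consistent with
per-variant counting); a per-annotation tally is emitted alongside for
transparency.

## Marker selection

Candidates are biallelic strain-unique SNPs with genotypes exactly `1/1` in
one substrain and `0/0` in the other (so `2/2` vs `0/0` and heterozygous
carriers are excluded), GQ ≥ 30 in both samples, and positions outside
soft-masked (lowercase) reference intervals — repeat regions are hard to
assay. Windows are fixed, non-overlapping, anchored at position 1 of each
chromosome: `window_index = floor((pos − anchor) / window_size)` with a
3-Mb default. Fixed tiling is the simplest reproducible reading of
"one SNP per 3-Mb window"; anchor and size are configurable, so a 0-anchored
grid is one argument away.

Within each non-empty (chromosome, window) cell the candidate with the
highest *average* GQ — the arithmetic mean of the two samples' GQs — is
selected. The published rule specifies no tie-break, so we impose a total
order: higher minimum GQ first (the more balanced call), then the smaller
position. Selection is therefore deterministic and byte-identical across
runs, which the tests check, along with agreement with a brute-force
per-window arg-max oracle and the set inclusions
panel ⊆ candidates ⊆ unique homozygous-discordant SNPs.

## The synthetic data generator

`simulate_substrains()` builds a complete, truth-labelled desk-scale
dataset: a 5-contig soft-masked reference (four autosome-like contigs plus
a Y-like one, 6.5 Mb each — longer than two marker windows, so window
boundaries are exercisable), a joint small-variant VCF, an SV VCF, two
depth tracks, a mask BED, an excluded-regions BED and a truth CSV with one
row per emitted record.

Defaults are chosen to emulate the statistical structure of a real
substrain comparison, scaled down roughly 1000-fold:

| parameter | default | rationale |
|---|---|---|
| shared SNP / indel / SV counts | 3000 / 600 / 100 | ~5:1 SNP:indel ratio of real shared calls |
| `shared_het_fraction` | 0.036 | 96.4% homozygosity expected in inbred lines |
| unique counts (A; B) | 506/228/22; 699/279/28 | published per-strain unique counts ÷ 10 |
| `gq_below_fraction` | 0.10 | GQ mixture mass below the 30 threshold, so filters do real work |
| `sv_pass_fraction` | 0.85 | non-PASS SV calls are a visible minority |
| `impact_mix` | 1/5/6/88% | intergenic/intronic MODIFIER dominance of real annotation |
| SV length | 50 bp + Exp(mean 270), ≤ 10 kb | short-event-dominated size spectrum implied by published divergent-base arithmetic (mean ≈ 320 bp) |
| `zero_frac_y` | 0.347 | Y-like contig with 34.7% zero coverage; autosomes 0.5% |
| `depth_mean` | 39.2x / 41.9x | ~40x long-read coverage per sample |
| `softmask_fraction` | 0.10 | enough masked sequence that mask exclusion is consequential |

Positions are drawn uniformly with a 10-bp guard band between variants —
simplicity over realism; there is no mutation-rate map. ANN strings come
from a fictitious interval gene model per chromosome so that effect labels
are internally consistent with positions: coding impacts (HIGH / MODERATE /
LOW) are placed inside genes, MODIFIER variants anywhere (intronic if they
land in a gene, intergenic otherwise). Depth tracks are piecewise-constant
with ~5-kb segments; the zero-coverage total per contig is planted exactly,
so the zero-bin percentage is recovered to the decimal. The generator keeps
two small strips of chr1 (positions 1–1000 and the 3-Mb window boundary
± 100 bp) clear of random content so that `plant_edge_cases()` can add its
guaranteed boundary records — GQ exactly 30 under both threshold
conventions, QUAL exactly 30, a shared heterozygote, a `1/1` vs `1/2`
discordance, a masked discordant SNP, a non-PASS SV, a missing genotype,
and SNPs at positions 3,000,000 and 3,000,001 — at fixed coordinates
without collisions.

The truth table records, per variant, the intended category *and* the
category the default thresholds should assign given the planted qualities
(`expected_category`), plus a marker-candidacy flag. Tests assert exact
recovery of both: with every planted quality above threshold the pipeline
must reproduce the truth with zero mismatches, and with sub-threshold
values planted, exactly those records must be discarded.

What the generator does **not** emulate: linked variants or LD structure,
realistic repeat families (mask runs are random exponential-length
intervals), mutation-rate heterogeneity, multi-sample cohorts, genotyping
error correlated with depth, or read-level artefacts. Passing tests
demonstrate the correctness of the *rules* — filtering, classification,
accounting, selection — on data with the right marginal structure, not the
behaviour of upstream callers on real genomes.

## Numerical and engineering choices

* Intervals are Bioconductor `IRanges` (1-based, closed) internally;
  BED and bedGraph input convert at the boundary, and the converters are
  tested as inverse bijections on the 1 ↔ 0 boundary. VCF positions stay
  1-based throughout.
* VCF parsing uses `vcfR`; whole files are held in memory as plain
  data.frames. At the package's design scale (10^3–10^6 records) this is
  simpler and faster than streaming, and every operation is vectorised or
  grouped on the table.
* Writing VCF is a small dedicated emitter whose output round-trips through
  the readers field-for-field (tested), including NA QUAL/GQ as `.`.
* Degenerate inputs: empty variant tables classify to empty results; empty
  VCFs parse; an empty BED yields an empty mask; an empty depth track is an
  error (there is no defensible summary of nothing); a depth track that
  does not tile its contig is an error rather than a silent renormalisation.
* Determinism: the generator consumes a single seed, and
  identical seeds give byte-identical output files; pipeline re-runs on
  identical inputs produce identical summary files (checksummed in tests).
* The test suite and the acceptance script use desk-scale problem sizes —
  a ~5,500-variant default cohort on a 32.5-Mb genome, 100 random
  marker fixtures of up to 10,000 candidates, coverage oracles on ≤ 100-kb
  contigs — chosen so the full suite completes in a few minutes while still
  exercising every rule and boundary.
* The package's interface is its exported functions
  (`run_config()`/`run_pipeline()` orchestrate the full analysis); the
  acceptance script under `scripts/` is the runnable entry point for
  reproducing the headline numbers.

## Known limitations

* "Unique" requires the non-carrier to be homozygous reference at a
  jointly called site; sites missing from the joint VCF entirely (private
  to one caller run) never reach the classifier.
* Heterozygous strain-unique variants are admitted as unique but flagged by
  zygosity; whether a real analysis should keep them is a judgement call —
  they are excluded from marker candidacy regardless.
* Unique-SV site coverage is taken from the record's per-sample `DP` when
  present; no pileup recomputation is attempted.
* The divergent-base total adds `|SVLEN|` at face value; overlapping or
  nested SVs would be double-counted (none are generated synthetically).
* Published genome-wide counts from the real dataset (millions of shared
  variants, the 500-marker panel) are not reproducible here by design: they
  require the deposited sequencing data and the upstream callers, which are
  out of scope.
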