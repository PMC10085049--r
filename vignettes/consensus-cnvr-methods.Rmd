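---
title: "Consensus construction of high-confidence CNVR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus construction of high-confidence CNVR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrcons)
```

## The problem

Copy-number variants (CNV) — deletions and duplications of genomic segments —
are called from two very different kinds of evidence: whole-genome sequencing
(read depth, discordant read pairs, split reads) and SNP-array intensity
signals (Log R Ratio and B-allele frequency). Every caller produces false
positives, and the two platforms fail in largely independent ways. A standard
strategy in livestock genomics is therefore to keep only copy-number
variation *regions* (CNVR) supported by more than one caller and more than
one molecular technique. `cnvrcons` implements this strategy as a tested,
reusable pipeline: it parses the native output of CNVnator, DELLY and
PennCNV, applies the per-caller retention rules, and constructs two
high-confidence region sets whose union is the final call set.

## Region construction

All internal coordinates are 1-based inclusive, the convention shared by
VCF, CNVnator and PennCNV output; BED's 0-based half-open coordinates are
converted only at the file boundary. Overlap lengths use inclusive
arithmetic: `ov = min(end_a, end_b) - max(start_a, start_b) + 1`.

**Merging.** A CNVR is a connected component of the call-overlap graph:
calls overlapping by at least 1 bp — directly or through a chain of
intermediates — form one region spanning `min(start)`–`max(end)`.
Book-ended intervals share 0 bp and never merge. For the default 1 bp rule
this is computed with a linear sweep over position-sorted calls; for a
stricter `min_overlap_bp` the pipeline falls back to explicit connected
components, because a sweep is only equivalent to graph connectivity at
the 1 bp threshold.

**Region type.** A region whose member calls are all deletions is a
DELETION, all duplications a DUPLICATION, and any mixture a COMPLEX region.
The type is always re-derived from the full member set, so a deletion
matched against a duplication across callers yields COMPLEX.

**Reciprocal overlap (RO).** For two intervals, the overlap length divided
by each interval's length; the pair's RO is the minimum of the two
fractions. RO ≥ 50% is the *equality* criterion used for every cross-set
decision: matching the two WGS callers, matching array against WGS
consensus, and comparing against external catalogues.

**The two high-confidence sets.**

* `CNVR_SEQ`: each WGS caller's filtered calls are merged per caller; a
  cross-caller RO ≥ 50% match is required, and matched clusters are merged.
* `CNVR_GEN`: the filtered PennCNV calls merged at ≥ 1 bp.
* `CNVR_POP` (population level): GEN and SEQ regions matched at RO ≥ 50%;
  each transitive match cluster becomes one region; regions carried by at
  least 5% of the population are kept.
* `CNVR_ANI` (per animal): for every animal with both platforms, PennCNV
  and CNVnator calls that reciprocally overlap ≥ 50% *within that animal*
  are retained, pooled across animals, and merged at ≥ 1 bp.
* `UNIQUE`: the ≥ 1 bp merge of POP ∪ ANI, with each region recording
  whether POP, ANI or both contributed.

**Resolving many-to-many matches.** RO matching can pair one region with
several. The pipeline resolves match edges by transitive clustering
(union-find over the match graph) and reports the *span union* of each
cluster. Alternatives — keeping only the GEN or only the SEQ interval, or
the intersection — were considered; the span union was chosen because it
is the only option under which every supporting call is contained in the
reported region, mirroring the ≥ 1 bp merge philosophy.

**Carrier frequency.** The frequency of a region is `|carriers| / n`,
where carriers is the union of sample ids over all member calls and `n` is
an *explicit* population-size argument, never inferred from the data. The
default denominator in the pipeline is the genotyped cohort (the QC-table
row count): the genotyped population is the largest cohort in which
presence/absence can be assessed, and a polymorphism threshold such as 5%
is conventionally defined against it. The sequenced cohort (or the union)
can be selected via `frequency_denominator`.

## Per-caller retention rules

| Parameter | Default | Applies to | Meaning |
|---|---|---|---|
| `min_size_bp` / `max_size_bp` | 1 000 / 5 000 000 bp | all | inclusive size window |
| `cnvnator_max_p` | 0.05 | CNVnator | e-value of the read-depth t-test, retain `p <` |
| `cnvnator_max_q0` | 0.5 | CNVnator | fraction of zero-mapping-quality reads, retain `q0 <` |
| `delly_min_pe` | 5 | DELLY | paired-end support, retain `pe >=` ("more than four read pairs") |
| `penncnv_min_snps` | 10 | PennCNV | markers per call, retain `>=` (strict `>` via `penncnv_strict_gt`) |
| `lrr_sd_max` | 0.30 | PennCNV | per-sample Log R Ratio SD |
| `baf_drift_max` | 0.01 | PennCNV | per-sample B-allele-frequency drift |
| `wf_max` | 0.05 | PennCNV | per-sample waviness factor, compared by absolute value |

Three deliberate readings of commonly ambiguous rules:

* **Size bounds are inclusive** (`1000 <= len <= 5e6`): WGS call sets
  routinely contain calls of exactly 1 000 bp, so "larger than 1 kb"
  behaves inclusively in practice.
* **Marker rule defaults to `>= 10`**: PennCNV call sets filtered this way
  routinely report a minimum of exactly 10 markers, so the operative rule
  is non-strict; the strict reading is available by configuration.
* **Array QC is sample-level**: LRR SD, BAF drift and the waviness factor
  are per-sample summary statistics of the PennCNV workflow, so a failing
  sample loses *all* its calls rather than individual calls being tested.
  The waviness factor can be negative and is compared by magnitude.

DELLY calls observed in a single animal (singletons) are labelled but
retained by default, since singleton counts are reported separately rather
than removed in the workflows this pipeline mirrors; `exclude_delly_singletons`
drops them. No p-value rule is applied to DELLY: the significance test is
a read-depth (CNVnator) concept. CNVnator emits four e-values and the
workflow does not pin down which one is thresholded; the parser stores the
first by default and exposes `e_value_col` to select another.

## The synthetic truth model

Because raw WGS/array data for a real population cannot ship with a
package, every stage is exercised against simulated caller output with
known truth:

* **Genome**: 5 synthetic autosomes of 50 Mb (large enough for hundreds of
  loci, small enough for sub-minute runs).
* **Cohort**: 547 genotyped, 38 sequenced, 36 dual-platform animals — the
  post-QC design of the study population this workflow emulates.
* **Truth loci**: non-overlapping (≥ 10 kb apart, so adjacent loci never
  merge and interval-exact comparisons are possible), log-normal sizes
  (median 80 kb, σ_log = 0.8, clamped to 1 kb–5 Mb), population
  frequencies log-uniform on [0.03, 0.5] — rare variants through common
  polymorphisms above 30%. Carriers are independent Bernoulli draws per
  animal at the locus frequency.
* **Caller emission**: per carrier–locus–platform, a call is emitted with
  probability `1 − fn_rate` if the locus exceeds the platform's
  detectability floor, with Gaussian breakpoint jitter (truncated to stay
  within the chromosome and non-inverted) and occasional splitting into
  two abutting calls. False positives are scattered uniformly at
  `fp_rate_per_Mb`, *independently per platform* — the assumption that
  makes consensus filtering work, and the basis of the precision property
  below. Quality fields (e-values, q0, paired-end support, marker counts)
  are drawn so that calls pass the default filters: the point of the
  simulation is to test what *consensus* removes, not what univariate
  thresholds remove.

The `moderate` preset gives the WGS callers fp rates of 0.3–0.5 per Mb per
sample with sub-kb jitter, and the array caller a 10 kb detectability
floor, 3 kb jitter (marker spacing scale), a 30% miss rate and very few
false positives. The `skewed` preset pushes the WGS false-positive
load and array miss rate to the regime where the dual-platform animals
show two to three orders of magnitude more WGS calls than array calls.
The array false-positive *count per animal* is matched to realistic
per-animal call counts; on a 10×-smaller synthetic genome this makes the
genome-wide density of array regions higher than in real data, which
inflates GEN region spans but not carrier logic.

What the simulation does **not** model: read- or intensity-level signal
(no BAM/IDAT), LD between loci, size-dependent sensitivity curves,
correlated errors between the two WGS callers (both see the same
alignments in reality), reference-genome artefact hotspots, and
chromosome-specific call density. Passing tests therefore demonstrate the
*set logic* — filtering, merging, matching, frequency accounting — not
caller accuracy on real cattle data.

## Metrics

* **Precision** of a region set: fraction of regions overlapping a truth
  locus by ≥ 1 bp.
* **Recovery** of a truth locus: some region overlaps it by ≥ 1 bp.
  Recovery deliberately uses the ≥ 1 bp overlap convention rather than
  RO ≥ 50%: consensus regions legitimately span the union of many
  jittered carrier calls, so a detected locus can sit inside a region
  considerably larger than itself; RO-based recovery would misread that
  span growth as a miss. RO-based recovery remains available via the
  `min_ro` argument.

## Numerical and degenerate-input choices

* Deterministic ordering everywhere: regions sort by (chromosome, start,
  end) with numeric-aware chromosome ordering; region ids are assigned
  after sorting.
* All simulation entry points require an explicit seed and restore the
  caller's RNG state; identical seeds give byte-identical output files.
* Empty inputs propagate as empty outputs (merging an empty call set,
  matching against an empty set), except where emptiness signals a broken
  run: an empty WGS caller input warns and yields an empty SEQ set; a
  missing QC row for a sample with calls is an error.
* A frequency denominator of zero, or smaller than an observed carrier
  count, is an error rather than a silent `Inf`/`>1` frequency.
* PennCNV `cn=2` lines are copy-neutral and rejected; a `length=` field
  disagreeing with the coordinates is a warning and the coordinates win.

## Problem sizes used by the test-suite

The oracle-equivalence tests run 500 random instances of up to 100
intervals against a brute-force pairwise-graph merge and 500 instances of
all-pairs RO matching. The zero-noise end-to-end test uses 40 loci over a
120/18/15 cohort; the consensus-precision property averages 20 replicates
of 50 loci at the full 547/38/36 cohort under the moderate preset. These
sizes keep the full suite in the minutes range while leaving every code
path at realistic density.

## Known limitations

* Coordinates are assumed to be on a single assembly; liftover of external
  catalogues is the user's responsibility and mixed-assembly input cannot
  be detected from coordinates alone.
* Carrier frequency is presence/absence; no copy-number dosage model.
* Gene annotation operates on whole feature spans unless exon sub-intervals
  are provided; QTL significance values are passed through from the source
  database, never recomputed.
* Enrichment analysis (GO/KEGG/MeSH) requires live databases and is out of
  scope; the annotation stage emits the gene lists such tools consume.
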