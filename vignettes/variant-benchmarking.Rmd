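---
title: "Methods: haplotype-aware benchmarking of germline variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-aware benchmarking of germline variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varbench)
```

## The problem

A clinical laboratory validating a germline variant calling pipeline must
show, over its reportable range, how often the pipeline finds the variants
that are really there (recall/sensitivity), how often its calls are real
(precision), and how reliably it stays silent where the genome matches the
reference (negative percent agreement, NPA). The inputs are a query
callset, a gold-standard truth set restricted to high-confidence regions,
and one or more regions of interest; the outputs are stratified
TP/FP/FN/UNK classifications and the derived metrics.

The technically hard part is deciding when a query call and a truth call
are *the same variant*. VCF permits many spellings of one event: an MNP
can be written as adjacent SNPs, an InDel inside a repeat can sit at any
position in the run, alleles can carry redundant reference padding. A
naive positional join miscounts all of these. `varbench` therefore
compares *local haplotypes*, not records.

## Classification procedure

1. **Decomposition.** Multi-allelic records are split into biallelic
   records per alternate allele actually carried by the genotype
   (`1/2` becomes two heterozygous records; uncarried alleles and `0/0`
   genotypes are dropped). All downstream genotypes index alleles {0, 1}.
2. **Normalization.** Shared allele suffix then prefix are trimmed
   (keeping one anchor base per side for length-changing records), and
   InDels are left-shifted one base at a time while the *same allele
   strings* still match the reference at the shifted position and spell
   the same alternate haplotype. On `CATTTTG`, the deletion `TT>T` at
   position 4 normalizes to position 3 — the start of the homopolymer
   run. Note this convention anchors inside the run rather than on the
   preceding base (where `vt`/`bcftools norm` would place it, as `AT>A`
   at position 2). Both truth and query pass through the same function,
   and matching is haplotype-based, so only internal consistency matters;
   the choice keeps the shift rule and its brute-force check elementary.
   Normalization is idempotent and preserves the spelled alternate
   chromosome (both are property-tested).
3. **Evaluation region.** The intersection of the high-confidence region
   with the region of interest (the ROI alone when no confidence region
   is given). Records whose normalized footprint does not overlap it are
   labeled UNK: written to the annotated output, never counted. An empty
   intersection is a configuration error, not an empty result.
4. **Clustering.** Truth and query records enter one proximity graph:
   records whose reference footprints lie within `window` bases (default
   30) join the same cluster, by transitive closure. Representation
   ambiguity is local, so equivalence only needs to be decided per
   cluster. Clusters with more than `max_cluster_size` members on one
   side (default 8, bounding phase enumeration at 2^7 per side) are split
   at their largest internal gap, left-most on ties — a deterministic
   tie-break, required for byte-identical reruns.
5. **Matching.** For each paired cluster, every phase assignment
   consistent with the genotypes is enumerated on each side (homozygotes
   on both haplotypes, phased heterozygotes fixed, unphased free);
   each assignment spells the cluster's span into an unordered pair of
   haplotype sequences. If the two sides share any spelled pair, all
   members on both sides are TP. If one side is empty, the other side's
   members are FP (query) or FN (truth). Otherwise matching falls back
   to exact representation: records equal in (chrom, pos, ref, alt) with
   equal genotype are TP; with unequal genotype the truth record counts
   FN and the query record FP — no partial credit for genotype errors.
   Assignments placing overlapping alleles on one haplotype are skipped;
   a cluster with no consistent assignment falls back to exact matching
   with a warning.
6. **Tallies.** TP is counted separately on the truth side (recall
   numerator) and the query side (precision numerator); the two differ
   exactly when representation splits match unequal record counts, e.g.
   one query MNP against two truth SNPs. Counts are kept per variant
   type (SNP, MNP, INDEL) and per InDel size bin.

## Metrics

With region base count $N$:

$$\mathrm{precision} = \frac{TP_q}{TP_q+FP},\quad
  \mathrm{recall} = \frac{TP_t}{TP_t+FN},\quad
  TN = N - (TP_q+FP+FN),\quad
  \mathrm{NPA} = \frac{TN}{TN+FP}.$$

The recall denominator is $TP+FN$ as the formula states, not a separately
reported "truth total" column — published benchmarking tables sometimes
carry a truth total that differs from $TP+FN$ because of tool-internal
bookkeeping, so the package treats (TP, FP, FN) as the primary tallies
and truth totals as an independent count. Undefined ratios (0/0) are
reported as `NA`, never 0 or 100, so empty strata cannot bias a report.
Values are stored at full precision; rendering is the writer's concern
(2 decimals half-up by default, with an integer option for NPA because
validation tables conventionally print NPA as "100"; whether such a
printed "100" was rounded or truncated is ambiguous, so the nearest-
integer convention is used). Merged size bins (e.g. 1–20 from 1–10 and
11–20) sum the counts and recompute — percentages are never averaged.

`indel_size` is $|\,\mathrm{len}(alt)-\mathrm{len}(ref)\,|$ after
normalization; 0 marks non-length-changing records, which are excluded
from InDel binning (MNPs are reported as their own type instead).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 30 bp | clustering distance; covers the 1–20 bp reportable InDel range with margin |
| `max_cluster_size` | 8 | per-side member bound; caps enumeration at 2^7 phasings per side |
| `flank` | 20 bp | ROI padding, pulling canonical and non-canonical splice sites into exon regions |
| `bins` | 10, 20, 50 | upper edges of the closed InDel size bins (1–10, 11–20, 21–50, >50) |
| `pass_only` | TRUE | drop non-passing query records; clinical assays report only passing calls |
| `chr_harmonize` | FALSE | strip "chr" prefixes; by default disjoint contig namespaces are a hard error |

Truth records are accepted regardless of FILTER (truth sets are already
restricted by their confidence regions); query records honor `pass_only`.
Deep-intronic additions to the clinical ROI are unioned unpadded — they
are defined by pathogenic sites, not by splice-site geometry.

## The synthetic test bed

`generate_fixture()` plants a known answer: a random contig (12 kb by
default), truth = TP ∪ FN units, query = TP (optionally re-represented)
∪ FP units, plus query-only records outside the ROI that must surface as
UNK. Planted units sit ≥160 bp apart — beyond any planted footprint plus
the cluster window — so each unit's intended label is recovered
independently; the generator's ledger is the oracle, and classification
must reproduce it *exactly*, not approximately. Re-representations
exercise the matcher: reference-base padding, right-shifted InDels inside
deliberately forced homopolymer runs, and MNP↔SNP splits. A fixed seed
gives byte-identical files; per-stage sub-seeds are derived from it so
adding one output does not reshuffle the others.

What the generator does *not* emulate: sequencing error profiles,
coverage-dependent genotype quality, clustered variation in repeats and
segmental duplications, reference bias, or realistic variant density.
Passing the recovery and invariance properties shows the comparison
engine is correct on well-separated, well-formed calls; it does not show
how a pipeline behaves in the genome's hard regions, which is precisely
what running the benchmark on real reference samples measures.

`plant_getrm_fixture()` rebuilds six published GeT-RM clinically
relevant variants (three of them within seven bases of each other on
chromosome 15) on short toy contigs, with the GRCh37 offsets recorded in
the manifest — a synthetic stand-in for the real cell-line callsets,
used to test verification semantics.

## Verification of named clinical variants

`verify_variants()` answers "is this variant present?", robust to
representation: the assertion's own alternate haplotype is spelled over a
local window (±30 bp), and the verdict is Yes when some *subset* of the
nearby query records, applied jointly to one haplotype, spells the same
sequence. Subset search rather than whole-cluster equality is what lets
three adjacent pathogenic variants verify independently — each assertion
picks out its own records and ignores its neighbours. Query MNPs are
split into per-base SNP primitives first, so an MNP call verifies an
assertion for any constituent substitution. Zygosity is checked only when
the assertion specifies it; presence tables conventionally do not.

## Numerical and degenerate-input choices

- Coordinates: VCF positions are 1-based; BED intervals 0-based
  half-open. The single audited conversion for pathogenic-site
  containment lives in one function, since off-by-one there is the
  classic failure mode.
- Book-ended intervals merge (as `bedtools merge` does); base counts are
  only reproducible under a fixed convention, and merging is the
  conservative one for NPA.
- Reference bases are uppercased on load; soft-masking never affects
  comparison.
- Missing genotypes (`./.`) are dropped with a logged count rather than
  an error — truth VCFs commonly contain half-calls outside their
  confidence regions. No other record is ever silently dropped.
- Half-up rounding (`floor(100x + 0.5)/100`) for rendering, because
  base R's round-half-to-even disagrees with how validation tables are
  printed.
- A derived TN < 0 (counts exceeding the region size) is an
  inconsistency error, never clamped.
- Reports contain no timestamps; identical inputs give byte-identical
  report bodies, and samples/ROIs are iterated in sorted order so input
  listing order cannot change the output.
- A failing sample × ROI stratum is logged and skipped; the remaining
  strata still run (the deliverable of a validation run is the
  multi-sample report) and the run status records the partial failure.

## Test problem sizes

The property suite runs at desk scale, chosen so the full suite stays in
the low minutes: 200 seeded fixtures (8 kb contigs, 3–25 planted units
each) for exact planted-count recovery, 40 perturbation-only fixtures for
representation invariance, 250 random cluster pairs of up to 4 variants
per side checked against an independent exhaustive phasing enumeration,
30 randomized region-set pairs for the inclusion–exclusion identity, and
two full orchestrator runs compared byte-for-byte.

## Known limitations

- The matcher decides equivalence per proximity cluster; a global
  graph-based comparison over arbitrarily long phase ranges (as the
  GA4GH reference implementations perform) can in principle rescue
  matches that span more than `window` bases of reference-identical
  sequence.
- Quality-score ROC stratification is out of scope; the classification
  is binary in the FILTER field.
- Structural variants, gVCF blocks, multi-sample cohort VCFs and
  CRAM/BAM-level evidence are out of scope.
- Phase sets are not parsed; all phased genotypes in one cluster are
  assumed to share a phase frame. At cluster scale (≤ tens of bases)
  this is almost always true, and unphased enumeration is exact anyway.
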