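# varbench

Benchmarking of germline small-variant calling assays, for clinical
genomics and bioinformatics teams who must establish — and keep
re-establishing — the analytical performance of a variant calling pipeline
before it backs a laboratory-developed test.

Given a query callset (VCF), a truth set (VCF plus high-confidence regions
BED, e.g. a Genome in a Bottle reference sample), and one or more regions
of interest (BED), `varbench` classifies every call as **TP**, **FP** or
**FN** within each stratified region, then derives the validation metrics
from the classification tallies and the region base count *N*:

```
precision = TP / (TP + FP)
recall    = TP / (TP + FN)
TN        = N − (TP + FP + FN)
NPA       = TN / (TN + FP)        (negative percent agreement, specificity)
```

Comparison is haplotype-aware: variants are decomposed to biallelic
records, normalized to a parsimonious left-most representation, clustered
by proximity, and two clusters match when some phasing of each side spells
the same unordered pair of local haplotype sequences. Differences of
representation — an MNP versus its constituent SNPs, shifted InDels inside
repeats, padded alleles — therefore never create false positives or false
negatives. InDel metrics are additionally stratified by size bin (1–10,
11–20, 21–50, >50 bp by default, with user-controlled bin merging), named
clinically relevant variants can be verified individually against a query
VCF, and a multi-sample run is consolidated into a single deterministic
validation report with input checksums.

A deterministic synthetic-fixture generator (toy reference, truth/query
VCF pair with planted TP/FP/FN structure and representation
perturbations, BEDs, assertion tables) ships as a first-class module and
is the test bed for everything else.

## Worked example

Generate a synthetic dataset with 20 planted SNP and 8 InDel true
positives, 3 false positives and 3 false negatives, then score it:

```r
library(varbench)

fx  <- generate_fixture(fixture_config(seed = 2), "fx")
ref <- ref_accessor(fx$paths$reference)
cl  <- classify(read_vcf(fx$paths$truth), read_vcf(fx$paths$query),
                read_bed(fx$paths$roi), ref,
                confident = read_bed(fx$paths$confident))
cl
#> varbench classification
#>   evaluation region: 11,900 bases
#>   SNP    TP(truth)=20 TP(query)=20 FP=2 FN=2
#>   MNP    TP(truth)=0 TP(query)=0 FP=0 FN=0
#>   INDEL  TP(truth)=8 TP(query)=8 FP=1 FN=1
```

Every planted count is recovered. Deriving the metrics (percentages on the
0–100 scale; `tn` counts the reference-concordant bases of the 11,900 bp
evaluation region):

```r
m <- compute_metrics(cl$counts)
m[m$size_bin == "ALL", c("variant_type", "tp_query", "fp", "fn", "tn",
                         "precision", "recall", "npa")]
#>   variant_type tp_query fp fn    tn precision  recall      npa
#> 1          SNP       20  2  2 11876   90.9091 90.9091  99.9832
#> 2          MNP        0  0  0 11900        NA      NA 100.0000
#> 7        INDEL        8  1  1 11890   88.8889 88.8889  99.9916
```

The same arithmetic applied to a published benchmarking row — 7,781 TP, 4
FP, 22 FN over a 13,728,555 bp clinical region — gives precision 99.95,
recall 99.72 and TN 13,720,748 at 2-decimal rendering:

```r
compute_metrics(data.frame(tp_query = 7781, fp = 4, fn = 22,
                           total_bases = 13728555))
#>   precision  recall       tn total_negatives npa
#>     99.9486 99.7181 13720748        13720752 100
```

A multi-sample run is driven by one YAML configuration
(`varbench run --config cfg.yaml --out out/` from the installed
`exec/varbench` script, or `run_benchmark("cfg.yaml", "out/")` in R) and
produces per-stratum annotated VCFs, InDel spectra, metrics tables and a
consolidated `final_benchmarking_metrics.txt`. Clinical truth variants are
verified with `verify_variants()`; `plant_getrm_fixture()` builds a toy
dataset of six published GeT-RM pathogenic variants on which all six
verdicts are Yes.

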