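# pamlcat

Molecular categorization and risk stratification of pediatric acute myeloid
leukemia (pAML) from RNA-seq-centred evidence.

## What this package is for

Pediatric AML is driven largely by gene fusions, internal/partial tandem
duplications (ITD/PTD) and enhancer-hijacking structural variants, many of
which adult-oriented classifications underrepresent. pamlcat implements, as
tested R functions, a framework that:

* screens tumor-only RNA-seq variant calls without a germline control
  (population allele frequency ≤ 0.1 %, cohort recurrence ≤ 5 %, > 5
  supporting reads, VAF > 5 %, gene panel, pathogenicity), including a
  dedicated soft-clip-aware detector for *UBTF* exon-13 tandem duplications
  and genotype-fingerprint deduplication (≥ 90 % concordance at ≥ 20×);
* tests allele-specific expression (ASE) for SV-driven subtypes
  (*MECOM*, *BCL11B*, *MNX1*): per-SNP exact two-sided binomial tests
  against p = 0.5 over heterozygous markers (0.2 ≤ WGS VAF ≤ 0.8, RNA
  coverage ≥ 10×), with the **median** per-marker p-value as the verdict;
* assigns every case to exactly one of **23 mutually exclusive molecular
  categories** (or Unclassified) through a tiered rule registry: defining
  fusions/SVs, then defining mutations/tandem duplications, then
  SV+ASE/outlier-expression categories, then conditional labels (GATA1,
  HOXr, KMT2A-PTD) requiring expression consistency — with every conflicting
  piece of evidence logged, never silently dropped;
* groups categories into HOXA/HOXB expression superfamilies by signature
  z-scores, and quantifies category × mutation co-occurrence with exact
  Fisher tests (minimum-likelihood two-sided rule) and Benjamini–Hochberg
  q-values;
* stratifies outcomes: Kaplan–Meier estimation, log-rank tests with tie
  correction, greedy log-rank-maximizing recursive partitioning of
  categories into low/intermediate/high risk, the **six risk strata**
  {low, intermediate, high} × {MRD−, MRD+}, event-free-survival encoding
  (nonresponse is an event at day 0), and bootstrap-compared Harrell
  concordance indices (1,000 replicates, 2.5/97.5 percentile intervals).

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the
genomic, transcriptomic and survival structure these analyses assume —
category frequencies, category-conditional cooperating mutations (FLT3-ITD
and WT1 enriched in HOXB categories, KRAS in HOXA), negative-binomial
signature expression blocks, skewed ASE counts, MRD, exponential survival —
with full ground truth, so the whole pipeline runs and is tested without any
protected patient data.

## Worked example

```r
library(pamlcat)

sim <- generate_cohort(generator_config(n_cases = 300, seed = 7))
sim$cohort
#> pAML cohort: 300 cases | 190 fusion/SV, 265 variant, 84 tandem-dup, 48 ASE-marker records | expression 168 genes

cl <- classify_cohort(sim$cohort)
cl
#> Classified 300 cases; coverage 89.7% (not Unclassified)
#>   KMT2Ar                 52
#>   NUP98r                 34
#>   Unclassified           31
#>   RUNX1::RUNX1T1         28
#>   CEBPA                  24
#>   NPM1                   22
#>   ...

mean(cl$results$label == sim$truth$category)   # recovery of generator truth
#> [1] 1

st <- assign_strata(cl$results$label, sim$cohort$cases$mrd_positive)
ok <- !is.na(st)
logrank_test(sim$cohort$cases$os_time[ok],
             sim$cohort$cases$os_event[ok], st[ok])$chisq
#> [1] 241.9   # six-strata separation, df = 5, p ~ 3e-50
```

Every case receives one label plus an evidence trail; coverage is the
fraction of cases not falling through to Unclassified (here 89.7 %, matching
the generator's configured non-Unclassified mass of 91.4 % up to sampling).
The six-strata log-rank statistic shows the survival separation that the
category × MRD framework is built to deliver.

Count arithmetic works directly on published tallies, e.g. cross-platform
validation of RNA-seq variant calls:

```r
validation_rate(374, 329, 35)
#> [1] 97.3
```

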