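# Shared fixture builders. Everything is generated in code; no data files.

variant_row <- function(case_id = "c1", gene = "WT1", chrom = "chr11",
                        pos = 32409321L, ref = "A", alt = "T", vaf = 0.4,
                        alt_reads = 40L, total_reads = 100L,
                        population_af = 0, pathogenicity = "pathogenic",
                        variant_class = "snv") {
  data.frame(case_id = case_id, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, vaf = vaf, alt_reads = alt_reads,
             total_reads = total_reads, population_af = population_af,
             pathogenicity = pathogenicity, variant_class = variant_class,
             stringsAsFactors = FALSE)
}

fusion_row <- function(case_id = "c1", gene_a = "RUNX1", gene_b = "RUNX1T1",
                       in_frame = TRUE, supporting_reads = 20L,
                       caller_score = 50, source = "rna_fusion") {
  data.frame(case_id = case_id, gene_a = gene_a, gene_b = gene_b,
             in_frame = in_frame, supporting_reads = supporting_reads,
             caller_score = caller_score, source = source,
             stringsAsFactors = FALSE)
}

td_row <- function(case_id = "c1", gene = "UBTF", chrom = "chr17",
                   start = 42288160L, end = 42288190L, build = "GRCh37",
                   supporting_reads = 5L, caller_score = 5, kind = "itd") {
  data.frame(case_id = case_id, gene = gene, chrom = chrom, start = start,
             end = end, build = build, supporting_reads = supporting_reads,
             caller_score = caller_score, kind = kind, stringsAsFactors = FALSE)
}

marker_row <- function(ref_reads = 20L, alt_reads = 20L, vaf_wgs = 0.5,
                       snp_id = "rs1", gene = "MECOM", case_id = "c1") {
  data.frame(case_id = case_id, gene = gene, snp_id = snp_id,
             ref_reads_rna = ref_reads, alt_reads_rna = alt_reads,
             vaf_wgs = vaf_wgs, cov_wgs = 40L, stringsAsFactors = FALSE)
}

cases_table <- function(ids, timepoint = "diagnosis", os_time = 1,
                        os_event = FALSE, ...) {
  data.frame(case_id = ids, age_years = 8, timepoint = timepoint,
             os_time = os_time, os_event = os_event, ...,
             stringsAsFactors = FALSE)
}

small_cohort <- function() {
  paml_cohort(
    cases_table(c("c1", "c2", "c3"),
                timepoint = c("diagnosis", "diagnosis", "relapse")),
    fusions = fusion_row("c1"),
    variants = rbind(variant_row("c2", gene = "NRAS", chrom = "chr1",
                                 pos = 115251200L),
                     variant_row("c2", gene = "KRAS", chrom = "chr12",
                                 pos = 25358200L)),
    tandem_dups = td_row("c3", gene = "FLT3", chrom = "chr13",
                         start = 28577400L, end = 28577450L))
}

# independent brute-force oracles -------------------------------------

# two-sided minimum-likelihood binomial p by direct enumeration
oracle_binomial <- function(ref, alt) {
  n <- ref + alt
  probs <- choose(n, 0:n) * 0.5^n
  sum(probs[probs <= probs[ref + 1] * (1 + 1e-7)])
}

# two-sided Fisher p by enumerating all tables with the observed margins,
# probabilities from products of binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

expect_cohort_equal <- function(a, b) {
  for (tab in c("cases", "fusions", "variants", "tandem_dups", "ase")) {
    expect_equal(a[[tab]], b[[tab]], ignore_attr = TRUE, label = tab)
  }
}
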