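# Tumor-only variant screening rules.
#
# These are the bespoke screens a tumor-only RNA-seq pipeline needs because
# no germline control is available: population-frequency and cohort-recurrence
# filters stand in for a matched normal, read-support/VAF cuts remove RNA-seq
# artifacts, a soft-clip-aware detector calls UBTF exon-13 tandem
# duplications, separate numeric criteria screen germline candidates, and
# genotype fingerprinting removes duplicate individuals.
#
# Boundary semantics follow the screening rules exactly: supporting reads
# "<= 5" and VAF "<= 5%" are filtered inclusively; ">= 3" reads, ">= 10"
# soft-clipped bases, ">= 90%" concordance, coverage ">= 20"/">= 15" and the
# 0.2-0.8 VAF window are kept inclusively.

#' Configuration for the tumor-only somatic filter
#'
#' @param max_population_af keep variants with population database allele
#'   frequency at or below this (default 0.001, i.e. 0.1%).
#' @param max_cohort_recurrence keep variants seen in at most this fraction of
#'   cohort cases (default 0.05); higher recurrence indicates germline
#'   polymorphism or systematic artifact.
#' @param min_supporting_reads_exclusive filter variants with `alt_reads` at
#'   or below this (default 5).
#' @param min_vaf_exclusive filter variants with VAF at or below this
#'   (default 0.05).
#' @param gene_panel restrict calls to this gene panel;
#'   default [default_somatic_panel()]. `NULL` disables the panel rule.
#' @return a list of class `"somatic_filter_config"`.
#' @export
somatic_filter_config <- function(max_population_af = 0.001,
                                  max_cohort_recurrence = 0.05,
                                  min_supporting_reads_exclusive = 5L,
                                  min_vaf_exclusive = 0.05,
                                  gene_panel = default_somatic_panel()) {
  stopifnot(max_population_af >= 0, max_population_af <= 1,
            max_cohort_recurrence >= 0, max_cohort_recurrence <= 1,
            min_supporting_reads_exclusive >= 0,
            min_vaf_exclusive >= 0, min_vaf_exclusive <= 1)
  structure(list(max_population_af = max_population_af,
                 max_cohort_recurrence = max_cohort_recurrence,
                 min_supporting_reads_exclusive = min_supporting_reads_exclusive,
                 min_vaf_exclusive = min_vaf_exclusive,
                 gene_panel = gene_panel),
            class = "somatic_filter_config")
}

#' Default somatic mutation gene panel
#'
#' An 87-gene panel of recurrently mutated pAML and myelodysplasia genes used
#' to restrict tumor-only SNV/indel calling. Shipped as an editable default:
#' panels differ between institutions, and callers should substitute their
#' own list via `somatic_filter_config(gene_panel = ...)`.
#'
#' @return character vector of 87 gene symbols.
#' @export
default_somatic_panel <- function() {
  c("FLT3", "NPM1", "CEBPA", "KIT", "KRAS", "NRAS", "PTPN11", "NF1", "CBL",
    "BRAF", "RIT1", "SOS1", "WT1", "GATA1", "GATA2", "RUNX1", "TP53", "UBTF",
    "CBFB", "JAK1", "JAK2", "JAK3", "MPL", "KMT2A", "KMT2C", "KMT2D", "NUP98",
    "ASXL1", "ASXL2", "BCOR", "BCORL1", "DNMT3A", "TET2", "IDH1", "IDH2",
    "EZH2", "SUZ12", "EED", "SRSF2", "SF3B1", "U2AF1", "ZRSR2", "STAG2",
    "RAD21", "SMC1A", "SMC3", "PHF6", "ETV6", "IKZF1", "PAX5", "MYC", "MYB",
    "MECOM", "MNX1", "BCL11B", "SETD2", "SETBP1", "CSF3R", "CALR", "SH2B3",
    "PTEN", "PIK3CA", "AKT1", "MTOR", "NOTCH1", "FBXW7", "CREBBP", "EP300",
    "KDM6A", "ARID1A", "ARID2", "CTCF", "CUX1", "DDX41", "ETNK1", "GNAS",
    "GNB1", "HRAS", "PPM1D", "PRPF8", "RB1", "SAMD9", "SAMD9L", "TERT",
    "USP7", "WHSC1", "ZBTB7A")
}

SOMATIC_RULES <- c("gene-panel", "pathogenicity", "population-af",
                   "recurrence", "read-support", "vaf")

#' Tumor-only somatic variant filter
#'
#' Applies the full tumor-only screen to a cohort's candidate variants. A
#' variant is kept iff all of the following hold: its gene is on the panel;
#' its pathogenicity is `pathogenic` or `likely_pathogenic`; population
#' allele frequency <= `max_population_af`; the exact allele
#' (chrom/pos/ref/alt) is present in at most `max_cohort_recurrence` of
#' cohort cases; supporting reads > `min_supporting_reads_exclusive`; and
#' VAF > `min_vaf_exclusive`. Every failed rule is recorded, so a removed
#' record always carries at least one reason.
#'
#' @param variants variants data.frame (cohort-wide, `case_id` column
#'   required for the recurrence rule).
#' @param cfg a [somatic_filter_config()].
#' @param n_cohort_cases denominator for the recurrence fraction; defaults to
#'   the number of distinct `case_id`s in `variants`. Pass the true cohort
#'   size when some cases carry no candidate variants.
#' @return the input table plus `kept` (logical) and `reasons`
#'   (semicolon-joined rule identifiers among
#'   `r paste(SOMATIC_RULES, collapse = ", ")`).
#' @export
filter_rna_somatic <- function(variants, cfg = somatic_filter_config(),
                               n_cohort_cases = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) {
    variants$kept <- logical(0); variants$reasons <- character(0)
    return(variants)
  }
  if (is.null(n_cohort_cases)) n_cohort_cases <- length(unique(variants$case_id))
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  cases_per_key <- tapply(variants$case_id, key, function(x) length(unique(x)))
  recurrence <- as.numeric(cases_per_key[key]) / n_cohort_cases

  fails <- cbind(
    `gene-panel` = if (is.null(cfg$gene_panel)) rep(FALSE, nrow(variants))
                   else !(variants$gene %in% cfg$gene_panel),
    pathogenicity = !(variants$pathogenicity %in% c("pathogenic", "likely_pathogenic")),
    `population-af` = variants$population_af > cfg$max_population_af,
    recurrence = recurrence > cfg$max_cohort_recurrence,
    `read-support` = variants$alt_reads <= cfg$min_supporting_reads_exclusive,
    vaf = variants$vaf <= cfg$min_vaf_exclusive)
  variants$kept <- !apply(fails, 1L, any)
  variants$reasons <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ";"))
  variants
}

#' Configuration for the UBTF tandem-duplication detector
#'
#' @param hotspot the exon-13 ITD/PTD hotspot interval
#'   (default chr17:42288162-42288192, GRCh37).
#' @param exon_window candidate intervals within this many bp of the hotspot
#'   count as "exon 13 or adjacent introns" (default 500; exact exon bounds
#'   are annotation-dependent).
#' @param min_supporting_reads retain candidates with at least this many
#'   supporting reads (default 3).
#' @param max_caller_score_exclusive retain candidates with caller score
#'   strictly below this (default 10).
#' @param min_softclip_len a read counts as soft-clip evidence when at least
#'   this many bases are clipped (default 10).
#' @param min_softclip_evidence soft-clip reads needed for a positive call in
#'   the absence of a retained candidate (default 3).
#' @return a list of class `"ubtf_td_config"`.
#' @export
ubtf_td_config <- function(hotspot = genomic_interval("chr17", 42288162, 42288192),
                           exon_window = 500L,
                           min_supporting_reads = 3L,
                           max_caller_score_exclusive = 10,
                           min_softclip_len = 10L,
                           min_softclip_evidence = 3L) {
  structure(list(hotspot = hotspot, exon_window = as.integer(exon_window),
                 min_supporting_reads = as.integer(min_supporting_reads),
                 max_caller_score_exclusive = max_caller_score_exclusive,
                 min_softclip_len = as.integer(min_softclip_len),
                 min_softclip_evidence = as.integer(min_softclip_evidence)),
            class = "ubtf_td_config")
}

#' Detect UBTF exon-13 tandem duplication in one case
#'
#' Combines two evidence channels for one case: (a) caller candidates
#' (ITD/PTD records) retained when their interval overlaps the hotspot
#' region +/- `exon_window`, supporting reads >= `min_supporting_reads` and
#' caller score < `max_caller_score_exclusive`; (b) soft-clipped reads with
#' clip length >= `min_softclip_len` whose clip point falls inside the
#' hotspot interval. The case is called positive when any candidate is
#' retained or when soft-clip evidence reaches `min_softclip_evidence`
#' reads. Both channels are reported separately.
#'
#' @param candidates tandem-duplication records for the case (gene, chrom,
#'   start, end, supporting_reads, caller_score, kind).
#' @param reads soft-clip read records for the case (chrom, clip_pos,
#'   clip_len).
#' @param cfg a [ubtf_td_config()].
#' @return list with `retained` (candidate subset), `softclip_count`,
#'   `total_reads_at_hotspot` and `positive`.
#' @export
detect_ubtf_td <- function(candidates, reads, cfg = ubtf_td_config()) {
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  hs <- cfg$hotspot
  lo <- hs$start - cfg$exon_window
  hi <- hs$end + cfg$exon_window
  if (nrow(candidates)) {
    keep <- candidates$gene == "UBTF" &
      candidates$chrom == hs$chrom &
      candidates$start <= hi & candidates$end >= lo &
      candidates$supporting_reads >= cfg$min_supporting_reads &
      candidates$caller_score < cfg$max_caller_score_exclusive
    retained <- candidates[keep, , drop = FALSE]
  } else retained <- candidates
  if (nrow(reads)) {
    at_hotspot <- reads$chrom == hs$chrom &
      reads$clip_pos >= hs$start & reads$clip_pos <= hs$end
    softclip_count <- sum(at_hotspot & reads$clip_len >= cfg$min_softclip_len)
    total_at_hotspot <- sum(at_hotspot)
  } else {
    softclip_count <- 0L
    total_at_hotspot <- 0L
  }
  list(retained = retained,
       softclip_count = as.integer(softclip_count),
       total_reads_at_hotspot = as.integer(total_at_hotspot),
       positive = nrow(retained) > 0L || softclip_count >= cfg$min_softclip_evidence)
}

#' Configuration for germline candidate screening
#'
#' @param max_population_af maximum population allele frequency (default
#'   0.001).
#' @param min_cov_snv,min_cov_indel minimum read coverage for SNVs (20) and
#'   indels (15).
#' @param snv_vaf_range closed VAF interval for SNVs (default `c(0.2, 0.8)`,
#'   the heterozygous window).
#' @param min_indel_alt_reads minimum reads supporting the alternative allele
#'   for indels (default 3).
#' @param gene_panel candidate germline genes; default
#'   [default_germline_panel()]. `NULL` disables the panel rule.
#' @return a list of class `"germline_filter_config"`.
#' @export
germline_filter_config <- function(max_population_af = 0.001,
                                   min_cov_snv = 20L, min_cov_indel = 15L,
                                   snv_vaf_range = c(0.2, 0.8),
                                   min_indel_alt_reads = 3L,
                                   gene_panel = default_germline_panel()) {
  stopifnot(length(snv_vaf_range) == 2L, snv_vaf_range[1] <= snv_vaf_range[2],
            snv_vaf_range[1] >= 0, snv_vaf_range[2] <= 1)
  structure(list(max_population_af = max_population_af,
                 min_cov_snv = as.integer(min_cov_snv),
                 min_cov_indel = as.integer(min_cov_indel),
                 snv_vaf_range = snv_vaf_range,
                 min_indel_alt_reads = as.integer(min_indel_alt_reads),
                 gene_panel = gene_panel),
            class = "germline_filter_config")
}

#' Default germline predisposition gene panel
#'
#' A 15-gene list of AML-relevant germline predisposition genes; editable
#' default, see [default_somatic_panel()] for the rationale.
#'
#' @return character vector of 15 gene symbols.
#' @export
default_germline_panel <- function() {
  c("CEBPA", "DDX41", "RUNX1", "GATA2", "ETV6", "ANKRD26", "TP53", "SAMD9",
    "SAMD9L", "FANCA", "BRCA1", "BRCA2", "NF1", "PTPN11", "TERT")
}

GERMLINE_RULES <- c("gene-panel", "population-af", "coverage", "vaf-range",
                    "alt-support")

#' Screen germline variant candidates
#'
#' Numeric germline criteria: keep an SNV iff population allele frequency <=
#' `max_population_af`, coverage >= `min_cov_snv` and VAF inside
#' `snv_vaf_range` (boundaries inclusive); keep an indel iff population
#' allele frequency <= `max_population_af`, coverage >= `min_cov_indel` and
#' alt reads >= `min_indel_alt_reads`.
#'
#' @param variants variants data.frame with `variant_class` set on every row.
#' @param cfg a [germline_filter_config()].
#' @return the table plus `kept` and `reasons` columns.
#' @export
germline_candidate_filter <- function(variants, cfg = germline_filter_config()) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) {
    variants$kept <- logical(0); variants$reasons <- character(0)
    return(variants)
  }
  if (any(is.na(variants$variant_class)))
    fail("variant_class must be set for every germline candidate")
  is_snv <- variants$variant_class == "snv"
  fails <- cbind(
    `gene-panel` = if (is.null(cfg$gene_panel)) rep(FALSE, nrow(variants))
                   else !(variants$gene %in% cfg$gene_panel),
    `population-af` = variants$population_af > cfg$max_population_af,
    coverage = ifelse(is_snv, variants$total_reads < cfg$min_cov_snv,
                      variants$total_reads < cfg$min_cov_indel),
    `vaf-range` = is_snv & (variants$vaf < cfg$snv_vaf_range[1] |
                            variants$vaf > cfg$snv_vaf_range[2]),
    `alt-support` = !is_snv & variants$alt_reads < cfg$min_indel_alt_reads)
  variants$kept <- !apply(fails, 1L, any)
  variants$reasons <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ";"))
  variants
}

#' Genotype-fingerprint concordance between two samples
#'
#' Pairwise genotype comparison used to find duplicate individuals in a
#' cohort: over SNPs covered at >= `min_cov` in both samples, the fraction
#' with identical genotype calls. Pairs at or above `dup_cutoff` are flagged
#' as the same individual.
#'
#' @param genotypes_a,genotypes_b data.frames with columns `snp_id`,
#'   `genotype` and optionally `coverage` (assumed >= `min_cov` when absent).
#' @param min_cov minimum coverage in both samples (default 20).
#' @param dup_cutoff concordance cutoff for duplicates (default 0.90).
#' @return list with `concordance`, `n_shared` and `duplicate`.
#' @export
genotype_concordance <- function(genotypes_a, genotypes_b, min_cov = 20L,
                                 dup_cutoff = 0.90) {
  covered <- function(g) {
    g <- as.data.frame(g, stringsAsFactors = FALSE)
    if (!is.null(g$coverage)) g <- g[g$coverage >= min_cov, , drop = FALSE]
    g
  }
  a <- covered(genotypes_a); b <- covered(genotypes_b)
  shared <- intersect(a$snp_id, b$snp_id)
  if (length(shared) == 0L) fail("no shared SNPs at >= %dx coverage", min_cov)
  ga <- a$genotype[match(shared, a$snp_id)]
  gb <- b$genotype[match(shared, b$snp_id)]
  conc <- mean(ga == gb)
  list(concordance = conc, n_shared = length(shared),
       duplicate = conc >= dup_cutoff)
}
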