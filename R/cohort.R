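# Cohort container and validation.
#
# A pAML cohort is a bundle of normalized evidence tables keyed by case_id:
#   cases        one row per patient: clinical record + karyotype flags
#   fusions      fusion / structural-variant calls (RNA fusion or DNA SV)
#   variants     somatic SNV/indel calls with pathogenicity annotation
#   tandem_dups  ITD/PTD candidate records (e.g. FLT3-ITD, UBTF-TD, KMT2A-PTD)
#   ase          per-SNP allele-specific-expression marker read counts
# plus an optional genes x samples expression matrix (see expression_matrix()).
# Coordinates are 1-based inclusive, GRCh37 build tag by default.

PATHOGENICITY_LEVELS <- c("pathogenic", "likely_pathogenic", "uncertain", "benign")
VARIANT_CLASSES      <- c("snv", "indel")
FUSION_SOURCES       <- c("rna_fusion", "dna_sv")
TIMEPOINTS           <- c("diagnosis", "relapse")
TD_KINDS             <- c("itd", "ptd")

#' Genomic interval (1-based, inclusive)
#'
#' @param chrom chromosome name (non-empty string).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param build genome build tag (default `"GRCh37"`).
#' @return a list with class `"genomic_interval"`.
#' @examples
#' genomic_interval("chr17", 42288162, 42288192)
#' @export
genomic_interval <- function(chrom, start, end, build = "GRCh37") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    fail("chrom must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    fail("invalid interval: start must be <= end")
  structure(list(chrom = chrom, start = start, end = end, build = build),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d [%s]\n", x$chrom, x$start, x$end, x$build))
  invisible(x)
}

empty_fusions <- function() data.frame(
  case_id = character(), gene_a = character(), gene_b = character(),
  in_frame = logical(), supporting_reads = integer(), caller_score = numeric(),
  source = character(), stringsAsFactors = FALSE)

empty_variants <- function() data.frame(
  case_id = character(), gene = character(), chrom = character(),
  pos = integer(), ref = character(), alt = character(), vaf = numeric(),
  alt_reads = integer(), total_reads = integer(), population_af = numeric(),
  pathogenicity = character(), variant_class = character(),
  stringsAsFactors = FALSE)

empty_tandem_dups <- function() data.frame(
  case_id = character(), gene = character(), chrom = character(),
  start = integer(), end = integer(), build = character(),
  supporting_reads = integer(), caller_score = numeric(), kind = character(),
  stringsAsFactors = FALSE)

empty_ase <- function() data.frame(
  case_id = character(), gene = character(), snp_id = character(),
  ref_reads_rna = integer(), alt_reads_rna = integer(),
  vaf_wgs = numeric(), cov_wgs = integer(), stringsAsFactors = FALSE)

# optional clinical / annotation columns filled with NA when absent
OPTIONAL_CASE_COLS <- c("mrd_positive", "efs_time", "efs_event", "nonresponse",
                        "relapse_flag", "complex_karyotype", "monosomy7",
                        "other_events", "has_wgs", "has_wes",
                        "category", "hox_group")

#' Assemble and validate a pAML cohort
#'
#' Bundles the evidence tables into a validated cohort object. All tables are
#' keyed by `case_id`; every `case_id` appearing in an evidence table must be
#' present in `cases`, and `case_id` must be unique within `cases`.
#'
#' @param cases data.frame with at least `case_id`, `age_years`, `timepoint`,
#'   `os_time`, `os_event`. Optional columns: `mrd_positive`, `efs_time`,
#'   `efs_event`, `nonresponse`, `relapse_flag`, `complex_karyotype`,
#'   `monosomy7`, `other_events`, `has_wgs`, `has_wes`, `category`,
#'   `hox_group`.
#' @param fusions,variants,tandem_dups,ase evidence tables (may be empty).
#' @param expression optional expression matrix from [expression_matrix()],
#'   columns keyed by `case_id`.
#' @return an object of class `"paml_cohort"`.
#' @export
paml_cohort <- function(cases, fusions = empty_fusions(),
                        variants = empty_variants(),
                        tandem_dups = empty_tandem_dups(),
                        ase = empty_ase(), expression = NULL) {
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  req <- c("case_id", "age_years", "timepoint", "os_time", "os_event")
  miss <- setdiff(req, names(cases))
  if (length(miss)) fail("cases table missing columns: %s", paste(miss, collapse = ", "))
  dup <- cases$case_id[duplicated(cases$case_id)]
  if (length(dup)) fail("duplicate case_id: %s", paste(unique(dup), collapse = ", "))
  if (any(cases$age_years < 0, na.rm = TRUE)) fail("age_years must be >= 0")
  if (any(cases$os_time < 0, na.rm = TRUE)) fail("os_time must be >= 0")
  check_enum(cases$timepoint, TIMEPOINTS, "timepoint")
  for (col in OPTIONAL_CASE_COLS)
    if (is.null(cases[[col]])) cases[[col]] <- rep(NA, nrow(cases))

  validate_keyed <- function(tab, what) {
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    orphan <- setdiff(tab$case_id, cases$case_id)
    if (length(orphan))
      fail("%s table refers to unknown case_id: %s", what,
           paste(utils::head(orphan, 5), collapse = ", "))
    tab
  }
  fusions <- validate_keyed(fusions, "fusions")
  if (nrow(fusions)) {
    check_enum(fusions$source, FUSION_SOURCES, "fusion source")
    if (any(fusions$supporting_reads < 0)) fail("fusion supporting_reads must be >= 0")
  }
  variants <- validate_keyed(variants, "variants")
  if (nrow(variants)) {
    check_enum(variants$pathogenicity, PATHOGENICITY_LEVELS, "pathogenicity")
    check_enum(variants$variant_class, VARIANT_CLASSES, "variant_class")
    if (any(variants$alt_reads > variants$total_reads))
      fail("variant alt_reads must be <= total_reads")
    if (any(variants$total_reads <= 0)) fail("variant total_reads must be > 0")
    off <- abs(variants$vaf - variants$alt_reads / variants$total_reads) > 0.011
    if (any(off))
      fail("vaf inconsistent with alt_reads/total_reads for %d variant(s)", sum(off))
    if (any(variants$vaf < 0 | variants$vaf > 1)) fail("vaf must be in [0, 1]")
    if (any(variants$population_af < 0 | variants$population_af > 1))
      fail("population_af must be in [0, 1]")
  }
  tandem_dups <- validate_keyed(tandem_dups, "tandem_dups")
  if (nrow(tandem_dups)) {
    check_enum(tandem_dups$kind, TD_KINDS, "tandem-duplication kind")
    if (any(tandem_dups$supporting_reads < 0)) fail("tandem_dup supporting_reads must be >= 0")
    if (any(tandem_dups$start > tandem_dups$end)) fail("tandem_dup interval start must be <= end")
  }
  ase <- validate_keyed(ase, "ase")
  if (nrow(ase)) {
    if (any(ase$ref_reads_rna < 0 | ase$alt_reads_rna < 0))
      fail("ASE read counts must be >= 0")
  }
  if (!is.null(expression)) {
    if (is.null(attr(expression, "units")))
      fail("expression must be built with expression_matrix()")
    unknown <- setdiff(colnames(expression), cases$case_id)
    if (length(unknown))
      fail("expression matrix has unknown case_id columns: %s",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(cases = cases, fusions = fusions, variants = variants,
                 tandem_dups = tandem_dups, ase = ase, expression = expression),
            class = "paml_cohort")
}

#' @export
print.paml_cohort <- function(x, ...) {
  cat(sprintf("pAML cohort: %d cases | %d fusion/SV, %d variant, %d tandem-dup, %d ASE-marker records%s\n",
              nrow(x$cases), nrow(x$fusions), nrow(x$variants),
              nrow(x$tandem_dups), nrow(x$ase),
              if (is.null(x$expression)) "" else
                sprintf(" | expression %d genes", nrow(x$expression))))
  invisible(x)
}

#' Number of cases in a cohort
#' @param cohort a `paml_cohort`.
#' @return integer count.
#' @export
n_cases <- function(cohort) nrow(cohort$cases)

#' Per-case evidence bundle
#'
#' Extracts one patient's complete evidence: clinical row plus the subsets of
#' the fusion, variant and tandem-duplication tables for that case.
#'
#' @param cohort a `paml_cohort`.
#' @param case_id a case identifier present in the cohort.
#' @return a list with elements `case_id`, `clinical`, `fusions`, `variants`,
#'   `tandem_dups`.
#' @export
case_bundle <- function(cohort, case_id) {
  if (!case_id %in% cohort$cases$case_id) fail("unknown case_id: %s", case_id)
  list(case_id = case_id,
       clinical = cohort$cases[cohort$cases$case_id == case_id, , drop = FALSE],
       fusions = cohort$fusions[cohort$fusions$case_id == case_id, , drop = FALSE],
       variants = cohort$variants[cohort$variants$case_id == case_id, , drop = FALSE],
       tandem_dups = cohort$tandem_dups[cohort$tandem_dups$case_id == case_id, , drop = FALSE])
}
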