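# Readers and writers for the tab-separated cohort dialects.
#
# One directory holds one cohort:
#   cases.tsv        required; clinical + karyotype columns (see paml_cohort)
#   fusions.tsv      optional
#   variants.tsv     optional (or a VCF, see read_variants_vcf)
#   tandem_dups.tsv  optional
#   ase.tsv          optional
#   expression.tsv   optional genes x samples count table (first column = gene)
# Columns use the exact field names of the in-memory tables; logical columns
# are written as TRUE/FALSE.

read_tsv_checked <- function(path, what, char_cols = character()) {
  # allele and identifier columns must never be auto-parsed
  # (an allele "T" is a base, not TRUE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  classes <- stats::setNames(rep("character", length(header)), header)
  classes[!header %in% char_cols] <- NA
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = classes),
    error = function(e) fail("failed to parse %s table '%s': %s", what, path,
                             conditionMessage(e)))
  tab
}

#' Read a cohort from a directory of TSV files
#'
#' @param dir directory containing `cases.tsv` and any of `fusions.tsv`,
#'   `variants.tsv`, `tandem_dups.tsv`, `ase.tsv`, `expression.tsv`.
#' @param paths optional named list overriding individual file paths
#'   (names among `cases`, `fusions`, `variants`, `tandem_dups`, `ase`,
#'   `expression`).
#' @return a validated [paml_cohort()].
#' @details Malformed rows (bad enum tokens, inconsistent read counts,
#'   duplicated `case_id`) raise errors naming the offending value. A
#'   `variants` path ending in `.vcf` is read with [read_variants_vcf()].
#' @export
read_cohort <- function(dir = NULL, paths = list()) {
  path_for <- function(name, file) {
    p <- paths[[name]]
    if (!is.null(p)) return(p)
    if (is.null(dir)) return(NULL)
    f <- file.path(dir, file)
    if (file.exists(f)) f else NULL
  }
  cases_path <- path_for("cases", "cases.tsv")
  if (is.null(cases_path) || !file.exists(cases_path))
    fail("cases table not found (looked for %s)",
         if (is.null(dir)) "paths$cases" else file.path(dir, "cases.tsv"))
  cases <- read_tsv_checked(cases_path, "cases")

  read_opt <- function(name, file, empty) {
    p <- path_for(name, file)
    if (is.null(p)) return(empty)
    if (name == "variants" && grepl("\\.vcf$", p, ignore.case = TRUE))
      return(read_variants_vcf(p))
    read_tsv_checked(p, name,
                     char_cols = c("ref", "alt", "chrom", "genotype",
                                   "case_id", "gene", "gene_a", "gene_b",
                                   "snp_id"))
  }
  fusions <- read_opt("fusions", "fusions.tsv", empty_fusions())
  variants <- read_opt("variants", "variants.tsv", empty_variants())
  tds <- read_opt("tandem_dups", "tandem_dups.tsv", empty_tandem_dups())
  ase <- read_opt("ase", "ase.tsv", empty_ase())

  expr <- NULL
  expr_path <- path_for("expression", "expression.tsv")
  if (!is.null(expr_path)) expr <- read_expression_tsv(expr_path)

  paml_cohort(cases, fusions, variants, tds, ase, expr)
}

#' Write a cohort to a directory of TSV files
#'
#' Inverse of [read_cohort()]: writing then reading reproduces the cohort
#' field-by-field.
#'
#' @param cohort a `paml_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, file) {
    utils::write.table(tab, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(cohort$cases, "cases.tsv")
  if (nrow(cohort$fusions)) wr(cohort$fusions, "fusions.tsv")
  if (nrow(cohort$variants)) wr(cohort$variants, "variants.tsv")
  if (nrow(cohort$tandem_dups)) wr(cohort$tandem_dups, "tandem_dups.tsv")
  if (nrow(cohort$ase)) wr(cohort$ase, "ase.tsv")
  if (!is.null(cohort$expression)) {
    m <- cohort$expression
    out <- data.frame(gene = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                      check.names = FALSE)
    wr(out, "expression.tsv")
  }
  invisible(dir)
}

#' Read variant calls from a VCF 4.x file
#'
#' Maps a single-sample VCF to the package's variant-table dialect. Per-record
#' fields are taken from INFO keys (configurable via `info_keys`); this
#' mirrors tumor-only pipelines that emit annotated VCFs with gene symbol,
#' VAF, read support, population allele frequency and a pathogenicity call.
#'
#' @param path VCF path.
#' @param case_id case identifier for all records; defaults to the file name
#'   without extension.
#' @param info_keys named list mapping the package fields `gene`, `vaf`,
#'   `alt_reads`, `total_reads`, `population_af`, `pathogenicity`,
#'   `variant_class` to INFO keys.
#' @return a variants data.frame in the TSV dialect.
#' @export
read_variants_vcf <- function(path, case_id = NULL, info_keys = list()) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    fail("reading VCF requires the vcfR package")
  keys <- utils::modifyList(list(gene = "GENE", vaf = "VAF", alt_reads = "ALT_READS",
                                 total_reads = "DP", population_af = "POP_AF",
                                 pathogenicity = "PATHOGENICITY",
                                 variant_class = "VARIANT_CLASS"), info_keys)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(case_id)) case_id <- sub("\\.vcf$", "", basename(path), ignore.case = TRUE)
  info <- function(key) vcfR::extract.info(v, element = key)
  data.frame(
    case_id = rep(case_id, nrow(fix)),
    gene = info(keys$gene),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vaf = as.numeric(info(keys$vaf)),
    alt_reads = as.integer(info(keys$alt_reads)),
    total_reads = as.integer(info(keys$total_reads)),
    population_af = as.numeric(info(keys$population_af)),
    pathogenicity = info(keys$pathogenicity),
    variant_class = info(keys$variant_class),
    stringsAsFactors = FALSE)
}

#' Read an expression count table
#'
#' `read_expression_tsv` expects genes in rows (first column = gene symbol)
#' and samples in columns. `read_expression_mtx` reads a MatrixMarket file
#' plus plain-text row (gene) and column (sample) name files, as written by
#' count pipelines.
#'
#' @param path TSV path.
#' @param units `"raw_counts"` (default) or `"log2cpm"`.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, units = "raw_counts") {
  tab <- read_tsv_checked(path, "expression")
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  expression_matrix(m, units = units)
}

#' @rdname read_expression_tsv
#' @param mtx,genes_file,samples_file MatrixMarket file and the row/column
#'   name files (one name per line).
#' @export
read_expression_mtx <- function(mtx, genes_file, samples_file, units = "raw_counts") {
  if (!requireNamespace("Matrix", quietly = TRUE))
    fail("reading MTX requires the Matrix package")
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(genes_file)
  colnames(m) <- readLines(samples_file)
  expression_matrix(m, units = units)
}
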