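# Cohort-level summary arithmetic.

#' Default RAS-pathway gene list
#'
#' Genes counted as RAS-pathway mutations in [cohort_summary()]. The set
#' covers the canonical RAS GTPases and the Noonan-syndrome-spectrum genes
#' through which pAML studies annotate "RAS pathway"; it is an argument, not
#' a constant, because the exact membership varies between studies.
#'
#' @return character vector of gene symbols.
#' @export
default_ras_genes <- function() {
  c("NRAS", "KRAS", "PTPN11", "NF1", "CBL", "BRAF", "RIT1", "SOS1")
}

#' Summarize a cohort's composition
#'
#' Computes the headline cohort shares, each reported with its
#' numerator/denominator pair and the percentage rounded half-up to one
#' decimal: timepoint composition, cases with at least one fusion/SV call,
#' cases with at least one pathogenic RAS-pathway mutation, the share of
#' RAS-mutant cases with more than one RAS-pathway gene mutated, the share
#' profiled on all three platforms (when `has_wgs`/`has_wes` are recorded),
#' and per-category counts with classification coverage (when categories are
#' assigned).
#'
#' @param cohort a `paml_cohort`.
#' @param ras_genes RAS-pathway gene list; default [default_ras_genes()].
#' @return a list of class `"paml_summary"` with elements `shares` (data.frame
#'   `statistic`, `numerator`, `denominator`, `percent`), `categories`
#'   (per-category counts, or NULL) and `n_cases`.
#' @export
cohort_summary <- function(cohort, ras_genes = default_ras_genes()) {
  n <- n_cases(cohort)
  if (n == 0L) fail("cohort is empty")
  cs <- cohort$cases

  ids_fused <- unique(cohort$fusions$case_id)
  path_var <- cohort$variants[cohort$variants$pathogenicity %in%
                                c("pathogenic", "likely_pathogenic"), , drop = FALSE]
  ras_var <- path_var[path_var$gene %in% ras_genes, , drop = FALSE]
  ras_cases <- unique(ras_var$case_id)
  genes_per_case <- tapply(ras_var$gene, ras_var$case_id,
                           function(g) length(unique(g)))
  multi_ras <- sum(genes_per_case >= 2)

  rows <- list(
    c("diagnosis", sum(cs$timepoint == "diagnosis"), n),
    c("relapse", sum(cs$timepoint == "relapse"), n),
    c("fusion_sv", length(ids_fused), n),
    c("ras_pathway", length(ras_cases), n),
    c("multi_ras", multi_ras, max(length(ras_cases), 1L)))
  if (!all(is.na(cs$has_wgs)) && !all(is.na(cs$has_wes))) {
    tri <- sum(cs$has_wgs & cs$has_wes, na.rm = TRUE)
    rows <- c(rows, list(c("tri_platform", tri, n)))
  }
  categories <- NULL
  if (!all(is.na(cs$category))) {
    counts <- sort(table(cs$category), decreasing = TRUE)
    categories <- data.frame(category = names(counts),
                             n = as.integer(counts),
                             percent = pct1(as.integer(counts), n),
                             stringsAsFactors = FALSE)
    classified <- sum(cs$category != "Unclassified", na.rm = TRUE)
    rows <- c(rows, list(c("classified", classified, n)))
  }
  shares <- data.frame(
    statistic = vapply(rows, `[[`, "", 1L),
    numerator = as.integer(vapply(rows, `[[`, "", 2L)),
    denominator = as.integer(vapply(rows, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  # an all-zero denominator only arises for multi_ras when no case is RAS-mutant
  shares$percent <- pct1(shares$numerator, shares$denominator)
  stopifnot(all(shares$percent >= 0 & shares$percent <= 100))
  structure(list(shares = shares, categories = categories, n_cases = n),
            class = "paml_summary")
}

#' @export
print.paml_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n_cases))
  for (i in seq_len(nrow(x$shares))) {
    r <- x$shares[i, ]
    cat(sprintf("  %-14s %4d / %4d  (%.1f%%)\n",
                r$statistic, r$numerator, r$denominator, r$percent))
  }
  if (!is.null(x$categories)) {
    cat(sprintf("  categories: %d labels assigned\n", nrow(x$categories)))
  }
  invisible(x)
}

#' Validation rate of RNA-seq variant calls against DNA platforms
#'
#' Cross-platform validation arithmetic: of `total_rna_calls` variant calls
#' from RNA-seq, `cross_called` were independently called from WGS or WES and
#' `additional_read_supported` of the remainder had supporting reads in the
#' DNA data without being formally called. The validation rate counts both.
#'
#' @param total_rna_calls number of RNA-seq SNV/indel calls (> 0).
#' @param cross_called calls also made from DNA data.
#' @param additional_read_supported further calls with DNA read support only.
#' @return percentage, rounded half-up to one decimal.
#' @examples
#' validation_rate(374, 329, 35)  # 97.3
#' validation_rate(374, 329, 0)   # 88.0
#' @export
validation_rate <- function(total_rna_calls, cross_called,
                            additional_read_supported) {
  if (total_rna_calls == 0) fail("total_rna_calls must be > 0")
  if (cross_called + additional_read_supported > total_rna_calls)
    fail("validated calls exceed total_rna_calls")
  pct1(cross_called + additional_read_supported, total_rna_calls)
}
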