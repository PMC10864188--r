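# Allele-specific expression (ASE) testing.
#
# Structural variants that hijack enhancers (MECOM, BCL11B, MNX1) leave the
# coding sequence intact but drive expression from a single allele. With a
# paired WGS genotype, heterozygous SNP markers in the gene locus should show
# balanced RNA read counts under the null; monoallelic expression skews them,
# which an exact binomial test against p = 0.5 detects. Without WGS the
# weaker criterion is gross allelic imbalance of every adequately covered
# marker.

#' Select heterozygous, adequately covered ASE markers
#'
#' Keeps markers with RNA coverage >= `min_cov` and WGS VAF inside
#' `[vaf_low, vaf_high]` (boundaries inclusive) - the heterozygous window.
#'
#' @param markers data.frame with `ref_reads_rna`, `alt_reads_rna`,
#'   `vaf_wgs`; rows with missing `vaf_wgs` are dropped.
#' @param min_cov minimum RNA coverage (default 10).
#' @param vaf_low,vaf_high heterozygous WGS VAF window (default 0.2-0.8).
#' @return the qualifying subset of `markers`.
#' @export
select_het_markers <- function(markers, min_cov = 10L, vaf_low = 0.2,
                               vaf_high = 0.8) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  cov <- markers$ref_reads_rna + markers$alt_reads_rna
  keep <- !is.na(markers$vaf_wgs) & cov >= min_cov &
    markers$vaf_wgs >= vaf_low & markers$vaf_wgs <= vaf_high
  markers[keep, , drop = FALSE]
}

#' Exact two-sided binomial test for allelic imbalance
#'
#' Two-sided exact binomial p-value under success probability 0.5, using the
#' minimum-likelihood construction: the sum of probabilities of all outcomes
#' no more probable than the observed count. At p = 0.5 the distribution is
#' symmetric, so the p-value is invariant under swapping ref and alt counts.
#'
#' @param ref_reads,alt_reads RNA read counts for the two alleles
#'   (`ref_reads + alt_reads >= 1`).
#' @return p-value in (0, 1].
#' @examples
#' ase_binomial(5, 5)    # 1
#' ase_binomial(10, 0)   # 2 * 0.5^10
#' @export
ase_binomial <- function(ref_reads, alt_reads) {
  n <- ref_reads + alt_reads
  if (length(n) != 1L || is.na(n) || n < 1L)
    fail("marker coverage must be >= 1")
  d <- stats::dbinom(0:n, n, 0.5)
  # relative-error guard against ties broken by floating-point noise
  min(1, sum(d[d <= d[ref_reads + 1L] * (1 + 1e-7)]))
}

#' Assess allele-specific expression for one gene in one case
#'
#' Two modes mirror data availability. `wgs_paired`: markers are restricted
#' to heterozygous, covered SNPs ([select_het_markers()]); the verdict is the
#' median of per-marker exact binomial p-values, called ASE-positive when the
#' median is below `alpha`. `rna_only`: without genotypes, ASE is supported
#' when markers with coverage >= `min_cov` show allelic imbalance (RNA VAF
#' <= `imbalance_low` or >= `imbalance_high`); by default all eligible
#' markers must be imbalanced (`min_fraction = 1`).
#'
#' @param markers data.frame of ASE markers (one gene, one case).
#' @param mode `"wgs_paired"` or `"rna_only"`.
#' @param alpha positivity threshold on the median p-value (default 0.05).
#' @param min_cov minimum RNA coverage for eligibility (default 10).
#' @param imbalance_low,imbalance_high RNA VAF imbalance bounds for
#'   `rna_only` (defaults 0.2 and 0.8).
#' @param min_fraction fraction of eligible markers that must be imbalanced
#'   in `rna_only` mode (default 1: all).
#' @return list of class `"ase_verdict"`: `verdict` (`"positive"`,
#'   `"negative"` or `"indeterminate"`), `positive` (logical, `NA` when
#'   indeterminate), `n_markers`, and `median_p` (wgs_paired) or
#'   `imbalance_fraction` (rna_only). No eligible markers yields
#'   `"indeterminate"`, distinct from a negative verdict.
#' @export
assess_ase <- function(markers, mode = c("wgs_paired", "rna_only"),
                       alpha = 0.05, min_cov = 10L,
                       imbalance_low = 0.2, imbalance_high = 0.8,
                       min_fraction = 1) {
  mode <- match.arg(mode)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (mode == "wgs_paired") {
    sel <- select_het_markers(markers, min_cov = min_cov)
    if (nrow(sel) == 0L)
      return(structure(list(verdict = "indeterminate", positive = NA,
                            n_markers = 0L, median_p = NA_real_),
                       class = "ase_verdict"))
    p <- mapply(ase_binomial, sel$ref_reads_rna, sel$alt_reads_rna)
    med <- stats::median(p)
    pos <- med < alpha
    structure(list(verdict = if (pos) "positive" else "negative",
                   positive = pos, n_markers = nrow(sel), median_p = med),
              class = "ase_verdict")
  } else {
    cov <- markers$ref_reads_rna + markers$alt_reads_rna
    elig <- markers[cov >= min_cov, , drop = FALSE]
    if (nrow(elig) == 0L)
      return(structure(list(verdict = "indeterminate", positive = NA,
                            n_markers = 0L, imbalance_fraction = NA_real_),
                       class = "ase_verdict"))
    vaf <- elig$alt_reads_rna / (elig$ref_reads_rna + elig$alt_reads_rna)
    frac <- mean(vaf <= imbalance_low | vaf >= imbalance_high)
    pos <- frac >= min_fraction
    structure(list(verdict = if (pos) "positive" else "negative",
                   positive = pos, n_markers = nrow(elig),
                   imbalance_fraction = frac),
              class = "ase_verdict")
  }
}

#' @export
print.ase_verdict <- function(x, ...) {
  extra <- if (!is.null(x$median_p) && !is.na(x$median_p))
    sprintf(", median p = %.4g", x$median_p)
  else if (!is.null(x$imbalance_fraction) && !is.na(x$imbalance_fraction))
    sprintf(", imbalanced fraction = %.2f", x$imbalance_fraction)
  else ""
  cat(sprintf("ASE verdict: %s (%d marker(s)%s)\n", x$verdict, x$n_markers, extra))
  invisible(x)
}
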