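# Expression preprocessing, signature scoring and two-group differential
# expression.

#' Expression matrix container
#'
#' A genes x samples numeric matrix tagged with its units: `"raw_counts"`
#' (non-negative integers) or `"log2cpm"` (log2 counts per million, floored
#' at zero by [log2cpm()]).
#'
#' @param m numeric matrix with gene rownames and case_id colnames.
#' @param units `"raw_counts"` or `"log2cpm"`.
#' @return the matrix with class `"paml_expr"` and a `units` attribute.
#' @export
expression_matrix <- function(m, units = c("raw_counts", "log2cpm")) {
  units <- match.arg(units)
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    fail("expression matrix needs gene rownames and sample colnames")
  if (units == "raw_counts" && any(m < 0))
    fail("raw counts must be non-negative")
  structure(m, units = units, class = c("paml_expr", class(m)))
}

expr_units <- function(m) attr(m, "units") %||% fail("not an expression_matrix")

require_units <- function(m, units) {
  if (!identical(expr_units(m), units))
    fail("expression matrix must have units '%s' (got '%s')", units, expr_units(m))
  invisible(m)
}

#' Filter to expressed genes
#'
#' A gene counts as expressed when at least `min_samples` samples reach
#' `min_cpm` counts per million.
#'
#' @param m raw-count [expression_matrix()].
#' @param min_cpm cpm threshold (default 10).
#' @param min_samples number of samples required at the threshold (default 5).
#' @return the filtered raw-count matrix.
#' @export
filter_expressed <- function(m, min_cpm = 10, min_samples = 5L) {
  require_units(m, "raw_counts")
  libsize <- colSums(m)
  if (any(libsize == 0))
    fail("zero library size for sample(s): %s",
         paste(colnames(m)[libsize == 0], collapse = ", "))
  cpm <- sweep(unclass(m), 2L, libsize, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  expression_matrix(unclass(m)[keep, , drop = FALSE], "raw_counts")
}

#' Transform counts to floored log2 counts per million
#'
#' cpm = count / library size x 1e6; values are log2-transformed and any
#' log2(cpm) below zero (including zero counts) is set to zero, reflecting
#' the empirical floor of the log-cpm distribution.
#'
#' @param m raw-count [expression_matrix()].
#' @return a `log2cpm` [expression_matrix()]; all values >= 0.
#' @export
log2cpm <- function(m) {
  require_units(m, "raw_counts")
  libsize <- colSums(m)
  if (any(libsize == 0))
    fail("zero library size for sample(s): %s",
         paste(colnames(m)[libsize == 0], collapse = ", "))
  cpm <- sweep(unclass(m), 2L, libsize, "/") * 1e6
  v <- suppressWarnings(log2(cpm))
  v[v < 0 | !is.finite(v)] <- 0
  expression_matrix(v, "log2cpm")
}

#' Select the most variable genes
#'
#' Top `n` genes by variance of log2-cpm across samples; ties are broken
#' deterministically by gene symbol.
#'
#' @param m `log2cpm` [expression_matrix()].
#' @param n number of genes (default 315).
#' @return a signature set: `list(name, genes)`.
#' @export
select_variable_genes <- function(m, n = 315L) {
  require_units(m, "log2cpm")
  if (n > nrow(m)) fail("n exceeds the number of genes (%d)", nrow(m))
  v <- apply(unclass(m), 1L, stats::var)
  ord <- order(-v, rownames(m))
  signature_set(sprintf("top%d_variable", n), rownames(m)[ord[seq_len(n)]])
}

#' Signature set constructor
#'
#' @param name signature name.
#' @param genes non-empty character vector of gene symbols.
#' @return `list(name, genes)` with class `"signature_set"`.
#' @export
signature_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) fail("signature '%s' is empty", name)
  structure(list(name = name, genes = genes), class = "signature_set")
}

#' HOXA- and HOXB-cluster expression signatures
#'
#' Default gene sets used to place cases on the HOXA/HOXB axis: the HOXA
#' signature covers posterior HOXA cluster genes and their cofactor MEIS1;
#' the HOXB signature covers the HOXB2-HOXB6 block.
#'
#' @return a [signature_set()].
#' @export
hoxa_signature <- function() {
  signature_set("HOXA", c("HOXA3", "HOXA5", "HOXA7", "HOXA9", "HOXA10", "MEIS1"))
}

#' @rdname hoxa_signature
#' @export
hoxb_signature <- function() {
  signature_set("HOXB", c("HOXB2", "HOXB3", "HOXB4", "HOXB5", "HOXB6"))
}

#' Erythro-megakaryocytic marker signature
#'
#' Used as the expression-consistency check for GATA1-driven cases.
#' @return a [signature_set()].
#' @export
ery_signature <- function() {
  signature_set("ERY", c("GATA1", "KLF1", "ITGA2B", "GYPA"))
}

# per-gene z-scores across samples; zero-variance genes map to 0
gene_zscores <- function(m) {
  v <- unclass(m)
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  z <- sweep(v, 1L, mu, "-")
  nz <- sd > 0
  z[nz, ] <- sweep(z[nz, , drop = FALSE], 1L, sd[nz], "/")
  z[!nz, ] <- 0
  z
}

#' Score cases on an expression signature
#'
#' The signature score of a case is the mean, over signature genes present
#' in the matrix, of the per-gene z-score (each gene standardized across the
#' cohort's samples). A case sitting at the cohort mean on every signature
#' gene scores 0; a case two standard deviations above on every gene scores 2.
#'
#' @param m `log2cpm` [expression_matrix()].
#' @param sig a [signature_set()].
#' @param cases case_ids to score (default: all samples).
#' @return named numeric vector of scores.
#' @export
signature_score <- function(m, sig, cases = colnames(m)) {
  require_units(m, "log2cpm")
  genes <- intersect(sig$genes, rownames(m))
  if (length(genes) == 0L)
    fail("no genes of signature '%s' present in the matrix", sig$name)
  z <- gene_zscores(unclass(m)[genes, , drop = FALSE])
  colMeans(z)[cases]
}

#' Assign cases to HOXA / HOXB / other expression groups
#'
#' Transparent threshold rule on the two signature scores: `HOXA` when the
#' HOXA score is at least `t_high` while the HOXB score is at most `t_low`
#' (posterior-HOXA-only pattern); `HOXB` when both scores reach `t_high`
#' (the co-expression pattern of the HOXB superfamily); otherwise `other`.
#'
#' @param m `log2cpm` [expression_matrix()].
#' @param hoxa_sig,hoxb_sig signature sets (defaults [hoxa_signature()],
#'   [hoxb_signature()]).
#' @param t_high,t_low score thresholds (defaults +0.5 and 0).
#' @return named character vector (`"HOXA"`, `"HOXB"`, `"other"`) per case.
#' @export
hox_group_assign <- function(m, hoxa_sig = hoxa_signature(),
                             hoxb_sig = hoxb_signature(),
                             t_high = 0.5, t_low = 0) {
  sa <- signature_score(m, hoxa_sig)
  sb <- signature_score(m, hoxb_sig)
  grp <- rep("other", length(sa))
  grp[sa >= t_high & sb <= t_low] <- "HOXA"
  grp[sa >= t_high & sb >= t_high] <- "HOXB"
  names(grp) <- names(sa)
  grp
}

#' Flag outlier expression of one gene in one case
#'
#' TRUE when the case's z-score for the gene (standardized across the
#' cohort) reaches `z_cut`. A zero-variance gene cannot produce an outlier
#' and returns FALSE with a warning.
#'
#' @param m `log2cpm` [expression_matrix()].
#' @param gene gene symbol present in `m`.
#' @param case case_id (default: all samples, returning a named vector).
#' @param z_cut z-score cutoff (default 3).
#' @return logical (named vector over `case`).
#' @export
outlier_expression_flag <- function(m, gene, case = colnames(m), z_cut = 3) {
  require_units(m, "log2cpm")
  if (!gene %in% rownames(m)) fail("gene '%s' not in expression matrix", gene)
  x <- unclass(m)[gene, ]
  s <- stats::sd(x)
  if (s == 0) {
    warning(sprintf("gene '%s' has zero variance; no outliers", gene))
    out <- rep(FALSE, length(case)); names(out) <- case
    return(out)
  }
  z <- (x - mean(x)) / s
  (z >= z_cut)[case]
}

#' Two-group differential expression
#'
#' Per-gene Welch two-sample t-test on log2-cpm values with
#' Benjamini-Hochberg adjustment. The fold change is computed on the cpm
#' scale from the difference of group means of log2-cpm; a gene is flagged
#' significant when |fold change| > `fc_cut` and FDR < `fdr_cut`.
#'
#' @param m `log2cpm` [expression_matrix()].
#' @param group_a,group_b disjoint case_id vectors, each of length >= 2.
#' @param fc_cut fold-change cutoff on the cpm scale (default 2).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return data.frame: `gene`, `mean_a`, `mean_b`, `log2_fc`, `fold_change`,
#'   `t`, `p`, `fdr`, `significant`.
#' @export
differential_expression <- function(m, group_a, group_b, fc_cut = 2,
                                    fdr_cut = 0.05) {
  require_units(m, "log2cpm")
  if (length(intersect(group_a, group_b)))
    fail("groups overlap: %s", paste(intersect(group_a, group_b), collapse = ", "))
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) fail("cases not in matrix: %s", paste(missing, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    fail("each group needs >= 2 samples")
  a <- unclass(m)[, group_a, drop = FALSE]
  b <- unclass(m)[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: both groups constant
  p[se2 == 0 & ma == mb] <- 1
  p[se2 == 0 & ma != mb] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  log2_fc <- ma - mb
  out <- data.frame(gene = rownames(m), mean_a = ma, mean_b = mb,
                    log2_fc = log2_fc, fold_change = 2^log2_fc,
                    t = tstat, p = p, fdr = fdr,
                    significant = abs(log2_fc) > log2(fc_cut) & fdr < fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
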