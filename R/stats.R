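# Exact co-occurrence / enrichment statistics.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value with margins fixed: the sum of hypergeometric probabilities
#' of all tables sharing the observed margins whose probability does not
#' exceed that of the observed table (minimum-likelihood two-sided rule, the
#' convention of mainstream statistical software). Probabilities are
#' computed from log-binomial coefficients for overflow safety. Degenerate
#' margins (an empty row or column) give p = 1.
#'
#' @param a,b,c,d cell counts: `a` = in-category and altered, `b` =
#'   in-category not altered, `c` = out-of-category altered, `d` = neither.
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return exact two-sided p-value.
#' @examples
#' fisher_two_sided(1, 9, 11, 3)
#' @export
fisher_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1] }
  if (any(c(a, b, c, d) < 0)) fail("cell counts must be non-negative")
  n <- a + b + c + d
  if (n == 0) fail("table total must be > 0")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p_obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control (`stats::p.adjust(method = "BH")`), returned
#' in input order and capped at 1.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) fail("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Build alteration indicator columns for a cohort
#'
#' Translates alteration predicates into a cases x alterations logical
#' matrix suitable for [enrichment_matrix()]. Each predicate is a list with
#' `type` (`"variant"`, `"itd"`, `"ptd"` or `"fusion"`) and `gene`:
#' `"variant"` means a pathogenic/likely-pathogenic variant in the gene,
#' `"itd"`/`"ptd"` a tandem duplication of that kind, `"fusion"` any
#' fusion/SV touching the gene.
#'
#' @param cohort a `paml_cohort`.
#' @param predicates named list of predicates, e.g.
#'   `list("FLT3-ITD" = list(type = "itd", gene = "FLT3"))`.
#' @return logical matrix, rownames = case_id.
#' @export
alteration_indicators <- function(cohort, predicates) {
  ids <- cohort$cases$case_id
  out <- matrix(FALSE, length(ids), length(predicates),
                dimnames = list(ids, names(predicates)))
  for (nm in names(predicates)) {
    p <- predicates[[nm]]
    hit_ids <- switch(p$type,
      variant = {
        v <- cohort$variants
        unique(v$case_id[v$gene == p$gene &
                         v$pathogenicity %in% c("pathogenic", "likely_pathogenic")])
      },
      itd = , ptd = {
        td <- cohort$tandem_dups
        unique(td$case_id[td$gene == p$gene & td$kind == p$type])
      },
      fusion = {
        f <- cohort$fusions
        unique(f$case_id[f$gene_a == p$gene | f$gene_b == p$gene])
      },
      fail("unknown alteration predicate type '%s'", p$type))
    out[hit_ids, nm] <- TRUE
  }
  out
}

#' Category x alteration enrichment matrix
#'
#' For every (category, alteration) cell: the alteration frequency within
#' the category, a two-sided Fisher exact p-value of the category vs the
#' rest of the cohort, and a Benjamini-Hochberg q-value. The adjustment
#' family is either the full grid (default) or each alteration's column.
#'
#' @param labels data.frame with `case_id` and `label` (e.g.
#'   `classify_cohort()$results`).
#' @param alterations logical matrix from [alteration_indicators()] (rows
#'   keyed by case_id).
#' @param family `"global"` (adjust across all cells) or `"per_alteration"`.
#' @param min_cases categories with fewer cases are excluded with a warning
#'   (default 1, i.e. only empty categories).
#' @return data.frame with one row per cell: `category`, `alteration`,
#'   `n_category`, `n_altered`, `frequency`, `p`, `q`, `sig_p`, `sig_q`.
#' @export
enrichment_matrix <- function(labels, alterations,
                              family = c("global", "per_alteration"),
                              min_cases = 1L) {
  family <- match.arg(family)
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  common <- intersect(labels$case_id, rownames(alterations))
  if (length(common) == 0L) fail("no shared case_ids between labels and alterations")
  labels <- labels[match(common, labels$case_id), ]
  alterations <- alterations[common, , drop = FALSE]
  cats <- sort(unique(labels$label))
  sizes <- table(labels$label)[cats]
  drop <- cats[sizes < min_cases]
  if (length(drop)) {
    warning(sprintf("excluding categories with < %d cases: %s", min_cases,
                    paste(drop, collapse = ", ")))
    cats <- setdiff(cats, drop)
  }
  cells <- expand.grid(category = cats, alteration = colnames(alterations),
                       stringsAsFactors = FALSE)
  stat <- t(mapply(function(cat, alt) {
    in_cat <- labels$label == cat
    altered <- alterations[, alt]
    a <- sum(in_cat & altered); b <- sum(in_cat & !altered)
    c_ <- sum(!in_cat & altered); d <- sum(!in_cat & !altered)
    c(n_category = a + b, n_altered = a,
      frequency = if (a + b > 0) a / (a + b) else NA_real_,
      p = fisher_two_sided(a, b, c_, d))
  }, cells$category, cells$alteration))
  out <- cbind(cells, as.data.frame(stat))
  out$q <- if (family == "global") bh_adjust(out$p)
           else stats::ave(out$p, out$alteration, FUN = bh_adjust)
  out$sig_p <- out$p < 0.05
  out$sig_q <- out$q < 0.05
  rownames(out) <- NULL
  out
}
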