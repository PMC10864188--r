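# Tiered, mutually exclusive category assignment.
#
# Every case receives exactly one label: rules are evaluated in (tier,
# registry-order) sequence and the first match wins; all later matches are
# recorded as notes so conflicting evidence is surfaced without ever
# producing a second label. Myelodysplasia-related mutations and karyotype
# events never classify - they remain annotations on the clinical table.

# does one fusion row match an unordered A::B pattern (wildcard "*")?
match_fusion_pairs <- function(fusions, patterns) {
  if (nrow(fusions) == 0L) return(logical(0))
  hit <- rep(FALSE, nrow(fusions))
  for (pat in patterns) {
    ab <- strsplit(pat, "::", fixed = TRUE)[[1]]
    fwd <- (ab[1] == "*" | fusions$gene_a == ab[1]) &
           (ab[2] == "*" | fusions$gene_b == ab[2])
    rev <- (ab[1] == "*" | fusions$gene_b == ab[1]) &
           (ab[2] == "*" | fusions$gene_a == ab[2])
    hit <- hit | fwd | rev
  }
  hit
}

# evidence strings for one rule against one case bundle; character(0) = no match
rule_evidence <- function(rule, bundle) {
  ev <- character()
  fus <- bundle$fusions
  if (!is.null(rule$fusion_pairs) && nrow(fus)) {
    hit <- match_fusion_pairs(fus, rule$fusion_pairs)
    if (any(hit))
      ev <- c(ev, sprintf("fusion:%s::%s", fus$gene_a[hit], fus$gene_b[hit]))
  }
  if (!is.null(rule$fusion_genes) && nrow(fus)) {
    hit <- fus$gene_a %in% rule$fusion_genes | fus$gene_b %in% rule$fusion_genes
    if (any(hit))
      ev <- c(ev, sprintf("fusion:%s::%s", fus$gene_a[hit], fus$gene_b[hit]))
  }
  if (!is.null(rule$mutation_genes) && nrow(bundle$variants)) {
    v <- bundle$variants
    hit <- v$gene %in% rule$mutation_genes &
      v$pathogenicity %in% c("pathogenic", "likely_pathogenic") &
      (rule$mutation_class == "any" | v$variant_class == rule$mutation_class)
    if (any(hit))
      ev <- c(ev, sprintf("mutation:%s(%s)", v$gene[hit], v$variant_class[hit]))
  }
  if (!is.null(rule$tandem_dup) && nrow(bundle$tandem_dups)) {
    td <- bundle$tandem_dups
    cl <- rule$tandem_dup
    hit <- td$gene == cl$gene & td$kind %in% cl$kinds &
      td$supporting_reads >= cl$min_reads & td$caller_score < cl$max_score
    if (any(hit)) ev <- c(ev, sprintf("tandem-dup:%s(%s)", td$gene[hit], td$kind[hit]))
  }
  unique(ev)
}

# look up ASE / outlier / score entries in a classification context
context_ase_ok <- function(context, case_id, gene) {
  if (is.null(context)) return(FALSE)
  ase_pos <- isTRUE(context$ase[[case_id]][[gene]])
  outlier <- isTRUE(context$outlier[[case_id]][[gene]])
  ase_pos || outlier
}

context_score <- function(context, case_id, score) {
  if (is.null(context) || is.null(context$scores)) return(NA_real_)
  s <- context$scores
  if (!case_id %in% rownames(s) || !score %in% colnames(s)) return(NA_real_)
  s[case_id, score]
}

#' Build the expression / ASE context for classification
#'
#' Precomputes, from the cohort's expression matrix and ASE marker table,
#' everything the tier-3 and tier-4 rules consult: per-case signature scores
#' (HOXA, HOXB, erythro-megakaryocytic), outlier-expression flags and ASE
#' verdicts for the SV-driven genes.
#'
#' @param cohort a `paml_cohort` with an expression matrix and/or ASE
#'   markers.
#' @param ase_genes genes assessed for ASE/outlier expression (default
#'   MECOM, BCL11B, MNX1).
#' @param signatures named list of [signature_set()]s scored per case.
#' @param alpha ASE positivity threshold passed to [assess_ase()].
#' @param z_cut outlier z-score cutoff (default 3).
#' @return list with `scores` (cases x signatures matrix), `ase` and
#'   `outlier` (per-case named logical lists).
#' @export
build_classification_context <- function(cohort,
                                         ase_genes = c("MECOM", "BCL11B", "MNX1"),
                                         signatures = list(HOXA = hoxa_signature(),
                                                           HOXB = hoxb_signature(),
                                                           ERY = ery_signature()),
                                         alpha = 0.05, z_cut = 3) {
  ids <- cohort$cases$case_id
  scores <- NULL
  outlier <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(cohort$expression)) {
    m <- cohort$expression
    if (identical(expr_units(m), "raw_counts")) m <- log2cpm(m)
    have <- Filter(function(s) any(s$genes %in% rownames(m)), signatures)
    if (length(have)) {
      scores <- vapply(have, function(s) signature_score(m, s), numeric(ncol(m)))
      rownames(scores) <- colnames(m)
    }
    for (g in intersect(ase_genes, rownames(m))) {
      fl <- suppressWarnings(outlier_expression_flag(m, g, z_cut = z_cut))
      for (id in intersect(ids, names(fl)))
        outlier[[id]][[g]] <- unname(fl[id])
    }
  }
  ase <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(cohort$ase)) {
    by_cg <- split(cohort$ase, list(cohort$ase$case_id, cohort$ase$gene), drop = TRUE)
    for (tab in by_cg) {
      mode <- if (all(is.na(tab$vaf_wgs))) "rna_only" else "wgs_paired"
      v <- assess_ase(tab, mode = mode, alpha = alpha)
      ase[[tab$case_id[1]]][[tab$gene[1]]] <- isTRUE(v$positive)
    }
  }
  list(scores = scores, ase = ase, outlier = outlier)
}

#' Classify one case
#'
#' Evaluates the registry's rules in tier order against the case's evidence
#' bundle. The first matching rule assigns the label; every other matching
#' rule is recorded in `notes` (prefix `also-matched:`), and two matches in
#' the same tier additionally produce a `tier-conflict:` note. Tier-3 rules
#' require allele-specific or outlier expression of the target gene; tier-4
#' rules require the expression-consistency score to reach their threshold
#' (an absent context fails the check, noted as
#' `consistency-unavailable:`). A case matching no rule falls back to
#' `Unclassified`.
#'
#' @param bundle a [case_bundle()].
#' @param registry a `paml_registry` (default [default_registry()]).
#' @param context optional [build_classification_context()] output.
#' @return one-row data.frame: `case_id`, `label`, `tier`, `evidence`,
#'   `notes`.
#' @export
classify_case <- function(bundle, registry = default_registry(), context = NULL) {
  ord <- order(vapply(registry, `[[`, 1L, "tier"), seq_along(registry))
  matched <- list()
  notes <- character()
  for (i in ord) {
    rule <- registry[[i]]
    ev <- rule_evidence(rule, bundle)
    if (length(ev) == 0L) next
    if (!is.null(rule$requires_ase)) {
      if (!context_ase_ok(context, bundle$case_id, rule$requires_ase)) {
        notes <- c(notes, sprintf(
          if (is.null(context)) "ase-unavailable:%s" else "ase-negative:%s",
          rule$label))
        next
      }
      ev <- c(ev, sprintf("ase-or-outlier:%s", rule$requires_ase))
    }
    if (!is.null(rule$consistency)) {
      sc <- context_score(context, bundle$case_id, rule$consistency$score)
      if (is.na(sc)) {
        notes <- c(notes, sprintf("consistency-unavailable:%s", rule$label))
        next
      }
      if (sc < rule$consistency$threshold) {
        notes <- c(notes, sprintf("inconsistent-expression:%s", rule$label))
        next
      }
      ev <- c(ev, sprintf("consistent-expression:%s=%.2f",
                          rule$consistency$score, sc))
    }
    matched[[length(matched) + 1L]] <- list(rule = rule, evidence = ev)
  }
  if (length(matched) == 0L) {
    return(data.frame(case_id = bundle$case_id, label = "Unclassified",
                      tier = NA_integer_, evidence = "",
                      notes = paste(notes, collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  first <- matched[[1L]]
  if (length(matched) > 1L) {
    for (m in matched[-1L]) {
      notes <- c(notes, sprintf("also-matched:%s(tier%d)",
                                m$rule$label, m$rule$tier))
      if (m$rule$tier == first$rule$tier)
        notes <- c(notes, sprintf("tier-conflict:%s|%s",
                                  first$rule$label, m$rule$label))
    }
  }
  data.frame(case_id = bundle$case_id, label = first$rule$label,
             tier = first$rule$tier,
             evidence = paste(first$evidence, collapse = ";"),
             notes = paste(notes, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Classify every case of a cohort
#'
#' Runs [classify_case()] over the cohort. When `context` is `NULL` and the
#' cohort carries expression or ASE data, the classification context is
#' built automatically.
#'
#' @param cohort a `paml_cohort`.
#' @param registry a `paml_registry`.
#' @param context optional precomputed context.
#' @return list of class `"paml_classification"`: `results` (one row per
#'   case) and `coverage` (fraction of cases not Unclassified).
#' @export
classify_cohort <- function(cohort, registry = default_registry(),
                            context = NULL) {
  if (is.null(context) && (!is.null(cohort$expression) || nrow(cohort$ase)))
    context <- build_classification_context(cohort)
  ids <- cohort$cases$case_id
  res <- do.call(rbind, lapply(ids, function(id)
    classify_case(case_bundle(cohort, id), registry, context)))
  structure(list(results = res,
                 coverage = mean(res$label != "Unclassified")),
            class = "paml_classification")
}

#' @export
print.paml_classification <- function(x, ...) {
  cat(sprintf("Classified %d cases; coverage %.1f%% (not Unclassified)\n",
              nrow(x$results), 100 * x$coverage))
  tab <- sort(table(x$results$label), decreasing = TRUE)
  for (lbl in names(utils::head(tab, 10)))
    cat(sprintf("  %-22s %d\n", lbl, tab[[lbl]]))
  if (length(tab) > 10) cat(sprintf("  ... and %d more labels\n", length(tab) - 10))
  invisible(x)
}
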