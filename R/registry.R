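# The category registry: an ordered, configurable rule set defining the 23
# mutually exclusive pAML molecular categories plus the Unclassified
# fallback.
#
# Rules are organized in four tiers mirroring the diagnostic workflow:
#   tier 1  category-defining fusions / structural variants
#   tier 2  defining mutations and tandem duplications
#   tier 3  SV-driven labels that additionally require allele-specific or
#           outlier expression of the target gene (MECOM, BCL11B, MNX1)
#   tier 4  conditional labels (GATA1, HOXr, KMT2A-PTD) assigned only when
#           no earlier rule fired AND the case's expression is consistent
#           with the category's expected signature
# Within a tier, registry order is the deterministic tie-break; any
# additional matches are logged as conflict notes, never as labels.

#' Construct a category rule
#'
#' A rule matches a case when any of its evidence clauses matches, subject
#' to its `requires_ase` and `consistency` conditions.
#'
#' @param label category label (unique within a registry).
#' @param tier integer priority, lower fires earlier (>= 1).
#' @param fusion_pairs character vector of unordered `"A::B"` gene-pair
#'   patterns; `"*"` is a wildcard for either side.
#' @param fusion_genes gene symbols or regular expressions (prefix `re:`)
#'   matched against either fusion partner.
#' @param mutation_genes gene symbols; a pathogenic or likely-pathogenic
#'   variant in one of them matches.
#' @param mutation_class restrict `mutation_genes` to `"snv"`, `"indel"` or
#'   `"any"` (default).
#' @param tandem_dup list with `gene`, and optional `kinds` (default both),
#'   `min_reads` (default 3) and `max_score` (default 10, exclusive).
#' @param requires_ase gene symbol: the case must be ASE-positive or an
#'   expression outlier for this gene (tier-3 style evidence).
#' @param consistency list with `score` (a score name in the classification
#'   context, e.g. `"HOXB"`) and `threshold` (default 0.5): tier-4 style
#'   expression-consistency requirement.
#' @return a list of class `"category_rule"`.
#' @export
category_rule <- function(label, tier, fusion_pairs = NULL, fusion_genes = NULL,
                          mutation_genes = NULL, mutation_class = "any",
                          tandem_dup = NULL, requires_ase = NULL,
                          consistency = NULL) {
  if (tier < 1) fail("tier must be >= 1")
  if (!is.null(tandem_dup)) {
    tandem_dup <- utils::modifyList(
      list(kinds = TD_KINDS, min_reads = 3L, max_score = 10), tandem_dup)
    if (is.null(tandem_dup$gene)) fail("tandem_dup clause needs a gene")
  }
  if (!is.null(consistency)) {
    consistency <- utils::modifyList(list(threshold = 0.5), consistency)
    if (is.null(consistency$score)) fail("consistency clause needs a score name")
  }
  if (!is.null(fusion_pairs) &&
      !all(grepl("^[^:]+::[^:]+$", fusion_pairs)))
    fail("fusion_pairs must look like 'A::B'")
  structure(list(label = label, tier = as.integer(tier),
                 fusion_pairs = fusion_pairs, fusion_genes = fusion_genes,
                 mutation_genes = mutation_genes, mutation_class = mutation_class,
                 tandem_dup = tandem_dup, requires_ase = requires_ase,
                 consistency = consistency),
            class = "category_rule")
}

#' HOX-cluster gene symbols
#'
#' Genes counted as HOX-cluster members for the HOXr rearrangement rule.
#' @return character vector.
#' @export
hox_cluster_genes <- function() {
  c(paste0("HOXA", 1:13), paste0("HOXB", 1:13))
}

#' The default 23-category registry
#'
#' Builds the shipped rule set: the 11 WHO-defined categories (APL,
#' RUNX1::RUNX1T1, CBFB::MYH11, DEK::NUP214, RBM15::MRTFA, BCR::ABL1,
#' KMT2Ar, MECOM, NUP98r, NPM1, CEBPA) and 12 further categories (UBTF,
#' GLISr, FET::ETS, BCL11B, PICALM::MLLT10, KAT6Ar, MNX1,
#' RUNX1::RUNX1T1-like, CBFB-GDXY, GATA1, HOXr, KMT2A-PTD). Unclassified is
#' the fallback, not a rule. Gene-family memberships (KMT2A and NUP98
#' partners, GLIS = GLIS2/GLIS3, FET x ETS pairs, RUNX1::RUNX1T1-like =
#' RUNX1 x CBFA2T2/CBFA2T3, HOX cluster genes) are encoded in the rules and
#' editable by rebuilding the registry.
#'
#' Notes on specific rules: NPM1 carries both its defining C-terminal-indel
#' clause and an NPM1-fusion clause, since fusion cases are assigned to the
#' same category; TBL1XR1::RARB is assigned to APL alongside PML::RARA; the
#' CEBPA rule accepts any pathogenic CEBPA mutation (set
#' `cebpa_require_inframe_indel = TRUE` for the stricter bZIP-style rule
#' restricted to in-frame indels).
#'
#' @param cebpa_require_inframe_indel restrict the CEBPA rule to indels.
#' @return an object of class `"paml_registry"` (ordered list of rules).
#' @export
default_registry <- function(cebpa_require_inframe_indel = FALSE) {
  r <- list(
    # --- tier 1: defining fusions / SVs -------------------------------
    category_rule("APL", 1, fusion_pairs = c("PML::RARA", "TBL1XR1::RARB")),
    category_rule("RUNX1::RUNX1T1", 1, fusion_pairs = "RUNX1::RUNX1T1"),
    category_rule("CBFB::MYH11", 1, fusion_pairs = "CBFB::MYH11"),
    category_rule("DEK::NUP214", 1, fusion_pairs = "DEK::NUP214"),
    category_rule("RBM15::MRTFA", 1, fusion_pairs = "RBM15::MRTFA"),
    category_rule("BCR::ABL1", 1, fusion_pairs = "BCR::ABL1"),
    category_rule("KMT2Ar", 1, fusion_pairs = "KMT2A::*"),
    category_rule("NUP98r", 1, fusion_pairs = "NUP98::*"),
    category_rule("GLISr", 1, fusion_genes = c("GLIS2", "GLIS3")),
    category_rule("FET::ETS", 1,
                  fusion_pairs = as.vector(outer(c("FUS", "EWSR1"),
                                                 c("ERG", "FEV", "FLI1"),
                                                 function(a, b) paste0(a, "::", b)))),
    category_rule("PICALM::MLLT10", 1, fusion_pairs = "PICALM::MLLT10"),
    category_rule("KAT6Ar", 1, fusion_pairs = "KAT6A::*"),
    category_rule("RUNX1::RUNX1T1-like", 1,
                  fusion_pairs = c("RUNX1::CBFA2T2", "RUNX1::CBFA2T3")),
    # --- tier 2: defining mutations / tandem duplications -------------
    category_rule("NPM1", 2, mutation_genes = "NPM1", mutation_class = "indel",
                  fusion_pairs = "NPM1::*"),
    category_rule("CEBPA", 2, mutation_genes = "CEBPA",
                  mutation_class = if (cebpa_require_inframe_indel) "indel" else "any"),
    category_rule("UBTF", 2,
                  tandem_dup = list(gene = "UBTF", min_reads = 3L, max_score = 10)),
    category_rule("CBFB-GDXY", 2, mutation_genes = "CBFB",
                  mutation_class = "indel"),
    # --- tier 3: SV + allele-specific / outlier expression ------------
    category_rule("MECOM", 3, fusion_genes = "MECOM", requires_ase = "MECOM"),
    category_rule("BCL11B", 3, fusion_genes = "BCL11B", requires_ase = "BCL11B"),
    category_rule("MNX1", 3, fusion_genes = "MNX1", requires_ase = "MNX1"),
    # --- tier 4: conditional, expression-consistency labels -----------
    category_rule("GATA1", 4, mutation_genes = "GATA1", fusion_genes = "GATA1",
                  consistency = list(score = "ERY", threshold = 0.5)),
    category_rule("HOXr", 4, fusion_genes = hox_cluster_genes(),
                  consistency = list(score = "HOXA", threshold = 0.5)),
    category_rule("KMT2A-PTD", 4,
                  tandem_dup = list(gene = "KMT2A", kinds = "ptd",
                                    min_reads = 3L, max_score = 10),
                  consistency = list(score = "HOXB", threshold = 0.5))
  )
  structure(r, class = "paml_registry")
}

#' All category labels of a registry (plus the fallback)
#' @param registry a `paml_registry`.
#' @param with_fallback include `"Unclassified"` (default TRUE).
#' @return character vector.
#' @export
registry_labels <- function(registry, with_fallback = TRUE) {
  labs <- vapply(registry, `[[`, "", "label")
  if (with_fallback) c(labs, "Unclassified") else labs
}

#' Lint a category registry
#'
#' Checks label uniqueness, tier values and ordering (non-decreasing tiers),
#' gene-pattern syntax, that no rule claims the reserved `Unclassified`
#' label, and - for the shipped default - that exactly 23 category labels
#' are defined.
#'
#' @param registry a `paml_registry`.
#' @param expect_n_labels expected number of rules (default 23); set `NULL`
#'   to skip the count check.
#' @return list with `ok` (logical), `problems` (character vector) and
#'   `n_labels`.
#' @export
registry_lint <- function(registry, expect_n_labels = 23L) {
  problems <- character()
  if (length(registry) == 0L) problems <- c(problems, "registry is empty")
  labs <- vapply(registry, function(r) r$label %||% NA_character_, "")
  if (anyDuplicated(labs))
    problems <- c(problems, sprintf("duplicated label(s): %s",
                                    paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  if ("Unclassified" %in% labs)
    problems <- c(problems, "'Unclassified' is the fallback and may not be a rule")
  tiers <- vapply(registry, function(r) r$tier %||% NA_integer_, 1L)
  if (any(is.na(tiers)) || any(tiers < 1L))
    problems <- c(problems, "every rule needs an integer tier >= 1")
  else if (is.unsorted(tiers))
    problems <- c(problems, "rules must be ordered by non-decreasing tier")
  for (r in registry) {
    if (!is.null(r$fusion_pairs) && !all(grepl("^[^:]+::[^:]+$", r$fusion_pairs)))
      problems <- c(problems, sprintf("rule '%s': malformed fusion pair pattern", r$label))
    has_clause <- !is.null(r$fusion_pairs) || !is.null(r$fusion_genes) ||
      !is.null(r$mutation_genes) || !is.null(r$tandem_dup)
    if (!has_clause)
      problems <- c(problems, sprintf("rule '%s': no evidence clause", r$label))
  }
  if (!is.null(expect_n_labels) && length(registry) != expect_n_labels)
    problems <- c(problems, sprintf("expected %d rules, found %d",
                                    expect_n_labels, length(registry)))
  list(ok = length(problems) == 0L, problems = problems, n_labels = length(registry))
}

#' Write / read a registry as YAML
#'
#' The registry serializes to a plain YAML document (one entry per rule) so
#' that sites can version and edit their rule set outside R.
#'
#' @param registry a `paml_registry`.
#' @param path file path.
#' @return `read_registry` returns a `paml_registry`; `write_registry`
#'   returns the path invisibly.
#' @export
write_registry <- function(registry, path) {
  plain <- lapply(registry, function(r) Filter(Negate(is.null), unclass(r)))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  plain <- yaml::read_yaml(path)
  rules <- lapply(plain, function(p) {
    do.call(category_rule, list(
      label = p$label, tier = p$tier,
      fusion_pairs = unlist(p$fusion_pairs),
      fusion_genes = unlist(p$fusion_genes),
      mutation_genes = unlist(p$mutation_genes),
      mutation_class = p$mutation_class %||% "any",
      tandem_dup = p$tandem_dup,
      requires_ase = p$requires_ase,
      consistency = p$consistency))
  })
  structure(rules, class = "paml_registry")
}
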