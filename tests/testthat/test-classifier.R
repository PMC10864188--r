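# one-case cohort builder for classification scenarios
one_case <- function(fusions = empty_fusions(), variants = empty_variants(),
                     tandem_dups = empty_tandem_dups(), id = "c1") {
  paml_cohort(cases_table(id), fusions, variants, tandem_dups)
}

classify_one <- function(cohort, context = NULL, id = "c1") {
  classify_case(case_bundle(cohort, id), default_registry(), context)
}

# context with chosen signature scores / ase flags for case c1
ctx <- function(HOXA = -1, HOXB = -1, ERY = -1, ase = list(), outlier = list(),
                id = "c1") {
  scores <- matrix(c(HOXA, HOXB, ERY), 1,
                   dimnames = list(id, c("HOXA", "HOXB", "ERY")))
  list(scores = scores,
       ase = stats::setNames(list(ase), id),
       outlier = stats::setNames(list(outlier), id))
}

test_that("the default registry lints clean with exactly 23 category labels", {
  lint <- registry_lint(default_registry())
  expect_true(lint$ok)
  expect_equal(lint$n_labels, 23L)
  expect_equal(length(registry_labels(default_registry())), 24L)  # + fallback

  dup <- c(default_registry(), default_registry()[1])
  expect_false(registry_lint(dup, expect_n_labels = NULL)$ok)
  expect_false(registry_lint(structure(list(), class = "paml_registry"),
                             expect_n_labels = NULL)$ok)
})

test_that("defining fusions assign their category regardless of cooperating mutations", {
  r <- classify_one(one_case(fusions = fusion_row()))
  expect_equal(r$label, "RUNX1::RUNX1T1")
  expect_equal(r$tier, 1L)

  # NUP98r with FLT3-ITD and WT1: cooperating mutations do not reassign
  ch <- one_case(
    fusions = fusion_row(gene_a = "NUP98", gene_b = "NSD1"),
    variants = variant_row(gene = "WT1"),
    tandem_dups = td_row(gene = "FLT3", chrom = "chr13",
                         start = 28577400L, end = 28577450L))
  r2 <- classify_one(ch)
  expect_equal(r2$label, "NUP98r")
  # orientation does not matter for family patterns
  r3 <- classify_one(one_case(fusions = fusion_row(gene_a = "NSD1", gene_b = "NUP98")))
  expect_equal(r3$label, "NUP98r")
})

test_that("special fusion mappings: TBL1XR1::RARB to APL, NPM1 fusions to NPM1", {
  expect_equal(classify_one(one_case(
    fusions = fusion_row(gene_a = "TBL1XR1", gene_b = "RARB")))$label, "APL")
  expect_equal(classify_one(one_case(
    fusions = fusion_row(gene_a = "NPM1", gene_b = "MLF1")))$label, "NPM1")
  expect_equal(classify_one(one_case(
    variants = variant_row(gene = "NPM1", variant_class = "indel")))$label, "NPM1")
})

test_that("KMT2A-PTD is conditional on expression consistency and earlier drivers", {
  ptd <- td_row(gene = "KMT2A", chrom = "chr11",
                start = 118307200L, end = 118307230L, kind = "ptd")
  # consistent HOXB expression, no fusion: KMT2A-PTD
  r <- classify_one(one_case(tandem_dups = ptd), ctx(HOXB = 1.5))
  expect_equal(r$label, "KMT2A-PTD")
  expect_equal(r$tier, 4L)
  # same case WITH a KMT2Ar fusion: the fusion wins, PTD surfaces as a note
  r2 <- classify_one(one_case(
    fusions = fusion_row(gene_a = "KMT2A", gene_b = "MLLT3"),
    tandem_dups = ptd), ctx(HOXB = 1.5))
  expect_equal(r2$label, "KMT2Ar")
  expect_match(r2$notes, "also-matched:KMT2A-PTD")
  # inconsistent expression: no label, but the evidence is noted
  r3 <- classify_one(one_case(tandem_dups = ptd), ctx(HOXB = -0.5))
  expect_equal(r3$label, "Unclassified")
  expect_match(r3$notes, "inconsistent-expression:KMT2A-PTD")
  # without any context the check cannot pass
  r4 <- classify_one(one_case(tandem_dups = ptd))
  expect_equal(r4$label, "Unclassified")
  expect_match(r4$notes, "consistency-unavailable")
})

test_that("SV-driven categories require ASE or outlier expression", {
  sv <- fusion_row(gene_a = "RPN1", gene_b = "MECOM", in_frame = FALSE,
                   source = "dna_sv")
  r <- classify_one(one_case(fusions = sv), ctx(ase = list(MECOM = TRUE)))
  expect_equal(r$label, "MECOM")
  expect_equal(r$tier, 3L)
  r2 <- classify_one(one_case(fusions = sv), ctx(outlier = list(MECOM = TRUE)))
  expect_equal(r2$label, "MECOM")
  r3 <- classify_one(one_case(fusions = sv), ctx())
  expect_equal(r3$label, "Unclassified")
  expect_match(r3$notes, "ase-negative:MECOM")
})

test_that("every case gets exactly one label, deterministically", {
  ch <- one_case(fusions = rbind(
    fusion_row(gene_a = "RUNX1", gene_b = "RUNX1T1"),
    fusion_row(gene_a = "KMT2A", gene_b = "MLLT3")))
  r <- replicate(3, classify_one(ch)$label)
  expect_equal(unique(r), "RUNX1::RUNX1T1")   # registry order resolves tier ties
  note <- classify_one(ch)$notes
  expect_match(note, "tier-conflict:RUNX1::RUNX1T1\\|KMT2Ar")
  # evidence-row order never changes the label
  ch2 <- ch; ch2$fusions <- ch2$fusions[2:1, ]
  expect_equal(classify_one(ch2)$label, "RUNX1::RUNX1T1")
  # no qualifying evidence: the fallback
  expect_equal(classify_one(one_case())$label, "Unclassified")
})

test_that("cohort classification reports coverage and handles edge cohorts", {
  ch <- paml_cohort(cases_table(c("c1", "c2")),
                    fusions = fusion_row("c1"))
  cl <- classify_cohort(ch)
  expect_equal(nrow(cl$results), 2L)
  expect_equal(cl$coverage, 0.5)
  expect_equal(sort(cl$results$label), c("RUNX1::RUNX1T1", "Unclassified"))
  # all-empty cohort: coverage 0
  empty <- paml_cohort(cases_table(c("e1", "e2")))
  expect_equal(classify_cohort(empty)$coverage, 0)
  # single defining case: coverage 1
  solo <- paml_cohort(cases_table("s"), fusions = fusion_row("s"))
  expect_equal(classify_cohort(solo)$coverage, 1)
})

test_that("registries survive a YAML round-trip", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(registry_labels(back), registry_labels(reg))
  expect_true(registry_lint(back)$ok)
  # a case classifies identically under the round-tripped registry
  ch <- one_case(fusions = fusion_row(gene_a = "KAT6A", gene_b = "CREBBP"))
  expect_equal(classify_case(case_bundle(ch, "c1"), back)$label, "KAT6Ar")
})
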