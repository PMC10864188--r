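test_that("somatic filter applies every rule with the documented boundary semantics", {
  cfg <- somatic_filter_config()
  v <- rbind(
    variant_row("c1", population_af = 0.002),          # fails population-af
    variant_row("c2", vaf = 0.05, alt_reads = 5L,
                total_reads = 100L),                   # VAF <= 5% and reads <= 5
    variant_row("c3", vaf = 0.06, alt_reads = 6L,
                total_reads = 100L),                   # just above both cuts
    variant_row("c4", pathogenicity = "uncertain"),
    variant_row("c5", gene = "ZZZ9"))
  dec <- filter_rna_somatic(v, cfg, n_cohort_cases = 100L)
  expect_equal(dec$kept, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_match(dec$reasons[1], "population-af")
  expect_match(dec$reasons[2], "read-support")
  expect_match(dec$reasons[2], "vaf")
  expect_match(dec$reasons[4], "pathogenicity")
  expect_match(dec$reasons[5], "gene-panel")
  # every removed record carries >= 1 documented reason
  expect_true(all(nzchar(dec$reasons[!dec$kept])))
  rules <- unique(unlist(strsplit(dec$reasons[!dec$kept], ";")))
  expect_true(all(rules %in% c("gene-panel", "pathogenicity", "population-af",
                               "recurrence", "read-support", "vaf")))
  expect_true(all(dec$reasons[dec$kept] == ""))
})

test_that("cohort recurrence above 5% of cases removes the shared allele", {
  # the same allele in 6 of 100 cases -> 6% recurrence -> removed everywhere
  shared <- do.call(rbind, lapply(1:6, function(i)
    variant_row(sprintf("c%d", i), pos = 777L)))
  private <- variant_row("c7", pos = 999L)
  dec <- filter_rna_somatic(rbind(shared, private), n_cohort_cases = 100L)
  expect_true(all(!dec$kept[dec$pos == 777L]))
  expect_true(all(grepl("recurrence", dec$reasons[dec$pos == 777L])))
  expect_true(dec$kept[dec$pos == 999L])
  # 5 of 100 is exactly 5%: kept (filter is "> 5%")
  dec5 <- filter_rna_somatic(shared[1:5, ], n_cohort_cases = 100L)
  expect_true(all(dec5$kept))
})

test_that("somatic filter handles empty input and is idempotent", {
  expect_equal(nrow(filter_rna_somatic(empty_variants())), 0L)
  set.seed(42)
  v <- do.call(rbind, lapply(1:60, function(i) {
    tot <- sample(20:120, 1)
    alt <- sample(1:tot, 1)
    variant_row(sprintf("c%d", sample(1:30, 1)),
                gene = sample(c("WT1", "NRAS", "ZZZ9"), 1),
                pos = sample(1:20L, 1),
                vaf = alt / tot, alt_reads = alt, total_reads = tot,
                population_af = sample(c(0, 0.0005, 0.002), 1),
                pathogenicity = sample(PATHOGENICITY_LEVELS, 1))
  }))
  dec <- filter_rna_somatic(v, n_cohort_cases = 30L)
  kept <- dec[dec$kept, names(v)]
  dec2 <- filter_rna_somatic(kept, n_cohort_cases = 30L)
  expect_true(all(dec2$kept))
  expect_equal(dec2[names(v)], kept, ignore_attr = TRUE)
})

test_that("tightening any somatic threshold never enlarges the kept set", {
  set.seed(7)
  v <- do.call(rbind, lapply(1:80, function(i) {
    tot <- sample(10:150, 1)
    alt <- sample(1:tot, 1)
    variant_row(sprintf("c%d", sample(1:40, 1)),
                gene = sample(default_somatic_panel(), 1),
                pos = sample(1:25L, 1),
                vaf = alt / tot, alt_reads = alt, total_reads = tot,
                population_af = stats::runif(1, 0, 0.004),
                pathogenicity = sample(PATHOGENICITY_LEVELS, 1))
  }))
  base_kept <- function(cfg) {
    d <- filter_rna_somatic(v, cfg, n_cohort_cases = 40L)
    which(d$kept)
  }
  loose <- base_kept(somatic_filter_config())
  tighter <- list(
    somatic_filter_config(max_population_af = 5e-4),
    somatic_filter_config(max_cohort_recurrence = 0.02),
    somatic_filter_config(min_supporting_reads_exclusive = 10L),
    somatic_filter_config(min_vaf_exclusive = 0.15),
    somatic_filter_config(gene_panel = default_somatic_panel()[1:10]))
  for (cfg in tighter) expect_true(all(base_kept(cfg) %in% loose))
})

test_that("UBTF-TD detector applies candidate and soft-clip criteria", {
  cfg <- ubtf_td_config()
  ok <- td_row(supporting_reads = 3L, caller_score = 5)
  low_reads <- td_row(supporting_reads = 2L, caller_score = 5)
  high_score <- td_row(supporting_reads = 8L, caller_score = 10)
  far <- td_row(start = 42300000L, end = 42300050L)
  res <- detect_ubtf_td(rbind(ok, low_reads, high_score, far),
                        data.frame(chrom = character(), clip_pos = integer(),
                                   clip_len = integer()), cfg)
  expect_equal(nrow(res$retained), 1L)
  expect_equal(res$retained$supporting_reads, 3L)
  expect_true(res$positive)

  # soft-clip channel: clip_len >= 10 inside the hotspot counts
  reads <- data.frame(
    chrom = "chr17",
    clip_pos = c(42288170L, 42288170L, 42288170L, 42288170L, 42288100L),
    clip_len = c(10L, 12L, 9L, 30L, 50L))
  res2 <- detect_ubtf_td(empty_tandem_dups(), reads, cfg)
  expect_equal(res2$softclip_count, 3L)              # clip_len 9 and outside excluded
  expect_equal(res2$total_reads_at_hotspot, 4L)
  expect_true(res2$positive)
  # brute-force oracle for the soft-clip count
  oracle <- 0L
  for (i in seq_len(nrow(reads)))
    if (reads$chrom[i] == "chr17" && reads$clip_len[i] >= 10 &&
        reads$clip_pos[i] >= 42288162 && reads$clip_pos[i] <= 42288192)
      oracle <- oracle + 1L
  expect_equal(res2$softclip_count, oracle)
  # two qualifying soft-clip reads only: below the evidence minimum
  res3 <- detect_ubtf_td(empty_tandem_dups(), reads[1:2, ], cfg)
  expect_false(res3$positive)
})

test_that("germline criteria keep both coverage and VAF boundaries inclusively", {
  snv_edge <- variant_row(gene = "RUNX1", vaf = 0.2, alt_reads = 4L, total_reads = 20L)
  snv_low_cov <- variant_row(gene = "RUNX1", vaf = 0.2, alt_reads = 4L, total_reads = 19L)
  snv_low_vaf <- variant_row(gene = "RUNX1", vaf = 0.19, alt_reads = 19L, total_reads = 100L)
  indel_edge <- variant_row(gene = "RUNX1", vaf = 0.2, alt_reads = 3L,
                            total_reads = 15L, variant_class = "indel")
  indel_thin <- variant_row(gene = "RUNX1", vaf = 0.13, alt_reads = 2L,
                            total_reads = 15L, variant_class = "indel")
  common <- variant_row(gene = "RUNX1", population_af = 0.002)
  dec <- germline_candidate_filter(rbind(snv_edge, snv_low_cov, snv_low_vaf,
                                         indel_edge, indel_thin, common))
  expect_equal(dec$kept, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_match(dec$reasons[2], "coverage")
  expect_match(dec$reasons[3], "vaf-range")
  expect_match(dec$reasons[5], "alt-support")
  expect_match(dec$reasons[6], "population-af")
})

test_that("genotype concordance flags duplicates at the 90% cutoff", {
  gt <- function(n_match, n_total) {
    a <- data.frame(snp_id = sprintf("rs%d", 1:n_total),
                    genotype = rep("AB", n_total), coverage = 30L)
    b <- a
    if (n_match < n_total)
      b$genotype[(n_match + 1):n_total] <- "AA"
    list(a = a, b = b)
  }
  g <- gt(100, 100)
  r <- genotype_concordance(g$a, g$b)
  expect_equal(r$concordance, 1)
  expect_true(r$duplicate)
  r89 <- genotype_concordance(gt(89, 100)$a, gt(89, 100)$b)
  expect_equal(r89$concordance, 0.89)
  expect_false(r89$duplicate)
  r90 <- genotype_concordance(gt(90, 100)$a, gt(90, 100)$b)
  expect_true(r90$duplicate)
  # low-coverage SNPs are excluded before comparison
  g2 <- gt(90, 100)
  g2$a$coverage[1:50] <- 5L
  expect_equal(genotype_concordance(g2$a, g2$b)$n_shared, 50L)
  g3 <- gt(5, 5); g3$a$coverage <- 1L
  expect_error(genotype_concordance(g3$a, g3$b), "shared")
})
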