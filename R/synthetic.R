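# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure the analyses assume - category-defining
# alterations at configurable frequencies, category-conditional cooperating
# mutations, HOXA/HOXB/marker signature expression blocks with
# negative-binomial counts, skewed ASE read counts for SV-driven categories,
# MRD status and exponential survival with uniform censoring - and returns
# the full ground truth, so every module is testable without patient data.
# Defining evidence is always emitted above the screening thresholds: a
# generated truth label is detectable by construction.

#' Default category frequency / structure table
#'
#' One row per category (plus Unclassified): the sampling frequency
#' (approximating the published cohort composition: KMT2Ar 20.3%,
#' RUNX1::RUNX1T1 12.4%, NPM1 7.6%, CEBPA 5.5%, Unclassified 8.6%, the rest
#' distributed plausibly), the HOX superfamily of the category (HOXA =
#' KMT2Ar/KAT6Ar/HOXr; HOXB = NPM1/NUP98r/UBTF/KMT2A-PTD/DEK::NUP214) and
#' the defining-evidence type emitted by the generator.
#'
#' @return data.frame `label`, `freq`, `hox`, `defining`.
#' @export
default_category_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
label freq hox defining
KMT2Ar 0.203 HOXA fusion
RUNX1::RUNX1T1 0.124 other fusion
NUP98r 0.095 HOXB fusion
CBFB::MYH11 0.085 other fusion
NPM1 0.076 HOXB mutation
CEBPA 0.055 other mutation
UBTF 0.045 HOXB tandem_dup
GLISr 0.030 other fusion
KMT2A-PTD 0.025 HOXB tandem_dup
APL 0.020 other fusion
DEK::NUP214 0.020 HOXB fusion
MECOM 0.020 other sv_ase
FET::ETS 0.015 other fusion
BCL11B 0.015 other sv_ase
RBM15::MRTFA 0.010 other fusion
BCR::ABL1 0.010 other fusion
PICALM::MLLT10 0.010 other fusion
KAT6Ar 0.010 HOXA fusion
MNX1 0.010 other sv_ase
GATA1 0.010 other mutation
HOXr 0.010 HOXA fusion
RUNX1::RUNX1T1-like 0.008 other fusion
CBFB-GDXY 0.008 other mutation
Unclassified 0.086 other none
")
  stopifnot(abs(sum(tab$freq) - 1) < 1e-9)
  tab
}

# fusion partner pools for the rearrangement families
FUSION_PARTNERS <- list(
  "APL" = c("PML::RARA", "PML::RARA", "TBL1XR1::RARB"),
  "RUNX1::RUNX1T1" = "RUNX1::RUNX1T1",
  "CBFB::MYH11" = "CBFB::MYH11",
  "DEK::NUP214" = "DEK::NUP214",
  "RBM15::MRTFA" = "RBM15::MRTFA",
  "BCR::ABL1" = "BCR::ABL1",
  "KMT2Ar" = paste0("KMT2A::", c("MLLT3", "MLLT10", "ELL", "AFDN", "MLLT11", "SEPTIN6")),
  "NUP98r" = paste0("NUP98::", c("NSD1", "NSD1", "KDM5A", "BPTF")),
  "GLISr" = c("CBFA2T3::GLIS2", "CBFA2T3::GLIS2", "PAX5::GLIS3"),
  "FET::ETS" = c("FUS::ERG", "FUS::ERG", "EWSR1::FLI1", "FUS::FEV"),
  "PICALM::MLLT10" = "PICALM::MLLT10",
  "KAT6Ar" = paste0("KAT6A::", c("CREBBP", "EP300")),
  "RUNX1::RUNX1T1-like" = c("RUNX1::CBFA2T2", "RUNX1::CBFA2T3"),
  "HOXr" = c("HOXA9::PRDM16", "HOXB8::PRDM16"),
  "MECOM" = "RPN1::MECOM",
  "BCL11B" = "ARID1B::BCL11B",
  "MNX1" = "ETV6::MNX1")

# representative loci for generated variants (chrom, anchor position)
GENE_LOCI <- list(
  NPM1 = c("chr5", 170814708), CEBPA = c("chr19", 33790840),
  CBFB = c("chr16", 67029147), GATA1 = c("chrX", 48644982),
  WT1 = c("chr11", 32409321), KRAS = c("chr12", 25358180),
  NRAS = c("chr1", 115251156), FLT3 = c("chr13", 28577411),
  UBTF = c("chr17", 42288162), KMT2A = c("chr11", 118307205),
  TET2 = c("chr4", 106155100), DNMT3A = c("chr2", 25457000))

#' Generator configuration
#'
#' All frequencies, conditional probabilities, expression effect sizes,
#' hazards and the seed for [generate_cohort()]. The defaults are the study
#' conditions the rest of the package is tested under; see the package
#' vignette for the rationale behind each value.
#'
#' @param n_cases cohort size (default 500).
#' @param seed RNG seed.
#' @param category_table category frequency/structure table
#'   (default [default_category_table()]); `freq` must sum to 1.
#' @param coop list of cooperating-mutation probabilities: each element has
#'   a `base` rate and named per-category (or per-HOX-group, prefix `hox:`)
#'   overrides.
#' @param expr_log2_effect log2 expression shift of signature blocks
#'   (default 3, i.e. 8-fold).
#' @param outlier_log2_effect log2 shift of the MECOM/BCL11B/MNX1 marker
#'   gene in its own category (default 4).
#' @param nb_size negative-binomial size (inverse dispersion) of counts
#'   (default 10).
#' @param n_noise_genes unstructured background genes (default 150).
#' @param ase_skew allele fraction of the overexpressed allele at ASE
#'   markers of SV-driven cases (default 0.9).
#' @param mrd_probs MRD-positivity probability per risk group.
#' @param mrd_missing_rate fraction of cases with unknown MRD (default 0.04).
#' @param stratum_hazards exponential hazard (per year) for each of the six
#'   risk strata, in [stratum_levels()] order.
#' @param censor_range uniform censoring window in years (default 3-10).
#' @param passenger_rate probability of a non-pathogenic passenger variant
#'   per case (default 0.3).
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_cases = 500L, seed = 1L,
                             category_table = default_category_table(),
                             coop = list(
                               `FLT3-ITD` = list(base = 0.05, `NUP98r` = 0.60,
                                                 NPM1 = 0.45, UBTF = 0.50,
                                                 `KMT2A-PTD` = 0.50, BCL11B = 0.50),
                               WT1 = list(base = 0.05, `NUP98r` = 0.45,
                                          UBTF = 0.45, BCL11B = 0.40),
                               KRAS = list(base = 0.04, `hox:HOXA` = 0.25),
                               NRAS = list(base = 0.18)),
                             expr_log2_effect = 3, outlier_log2_effect = 4,
                             nb_size = 10, n_noise_genes = 150L,
                             ase_skew = 0.9,
                             mrd_probs = c(low = 0.30, intermediate = 0.40,
                                           high = 0.50),
                             mrd_missing_rate = 0.04,
                             stratum_hazards = c(0.02, 0.10, 0.25, 0.55, 1.0, 2.0),
                             censor_range = c(3, 10),
                             passenger_rate = 0.3) {
  if (abs(sum(category_table$freq) - 1) > 1e-9)
    fail("category frequencies must sum to 1")
  probs <- unlist(lapply(coop, function(x) unlist(x)))
  if (any(probs < 0 | probs > 1)) fail("cooperating-mutation probabilities must be in [0, 1]")
  if (any(stratum_hazards <= 0)) fail("stratum hazards must be > 0")
  if (length(stratum_hazards) != 6L) fail("need one hazard per stratum (6)")
  if (ase_skew <= 0.5 || ase_skew > 1) fail("ase_skew must be in (0.5, 1]")
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 category_table = category_table, coop = coop,
                 expr_log2_effect = expr_log2_effect,
                 outlier_log2_effect = outlier_log2_effect,
                 nb_size = nb_size, n_noise_genes = as.integer(n_noise_genes),
                 ase_skew = ase_skew, mrd_probs = mrd_probs,
                 mrd_missing_rate = mrd_missing_rate,
                 stratum_hazards = stats::setNames(stratum_hazards, stratum_levels()),
                 censor_range = censor_range,
                 passenger_rate = passenger_rate),
            class = "generator_config")
}

# one somatic variant row; pos jittered so exact alleles do not recur across
# cases (the cohort-recurrence screen keys on chrom/pos/ref/alt)
make_variant <- function(case_id, gene, class, pathogenicity = "pathogenic",
                         vaf_lo = 0.25, vaf_hi = 0.55) {
  loc <- GENE_LOCI[[gene]] %||% c("chr1", 1e6)
  total <- 30L + stats::rpois(1L, 50)
  vaf <- stats::runif(1L, vaf_lo, vaf_hi)
  alt <- max(6L, as.integer(round(vaf * total)))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1L)
  alt_allele <- if (class == "indel") paste0(ref, paste(sample(bases, 3L, TRUE), collapse = ""))
                else sample(setdiff(bases, ref), 1L)
  data.frame(case_id = case_id, gene = gene, chrom = loc[1],
             pos = as.integer(as.numeric(loc[2]) + sample.int(20000L, 1L)),
             ref = ref, alt = alt_allele, vaf = alt / total,
             alt_reads = alt, total_reads = total,
             population_af = stats::runif(1L, 0, 5e-4),
             pathogenicity = pathogenicity, variant_class = class,
             stringsAsFactors = FALSE)
}

make_fusion <- function(case_id, pair, in_frame = TRUE, source = "rna_fusion") {
  ab <- strsplit(pair, "::", fixed = TRUE)[[1]]
  data.frame(case_id = case_id, gene_a = ab[1], gene_b = ab[2],
             in_frame = in_frame,
             supporting_reads = 10L + stats::rpois(1L, 30),
             caller_score = stats::runif(1L, 20, 90), source = source,
             stringsAsFactors = FALSE)
}

make_td <- function(case_id, gene, kind) {
  loc <- GENE_LOCI[[gene]]
  anchor <- as.numeric(loc[2])
  data.frame(case_id = case_id, gene = gene, chrom = loc[1],
             start = as.integer(anchor - 5L), end = as.integer(anchor + 25L),
             build = "GRCh37",
             supporting_reads = 4L + stats::rpois(1L, 10),
             caller_score = stats::runif(1L, 0, 8), kind = kind,
             stringsAsFactors = FALSE)
}

coop_prob <- function(coop_entry, category, hox) {
  p <- coop_entry[[category]] %||% coop_entry[[paste0("hox:", hox)]] %||%
    coop_entry$base
  p
}

#' Generate a synthetic pAML cohort
#'
#' Draws, for each case: a molecular category from the configured
#' frequencies; the category's defining evidence (fusion/SV, mutation,
#' tandem duplication, or SV with skewed ASE markers and outlier
#' expression), always above the detection thresholds of the screening
#' module; cooperating mutations from the category-conditional
#' probabilities; negative-binomial expression counts with the category's
#' signature blocks shifted; MRD status; and exponential survival censored
#' uniformly, with the hazard of the case's risk stratum. All draws come
#' from the seeded generator, so a fixed seed reproduces the cohort
#' byte-identically; the global RNG state is left untouched.
#'
#' @param config a [generator_config()].
#' @return list of class `"synthetic_cohort"`: `cohort` (a [paml_cohort()]
#'   with expression and ASE markers attached) and `truth` (per-case true
#'   category, HOX group, risk group, stratum and planted mutation flags,
#'   with attribute `asserted_enrichments`: the category-mutation pairs
#'   powered for detection at the default cohort size).
#' @export
generate_cohort <- function(config = generator_config()) {
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  tab <- config$category_table
  n <- config$n_cases
  ids <- sprintf("case_%04d", seq_len(n))
  category <- sample(tab$label, n, replace = TRUE, prob = tab$freq)
  hox <- tab$hox[match(category, tab$label)]
  risk_map <- default_risk_map()
  risk <- risk_map$group[match(category, risk_map$category)]

  fusions <- list(); variants <- list(); tds <- list(); ase <- list()
  for (i in seq_len(n)) {
    cat_i <- category[i]; id <- ids[i]
    def <- tab$defining[match(cat_i, tab$label)]
    if (def == "fusion") {
      pair <- sample(FUSION_PARTNERS[[cat_i]], 1L)
      fusions[[length(fusions) + 1L]] <- make_fusion(id, pair)
    } else if (def == "mutation") {
      if (cat_i == "NPM1") {
        # mostly C-terminal-style indels, occasionally an NPM1 fusion
        if (stats::runif(1L) < 0.9)
          variants[[length(variants) + 1L]] <- make_variant(id, "NPM1", "indel")
        else
          fusions[[length(fusions) + 1L]] <- make_fusion(id, "NPM1::MLF1")
      } else if (cat_i == "CEBPA") {
        variants[[length(variants) + 1L]] <-
          make_variant(id, "CEBPA", sample(c("snv", "indel"), 1L))
      } else if (cat_i == "CBFB-GDXY") {
        variants[[length(variants) + 1L]] <- make_variant(id, "CBFB", "indel")
      } else if (cat_i == "GATA1") {
        if (stats::runif(1L) < 0.7)
          variants[[length(variants) + 1L]] <- make_variant(id, "GATA1", "snv")
        else
          fusions[[length(fusions) + 1L]] <- make_fusion(id, "MYB::GATA1")
      }
    } else if (def == "tandem_dup") {
      gene <- if (cat_i == "UBTF") "UBTF" else "KMT2A"
      kind <- if (cat_i == "UBTF") sample(c("itd", "ptd"), 1L) else "ptd"
      tds[[length(tds) + 1L]] <- make_td(id, gene, kind)
    } else if (def == "sv_ase") {
      fusions[[length(fusions) + 1L]] <-
        make_fusion(id, FUSION_PARTNERS[[cat_i]], in_frame = FALSE,
                    source = "dna_sv")
      skew <- if (stats::runif(1L) < 0.5) config$ase_skew else 1 - config$ase_skew
      for (k in 1:4) {
        cov <- 15L + stats::rpois(1L, 40)
        alt <- stats::rbinom(1L, cov, skew)
        ase[[length(ase) + 1L]] <- data.frame(
          case_id = id, gene = cat_i, snp_id = sprintf("%s_snp%d", cat_i, k),
          ref_reads_rna = cov - alt, alt_reads_rna = alt,
          vaf_wgs = stats::runif(1L, 0.35, 0.65),
          cov_wgs = 30L + stats::rpois(1L, 20), stringsAsFactors = FALSE)
      }
    }
    # cooperating mutations
    for (mut in names(config$coop)) {
      p <- coop_prob(config$coop[[mut]], cat_i, hox[i])
      if (stats::runif(1L) >= p) next
      if (mut == "FLT3-ITD") {
        tds[[length(tds) + 1L]] <- make_td(id, "FLT3", "itd")
      } else {
        variants[[length(variants) + 1L]] <-
          make_variant(id, mut, "snv", vaf_lo = 0.15, vaf_hi = 0.45)
      }
    }
    if (stats::runif(1L) < config$passenger_rate) {
      variants[[length(variants) + 1L]] <-
        make_variant(id, sample(c("TET2", "DNMT3A"), 1L), "snv",
                     pathogenicity = sample(c("uncertain", "benign"), 1L))
    }
  }
  fusions <- if (length(fusions)) do.call(rbind, fusions) else empty_fusions()
  variants <- if (length(variants)) do.call(rbind, variants) else empty_variants()
  tds <- if (length(tds)) do.call(rbind, tds) else empty_tandem_dups()
  ase_tab <- if (length(ase)) do.call(rbind, ase) else empty_ase()

  # ---- expression ----------------------------------------------------
  sig_genes <- list(hoxa = hoxa_signature()$genes, hoxb = hoxb_signature()$genes,
                    ery = ery_signature()$genes,
                    markers = c("MECOM", "BCL11B", "MNX1"))
  genes <- c(unlist(sig_genes, use.names = FALSE),
             sprintf("NOISE%03d", seq_len(config$n_noise_genes)))
  genes <- unique(genes)
  base_mu <- stats::setNames(stats::rlnorm(length(genes), meanlog = 4.5, sdlog = 0.8),
                             genes)
  eff <- matrix(0, length(genes), n, dimnames = list(genes, ids))
  e <- config$expr_log2_effect
  eff[sig_genes$hoxa, hox == "HOXA" | hox == "HOXB"] <- e
  eff[sig_genes$hoxb, hox == "HOXB"] <- e
  eff[sig_genes$ery, category == "GATA1"] <- e
  for (g in sig_genes$markers)
    eff[g, category == g] <- config$outlier_log2_effect
  libfac <- stats::runif(n, 0.8, 1.2)
  mu <- sweep(base_mu * 2^eff, 2L, libfac, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                   nrow = length(genes), dimnames = list(genes, ids))
  expr <- expression_matrix(counts, "raw_counts")

  # ---- clinical / survival -------------------------------------------
  mrd_latent <- stats::runif(n) < config$mrd_probs[risk]
  stratum <- paste0(risk, "/", ifelse(mrd_latent, "MRD+", "MRD-"))
  hz <- config$stratum_hazards[stratum]
  os_raw <- stats::rexp(n, hz)
  censor <- stats::runif(n, config$censor_range[1], config$censor_range[2])
  os_time <- pmin(os_raw, censor)
  os_event <- os_raw <= censor
  nonresp_prob <- c(low = 0.005, intermediate = 0.02, high = 0.06)[risk]
  nonresponse <- stats::runif(n) < nonresp_prob
  relapse <- os_event & !nonresponse & stats::runif(n) < 0.6
  efs_time <- ifelse(nonresponse, 0,
                     ifelse(relapse, os_time * stats::runif(n, 0.5, 0.95), os_time))
  efs_event <- nonresponse | relapse | os_event
  mrd <- mrd_latent
  mrd[stats::runif(n) < config$mrd_missing_rate] <- NA

  cases <- data.frame(
    case_id = ids,
    age_years = pmin(round(stats::rgamma(n, shape = 2, scale = 4), 1), 23.5),
    timepoint = sample(TIMEPOINTS, n, replace = TRUE, prob = c(0.883, 0.117)),
    os_time = os_time, os_event = os_event,
    mrd_positive = mrd, efs_time = efs_time, efs_event = efs_event,
    nonresponse = nonresponse, relapse_flag = relapse,
    complex_karyotype = stats::runif(n) < 0.1,
    monosomy7 = stats::runif(n) < 0.05,
    stringsAsFactors = FALSE)

  cohort <- paml_cohort(cases, fusions, variants, tds, ase_tab, expr)

  truth <- data.frame(
    case_id = ids, category = category, hox_group = hox, risk_group = risk,
    mrd_positive = mrd_latent, stratum = stratum,
    flt3_itd = ids %in% tds$case_id[tds$gene == "FLT3" & tds$kind == "itd"],
    wt1 = ids %in% variants$case_id[variants$gene == "WT1" &
                                    variants$pathogenicity == "pathogenic"],
    kras = ids %in% variants$case_id[variants$gene == "KRAS" &
                                     variants$pathogenicity == "pathogenic"],
    nras = ids %in% variants$case_id[variants$gene == "NRAS" &
                                     variants$pathogenicity == "pathogenic"],
    stringsAsFactors = FALSE)
  # the planted enrichment patterns guaranteed detectable at the default
  # cohort size (one per planted pattern; the same mutations are also
  # enriched in smaller categories, where a single-seed assertion would be
  # underpowered - see the methods vignette)
  attr(truth, "asserted_enrichments") <- data.frame(
    category = c("NUP98r", "NUP98r", "KMT2Ar"),
    alteration = c("FLT3-ITD", "WT1", "KRAS"),
    stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Inject ambiguous secondary alterations
#'
#' Stresses the classifier's tier logic: a random subset of cases whose true
#' category is defined by a tier-1/2 alteration receives a second,
#' lower-tier alteration (a GATA1 mutation, a HOX-cluster fusion or a
#' KMT2A-PTD). The expected resolution - the defining alteration wins, the
#' secondary evidence is logged as a note - is recorded in the truth table
#' (`expected_label`, `injected`).
#'
#' @param sim a [generate_cohort()] result.
#' @param rate fraction of eligible cases to perturb, in `[0, 1]`.
#' @param seed RNG seed for the injection draws (default: the generator's
#'   seed + 1).
#' @return a modified `synthetic_cohort` with updated truth table.
#' @export
ambiguity_injector <- function(sim, rate, seed = sim$config$seed + 1L) {
  if (rate < 0 || rate > 1) fail("rate must be in [0, 1]")
  truth <- sim$truth
  truth$expected_label <- truth$category
  truth$injected <- FALSE
  tier12 <- setdiff(registry_labels(default_registry(), with_fallback = FALSE),
                    c("GATA1", "HOXr", "KMT2A-PTD", "MECOM", "BCL11B", "MNX1"))
  eligible <- which(truth$category %in% tier12)
  k <- round(rate * length(eligible))
  if (k == 0L) { sim$truth <- truth; return(sim) }
  cohort <- sim$cohort
  with_seed(seed, {
    picked <- sample(eligible, k)
    for (i in picked) {
      id <- truth$case_id[i]
      kind <- sample(c("gata1", "hoxr", "kmt2a_ptd"), 1L)
      if (kind == "gata1") {
        cohort$variants <- rbind(cohort$variants, make_variant(id, "GATA1", "snv"))
      } else if (kind == "hoxr") {
        cohort$fusions <- rbind(cohort$fusions, make_fusion(id, "HOXA9::PRDM16"))
      } else {
        cohort$tandem_dups <- rbind(cohort$tandem_dups, make_td(id, "KMT2A", "ptd"))
      }
    }
    truth$injected[picked] <- TRUE
  })
  sim$cohort <- cohort
  sim$truth <- truth
  sim
}

#' Build a cohort with specified marginal counts
#'
#' Constructs a minimal cohort whose [cohort_summary()] marginals equal the
#' requested counts: cases at diagnosis, cases with a fusion/SV record,
#' cases with one (or several) pathogenic RAS-pathway mutations, and cases
#' profiled on all three platforms. Used to recompute printed cohort
#' percentages from their underlying counts.
#'
#' @param n cohort size.
#' @param n_diagnosis cases sampled at diagnosis (rest at relapse).
#' @param n_fusion cases with at least one fusion/SV call.
#' @param n_ras cases with at least one RAS-pathway mutation.
#' @param n_multi_ras among those, cases with two RAS-pathway genes mutated.
#' @param n_triplatform cases with WGS + WES + RNA-seq.
#' @return a [paml_cohort()].
#' @export
synthetic_marginal_cohort <- function(n, n_diagnosis, n_fusion, n_ras,
                                      n_multi_ras, n_triplatform) {
  stopifnot(n_diagnosis <= n, n_fusion <= n, n_ras <= n, n_multi_ras <= n_ras,
            n_triplatform <= n)
  ids <- sprintf("case_%04d", seq_len(n))
  cases <- data.frame(
    case_id = ids, age_years = 8,
    timepoint = rep(c("diagnosis", "relapse"), c(n_diagnosis, n - n_diagnosis)),
    os_time = 1, os_event = FALSE,
    has_wgs = seq_len(n) <= n_triplatform,
    has_wes = seq_len(n) <= n_triplatform,
    stringsAsFactors = FALSE)
  fusions <- data.frame(
    case_id = ids[seq_len(n_fusion)], gene_a = "RUNX1", gene_b = "RUNX1T1",
    in_frame = TRUE, supporting_reads = 20L, caller_score = 50,
    source = "rna_fusion", stringsAsFactors = FALSE)
  ras_variant <- function(id, gene, pos) data.frame(
    case_id = id, gene = gene, chrom = "chr1", pos = pos, ref = "A", alt = "T",
    vaf = 0.4, alt_reads = 40L, total_reads = 100L, population_af = 0,
    pathogenicity = "pathogenic", variant_class = "snv", stringsAsFactors = FALSE)
  ras_ids <- ids[seq_len(n_ras)]
  variants <- do.call(rbind, c(
    lapply(seq_len(n_ras), function(i) ras_variant(ras_ids[i], "NRAS", 100L + i)),
    lapply(seq_len(n_multi_ras), function(i) ras_variant(ras_ids[i], "KRAS", 5000L + i))))
  paml_cohort(cases, fusions, variants %||% empty_variants())
}
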