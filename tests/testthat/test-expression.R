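make_counts <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, "raw_counts")
}

test_that("expressed-gene filter requires the cpm threshold in enough samples", {
  # library size 1e5 -> 10 cpm = 1 count
  m <- make_counts(rbind(
    rep(c(1, 0), c(5, 3)),     # >=10 cpm in exactly 5 samples: kept
    rep(c(1, 0), c(4, 4)),     # only 4 samples: dropped
    rep(0, 8),                 # all zero: dropped
    rep(99992, 8)))            # fills the library
  m[4, ] <- 1e5 - colSums(m[-4, , drop = FALSE])
  f <- filter_expressed(m, min_cpm = 10, min_samples = 5)
  expect_equal(rownames(f), c("g1", "g4"))
  # sample order does not matter
  f2 <- filter_expressed(make_counts(unclass(m)[, 8:1],
                                     samples = colnames(m)[8:1]))
  expect_setequal(rownames(f2), rownames(f))
})

test_that("log2cpm floors at zero and errors on empty libraries", {
  m <- make_counts(matrix(c(8, 0, 999992,
                            0.5, 2, 999997.5), ncol = 2))
  lc <- log2cpm(m)   # library sizes are 1e6: cpm equals the raw count
  expect_equal(unname(unclass(lc)[1, 1]), 3)      # log2(8)
  expect_equal(unname(unclass(lc)[1, 2]), 0)      # cpm 0.5 -> negative log -> floored
  expect_equal(unname(unclass(lc)[2, 1]), 0)      # zero count
  expect_equal(unname(unclass(lc)[2, 2]), 1)      # log2(2)
  expect_true(all(unclass(lc) >= 0))
  bad <- make_counts(matrix(c(1, 0, 0, 0), 2))
  expect_error(log2cpm(bad), "s2")
})

test_that("variable-gene selection recovers a planted high-variance block", {
  set.seed(3)
  quiet <- matrix(rnorm(40 * 20, sd = 0.05), 40)
  loud <- matrix(rnorm(5 * 20, sd = 4), 5)
  m <- abs(rbind(loud, quiet))
  dimnames(m) <- list(c(sprintf("LOUD%d", 1:5), sprintf("g%02d", 1:40)),
                      sprintf("s%d", 1:20))
  lc <- expression_matrix(m, "log2cpm")
  sig <- select_variable_genes(lc, n = 5)
  expect_setequal(sig$genes, sprintf("LOUD%d", 1:5))
  all_genes <- select_variable_genes(lc, n = 45)
  expect_equal(length(all_genes$genes), 45L)
  expect_error(select_variable_genes(lc, n = 100), "exceeds")
})

test_that("signature scores are mean per-gene z-scores", {
  m <- matrix(c(1, 2, 3,
                10, 20, 30), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  lc <- expression_matrix(m, "log2cpm")
  sc <- signature_score(lc, signature_set("ab", c("a", "b")))
  expect_equal(unname(sc["s2"]), 0)            # both genes at their means
  expect_equal(sc[["s1"]], -sc[["s3"]])        # symmetric samples
  expect_error(signature_score(lc, signature_set("none", "zzz")), "no genes")
})

test_that("HOX group assignment follows the two-threshold rule", {
  # build a matrix whose signature scores are controlled via single genes
  m <- rbind(HOXA9 = c(4, 4, 0, 0), HOXB5 = c(-1, 4, 4, 0),
             NOISE = c(1, 2, 3, 4))
  colnames(m) <- sprintf("s%d", 1:4)
  lc <- expression_matrix(abs(m), "log2cpm")
  sa <- signature_score(lc, signature_set("A", "HOXA9"))
  sb <- signature_score(lc, signature_set("B", "HOXB5"))
  grp <- hox_group_assign(lc, signature_set("A", "HOXA9"),
                          signature_set("B", "HOXB5"))
  manual <- ifelse(sa >= 0.5 & sb <= 0, "HOXA",
                   ifelse(sa >= 0.5 & sb >= 0.5, "HOXB", "other"))
  expect_equal(unname(grp), unname(manual))
  expect_true("HOXA" %in% grp && "other" %in% grp)
})

test_that("outlier flag fires at the z cutoff and never on flat genes", {
  x <- c(rep(1, 20), 9)   # last sample far above the rest
  m <- rbind(MECOM = x, OTHER = rep(2, 21))
  colnames(m) <- sprintf("s%d", 1:21)
  lc <- expression_matrix(m, "log2cpm")
  fl <- outlier_expression_flag(lc, "MECOM")
  expect_true(fl[["s21"]])
  expect_false(any(fl[1:20]))
  expect_warning(fl0 <- outlier_expression_flag(lc, "OTHER"), "zero variance")
  expect_false(any(fl0))
})

test_that("differential expression flags planted fold changes and controls the null", {
  set.seed(21)
  n <- 20
  base <- matrix(rnorm(50 * 2 * n, mean = 6, sd = 0.3), 50)
  dimnames(base) <- list(sprintf("g%02d", 1:50), sprintf("s%d", 1:(2 * n)))
  grp_a <- colnames(base)[1:n]; grp_b <- colnames(base)[(n + 1):(2 * n)]
  base["g01", grp_a] <- base["g01", grp_a] + 2   # planted 4-fold gene
  lc <- expression_matrix(abs(base), "log2cpm")
  de <- differential_expression(lc, grp_a, grp_b)
  expect_true(de$significant[de$gene == "g01"])
  expect_equal(de$fold_change[de$gene == "g01"], 4, tolerance = 0.3)
  expect_true(sum(de$significant) <= 3)   # null genes essentially clean

  # identical groups: nothing significant
  same <- differential_expression(lc, grp_a[1:10], grp_a[1:10 + 10])
  expect_equal(sum(same$significant), 0L)
  expect_error(differential_expression(lc, grp_a, grp_a), "overlap")

  # permuted labels behave like a null
  set.seed(22)
  perm <- sample(colnames(base))
  de_perm <- differential_expression(lc, perm[1:n], perm[(n + 1):(2 * n)])
  expect_true(sum(de_perm$significant) <= 2)
})
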