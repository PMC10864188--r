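test_that("KM estimates match closed forms", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  all_cens <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$surv == 1))
  # hand-computed mixed fixture: events at 1, 3, 5; censored at 2, 4
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(km2$surv[km2$time == 1], 4/5)
  expect_equal(km2$surv[km2$time == 3], 4/5 * 2/3)
  expect_equal(km2$surv[km2$time == 5], 4/5 * 2/3 * 0)
  expect_error(km_estimate(numeric(0), logical(0)), "no survival")
})

test_that("KM is a non-increasing step function matching the survival package", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    t <- round(rexp(n, 0.3), 2)
    e <- runif(n) < 0.7
    km <- km_estimate(t, e)
    expect_true(all(diff(km$surv) <= 1e-12))
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    expect_equal(km$surv, sf$surv, tolerance = 1e-10)
    s <- summary(sf, censored = TRUE)
    ok <- is.finite(s$std.err)
    expect_equal(km$var_greenwood[ok], (s$std.err^2)[ok], tolerance = 1e-10)
  }
})

test_that("log-rank is zero for identical groups and label-invariant", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- rep(TRUE, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  relabeled <- logrank_test(t, e, rep(c("x", "y"), each = 4))
  expect_equal(lr$chisq, relabeled$chisq)
  expect_error(logrank_test(t, e, rep("a", 8)), "2")
})

test_that("log-rank matches survdiff with ties and detects separated hazards", {
  skip_if_not_installed("survival")
  set.seed(32)
  for (i in 1:10) {
    n <- 60
    g <- rep(1:3, each = n / 3)
    t <- round(rexp(n, c(0.1, 0.2, 0.4)[g]), 1)  # rounding creates ties
    e <- runif(n) < 0.8
    lr <- logrank_test(t, e, g)
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-8)
    expect_equal(lr$df, 2L)
  }
  # hazard ratio 3 with n = 200/arm is essentially always detected
  reject <- replicate(20, {
    t1 <- rexp(200, 0.1); t2 <- rexp(200, 0.3)
    cns <- runif(400, 3, 10)
    tt <- pmin(c(t1, t2), cns); ev <- c(t1, t2) <= cns
    logrank_test(tt, ev, rep(1:2, each = 200))$p < 0.001
  })
  expect_gte(mean(reject), 0.99)
})

test_that("risk partition separates well-spaced hazards into ordered groups", {
  set.seed(33)
  cats <- rep(c("A", "B", "C"), each = 150)
  hz <- c(A = 0.05, B = 0.15, C = 0.45)[cats]
  t0 <- rexp(length(cats), hz)
  cns <- runif(length(cats), 3, 10)
  tt <- pmin(t0, cns); ev <- t0 <= cns
  map <- fit_risk_partition(tt, ev, cats)
  expect_equal(map$group[map$category == "A"], "low")
  expect_equal(map$group[map$category == "B"], "intermediate")
  expect_equal(map$group[map$category == "C"], "high")
  expect_equal(attr(map, "provenance"), "fitted")
  # permuting record order leaves the map unchanged
  perm <- sample(length(tt))
  map2 <- fit_risk_partition(tt[perm], ev[perm], cats[perm])
  expect_equal(map2, map, ignore_attr = TRUE)
})

test_that("identical hazards collapse to a single group", {
  set.seed(34)
  cats <- rep(c("A", "B", "C"), each = 80)
  t0 <- rexp(length(cats), 0.2)
  cns <- runif(length(cats), 3, 10)
  expect_warning(
    map <- fit_risk_partition(pmin(t0, cns), t0 <= cns, cats),
    "fewer than 3")
  expect_equal(unique(map$group), "intermediate")
})

test_that("strata assignment crosses risk group with MRD and reports exclusions", {
  map <- default_risk_map()
  cats <- c("RUNX1::RUNX1T1", "KMT2Ar", "UBTF", "RUNX1::RUNX1T1", "KMT2Ar", "UBTF", "NPM1")
  mrd <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, NA)
  st <- assign_strata(cats, mrd, map)
  expect_equal(as.character(st[1]), "low/MRD-")
  expect_equal(as.character(st[6]), "high/MRD+")
  expect_equal(length(levels(st)), 6L)
  expect_equal(sort(as.character(unique(st[!is.na(st)]))), sort(stratum_levels()))
  expect_equal(attr(st, "excluded"), 1L)
  expect_true(is.na(st[7]))
  expect_error(assign_strata("NotACategory", TRUE, map), "NotACategory")
})

test_that("the shipped risk map covers every registry label", {
  map <- default_risk_map()
  expect_setequal(map$category, registry_labels(default_registry()))
  expect_setequal(unique(map$group), c("low", "intermediate", "high"))
  expect_equal(attr(map, "provenance"), "configured")
})

test_that("EFS encoding counts relapse, death in remission and day-0 nonresponse", {
  cl <- cases_table(c("n1", "r1", "d1", "c1"),
                    os_time = c(2, 3, 1.5, 4),
                    os_event = c(FALSE, TRUE, TRUE, FALSE),
                    nonresponse = c(TRUE, FALSE, FALSE, FALSE),
                    relapse_flag = c(FALSE, TRUE, FALSE, FALSE),
                    efs_time = c(NA, 1.2, NA, NA),
                    efs_event = c(NA, NA, NA, NA))
  efs <- efs_encode(cl)
  expect_equal(efs$time, c(0, 1.2, 1.5, 4))
  expect_equal(efs$event, c(TRUE, TRUE, TRUE, FALSE))
  bad <- cases_table("x", nonresponse = TRUE, relapse_flag = TRUE)
  expect_error(efs_encode(bad), "contradictory")
})

test_that("Harrell's C is 1 for perfect ordering and matches the survival package", {
  skip_if_not_installed("survival")
  t <- c(5, 4, 3, 2, 1)
  e <- rep(TRUE, 5)
  score <- c(1, 2, 3, 4, 5)  # higher risk = earlier event
  expect_equal(harrell_c(t, e, score), 1)
  set.seed(35)
  for (i in 1:10) {
    n <- 80
    tt <- rexp(n); ev <- runif(n) < 0.7
    sc <- -tt + rnorm(n)
    cc <- survival::concordance(survival::Surv(tt, ev) ~ sc, reverse = TRUE)
    expect_equal(harrell_c(tt, ev, sc), unname(cc$concordance), tolerance = 1e-12)
  }
})

test_that("bootstrap concordance is seed-reproducible with sane intervals", {
  set.seed(36)
  n <- 120
  t0 <- rexp(n, 0.2); cns <- runif(n, 1, 8)
  tt <- pmin(t0, cns); ev <- t0 <= cns
  informative <- -t0 + rnorm(n, 0, 0.5)
  noise <- rnorm(n)
  b1 <- concordance_bootstrap(tt, ev, list(inf = informative, noise = noise),
                              n_boot = 100, seed = 4)
  b2 <- concordance_bootstrap(tt, ev, list(inf = informative, noise = noise),
                              n_boot = 100, seed = 4)
  expect_equal(b1$ci, b2$ci)
  expect_gt(b1$c_index[["inf"]], b1$c_index[["noise"]])
  expect_true(b1$ci["inf", 1] > 0.5)            # informative: interval above chance
  d <- b1$differences
  expect_equal(d$system_a, "inf")
  expect_gt(d$difference, 0)
  expect_true(all(d$lower <= d$difference & d$difference <= d$upper))
})
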