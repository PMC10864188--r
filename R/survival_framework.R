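# Censored-survival machinery for the prognostic framework: product-limit
# estimation, log-rank testing, recursive partitioning of molecular
# categories into risk groups, the six category-by-MRD strata, event-free
# survival encoding, and bootstrap concordance comparison.

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator with Greenwood variance. The curve starts at
#' S(0) = 1; censored observations reduce the risk set without producing a
#' step. One row is reported per distinct observed time (event or censor).
#'
#' @param time non-negative follow-up times.
#' @param event logical event indicators.
#' @return data.frame of class `"paml_km"`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `var_greenwood` (variance of S).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) fail("no survival records")
  if (any(time < 0)) fail("time must be >= 0")
  event <- as.logical(event)
  ut <- sort(unique(time))
  d <- vapply(ut, function(t) sum(time == t & event), 0)
  cns <- vapply(ut, function(t) sum(time == t & !event), 0)
  n_risk <- length(time) - c(0, cumsum(d + cns))[seq_along(ut)]
  surv <- cumprod(1 - d / n_risk)
  gw_terms <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), 0)
  var_gw <- surv^2 * cumsum(gw_terms)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = d,
                       n_censor = cns, surv = surv, var_greenwood = var_gw),
            class = c("paml_km", "data.frame"))
}

#' Restricted mean survival time from a KM curve
#'
#' Area under the KM step function from 0 to `tau`; the standard
#' whole-curve summary used here to order strata.
#'
#' @param km a [km_estimate()] result.
#' @param tau truncation time.
#' @return restricted mean survival time in the same units as `time`.
#' @export
km_rmst <- function(km, tau) {
  times <- c(0, km$time[km$time <= tau], tau)
  surv <- c(1, km$surv[km$time <= tau])
  sum(diff(times) * surv)
}

#' Log-rank test for two or more groups
#'
#' Standard observed-minus-expected log-rank statistic with the
#' hypergeometric tie correction; the statistic is compared to a chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param time,event survival data.
#' @param group group membership (>= 2 non-empty groups).
#' @return list: `chisq`, `df`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) fail("log-rank test needs >= 2 non-empty groups")
  event <- as.logical(event)
  ut <- sort(unique(time[event]))
  m <- length(ut)
  if (m == 0L)
    return(list(chisq = 0, df = k - 1L, p = 1,
                observed = table(group) * 0, expected = table(group) * 0))
  # per-group at-risk counts and event counts at each distinct event time
  nrisk <- matrix(0, m, k)
  devents <- matrix(0, m, k)
  for (g in seq_len(k)) {
    tg <- sort(time[group == levels(group)[g]])
    nrisk[, g] <- length(tg) - findInterval(ut - 1e-9 * pmax(1, abs(ut)), tg)
    te <- time[group == levels(group)[g] & event]
    devents[, g] <- tabulate(match(te, ut), nbins = m)
  }
  n_j <- rowSums(nrisk)
  d_j <- rowSums(devents)
  O <- colSums(devents)
  E <- colSums(devents * 0 + nrisk * (d_j / n_j))
  # covariance of (O - E) with ties: sum_j d_j (n_j - d_j)/(n_j - 1) (diag p - p p')
  V <- matrix(0, k, k)
  w <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  p_ij <- nrisk / n_j
  for (j in seq_len(m)) {
    pj <- p_ij[j, ]
    V <- V + w[j] * (diag(pj, k) - tcrossprod(pj))
  }
  oe <- (O - E)[-k]
  Vr <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(oe) %*% solve(Vr, oe)), error = function(e) {
    # singular covariance (degenerate groups): generalized inverse
    s <- svd(Vr)
    pos <- s$d > max(s$d) * 1e-12
    drop(t(oe) %*% s$v[, pos, drop = FALSE] %*%
           ((t(s$u[, pos, drop = FALSE]) %*% oe) / s$d[pos]))
  })
  chisq <- max(chisq, 0)
  list(chisq = chisq, df = k - 1L,
       p = stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE),
       observed = stats::setNames(O, levels(group)),
       expected = stats::setNames(E, levels(group)))
}

# total Nelson-Aalen cumulative hazard of one sample (ordering summary)
nelson_aalen_total <- function(time, event) {
  ut <- sort(unique(time[event]))
  if (length(ut) == 0L) return(0)
  d <- vapply(ut, function(t) sum(time == t & event), 0)
  n <- vapply(ut, function(t) sum(time >= t), 0)
  sum(d / n)
}

#' Partition molecular categories into risk groups
#'
#' Greedy recursive partitioning for censored event times over a
#' categorical covariate: categories are ordered by their Nelson-Aalen
#' cumulative-hazard summary, candidate binary splits run along that order,
#' and each split is chosen to maximize the two-sample log-rank statistic.
#' Splitting recurses on the leaf offering the best split until `max_leaves`
#' is reached, a candidate side would fall below `min_node` records, or no
#' split reaches `min_split_stat`. Leaves are ranked by pooled cumulative
#' hazard into low / intermediate / high risk.
#'
#' @param time,event survival data.
#' @param category category label per record.
#' @param max_leaves maximum number of leaves (default 3).
#' @param min_node minimum records per leaf (default 20).
#' @param min_split_stat minimum log-rank chi-square to accept a split
#'   (default `qchisq(0.95, 1)`).
#' @return data.frame of class `"risk_group_map"` with `category` and
#'   `group`; attributes `provenance` (`"fitted"`) and `leaf_hazard`. With
#'   fewer leaves than three the available ranks are used (a single leaf is
#'   `intermediate`; two leaves are `low`/`high`) with a warning.
#' @export
fit_risk_partition <- function(time, event, category, max_leaves = 3L,
                               min_node = 20L,
                               min_split_stat = stats::qchisq(0.95, 1)) {
  event <- as.logical(event)
  category <- as.character(category)
  cats <- sort(unique(category))
  if (sum(vapply(cats, function(cc) any(event[category == cc]), TRUE)) < 2L)
    fail("need >= 2 categories with events")
  haz <- vapply(cats, function(cc)
    nelson_aalen_total(time[category == cc], event[category == cc]), 0)
  ord_cats <- cats[order(haz, cats)]   # hazard order, ties by label
  leaves <- list(ord_cats)
  repeat {
    if (length(leaves) >= max_leaves) break
    best <- NULL
    for (li in seq_along(leaves)) {
      leaf <- leaves[[li]]
      if (length(leaf) < 2L) next
      for (cut in seq_len(length(leaf) - 1L)) {
        left <- leaf[seq_len(cut)]
        grp <- ifelse(category %in% left, "L", "R")
        sel <- category %in% leaf
        if (sum(sel & grp == "L") < min_node || sum(sel & grp == "R") < min_node)
          next
        lr <- logrank_test(time[sel], event[sel], grp[sel])
        if (is.null(best) || lr$chisq > best$chisq)
          best <- list(li = li, cut = cut, chisq = lr$chisq)
      }
    }
    if (is.null(best) || best$chisq < min_split_stat) break
    leaf <- leaves[[best$li]]
    leaves <- append(leaves[-best$li],
                     list(leaf[seq_len(best$cut)],
                          leaf[-seq_len(best$cut)]))
  }
  leaf_haz <- vapply(leaves, function(le) {
    sel <- category %in% le
    nelson_aalen_total(time[sel], event[sel])
  }, 0)
  leaves <- leaves[order(leaf_haz)]
  leaf_haz <- sort(leaf_haz)
  rank_names <- switch(as.character(length(leaves)),
                       "1" = "intermediate",
                       "2" = c("low", "high"),
                       "3" = c("low", "intermediate", "high"),
                       paste0("group", seq_along(leaves)))
  if (length(leaves) < 3L)
    warning(sprintf("partition produced %d group(s), fewer than 3", length(leaves)))
  map <- do.call(rbind, lapply(seq_along(leaves), function(i)
    data.frame(category = leaves[[i]], group = rank_names[i],
               stringsAsFactors = FALSE)))
  map <- map[order(map$category), ]
  rownames(map) <- NULL
  structure(map, provenance = "fitted",
            leaf_hazard = stats::setNames(leaf_haz, rank_names),
            class = c("risk_group_map", "data.frame"))
}

#' The shipped category-to-risk-group map
#'
#' Figure-informed default assignment of the 23 categories (plus
#' Unclassified) to low / intermediate / high risk: favorable categories
#' (core-binding-factor leukemias, CEBPA, DEK::NUP214, MNX1,
#' RUNX1::RUNX1T1-like, CBFB-GDXY) are low; GLISr, MECOM, PICALM::MLLT10,
#' KAT6Ar and UBTF are high; all remaining categories, including
#' Unclassified, are intermediate. Provenance is `"configured"`; use
#' [fit_risk_partition()] to refit from outcome data.
#'
#' @param registry registry whose labels the map must cover.
#' @return a `risk_group_map` data.frame.
#' @export
default_risk_map <- function(registry = default_registry()) {
  low <- c("RUNX1::RUNX1T1", "CBFB::MYH11", "CEBPA", "DEK::NUP214", "MNX1",
           "RUNX1::RUNX1T1-like", "CBFB-GDXY")
  high <- c("GLISr", "MECOM", "PICALM::MLLT10", "KAT6Ar", "UBTF")
  labs <- registry_labels(registry)
  map <- data.frame(category = labs,
                    group = ifelse(labs %in% low, "low",
                                   ifelse(labs %in% high, "high", "intermediate")),
                    stringsAsFactors = FALSE)
  structure(map, provenance = "configured",
            class = c("risk_group_map", "data.frame"))
}

#' The six risk-stratum labels
#'
#' Cross of risk group and MRD status, ordered from best to worst prognosis.
#' @return character vector of length 6.
#' @export
stratum_levels <- function() {
  as.vector(outer(c("MRD-", "MRD+"), c("low", "intermediate", "high"),
                  function(m, g) paste0(g, "/", m)))
}

#' Assign cases to the six category-by-MRD strata
#'
#' Maps each case's category to its risk group and crosses it with MRD
#' status. Cases with missing MRD are excluded (returned as `NA`) and
#' counted in the exclusion report.
#'
#' @param category category label per case.
#' @param mrd_positive logical MRD status per case (NA allowed).
#' @param map a `risk_group_map` covering every category present.
#' @return factor with the six ordered [stratum_levels()]; attribute
#'   `excluded` gives the number of missing-MRD cases.
#' @export
assign_strata <- function(category, mrd_positive, map = default_risk_map()) {
  unmapped <- setdiff(unique(category), map$category)
  if (length(unmapped))
    fail("categories missing from the risk map: %s", paste(unmapped, collapse = ", "))
  grp <- map$group[match(category, map$category)]
  lab <- ifelse(is.na(mrd_positive), NA_character_,
                paste0(grp, "/", ifelse(mrd_positive, "MRD+", "MRD-")))
  out <- factor(lab, levels = stratum_levels(), ordered = TRUE)
  attr(out, "excluded") <- sum(is.na(mrd_positive))
  out
}

#' Encode event-free survival from a clinical record
#'
#' EFS events are relapse, death in remission (any cause) and nonresponse;
#' nonresponse is an event at time 0 (the date of diagnosis). Precedence:
#' nonresponse, then relapse (at `efs_time`), then an explicit
#' `efs_event`/`efs_time` pair, then death (event at `os_time`), else
#' censoring at the follow-up time. A record flagged both nonresponder and
#' relapsed is contradictory and raises an error.
#'
#' @param clinical one or more rows of a cohort's `cases` table.
#' @return data.frame `case_id`, `time`, `event`.
#' @export
efs_encode <- function(clinical) {
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  nonresp <- isTRUE_vec(clinical$nonresponse)
  relapse <- isTRUE_vec(clinical$relapse_flag)
  if (any(nonresp & relapse))
    fail("contradictory flags: nonresponse and relapse on case(s) %s",
         paste(clinical$case_id[nonresp & relapse], collapse = ", "))
  n <- nrow(clinical)
  time <- numeric(n); evt <- logical(n)
  for (i in seq_len(n)) {
    if (nonresp[i]) { time[i] <- 0; evt[i] <- TRUE; next }
    if (relapse[i]) {
      time[i] <- if (!is.na(clinical$efs_time[i])) clinical$efs_time[i]
                 else clinical$os_time[i]
      evt[i] <- TRUE; next
    }
    if (!is.na(clinical$efs_event[i])) {
      time[i] <- clinical$efs_time[i]
      evt[i] <- clinical$efs_event[i]
      next
    }
    time[i] <- clinical$os_time[i]
    evt[i] <- isTRUE(as.logical(clinical$os_event[i]))  # death in remission
  }
  data.frame(case_id = clinical$case_id, time = time, event = evt,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Harrell's concordance index for an ordinal risk score
#'
#' Fraction of usable pairs ordered concordantly by the score: a pair is
#' usable when the shorter follow-up ends in an event; it is concordant when
#' the higher-risk score belongs to the earlier event, and score ties count
#' one half.
#'
#' @param time,event survival data.
#' @param score numeric risk score (higher = higher risk).
#' @return concordance in `[0, 1]`.
#' @export
harrell_c <- function(time, event, score) {
  event <- as.logical(event)
  n <- length(time)
  ti <- matrix(time, n, n); tj <- t(ti)
  ei <- matrix(event, n, n)
  usable <- (ti < tj & ei) | (ti == tj & ei & !t(ei))
  diag(usable) <- FALSE
  if (!any(usable)) fail("no usable pairs for concordance")
  si <- matrix(score, n, n); sj <- t(si)
  conc <- usable & (si > sj)
  ties <- usable & (si == sj)
  (sum(conc) + 0.5 * sum(ties)) / sum(usable)
}

#' Bootstrap comparison of risk classification systems
#'
#' Computes Harrell's C for one or more ordinal risk scores, with bootstrap
#' percentile confidence intervals (patients resampled with replacement) and
#' pairwise C-index differences between systems from the same bootstrap
#' replicates, so a difference interval excluding zero indicates a
#' significant predictiveness difference.
#'
#' @param time,event survival data.
#' @param scores named list (or matrix columns) of risk scores.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param probs CI percentiles (default 2.5 and 97.5).
#' @return list: `c_index` (point estimates), `ci` (matrix systems x 2),
#'   `differences` (data.frame of pairwise differences with CIs),
#'   `n_boot`.
#' @export
concordance_bootstrap <- function(time, event, scores, n_boot = 1000L,
                                  seed = 1L, probs = c(0.025, 0.975)) {
  if (is.matrix(scores)) scores <- as.data.frame(scores)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    fail("scores must be named")
  nsys <- length(scores)
  point <- vapply(scores, function(s) harrell_c(time, event, s), 0)
  n <- length(time)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      vapply(scores, function(s)
        tryCatch(harrell_c(time[idx], event[idx], s[idx]),
                 error = function(e) NA_real_), 0)
    }, numeric(nsys))
  })
  boots <- matrix(boots, nrow = nsys)  # systems x n_boot
  ci <- t(apply(boots, 1L, stats::quantile, probs = probs, na.rm = TRUE))
  rownames(ci) <- names(scores)
  diffs <- NULL
  if (nsys >= 2L) {
    pairs <- utils::combn(names(scores), 2L)
    diffs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      dd <- boots[match(a, names(scores)), ] - boots[match(b, names(scores)), ]
      q <- stats::quantile(dd, probs = probs, na.rm = TRUE)
      data.frame(system_a = a, system_b = b,
                 difference = point[[a]] - point[[b]],
                 lower = q[1], upper = q[2], row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  }
  list(c_index = point, ci = ci, differences = diffs, n_boot = n_boot)
}
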