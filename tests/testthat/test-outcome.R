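surv_tbl <- function(times, events = rep(1L, length(times)),
                     ids = sprintf("p%02d", seq_along(times))) {
  tibble::tibble(sample = ids, time = times, event = events)
}

test_that("co-survival rescales pairwise time differences into [0,1]", {
  s <- co_survival(surv_tbl(c(0, 5, 10)))
  expect_equal(s["p01", "p02"], 0.5)   # d = 5, max d = 10
  expect_equal(s["p01", "p03"], 0)     # the maximal-distance pair
  expect_true(all(unclass(s) >= 0 & unclass(s) <= 1))
  s <- co_survival(surv_tbl(c(3, 3, 10)))
  expect_equal(s["p01", "p02"], 1)     # equal times iff similarity 1
  expect_equal(sum(unclass(s)[upper.tri(s)] == 1), 1)
})

test_that("co-survival restricts to death events by default", {
  tbl <- surv_tbl(c(0, 5, 10, 99), events = c(1L, 1L, 1L, 0L))
  s <- co_survival(tbl)
  expect_equal(nrow(s), 3)
  expect_false("p04" %in% rownames(s))
  s_all <- co_survival(tbl, death_only = FALSE)
  expect_equal(nrow(s_all), 4)
})

test_that("degenerate all-equal survival times raise a clear error", {
  expect_error(co_survival(surv_tbl(c(7, 7, 7))), "degenerate")
})

test_that("the raw linear transform variant is exposed", {
  s <- co_survival(surv_tbl(c(0, 5, 10)), variant = "raw")
  expect_equal(s["p01", "p02"], (1 - 5) / 10)  # leaves [0,1] by design
})

test_that("kernel alignment satisfies its contracts and matches the oracle", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      a <- random_symmetric(5); b <- random_symmetric(5)
      expect_equal(kernel_alignment(a, b), oracle_kernel_alignment(a, b),
                   tolerance = 1e-12)
      expect_equal(kernel_alignment(a, b), kernel_alignment(b, a))
      expect_equal(kernel_alignment(a, a), 1)
      # invariance: positive scaling and additive constants
      expect_equal(kernel_alignment(a, 3.7 * a + 2), 1, tolerance = 1e-12)
    }
  })
  cst <- matrix(5, 4, 4)
  expect_error(kernel_alignment(cst, cst), "all zero")
})

test_that("kernel alignment refuses mismatched sample sets", {
  a <- random_symmetric(4); b <- random_symmetric(4)
  rownames(b) <- colnames(b) <- paste0("x", 1:4)
  expect_error(kernel_alignment(a, b), "sample ids differ")
})

test_that("log-rank evaluation separates distinct hazards and not identical data", {
  # identical survival in both clusters: statistic 0, p = 1
  tbl <- surv_tbl(rep(c(10, 20, 30, 40, 50), 2))
  lab <- tibble::tibble(sample = tbl$sample, cluster = rep(1:2, each = 5))
  lr <- logrank_evaluate(lab, tbl)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  withr::with_seed(41, {
    n <- 200
    tbl <- tibble::tibble(sample = sprintf("p%03d", 1:(2 * n)),
                          time = c(rexp(n, 1.0), rexp(n, 0.2)),
                          event = 1L)
    lab <- tibble::tibble(sample = tbl$sample, cluster = rep(1:2, each = n))
    lr <- logrank_evaluate(lab, tbl)
    expect_lt(lr$p_value, 1e-6)
    expect_equal(lr$df, 1L)
  })
})

test_that("clusters below the size threshold are excluded before testing", {
  tbl <- surv_tbl(1:14)
  lab <- tibble::tibble(sample = tbl$sample,
                        cluster = c(rep(1, 5), rep(2, 5), rep(3, 4)))
  lr <- logrank_evaluate(lab, tbl, min_cluster_size = 5)
  expect_equal(lr$excluded, "3")
  expect_equal(lr$df, 1L)  # only clusters 1 and 2 tested
  expect_error(logrank_evaluate(lab, tbl, min_cluster_size = 6),
               "fewer than 2 clusters")
})

test_that("KM curves respect censoring and tidy into step functions", {
  tbl <- surv_tbl(c(5, 10, 15, 20, 25, 6, 12, 18, 24, 30),
                  events = c(1L, 0L, 1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L))
  lab <- tibble::tibble(sample = tbl$sample, cluster = rep(1:2, each = 5))
  lr <- logrank_evaluate(lab, tbl)
  curves <- tidy(lr)
  expect_true(all(c("cluster", "time", "survival", "n_risk") %in% names(curves)))
  expect_true(all(curves$survival >= 0 & curves$survival <= 1))
  # survival is non-increasing within each cluster
  for (cl in unique(curves$cluster)) {
    s <- curves$survival[curves$cluster == cl]
    expect_true(all(diff(s) <= 1e-12))
  }
  g <- glance(lr)
  expect_equal(g$n_clusters, 2L)
})

test_that("conditional density partitions all pairs into equal-count bands", {
  withr::with_seed(51, {
    f <- new_similarity(random_symmetric(20, c(0, 1)), 1, "f")
    o <- new_similarity(random_symmetric(20, c(0, 1)), 1, "o")
    cd <- conditional_density(f, o, n_bands = 5)
    expect_equal(sum(cd$bands$n_pairs), 20 * 19 / 2)
    expect_lte(diff(range(cd$bands$n_pairs)), 1)
    expect_equal(cd$alignment, kernel_alignment(f, o))
    # histogram counts per band sum to band sizes
    hs <- dplyr::summarise(dplyr::group_by(cd$histograms, band),
                           n = sum(count), .groups = "drop")
    expect_equal(hs$n, cd$bands$n_pairs)
  })
})

test_that("bands are ordered when outcome equals feature similarity", {
  withr::with_seed(52, {
    f <- new_similarity(random_symmetric(15, c(0, 1)), 1, "f")
    cd <- conditional_density(f, f, n_bands = 5)
    expect_true(all(diff(cd$bands$outcome_mean) > 0))
  })
})

test_that("independent similarities give flat band distributions", {
  withr::with_seed(53, {
    m <- 64  # 2016 pairs
    f <- new_similarity(random_symmetric(m, c(0, 1)), 1, "f")
    o <- new_similarity(random_symmetric(m, c(0, 1)), 1, "o")
    cd <- conditional_density(f, o, n_bands = 5)
    counts <- tidyr::pivot_wider(cd$histograms, names_from = band,
                                 values_from = count)
    tab <- as.matrix(counts[, -1])
    tab <- tab[rowSums(tab) > 0, ]
    p <- suppressWarnings(chisq.test(tab)$p.value)
    expect_gt(p, 0.01)
  })
})

test_that("fewer pairs than bands is an error", {
  f <- new_similarity(random_symmetric(3, c(0, 1)), 1, "f")
  expect_error(conditional_density(f, f, n_bands = 5), "fewer pairs")
})

test_that("order selection is parsimonious within the alignment margin", {
  mk <- function(m) new_similarity(random_symmetric(6, c(0, 1)), 1, "x")
  withr::with_seed(61, {
    ladder <- list(mk(), mk(), mk(), mk())
    outcome <- mk()
    # stub alignment pattern by direct construction: use matrices whose
    # alignment we can steer is overkill; instead check the rule on the
    # real alignments computed from these matrices
    ord <- select_order_by_alignment(ladder, outcome, parsimony_margin = 0.01)
    al <- attr(ord, "alignments")$alignment
    best <- max(al)
    expect_equal(unclass(ord), which(al >= best - 0.01)[1],
                 ignore_attr = TRUE)
    # margin large enough to cover all rungs -> order 1 (parsimony)
    ord <- select_order_by_alignment(ladder, outcome, parsimony_margin = 2)
    expect_equal(as.integer(ord), 1L)
    # single-rung ladder -> that order
    ord <- select_order_by_alignment(ladder[1], outcome)
    expect_equal(as.integer(ord), 1L)
  })
})

test_that("alignment with co-survival peaks above order 1 when communities drive hazard", {
  peaks <- vapply(1:20, function(r) {
    co <- simulate_cohort(seed = r)
    lad <- order_ladder(co$features, max_order = 4)
    al <- attr(select_order_by_alignment(lad, co_survival(co$survival)),
               "alignments")$alignment
    which.max(al) > 1
  }, logical(1))
  expect_gte(mean(peaks), 0.7)
})

test_that("order selection mirrors the third-vs-fourth order narrative", {
  # alignments {0.10, 0.08, 0.30, 0.30} with margin 0.01 -> order 3:
  # construct kernels whose alignments with the outcome are exactly these
  # via convex mixing is fragile; instead drive the decision rule directly
  al <- c(0.10, 0.08, 0.30, 0.30)
  chosen <- which(al >= max(al) - 0.01)[1]
  expect_equal(chosen, 3L)
  # and verify the exported function applies that exact rule on real input
  base <- random_symmetric(8, c(0, 1))
  noise <- random_symmetric(8, c(0, 1))
  mix <- function(w) new_similarity(w * base + (1 - w) * noise, 1, "mix")
  ladder <- list(mix(0.1), mix(0.05), mix(0.9), mix(0.9))
  out <- new_similarity(base, 1, "outcome")
  ord <- select_order_by_alignment(ladder, out, parsimony_margin = 0.01)
  expect_equal(as.integer(ord), 3L)
})
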