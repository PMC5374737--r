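test_that("Hamming similarity counts matching positions", {
  x <- matrix(c(1L, 1L, 0L, 0L, 0L,
                1L, 0L, 0L, 0L, 1L), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("f", 1:5)))
  s <- hamming_similarity(feature_matrix(x, "binary"))
  expect_equal(s["a", "b"], 0.6)  # 3 matches of 5
  expect_equal(diag(unclass(s)), c(a = 1, b = 1))
  expect_equal(similarity_order(s), 1L)

  y <- matrix(c(1L, 0L, 1L,
                1L, 0L, 1L,
                0L, 1L, 0L), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("f", 1:3)))
  s <- hamming_similarity(feature_matrix(y, "binary"))
  expect_equal(s["a", "b"], 1)   # identical vectors
  expect_equal(s["a", "c"], 0)   # no matching positions
})

test_that("Hamming similarity treats identical ordinal values as matches", {
  x <- matrix(c(-2L, 0L, 2L, 1L,
                -2L, 1L, 2L, 0L), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("g", 1:4)))
  s <- hamming_similarity(feature_matrix(x, "ordinal"))
  expect_equal(s["a", "b"], 0.5)  # -2 and 2 match; 0/1 and 1/0 do not
})

test_that("matrix route agrees with a per-pair counting oracle", {
  fm <- small_binary_features(m = 10, n = 25, seed = 3)
  s <- hamming_similarity(fm)
  for (j in 1:9) for (k in (j + 1):10) {
    expect_equal(s[j, k], oracle_hamming(unclass(fm)[j, ], unclass(fm)[k, ]))
  }
})

test_that("pearson neighborhood similarity equals a per-pair correlation oracle", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      s <- random_symmetric(20, c(0, 1))
      s2 <- second_order(new_similarity(s, 1, "test"))
      for (pair in list(c(1, 2), c(3, 17), c(5, 20), c(9, 10))) {
        expect_equal(s2[pair[1], pair[2]],
                     oracle_row_correlation(s, pair[1], pair[2]),
                     tolerance = 1e-10)
      }
      expect_lt(max(abs(unclass(s2) - t(unclass(s2)))), 1e-12)
      expect_equal(similarity_order(s2), 2L)
    }
  })
})

test_that("identical rows correlate at 1; an exact antithetic pair at -1", {
  s <- matrix(c(1, .5, 0,
                .5, 1, .5,
                0, .5, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  s2 <- second_order(new_similarity(s, 1, "test"))
  expect_equal(s2["a", "c"], -1)  # centered rows are exact negatives
  sid <- matrix(c(1, 1, 0,
                  1, 1, 0,
                  0, 0, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  s2 <- second_order(new_similarity(sid, 1, "test"))
  expect_equal(s2["a", "b"], 1)
})

test_that("zero-variance rows get correlation 0 with a warning, never NaN", {
  s <- matrix(c(1, 1, 1,
                1, 1, 0.5,
                1, 0.5, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  s[1, ] <- s[, 1] <- 1  # row a constant
  expect_warning(s2 <- second_order(new_similarity(s, 1, "test")),
                 "zero-variance")
  expect_false(anyNA(unclass(s2)))
  expect_equal(s2["a", "b"], 0)
  expect_equal(s2["a", "a"], 1)
})

test_that("sum-normalized variant matches its defining formula", {
  withr::with_seed(7, {
    s <- random_symmetric(8, c(0.2, 1))
    n_feat <- 30L
    sim <- new_similarity(s, 1, "test", n_features = n_feat)
    s2 <- second_order(sim, variant = "sum_norm")
    for (j in 1:8) for (k in 1:8) {
      num <- sum(s[j, ] * s[, k]) / n_feat
      den <- sqrt(sum(s[j, ])) * sqrt(sum(s[, k]))
      expect_equal(s2[j, k], num / den, tolerance = 1e-12)
    }
  })
})

test_that("power_features follows the d-1 convention", {
  s <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sim <- new_similarity(s, 1, "test")
  expect_equal(unname(power_features(sim, 1)), unname(s))      # unchanged
  expect_equal(unname(power_features(sim, 3)),
               matrix(c(1.25, 1, 1, 1.25), 2))                  # S^2
  withr::with_seed(2, {
    s <- random_symmetric(6)
    p <- power_features(new_similarity(s, 1, "t"), 4)
    expect_lt(max(abs(p - t(p))), 1e-12)                        # stays symmetric
  })
})

test_that("order ladder honors max_order and the redundancy stop rule", {
  fm <- small_binary_features(m = 15, n = 40, seed = 8)
  # threshold 1: alignment can never strictly exceed it, full ladder built
  lad <- order_ladder(fm, max_order = 4, redundancy_threshold = 1)
  expect_length(lad, 4)
  expect_equal(vapply(lad, similarity_order, 1L), 1:4)
  expect_length(order_ladder(fm, max_order = 1), 1)
  # a tiny threshold stops immediately after the first rung
  lad <- order_ladder(fm, max_order = 4, redundancy_threshold = 1e-6)
  expect_length(lad, 1)
  expect_s3_class(tidy(lad), "tbl_df")
})

test_that("higher orders widen the within/between community contrast in sparse data", {
  wins <- vapply(1:20, function(sd) {
    co <- planted_communities(m = 60, n = 300, n_communities = 3,
                              p_in = 0.08, p_bg = 0.01, seed = sd)
    s1 <- hamming_similarity(co$features)
    s3 <- second_order(second_order(s1))
    comm <- co$truth$community
    w <- outer(comm, comm, "==") & upper.tri(s1)
    b <- outer(comm, comm, "!=") & upper.tri(s1)
    gap <- function(s) mean(unclass(s)[w]) - mean(unclass(s)[b])
    gap(s3) > gap(s1)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("ladder rungs become redundant on perfectly separable data", {
  co <- planted_communities(m = 30, n = 60, n_communities = 3,
                            p_in = 1, p_bg = 0, seed = 4)
  lad <- order_ladder(co$features, max_order = 5,
                      redundancy_threshold = 0.999)
  aligns <- attr(lad, "redundancy")
  expect_true(any(aligns > 0.999))   # ladder stopped early
  expect_lt(length(lad), 5)
})
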