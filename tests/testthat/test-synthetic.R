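test_that("same parameters and seed give bit-identical cohorts", {
  a <- planted_communities(m = 20, n = 50, n_communities = 2,
                           p_in = 0.3, p_bg = 0.05, seed = 123)
  b <- planted_communities(m = 20, n = 50, n_communities = 2,
                           p_in = 0.3, p_bg = 0.05, seed = 123)
  expect_identical(a, b)
  c2 <- planted_communities(m = 20, n = 50, n_communities = 2,
                            p_in = 0.3, p_bg = 0.05, seed = 124)
  expect_false(identical(unclass(a$features), unclass(c2$features)))

  s1 <- community_survival(a$truth, seed = 9)
  s2 <- community_survival(a$truth, seed = 9)
  expect_identical(s1, s2)
})

test_that("generated matrices satisfy the preprocessing invariants", {
  for (sd in 1:5) {
    co <- planted_communities(m = 25, n = 60, n_communities = 3,
                              p_in = 0.08, p_bg = 0.01, seed = sd)
    expect_true(all(rowSums(co$features) >= 1))
    expect_true(all(colSums(co$features) >= 1))
    expect_setequal(co$truth$sample, rownames(co$features))
  }
})

test_that("no-signal and full-signal regimes behave as expected", {
  skip_if_not_installed("mclust")
  # p_in = p_bg: labels are exchangeable, clustering finds nothing
  co <- planted_communities(m = 40, n = 80, n_communities = 2,
                            p_in = 0.2, p_bg = 0.2, seed = 2)
  s <- unclass(hamming_similarity(co$features))
  lab <- cutree(hclust(as.dist(1 - s), "average"), 2)
  expect_lt(abs(mclust::adjustedRandIndex(lab, co$truth$community)), 0.15)
  # p_in = 1, p_bg = 0: first-order is already block structured
  co <- planted_communities(m = 30, n = 60, n_communities = 3,
                            p_in = 1, p_bg = 0, seed = 0)
  s <- unclass(hamming_similarity(co$features))
  lab <- cutree(hclust(as.dist(1 - s), "average"), 3)
  expect_equal(mclust::adjustedRandIndex(lab, co$truth$community), 1)
})

test_that("empirical event rates match the generator probabilities", {
  co <- planted_communities(m = 60, n = 600, n_communities = 3,
                            p_in = 0.2, p_bg = 0.05, seed = 33)
  x <- unclass(co$features)
  comm <- co$truth$community
  fblock <- rep(1:3, each = 200)
  inblock <- x[, fblock == 1][comm == 1, ]
  bg <- x[, fblock == 1][comm != 1, ]
  se_in <- sqrt(0.2 * 0.8 / length(inblock))
  se_bg <- sqrt(0.05 * 0.95 / length(bg))
  expect_lt(abs(mean(inblock) - 0.2), 3 * se_in + 1e-3)
  expect_lt(abs(mean(bg) - 0.05), 3 * se_bg + 1e-3)
})

test_that("remainder samples are distributed round-robin", {
  co <- planted_communities(m = 11, n = 10, n_communities = 3,
                            p_in = 0.9, p_bg = 0.1, seed = 1)
  expect_equal(as.integer(table(co$truth$community)), c(4L, 4L, 3L))
})

test_that("p_in = p_bg = 0 is rejected", {
  expect_error(planted_communities(m = 10, n = 10, n_communities = 2,
                                   p_in = 0, p_bg = 0, seed = 1),
               "event count")
})

test_that("community survival couples hazards to communities", {
  truth <- tibble::tibble(sample = sprintf("p%03d", 1:400),
                          community = rep(1:2, each = 200))
  surv <- community_survival(truth, hazards = c(1.0, 0.2), censor_rate = 0,
                             max_follow_up = Inf, seed = 3)
  expect_true(all(surv$event == 1L))   # no censoring
  lr <- logrank_evaluate(tibble::tibble(sample = truth$sample,
                                        cluster = truth$community), surv)
  expect_lt(lr$p_value, 1e-6)
})

test_that("censoring rate is respected on average", {
  truth <- tibble::tibble(sample = sprintf("p%04d", 1:2000),
                          community = rep(1:2, each = 1000))
  surv <- community_survival(truth, hazards = c(0.01, 0.005),
                             censor_rate = 0.3, max_follow_up = Inf, seed = 4)
  expect_lt(abs(mean(surv$event == 0L) - 0.3), 0.04)
})

test_that("voxel phantoms respect jitter and community geometry", {
  ph <- voxel_phantom(grid = c(20, 20, 20),
                      centers = rbind(c(6, 6, 6), c(14, 14, 14)),
                      radii = c(3, 4), jitter = 0, m_per_community = 4,
                      seed = 5)
  # jitter 0: all masks within a community identical
  expect_identical(ph$masks$masks[["c1_s01"]], ph$masks$masks[["c1_s04"]])
  fm <- flatten_and_filter_voxels(ph$masks, min_count = 1)
  s <- hamming_similarity(fm)
  within <- s["c1_s01", "c1_s02"]
  expect_equal(within, 1)
  # disjoint spheres: retained voxels are one community's or the other's,
  # so between-community similarity on them is ~0
  expect_lt(s["c1_s01", "c2_s01"], 1e-9)
})

test_that("jittered phantoms keep within-community similarity above between", {
  ph <- voxel_phantom(seed = 6, m_per_community = 5)
  fm <- flatten_and_filter_voxels(ph$masks, min_count = 2)
  s <- unclass(hamming_similarity(fm))
  comm <- ph$truth$community
  w <- outer(comm, comm, "==") & upper.tri(s)
  b <- outer(comm, comm, "!=") & upper.tri(s)
  expect_gt(mean(s[w]), mean(s[b]))
})

test_that("degenerate phantom radii and overflowing spheres are rejected", {
  expect_error(voxel_phantom(radii = c(0.5, 6, 7)), "degenerate radius")
  expect_error(voxel_phantom(grid = c(10, 10, 10)), "fit inside")
})
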