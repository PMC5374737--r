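# Deterministic sub-stream seeds: one user-facing seed per simulated cohort,
# with a stage tag hashed in so adding a stage never perturbs earlier draws.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 1))
}

#' Planted-community binary feature matrix
#'
#' Generates the sparse regime that motivates higher-order metrics: samples
#' fall into C hidden communities, features split into C matching blocks,
#' and a sample carries an event on an own-block feature with probability
#' `p_in` and elsewhere with probability `p_bg`. With `p_in` close to
#' `p_bg` and both small, few events are shared between any two samples and
#' first-order similarity is only weakly associated with the communities.
#'
#' Defaults are the sparse study regime used throughout the package's
#' evaluations: 120 samples, 600 features, 3 communities, `p_in = 0.08`,
#' `p_bg = 0.01`. All-zero rows and columns are redrawn so the output always
#' satisfies the preprocessing invariants (every sample and feature has at
#' least one event). Non-divisible sample or feature counts assign the
#' remainder round-robin to the first communities.
#'
#' @param m,n Samples and features.
#' @param n_communities Number of planted communities C (>= 2).
#' @param p_in,p_bg Within-block / background event probabilities,
#'   `0 <= p_bg <= p_in <= 1`.
#' @param seed Integer seed; same parameters + seed give a bit-identical
#'   cohort.
#' @return A `hocus_cohort` list: `features` (binary `hocus_features`),
#'   `truth` (tibble `sample`, `community`), `params`.
#' @export
planted_communities <- function(m = 120L, n = 600L, n_communities = 3L,
                                p_in = 0.08, p_bg = 0.01, seed = 1L) {
  stopifnot(n_communities >= 2L, m >= 2L * n_communities,
            n >= n_communities, p_bg >= 0, p_in <= 1, p_bg <= p_in)
  if (p_in == 0) stop("expected event count is zero (p_in = p_bg = 0)",
                      call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(seed, "features"))

  block_sizes <- function(total, C) {
    rep(total %/% C, C) + (seq_len(C) <= total %% C)
  }
  comm <- rep(seq_len(n_communities), times = block_sizes(m, n_communities))
  fblock <- rep(seq_len(n_communities), times = block_sizes(n, n_communities))
  probs <- matrix(p_bg, m, n)
  probs[outer(comm, fblock, "==")] <- p_in

  draw <- function(p) (stats::runif(length(p)) < p) * 1L
  x <- matrix(draw(probs), m, n)
  for (round in 1:100) {
    zr <- which(rowSums(x) == 0L)
    for (i in zr) {
      while (sum(x[i, ] <- draw(probs[i, ])) == 0L) NULL
    }
    zc <- which(colSums(x) == 0L)
    for (j in zc) {
      while (sum(x[, j] <- draw(probs[, j])) == 0L) NULL
    }
    if (!length(zr) && !length(zc)) break
  }
  dimnames(x) <- list(sprintf("s%03d", seq_len(m)), sprintf("f%04d", seq_len(n)))
  structure(list(
    features = feature_matrix(x, "binary"),
    truth = tibble::tibble(sample = rownames(x), community = comm),
    params = list(m = m, n = n, n_communities = n_communities, p_in = p_in,
                  p_bg = p_bg, seed = as.integer(seed))),
    class = "hocus_cohort")
}

#' @export
print.hocus_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf("<hocus_cohort> %d samples x %d features, %d communities\n",
              p$m, p$n, p$n_communities))
  if (!is.null(x$survival)) cat(sprintf("  with survival (%d events)\n",
                                        sum(x$survival$event)))
  invisible(x)
}

#' Survival outcomes driven by community membership
#'
#' Draws exponential event times with a per-community hazard, applies
#' independent exponential censoring calibrated so that roughly
#' `censor_rate` of observations are censored, plus administrative
#' censoring at `max_follow_up`. Identical hazards give a null cohort for
#' type-I calibration; well-separated hazards give strongly separated
#' Kaplan-Meier curves.
#'
#' Default hazards are spaced by the same 5-fold ratio used in the
#' two-group power checks (`hazards = c(1.0, 0.2)` up to time units),
#' expressed in days: `log(2) / c(90, 450, 2250)`, i.e. median survival of
#' about 3, 15 and 75 months — a poor/intermediate/good-prognosis spread of
#' the kind seen between aggressive and indolent disease subtypes — with
#' 20% random censoring and 5 years of follow-up.
#'
#' @param truth Tibble with columns `sample`, `community` (or a
#'   `hocus_cohort`).
#' @param hazards Per-community event hazard (per day), recycled to the
#'   number of communities; all > 0.
#' @param censor_rate Target random-censoring fraction in [0, 1).
#' @param max_follow_up Administrative censoring horizon in days
#'   (default 1825).
#' @param seed Integer seed.
#' @return A survival tibble (`sample`, `time`, `event`).
#' @export
community_survival <- function(truth, hazards = log(2) / c(90, 450, 2250),
                               censor_rate = 0.2, max_follow_up = 1825,
                               seed = 1L) {
  if (inherits(truth, "hocus_cohort")) truth <- truth$truth
  truth <- tibble::as_tibble(truth)
  stopifnot(all(c("sample", "community") %in% names(truth)),
            all(hazards > 0), censor_rate >= 0, censor_rate < 1)
  C <- max(truth$community)
  hazards <- rep_len(hazards, C)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(seed, "survival"))
  lam <- hazards[truth$community]
  t_event <- stats::rexp(nrow(truth), rate = lam)
  t_cens <- if (censor_rate > 0) {
    # exponential censoring with rate lam*r/(1-r) censors a fraction r
    stats::rexp(nrow(truth), rate = lam * censor_rate / (1 - censor_rate))
  } else {
    rep(Inf, nrow(truth))
  }
  t_cens <- pmin(t_cens, max_follow_up)
  tibble::tibble(sample = truth$sample,
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
}

#' Simulate a full cohort: features, truth and coupled survival
#'
#' Convenience wrapper running [planted_communities()] and
#' [community_survival()] on independent sub-streams of one seed.
#'
#' @inheritParams planted_communities
#' @inheritParams community_survival
#' @return A `hocus_cohort` with an additional `survival` tibble.
#' @export
simulate_cohort <- function(m = 120L, n = 600L, n_communities = 3L,
                            p_in = 0.08, p_bg = 0.01,
                            hazards = log(2) / c(90, 450, 2250),
                            censor_rate = 0.2, max_follow_up = 1825,
                            seed = 1L) {
  cohort <- planted_communities(m, n, n_communities, p_in, p_bg, seed = seed)
  cohort$survival <- community_survival(
    cohort$truth, hazards = hazards, censor_rate = censor_rate,
    max_follow_up = max_follow_up, seed = seed)
  cohort$params <- c(cohort$params,
                     list(hazards = hazards, censor_rate = censor_rate,
                          max_follow_up = max_follow_up))
  cohort
}

#' Spherical tumor voxel phantoms
#'
#' Stand-in for registered tumor masks: each community has a sphere center
#' and radius on a shared grid, and each sample's mask is its community
#' sphere with the center jittered by a uniform integer offset in
#' `[-jitter, jitter]` per axis and the radius jittered by up to
#' `jitter / 2` voxels. With `jitter = 0` all masks within a community are
#' identical. The spheres (plus jitter) must fit inside the grid.
#'
#' @param grid Grid dimensions (default `c(32, 32, 32)`).
#' @param centers C-by-3 matrix of sphere centers; the default places 3
#'   well-separated centers that (with default radii and jitter) fit the
#'   default grid.
#' @param radii Per-community radii (default `c(5, 6, 7)`, a volume
#'   gradient).
#' @param jitter Non-negative jitter magnitude in voxels (default 2).
#' @param m_per_community Samples per community (default 20).
#' @param seed Integer seed.
#' @return A list with `masks` (a [voxel_mask_set()]) and `truth` (tibble
#'   `sample`, `community`).
#' @export
voxel_phantom <- function(grid = c(32L, 32L, 32L),
                          centers = rbind(c(10, 10, 10), c(22, 22, 10),
                                          c(16, 16, 22)),
                          radii = c(5, 6, 7), jitter = 2,
                          m_per_community = 20L, seed = 1L) {
  centers <- as.matrix(centers)
  C <- nrow(centers)
  stopifnot(ncol(centers) == 3L, length(radii) == C, jitter >= 0,
            m_per_community >= 1L)
  if (any(radii < 1)) stop("degenerate radius (< 1 voxel)", call. = FALSE)
  reach <- radii + jitter + jitter / 2
  grid_mat <- matrix(grid, C, 3L, byrow = TRUE)
  if (any(sweep(centers, 1L, reach, "-") < 1) ||
      any(sweep(centers, 1L, reach, "+") > grid_mat)) {
    stop("spheres (plus jitter) must fit inside the grid", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(seed, "phantom"))

  coords <- as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                                  z = seq_len(grid[3])))
  sphere <- function(center, r) {
    d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
      (coords[, 3] - center[3])^2
    a <- array(0L, grid)
    a[coords[d2 <= r^2, , drop = FALSE]] <- 1L
    a
  }
  masks <- list(); comm <- integer(0)
  for (cc in seq_len(C)) {
    for (i in seq_len(m_per_community)) {
      off <- if (jitter > 0) sample(seq(-jitter, jitter), 3L, replace = TRUE)
             else c(0, 0, 0)
      r <- radii[cc] + if (jitter > 0) stats::runif(1, -jitter / 2, jitter / 2)
                       else 0
      id <- sprintf("c%d_s%02d", cc, i)
      masks[[id]] <- sphere(centers[cc, ] + off, r)
      comm <- c(comm, cc)
    }
  }
  list(masks = voxel_mask_set(masks),
       truth = tibble::tibble(sample = names(masks), community = comm))
}
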