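#' Resampling-based consensus clustering
#'
#' Monti-style consensus clustering: for each candidate k, the rows
#' (samples) and columns (features) of the input are repeatedly subsampled,
#' each subsample is partitioned with k-means, and the consensus entry for a
#' sample pair is the proportion of iterations in which the two samples were
#' clustered together among the iterations in which both were sampled.
#' Final per-k labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at k; the number of clusters is chosen by
#' [select_k()] from the consensus CDF delta-area and the average silhouette.
#'
#' Pairs never co-sampled (possible at small `n_iter`) are imputed with the
#' mean observed consensus of their two rows and noted via `message()`.
#' Degenerate subsamples (k exceeding the distinct rows drawn) are redrawn;
#' if more than 10% of iterations degenerate the run stops.
#'
#' @param x Samples-by-features numeric matrix with sample rownames —
#'   typically [power_features()] output, where the columns are the sample
#'   neighborhood profile; a `hocus_features` matrix also works.
#' @param k_range Candidate cluster numbers (default `2:10`).
#' @param n_iter Subsampling iterations per k (default 1000).
#' @param sample_frac,feature_frac Row/column subsampling fractions
#'   (default 0.8).
#' @param seed Integer seed; fixed seed + inputs gives a byte-identical
#'   result.
#' @param nstart k-means restarts per iteration (default 10, best inertia
#'   kept).
#' @return A `hocus_consensus` object: per-k consensus matrices, CDF curves,
#'   per-k metrics (`area`, `delta_area`, `silhouette`), `chosen_k`, tidy
#'   `labels` for every k, and the seed. `tidy()` returns the per-k metrics,
#'   `glance()` the chosen-k row, `cluster_labels()` the labels at any k.
#' @export
consensus_cluster <- function(x, k_range = 2:10, n_iter = 1000L,
                              sample_frac = 0.8, feature_frac = 0.8,
                              seed = 1L, nstart = 10L) {
  x <- unclass(x)
  storage.mode(x) <- "double"
  m <- nrow(x); n <- ncol(x)
  stopifnot(m >= 3L, n >= 1L, sample_frac > 0, sample_frac <= 1,
            feature_frac > 0, feature_frac <= 1, n_iter >= 1L)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > m - 1L) {
    stop("k_range must lie within [2, m-1]", call. = FALSE)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  n_samp <- max(2L, round(sample_frac * m))
  n_feat <- max(1L, round(feature_frac * n))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  consensus <- list(); labels_by_k <- list()
  cdf_tbl <- list(); grid <- seq(0, 1, by = 0.01)
  areas <- sil <- numeric(length(k_range))

  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    degenerate <- 0L
    trace <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      repeat {
        rows <- sort(sample.int(m, n_samp))
        cols <- sort(sample.int(n, n_feat))
        sub <- x[rows, cols, drop = FALSE]
        km <- tryCatch(
          suppressWarnings(
            stats::kmeans(sub, centers = k, nstart = nstart, iter.max = 50L)),
          error = function(e) NULL)
        if (!is.null(km)) break
        degenerate <- degenerate + 1L
        if (degenerate > 0.1 * n_iter) {
          stop("more than 10% of subsamples degenerate at k = ", k,
               call. = FALSE)
        }
      }
      trace[[it]] <- list(rows = rows, cluster = km$cluster)
    }
    cons <- consensus_from_trace(trace, m, ids)

    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    lab <- stats::cutree(hc, k = k)
    cdf <- consensus_cdf(cons, grid = grid)
    areas[ki] <- sum(diff(grid) * cdf$cdf[-1L])
    sw <- cluster::silhouette(lab, dmatrix = 1 - cons)
    sil[ki] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_

    consensus[[as.character(k)]] <- cons
    labels_by_k[[ki]] <- tibble::tibble(k = k, sample = ids,
                                        cluster = unname(lab))
    cdf_tbl[[ki]] <- tibble::tibble(k = k, value = cdf$value, cdf = cdf$cdf)
  }

  metrics <- tibble::tibble(
    k = k_range, area = areas,
    delta_area = c(areas[1L],
                   if (length(areas) > 1L) diff(areas) / areas[-length(areas)]),
    silhouette = sil)
  chosen_k <- select_k(metrics)
  labels_by_k <- dplyr::bind_rows(labels_by_k)
  res <- structure(list(
    k_range = k_range, consensus = consensus,
    cdf = dplyr::bind_rows(cdf_tbl), metrics = metrics,
    chosen_k = chosen_k,
    labels = labels_by_k[labels_by_k$k == chosen_k,
                         c("sample", "cluster"), drop = FALSE],
    labels_by_k = labels_by_k, seed = as.integer(seed),
    params = list(n_iter = as.integer(n_iter), sample_frac = sample_frac,
                  feature_frac = feature_frac, nstart = as.integer(nstart))),
    class = "hocus_consensus")
  res
}

# Monti-style consensus from a trace of subsampled partitions. Each trace
# element has `rows` (indices sampled that iteration) and `cluster` (their
# labels). Consensus(i,j) = co-clustered count / co-sampled count; pairs
# never co-sampled are imputed with the mean observed consensus of their
# two rows (and reported via message); diagonal forced to 1.
consensus_from_trace <- function(trace, m, ids = as.character(seq_len(m))) {
  together <- matrix(0, m, m)
  co_sampled <- matrix(0, m, m)
  for (it in trace) {
    rows <- it$rows
    co_sampled[rows, rows] <- co_sampled[rows, rows] + 1
    for (cl in unique(it$cluster)) {
      inc <- rows[it$cluster == cl]
      together[inc, inc] <- together[inc, inc] + 1
    }
  }
  cons <- together / co_sampled
  never <- co_sampled == 0 & upper.tri(co_sampled)
  if (any(never)) {
    message(sum(never), " sample pair(s) never co-sampled; ",
            "imputed with row-pair mean consensus")
    idx <- which(never, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      vals <- c(cons[i, ], cons[j, ])
      cons[i, j] <- cons[j, i] <- mean(vals[is.finite(vals)])
    }
  }
  diag(cons) <- 1
  cons <- (cons + t(cons)) / 2
  dimnames(cons) <- list(ids, ids)
  cons
}

#' Empirical CDF of consensus values
#'
#' The empirical cumulative distribution of the upper-triangular consensus
#' entries, evaluated on a fixed grid in [0, 1]. The area under this curve
#' grows with k; the relative change in area (delta-area) locates the k of
#' maximum stability.
#'
#' @param consensus m-by-m consensus matrix with values in [0, 1].
#' @param grid Evaluation grid (default `seq(0, 1, by = 0.01)`).
#' @return A tibble with columns `value` (grid) and `cdf`.
#' @export
consensus_cdf <- function(consensus, grid = seq(0, 1, by = 0.01)) {
  consensus <- unclass(consensus)
  v <- consensus[upper.tri(consensus)]
  tibble::tibble(value = grid,
                 cdf = vapply(grid, function(g) mean(v <= g), numeric(1)))
}

#' Choose the number of clusters from consensus diagnostics
#'
#' Stability first, cohesion second: candidate k up to the largest k whose
#' relative delta-area is at least `delta_min` are considered stable, and
#' among those the k with the highest average silhouette wins; ties go to
#' the smaller k. With a single candidate that k is returned.
#'
#' @param metrics Tibble with columns `k`, `delta_area`, `silhouette`
#'   (as in `hocus_consensus$metrics`), or a `hocus_consensus` object.
#' @param delta_min Relative delta-area threshold for stability
#'   (default 0.05).
#' @return The chosen k (integer).
#' @export
select_k <- function(metrics, delta_min = 0.05) {
  if (inherits(metrics, "hocus_consensus")) metrics <- metrics$metrics
  metrics <- tibble::as_tibble(metrics)
  stopifnot(all(c("k", "delta_area", "silhouette") %in% names(metrics)))
  if (nrow(metrics) == 1L) return(as.integer(metrics$k))
  if (all(!is.finite(metrics$silhouette))) {
    stop("silhouette undefined for every candidate k", call. = FALSE)
  }
  stable_upper <- if (any(metrics$delta_area >= delta_min)) {
    max(metrics$k[metrics$delta_area >= delta_min])
  } else {
    min(metrics$k)
  }
  cand <- metrics[metrics$k <= stable_upper & is.finite(metrics$silhouette), ]
  cand <- cand[order(-cand$silhouette, cand$k), ]
  as.integer(cand$k[1L])
}

#' Cluster labels at a given k
#'
#' @param result A `hocus_consensus`.
#' @param k Number of clusters (default the chosen k).
#' @return Tibble with columns `sample`, `cluster`.
#' @export
cluster_labels <- function(result, k = result$chosen_k) {
  stopifnot(inherits(result, "hocus_consensus"), k %in% result$k_range)
  out <- result$labels_by_k[result$labels_by_k$k == k,
                            c("sample", "cluster"), drop = FALSE]
  tibble::as_tibble(out)
}

#' @export
print.hocus_consensus <- function(x, ...) {
  cat(sprintf("<hocus_consensus> %d samples, k in {%s}, chosen k = %d\n",
              nrow(x$consensus[[1L]]),
              paste(range(x$k_range), collapse = ".."), x$chosen_k))
  cat(sprintf("  n_iter = %d, sample_frac = %.2f, feature_frac = %.2f, seed = %d\n",
              x$params$n_iter, x$params$sample_frac, x$params$feature_frac,
              x$seed))
  invisible(x)
}

#' @export
tidy.hocus_consensus <- function(x, ...) x$metrics

#' @export
glance.hocus_consensus <- function(x, ...) {
  row <- x$metrics[x$metrics$k == x$chosen_k, ]
  tibble::tibble(chosen_k = x$chosen_k, area = row$area,
                 delta_area = row$delta_area, silhouette = row$silhouette,
                 n_iter = x$params$n_iter, seed = x$seed)
}

#' @export
autoplot.hocus_consensus <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$value, y = .data$cdf,
                               colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Consensus value", y = "CDF", colour = "k") +
    ggplot2::theme_minimal()
}

#' Construct a cluster solution
#'
#' Labels plus the provenance (metric order, k, seed) that produced them,
#' consumed by evaluation and characterization.
#'
#' @param labels Tibble/data frame with columns `sample`, `cluster`, or a
#'   named vector of cluster ids.
#' @param order Metric order that produced the clustering.
#' @param k Number of clusters.
#' @param seed Seed used.
#' @return A `hocus_solution` tibble (columns `sample`, `cluster`) with
#'   `order`, `k`, `seed` attributes. Cluster ids are relabeled to be
#'   contiguous from 1, preserving order of first appearance.
#' @export
cluster_solution <- function(labels, order = NA_integer_, k = NA_integer_,
                             seed = NA_integer_) {
  lab <- as_labels_tibble(labels)
  lab$cluster <- as.integer(factor(lab$cluster, levels = unique(lab$cluster)))
  if (is.na(k)) k <- length(unique(lab$cluster))
  structure(lab, order = as.integer(order), k = as.integer(k),
            seed = as.integer(seed),
            class = c("hocus_solution", class(lab)))
}

as_labels_tibble <- function(labels) {
  if (inherits(labels, "hocus_consensus")) return(labels$labels)
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample", "cluster") %in% names(labels)))
    out <- tibble::as_tibble(labels[, c("sample", "cluster")])
  } else {
    if (is.null(names(labels))) stop("labels vector must be named by sample",
                                     call. = FALSE)
    out <- tibble::tibble(sample = names(labels), cluster = unname(labels))
  }
  if (anyDuplicated(out$sample)) stop("duplicate samples in labels",
                                      call. = FALSE)
  out
}
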