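#' Centered kernel alignment between two similarity matrices
#'
#' Double-centers both matrices (removing row and column means) and returns
#' their Frobenius inner product normalized by the product of Frobenius
#' norms: a centered correlation between two full sample-by-sample
#' similarity matrices, in [-1, 1]. Used both to score a feature-derived
#' metric against the co-survival metric and to detect when successive
#' metric orders have become redundant.
#'
#' The alignment is symmetric in its arguments and invariant to adding a
#' constant to either matrix and to positive rescaling.
#'
#' @param k1,k2 Square matrices over the same samples in the same order
#'   (sample ids are checked when both carry dimnames).
#' @return A scalar alignment in [-1, 1].
#' @export
kernel_alignment <- function(k1, k2) {
  a <- unclass(k1); b <- unclass(k2)
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("sample ids differ between the two matrices", call. = FALSE)
  }
  ac <- double_center(a)
  bc <- double_center(b)
  na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
  if (na == 0 || nb == 0) {
    stop("alignment undefined: a centered matrix is all zero", call. = FALSE)
  }
  sum(ac * bc) / (na * nb)
}

double_center <- function(x) {
  rm <- rowMeans(x); cm <- colMeans(x)
  x - outer(rm, rep(1, ncol(x))) - outer(rep(1, nrow(x)), cm) + mean(x)
}

#' Co-survival similarity between patients
#'
#' Converts pairwise absolute differences in survival time,
#' `d_ij = |T(i) - T(j)|` (days), into a similarity. The default `"range"`
#' variant rescales linearly so that `s_ij = 1 - d_ij / max(d)` lies in
#' [0, 1], with `s_ij = 1` iff the two survival times are equal and 0 at
#' the maximal pairwise difference. The `"raw"` variant
#' `s_ij = (1 - d_ij) / max(d)` is an alternative linear transform kept for
#' comparison; it is not bounded in [0, 1] when differences exceed one day.
#'
#' @param surv Survival table: tibble/data frame with columns `sample`,
#'   `time` (non-negative days) and `event` (0/1).
#' @param death_only If `TRUE` (default), restrict to patients with a death
#'   event before computing pairwise differences, so censoring times are
#'   never compared with event times.
#' @param variant `"range"` (default) or `"raw"`.
#' @return A `hocus_similarity` over the retained patients.
#' @export
co_survival <- function(surv, death_only = TRUE, variant = c("range", "raw")) {
  variant <- match.arg(variant)
  surv <- validate_survival(surv)
  if (death_only) surv <- surv[surv$event == 1L, , drop = FALSE]
  if (nrow(surv) < 2L) stop("fewer than 2 retained patients", call. = FALSE)
  d <- abs(outer(surv$time, surv$time, "-"))
  maxd <- max(d)
  if (maxd == 0) {
    stop("degenerate survival input: all retained times identical",
         call. = FALSE)
  }
  s <- switch(variant,
              range = 1 - d / maxd,
              raw = (1 - d) / maxd)
  dimnames(s) <- list(surv$sample, surv$sample)
  new_similarity(s, order = 1L, metric = paste0("co_survival_", variant))
}

validate_survival <- function(surv) {
  surv <- tibble::as_tibble(surv)
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  if (anyDuplicated(surv$sample)) stop("duplicate sample ids in survival table",
                                       call. = FALSE)
  if (any(!is.finite(surv$time)) || any(surv$time < 0)) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  surv$event <- as.integer(surv$event)
  surv
}

#' Log-rank evaluation of a cluster solution
#'
#' Scores how well a clustering separates patient outcomes: clusters with
#' fewer than `min_cluster_size` samples are excluded, then a multi-group
#' log-rank test (chi-square with #groups - 1 degrees of freedom) is run
#' across the surviving clusters, and a Kaplan-Meier curve is estimated per
#' cluster. Censoring is respected here; no death-only restriction applies.
#'
#' @param labels Cluster labels: a tibble/data frame with columns `sample`
#'   and `cluster`, or a [cluster_solution()].
#' @param surv Survival table (`sample`, `time`, `event`).
#' @param min_cluster_size Minimum cluster size retained (default 5).
#' @return A `hocus_logrank` object with elements `statistic`, `df`,
#'   `p_value`, `curves` (tidy KM step functions), `cluster_sizes`, and
#'   `excluded` (clusters dropped by the size filter). `glance()` gives the
#'   one-row test summary; `tidy()` the KM curves.
#' @export
logrank_evaluate <- function(labels, surv, min_cluster_size = 5L) {
  lab <- as_labels_tibble(labels)
  surv <- validate_survival(surv)
  df <- dplyr::inner_join(lab, surv, by = "sample")
  if (nrow(df) < 2L) stop("no overlap between labels and survival table",
                          call. = FALSE)
  sizes <- table(df$cluster)
  keep <- names(sizes)[sizes >= min_cluster_size]
  excluded <- setdiff(names(sizes), keep)
  df <- df[df$cluster %in% keep, , drop = FALSE]
  if (length(keep) < 2L) {
    stop("fewer than 2 clusters of size >= ", min_cluster_size, call. = FALSE)
  }
  df$cluster <- factor(df$cluster)
  sd <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = df)
  dfree <- length(keep) - 1L
  p <- stats::pchisq(sd$chisq, df = dfree, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ cluster, data = df)
  sm <- summary(fit, censored = TRUE)
  curves <- tibble::tibble(
    cluster = sub("^cluster=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv, std_err = sm$std.err)
  structure(list(statistic = unname(sd$chisq), df = dfree, p_value = p,
                 curves = curves,
                 cluster_sizes = tibble::tibble(cluster = names(sizes),
                                                n = as.integer(sizes)),
                 excluded = excluded,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "hocus_logrank")
}

#' @export
print.hocus_logrank <- function(x, ...) {
  cat(sprintf("<hocus_logrank> chi-square %.3f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (length(x$excluded)) {
    cat("  excluded clusters (<", x$min_cluster_size, "samples):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.hocus_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 neglog10_p = -log10(x$p_value),
                 n_clusters = x$df + 1L,
                 n_excluded = length(x$excluded))
}

#' @export
tidy.hocus_logrank <- function(x, ...) x$curves

#' @export
autoplot.hocus_logrank <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$cluster)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = "Cluster",
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Conditional density of outcome similarity given feature similarity
#'
#' Splits all upper-triangular sample pairs into `n_bands` bands of
#' approximately equal size by feature-derived similarity, and summarizes
#' the distribution of outcome similarity (e.g. co-survival) within each
#' band. A distribution that shifts across bands indicates that the
#' feature-based metric carries outcome-relevant information. The overall
#' centered kernel alignment between the two matrices is attached.
#'
#' Pairs are ordered by feature similarity with ties broken by the
#' lexicographic sample-id pair, so band assignment is stable.
#'
#' @param feature_sim,outcome_sim `hocus_similarity` matrices over the same
#'   samples (subset `feature_sim` to the outcome's samples first if needed;
#'   see [subset_similarity()]).
#' @param n_bands Number of equal-count bands (default 5).
#' @param n_bins Number of histogram bins for outcome similarity (default 20).
#' @return A `hocus_cond_density` with `bands` (per-band summaries),
#'   `histograms` (per-band outcome-similarity counts) and `alignment`.
#' @export
conditional_density <- function(feature_sim, outcome_sim, n_bands = 5L,
                                n_bins = 20L) {
  a <- unclass(feature_sim); b <- unclass(outcome_sim)
  stopifnot(all(dim(a) == dim(b)), n_bands >= 2L)
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("sample ids differ between the two matrices", call. = FALSE)
  }
  m <- nrow(a)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  n_pairs <- nrow(ut)
  if (n_pairs < n_bands) stop("fewer pairs than bands", call. = FALSE)
  ids <- rownames(a)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  pairs <- tibble::tibble(
    sample_i = ids[ut[, 1L]], sample_j = ids[ut[, 2L]],
    feature_similarity = a[ut], outcome_similarity = b[ut])
  pairs <- dplyr::arrange(pairs, .data$feature_similarity, .data$sample_i,
                          .data$sample_j)
  sizes <- diff(floor(seq(0, n_pairs, length.out = n_bands + 1L)))
  pairs$band <- rep(seq_len(n_bands), times = sizes)
  rng <- range(pairs$outcome_similarity)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  hist_tbl <- dplyr::group_modify(
    dplyr::group_by(pairs, .data$band),
    function(d, g) {
      h <- graphics::hist(d$outcome_similarity, breaks = breaks, plot = FALSE)
      tibble::tibble(bin_mid = h$mids, count = h$counts)
    })
  hist_tbl <- dplyr::ungroup(hist_tbl)
  bands <- dplyr::summarise(
    dplyr::group_by(pairs, .data$band),
    n_pairs = dplyr::n(),
    feature_min = min(.data$feature_similarity),
    feature_max = max(.data$feature_similarity),
    outcome_mean = mean(.data$outcome_similarity),
    outcome_median = stats::median(.data$outcome_similarity),
    .groups = "drop")
  structure(list(bands = bands, histograms = hist_tbl, pairs = pairs,
                 alignment = kernel_alignment(feature_sim, outcome_sim),
                 n_bands = as.integer(n_bands)),
            class = "hocus_cond_density")
}

#' @export
print.hocus_cond_density <- function(x, ...) {
  cat(sprintf("<hocus_cond_density> %d pairs in %d bands; kernel alignment %.4f\n",
              sum(x$bands$n_pairs), x$n_bands, x$alignment))
  invisible(x)
}

#' @export
tidy.hocus_cond_density <- function(x, ...) x$bands

#' @export
autoplot.hocus_cond_density <- function(object, ...) {
  ggplot2::ggplot(object$histograms,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(range(object$histograms$bin_mid)) /
                        max(1L, length(unique(object$histograms$bin_mid))),
                      fill = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$band)) +
    ggplot2::labs(x = "Outcome similarity", y = "Pair count",
                  subtitle = sprintf("kernel alignment %.4f", object$alignment)) +
    ggplot2::theme_minimal()
}

#' Subset a similarity matrix to a set of samples
#'
#' @param sim A `hocus_similarity`.
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return A `hocus_similarity` over `samples`.
#' @export
subset_similarity <- function(sim, samples) {
  stopifnot(all(samples %in% rownames(sim)))
  new_similarity(unclass(sim)[samples, samples, drop = FALSE],
                 order = attr(sim, "order"), metric = attr(sim, "metric"),
                 n_features = attr(sim, "n_features"))
}

#' Select the metric order by kernel alignment with an outcome similarity
#'
#' Aligns every rung of the order ladder with an outcome-derived similarity
#' (typically [co_survival()]) and returns the smallest order whose
#' alignment is within `parsimony_margin` of the ladder maximum: when a
#' higher order offers no material gain, its added complexity is not
#' justified.
#'
#' Each rung is restricted to the outcome matrix's samples before aligning
#' (the co-survival metric may cover only patients with a death event).
#'
#' @param ladder A `hocus_ladder` (or list of `hocus_similarity`).
#' @param outcome A `hocus_similarity` from the outcome.
#' @param parsimony_margin Alignment slack under the maximum within which a
#'   smaller order is preferred (default 0.01).
#' @return The chosen order (integer), with an `alignments` attribute: a
#'   tibble of (order, alignment).
#' @export
select_order_by_alignment <- function(ladder, outcome,
                                      parsimony_margin = 0.01) {
  stopifnot(length(ladder) >= 1L)
  ids <- rownames(outcome)
  aligns <- vapply(seq_along(ladder), function(d) {
    rung <- ladder[[d]]
    if (!is.null(ids) && !is.null(rownames(rung))) {
      common <- intersect(rownames(rung), ids)
      if (length(common) < 2L) stop("no common samples with outcome",
                                    call. = FALSE)
      rung <- subset_similarity(rung, common)
      out <- subset_similarity(outcome, common)
    } else {
      out <- outcome
    }
    kernel_alignment(rung, out)
  }, numeric(1))
  best <- max(aligns)
  chosen <- which(aligns >= best - parsimony_margin)[1L]
  structure(as.integer(chosen),
            alignments = tibble::tibble(order = seq_along(ladder),
                                        alignment = aligns))
}
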