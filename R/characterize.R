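#' Gene-cluster association by one-vs-rest chi-squared tests
#'
#' For every gene and every cluster, tests independence of mutation presence
#' and cluster membership in a 2x2 contingency table (mutated/not x
#' in-cluster/rest) with a chi-squared test (no continuity correction).
#' Genes constant across the cohort (all mutated or none) carry no contrast
#' and are skipped with a message. Per cluster, the `top_n` genes with the
#' smallest p-values are selected; the union of these gene sets is reported
#' (with every cluster's row for each selected gene), so overlapping top
#' lists yield fewer than `k * top_n` distinct genes.
#'
#' Ties in the top-`n` selection are broken by p-value, then by larger
#' absolute difference between in-cluster and out-of-cluster mutation
#' proportions, then by gene id.
#'
#' @param features Binary `hocus_features` matrix.
#' @param labels Cluster labels (tibble `sample`/`cluster`,
#'   [cluster_solution()] or `hocus_consensus`).
#' @param top_n Genes per cluster to report (default 15); `Inf` reports all
#'   tested genes.
#' @param fdr If `TRUE`, add a Benjamini-Hochberg adjusted `q_value` column
#'   (computed over all tested gene-cluster pairs). Selection still uses raw
#'   p-values.
#' @return A tibble with columns `gene`, `cluster`, `statistic`, `p_value`,
#'   `prop_in`, `prop_out`, `low_expected` (TRUE when some expected cell
#'   count is below 5) and, with `fdr`, `q_value`; attribute `n_tested`
#'   gives the number of gene-cluster tests performed.
#' @export
gene_cluster_association <- function(features, labels, top_n = 15L,
                                     fdr = FALSE) {
  stopifnot(inherits(features, "hocus_features"),
            attr(features, "kind") == "binary")
  lab <- as_labels_tibble(labels)
  common <- intersect(rownames(features), lab$sample)
  if (length(common) < 2L) stop("labels do not match feature samples",
                                call. = FALSE)
  x <- unclass(features)[common, , drop = FALSE]
  cl <- lab$cluster[match(common, lab$sample)]
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L) stop("need at least 2 clusters", call. = FALSE)

  csums <- colSums(x)
  constant <- csums == 0L | csums == nrow(x)
  if (any(constant)) {
    message(sum(constant), " constant gene(s) skipped (no variation)")
  }
  genes <- colnames(x)[!constant]

  rows <- purrr::map(genes, function(g) {
    mut <- x[, g] == 1L
    purrr::map(clusters, function(cc) {
      inc <- cl == cc
      tab <- matrix(c(sum(mut & inc), sum(mut & !inc),
                      sum(!mut & inc), sum(!mut & !inc)), nrow = 2L,
                    byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tibble::tibble(gene = g, cluster = cc,
                     statistic = unname(ct$statistic),
                     p_value = unname(ct$p.value),
                     prop_in = mean(mut[inc]), prop_out = mean(mut[!inc]),
                     low_expected = any(expected < 5))
    })
  })
  tbl <- dplyr::bind_rows(purrr::flatten(rows))
  # a gene uniform across clusters gives statistic 0, p 1; keep NaN-free
  tbl$statistic[!is.finite(tbl$statistic)] <- 0
  tbl$p_value[!is.finite(tbl$p_value)] <- 1
  if (fdr) tbl$q_value <- stats::p.adjust(tbl$p_value, method = "BH")

  if (is.finite(top_n)) {
    top_genes <- unique(unlist(lapply(clusters, function(cc) {
      sub <- tbl[tbl$cluster == cc, ]
      sub <- sub[order(sub$p_value, -abs(sub$prop_in - sub$prop_out),
                       sub$gene), ]
      utils::head(sub$gene, top_n)
    })))
    out <- tbl[tbl$gene %in% top_genes, , drop = FALSE]
  } else {
    out <- tbl
  }
  out <- dplyr::arrange(out, .data$cluster, .data$p_value, .data$gene)
  attr(out, "n_tested") <- nrow(tbl)
  out
}

#' Per-sample mutation counts and per-cluster rate summaries
#'
#' Summarizes overall mutational frequency: per-sample event counts (row
#' sums of the binary matrix), quartile summaries per cluster, and the
#' cohort median (the reference line drawn over oncoprints).
#'
#' @param features Binary `hocus_features` matrix.
#' @param labels Optional cluster labels; without them only per-sample
#'   counts and the cohort median are returned.
#' @return A list of class `hocus_mutation_rates` with `per_sample` (tibble
#'   `sample`, `n_mutations`, and `cluster` when labels are given),
#'   `per_cluster` (tibble `cluster`, `n`, `q25`, `median`, `q75`) and
#'   `cohort_median`.
#' @export
mutation_rate_summary <- function(features, labels = NULL) {
  stopifnot(inherits(features, "hocus_features"),
            attr(features, "kind") == "binary")
  per_sample <- tibble::tibble(sample = rownames(features),
                               n_mutations = as.integer(rowSums(features)))
  per_cluster <- NULL
  if (!is.null(labels)) {
    lab <- as_labels_tibble(labels)
    per_sample <- dplyr::inner_join(per_sample, lab, by = "sample")
    per_cluster <- dplyr::summarise(
      dplyr::group_by(per_sample, .data$cluster),
      n = dplyr::n(),
      q25 = stats::quantile(.data$n_mutations, 0.25),
      median = stats::median(.data$n_mutations),
      q75 = stats::quantile(.data$n_mutations, 0.75),
      .groups = "drop")
  }
  structure(list(per_sample = per_sample, per_cluster = per_cluster,
                 cohort_median = stats::median(per_sample$n_mutations)),
            class = "hocus_mutation_rates")
}

#' @export
print.hocus_mutation_rates <- function(x, ...) {
  cat(sprintf("<hocus_mutation_rates> %d samples, cohort median %.1f\n",
              nrow(x$per_sample), x$cohort_median))
  if (!is.null(x$per_cluster)) print(x$per_cluster)
  invisible(x)
}

#' @export
tidy.hocus_mutation_rates <- function(x, ...) x$per_sample

#' Group samples by overall mutational frequency
#'
#' Generic quantile grouping of per-sample mutation counts (e.g. 2 for a
#' median split, 3 for tertiles).
#'
#' @param rates A `hocus_mutation_rates` object or the `per_sample` tibble.
#' @param n_groups Number of quantile groups (default 2).
#' @return The per-sample tibble with an added integer `rate_group` column
#'   (1 = lowest).
#' @export
mutation_rate_groups <- function(rates, n_groups = 2L) {
  df <- if (inherits(rates, "hocus_mutation_rates")) rates$per_sample else
    tibble::as_tibble(rates)
  stopifnot("n_mutations" %in% names(df), n_groups >= 2L)
  df$rate_group <- as.integer(
    cut(rank(df$n_mutations, ties.method = "first"),
        breaks = n_groups, labels = FALSE))
  df
}

#' Oncoprint-ready matrix export
#'
#' Orders a genes-by-samples presence matrix for oncoprint-style display:
#' samples grouped by cluster (then by descending mutation count), genes by
#' descending cohort frequency.
#'
#' @param features Binary `hocus_features` matrix.
#' @param labels Cluster labels.
#' @param genes Genes to include (default: all, frequency-ordered).
#' @return Integer genes-by-samples matrix with a `clusters` attribute
#'   (named cluster id per sample column).
#' @export
oncoprint_matrix <- function(features, labels, genes = NULL) {
  stopifnot(inherits(features, "hocus_features"))
  lab <- as_labels_tibble(labels)
  common <- intersect(rownames(features), lab$sample)
  x <- unclass(features)[common, , drop = FALSE]
  cl <- lab$cluster[match(common, lab$sample)]
  if (is.null(genes)) genes <- colnames(x)[order(-colSums(x), colnames(x))]
  stopifnot(all(genes %in% colnames(x)))
  ord <- order(cl, -rowSums(x), rownames(x))
  out <- t(x[ord, genes, drop = FALSE])
  attr(out, "clusters") <- stats::setNames(cl[ord], rownames(x)[ord])
  out
}
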