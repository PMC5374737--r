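#' Run the full higher-order stratification workflow
#'
#' End-to-end pipeline: build the order ladder of similarity metrics from
#' the feature data, consensus-cluster the similarity-as-features matrix at
#' every retained order, and — when a survival table is supplied — score
#' each order's alignment with the co-survival metric, pick the order (the
#' smallest within a parsimony margin of the best alignment), and evaluate
#' every order's chosen clustering with a log-rank test. For binary
#' features the chosen solution is characterized with per-gene chi-squared
#' association tables and mutation-rate summaries.
#'
#' Without a survival table the outcome-dependent steps are skipped with a
#' warning and the highest non-redundant order is used.
#'
#' @param features A `hocus_features` matrix.
#' @param survival Optional survival tibble (`sample`, `time`, `event`).
#' @param max_order Highest metric order to examine (default 4).
#' @param k_range Candidate cluster numbers (default `2:10`).
#' @param n_iter Consensus iterations per k (default 1000).
#' @param sample_frac,feature_frac Consensus subsampling fractions.
#' @param min_cluster_size Log-rank size filter (default 5).
#' @param death_only Restrict co-survival to death events (default TRUE).
#' @param parsimony_margin Alignment slack for order selection.
#' @param redundancy_threshold Ladder early-stop threshold.
#' @param top_n Genes per cluster in the association table.
#' @param seed Integer seed driving every stochastic step.
#' @return A `hocus_fit` with elements `ladder`, `consensus` (per order),
#'   `alignment` (tibble, when survival given), `chosen_order`, `chosen_k`,
#'   `labels` (a [cluster_solution()]), `logrank` (per order, when survival
#'   given), `association`, `mutation_rates`, and `config`.
#' @export
hocus_run <- function(features, survival = NULL, max_order = 4L,
                      k_range = 2:10, n_iter = 1000L, sample_frac = 0.8,
                      feature_frac = 0.8, min_cluster_size = 5L,
                      death_only = TRUE, parsimony_margin = 0.01,
                      redundancy_threshold = 0.999, top_n = 15L, seed = 1L) {
  stopifnot(inherits(features, "hocus_features"))
  config <- list(
    m = nrow(features), n = ncol(features), kind = attr(features, "kind"),
    max_order = as.integer(max_order), k_range = as.integer(k_range),
    n_iter = as.integer(n_iter), sample_frac = sample_frac,
    feature_frac = feature_frac, min_cluster_size = as.integer(min_cluster_size),
    death_only = death_only, parsimony_margin = parsimony_margin,
    redundancy_threshold = redundancy_threshold, top_n = top_n,
    seed = as.integer(seed))

  ladder <- order_ladder(features, max_order = max_order,
                         redundancy_threshold = redundancy_threshold)
  # Each rung's similarity matrix is supplied directly as the feature matrix:
  # this implementation's k-means operates on the features with Euclidean
  # distance, so the d-1 matrix powering that compensates for an internal
  # correlation metric in ConsensusClusterPlus-style tools (power_features)
  # is not applied here.
  consensus <- lapply(seq_along(ladder), function(d) {
    consensus_cluster(unclass(ladder[[d]]), k_range = k_range,
                      n_iter = n_iter, sample_frac = sample_frac,
                      feature_frac = feature_frac,
                      seed = derive_seed(seed, paste0("consensus", d)))
  })

  alignment <- NULL; logrank <- NULL
  if (!is.null(survival)) {
    outcome <- co_survival(survival, death_only = death_only)
    chosen_order <- select_order_by_alignment(ladder, outcome,
                                              parsimony_margin = parsimony_margin)
    alignment <- attr(chosen_order, "alignments")
    logrank <- lapply(consensus, function(cr) {
      tryCatch(logrank_evaluate(cluster_labels(cr), survival,
                                min_cluster_size = min_cluster_size),
               error = function(e) e$message)
    })
  } else {
    warning("no survival table: order selected as highest non-redundant order",
            call. = FALSE)
    chosen_order <- length(ladder)
  }
  chosen_order <- as.integer(chosen_order)
  chosen <- consensus[[chosen_order]]
  labels <- cluster_solution(cluster_labels(chosen), order = chosen_order,
                             k = chosen$chosen_k, seed = seed)

  association <- NULL; rates <- NULL
  if (attr(features, "kind") == "binary") {
    association <- withCallingHandlers(
      gene_cluster_association(features, labels, top_n = top_n),
      message = function(m) invokeRestart("muffleMessage"))
    rates <- mutation_rate_summary(features, labels)
  }

  structure(list(ladder = ladder, consensus = consensus,
                 alignment = alignment, chosen_order = chosen_order,
                 chosen_k = chosen$chosen_k, labels = labels,
                 logrank = logrank, association = association,
                 mutation_rates = rates, config = config),
            class = "hocus_fit")
}

#' @export
print.hocus_fit <- function(x, ...) {
  cat(sprintf("<hocus_fit> %d samples x %d features (%s)\n", x$config$m,
              x$config$n, x$config$kind))
  cat(sprintf("  orders examined: 1..%d; chosen order %d, k = %d\n",
              length(x$ladder), x$chosen_order, x$chosen_k))
  if (!is.null(x$alignment)) {
    cat("  alignment with co-survival:",
        paste(sprintf("%.3f", x$alignment$alignment), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.hocus_fit <- function(x, ...) {
  lr <- if (!is.null(x$logrank) &&
            inherits(x$logrank[[x$chosen_order]], "hocus_logrank")) {
    glance(x$logrank[[x$chosen_order]])
  } else {
    tibble::tibble(statistic = NA_real_, p_value = NA_real_)
  }
  tibble::tibble(n_samples = x$config$m, n_features = x$config$n,
                 chosen_order = x$chosen_order, chosen_k = x$chosen_k,
                 logrank_statistic = lr$statistic, logrank_p = lr$p_value,
                 seed = x$config$seed)
}

#' @export
tidy.hocus_fit <- function(x, ...) {
  per_order <- purrr::map_dfr(seq_along(x$consensus), function(d) {
    g <- glance(x$consensus[[d]])
    lr_p <- if (!is.null(x$logrank) && inherits(x$logrank[[d]], "hocus_logrank"))
      x$logrank[[d]]$p_value else NA_real_
    tibble::tibble(order = d, chosen_k = g$chosen_k,
                   silhouette = g$silhouette, logrank_p = lr_p)
  })
  if (!is.null(x$alignment)) {
    per_order <- dplyr::left_join(per_order, x$alignment, by = "order")
  }
  per_order
}

# 32-bit FNV-1a over a string; used to stamp outputs with a config hash.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Write a full result bundle to a directory
#'
#' Exports every artifact of a [hocus_run()] fit as plain TSV/JSON so a run
#' is fully reconstructable from its output directory: per-order similarity
#' and consensus matrices, selection diagnostics, labels, alignment table,
#' log-rank summaries with Kaplan-Meier step curves, association and
#' mutation-rate tables, and the configuration (stamped with a config
#' hash). Identical fits produce byte-identical bundles.
#'
#' @param fit A `hocus_fit`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_hocus_bundle <- function(fit, dir) {
  stopifnot(inherits(fit, "hocus_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(fit$config)
  wjson <- function(x, name) {
    jsonlite::write_json(c(list(config_hash = hash), x),
                         file.path(dir, name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  wmat <- function(m, name) {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    readr::write_tsv(df, file.path(dir, name))
  }
  wjson(fit$config, "config.json")
  for (d in seq_along(fit$ladder)) {
    rung <- fit$ladder[[d]]
    wmat(unclass(rung), sprintf("similarity_order%d.tsv", d))
    wjson(list(order = d, metric = attr(rung, "metric"),
               n_features = attr(rung, "n_features")),
          sprintf("similarity_order%d.json", d))
    cr <- fit$consensus[[d]]
    wmat(cr$consensus[[as.character(cr$chosen_k)]],
         sprintf("consensus_order%d_k%d.tsv", d, cr$chosen_k))
    readr::write_tsv(cr$labels_by_k, file.path(dir, sprintf("labels_order%d.tsv", d)))
    wjson(list(order = d, metrics = cr$metrics, chosen_k = cr$chosen_k,
               cdf = cr$cdf, params = cr$params, seed = cr$seed),
          sprintf("selection_order%d.json", d))
  }
  readr::write_tsv(fit$labels, file.path(dir, "labels_chosen.tsv"))
  if (!is.null(fit$alignment)) {
    wjson(list(alignment = fit$alignment, chosen_order = fit$chosen_order),
          "alignment.json")
  }
  if (!is.null(fit$logrank)) {
    summaries <- purrr::map(seq_along(fit$logrank), function(d) {
      lr <- fit$logrank[[d]]
      if (inherits(lr, "hocus_logrank")) {
        readr::write_tsv(lr$curves, file.path(dir, sprintf("km_order%d.tsv", d)))
        list(order = d, statistic = lr$statistic, df = lr$df,
             p_value = lr$p_value, neglog10_p = -log10(lr$p_value))
      } else {
        list(order = d, error = lr)
      }
    })
    wjson(list(evaluations = summaries), "logrank.json")
  }
  if (!is.null(fit$association)) {
    readr::write_tsv(fit$association, file.path(dir, "gene_associations.tsv"))
  }
  if (!is.null(fit$mutation_rates)) {
    readr::write_tsv(fit$mutation_rates$per_sample,
                     file.path(dir, "mutation_counts.tsv"))
    if (!is.null(fit$mutation_rates$per_cluster)) {
      readr::write_tsv(fit$mutation_rates$per_cluster,
                       file.path(dir, "mutation_rates_by_cluster.tsv"))
    }
  }
  invisible(dir)
}

#' Write / read a similarity matrix as TSV with a JSON sidecar
#'
#' Sample ids appear as both the header row and the first column; the
#' sidecar (`<path>.json`) records the order and metric tag.
#'
#' @param sim A `hocus_similarity`.
#' @param path TSV path.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "hocus_similarity"))
  df <- data.frame(sample = rownames(sim), unclass(sim), check.names = FALSE)
  readr::write_tsv(df, path)
  jsonlite::write_json(list(order = attr(sim, "order"),
                            metric = attr(sim, "metric"),
                            n_features = attr(sim, "n_features")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"))
  } else {
    list(order = 1L, metric = "unknown", n_features = NULL)
  }
  new_similarity(m, order = meta$order, metric = meta$metric,
                 n_features = meta$n_features)
}
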