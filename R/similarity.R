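new_similarity <- function(values, order, metric, n_features = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, order = as.integer(order), metric = metric,
            n_features = n_features,
            class = c("hocus_similarity", "matrix", "array"))
}

#' @export
print.hocus_similarity <- function(x, ...) {
  cat(sprintf("<hocus_similarity> %d x %d, order %d (%s)\n", nrow(x), ncol(x),
              attr(x, "order"), attr(x, "metric")))
  q <- stats::quantile(x[upper.tri(x)], c(0, .5, 1))
  cat(sprintf("  off-diagonal min/median/max: %.3f / %.3f / %.3f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' Order of a similarity metric
#' @param x A `hocus_similarity`.
#' @return Integer order (1 = raw Hamming similarity).
#' @export
similarity_order <- function(x) attr(x, "order")

#' First-order Hamming similarity between samples
#'
#' For samples j, k with n features, `s(j,k) = (1/n) * sum_i I(x_ij, x_ik)`
#' where `I` is the equality indicator: the fraction of features with
#' matching values. For binary data this counts matching mutated (and
#' unmutated) genes; for ordinal copy-number data any identical value is a
#' match. Values lie in [0, 1]; the diagonal is exactly 1.
#'
#' @param features A `hocus_features` matrix (binary or ordinal), or any
#'   integer matrix with sample rownames.
#' @return A `hocus_similarity` of order 1.
#' @examples
#' m <- matrix(c(1L,1L,0L,0L,0L, 1L,0L,0L,0L,1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a","b"), paste0("f", 1:5)))
#' hamming_similarity(feature_matrix(m, "binary"))  # s(a,b) = 3/5
#' @export
hamming_similarity <- function(features) {
  x <- unclass(features)
  if (ncol(x) == 0L) stop("no features", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- ncol(x)
  vals <- sort(unique(as.vector(x)))
  matches <- matrix(0, nrow(x), nrow(x))
  for (v in vals) {
    iv <- (x == v) * 1
    matches <- matches + tcrossprod(iv)
  }
  s <- matches / n
  diag(s) <- 1
  dimnames(s) <- list(rownames(x), rownames(x))
  new_similarity(s, order = 1L, metric = "hamming", n_features = n)
}

#' Neighborhood (higher-order) similarity
#'
#' Derives the next-order similarity by comparing each pair of samples'
#' rows of the current similarity matrix ("my neighborhood looks like your
#' neighborhood"), incrementing the metric order by one.
#'
#' Two variants are provided. `"pearson"` (default) is the centered Pearson
#' correlation of rows j and k, with the diagonal entries included as
#' coordinates. `"sum_norm"` is an alternative sum-normalized transform:
#' numerator `(1/n) * sum_l S(j,l) S(l,k)`, denominator
#' `sqrt(sum_l S(j,l)) * sqrt(sum_l S(l,k))`; it is not a correlation (the
#' denominator uses plain row sums rather than centered norms) and is kept
#' for fidelity experiments on non-negative first-order input.
#'
#' @param sim A `hocus_similarity` (symmetric).
#' @param variant `"pearson"` or `"sum_norm"`.
#' @return A `hocus_similarity` of order `similarity_order(sim) + 1`.
#'   Pearson entries lie in [-1, 1]; negative entries are retained.
#' @section Zero-variance rows: a sample whose similarity row is constant
#'   carries no neighborhood information; under `"pearson"` its off-diagonal
#'   correlations are set to 0 (diagonal 1) and a warning is issued.
#' @export
second_order <- function(sim, variant = c("pearson", "sum_norm")) {
  variant <- match.arg(variant)
  s <- unclass(sim)
  if (max(abs(s - t(s))) > 1e-8) stop("similarity matrix is not symmetric",
                                      call. = FALSE)
  m <- nrow(s)
  if (variant == "pearson") {
    sds <- apply(s, 1L, stats::sd)
    flat <- sds == 0
    out <- suppressWarnings(stats::cor(t(s)))
    if (any(flat)) {
      warning(sum(flat), " zero-variance row(s); correlations set to 0",
              call. = FALSE)
      out[flat, ] <- 0
      out[, flat] <- 0
    }
    diag(out) <- 1
    out <- (out + t(out)) / 2
  } else {
    n <- attr(sim, "n_features")
    if (is.null(n)) n <- m
    rs <- rowSums(s)
    if (any(rs <= 0)) {
      stop("sum_norm variant requires positive row sums", call. = FALSE)
    }
    out <- (s %*% s) / n / outer(sqrt(rs), sqrt(rs))
    out <- (out + t(out)) / 2
  }
  dimnames(out) <- dimnames(s)
  new_similarity(out, order = similarity_order(sim) + 1L,
                 metric = paste0(attr(sim, "metric"), "+", variant),
                 n_features = attr(sim, "n_features"))
}

#' Similarity-as-features for order-d clustering
#'
#' Packages a similarity matrix as the feature matrix handed to consensus
#' clustering. For clustering at order `d` the matrix is raised to the
#' `d - 1` power (order 1 passes the matrix through unchanged): the
#' downstream clustering metric effectively squares its input, so supplying
#' `S^(d-1)` probes the even matrix powers. Order counts metric iterations,
#' not matrix powers.
#'
#' @param sim A `hocus_similarity`.
#' @param order Clustering order, `>= 1`.
#' @return A plain numeric m-by-m matrix (samples in rows; columns are
#'   treated as features downstream).
#' @export
power_features <- function(sim, order) {
  stopifnot(order >= 1L)
  s <- unclass(sim)
  attributes(s) <- attributes(s)[c("dim", "dimnames")]
  out <- s  # order 1 and 2 both use S itself (S^0 convention: pass-through)
  for (i in seq_len(max(0L, order - 2L))) out <- out %*% s
  out
}

#' Build the ladder of higher-order similarity metrics
#'
#' Starts from first-order Hamming similarity and repeatedly applies the
#' neighborhood transform, keeping every order that adds non-redundant
#' relations between samples: the ladder stops early when the next order's
#' kernel alignment with the current one exceeds `redundancy_threshold`
#' (the successor carries essentially the same relative similarities).
#'
#' @param features A `hocus_features` matrix.
#' @param max_order Highest order to examine (default 4).
#' @param redundancy_threshold Kernel alignment above which the next order
#'   is considered redundant (default 0.999). With threshold 1 the ladder
#'   always has `max_order` rungs.
#' @param variant Passed to [second_order()].
#' @return A `hocus_ladder`: list of `hocus_similarity` objects for orders
#'   `1..K`, with a `redundancy` attribute holding the successive alignment
#'   values examined.
#' @export
order_ladder <- function(features, max_order = 4L, redundancy_threshold = 0.999,
                         variant = c("pearson", "sum_norm")) {
  stopifnot(max_order >= 1L, redundancy_threshold > 0,
            redundancy_threshold <= 1)
  variant <- match.arg(variant)
  rungs <- list(hamming_similarity(features))
  aligns <- numeric(0)
  while (length(rungs) < max_order) {
    cur <- rungs[[length(rungs)]]
    nxt <- second_order(cur, variant = variant)
    a <- kernel_alignment(cur, nxt)
    aligns <- c(aligns, a)
    if (a > redundancy_threshold) break
    rungs[[length(rungs) + 1L]] <- nxt
  }
  structure(rungs, redundancy = aligns, class = "hocus_ladder")
}

#' @export
print.hocus_ladder <- function(x, ...) {
  cat(sprintf("<hocus_ladder> orders 1..%d (%s)\n", length(x),
              attr(x[[1L]], "metric")))
  invisible(x)
}

#' @export
tidy.hocus_ladder <- function(x, ...) {
  aligns <- attr(x, "redundancy")
  tibble::tibble(
    order = seq_along(x),
    metric = vapply(x, attr, "", "metric"),
    alignment_with_next = c(aligns, rep(NA_real_, length(x) - length(aligns)))
  )
}
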