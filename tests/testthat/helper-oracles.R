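# Independent oracles used across the suite. Each is a deliberately naive
# implementation (double loops, direct counting) kept separate from the
# package's vectorized code paths.

# Pair-wise correlation of two rows, the long way.
oracle_row_correlation <- function(s, j, k) {
  x <- s[j, ]; y <- s[k, ]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Double-loop centered kernel alignment.
oracle_kernel_alignment <- function(a, b) {
  m <- nrow(a)
  center <- function(k) {
    out <- matrix(0, m, m)
    for (i in 1:m) for (j in 1:m) {
      out[i, j] <- k[i, j] - mean(k[i, ]) - mean(k[, j]) + mean(k)
    }
    out
  }
  ac <- center(a); bc <- center(b)
  num <- 0; na <- 0; nb <- 0
  for (i in 1:m) for (j in 1:m) {
    num <- num + ac[i, j] * bc[i, j]
    na <- na + ac[i, j]^2
    nb <- nb + bc[i, j]^2
  }
  num / sqrt(na * nb)
}

# Hamming similarity by direct position counting.
oracle_hamming <- function(x, y) mean(x == y)

# Chi-squared statistic for a 2x2 table from first principles.
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Consensus matrix from a scripted trace of (sampled ids, cluster labels).
oracle_consensus_trace <- function(trace, ids) {
  m <- length(ids)
  together <- co <- matrix(0, m, m, dimnames = list(ids, ids))
  for (it in trace) {
    for (a in it$sampled) for (b in it$sampled) {
      co[a, b] <- co[a, b] + 1
      if (it$cluster[[a]] == it$cluster[[b]]) together[a, b] <- together[a, b] + 1
    }
  }
  together / co
}

random_symmetric <- function(m, rng = c(-1, 1)) {
  s <- matrix(runif(m * m, rng[1], rng[2]), m, m)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(paste0("s", 1:m), paste0("s", 1:m))
  s
}

small_binary_features <- function(m = 12, n = 30, p = 0.3, seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(m * n, 1, p), m, n,
                dimnames = list(paste0("s", 1:m), paste0("f", 1:n)))
    # guarantee no empty rows/cols for constructor invariants
    x[cbind(seq_len(m), rep_len(seq_len(n), m))] <- 1L
    x[cbind(rep_len(seq_len(m), n), seq_len(n))] <- 1L
    feature_matrix(x, "binary")
  })
}

toy_mutation_table <- function() {
  tibble::tibble(
    sample = c("s1", "s1", "s2", "s2", "s3"),
    gene = c("TP53", "TTN", "TP53", "KRAS", "EGFR"),
    variant_class = c("Missense", "Silent", "Nonsense", "Splice_Site", "Silent"))
}
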