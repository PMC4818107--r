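# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths: brute-force enumeration for the
# combinatorial tests, base glm for the logistic fit.

# Exact two-sided rank-sum p by enumerating every assignment of ranks to
# group a (tie-free data only).
oracle_ranksum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2, function(idx) sum(seq_len(length(pooled))[idx]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Hypergeometric upper tail by enumerating all K-subsets of 1..N with the
# first n elements marked.
oracle_hyper_tail <- function(N, n, K, r) {
  combos <- utils::combn(N, K)
  mean(apply(combos, 2, function(s) sum(s <= n)) >= r)
}

# Reference logistic fit: base R glm (independent IRLS), MAPK (-1) coded as
# success to match the package's convention.
oracle_logistic <- function(panel, cols) {
  y <- as.numeric(panel$class_label == -1)
  df <- data.frame(y = y, panel[, cols, drop = FALSE])
  stats::coef(stats::glm(y ~ ., data = df, family = stats::binomial()))
}

# A tiny panel with a continuous-feature signal that does not separate the
# classes (for exact-MLE comparisons).
toy_panel <- function(seed = 57, n = 10) {
  withr::with_seed(seed, {
    cls <- rep(c(1, -1), length.out = n)
    data.frame(
      sample_id = paste0("S", seq_len(n)),
      x1 = cls * 0.4 + rnorm(n, sd = 1.2),
      x2 = rnorm(n),
      bias = cls * 0.8,
      class_label = cls)
  })
}
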