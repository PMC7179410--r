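# Shared builders and independent oracles used across the test files.

# small feature table built in code: n_a/n_b biological samples + n_qc QC,
# values supplied column-wise per feature
make_table <- function(values, n_a, n_b, n_qc = 0,
                       feature_ids = sprintf("F%02d", seq_len(ncol(values)))) {
  colnames(values) <- feature_ids
  rownames(values) <- c(sprintf("a%02d", seq_len(n_a)),
                        sprintf("b%02d", seq_len(n_b)),
                        if (n_qc > 0) sprintf("q%02d", seq_len(n_qc)))
  feature_table(values,
                c(rep("group_a", n_a), rep("group_b", n_b),
                  rep("qc", n_qc)),
                feature_mz = seq_len(ncol(values)) + 100,
                feature_rt = seq_len(ncol(values)))
}

# independent 1-component NIPALS PLS oracle, written out step by step as in
# the textbook algorithm (u stays equal to the single centered response)
nipals_pls1 <- function(X, y) {
  u <- y - mean(y)
  w <- drop(crossprod(X, u)) / sum(u * u)
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  q <- sum(u * t) / sum(t^2)
  list(w = w, t = t, q = q)
}

# Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- (same_a == same_b)
  (sum(agree) - n) / (n^2 - n)
}

# informative two-group matrix for model tests: k signal features shifted by
# delta, rest standard normal noise; returns centered matrix + labels
make_signal_matrix <- function(n_a = 20, n_b = 20, p = 40, k = 5,
                               delta = 2, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm((n_a + n_b) * p), n_a + n_b, p)
  X[seq_len(n_a), seq_len(k)] <- X[seq_len(n_a), seq_len(k)] + delta
  rownames(X) <- sprintf("s%03d", seq_len(n_a + n_b))
  colnames(X) <- sprintf("V%03d", seq_len(p))
  X <- scale(X, center = TRUE, scale = FALSE)
  list(x = X, y = c(rep("ga", n_a), rep("gb", n_b)))
}
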