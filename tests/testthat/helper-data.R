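# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# p variables in K equal clusters, in index order
cluster_labels_fixture <- function(p, K = 2) {
  rep(seq_len(K), times = diff(round(seq(0, p, length.out = K + 1))))
}

# n rows from N(0, block_sigma(labels))
gauss_segment <- function(n, labels) {
  matrix(rnorm(n * length(labels)), n, length(labels)) %*%
    chol(block_sigma(labels))
}

# positive-shifted series with one regime change (labels reshuffled) at q
one_change_matrix <- function(n1, n2, p, K = 2) {
  lab <- cluster_labels_fixture(p, K)
  shift_nonnegative(rbind(gauss_segment(n1, lab),
                          gauss_segment(n2, sample(lab))))
}

# positive-shifted stationary series
stationary_matrix <- function(n, p, K = 2) {
  shift_nonnegative(gauss_segment(n, cluster_labels_fixture(p, K)))
}
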