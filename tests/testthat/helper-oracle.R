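# Independent oracles and small fixture builders shared across tests.

# All-pairs condensed correlation via stats::cor (independent of the
# package's engine). For a symmetric C, column-major traversal of the lower
# triangle enumerates pairs (i, j>i) in exactly the row-major upper-triangle
# order the package uses.
oracle_condensed <- function(vals) {
  C <- stats::cor(t(vals))
  C[lower.tri(C)]
}

# lexicographic enumeration of all 0-based pairs i < j for small n
enumerate_pairs <- function(n) {
  out <- do.call(rbind, lapply(0:(n - 2), function(i) {
    cbind(i = i, j = (i + 1):(n - 1))
  }))
  as.data.frame(out)
}

random_ts <- function(n, m, seed) {
  set.seed(seed)
  ts_matrix(matrix(rnorm(n * m), nrow = n, ncol = m),
            voxel_order_tag = sprintf("test fixture seed=%d", seed))
}

# condensed-array positions of all pairs touching voxel v (0-based)
pairs_touching <- function(v, n) {
  others <- setdiff(0:(n - 1), v)
  pair_to_linear(pmin(others, v), pmax(others, v), n) + 1
}
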