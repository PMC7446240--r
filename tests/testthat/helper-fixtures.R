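# Shared in-code fixtures: small movement sets and planted geometries.

small_movements <- function(n = 12L) {
  full <- movement_set()
  movement_set(full$labels[seq_len(n)], full$categories[full$labels[seq_len(n)]])
}

small_target <- function(movements, dim = 3L, seed = 5L) {
  random_geometry_rdm(movements$labels, dim = dim, seed = seed)
}

# Brute-force Spearman between the lower triangles of two square matrices,
# written independently of the package helpers (rank then Pearson).
brute_spearman <- function(a, b) {
  av <- a[lower.tri(a)]
  bv <- b[lower.tri(b)]
  ra <- rank(av)
  rb <- rank(bv)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
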