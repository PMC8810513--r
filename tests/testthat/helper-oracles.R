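# Independent oracles and small fixture builders used across the suite.

# Brute-force upper-tail hypergeometric probability by enumerating every
# n-subset of an N-gene background with genes 1..K marked as pathway members.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Exact combinatorial summation of the upper tail via log binomial
# coefficients (independent of phyper's algorithm).
sum_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  if (length(js) == 0L) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Hand-rolled Benjamini-Hochberg step-up, kept deliberately naive.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (r in seq_len(m)) {
    adj_sorted[r] <- min(1, min(m * p[ord][r:m] / (r:m)))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Random gene set of distinct IDs drawn from 1..pool.
random_id_set <- function(size, pool = 100L) {
  sort(sample.int(pool, size))
}

# Random interactome over `n` nodes with `m` attempted edges.
random_interactome <- function(n = 30L, m = 60L) {
  interactome(sample.int(n, m, replace = TRUE), sample.int(n, m, replace = TRUE))
}

# Write a small gene-list TSV and return its path.
write_gene_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_synthetic <- function(seed = 1L, ...) {
  generate_synthetic(synthetic_config(
    seed = seed, n_genes = 300L, edge_param = 900L,
    n_a = 30L, n_b = 30L, n_shared = 10L,
    n_candidates = 5L, candidate_wiring = 4L,
    n_pathways = 12L, pathway_size_range = c(5L, 20L),
    n_enriched_per_disease = 2L, enrichment_fraction = 0.8, ...
  ))
}

shared_fixture_path <- function() {
  system.file("extdata", "shared_ad_mdd_genes.tsv", package = "comorbidnet")
}
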