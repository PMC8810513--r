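test_that("edge-list reading canonicalises, deduplicates and drops self-pairs", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("1\t2", "2\t1", "3\t3"), p)
  net <- read_edge_list(p)
  expect_equal(n_edges(net), 1L)
  expect_equal(net$edges[1, ], c(a = 1L, b = 2L))
  expect_equal(attr(net, "n_self_dropped") + attr(net, "n_dup_dropped"), 2L)
  # header auto-detection and empty files
  writeLines(c("gene_a\tgene_b", "5\t6", "7\t8", "9\t10"), p)
  expect_equal(n_edges(read_edge_list(p)), 3L)
  writeLines(character(0), p)
  expect_equal(n_edges(read_edge_list(p)), 0L)
  writeLines(c("1"), p)
  expect_error(read_edge_list(p), class = "comorbidnet_bad_edge_list")
  writeLines(c("1\t2", "3\tx"), p)
  expect_error(read_edge_list(p), class = "comorbidnet_bad_gene_id")
})

test_that("interactome merging unions edges and applies the exclusion list", {
  n1 <- interactome(1L, 2L)
  n2 <- interactome(c(1L, 2L), c(2L, 3L))
  merged <- merge_interactomes(list(n1, n2), exclude = integer(0))
  expect_equal(n_edges(merged), 2L)
  # edges touching an excluded hub disappear entirely
  with_ubc <- interactome(c(7316L, 5L), c(5L, 9L))
  cleaned <- merge_interactomes(with_ubc)
  expect_equal(n_edges(cleaned), 1L)
  expect_false(7316L %in% cleaned$nodes)
  # nodes are exactly the edge endpoints
  expect_setequal(cleaned$nodes, as.integer(cleaned$edges))
})

test_that("disease-network extraction follows the edge-incident and induced rules", {
  net <- interactome(c(10L, 20L), c(20L, 30L))  # path 10-20-30
  star <- extract_disease_network(net, 20L)
  expect_equal(n_edges(star$network), 2L)
  expect_equal(n_nodes(star$network), 3L)
  ind <- extract_disease_network(net, c(10L, 20L), rule = "induced")
  expect_equal(n_edges(ind$network), 1L)
  expect_equal(n_nodes(ind$network), 2L)
  # seeds with no incident edges give an empty network
  lonely <- extract_disease_network(net, 99L)
  expect_equal(n_edges(lonely$network), 0L)
  expect_error(extract_disease_network(net, integer(0)),
               class = "comorbidnet_empty_seeds")
})

test_that("network union and intersection satisfy edge algebra on random graphs", {
  set.seed(53)
  for (i in 1:40) {
    src <- random_interactome(25L, 80L)
    seeds_a <- sample(src$nodes, 6L)
    seeds_b <- sample(src$nodes, 6L)
    a <- extract_disease_network(src, seeds_a)
    b <- extract_disease_network(src, seeds_b)
    u <- union_networks(a, b)
    x <- intersect_networks(a, b)
    # inclusion-exclusion on edge counts, exactly
    expect_identical(n_edges(a$network) + n_edges(b$network),
                     n_edges(u) + n_edges(x))
    # subnetwork algebra: intersect <= each <= union <= source
    ek <- function(n) paste(n$edges[, 1], n$edges[, 2])
    expect_true(all(ek(x) %in% ek(a$network)))
    expect_true(all(ek(a$network) %in% ek(u)))
    expect_true(all(ek(u) %in% ek(src)))
  }
})

test_that("intersection nodes are endpoints of common edges, not node-set overlap", {
  a <- interactome(c(1L, 2L), c(2L, 3L))
  b <- interactome(c(2L, 3L), c(3L, 4L))
  x <- intersect_networks(a, b)
  expect_equal(n_edges(x), 1L)
  expect_equal(x$nodes, c(2L, 3L))
  expect_equal(intersect_networks(a, a)$edges, a$edges)
})

test_that("every non-seed node of the overlap network touches a shared seed", {
  set.seed(67)
  for (i in 1:10) {
    ds <- tiny_synthetic(seed = i)
    a <- extract_disease_network(ds$interactome, ds$genes_a)
    b <- extract_disease_network(ds$interactome, ds$genes_b)
    overlap <- intersect_networks(a, b)
    shared_ids <- intersect(ds$genes_a$gene_id, ds$genes_b$gene_id)
    counts <- shared_gene_neighbor_count(overlap, shared_ids)
    non_disease <- setdiff(overlap$nodes,
                           union(ds$genes_a$gene_id, ds$genes_b$gene_id))
    expect_true(all(counts[as.character(non_disease)] >= 1L))
    # for non-disease nodes the count equals overlap-network degree
    deg <- table(factor(as.integer(overlap$edges), levels = overlap$nodes))
    expect_equal(unname(counts[as.character(non_disease)]),
                 as.integer(deg[as.character(non_disease)]))
  }
})

test_that("shared-neighbor counting scores stars and isolated nodes correctly", {
  star <- interactome(rep(100L, 4), c(1L, 2L, 3L, 4L))
  counts <- shared_gene_neighbor_count(star, 1:4)
  expect_equal(unname(counts["100"]), 4L)
  expect_equal(unname(counts["1"]), 0L)  # leaf's only neighbor is the center
  counts2 <- shared_gene_neighbor_count(star, c(100L, 1L))
  expect_equal(unname(counts2["2"]), 1L)
})

test_that("candidate prediction excludes known genes and orders deterministically", {
  counts <- c(`5` = 7L, `6` = 7L, `7` = 9L, `8` = 2L, `9` = 6L)
  ranking <- predict_candidates(counts, known = 6L, min_count = 6L)
  expect_equal(ranking$gene_id, c(7L, 5L, 6L, 9L, 8L))  # count desc, id asc
  expect_equal(novel_candidates(ranking), c(7L, 5L, 9L))
  expect_true(all(!ranking$is_novel_candidate[ranking$is_known_disease_gene]))
  # all genes known -> nothing novel
  expect_length(novel_candidates(predict_candidates(counts, known = c(5:9))), 0L)
  expect_error(predict_candidates(counts, 1L, min_count = 0L),
               class = "comorbidnet_bad_threshold")
})

test_that("planted candidates are recovered exactly on noise-free synthetic data", {
  ds <- tiny_synthetic(seed = 3)
  a <- extract_disease_network(ds$interactome, ds$genes_a)
  b <- extract_disease_network(ds$interactome, ds$genes_b)
  overlap <- intersect_networks(a, b)
  shared_ids <- intersect(ds$genes_a$gene_id, ds$genes_b$gene_id)
  counts <- shared_gene_neighbor_count(overlap, shared_ids)
  known <- union(ds$genes_a$gene_id, ds$genes_b$gene_id)
  ranking <- predict_candidates(counts, known,
                                min_count = ds$config$candidate_wiring)
  expect_setequal(novel_candidates(ranking), ds$truth$planted_candidates)
})

test_that("candidate neighborhoods include exactly the incident edges", {
  net <- interactome(c(1L, 1L, 1L, 5L), c(2L, 3L, 4L, 6L))
  nb <- extract_candidate_neighborhood(net, 1L,
                                       genes_a = gene_set(2L), genes_b = gene_set(c(3L, 2L)))
  expect_equal(n_nodes(nb$network), 4L)
  expect_equal(n_edges(nb$network), 3L)
  cls <- setNames(nb$node_class$node_class, nb$node_class$gene_id)
  expect_equal(unname(cls[c("1", "2", "3", "4")]),
               c("candidate", "shared", "b", "other"))
  # two candidates sharing a neighbor: the neighbor appears once
  nb2 <- extract_candidate_neighborhood(interactome(c(1L, 2L), c(9L, 9L)),
                                        c(1L, 2L), gene_set(9L), gene_set(9L))
  expect_equal(n_nodes(nb2$network), 3L)
  expect_error(extract_candidate_neighborhood(net, 99L, gene_set(2L), gene_set(3L)),
               class = "comorbidnet_missing_candidate")
})

test_that("annotated gene networks export and interactomes round-trip as TSV", {
  net <- interactome(c(1L, 2L, 3L), c(2L, 3L, 4L))
  p <- tempfile(fileext = ".tsv")
  write_edge_list(net, p)
  expect_equal(read_edge_list(p)$edges, net$edges)
  nb <- extract_candidate_neighborhood(net, 2L, gene_set(1L), gene_set(4L))
  g <- tempfile(fileext = ".graphml")
  export_gene_network(nb, g, "graphml")
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gsize(gr), n_edges(nb$network))
  expect_setequal(igraph::V(gr)$node_class,
                  unique(nb$node_class$node_class))
})
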