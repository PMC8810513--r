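test_that("Jaccard and Overlap coefficients match enumeration on fixed sets", {
  expect_equal(jaccard(1:3, 1:3), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(1:3, 2:4), 0.5)           # 2 shared / 4 in union
  expect_equal(overlap_coefficient(1:2, 1:10), 1) # nested sets
  expect_equal(overlap_coefficient(1:3, 4:6), 0)
  expect_equal(overlap_coefficient(1:3, 2:4), 2 / 3)
  expect_error(jaccard(integer(0), integer(0)), class = "comorbidnet_empty_sets")
  expect_error(overlap_coefficient(1:3, integer(0)), class = "comorbidnet_empty_sets")
})

test_that("0 <= JC <= OC <= 1 with equality characterisations on random sets", {
  set.seed(23)
  for (i in 1:300) {
    A <- random_id_set(sample(1:15, 1), pool = 25L)
    B <- random_id_set(sample(1:15, 1), pool = 25L)
    jc <- jaccard(A, B)
    oc <- overlap_coefficient(A, B)
    expect_gte(jc, 0); expect_lte(oc, 1)
    expect_lte(jc, oc + 1e-12)
    expect_equal(jc == 1, setequal(A, B))
    expect_equal(oc == 1, all(A %in% B) || all(B %in% A))
  }
})

test_that("membership restriction intersects pathways with disease genes", {
  col <- pathway_collection(c("P1", "P2", "P3"),
                            members = list(1:4, c(2L, 4L, 9L), 20:22),
                            background = 1:30)
  mem <- restrict_memberships(col, c(2L, 4L, 9L))
  expect_equal(mem$restricted[["P1"]], c(2L, 4L))
  expect_equal(mem$restricted[["P2"]], c(2L, 4L, 9L))
  expect_equal(mem$restricted[["P3"]], integer(0))
  # disease genes superset -> full membership; NULL -> full-membership mode
  expect_equal(restrict_memberships(col, 1:30)$restricted[["P1"]], 1:4)
  expect_equal(restrict_memberships(col)$restricted[["P3"]], 20:22)
  expect_error(restrict_memberships(col, pathway_ids = "NOPE"),
               class = "comorbidnet_unknown_pathway")
})

test_that("cross-talk network applies both thresholds and scores edges", {
  col <- pathway_collection(c("P1", "P2", "P3"),
                            members = list(1:3, 2:4, 9L), background = 1:10)
  mem <- restrict_memberships(col)
  net <- build_crosstalk_network(mem, min_genes = 2L, min_shared = 2L)
  expect_equal(nrow(net), 1L)
  expect_equal(net$pathway_a, "P1")
  expect_equal(net$pathway_b, "P2")
  expect_equal(net$jc, 0.5)
  expect_equal(net$oc, 2 / 3)
  expect_equal(net$weight, (0.5 + 2 / 3) / 2)
  expect_equal(net$shared_genes[[1]], 2:3)
  # single pathway and identical memberships
  single <- restrict_memberships(pathway_collection("X", members = list(1:5)))
  expect_equal(nrow(build_crosstalk_network(single)), 0L)
  same <- pathway_collection(c("A", "B", "C"), members = list(1:4, 1:4, 1:4))
  full <- build_crosstalk_network(restrict_memberships(same), 3L, 2L)
  expect_equal(nrow(full), choose(3, 2))
  expect_true(all(full$weight == 1))
})

test_that("cross-talk output is order-invariant and monotone in thresholds", {
  set.seed(37)
  members <- replicate(8, sort(sample.int(40, sample(3:12, 1))), simplify = FALSE)
  ids <- sprintf("P%d", 1:8)
  col1 <- pathway_collection(ids, members = members, background = 1:40)
  perm <- sample(8)
  col2 <- pathway_collection(ids[perm], members = members[perm], background = 1:40)
  n1 <- build_crosstalk_network(restrict_memberships(col1), 2L, 1L)
  n2 <- build_crosstalk_network(restrict_memberships(col2), 2L, 1L)
  expect_equal(n1, n2)
  expect_true(all(n1$pathway_a < n1$pathway_b))
  base_keys <- paste(n1$pathway_a, n1$pathway_b)
  for (mg in 2:4) {
    for (ms in 1:3) {
      sub <- build_crosstalk_network(restrict_memberships(col1), mg, ms)
      expect_true(all(paste(sub$pathway_a, sub$pathway_b) %in% base_keys))
    }
  }
  p_pass <- sum(lengths(restrict_memberships(col1)$restricted) >= 2L)
  expect_lte(nrow(n1), choose(p_pass, 2))
})

test_that("tripartite assembly counts pathway and gene edges separately", {
  col <- pathway_collection(c("P1", "P2"), members = list(1:3, 2:4))
  mem <- restrict_memberships(col)
  edges <- build_crosstalk_network(mem, min_genes = 2L, min_shared = 2L)
  net <- build_tripartite(edges, mem, genes = c(2L, 3L))
  expect_equal(length(net$pathway_nodes), 2L)
  expect_equal(net$gene_nodes, c(2L, 3L))
  expect_equal(nrow(net$pp_edges), 1L)
  expect_equal(nrow(net$pg_edges), 4L)  # both genes sit in both pathways
  # genes must belong to the pathway's considered membership
  expect_true(all(mapply(function(g, m) g %in% m,
                         net$pg_edges$gene_id,
                         mem$restricted[net$pg_edges$pathway_id])))
  # empty case
  e0 <- build_crosstalk_network(restrict_memberships(pathway_collection("Z", members = list(1:2))))
  net0 <- build_tripartite(e0, restrict_memberships(pathway_collection("Z", members = list(1:2))),
                           genes = integer(0))
  expect_equal(length(net0$pathway_nodes), 0L)
  expect_equal(nrow(net0$pg_edges), 0L)
})

test_that("network export round-trips through graphml, tsv and sif", {
  col <- pathway_collection(c("P1", "P2", "P3"),
                            members = list(1:4, 2:5, c(4L, 5L, 6L)))
  mem <- restrict_memberships(col)
  edges <- build_crosstalk_network(mem, 2L, 1L)
  net <- build_tripartite(edges, mem, genes = c(2L, 4L, 5L),
                          gene_class = c(`2` = "shared", `4` = "A", `5` = "B"))
  for (fmt in c("graphml", "tsv", "sif")) {
    f <- tempfile(fileext = paste0(".", fmt))
    export_network(net, f, fmt)
    back <- read_network(f, fmt)
    expect_setequal(back$pathway_nodes, net$pathway_nodes)
    expect_setequal(back$gene_nodes, net$gene_nodes)
    expect_equal(
      sort(paste(back$pp_edges$pathway_a, back$pp_edges$pathway_b)),
      sort(paste(net$pp_edges$pathway_a, net$pp_edges$pathway_b))
    )
    expect_equal(
      sort(paste(back$pg_edges$pathway_id, back$pg_edges$gene_id)),
      sort(paste(net$pg_edges$pathway_id, net$pg_edges$gene_id))
    )
    if (fmt != "sif") {
      expect_equal(sort(back$pp_edges$weight), sort(net$pp_edges$weight))
      expect_equal(unname(back$gene_class[as.character(net$gene_nodes)]),
                   unname(net$gene_class[as.character(net$gene_nodes)]))
    }
  }
  # empty network writes a valid zero-edge file; 1-edge sif has 1 + pg lines
  empty <- build_tripartite(build_crosstalk_network(mem, 5L, 5L), mem, integer(0))
  f <- tempfile(fileext = ".sif")
  export_network(empty, f, "sif")
  expect_length(readLines(f), 0L)
  expect_error(export_network(net, tempfile(), "dot"),
               class = "comorbidnet_unknown_format")
})
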