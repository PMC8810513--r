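#' Construct a cleaned undirected interactome
#'
#' An interactome is a simple undirected graph over Entrez gene IDs.
#' Construction canonicalises each pair to `(min, max)` order, drops
#' self-interactions, and collapses redundant pairs; the numbers of dropped
#' self-pairs and duplicates are recorded as attributes `n_self_dropped` and
#' `n_dup_dropped`. Only nodes incident to at least one edge are retained.
#'
#' @param from,to integer vectors of interacting gene IDs (parallel).
#' @return An object of class `interactome`: a list with `edges`, an
#'   integer matrix with columns `a < b`, one row per unique interaction,
#'   sorted; and `nodes`, the sorted endpoint set.
#' @export
interactome <- function(from = integer(0), to = integer(0)) {
  from <- as_gene_id(from, "interactome gene")
  to <- as_gene_id(to, "interactome gene")
  stopifnot(length(from) == length(to))
  a <- pmin(from, to)
  b <- pmax(from, to)
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  key <- paste(a, b)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  ord <- order(a, b)
  edges <- cbind(a = a[ord], b = b[ord])
  structure(
    list(edges = edges, nodes = sort(unique(c(a, b)))),
    class = "interactome", n_self_dropped = n_self, n_dup_dropped = n_dup
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts of an interactome
#' @param x an `interactome`.
#' @return An integer count.
#' @export
n_nodes <- function(x) length(x$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(x) nrow(x$edges)

edge_keys <- function(x) paste(x$edges[, 1L], x$edges[, 2L])

#' Default exclusion list: promiscuous ubiquitin genes
#'
#' Ubiquitin-C, -B and -D (Entrez 7316, 7314, 10537) bind non-specifically
#' to proteins destined for degradation and are conventionally removed from
#' physical interactomes before network analysis.
#'
#' @return A named integer vector of Entrez IDs.
#' @export
ubiquitin_exclusion <- function() {
  c(UBC = 7316L, UBB = 7314L, UBD = 10537L)
}

#' Read an interactome edge list from TSV
#'
#' Two (or more) tab-separated columns of gene IDs; a header row is
#' auto-detected (first line whose first two fields are not integers).
#' Self-pairs and duplicate pairs are dropped with counts recorded on the
#' result.
#'
#' @param path path to the edge-list file.
#' @return An [interactome].
#' @export
read_edge_list <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    cn_stop("unreadable_file", "cannot read edge list: %s", as.character(path)[1])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(interactome())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    cn_stop("bad_edge_list", "edge list %s has lines with fewer than 2 columns", path)
  }
  first <- suppressWarnings(as.integer(c(parts[[1L]][1L], parts[[1L]][2L])))
  if (any(is.na(first))) parts <- parts[-1L]  # header
  if (length(parts) == 0L) return(interactome())
  interactome(
    from = vapply(parts, `[[`, character(1), 1L),
    to = vapply(parts, `[[`, character(1), 2L)
  )
}

#' Write an interactome edge list to TSV
#' @param x an [interactome].
#' @param path destination file.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(x, path) {
  stopifnot(inherits(x, "interactome"))
  write_tsv(data.frame(gene_a = x$edges[, 1L], gene_b = x$edges[, 2L]), path)
}

#' Merge interactomes and apply a gene exclusion list
#'
#' Takes the union of the edge sets of several interactomes (redundant pairs
#' and self-interactions are removed by construction) and then deletes every
#' edge touching an excluded gene (by default the promiscuous ubiquitin
#' genes, [ubiquitin_exclusion()]).
#'
#' @param nets a list of [interactome] objects (or a single one).
#' @param exclude integer vector of gene IDs to remove entirely.
#' @return An [interactome].
#' @export
merge_interactomes <- function(nets, exclude = ubiquitin_exclusion()) {
  if (inherits(nets, "interactome")) nets <- list(nets)
  stopifnot(all(vapply(nets, inherits, logical(1), "interactome")))
  a <- unlist(lapply(nets, function(n) n$edges[, 1L]), use.names = FALSE)
  b <- unlist(lapply(nets, function(n) n$edges[, 2L]), use.names = FALSE)
  merged <- interactome(a, b)
  if (length(exclude)) {
    keep <- !(merged$edges[, 1L] %in% exclude | merged$edges[, 2L] %in% exclude)
    merged <- interactome(merged$edges[keep, 1L], merged$edges[keep, 2L])
  }
  merged
}

#' Extract a disease-specific subnetwork around seed genes
#'
#' Two extraction semantics are supported. The default, `"edge_incident"`,
#' keeps every interactome edge with at least one endpoint in the seed gene
#' set (the "star expansion" around the seeds); the node set is then the
#' endpoints of the kept edges, so it contains the seeds' first neighbors.
#' The alternative, `"induced"`, keeps only edges with both endpoints in the
#' seed set.
#'
#' @param net an [interactome].
#' @param seeds a [gene_set] or integer vector of seed (disease) gene IDs.
#' @param rule extraction rule, `"edge_incident"` (default) or `"induced"`.
#' @return An object of class `disease_network`: a list with elements
#'   `network` (an [interactome]), `seeds` (the seed IDs present in the
#'   source network), and `rule`.
#' @export
extract_disease_network <- function(net, seeds,
                                    rule = c("edge_incident", "induced")) {
  stopifnot(inherits(net, "interactome"))
  rule <- match.arg(rule)
  s <- if (inherits(seeds, "gene_set")) seeds$gene_id else as_gene_id(seeds, "seed gene")
  if (length(s) == 0L) cn_stop("empty_seeds", "seed gene set is empty")
  in_a <- net$edges[, 1L] %in% s
  in_b <- net$edges[, 2L] %in% s
  keep <- if (rule == "edge_incident") in_a | in_b else in_a & in_b
  sub <- interactome(net$edges[keep, 1L], net$edges[keep, 2L])
  structure(list(network = sub, seeds = sort(intersect(s, net$nodes)), rule = rule),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network> rule=%s, %d seeds present; %d nodes, %d edges\n",
              x$rule, length(x$seeds), n_nodes(x$network), n_edges(x$network)))
  invisible(x)
}

as_interactome <- function(x) {
  if (inherits(x, "disease_network")) x$network else x
}

#' Union of two disease networks
#'
#' Edge-set union; `|a| + |b| = |union| + |intersection|` holds exactly on
#' edge counts.
#'
#' @param a,b [interactome] or `disease_network` objects.
#' @return An [interactome].
#' @export
union_networks <- function(a, b) {
  a <- as_interactome(a); b <- as_interactome(b)
  interactome(c(a$edges[, 1L], b$edges[, 1L]), c(a$edges[, 2L], b$edges[, 2L]))
}

#' Intersection (overlap) of two disease networks
#'
#' Edges present in both networks; the node set is the endpoint set of those
#' common edges (not the intersection of the two node sets).
#'
#' @param a,b [interactome] or `disease_network` objects.
#' @return An [interactome].
#' @export
intersect_networks <- function(a, b) {
  a <- as_interactome(a); b <- as_interactome(b)
  keep <- edge_keys(a) %in% edge_keys(b)
  interactome(a$edges[keep, 1L], a$edges[keep, 2L])
}

#' Count shared-gene neighbors of every node
#'
#' For each node of the network, the number of distinct direct neighbors
#' that belong to the shared gene set. This is the guilt-by-association
#' score: for a node outside both disease gene sets, every neighbor it has
#' in the overlap network is necessarily a shared gene, so this count equals
#' its overlap-network degree.
#'
#' @param net an [interactome] (typically the overlap network).
#' @param shared a [gene_set] or integer vector of shared gene IDs.
#' @return A named integer vector over all network nodes (names are gene
#'   IDs).
#' @export
shared_gene_neighbor_count <- function(net, shared) {
  net <- as_interactome(net)
  s <- if (inherits(shared, "gene_set")) shared$gene_id else
    as_gene_id(shared, "shared gene")
  counts <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (n_edges(net) == 0L) return(counts)
  a <- net$edges[, 1L]; b <- net$edges[, 2L]
  # each unique pair contributes at most once per direction
  inc_a <- table(factor(a[b %in% s], levels = net$nodes))
  inc_b <- table(factor(b[a %in% s], levels = net$nodes))
  counts[] <- as.integer(inc_a + inc_b)
  counts
}

#' Rank candidate genes by shared-gene neighbor count
#'
#' Implements the guilt-by-association call: genes already known to be
#' disease-associated are flagged, and the novel candidates are exactly the
#' unknown genes whose shared-gene neighbor count reaches `min_count`
#' (default 6, i.e. "more than 5" direct shared-gene interactions). Entries
#' are ordered by descending count, ties broken by ascending gene ID.
#'
#' @param counts named integer vector from [shared_gene_neighbor_count()].
#' @param known a [gene_set] or integer vector of known disease genes
#'   (typically the union of both disease sets).
#' @param min_count minimal count for a novel-candidate call (default 6).
#' @return A data frame of class `candidate_ranking` with columns
#'   `gene_id`, `shared_neighbor_count`, `is_known_disease_gene`,
#'   `is_novel_candidate`; attribute `threshold` records `min_count`.
#' @export
predict_candidates <- function(counts, known, min_count = 6L) {
  if (min_count < 1L) cn_stop("bad_threshold", "min_count must be >= 1")
  k <- if (inherits(known, "gene_set")) known$gene_id else
    as_gene_id(known, "known gene")
  ids <- as.integer(names(counts))
  out <- data.frame(
    gene_id = ids,
    shared_neighbor_count = as.integer(counts),
    is_known_disease_gene = ids %in% k,
    stringsAsFactors = FALSE
  )
  out$is_novel_candidate <- !out$is_known_disease_gene &
    out$shared_neighbor_count >= min_count
  out <- out[order(-out$shared_neighbor_count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_ranking", "data.frame"),
            threshold = as.integer(min_count))
}

#' Novel candidate gene IDs of a ranking
#' @param x a `candidate_ranking`.
#' @return Integer vector of novel candidate gene IDs (ranking order).
#' @export
novel_candidates <- function(x) {
  stopifnot(inherits(x, "candidate_ranking"))
  x$gene_id[x$is_novel_candidate]
}

#' Extract the neighborhood subnetwork of candidate genes
#'
#' Keeps the edges of a disease network that are incident to at least one
#' candidate gene and labels every node by its class: `candidate`, the two
#' disease provenances (`a`, `b`), `shared`, or `other`. Candidates must be
#' nodes of the network.
#'
#' @param net an [interactome] (typically the union disease network).
#' @param candidates integer vector of candidate gene IDs.
#' @param genes_a,genes_b [gene_set]s of the two diseases (used to derive
#'   the `a` / `b` / `shared` labels).
#' @return An object of class `annotated_network`: a list with `network`
#'   (an [interactome]) and `node_class` (data frame `gene_id`,
#'   `node_class`).
#' @export
extract_candidate_neighborhood <- function(net, candidates, genes_a, genes_b) {
  net <- as_interactome(net)
  candidates <- as_gene_id(candidates, "candidate gene")
  missing <- setdiff(candidates, net$nodes)
  if (length(missing)) {
    cn_stop("missing_candidate", "candidate gene(s) absent from the network: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  ga <- if (inherits(genes_a, "gene_set")) genes_a$gene_id else as_gene_id(genes_a)
  gb <- if (inherits(genes_b, "gene_set")) genes_b$gene_id else as_gene_id(genes_b)
  keep <- net$edges[, 1L] %in% candidates | net$edges[, 2L] %in% candidates
  sub <- interactome(net$edges[keep, 1L], net$edges[keep, 2L])
  cls <- ifelse(sub$nodes %in% candidates, "candidate",
         ifelse(sub$nodes %in% intersect(ga, gb), "shared",
         ifelse(sub$nodes %in% ga, "a",
         ifelse(sub$nodes %in% gb, "b", "other"))))
  structure(
    list(network = sub,
         node_class = data.frame(gene_id = sub$nodes, node_class = cls,
                                 stringsAsFactors = FALSE)),
    class = "annotated_network"
  )
}

#' Export an annotated gene network
#'
#' Same formats as [export_network()]: graphml carries the `node_class`
#' attribute, sif writes `gene interacts gene` triples, tsv writes the edge
#' table plus a `<path>.nodes` class table.
#'
#' @param net an `annotated_network` (or plain [interactome]).
#' @param path destination file.
#' @param format one of `"graphml"`, `"sif"`, `"tsv"`.
#' @return The path, invisibly.
#' @export
export_gene_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  if (inherits(net, "interactome")) {
    net <- structure(
      list(network = net,
           node_class = data.frame(gene_id = net$nodes,
                                   node_class = rep("gene", n_nodes(net)),
                                   stringsAsFactors = FALSE)),
      class = "annotated_network"
    )
  }
  stopifnot(inherits(net, "annotated_network"))
  if (length(format) != 1L || !format %in% c("graphml", "sif", "tsv")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) cn_stop("unknown_format",
                                                   "unknown export format: %s",
                                                   paste(format, collapse = "/")))
  }
  edges <- data.frame(gene_a = net$network$edges[, 1L],
                      gene_b = net$network$edges[, 2L])
  if (format == "graphml") {
    nodes <- data.frame(name = as.character(net$node_class$gene_id),
                        node_class = net$node_class$node_class,
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$gene_a),
                 to = as.character(edges$gene_b)),
      directed = FALSE, vertices = nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(paste(edges$gene_a, "interacts", edges$gene_b, sep = "\t"), path)
  } else {
    write_tsv(edges, path)
    write_tsv(net$node_class, paste0(path, ".nodes"))
  }
  invisible(path)
}
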