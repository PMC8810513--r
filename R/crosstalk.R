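#' Jaccard coefficient of two gene sets
#'
#' `|A intersect B| / |A union B|`. Measures the overlap between the gene
#' memberships of two pathways.
#'
#' @param A,B integer vectors of gene IDs; at least one must be non-empty.
#' @return A value in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L && length(B) == 0L) {
    cn_stop("empty_sets", "Jaccard coefficient is undefined for two empty sets")
  }
  length(intersect(A, B)) / length(union(A, B))
}

#' Overlap coefficient of two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`. Equals 1 whenever one set contains the
#' other, and always dominates the Jaccard coefficient.
#'
#' @param A,B non-empty integer vectors of gene IDs.
#' @return A value in `[0, 1]`.
#' @export
overlap_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L) {
    cn_stop("empty_sets", "Overlap coefficient is undefined when either set is empty")
  }
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Restrict pathway memberships to disease-associated genes
#'
#' For pathway cross-talk the relevant membership of each pathway is its
#' intersection with the disease-associated genes under study; pathways with
#' an empty restricted membership are carried along with an empty set.
#'
#' @param collection a [pathway_collection].
#' @param disease_genes a [gene_set] or integer vector of gene IDs; `NULL`
#'   keeps the full memberships (full-membership mode).
#' @param pathway_ids optional subset of pathway IDs to retain (e.g. the
#'   shared or disease-specific pathways).
#' @return An object of class `pathway_membership`: a list with `ids`,
#'   `restricted` (list of restricted member vectors) and `full` (list of
#'   full member vectors).
#' @export
restrict_memberships <- function(collection, disease_genes = NULL,
                                 pathway_ids = NULL) {
  stopifnot(inherits(collection, "pathway_collection"))
  ids <- collection$ids
  if (!is.null(pathway_ids)) {
    missing <- setdiff(pathway_ids, ids)
    if (length(missing)) {
      cn_stop("unknown_pathway", "pathway ID(s) not in collection: %s",
              paste(utils::head(missing, 5L), collapse = ", "))
    }
    ids <- ids[ids %in% pathway_ids]
  }
  full <- collection$members[ids]
  restricted <- if (is.null(disease_genes)) {
    full
  } else {
    g <- if (inherits(disease_genes, "gene_set")) disease_genes$gene_id else
      as_gene_id(disease_genes, "disease gene")
    lapply(full, function(m) intersect(m, g))
  }
  structure(list(ids = ids, restricted = restricted, full = full),
            class = "pathway_membership")
}

#' Build the pathway cross-talk network
#'
#' Scores every unordered pair of pathways whose (restricted) memberships
#' both contain at least `min_genes` genes and which share at least
#' `min_shared` genes. Each retained pair becomes an edge carrying the
#' Jaccard coefficient, the Overlap coefficient, their arithmetic mean as
#' the edge weight, and the shared genes. Edges are canonicalised with
#' `pathway_a < pathway_b` and sorted, so the result is independent of the
#' input pathway order.
#'
#' @param memberships a `pathway_membership` from [restrict_memberships()].
#' @param min_genes minimum (restricted) membership size per pathway
#'   (default 3).
#' @param min_shared minimum number of shared genes per pair (default 2).
#' @return A data frame of class `crosstalk_edges` with columns `pathway_a`,
#'   `pathway_b`, `jc`, `oc`, `weight`, `n_shared`, and list column
#'   `shared_genes`.
#' @export
build_crosstalk_network <- function(memberships, min_genes = 3L, min_shared = 2L) {
  stopifnot(inherits(memberships, "pathway_membership"))
  if (min_genes < 1L || min_shared < 1L) {
    cn_stop("bad_threshold", "min_genes and min_shared must both be >= 1")
  }
  keep <- lengths(memberships$restricted) >= min_genes
  ids <- memberships$ids[keep]
  mem <- memberships$restricted[keep]
  empty <- data.frame(pathway_a = character(0), pathway_b = character(0),
                      jc = numeric(0), oc = numeric(0), weight = numeric(0),
                      n_shared = integer(0), stringsAsFactors = FALSE)
  empty$shared_genes <- list()
  if (length(ids) < 2L) {
    return(structure(empty, class = c("crosstalk_edges", "data.frame")))
  }
  ord <- order(ids)
  ids <- ids[ord]; mem <- mem[ord]
  pairs <- utils::combn(length(ids), 2L)
  rows <- vector("list", ncol(pairs))
  n_kept <- 0L
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    shared <- intersect(mem[[i1]], mem[[i2]])
    if (length(shared) < min_shared) next
    jc <- jaccard(mem[[i1]], mem[[i2]])
    oc <- overlap_coefficient(mem[[i1]], mem[[i2]])
    n_kept <- n_kept + 1L
    rows[[n_kept]] <- list(pathway_a = ids[[i1]], pathway_b = ids[[i2]],
                           jc = jc, oc = oc, weight = (jc + oc) / 2,
                           n_shared = length(shared),
                           shared_genes = sort(shared))
  }
  if (n_kept == 0L) {
    return(structure(empty, class = c("crosstalk_edges", "data.frame")))
  }
  rows <- rows[seq_len(n_kept)]
  out <- data.frame(
    pathway_a = vapply(rows, `[[`, character(1), "pathway_a"),
    pathway_b = vapply(rows, `[[`, character(1), "pathway_b"),
    jc = vapply(rows, `[[`, numeric(1), "jc"),
    oc = vapply(rows, `[[`, numeric(1), "oc"),
    weight = vapply(rows, `[[`, numeric(1), "weight"),
    n_shared = vapply(rows, `[[`, integer(1), "n_shared"),
    stringsAsFactors = FALSE
  )
  out$shared_genes <- lapply(rows, `[[`, "shared_genes")
  out <- out[order(out$pathway_a, out$pathway_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("crosstalk_edges", "data.frame"))
}

#' Attach genes to the pathway cross-talk network
#'
#' Builds the pathway-pathway-gene ("tripartite") network: pathways retained
#' in the cross-talk network are linked to each of their considered member
#' genes drawn from `genes` (typically the shared disease genes, or all
#' disease genes for the disease-specific variant). Pathway-pathway and
#' pathway-gene edges are counted separately.
#'
#' @param edges a `crosstalk_edges` data frame from
#'   [build_crosstalk_network()].
#' @param memberships the `pathway_membership` the edges were built from.
#' @param genes a [gene_set] or integer vector of gene IDs to attach.
#' @param gene_class optional named character vector mapping gene IDs to a
#'   class label (e.g. disease provenance) recorded as a node attribute.
#' @return An object of class `tripartite_network`: a list with
#'   `pathway_nodes`, `gene_nodes`, `pp_edges` (the cross-talk edges), and
#'   `pg_edges` (data frame `pathway_id`, `gene_id`).
#' @export
build_tripartite <- function(edges, memberships, genes, gene_class = NULL) {
  stopifnot(inherits(edges, "crosstalk_edges"),
            inherits(memberships, "pathway_membership"))
  g <- if (inherits(genes, "gene_set")) genes$gene_id else
    as_gene_id(genes, "attached gene")
  pathway_nodes <- sort(unique(c(edges$pathway_a, edges$pathway_b)))
  pg <- list()
  for (pid in pathway_nodes) {
    m <- intersect(memberships$restricted[[match(pid, memberships$ids)]], g)
    if (length(m)) pg[[pid]] <- data.frame(pathway_id = pid, gene_id = sort(m),
                                           stringsAsFactors = FALSE)
  }
  pg_edges <- if (length(pg)) {
    out <- do.call(rbind, pg)
    rownames(out) <- NULL
    out
  } else {
    data.frame(pathway_id = character(0), gene_id = integer(0),
               stringsAsFactors = FALSE)
  }
  gene_nodes <- sort(unique(pg_edges$gene_id))
  cls <- if (is.null(gene_class)) {
    stats::setNames(rep("gene", length(gene_nodes)), gene_nodes)
  } else {
    got <- gene_class[as.character(gene_nodes)]
    got[is.na(got)] <- "gene"
    stats::setNames(unname(got), gene_nodes)
  }
  structure(
    list(pathway_nodes = pathway_nodes, gene_nodes = gene_nodes,
         pp_edges = edges, pg_edges = pg_edges, gene_class = cls),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf(
    "<tripartite_network> %d pathway + %d gene nodes; %d pathway-pathway + %d pathway-gene edges\n",
    length(x$pathway_nodes), length(x$gene_nodes),
    nrow(x$pp_edges), nrow(x$pg_edges)
  ))
  invisible(x)
}

tripartite_edge_table <- function(net) {
  pp <- data.frame(
    source = net$pp_edges$pathway_a, target = net$pp_edges$pathway_b,
    kind = rep("pathway_pathway", nrow(net$pp_edges)),
    jc = net$pp_edges$jc, oc = net$pp_edges$oc, weight = net$pp_edges$weight,
    stringsAsFactors = FALSE
  )
  pg <- data.frame(
    source = net$pg_edges$pathway_id, target = as.character(net$pg_edges$gene_id),
    kind = rep("pathway_gene", nrow(net$pg_edges)),
    jc = rep(NA_real_, nrow(net$pg_edges)), oc = rep(NA_real_, nrow(net$pg_edges)),
    weight = rep(NA_real_, nrow(net$pg_edges)),
    stringsAsFactors = FALSE
  )
  rbind(pp, pg)
}

tripartite_node_table <- function(net) {
  data.frame(
    node = c(net$pathway_nodes, as.character(net$gene_nodes)),
    node_class = c(rep("pathway", length(net$pathway_nodes)),
                   unname(net$gene_class)),
    stringsAsFactors = FALSE
  )
}

#' Export a tripartite network for Cytoscape or re-import
#'
#' Formats: `"graphml"` (full node and edge attributes, Cytoscape-ready),
#' `"sif"` (simple interaction format; edge attributes are not representable
#' and are dropped), `"tsv"` (two tab-delimited tables, `<path>` with the
#' edges and `<path>.nodes` with node classes; lossless). [read_network()]
#' reconstructs the network from the graphml and tsv forms, and the node and
#' edge sets from sif.
#'
#' @param net a `tripartite_network`.
#' @param path destination file.
#' @param format one of `"graphml"`, `"sif"`, `"tsv"`.
#' @return The path, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(net, "tripartite_network"))
  if (length(format) != 1L || !format %in% c("graphml", "sif", "tsv")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) cn_stop("unknown_format",
                                                   "unknown export format: %s",
                                                   paste(format, collapse = "/")))
  }
  nodes <- tripartite_node_table(net)
  edges <- tripartite_edge_table(net)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges)) edges else data.frame(source = character(0), target = character(0)),
      directed = FALSE, vertices = nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(edges)) {
      paste(edges$source, edges$kind, edges$target, sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
  } else {
    write_tsv(edges, path)
    write_tsv(nodes, paste0(path, ".nodes"))
  }
  invisible(path)
}

#' Re-read an exported network
#'
#' Inverse of [export_network()] for the `graphml` and `tsv` formats; for
#' `sif` only the node and edge sets are recoverable (weights were not
#' written).
#'
#' @param path file written by [export_network()].
#' @param format the format it was written in.
#' @return A `tripartite_network`.
#' @export
read_network <- function(path, format = c("graphml", "sif", "tsv")) {
  if (length(format) != 1L || !format %in% c("graphml", "sif", "tsv")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) cn_stop("unknown_format",
                                                   "unknown import format: %s",
                                                   paste(format, collapse = "/")))
  }
  if (!file.exists(path)) cn_stop("unreadable_file", "no such file: %s", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(node = igraph::V(g)$name,
                        node_class = igraph::V(g)$node_class,
                        stringsAsFactors = FALSE)
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(source = ed$from, target = ed$to, kind = ed$kind,
                        jc = if (nrow(ed)) ed$jc else numeric(0),
                        oc = if (nrow(ed)) ed$oc else numeric(0),
                        weight = if (nrow(ed)) ed$weight else numeric(0),
                        stringsAsFactors = FALSE)
  } else if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- data.frame(
      source = vapply(parts, `[[`, character(1), 1L),
      kind = vapply(parts, `[[`, character(1), 2L),
      target = vapply(parts, `[[`, character(1), 3L),
      stringsAsFactors = FALSE
    )
    edges$jc <- NA_real_; edges$oc <- NA_real_; edges$weight <- NA_real_
    pnodes <- unique(c(edges$source, edges$target[edges$kind == "pathway_pathway"]))
    gnodes <- unique(edges$target[edges$kind == "pathway_gene"])
    nodes <- data.frame(
      node = c(pnodes, gnodes),
      node_class = c(rep("pathway", length(pnodes)), rep("gene", length(gnodes))),
      stringsAsFactors = FALSE
    )
  } else {
    e <- read_tsv(path)
    edges <- data.frame(source = e$source, target = e$target, kind = e$kind,
                        jc = suppressWarnings(as.numeric(e$jc)),
                        oc = suppressWarnings(as.numeric(e$oc)),
                        weight = suppressWarnings(as.numeric(e$weight)),
                        stringsAsFactors = FALSE)
    nodes <- read_tsv(paste0(path, ".nodes"))
  }
  rebuild_tripartite(nodes, edges)
}

rebuild_tripartite <- function(nodes, edges) {
  is_pathway <- nodes$node_class == "pathway"
  pp_raw <- edges[edges$kind == "pathway_pathway", , drop = FALSE]
  pg_raw <- edges[edges$kind == "pathway_gene", , drop = FALSE]
  a <- pmin(pp_raw$source, pp_raw$target)
  b <- pmax(pp_raw$source, pp_raw$target)
  pp <- data.frame(pathway_a = a, pathway_b = b,
                   jc = pp_raw$jc, oc = pp_raw$oc, weight = pp_raw$weight,
                   n_shared = rep(NA_integer_, nrow(pp_raw)),
                   stringsAsFactors = FALSE)
  pp <- pp[order(pp$pathway_a, pp$pathway_b), , drop = FALSE]
  rownames(pp) <- NULL
  pp$shared_genes <- rep(list(NULL), nrow(pp))
  pg <- data.frame(pathway_id = pg_raw$source,
                   gene_id = as.integer(pg_raw$target),
                   stringsAsFactors = FALSE)
  pg <- pg[order(pg$pathway_id, pg$gene_id), , drop = FALSE]
  rownames(pg) <- NULL
  gene_nodes <- sort(as.integer(nodes$node[!is_pathway]))
  cls <- stats::setNames(
    nodes$node_class[!is_pathway][order(as.integer(nodes$node[!is_pathway]))],
    gene_nodes
  )
  structure(
    list(pathway_nodes = sort(nodes$node[is_pathway]),
         gene_nodes = gene_nodes,
         pp_edges = structure(pp, class = c("crosstalk_edges", "data.frame")),
         pg_edges = pg, gene_class = cls),
    class = "tripartite_network"
  )
}
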