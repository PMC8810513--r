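#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions for a fully synthetic comorbidity dataset:
#' a background interactome, two partially overlapping disease gene sets,
#' planted candidate genes wired to shared genes, and a pathway collection
#' with planted enriched pathways. Defaults describe a 5,000-gene universe
#' with two diseases of 100 genes sharing 30, 20 planted candidates each
#' wired to 8 shared genes, and 4 planted pathways per disease drawing 80%
#' of their members from the disease set.
#'
#' @param seed integer seed; the single source of randomness.
#' @param n_genes size of the gene universe (IDs `1..n_genes`).
#' @param edge_model background graph model, `"erdos_renyi"` (fixed edge
#'   count) or `"preferential_attachment"`.
#' @param edge_param for `erdos_renyi`, the number of background edges; for
#'   `preferential_attachment`, the number of edges added per node.
#' @param n_a,n_b sizes of the two disease gene sets.
#' @param n_shared number of genes shared by both diseases
#'   (`<= min(n_a, n_b)`).
#' @param n_candidates number of planted candidate genes.
#' @param candidate_wiring number of distinct shared-gene neighbors wired to
#'   each planted candidate (`<= n_shared`).
#' @param n_pathways total number of pathways in the collection.
#' @param pathway_size_range integer `(min, max)` pathway sizes.
#' @param n_enriched_per_disease planted enriched pathways per disease.
#' @param enrichment_fraction fraction of a planted pathway's members drawn
#'   from its disease gene set, in `(0, 1]`.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 5000L,
                             edge_model = c("erdos_renyi", "preferential_attachment"),
                             edge_param = 15000L,
                             n_a = 100L, n_b = 100L, n_shared = 30L,
                             n_candidates = 20L, candidate_wiring = 8L,
                             n_pathways = 50L,
                             pathway_size_range = c(10L, 60L),
                             n_enriched_per_disease = 4L,
                             enrichment_fraction = 0.8) {
  edge_model <- match.arg(edge_model)
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    edge_model = edge_model, edge_param = as.integer(edge_param),
    n_a = as.integer(n_a), n_b = as.integer(n_b), n_shared = as.integer(n_shared),
    n_candidates = as.integer(n_candidates),
    candidate_wiring = as.integer(candidate_wiring),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_enriched_per_disease = as.integer(n_enriched_per_disease),
    enrichment_fraction = as.numeric(enrichment_fraction)
  )
  with(cfg, {
    if (n_shared > min(n_a, n_b)) {
      cn_stop("infeasible_config", "n_shared must not exceed min(n_a, n_b)")
    }
    if (candidate_wiring > n_shared) {
      cn_stop("infeasible_config", "candidate_wiring must not exceed n_shared")
    }
    if (any(c(n_a, n_b, n_candidates, n_pathways) > n_genes) ||
        max(pathway_size_range) > n_genes) {
      cn_stop("infeasible_config", "component sizes must not exceed n_genes")
    }
    if (n_a + n_b - n_shared + n_candidates > n_genes) {
      cn_stop("infeasible_config",
              "disease sets and candidates cannot be disjointly placed in the universe")
    }
    if (length(pathway_size_range) != 2L ||
        pathway_size_range[1L] > pathway_size_range[2L] ||
        pathway_size_range[1L] < 1L) {
      cn_stop("infeasible_config", "pathway_size_range must be an increasing pair >= 1")
    }
    if (enrichment_fraction <= 0 || enrichment_fraction > 1) {
      cn_stop("infeasible_config", "enrichment_fraction must lie in (0, 1]")
    }
    if (2L * n_enriched_per_disease > n_pathways) {
      cn_stop("infeasible_config", "more planted pathways than pathways")
    }
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic comorbidity dataset
#'
#' Builds, from a single seed: (1) a background interactome under the
#' configured random-graph model; (2) two disease gene sets sampled without
#' replacement, with the shared subset drawn first so the overlap is exactly
#' `n_shared`; (3) planted candidate genes outside both disease sets, whose
#' background edges to disease genes are removed and which are then wired to
#' exactly `candidate_wiring` sampled shared genes — so noise-free recovery
#' of the planted set is guaranteed by construction; (4) a pathway
#' collection over the full universe in which the first
#' `n_enriched_per_disease` pathways per disease draw
#' `ceiling(enrichment_fraction * size)` members from that disease's gene
#' set. Truth labels for candidates and enriched pathways are returned.
#'
#' @param config a [synthetic_config].
#' @return An object of class `synthetic_dataset`: a list with
#'   `interactome`, `genes_a`, `genes_b`, `collection`, `truth` (list of
#'   `planted_candidates`, `planted_enriched_a`, `planted_enriched_b`), and
#'   the `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    n <- config$n_genes
    universe <- seq_len(n)

    # --- background graph ---
    g <- if (config$edge_model == "erdos_renyi") {
      igraph::sample_gnm(n, min(config$edge_param, n * (n - 1) / 2))
    } else {
      igraph::sample_pa(n, m = config$edge_param, directed = FALSE)
    }
    el <- igraph::as_edgelist(g, names = FALSE)

    # --- disease sets: shared subset first, then disjoint specifics ---
    shared <- sort(resample(universe, config$n_shared))
    rest <- setdiff(universe, shared)
    a_only <- sort(resample(rest, config$n_a - config$n_shared))
    rest <- setdiff(rest, a_only)
    b_only <- sort(resample(rest, config$n_b - config$n_shared))
    rest <- setdiff(rest, b_only)
    genes_a_ids <- sort(c(shared, a_only))
    genes_b_ids <- sort(c(shared, b_only))
    disease_all <- union(genes_a_ids, genes_b_ids)

    # --- planted candidates ---
    candidates <- sort(resample(rest, config$n_candidates))
    # strip background edges between candidates and any disease gene, so a
    # candidate's shared-neighbor count is exactly its wiring
    drop <- (el[, 1L] %in% candidates & el[, 2L] %in% disease_all) |
      (el[, 2L] %in% candidates & el[, 1L] %in% disease_all)
    el <- el[!drop, , drop = FALSE]
    wires <- lapply(candidates, function(cand) {
      cbind(rep(cand, config$candidate_wiring),
            resample(shared, config$candidate_wiring))
    })
    el <- rbind(el, do.call(rbind, wires))
    net <- interactome(el[, 1L], el[, 2L])

    # --- pathway collection with planted enrichment ---
    sizes <- resample(seq(config$pathway_size_range[1L],
                        config$pathway_size_range[2L]),
                    config$n_pathways, replace = TRUE)
    ne <- config$n_enriched_per_disease
    ids <- sprintf("PW%03d", seq_len(config$n_pathways))
    members <- vector("list", config$n_pathways)
    for (i in seq_len(config$n_pathways)) {
      s <- sizes[[i]]
      if (i <= 2L * ne) {
        dset <- if (i <= ne) genes_a_ids else genes_b_ids
        n_in <- min(ceiling(config$enrichment_fraction * s), length(dset))
        members[[i]] <- c(resample(dset, n_in),
                          resample(setdiff(universe, dset), s - n_in))
      } else {
        members[[i]] <- resample(universe, s)
      }
    }
    collection <- pathway_collection(ids, paste("synthetic pathway", ids),
                                     members, background = universe)

    structure(
      list(
        interactome = net,
        genes_a = gene_set(genes_a_ids,
                           sources = rep("synthetic", length(genes_a_ids)),
                           disease = "A"),
        genes_b = gene_set(genes_b_ids,
                           sources = rep("synthetic", length(genes_b_ids)),
                           disease = "B"),
        collection = collection,
        truth = list(
          planted_candidates = candidates,
          planted_enriched_a = ids[seq_len(ne)],
          planted_enriched_b = if (ne > 0L) ids[ne + seq_len(ne)] else character(0)
        ),
        config = config
      ),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d-gene universe; %d edges; |A|=%d, |B|=%d, shared=%d; %d planted candidates; %d pathways\n",
    x$config$n_genes, n_edges(x$interactome), nrow(x$genes_a), nrow(x$genes_b),
    x$config$n_shared, length(x$truth$planted_candidates),
    length(x$collection$ids)
  ))
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `genes_a.tsv`, `genes_b.tsv`, `pathways.gmt`, `ppin.tsv` and
#' `truth.json` into `dir`, byte-identical across runs for the same dataset.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes_a = file.path(dir, "genes_a.tsv"),
    genes_b = file.path(dir, "genes_b.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    ppin = file.path(dir, "ppin.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_gene_list(ds$genes_a, paths[["genes_a"]])
  write_gene_list(ds$genes_b, paths[["genes_b"]])
  write_gmt(ds$collection, paths[["gmt"]])
  write_edge_list(ds$interactome, paths[["ppin"]])
  jsonlite::write_json(ds$truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read back truth labels written by [write_synthetic_dataset()]
#' @param path path to `truth.json`.
#' @return A list with `planted_candidates`, `planted_enriched_a`,
#'   `planted_enriched_b`.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    planted_candidates = as.integer(raw$planted_candidates),
    planted_enriched_a = as.character(raw$planted_enriched_a),
    planted_enriched_b = as.character(raw$planted_enriched_b)
  )
}

#' Randomly rewire a fraction of interactome edges
#'
#' Replaces approximately `rate * n_edges` randomly chosen edges with random
#' non-self, non-duplicate pairs over the same node set. The edge count is
#' conserved; the degree sequence is not. Used as the noise model for
#' robustness studies of candidate recovery.
#'
#' @param net an [interactome].
#' @param rate fraction of edges to rewire, in `[0, 1]`.
#' @param seed integer seed for the rewiring stream.
#' @return An [interactome] with the same number of edges.
#' @export
rewire_network <- function(net, rate, seed = 1L) {
  stopifnot(inherits(net, "interactome"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    cn_stop("bad_rate", "rewiring rate must lie in [0, 1]")
  }
  m <- n_edges(net)
  n_rewire <- round(rate * m)
  if (n_rewire == 0L) return(net)
  with_local_seed(seed, {
    nodes <- net$nodes
    drop_idx <- sample(m, n_rewire)
    kept <- net$edges[-drop_idx, , drop = FALSE]
    keys <- paste(kept[, 1L], kept[, 2L])
    new_a <- integer(0); new_b <- integer(0)
    needed <- n_rewire
    while (needed > 0L) {
      ca <- resample(nodes, needed, replace = TRUE)
      cb <- resample(nodes, needed, replace = TRUE)
      lo <- pmin(ca, cb); hi <- pmax(ca, cb)
      k <- paste(lo, hi)
      ok <- lo != hi & !k %in% keys & !duplicated(k)
      new_a <- c(new_a, lo[ok]); new_b <- c(new_b, hi[ok])
      keys <- c(keys, k[ok])
      needed <- n_rewire - length(new_a)
    }
    interactome(c(kept[, 1L], new_a), c(kept[, 2L], new_b))
  })
}
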