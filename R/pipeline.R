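#' Pipeline configuration
#'
#' Bundles all input paths and thresholds of the comorbidity analysis.
#' Defaults: association-score cutoff 0.2 (strict), FDR threshold 0.05,
#' cross-talk thresholds of 3 disease genes per pathway and 2 shared genes
#' per pair, candidate call at 6 or more shared-gene neighbors, and the
#' ubiquitin exclusion list.
#'
#' @param genes_a,genes_b paths to the two disease gene-list TSVs.
#' @param gmt path to the pathway collection (GMT).
#' @param ppin path to the interactome edge list (TSV).
#' @param out_dir output directory.
#' @param label_a,label_b disease labels.
#' @param gda_threshold association-score cutoff in `[0, 1]`.
#' @param alpha FDR significance threshold in `(0, 1)`.
#' @param min_genes,min_shared pathway cross-talk thresholds (each `>= 1`).
#' @param min_count candidate-call threshold (`>= 1`).
#' @param exclude gene IDs removed from the interactome.
#' @param extraction_rule disease-subnetwork rule, `"edge_incident"` or
#'   `"induced"`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes_a, genes_b, gmt, ppin, out_dir,
                            label_a = "A", label_b = "B",
                            gda_threshold = 0.2, alpha = 0.05,
                            min_genes = 3L, min_shared = 2L, min_count = 6L,
                            exclude = ubiquitin_exclusion(),
                            extraction_rule = c("edge_incident", "induced")) {
  extraction_rule <- match.arg(extraction_rule)
  for (nm in c("genes_a", "genes_b", "gmt", "ppin")) {
    p <- get(nm)
    if (!is.character(p) || length(p) != 1L || !nzchar(p)) {
      cn_stop("config_error", "input path '%s' is missing or empty", nm)
    }
    if (!file.exists(p)) {
      cn_stop("config_error", "input file for '%s' does not exist: %s", nm, p)
    }
  }
  if (gda_threshold < 0 || gda_threshold > 1) {
    cn_stop("config_error", "gda_threshold must lie in [0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) cn_stop("config_error", "alpha must lie in (0, 1)")
  if (min_genes < 1L || min_shared < 1L || min_count < 1L) {
    cn_stop("config_error", "min_genes, min_shared and min_count must all be >= 1")
  }
  structure(
    list(genes_a = genes_a, genes_b = genes_b, gmt = gmt, ppin = ppin,
         out_dir = out_dir, label_a = label_a, label_b = label_b,
         gda_threshold = as.numeric(gda_threshold), alpha = as.numeric(alpha),
         min_genes = as.integer(min_genes), min_shared = as.integer(min_shared),
         min_count = as.integer(min_count),
         exclude = as.integer(exclude), extraction_rule = extraction_rule),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) cn_stop("config_error", "no such config file: %s", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  args <- list(
    genes_a = resolve(raw$genes_a), genes_b = resolve(raw$genes_b),
    gmt = resolve(raw$gmt), ppin = resolve(raw$ppin),
    out_dir = if (is.null(raw$out_dir)) file.path(base, "results") else resolve(raw$out_dir)
  )
  for (nm in c("label_a", "label_b", "gda_threshold", "alpha", "min_genes",
               "min_shared", "min_count", "exclude", "extraction_rule")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  missing <- names(Filter(is.null, args[c("genes_a", "genes_b", "gmt", "ppin")]))
  if (length(missing)) {
    cn_stop("config_error", "config is missing required key(s): %s",
            paste(missing, collapse = ", "))
  }
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cn_stop("stage_error", "stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full comorbidity analysis pipeline
#'
#' Orchestrates all stages: gene-list reading and score policy, shared-gene
#' intersection, per-disease over-representation analysis and pathway
#' classification, cross-talk networks for shared and disease-specific
#' pathways, interactome cleaning, disease-subnetwork extraction, union and
#' overlap, guilt-by-association candidate ranking, and the candidate
#' neighborhood subnetwork. All tables, networks (TSV/GraphML/SIF) and a
#' machine-readable `summary.json` of stage counts are written to
#' `config$out_dir`; outputs are deterministic for identical inputs.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with the intermediate objects and the `summary`
#'   list of stage counts.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  # --- gene sets ---
  res <- run_stage("genesets", {
    ga <- apply_gda_policy(read_gene_list(config$genes_a, config$label_a),
                           config$gda_threshold)
    gb <- apply_gda_policy(read_gene_list(config$genes_b, config$label_b),
                           config$gda_threshold)
    shared <- intersect_gene_sets(ga, gb)
    write_gene_list(shared, out("shared_genes.tsv"))
    list(ga = ga, gb = gb, shared = shared)
  })
  ga <- res$ga; gb <- res$gb; shared <- res$shared

  # --- enrichment ---
  enr <- run_stage("enrichment", {
    collection <- read_gmt(config$gmt)
    ea <- run_enrichment(ga, collection, alpha = config$alpha)
    eb <- run_enrichment(gb, collection, alpha = config$alpha)
    cls <- classify_pathways(ea, eb, alpha = config$alpha)
    write_tsv(as.data.frame(ea), out(sprintf("enrichment_%s.tsv", config$label_a)))
    write_tsv(as.data.frame(eb), out(sprintf("enrichment_%s.tsv", config$label_b)))
    write_tsv(
      data.frame(
        pathway_id = c(cls$shared, cls$a_specific, cls$b_specific),
        class = c(rep("shared", length(cls$shared)),
                  rep(paste0(config$label_a, "_specific"), length(cls$a_specific)),
                  rep(paste0(config$label_b, "_specific"), length(cls$b_specific)))
      ),
      out("pathway_classification.tsv")
    )
    list(collection = collection, ea = ea, eb = eb, cls = cls)
  })

  # --- cross-talk ---
  ct <- run_stage("crosstalk", {
    disease_genes <- merge_gene_sets(ga, gb, disease_label = "both")
    gene_class <- stats::setNames(
      ifelse(disease_genes$gene_id %in% shared$gene_id, "shared",
             ifelse(disease_genes$gene_id %in% ga$gene_id, config$label_a,
                    config$label_b)),
      disease_genes$gene_id
    )
    shared_net <- specific_net <- NULL
    if (length(enr$cls$shared) > 0L) {
      mem_shared <- restrict_memberships(enr$collection, disease_genes,
                                         pathway_ids = enr$cls$shared)
      edges_shared <- build_crosstalk_network(mem_shared, config$min_genes,
                                              config$min_shared)
      shared_net <- build_tripartite(edges_shared, mem_shared, shared,
                                     gene_class = gene_class)
      write_tsv(tripartite_edge_table(shared_net), out("crosstalk_shared_edges.tsv"))
      export_network(shared_net, out("crosstalk_shared.graphml"), "graphml")
      export_network(shared_net, out("crosstalk_shared.sif"), "sif")
    }
    specific_ids <- c(enr$cls$a_specific, enr$cls$b_specific)
    if (length(specific_ids) > 0L) {
      mem_spec <- restrict_memberships(enr$collection, disease_genes,
                                       pathway_ids = specific_ids)
      edges_spec <- build_crosstalk_network(mem_spec, config$min_genes,
                                            config$min_shared)
      specific_net <- build_tripartite(edges_spec, mem_spec, disease_genes,
                                       gene_class = gene_class)
      write_tsv(tripartite_edge_table(specific_net), out("crosstalk_specific_edges.tsv"))
      export_network(specific_net, out("crosstalk_specific.graphml"), "graphml")
    }
    list(shared_net = shared_net, specific_net = specific_net)
  })

  # --- interactome and candidates ---
  ppin <- run_stage("network", {
    raw <- read_edge_list(config$ppin)
    net <- merge_interactomes(raw, exclude = config$exclude)
    net_a <- extract_disease_network(net, ga, rule = config$extraction_rule)
    net_b <- extract_disease_network(net, gb, rule = config$extraction_rule)
    disease_union <- union_networks(net_a, net_b)
    overlap <- intersect_networks(net_a, net_b)
    counts <- shared_gene_neighbor_count(overlap, shared)
    known <- merge_gene_sets(ga, gb, disease_label = "both")
    ranking <- predict_candidates(counts, known, min_count = config$min_count)
    write_tsv(as.data.frame(ranking), out("candidate_ranking.tsv"))
    write_edge_list(overlap, out("overlap_network.tsv"))
    export_gene_network(overlap, out("overlap_network.graphml"), "graphml")
    cands <- novel_candidates(ranking)
    neighborhood <- NULL
    if (length(cands) > 0L) {
      neighborhood <- extract_candidate_neighborhood(disease_union, cands, ga, gb)
      export_gene_network(neighborhood, out("candidate_neighborhood.graphml"),
                          "graphml")
    }
    list(net = net, net_a = net_a, net_b = net_b, disease_union = disease_union,
         overlap = overlap, counts = counts, ranking = ranking,
         neighborhood = neighborhood)
  })

  # --- summary ---
  first_neighbors <- with(ppin, {
    non_disease <- setdiff(overlap$nodes,
                           union(ga$gene_id, gb$gene_id))
    sum(counts[as.character(non_disease)] >= 1L)
  })
  summary <- list(
    genes = list(
      n_a = nrow(ga), n_b = nrow(gb), n_shared = nrow(shared),
      n_union = nrow(ga) + nrow(gb) - nrow(shared)
    ),
    enrichment = list(
      n_pathways = length(enr$collection$ids),
      n_significant_a = sum(enr$ea$significant),
      n_significant_b = sum(enr$eb$significant),
      n_shared_pathways = length(enr$cls$shared),
      n_a_specific = length(enr$cls$a_specific),
      n_b_specific = length(enr$cls$b_specific)
    ),
    crosstalk = list(
      shared_pathway_nodes = if (is.null(ct$shared_net)) 0L else length(ct$shared_net$pathway_nodes),
      shared_gene_nodes = if (is.null(ct$shared_net)) 0L else length(ct$shared_net$gene_nodes),
      shared_pp_edges = if (is.null(ct$shared_net)) 0L else nrow(ct$shared_net$pp_edges),
      shared_pg_edges = if (is.null(ct$shared_net)) 0L else nrow(ct$shared_net$pg_edges),
      specific_pathway_nodes = if (is.null(ct$specific_net)) 0L else length(ct$specific_net$pathway_nodes),
      specific_pp_edges = if (is.null(ct$specific_net)) 0L else nrow(ct$specific_net$pp_edges),
      specific_pg_edges = if (is.null(ct$specific_net)) 0L else nrow(ct$specific_net$pg_edges)
    ),
    network = list(
      interactome_nodes = n_nodes(ppin$net), interactome_edges = n_edges(ppin$net),
      a_nodes = n_nodes(ppin$net_a$network), a_edges = n_edges(ppin$net_a$network),
      b_nodes = n_nodes(ppin$net_b$network), b_edges = n_edges(ppin$net_b$network),
      union_nodes = n_nodes(ppin$disease_union), union_edges = n_edges(ppin$disease_union),
      overlap_nodes = n_nodes(ppin$overlap), overlap_edges = n_edges(ppin$overlap),
      n_first_neighbors = as.integer(first_neighbors),
      n_novel_candidates = length(novel_candidates(ppin$ranking))
    )
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    genes_a = ga, genes_b = gb, shared = shared,
    enrichment_a = enr$ea, enrichment_b = enr$eb, classification = enr$cls,
    crosstalk_shared = ct$shared_net, crosstalk_specific = ct$specific_net,
    interactome = ppin$net, network_a = ppin$net_a, network_b = ppin$net_b,
    disease_union = ppin$disease_union, overlap = ppin$overlap,
    counts = ppin$counts, ranking = ppin$ranking,
    neighborhood = ppin$neighborhood, summary = summary
  ))
}
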