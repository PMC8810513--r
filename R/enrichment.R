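#' Construct a pathway collection
#'
#' Named gene sets in the sense of the GMT format, used both for
#' over-representation analysis and for pathway cross-talk. The background
#' gene universe defaults to the union of all pathway members; a larger
#' explicit universe may be supplied.
#'
#' @param ids character vector of unique pathway identifiers.
#' @param names character vector of human-readable pathway names.
#' @param members list of integer vectors of member gene IDs (each pathway
#'   must have at least one member).
#' @param background optional integer vector of background gene IDs; must
#'   contain every pathway member.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(ids, names = ids, members, background = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    cn_stop("duplicate_pathway_id", "pathway identifiers must be unique")
  }
  stopifnot(length(ids) == length(members), length(names) == length(ids))
  members <- lapply(members, function(m) sort(unique(as_gene_id(m, "pathway member"))))
  if (any(lengths(members) == 0L)) {
    cn_stop("empty_pathway", "every pathway must have at least one member")
  }
  all_members <- sort(unique(unlist(members, use.names = FALSE)))
  background <- if (is.null(background)) all_members else sort(unique(as_gene_id(background, "background gene")))
  if (!all(all_members %in% background)) {
    cn_stop("member_outside_background", "pathway members must be a subset of the background")
  }
  structure(
    list(ids = ids, names = as.character(names),
         members = stats::setNames(members, ids), background = background),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, background of %d genes\n",
              length(x$ids), length(x$background)))
  invisible(x)
}

#' Read a GMT pathway file
#'
#' Standard (Broad dialect) GMT: one pathway per line, tab-separated fields
#' `name`, `description`, then one or more member gene IDs. Duplicate
#' members within a line are collapsed. The background defaults to the union
#' of all members.
#'
#' @param path path to the GMT file.
#' @param background optional explicit background gene universe.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    cn_stop("unreadable_file", "cannot read GMT file: %s", as.character(path)[1])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) cn_stop("empty_gmt", "GMT file %s has no records", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (length(f) < 3L || length(members) == 0L) {
      cn_stop("bad_gmt_line", "GMT line %d has fewer than 3 non-empty fields", i)
    }
    fields[[i]] <- list(id = f[[1L]], name = f[[2L]], members = members)
  }
  pathway_collection(
    ids = vapply(fields, `[[`, character(1), "id"),
    names = vapply(fields, function(f) if (nzchar(f$name)) f$name else f$id, character(1)),
    members = lapply(fields, `[[`, "members"),
    background = background
  )
}

#' Write a pathway collection to GMT
#' @param x a [pathway_collection].
#' @param path destination file.
#' @return The path, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "pathway_collection"))
  lines <- vapply(seq_along(x$ids), function(i) {
    paste(c(x$ids[[i]], x$names[[i]], x$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value for gene-set overlap
#'
#' The probability of observing `k` or more query genes inside a pathway of
#' size `K`, when `n` query genes are drawn without replacement from a
#' background of `N` genes: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' This is the classical one-sided over-representation statistic. Returns 1
#' when `k = 0`. All arguments are vectorised.
#'
#' @param k observed overlap count(s).
#' @param K pathway size(s).
#' @param n query size(s), restricted to the background.
#' @param N background size(s).
#' @return Numeric vector of upper-tail probabilities in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_pvalue(2, K = 4, n = 3, N = 10)  # 1/3
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 1 | k > pmin(K, n) | K > N | n > N)) {
    cn_stop("bad_hypergeom_bounds",
            "require 0 <= k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate, returned in the
#' original input order. Thin wrapper over [stats::p.adjust()] with input
#' validation: raw p-values must lie in `(0, 1]`.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return Numeric vector of BH-adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    cn_stop("bad_pvalue", "all p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a gene set against a pathway collection
#'
#' For each pathway, counts the overlap between the query gene set
#' (restricted to the collection's background) and the pathway members,
#' computes the upper-tail hypergeometric p-value, and adjusts across the
#' whole collection with Benjamini-Hochberg. A pathway is significant when
#' its FDR is strictly below `alpha`.
#'
#' @param query a [gene_set] or integer vector of gene IDs.
#' @param collection a [pathway_collection].
#' @param alpha FDR significance threshold in `(0, 1)` (default `0.05`).
#' @return A data frame of class `enrichment_result` with one row per
#'   pathway, columns `pathway_id`, `name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fdr`, `significant`, sorted by `fdr` then `pathway_id`.
#' @export
run_enrichment <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    cn_stop("bad_alpha", "alpha must be a single value in (0, 1)")
  }
  q <- if (inherits(query, "gene_set")) query$gene_id else as_gene_id(query, "query gene")
  q <- intersect(unique(q), collection$background)
  if (length(q) == 0L) {
    cn_stop("empty_query",
            "no query genes remain after restriction to the background universe")
  }
  N <- length(collection$background)
  n <- length(q)
  K <- lengths(collection$members)
  k <- vapply(collection$members, function(m) length(intersect(q, m)), integer(1),
              USE.NAMES = FALSE)
  p <- hypergeom_pvalue(k, K, n, N)
  fdr <- bh_adjust(p)
  out <- data.frame(
    pathway_id = collection$ids, name = collection$names,
    k = k, K = as.integer(K), n = n, N = N,
    p_value = p, fdr = fdr, significant = fdr < alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fdr, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"), alpha = alpha)
}

#' Significant pathway identifiers of an enrichment result
#' @param x an `enrichment_result`.
#' @return Character vector of significant pathway IDs.
#' @export
significant_pathways <- function(x) {
  stopifnot(inherits(x, "enrichment_result"))
  x$pathway_id[x$significant]
}

#' Classify pathways as shared or disease-specific
#'
#' Given enrichment results for two diseases computed against the same
#' pathway collection, partitions the significant pathways into those
#' significant in both diseases (shared) and those significant in exactly
#' one. The three sets are pairwise disjoint and satisfy
#' `|significant(A)| = |shared| + |a_specific|`.
#'
#' @param results_a,results_b `enrichment_result` objects from
#'   [run_enrichment()] over the same collection.
#' @param alpha FDR threshold used to call significance (default `0.05`).
#' @return A list of class `pathway_classification` with character-vector
#'   elements `shared`, `a_specific`, `b_specific`.
#' @export
classify_pathways <- function(results_a, results_b, alpha = 0.05) {
  stopifnot(inherits(results_a, "enrichment_result"),
            inherits(results_b, "enrichment_result"))
  if (!identical(sort(results_a$pathway_id), sort(results_b$pathway_id))) {
    cn_stop("mismatched_collections",
            "the two enrichment results cover different pathway collections")
  }
  sig_a <- results_a$pathway_id[results_a$fdr < alpha]
  sig_b <- results_b$pathway_id[results_b$fdr < alpha]
  structure(
    list(
      shared = sort(intersect(sig_a, sig_b)),
      a_specific = sort(setdiff(sig_a, sig_b)),
      b_specific = sort(setdiff(sig_b, sig_a))
    ),
    class = "pathway_classification"
  )
}

#' @export
print.pathway_classification <- function(x, ...) {
  cat(sprintf("<pathway_classification> shared=%d, a_specific=%d, b_specific=%d\n",
              length(x$shared), length(x$a_specific), length(x$b_specific)))
  invisible(x)
}
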