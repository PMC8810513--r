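#' Construct a disease gene set
#'
#' A `gene_set` is the package's container for a disease-labelled list of
#' unique gene records keyed by Entrez ID. Symbols and provenance tags are
#' metadata; all set algebra is performed on the integer IDs. Records are
#' always stored sorted by ascending `gene_id` so that written files diff
#' stably.
#'
#' @param gene_id integer vector of positive Entrez gene identifiers.
#' @param symbol optional character vector of gene symbols (`NA` allowed).
#' @param sources optional character vector of comma-joined provenance tags
#'   (e.g. `"literature,disgenet"`); normalised to sorted unique tags.
#' @param gda_score optional numeric vector of gene-disease association
#'   scores in `[0, 1]`; `NA` marks records without a score (typical for
#'   literature-curated genes).
#' @param disease single string labelling the disease the set belongs to.
#'
#' @return An object of class `gene_set`: a data frame with columns
#'   `gene_id`, `symbol`, `sources`, `gda_score` and attribute `disease`.
#' @export
#' @examples
#' gs <- gene_set(c(348L, 627L), symbol = c("APOE", "BDNF"), disease = "AD")
#' nrow(gs)
gene_set <- function(gene_id, symbol = NULL, sources = NULL, gda_score = NULL,
                     disease = NA_character_) {
  gene_id <- as_gene_id(gene_id)
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) {
    cn_stop("duplicate_gene_id", "gene_id values must be unique within a gene_set")
  }
  symbol <- if (is.null(symbol)) rep(NA_character_, n) else as.character(symbol)
  sources <- if (is.null(sources)) rep("", n) else normalize_sources(as.character(sources))
  gda_score <- if (is.null(gda_score)) rep(NA_real_, n) else as.numeric(gda_score)
  stopifnot(length(symbol) == n, length(sources) == n, length(gda_score) == n)
  if (any(!is.na(gda_score) & (gda_score < 0 | gda_score > 1))) {
    cn_stop("bad_gda_score", "gda_score values must lie in [0, 1]")
  }
  if (any(!is.na(symbol) & !nzchar(symbol))) {
    cn_stop("bad_symbol", "symbol, when provided, must be non-empty")
  }
  ord <- order(gene_id)
  out <- data.frame(
    gene_id = gene_id[ord], symbol = symbol[ord], sources = sources[ord],
    gda_score = gda_score[ord], stringsAsFactors = FALSE
  )
  structure(out, class = c("gene_set", "data.frame"), disease = disease)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> disease=%s, %d genes\n", attr(x, "disease"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Disease label of a gene set
#' @param x a `gene_set`.
#' @return The disease label string.
#' @export
disease_label <- function(x) attr(x, "disease")

#' Read a disease gene list from a TSV file
#'
#' Expects a tab-delimited file with a header row naming at least a gene-ID
#' column (`gene_id`, or the first column as a fallback when no recognised
#' name is present). Optional columns `symbol`, `sources` (comma-joined) and
#' `gda_score` are used when present. Duplicate rows for the same gene are
#' collapsed: provenance tags are unioned and the maximum GDA score is kept.
#'
#' @param path path to the TSV file.
#' @param disease_label disease label attached to the returned set.
#' @return A [gene_set].
#' @export
read_gene_list <- function(path, disease_label) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    cn_stop("unreadable_file", "cannot read gene list file: %s", as.character(path)[1])
  }
  df <- tryCatch(read_tsv(path), error = function(e) {
    cn_stop("unreadable_file", "failed to parse %s: %s", path, conditionMessage(e))
  })
  if (nrow(df) == 0L) {
    cn_stop("empty_gene_list", "gene list %s contains no records after the header", path)
  }
  cols <- tolower(names(df))
  id_col <- match(TRUE, cols %in% c("gene_id", "geneid", "entrez", "entrez_id", "id"))
  if (is.na(id_col)) id_col <- 1L
  ids <- as_gene_id(df[[id_col]], what = sprintf("gene ID (column '%s')", names(df)[id_col]))
  pick <- function(nm) if (any(cols == nm)) df[[match(nm, cols)]] else NULL
  symbol <- pick("symbol")
  sources <- pick("sources")
  if (is.null(sources)) sources <- pick("source")
  score <- pick("gda_score")
  if (is.null(score)) score <- pick("score")
  score <- if (is.null(score)) rep(NA_real_, nrow(df)) else suppressWarnings(as.numeric(score))

  # Collapse duplicate gene rows: union sources, keep the maximum score.
  ids_u <- unique(ids)
  groups <- split(seq_along(ids), factor(match(ids, ids_u), levels = seq_along(ids_u)))
  gene_set(
    gene_id = ids_u,
    symbol = if (is.null(symbol)) NULL else {
      vapply(groups, function(i) {
        s <- as.character(symbol)[i]
        s <- s[!is.na(s) & nzchar(s)]
        if (length(s)) s[[1L]] else NA_character_
      }, character(1), USE.NAMES = FALSE)
    },
    sources = if (is.null(sources)) NULL else {
      vapply(groups, function(i) {
        s <- as.character(sources)[i]
        paste(s[!is.na(s)], collapse = ",")
      }, character(1), USE.NAMES = FALSE)
    },
    gda_score = vapply(groups, function(i) {
      s <- score[i]
      if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
    }, numeric(1), USE.NAMES = FALSE),
    disease = disease_label
  )
}

#' Write a gene set to TSV
#'
#' @param x a [gene_set].
#' @param path destination file.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_set"))
  write_tsv(as.data.frame(x), path)
}

#' Filter gene records by gene-disease association score
#'
#' Keeps exactly the records whose GDA score exceeds `threshold`
#' (strict inequality by default, the DisGeNET "score above 0.2" reading);
#' records without a score are dropped. To instead retain unscored records —
#' appropriate when literature-curated genes carry no score and should pass
#' through on their own merit — use [apply_gda_policy()].
#'
#' @param x a [gene_set].
#' @param threshold score cutoff in `[0, 1]` (default `0.2`).
#' @param strict if `TRUE` (default) keep `score > threshold`, else
#'   `score >= threshold`.
#' @return A [gene_set] with the retained records.
#' @export
filter_by_gda <- function(x, threshold = 0.2, strict = TRUE) {
  stopifnot(inherits(x, "gene_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    cn_stop("bad_threshold", "threshold must be a single value in [0, 1]")
  }
  keep <- if (strict) {
    !is.na(x$gda_score) & x$gda_score > threshold
  } else {
    !is.na(x$gda_score) & x$gda_score >= threshold
  }
  subset_gene_set(x, keep, disease = disease_label(x))
}

#' Apply the two-route inclusion policy for scored and unscored records
#'
#' Disease gene lists are typically assembled from two routes: a curated
#' database route whose records carry association scores, and a literature
#' route whose records do not. This policy keeps a gene if it passes either
#' route: unscored records pass through untouched, scored records must
#' exceed the threshold.
#'
#' @inheritParams filter_by_gda
#' @return A [gene_set].
#' @export
apply_gda_policy <- function(x, threshold = 0.2, strict = TRUE) {
  stopifnot(inherits(x, "gene_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    cn_stop("bad_threshold", "threshold must be a single value in [0, 1]")
  }
  keep <- is.na(x$gda_score) |
    (if (strict) x$gda_score > threshold else x$gda_score >= threshold)
  subset_gene_set(x, keep, disease = disease_label(x))
}

subset_gene_set <- function(x, keep, disease) {
  gene_set(x$gene_id[keep], x$symbol[keep], x$sources[keep], x$gda_score[keep],
           disease = disease)
}

#' Merge two gene sets (union by gene ID)
#'
#' The union of the two sets keyed by `gene_id`. For genes present in both,
#' provenance tags are unioned, the maximum GDA score is retained, and the
#' first non-missing symbol wins. `|merge(a, b)| = |a| + |b| - |a -intersect- b|`.
#'
#' @param a,b [gene_set] objects over the same identifier namespace.
#' @param disease_label label for the merged set (defaults to `a`'s label).
#' @return A [gene_set].
#' @export
merge_gene_sets <- function(a, b, disease_label = attr(a, "disease")) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  ids <- sort(unique(c(a$gene_id, b$gene_id)))
  ia <- match(ids, a$gene_id)
  ib <- match(ids, b$gene_id)
  sym <- ifelse(!is.na(ia) & !is.na(a$symbol[ia]), a$symbol[ia],
                ifelse(!is.na(ib), b$symbol[ib], NA_character_))
  src <- union_sources(
    ifelse(is.na(ia), "", a$sources[ia]),
    ifelse(is.na(ib), "", b$sources[ib])
  )
  sa <- ifelse(is.na(ia), NA_real_, a$gda_score[ia])
  sb <- ifelse(is.na(ib), NA_real_, b$gda_score[ib])
  score <- pmax(sa, sb, na.rm = TRUE)
  score[is.na(sa) & is.na(sb)] <- NA_real_
  gene_set(ids, sym, src, score, disease = disease_label)
}

#' Intersect two gene sets
#'
#' Records whose `gene_id` occurs in both sets, with provenance tags unioned
#' and the output sorted by ascending gene ID.
#'
#' @param a,b [gene_set] objects over the same identifier namespace.
#' @param disease_label label for the intersection (default combines both).
#' @return A [gene_set] of the shared genes.
#' @export
intersect_gene_sets <- function(a, b,
                                disease_label = paste(attr(a, "disease"),
                                                      attr(b, "disease"),
                                                      sep = "&")) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  ids <- sort(intersect(a$gene_id, b$gene_id))
  ia <- match(ids, a$gene_id)
  ib <- match(ids, b$gene_id)
  sym <- ifelse(!is.na(a$symbol[ia]), a$symbol[ia], b$symbol[ib])
  src <- union_sources(a$sources[ia], b$sources[ib])
  score <- pmax(a$gda_score[ia], b$gda_score[ib], na.rm = TRUE)
  score[is.na(a$gda_score[ia]) & is.na(b$gda_score[ib])] <- NA_real_
  gene_set(ids, sym, src, score, disease = disease_label)
}
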