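# Internal helpers shared across modules.

# Signal a classed error so callers (and tests) can distinguish failure modes.
cn_stop <- function(class, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(paste0("comorbidnet_", class), "comorbidnet_error", "error", "condition")
  ))
}

# Evaluate `code` with a temporary RNG state seeded from `seed`; the caller's
# global RNG state is untouched.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cn_stop("bad_seed", "seed must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a vector to positive integer gene IDs, failing loudly on anything
# that is not a whole positive number.
as_gene_id <- function(x, what = "gene ID") {
  if (length(x) == 0L) return(integer(0))
  xi <- suppressWarnings(as.integer(as.character(x)))
  bad <- is.na(xi) | as.character(xi) != trimws(as.character(x)) | xi <= 0L
  if (any(bad)) {
    cn_stop(
      "bad_gene_id", "%s values must be positive integers; offending value(s): %s",
      what, paste(utils::head(unique(as.character(x)[bad]), 5L), collapse = ", ")
    )
  }
  xi
}

# Normalise a comma-joined provenance string: split, trim, drop empties,
# unique, sort, re-join. Keeps file output stable under merging.
normalize_sources <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
    parts <- sort(unique(parts[nzchar(parts)]))
    paste(parts, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

union_sources <- function(a, b) {
  normalize_sources(paste(a, b, sep = ","))
}

# sample() that treats a length-1 vector as a one-element urn rather than 1:x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
}
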