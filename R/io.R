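#' Read and write protein FASTA
#'
#' Thin wrappers over Biostrings that move between files and plain named
#' character vectors, the sequence container used across the package.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write the per-genome gene-order table
#'
#' Columns: genome, contig, gene_id, family_truth, start, end, strand.
#' Coordinates are 0-based half-open.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_gene_table
#' @param tab data.frame as above.
#' @export
write_gene_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hits table (query, target, raw, bits, evalue, intervals) as TSV
#' @param hits data.frame of hits.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / load the synthetic-truth log as JSON
#' @param truth truth-log list (see [simulate_dataset()]).
#' @param path JSON path.
#' @export
write_truth_log <- function(truth, path) {
  if (is.matrix(truth$leaf_counts)) {
    m <- truth$leaf_counts
    df <- data.frame(family = rownames(m),
                     as.data.frame(m, check.names = FALSE),
                     check.names = FALSE)
    rownames(df) <- NULL
    truth$leaf_counts <- df
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth_log
#' @export
read_truth_log <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  lc <- truth$leaf_counts
  if (is.list(lc) && !is.null(lc$family)) {
    fam <- lc$family
    cols <- setdiff(names(lc), c("family", "_row"))
    m <- do.call(cbind, lapply(lc[cols], as.integer))
    dimnames(m) <- list(fam, cols)
    truth$leaf_counts <- m
  }
  truth
}

# Evaluate expr with a private, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
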