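#' Assign family labels to genes by clade membership on a gene tree
#'
#' Each unlabeled gene takes the label of the smallest clade that contains
#' it, has bootstrap support at or above `min_support`, and contains
#' reference genes of a single family. Ascending from the gene, the first
#' supported ancestor that contains any reference decides: a single-family
#' reference set assigns that family, a conflicting (multi-family) set
#' leaves the gene unassigned, since every larger clade contains the same
#' conflict. Unlabeled internal nodes (including the root) are treated as
#' fully supported.
#'
#' @param gene_tree rooted `phylo`; `node.label` holds percent bootstrap
#'   supports (empty/NA labels count as 100).
#' @param references named character vector gene id -> family label.
#' @param min_support minimum percent support for a clade to be used.
#' @return data.frame: gene_id, family (NA when unassigned), evidence
#'   ("clade"), support (support of the deciding clade).
#' @export
assign_by_clade <- function(gene_tree, references, min_support = 70) {
  stopifnot(min_support >= 0, min_support <= 100)
  tips <- gene_tree$tip.label
  missing_refs <- setdiff(names(references), tips)
  if (length(missing_refs))
    stop("reference gene(s) absent from tree: ",
         paste(missing_refs, collapse = ", "))
  nt <- ape::Ntip(gene_tree)
  pm <- parent_map(gene_tree)
  supp <- rep(100, gene_tree$Nnode)
  if (!is.null(gene_tree$node.label)) {
    raw <- suppressWarnings(as.numeric(gene_tree$node.label))
    supp[!is.na(raw)] <- raw[!is.na(raw)]
  }
  # cache: families of references under each internal node
  fam_under <- vector("list", nt + gene_tree$Nnode)
  ref_fams_below <- function(node) {
    if (!is.null(fam_under[[node]])) return(fam_under[[node]])
    dts <- tips[descendant_tips(gene_tree, node)]
    fams <- unique(unname(references[intersect(dts, names(references))]))
    fam_under[[node]] <<- fams
    fams
  }
  out <- list()
  for (g in setdiff(tips, names(references))) {
    node <- match(g, tips)
    family <- NA_character_
    support <- NA_real_
    cur <- pm[node]
    while (!is.na(cur)) {
      s <- supp[cur - nt]
      if (s >= min_support) {
        fams <- ref_fams_below(cur)
        if (length(fams) == 1) { family <- fams; support <- s; break }
        if (length(fams) > 1) break # conflict persists in every superset
      }
      cur <- pm[cur]
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, family = family, evidence = "clade", support = support,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(gene_id = character(0), family = character(0),
                    evidence = character(0), support = numeric(0))
  rownames(res) <- NULL
  res
}
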