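#' Max-gap gene clusters of target families
#'
#' Scans each contig (genes ordered by start) for maximal runs of genes
#' belonging to the target families with at most `max_gap` intervening
#' non-target genes between consecutive members. Strand is ignored unless
#' `same_strand = TRUE`. Runs with fewer than two target genes are not
#' clusters.
#'
#' @param gene_table data.frame as from [assemble_genomes()] /
#'   [read_gene_table()].
#' @param family_map named character vector gene_id -> family label for
#'   the detected pathway genes (others count as intervening).
#' @param max_gap maximum intervening non-target genes (default 3).
#' @param target_families families considered cluster members (default:
#'   all in `family_map`).
#' @param same_strand require all members on one strand.
#' @return data.frame, one row per cluster: genome, contig, members
#'   (comma-joined gene ids), families (ordered, dash-joined), n_members,
#'   max_internal_gap, start, end.
#' @export
find_clusters <- function(gene_table, family_map, max_gap = 3,
                          target_families = NULL, same_strand = FALSE) {
  if (is.null(target_families))
    target_families <- sort(unique(unname(family_map)))
  out <- list()
  for (key in unique(paste(gene_table$genome, gene_table$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- gene_table[gene_table$genome == parts[1] &
                        gene_table$contig == parts[2], , drop = FALSE]
    if (is.unsorted(sub$start)) {
      warning("gene table not sorted by start; sorting")
      sub <- sub[order(sub$start), , drop = FALSE]
    }
    fams <- unname(family_map[sub$gene_id])
    is_target <- !is.na(fams) & fams %in% target_families
    idx <- which(is_target)
    if (length(idx) < 2) next
    # greedy maximal runs under the gap constraint
    runs <- list()
    cur <- idx[1]
    for (i in idx[-1]) {
      gap <- i - cur[length(cur)] - 1L
      strand_ok <- !same_strand ||
        length(unique(sub$strand[c(cur, i)])) == 1
      if (gap <= max_gap && strand_ok) cur <- c(cur, i)
      else { runs[[length(runs) + 1L]] <- cur; cur <- i }
    }
    runs[[length(runs) + 1L]] <- cur
    for (r in runs) {
      if (length(r) < 2) next
      gaps <- diff(r) - 1L
      out[[length(out) + 1L]] <- data.frame(
        genome = parts[1], contig = parts[2],
        members = paste(sub$gene_id[r], collapse = ","),
        families = paste(fams[r], collapse = "-"),
        n_members = length(r),
        max_internal_gap = if (length(gaps)) max(gaps) else 0L,
        start = sub$start[r[1]], end = sub$end[r[length(r)]],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(genome = character(0), contig = character(0),
                    members = character(0), families = character(0),
                    n_members = integer(0), max_internal_gap = integer(0),
                    start = integer(0), end = integer(0))
  rownames(res) <- NULL
  res
}

#' Detect gene fusions from per-family profile hits on each gene
#'
#' A gene matching two distinct families on near-disjoint protein
#' intervals is called fused. Intervals must each reach `min_len` residues
#' and overlap by at most `max_overlap` of the shorter interval. The call
#' is symmetric in the two families; both count as present (with fusion
#' provenance) for the genome.
#'
#' @param gene_hits data.frame: gene_id, family, tstart, tend (0-based
#'   half-open intervals on the gene's protein).
#' @param min_len minimum matched interval length.
#' @param max_overlap maximum allowed overlap fraction (default 0.2).
#' @return data.frame: gene_id, family1, family2, start1, end1, start2,
#'   end2, overlap_frac (families ordered by interval position).
#' @export
detect_fusions <- function(gene_hits, min_len = 50, max_overlap = 0.2) {
  out <- list()
  for (g in unique(gene_hits$gene_id)) {
    h <- gene_hits[gene_hits$gene_id == g, , drop = FALSE]
    # best interval per family
    h <- h[order(h$family, -(h$tend - h$tstart)), , drop = FALSE]
    h <- h[!duplicated(h$family), , drop = FALSE]
    if (nrow(h) < 2) next
    for (i in seq_len(nrow(h) - 1)) for (j in (i + 1):nrow(h)) {
      l1 <- h$tend[i] - h$tstart[i]; l2 <- h$tend[j] - h$tstart[j]
      if (l1 < min_len || l2 < min_len) next
      ov <- max(0, min(h$tend[i], h$tend[j]) - max(h$tstart[i], h$tstart[j]))
      frac <- ov / min(l1, l2)
      if (frac > max_overlap) next
      first <- if (h$tstart[i] <= h$tstart[j]) i else j
      second <- if (first == i) j else i
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g,
        family1 = h$family[first], family2 = h$family[second],
        start1 = h$tstart[first], end1 = h$tend[first],
        start2 = h$tstart[second], end2 = h$tend[second],
        overlap_frac = frac, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(gene_id = character(0), family1 = character(0),
                    family2 = character(0), start1 = numeric(0),
                    end1 = numeric(0), start2 = numeric(0),
                    end2 = numeric(0), overlap_frac = numeric(0))
  rownames(res) <- NULL
  res
}

#' Cluster-composition frequencies localized on the species tree
#'
#' Aggregates clusters by family composition (both the ordered signature
#' and an order-insensitive key) and reports, per composition, how many
#' genomes carry it and the smallest species-tree clade containing them.
#'
#' @param clusters output of [find_clusters()].
#' @param species_tree rooted `phylo` over the genomes.
#' @return data.frame: families (ordered signature), families_unordered,
#'   n_genomes, genomes (comma-joined), clade (node label of the MRCA).
#' @export
cluster_conservation_report <- function(clusters, species_tree) {
  if (!nrow(clusters))
    return(data.frame(families = character(0),
                      families_unordered = character(0),
                      n_genomes = integer(0), genomes = character(0),
                      clade = character(0)))
  labs <- node_labels(species_tree)
  key <- clusters$families
  out <- lapply(unique(key), function(k) {
    gms <- sort(unique(clusters$genome[key == k]))
    in_tree <- intersect(gms, species_tree$tip.label)
    clade <- if (length(in_tree) >= 2)
      labs[ape::getMRCA(species_tree, in_tree)]
    else if (length(in_tree) == 1) in_tree
    else NA_character_
    data.frame(
      families = k,
      families_unordered = paste(sort(strsplit(k, "-")[[1]]), collapse = ","),
      n_genomes = length(gms), genomes = paste(gms, collapse = ","),
      clade = clade, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(-res$n_genomes, res$families), , drop = FALSE]
}
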