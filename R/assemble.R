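#' Assemble per-genome gene orders with planted clusters and fusions
#'
#' Lays the evolved family copies plus random decoy genes onto one contig
#' per genome. Families named in `cluster_spec` are emitted as a contiguous
#' run (one copy each, in the stated order) with at most `gap` planted
#' intervening decoys between consecutive members; everything else follows
#' in shuffled order. With probability `fusion_prob` per genome, the two
#' `fusion_pair` families (both present, and both cluster members when the
#' pair lies inside a cluster) are concatenated into a single gene with a
#' zero-length linker, replacing the two parents.
#'
#' Coordinates are 0-based half-open on the nucleotide scale
#' (`end = start + 3 * length(aa) + 3`), non-overlapping per contig; strand
#' is drawn at random and ignored by downstream clustering.
#'
#' @param evolved result of [evolve_sequences()].
#' @param cluster_specs list of cluster specs, each
#'   `list(families = c(...), gap = 0)` in emission order.
#' @param fusion_pair character(2) family names to fuse, or NULL.
#' @param fusion_prob per-genome fusion probability.
#' @param n_decoys random unrelated genes per genome.
#' @param decoy_len_range length range for decoy proteins.
#' @param seed integer seed.
#' @return list: `gene_table` (genome, contig, gene_id, family_truth, start,
#'   end, strand), `proteomes` (genome -> named protein vector), `truth`
#'   (`clusters` data.frame, `fusions` data.frame).
#' @export
assemble_genomes <- function(evolved, cluster_specs = list(),
                             fusion_pair = NULL, fusion_prob = 0,
                             n_decoys = 15, decoy_len_range = c(200, 400),
                             seed = 1) {
  for (cs in cluster_specs) {
    missing <- setdiff(cs$families, unique(evolved$meta$family))
    if (length(missing))
      stop("cluster_spec names unknown families: ",
           paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    rows <- list(); cl_truth <- list(); fu_truth <- list()
    proteomes <- list()
    for (gm in names(evolved$genomes)) {
      seqs <- evolved$genomes[[gm]]
      fam_of <- setNames(evolved$meta$family, evolved$meta$gene_id)
      fam_of <- fam_of[names(seqs)]
      # decoys
      dl <- sample(decoy_len_range[1]:decoy_len_range[2], n_decoys,
                   replace = TRUE)
      decoys <- setNames(vapply(dl, random_protein, character(1)),
                         sprintf("%s|decoy%02d", gm, seq_len(n_decoys)))
      # fusion
      if (!is.null(fusion_pair) && runif(1) < fusion_prob) {
        i1 <- which(fam_of == fusion_pair[1])[1]
        i2 <- which(fam_of == fusion_pair[2])[1]
        if (!is.na(i1) && !is.na(i2)) {
          fid <- sprintf("%s|%s-%s#fus", gm, fusion_pair[1], fusion_pair[2])
          fseq <- paste0(seqs[[i1]], seqs[[i2]])
          drop <- names(seqs)[c(i1, i2)]
          seqs <- seqs[setdiff(names(seqs), drop)]
          fam_of <- fam_of[names(seqs)]
          seqs[fid] <- fseq
          fam_of[fid] <- paste(fusion_pair, collapse = "+")
          fu_truth[[length(fu_truth) + 1L]] <- data.frame(
            genome = gm, gene_id = fid, family1 = fusion_pair[1],
            family2 = fusion_pair[2], stringsAsFactors = FALSE)
        }
      }
      # order: clusters first (with planted decoy gaps), then the rest
      order_ids <- character(0)
      used <- character(0)
      decoy_pool <- names(decoys)
      ci <- 0L
      for (cs in cluster_specs) {
        ci <- ci + 1L
        members <- character(0)
        for (f in cs$families) {
          cand <- setdiff(names(fam_of)[fam_of == f |
                                          grepl(paste0("(^|[+])", f, "($|[+])"),
                                                fam_of)], used)
          if (length(cand)) members <- c(members, cand[1])
        }
        members <- unique(members)
        if (length(members) >= 2) {
          run <- character(0)
          for (j in seq_along(members)) {
            if (j > 1 && cs$gap > 0 && length(decoy_pool)) {
              ng <- sample(0:min(cs$gap, length(decoy_pool)), 1)
              if (ng > 0) {
                run <- c(run, decoy_pool[seq_len(ng)])
                decoy_pool <- decoy_pool[-seq_len(ng)]
              }
            }
            run <- c(run, members[j])
          }
          order_ids <- c(order_ids, run)
          used <- c(used, members)
          cl_truth[[length(cl_truth) + 1L]] <- data.frame(
            genome = gm, cluster = ci,
            gene_id = members,
            families = paste(cs$families, collapse = "-"),
            stringsAsFactors = FALSE)
        } else if (length(members) == 1) {
          used <- c(used, members) # too short to be a planted cluster
          order_ids <- c(order_ids, members)
        }
      }
      rest <- c(setdiff(names(seqs), used), decoy_pool)
      if (length(rest)) rest <- sample(rest)
      order_ids <- c(order_ids, rest)
      all_seqs <- c(seqs, decoys)
      proteomes[[gm]] <- all_seqs[order_ids]
      # coordinates
      pos <- 0L
      for (gid in order_ids) {
        len_nt <- 3L * nchar(all_seqs[[gid]]) + 3L
        start <- pos + sample(20:200, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          genome = gm, contig = paste0(gm, "_c1"), gene_id = gid,
          family_truth = if (gid %in% names(fam_of)) fam_of[[gid]]
                         else "decoy",
          start = start, end = start + len_nt,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
        pos <- start + len_nt
      }
    }
    gene_table <- do.call(rbind, rows)
    rownames(gene_table) <- NULL
    truth <- list(
      clusters = if (length(cl_truth)) do.call(rbind, cl_truth)
        else data.frame(genome = character(0), cluster = integer(0),
                        gene_id = character(0), families = character(0)),
      fusions = if (length(fu_truth)) do.call(rbind, fu_truth)
        else data.frame(genome = character(0), gene_id = character(0),
                        family1 = character(0), family2 = character(0)))
    list(gene_table = gene_table, proteomes = proteomes, truth = truth)
  })
}
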