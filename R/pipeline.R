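#' Default end-to-end run configuration
#'
#' Defaults mirror the study settings: E-value cutoff 0.01 for both search
#' stages, the constant-database-size convention 320 x 20,000 = 6,400,000
#' for pairwise E-values and the constant trial count 20,000 for profile
#' HMM E-values, 1,000 bootstrap replicates, clade assignment support 70,
#' and max-gap 3 for cluster detection.
#'
#' @param n_taxa genomes to simulate.
#' @param seed master seed.
#' @return config list for [run_pipeline()].
#' @export
run_config <- function(n_taxa = 20, seed = 1) {
  list(
    sim = default_sim_config(n_taxa = n_taxa, seed = seed),
    seed = seed,
    cutoff = 0.01,
    avg_query_len = 320,
    genome_size = 20000,
    hmm_n_trials = 20000,
    bootstrap_reps = 1000,
    min_support = 70,
    max_gap = 3,
    hmm_occupancy = 0.5,
    hmm_calibration_n = 800,
    outgroup = NULL)
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a config file and merges it onto [run_config()] defaults: top-level
#' keys override pipeline settings, keys under `sim` override the
#' simulation spec. Unknown keys are an error so typos cannot silently
#' revert a threshold to its default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return config list as from [run_config()].
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(
    n_taxa = if (!is.null(raw$sim$n_taxa)) raw$sim$n_taxa else 20,
    seed = if (!is.null(raw$seed)) raw$seed else 1)
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in setdiff(names(raw), "sim")) cfg[[k]] <- raw[[k]]
  if (!is.null(raw$sim)) {
    bad <- setdiff(names(raw$sim), names(cfg$sim))
    if (length(bad)) stop("unknown sim keys: ", paste(bad, collapse = ", "))
    for (k in names(raw$sim)) cfg$sim[[k]] <- raw$sim[[k]]
  }
  cfg
}

#' Run the full pipeline: simulate, detect, classify, trees, events, context
#'
#' Every stage writes plain-text artifacts (FASTA/TSV/JSON/Newick) into
#' `out_dir` and the run ends with a manifest recording settings, seeds,
#' per-stage counts and artifact checksums; identical configs reproduce
#' byte-identical artifacts. A stage failure stops the run but leaves the
#' completed stages' artifacts with their status recorded.
#'
#' @param config from [run_config()].
#' @param out_dir output directory (created).
#' @return list: `manifest`, `data` (in-memory stage results).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("lpxrun")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  manifest <- list(package = "lpxevo",
                   version = as.character(utils::packageVersion("lpxevo")),
                   seed = cfg$seed,
                   settings = cfg[setdiff(names(cfg), "sim")],
                   sim = cfg$sim[setdiff(names(cfg$sim), "clusters")],
                   stages = list())
  res <- list()
  status <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # -- stage 1: simulate -----------------------------------------------
  ds <- simulate_dataset(cfg$sim)
  res$dataset <- ds
  ape::write.tree(ds$tree, file.path(out_dir, "species_tree.nwk"))
  write_gene_table(ds$assembly$gene_table,
                   file.path(out_dir, "gene_table.tsv"))
  dir.create(file.path(out_dir, "proteomes"), showWarnings = FALSE)
  for (gm in names(ds$assembly$proteomes))
    write_fasta(ds$assembly$proteomes[[gm]],
                file.path(out_dir, "proteomes", paste0(gm, ".faa")))
  write_truth_log(ds$truth, file.path(out_dir, "truth.json"))
  status("simulate", genomes = length(ds$assembly$proteomes),
         genes = nrow(ds$assembly$gene_table),
         families = length(cfg$sim$families))

  # -- stage 2: pairwise search + RBH ----------------------------------
  scheme <- calibrate_scheme(scoring_scheme(), seed = cfg$seed + 11L)
  scfg <- search_config(cutoff = cfg$cutoff,
                        avg_query_len = cfg$avg_query_len,
                        genome_size = cfg$genome_size)
  proteomes <- ds$assembly$proteomes
  ref_genome <- pick_reference_genome(ds)
  references <- reference_genes(ds, ref_genome)
  rbh <- reciprocal_best_hits(references, proteomes, ref_genome, scfg, scheme)
  write_hits(rbh, file.path(out_dir, "rbh.tsv"))
  res$scheme <- scheme; res$search_config <- scfg
  res$ref_genome <- ref_genome; res$references <- references
  res$rbh <- rbh
  status("search", ref_genome = ref_genome, assignments = nrow(rbh),
         eff_db_len = scfg$eff_db_len)

  # -- stage 3: profile HMM search -------------------------------------
  hmms <- list(); hmm_hits <- list()
  for (fam in names(references)) {
    seed_ids <- rbh[rbh$family == fam & rbh$top_hit, c("genome", "gene_id")]
    if (nrow(seed_ids) < 2) next
    seed_seqs <- setNames(
      vapply(seq_len(nrow(seed_ids)), function(i)
        proteomes[[seed_ids$genome[i]]][[seed_ids$gene_id[i]]],
        character(1)),
      seed_ids$gene_id)
    seed_seqs <- head(seed_seqs, 20)
    aln <- progressive_align(seed_seqs, scheme)
    hmm <- build_hmm(aln, occupancy_threshold = cfg$hmm_occupancy)
    hmm <- calibrate_hmm(hmm, n_random = cfg$hmm_calibration_n,
                         seed = cfg$seed + 21L,
                         n_trials = cfg$hmm_n_trials)
    hmms[[fam]] <- hmm
    for (gm in names(proteomes)) {
      h <- hmm_search(hmm, proteomes[[gm]], cutoff = cfg$cutoff)
      if (nrow(h)) {
        h$family <- fam; h$genome <- gm
        hmm_hits[[length(hmm_hits) + 1L]] <- h
      }
    }
  }
  hmm_hits <- if (length(hmm_hits)) do.call(rbind, hmm_hits)
    else data.frame(target = character(0), bits = numeric(0),
                    evalue = numeric(0), family = character(0),
                    genome = character(0))
  write_hits(hmm_hits, file.path(out_dir, "hmm_hits.tsv"))
  dir.create(file.path(out_dir, "hmms"), showWarnings = FALSE)
  for (fam in names(hmms))
    hmm_to_json(hmms[[fam]], file.path(out_dir, "hmms", paste0(fam, ".json")))
  res$hmms <- hmms; res$hmm_hits <- hmm_hits
  status("hmm", models = length(hmms), hits = nrow(hmm_hits))

  # -- stage 4: combine evidence, classify -----------------------------
  assignments <- combine_evidence(rbh, hmm_hits)
  write_hits(assignments, file.path(out_dir, "assignments.tsv"))
  # motif classification on genes of the motif family
  motif_calls <- data.frame(gene_id = character(0), call = character(0))
  mf <- cfg$sim$motif_family
  if (!is.null(mf) && mf %in% assignments$family) {
    rows <- assignments[assignments$family == mf, , drop = FALSE]
    calls <- vapply(seq_len(nrow(rows)), function(i) {
      s <- proteomes[[rows$genome[i]]][[rows$gene_id[i]]]
      m <- scan_motif(s, motif_pattern())
      if (!length(m)) "no-motif" else classify_h_vs_h2(m[[1]])
    }, character(1))
    motif_calls <- data.frame(gene_id = rows$gene_id, call = calls,
                              stringsAsFactors = FALSE)
  }
  write_hits(motif_calls, file.path(out_dir, "motif_calls.tsv"))
  res$assignments <- assignments; res$motif_calls <- motif_calls
  status("classify", assignments = nrow(assignments),
         motif_calls = nrow(motif_calls))

  # -- stage 5: gene trees ---------------------------------------------
  dir.create(file.path(out_dir, "gene_trees"), showWarnings = FALSE)
  gene_trees <- list()
  for (fam in unique(assignments$family)) {
    rows <- assignments[assignments$family == fam, , drop = FALSE]
    if (nrow(rows) < 4) next
    seqs <- setNames(
      vapply(seq_len(nrow(rows)), function(i)
        proteomes[[rows$genome[i]]][[rows$gene_id[i]]], character(1)),
      rows$gene_id)
    aln <- progressive_align(seqs, scheme)
    tr <- nj_bootstrap(aln, n_reps = cfg$bootstrap_reps,
                       seed = cfg$seed + 31L)
    og <- if (!is.null(cfg$outgroup))
      grep(paste0("^", cfg$outgroup, "\\|"), tr$tip.label, value = TRUE)
    else character(0)
    tr_rooted <- if (length(og)) root_on_outgroup(tr, og[1])
      else midpoint_root(tr)
    gene_trees[[fam]] <- tr_rooted
    ape::write.tree(tr_rooted,
                    file.path(out_dir, "gene_trees", paste0(fam, ".nwk")))
  }
  res$gene_trees <- gene_trees
  status("trees", gene_trees = length(gene_trees),
         bootstrap_reps = cfg$bootstrap_reps)

  # -- stage 6: events --------------------------------------------------
  pmat <- build_presence_matrix(assignments,
                                genomes = ds$tree$tip.label,
                                families = cfg$sim$families)
  events <- list()
  for (fam in colnames(pmat$counts)) {
    col <- pmat$counts[, fam]
    ev <- if (any(col > 0)) dollo_infer(col, ds$tree)
      else list(gain = NA_character_, losses = character(0), n_losses = 0L)
    dups <- character(0)
    if (!is.null(gene_trees[[fam]])) {
      rec <- reconcile(gene_trees[[fam]], ds$tree)
      dups <- rec$duplications
    }
    events[[fam]] <- list(family = fam, gain = ev$gain,
                          losses = ev$losses, duplications = dups)
  }
  jsonlite::write_json(events, file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(data.frame(pmat$counts, check.names = FALSE),
              file.path(out_dir, "presence_matrix.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  res$presence <- pmat; res$events <- events
  status("events", families_with_gain = sum(!vapply(
    events, function(e) is.na(e$gain), logical(1))))

  # -- stage 7: genome context -----------------------------------------
  family_map <- setNames(assignments$family, assignments$gene_id)
  clusters <- find_clusters(ds$assembly$gene_table, family_map,
                            max_gap = cfg$max_gap)
  gene_hits <- fusion_candidate_hits(assignments, references, proteomes,
                                     ref_genome, scfg, scheme)
  fusions <- detect_fusions(gene_hits)
  conservation <- cluster_conservation_report(clusters, ds$tree)
  write_hits(clusters, file.path(out_dir, "clusters.tsv"))
  write_hits(fusions, file.path(out_dir, "fusions.tsv"))
  write_hits(conservation, file.path(out_dir, "cluster_conservation.tsv"))
  res$clusters <- clusters; res$fusions <- fusions
  res$conservation <- conservation
  status("context", clusters = nrow(clusters), fusions = nrow(fusions))

  # -- stage 8: report --------------------------------------------------
  dist_tab <- render_distribution(pmat, ds$tree, events)
  writeLines(dist_tab$text, file.path(out_dir, "distribution.txt"))
  write.table(dist_tab$table, file.path(out_dir, "distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res$distribution <- dist_tab
  status("report", genomes = nrow(dist_tab$table))

  files <- sort(list.files(out_dir, recursive = TRUE))
  manifest$artifacts <- lapply(setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(manifest = manifest, data = res, out_dir = out_dir)
}

# genome with the most families represented (ties: first in tip order)
pick_reference_genome <- function(ds) {
  counts <- ds$truth$leaf_counts
  ngenes <- colSums(counts > 0)
  names(ngenes)[which.max(ngenes)]
}

# one reference gene id per family present in the reference genome
reference_genes <- function(ds, ref_genome) {
  meta <- ds$sequences$meta
  refs <- list()
  for (fam in rownames(ds$truth$leaf_counts)) {
    ids <- meta$gene_id[meta$family == fam & meta$genome == ref_genome]
    ids <- intersect(ids, names(ds$assembly$proteomes[[ref_genome]]))
    if (length(ids)) refs[[fam]] <- sort(ids)
  }
  refs
}

# union of RBH and HMM detections with provenance
combine_evidence <- function(rbh, hmm_hits) {
  a <- unique(rbh[, c("family", "genome", "gene_id")])
  a$evidence <- "RBH"
  if (nrow(hmm_hits)) {
    b <- unique(data.frame(family = hmm_hits$family,
                           genome = hmm_hits$genome,
                           gene_id = hmm_hits$target,
                           stringsAsFactors = FALSE))
    b$evidence <- "HMM"
    key <- function(d) paste(d$family, d$genome, d$gene_id, sep = "\r")
    both <- key(b) %in% key(a)
    a$evidence[key(a) %in% key(b)] <- "both"
    out <- rbind(a, b[!both, , drop = FALSE])
  } else out <- a
  out <- out[order(out$family, out$genome, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# SW intervals of each family reference against genes assigned to >= 2
# families (fusion candidates)
fusion_candidate_hits <- function(assignments, references, proteomes,
                                  ref_genome, scfg, scheme) {
  tab <- table(assignments$gene_id)
  cand <- names(tab)[tab >= 2]
  out <- list()
  for (g in cand) {
    rows <- assignments[assignments$gene_id == g, , drop = FALSE]
    gseq <- proteomes[[rows$genome[1]]][[g]]
    for (fam in unique(rows$family)) {
      ref <- references[[fam]][1]
      hit <- smith_waterman(proteomes[[ref_genome]][[ref]], gseq, scheme)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, family = fam, tstart = hit$tstart, tend = hit$tend,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene_id = character(0), family = character(0),
                  tstart = numeric(0), tend = numeric(0))
}

#' Distribution table: presence marks in tree order with event annotations
#'
#' Emits the genomes x families copy-count grid with leaves in ladderized
#' tree order (absence rendered as "."), plus annotation lines marking the
#' inferred gain branch and loss branches of every family. Genomes in the
#' matrix but not on the tree are listed in an "unplaced" footer.
#'
#' @param pmat a [build_presence_matrix()] result.
#' @param species_tree rooted `phylo`.
#' @param events named list per family with `gain` and `losses` (as from
#'   [run_pipeline()] stage 6), or NULL.
#' @return list: `table` (data.frame), `annotations`, `unplaced`, `text`
#'   (the rendered lines).
#' @export
render_distribution <- function(pmat, species_tree, events = NULL) {
  counts <- pmat$counts
  lad <- ape::ladderize(species_tree)
  lad <- ape::reorder.phylo(lad, "cladewise")
  ord <- lad$tip.label[lad$edge[lad$edge[, 2] <= ape::Ntip(lad), 2]]
  placed <- intersect(ord, rownames(counts))
  unplaced <- setdiff(rownames(counts), species_tree$tip.label)
  tab <- data.frame(genome = placed,
                    apply(counts[placed, , drop = FALSE], 2, function(x)
                      ifelse(x == 0, ".", as.character(x))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  ann <- character(0)
  if (!is.null(events)) {
    for (fam in names(events)) {
      e <- events[[fam]]
      if (!is.null(e$gain) && !is.na(e$gain))
        ann <- c(ann, sprintf("# gain %s -> %s", fam, e$gain))
      for (l in e$losses) ann <- c(ann, sprintf("# loss %s -> %s", fam, l))
      for (d in e$duplications)
        ann <- c(ann, sprintf("# duplication %s -> %s", fam, d))
    }
  }
  header <- paste(c("genome", colnames(counts)), collapse = "\t")
  body <- apply(tab, 1, paste, collapse = "\t")
  text <- c(header, body, ann,
            if (length(unplaced))
              paste0("# unplaced: ", paste(unplaced, collapse = ",")))
  list(table = tab, annotations = ann, unplaced = unplaced, text = text)
}
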