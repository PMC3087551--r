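#!/usr/bin/env Rscript
# Stage 7: genome context. Detects max-gap clusters of pathway genes,
# calls lpxC/fabZ fusions from near-disjoint profile intervals, and
# localizes conserved cluster compositions on the species tree.

suppressMessages(library(lpxevo))

data_dir <- "results/data"
tree <- ape::read.tree(file.path(data_dir, "species_tree.nwk"))
gene_table <- read_gene_table(file.path(data_dir, "gene_table.tsv"))
assignments <- read.delim("results/assignments.tsv")
truth <- read_truth_log(file.path(data_dir, "truth.json"))
proteome_files <- list.files(file.path(data_dir, "proteomes"),
                             full.names = TRUE)
proteomes <- lapply(proteome_files, read_fasta)
names(proteomes) <- sub("\\.faa$", "", basename(proteome_files))
scheme <- calibrate_scheme(scoring_scheme(), seed = 12)
cfg <- search_config()

family_map <- setNames(assignments$family, assignments$gene_id)
clusters <- find_clusters(gene_table, family_map, max_gap = 3)
write_hits(clusters, "results/clusters.tsv")

# same reference genome rule as stage 2: most families represented
genes <- read.delim(file.path(data_dir, "genes.tsv"))
ref_genome <- colnames(truth$leaf_counts)[
  which.max(colSums(truth$leaf_counts > 0))]
refs <- lapply(split(genes$gene_id[genes$genome == ref_genome],
                     genes$family[genes$genome == ref_genome]), sort)
refs <- lapply(refs, function(x) intersect(x, names(proteomes[[ref_genome]])))
refs <- refs[vapply(refs, length, integer(1)) > 0]
gene_hits <- lpxevo:::fusion_candidate_hits(assignments, refs, proteomes,
                                            ref_genome, cfg, scheme)
fusions <- detect_fusions(gene_hits)
write_hits(fusions, "results/fusions.tsv")

conservation <- cluster_conservation_report(clusters, tree)
write_hits(conservation, "results/cluster_conservation.tsv")

five <- grepl("lpxD.*lpxC.*fabZ.*lpxA.*lpxB", conservation$families)
cat("Clusters found:", nrow(clusters), "in",
    length(unique(clusters$genome)), "genomes;",
    "the five-gene composition appears in",
    if (any(five)) conservation$n_genomes[five][1] else 0, "genomes.\n")
cat("Fusions called:", nrow(fusions), "- planted:",
    length(truth$fusions$gene_id), "\n")
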