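#!/usr/bin/env Rscript
# Stage 4: classification. Combines RBH and HMM evidence into one
# assignment table, scans detected lpxH copies for the five-block
# metallophosphoesterase signature D-Xn-GD-Xn-GN[HR](E/D)-Xn-H-Xn-GHXH,
# applies the H/R diagnostic-residue rule, and reports per-block
# conservation.

suppressMessages(library(lpxevo))

data_dir <- "results/data"
proteome_files <- list.files(file.path(data_dir, "proteomes"),
                             full.names = TRUE)
proteomes <- lapply(proteome_files, read_fasta)
names(proteomes) <- sub("\\.faa$", "", basename(proteome_files))
rbh <- read.delim("results/rbh.tsv")
hmm_hits <- read.delim("results/hmm_hits.tsv")

assignments <- lpxevo:::combine_evidence(rbh, hmm_hits)
write_hits(assignments, "results/assignments.tsv")

lpxh <- assignments[assignments$family == "lpxH", ]
pat <- motif_pattern()
matches <- list(); calls <- character(0)
for (i in seq_len(nrow(lpxh))) {
  s <- proteomes[[lpxh$genome[i]]][[lpxh$gene_id[i]]]
  m <- scan_motif(s, pat)
  if (!length(m)) { calls <- c(calls, "no-motif"); next }
  matches[[length(matches) + 1L]] <- m[[1]]
  calls <- c(calls, classify_h_vs_h2(m[[1]]))
}
write.table(data.frame(gene_id = lpxh$gene_id, call = calls),
            "results/motif_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cons <- block_conservation_report(matches)
write.table(cons, "results/motif_conservation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Assignments:", nrow(assignments), "genes;",
    sum(assignments$evidence == "HMM"), "by profile evidence only.\n")
cat("lpxH motif calls:", paste(names(table(calls)), table(calls),
                               collapse = ", "), "\n")
key <- cons[cons$block == 3 & cons$position == 3, ]
cat("Third-block key residue frequencies:",
    paste(key$residue, round(key$freq, 2), collapse = ", "), "\n")
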