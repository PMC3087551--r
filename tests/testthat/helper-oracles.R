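# Independent oracles shared across test files. Each reimplements the
# checked computation from scratch (plain R, brute force or a different
# library primitive) and never calls the code path under test.

# --- motif: bounded-repetition lazy regex ------------------------------
regex_motif_oracle <- function(seq, smin = 1, smax = 300) {
  pat <- sprintf(paste0("(D)(?:.{%d,%d}?)(GD)(?:.{%d,%d}?)(GN[HR][ED])",
                        "(?:.{%d,%d}?)(H)(?:.{%d,%d}?)(GH.H)"),
                 smin, smax, smin, smax, smin, smax, smin, smax)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(list())
  cs <- attr(m, "capture.start")
  lapply(seq_along(m), function(i) list(starts = unname(cs[i, ]) - 1L))
}

make_motif_seq <- function(spacers, key = "H", tail4 = "GHAH") {
  paste0(random_aa_string(spacers[1]), "D",
         random_aa_string(spacers[2]), "GD",
         random_aa_string(spacers[3]), "GN", key, sample(c("E", "D"), 1),
         random_aa_string(spacers[4]), "H",
         random_aa_string(spacers[5]), tail4,
         random_aa_string(spacers[6]))
}

# --- Dollo: brute force over all single-gain placements ----------------
dollo_oracle <- function(presence, tree) {
  tips <- tree$tip.label
  nt <- ape::Ntip(tree)
  ch <- lpxevo:::children_map(tree)
  pres_tips <- which(as.numeric(presence[tips]) > 0)
  losses_under <- function(node) {
    desc <- lpxevo:::descendant_tips(tree, node)
    if (!all(pres_tips %in% desc)) return(Inf)
    count <- function(v) {
      dts <- lpxevo:::descendant_tips(tree, v)
      if (!any(dts %in% pres_tips)) return(1L)
      if (v <= nt) return(0L)
      sum(vapply(ch[[v]], count, integer(1)))
    }
    sum(vapply(ch[[node]], count, integer(1)))
  }
  cand <- seq_len(nt + tree$Nnode)
  min(vapply(cand, function(v)
    if (v <= nt) { if (identical(pres_tips, v)) 0 else Inf }
    else losses_under(v), numeric(1)))
}

# --- clusters: quadratic window enumeration ----------------------------
window_cluster_oracle <- function(fams, max_gap, targets) {
  idx <- which(!is.na(fams) & fams %in% targets)
  if (length(idx) < 2) return(list())
  runs <- list()
  for (s in seq_along(idx)) {
    run <- idx[s]
    for (t in seq_along(idx)) {
      if (idx[t] <= run[length(run)]) next
      if (idx[t] - run[length(run)] - 1 <= max_gap) run <- c(run, idx[t])
      else break
    }
    runs[[length(runs) + 1L]] <- run
  }
  keep <- vapply(seq_along(runs), function(i) {
    !any(vapply(seq_along(runs), function(j)
      i != j && all(runs[[i]] %in% runs[[j]]), logical(1)))
  }, logical(1))
  Filter(function(r) length(r) >= 2, unique(runs[keep]))
}

toy_table <- function(fams, genome = "g", contig = "c") {
  n <- length(fams)
  data.frame(genome = genome, contig = contig,
             gene_id = sprintf("%s_x%03d", genome, seq_len(n)),
             family_truth = ifelse(is.na(fams), "decoy", fams),
             start = seq(0, by = 1000, length.out = n),
             end = seq(900, by = 1000, length.out = n),
             strand = rep(c("+", "-"), length.out = n),
             stringsAsFactors = FALSE)
}

fam_map_of <- function(tab) {
  keep <- tab$family_truth != "decoy"
  setNames(tab$family_truth[keep], tab$gene_id[keep])
}

# --- profile HMM forward: exhaustive path enumeration ------------------
hmm_enum_odds <- function(h, codes) {
  m <- h$m; L <- length(codes)
  oe <- h$match_odds
  total <- 0
  recurse <- function(state, k, pos, w) {
    if (w == 0) return()
    if (state == "M") {
      total <<- total + w * h$exit[k]
      if (k < m) {
        if (pos < L)
          recurse("M", k + 1, pos + 1,
                  w * h$t_mm[k] * oe[k + 1, codes[pos + 1] + 1])
        if (pos < L) recurse("I", k, pos + 1, w * h$t_mi[k])
        recurse("D", k + 1, pos, w * h$t_md[k])
      }
    } else if (state == "I") {
      if (pos < L) {
        recurse("I", k, pos + 1, w * h$t_ii[k])
        recurse("M", k + 1, pos + 1,
                w * h$t_im[k] * oe[k + 1, codes[pos + 1] + 1])
      }
    } else {
      if (k == m) { total <<- total + w; return() }
      if (pos < L)
        recurse("M", k + 1, pos + 1,
                w * h$t_dm[k] * oe[k + 1, codes[pos + 1] + 1])
      recurse("D", k + 1, pos, w * h$t_dd[k])
    }
  }
  for (start in seq_len(L)) for (k in seq_len(m))
    recurse("M", k, start, h$entry[k] * oe[k, codes[start] + 1])
  unname(total)
}
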