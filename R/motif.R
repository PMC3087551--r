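#' Variable-spacer motif pattern
#'
#' An ordered set of residue blocks separated by variable-length spacers.
#' Each block is a list of positions; a position is a character vector of
#' allowed residues, or `"*"` for any residue. The default (no arguments)
#' is the five-block metallophosphoesterase signature
#' `D-Xn-GD-Xn-GN[HR](E/D)-Xn-H-Xn-GHXH`, with the third-block key position
#' admitting both H and R so that LpxH (arginine) and LpxH2 (histidine)
#' sequences are both matched and can be told apart afterwards by
#' [classify_h_vs_h2()].
#'
#' @param blocks list of blocks (see above).
#' @param spacer_min,spacer_max integer vectors (length `nblocks - 1`) of
#'   spacer bounds between consecutive blocks; scalars are recycled.
#' @return object of class `motif_pattern`.
#' @export
motif_pattern <- function(blocks = NULL, spacer_min = 1, spacer_max = 300) {
  if (is.null(blocks)) {
    blocks <- list(
      list("D"),
      list("G", "D"),
      list("G", "N", c("H", "R"), c("E", "D")),
      list("H"),
      list("G", "H", "*", "H"))
  }
  nb <- length(blocks)
  if (nb < 1) stop("pattern needs >= 1 block")
  spacer_min <- as.integer(rep(spacer_min, length.out = max(nb - 1, 0)))
  spacer_max <- as.integer(rep(spacer_max, length.out = max(nb - 1, 0)))
  if (any(spacer_min > spacer_max)) stop("spacer min > max")
  structure(list(blocks = blocks, spacer_min = spacer_min,
                 spacer_max = spacer_max), class = "motif_pattern")
}

block_matches_at <- function(chars, block, pos) {
  L <- length(chars)
  bl <- length(block)
  if (pos + bl - 1 > L) return(FALSE)
  for (p in seq_len(bl)) {
    alt <- block[[p]]
    if (identical(alt, "*") || is.null(alt)) next
    if (!(chars[pos + p - 1] %in% alt)) return(FALSE)
  }
  TRUE
}

#' Scan a sequence for all non-overlapping motif matches
#'
#' Leftmost-first, shortest-spacer semantics (the same matches a lazy
#' bounded-repetition regular expression produces with global scanning):
#' the earliest feasible start is taken, each spacer is extended as little
#' as possible while still allowing the remaining blocks to match, and
#' scanning resumes after the end of each reported match.
#'
#' @param seq protein string.
#' @param pattern a [motif_pattern()].
#' @return list of matches; each is `list(starts, residues)` with 0-based
#'   block start positions. Empty list if none.
#' @export
scan_motif <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  blocks <- pattern$blocks
  nb <- length(blocks)
  bl <- vapply(blocks, length, integer(1))
  # find the lazily-leftmost match with block1 starting at >= from;
  # returns starts vector or NULL
  find_one <- function(from) {
    starts <- integer(nb)
    # backtracking over block start positions, preferring smaller
    try_block <- function(b, minpos) {
      maxpos <- L - sum(bl[b:nb]) + 1L - if (b < nb)
        sum(pattern$spacer_min[b:(nb - 1)]) else 0L
      if (b > 1) {
        hi <- starts[b - 1] + bl[b - 1] + pattern$spacer_max[b - 1]
        maxpos <- min(maxpos, hi)
      }
      pos <- minpos
      while (pos <= maxpos) {
        if (block_matches_at(chars, blocks[[b]], pos)) {
          starts[b] <<- pos
          if (b == nb) return(TRUE)
          nxt <- pos + bl[b] + pattern$spacer_min[b]
          if (try_block(b + 1, nxt)) return(TRUE)
        }
        pos <- pos + 1L
      }
      FALSE
    }
    if (try_block(1, from)) starts else NULL
  }
  out <- list()
  from <- 1L
  while (from <= L) {
    st <- find_one(from)
    if (is.null(st)) break
    res <- vapply(seq_len(nb), function(b)
      paste(chars[st[b]:(st[b] + bl[b] - 1)], collapse = ""), character(1))
    out[[length(out) + 1L]] <- list(starts = st - 1L, residues = res)
    from <- st[nb] + bl[nb]
  }
  out
}

#' LpxH vs LpxH2 from the third-block diagnostic residue
#'
#' Within the metallophosphoesterase signature the third block is
#' `GN[HR](E/D)`; the histidine there is substituted to arginine only in
#' LpxH, so R at the key position calls LpxH, H calls LpxH2, and anything
#' else is indeterminate.
#'
#' @param match one element of [scan_motif()] output.
#' @param key_block index of the diagnostic block.
#' @param key_pos position of the diagnostic residue within the block.
#' @return `"LpxH"`, `"LpxH2"` or `"indeterminate"`.
#' @export
classify_h_vs_h2 <- function(match, key_block = 3, key_pos = 3) {
  res <- substr(match$residues[key_block], key_pos, key_pos)
  if (res == "R") "LpxH" else if (res == "H") "LpxH2" else "indeterminate"
}

#' Per-block residue-conservation table from a set of motif matches
#'
#' @param matches list of [scan_motif()] matches (possibly across many
#'   sequences).
#' @return data.frame: block, position, residue, count, freq.
#' @export
block_conservation_report <- function(matches) {
  if (!length(matches))
    return(data.frame(block = integer(0), position = integer(0),
                      residue = character(0), count = integer(0),
                      freq = numeric(0)))
  nb <- length(matches[[1]]$residues)
  rows <- list()
  for (b in seq_len(nb)) {
    res <- vapply(matches, function(m) m$residues[b], character(1))
    width <- nchar(res[1])
    for (p in seq_len(width)) {
      tab <- table(substr(res, p, p))
      for (r in names(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          block = b, position = p, residue = r,
          count = as.integer(tab[[r]]),
          freq = as.integer(tab[[r]]) / length(res),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
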