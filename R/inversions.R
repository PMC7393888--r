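MAX_STEM_SCAN <- 60L   # cap on how far a stem arm is chased
CLUSTER_GAP <- 10L     # mismatch clustering distance for candidate loops

# stem length at a window boundary: longest inverted-repeat pairing
# row[s-q] == complement(row[e+q]) extending outward, tolerating up to
# `allow` mismatched pairs (the reported length ends on a matched pair)
stem_length_at <- function(row, valid, s, e, allow) {
  L <- length(row)
  k <- 0L; bad <- 0L; q <- 0L
  while (q < MAX_STEM_SCAN && s - q - 1L >= 1L && e + q + 1L <= L) {
    i1 <- s - q - 1L; i2 <- e + q + 1L
    if (!valid[i1] || !valid[i2]) break
    if (row[i1] == COMPLEMENT[[row[i2]]]) k <- q + 1L else {
      bad <- bad + 1L
      if (bad > allow) break
    }
    q <- q + 1L
  }
  k
}

# Pairwise stem-loop inversion windows between two aligned rows.
#
# A window [s, e] is an inversion call iff (i) both boundary columns
# mismatch between the rows, (ii) the reverse-complement identity over
# the window (rowB[i] vs complement(rowA[s + e - i])) reaches
# loop_identity and exceeds the direct identity, (iii) the loop length is
# in [2, max_loop] with no gaps/N inside, and (iv) both rows carry a
# flanking inverted repeat (stem) of at least min_stem bp, allowing
# stem_mismatch mismatched pairs per arm (stems decay by substitution
# after the inversion arises). Windows contained in a larger reported
# window are dropped. Candidate boundaries are mismatch positions,
# enumerated within mismatch clusters: a window must start and end on a
# mismatch, which anchors it canonically, and any window satisfying the
# predicate has mismatching boundary columns by construction.
find_inversion_windows <- function(rowA, rowB, min_stem = 7L,
                                   max_loop = 100L, loop_identity = 0.8,
                                   stem_mismatch = 2L) {
  L <- length(rowA)
  valid <- rowA %in% names(BASE_BITS) & rowB %in% names(BASE_BITS)
  compA <- unname(COMPLEMENT[rowA])
  mism <- which(valid & rowA != rowB)
  if (!length(mism)) return(list())
  cl <- cumsum(c(1L, diff(mism) > CLUSTER_GAP))
  out <- list()
  for (cid in unique(cl)) {
    pts <- mism[cl == cid]
    if (length(pts) < 2L) next
    pairs <- expand.grid(s = pts, e = pts)
    pairs <- pairs[pairs$e >= pairs$s + 1L &
                     pairs$e - pairs$s + 1L <= max_loop, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      s <- pairs$s[r]; e <- pairs$e[r]
      idx <- s:e
      if (!all(valid[idx])) next
      rc_id <- mean(rowB[idx] == compA[(s + e) - idx])
      if (rc_id < loop_identity) next
      if (mean(rowB[idx] == rowA[idx]) >= rc_id) next
      kA <- stem_length_at(rowA, valid, s, e, stem_mismatch)
      if (kA < min_stem) next
      kB <- stem_length_at(rowB, valid, s, e, stem_mismatch)
      if (kB < min_stem) next
      out[[length(out) + 1L]] <- c(start_col = s, end_col = e,
                                   loop_length = e - s + 1L,
                                   stem_length = min(kA, kB))
    }
  }
  if (!length(out)) return(list())
  w <- unique(do.call(rbind, out))
  # drop windows strictly contained in another reported window
  keep <- vapply(seq_len(nrow(w)), function(i) {
    !any(w[, "start_col"] <= w[i, "start_col"] &
           w[, "end_col"] >= w[i, "end_col"] &
           (w[, "start_col"] < w[i, "start_col"] |
              w[, "end_col"] > w[i, "end_col"]))
  }, logical(1L))
  w <- w[keep, , drop = FALSE]
  lapply(seq_len(nrow(w)), function(i) w[i, ])
}

#' Detect stem-loop inversions in the alignment
#'
#' Scans each ingroup taxon against each outgroup for maximal windows where
#' one sequence equals the reverse complement of the other at homologous
#' columns, flanked by a shared inverted repeat (the stem) of at least
#' `min_stem` bp. For each detected span, every taxon is assigned an
#' orientation; the carriers of the derived orientation are mapped to
#' branches by parsimony. Orientation polarity (which state is ancestral)
#' is read from the rank outgroups; when they disagree the event is still
#' reported with `polarity_known = FALSE` — inversions are non-directional
#' and polarity is a report field, never a filter. Convergent occurrences
#' of one inversion in non-sister taxa are reported per carrier clade, not
#' merged.
#'
#' @param aln a [plastome_alignment()].
#' @param topo a [dated_topology()].
#' @param min_stem minimum stem (inverted repeat) length in bp, default 7.
#' @param max_loop maximum loop length in bp, default 100.
#' @param loop_identity minimum reverse-complement identity over the loop
#'   (1 = exact; the default 0.8 tolerates post-inversion substitutions).
#' @param stem_mismatch mismatched pairs tolerated per stem arm.
#' @return data.frame: `start_col`, `end_col`, `loop_length`,
#'   `stem_length`, `carriers`, `branch`, `rank`, `parallel`,
#'   `polarity_known`.
#' @export
detect_inversions <- function(aln, topo, min_stem = 7L, max_loop = 100L,
                              loop_identity = 0.8, stem_mismatch = 2L) {
  empty <- data.frame(start_col = integer(), end_col = integer(),
                      loop_length = integer(), stem_length = integer(),
                      carriers = character(), branch = character(),
                      rank = character(), parallel = logical(),
                      polarity_known = logical(), stringsAsFactors = FALSE)
  spans <- list()
  for (tx in topo$ingroup_tips) {
    for (og in topo$outgroup_tips) {
      ws <- find_inversion_windows(aln$mat[tx, ], aln$mat[og, ],
                                   min_stem, max_loop, loop_identity,
                                   stem_mismatch)
      for (w in ws) spans[[length(spans) + 1L]] <- w
    }
  }
  if (!length(spans)) return(empty)
  # merge windows of the same inversion found in different pairs
  # (reciprocal overlap >= 50%); keep the widest representative
  sp <- unique(do.call(rbind, spans))
  sp <- sp[order(-(sp[, "end_col"] - sp[, "start_col"])), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(sp))) {
    dup <- any(vapply(merged, function(m) {
      ov <- min(m[["end_col"]], sp[i, "end_col"]) -
        max(m[["start_col"]], sp[i, "start_col"]) + 1L
      ov >= 0.5 * (sp[i, "end_col"] - sp[i, "start_col"] + 1L) &&
        ov >= 0.5 * (m[["end_col"]] - m[["start_col"]] + 1L)
    }, logical(1L)))
    if (!dup) merged[[length(merged) + 1L]] <- sp[i, ]
  }
  rows <- list()
  for (w in merged) {
    s <- w[["start_col"]]; e <- w[["end_col"]]
    seqs <- apply(aln$mat[topo$tips, s:e, drop = FALSE], 1L, paste,
                  collapse = "")
    ok <- setNames(!grepl("[^ACGT]", seqs), names(seqs))
    # orientation by similarity to the first valid outgroup's state
    og_ok <- topo$outgroup_tips[ok[topo$outgroup_tips]]
    if (!length(og_ok)) next
    ref_chars <- strsplit(seqs[og_ok[1L]], "")[[1L]]
    rc_chars <- rev(unname(COMPLEMENT[ref_chars]))
    orient <- vapply(topo$tips, function(t2) {
      if (!ok[[t2]]) return(NA_integer_)
      ch <- strsplit(seqs[[t2]], "")[[1L]]
      fwd <- mean(ch == ref_chars); rc <- mean(ch == rc_chars)
      if (fwd > rc) 1L else if (rc > fwd) 2L else NA_integer_
    }, integer(1L))
    if (!any(orient[topo$ingroup_tips] %in% 2L)) next
    # polarity: do the subfamily outgroups agree on one orientation?
    og_states <- orient[topo$outgroup_tips]
    polarity_known <- all(!is.na(og_states)) && length(unique(og_states)) == 1L
    bits <- ifelse(is.na(orient), MISSING_BITS,
                   ifelse(orient == 1L, PRESENT_BIT, ABSENT_BIT))
    bits <- matrix(as.integer(bits), ncol = 1L,
                   dimnames = list(topo$tips, NULL))
    mp <- map_sites_to_branches(bits, topo)
    if (identical(mp$rank[1L], "outgroup")) next  # outgroup autapomorphy
    if (!is.na(mp$branch[1L])) {
      below <- intersect(tips_below(topo, mp$branch[1L]), topo$ingroup_tips)
      rows[[length(rows) + 1L]] <- data.frame(
        start_col = s, end_col = e, loop_length = w[["loop_length"]],
        stem_length = w[["stem_length"]],
        carriers = paste(below, collapse = ","),
        branch = mp$branch[1L], rank = mp$rank[1L], parallel = FALSE,
        polarity_known = polarity_known, stringsAsFactors = FALSE)
    } else {
      # convergent (or ambiguous): report per maximal carrier clade
      carriers <- topo$ingroup_tips[orient[topo$ingroup_tips] %in% 2L]
      clades <- decompose_into_clades(carriers, topo)
      for (br in clades) {
        below <- intersect(tips_below(topo, br), topo$ingroup_tips)
        rows[[length(rows) + 1L]] <- data.frame(
          start_col = s, end_col = e, loop_length = w[["loop_length"]],
          stem_length = w[["stem_length"]],
          carriers = paste(below, collapse = ","),
          branch = br, rank = topo$branch_rank[[br]], parallel = TRUE,
          polarity_known = polarity_known, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimal set of branches whose tip sets partition the carrier set
decompose_into_clades <- function(carriers, topo) {
  res <- character()
  remaining <- carriers
  branches <- names(topo$branch_rank)[topo$branch_rank != "outgroup"]
  sizes <- vapply(branches, function(b) length(tips_below(topo, b)), integer(1L))
  for (b in branches[order(-sizes)]) {
    tb <- intersect(tips_below(topo, b), topo$ingroup_tips)
    if (length(tb) && all(tb %in% remaining)) {
      res <- c(res, b)
      remaining <- setdiff(remaining, tb)
    }
  }
  res
}

#' Alignment columns covered by detected inversion loops
#'
#' Use as `mask_columns` for [annotate_snps()]: loop columns record one
#' structural event, not independent substitutions.
#'
#' @param inversions output of [detect_inversions()].
#' @return integer vector of columns.
#' @export
inversion_mask <- function(inversions) {
  if (!nrow(inversions)) return(integer())
  unique(unlist(mapply(seq, inversions$start_col, inversions$end_col,
                       SIMPLIFY = FALSE)))
}
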