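PRESENT_BIT <- 1L  # encodes "segment present" as allele A
ABSENT_BIT <- 2L   # encodes "segment absent (gapped)" as allele C

#' Extract candidate structural events from alignment gap runs
#'
#' Maximal runs of contiguous columns sharing an identical gap pattern (the
#' same set of taxa gapped) become one candidate event; nested or
#' overlapping distinct patterns are split at pattern boundaries, and
#' pieces of one pattern separated only by columns that are also gapped in
#' all of its taxa (another lineage's insertion inside a deleted span) are
#' re-joined, with the interrupting columns excluded from the event's
#' `core` and `length`. Each candidate is mapped to a branch and rank by
#' the same parsimony machinery as SNPs, applied to the binary
#' present/absent character.
#'
#' @param aln a [plastome_alignment()].
#' @param topo a [dated_topology()].
#' @return data.frame: `start_col`, `end_col`, `length`, `gap_taxa`
#'   (comma-separated), `branch`, `rank`, `parallel`, `derived_state`
#'   (`"present"`/`"absent"`/NA), `carriers` (taxa bearing the derived
#'   state; the gapped set when the branch is ambiguous).
#' @export
extract_gap_events <- function(aln, topo) {
  mat <- aln$mat[topo$tips, , drop = FALSE]
  gap <- mat == "-"
  pat <- as.integer(colSums(gap * 2^(seq_len(nrow(gap)) - 1L)))
  runs <- rle(pat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L & runs$values != sum(2^(seq_len(nrow(gap)) - 1L))
  starts <- starts[keep]; ends <- ends[keep]; vals <- runs$values[keep]
  # re-join pieces of one gap pattern split only by columns that are also
  # gapped in all of its taxa (insertions by other lineages inside a
  # deleted span interrupt the column run but not the carrier's gap)
  cores <- lapply(seq_along(starts), function(i)
    cbind(starts[i], ends[i]))
  if (length(starts) > 1L) {
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]; vals <- vals[ord]
    cores <- cores[ord]
    taxa_bits <- 2^(seq_len(nrow(gap)) - 1L)
    merged <- TRUE
    while (merged) {
      merged <- FALSE
      i <- 1L
      while (i < length(starts)) {
        js <- which(vals == vals[i] & starts > ends[i])
        if (length(js)) {
          j <- js[which.min(starts[js])]
          between <- (ends[i] + 1L):(starts[j] - 1L)
          set <- which(bitwAnd(vals[i], taxa_bits) > 0L)
          if (all(gap[set, between, drop = FALSE])) {
            ends[i] <- ends[j]
            cores[[i]] <- rbind(cores[[i]], cores[[j]])
            starts <- starts[-j]; ends <- ends[-j]; vals <- vals[-j]
            cores <- cores[-j]
            merged <- TRUE
            next
          }
        }
        i <- i + 1L
      }
    }
  }
  n <- length(starts)
  if (n == 0L)
    return(data.frame(start_col = integer(), end_col = integer(),
                      length = integer(), gap_taxa = character(),
                      branch = character(), rank = character(),
                      parallel = logical(), derived_state = character(),
                      carriers = character(), stringsAsFactors = FALSE))
  gap_sets <- lapply(vals, function(v)
    topo$tips[bitwAnd(v, 2^(seq_along(topo$tips) - 1L)) > 0L])
  tip_bits <- vapply(seq_len(n), function(i)
    ifelse(topo$tips %in% gap_sets[[i]], ABSENT_BIT, PRESENT_BIT),
    integer(length(topo$tips)))
  tip_bits <- matrix(tip_bits, nrow = length(topo$tips),
                     dimnames = list(topo$tips, NULL))
  mp <- map_sites_to_branches(tip_bits, topo)
  carriers <- character(n)
  derived <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(mp$branch[i])) {
      below <- tips_below(topo, mp$branch[i])
      carriers[i] <- paste(below, collapse = ",")
      derived[i] <- if (mp$derived_fitch[i] == ABSENT_BIT) "absent" else "present"
    } else {
      carriers[i] <- paste(gap_sets[[i]], collapse = ",")
    }
  }
  data.frame(start_col = starts, end_col = ends,
             length = vapply(cores, function(m)
               sum(m[, 2L] - m[, 1L] + 1L), integer(1L)),
             core = vapply(cores, function(m)
               paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ","),
               character(1L)),
             gap_taxa = vapply(gap_sets, paste, character(1L), collapse = ","),
             branch = mp$branch, rank = mp$rank, parallel = mp$parallel,
             derived_state = derived, carriers = carriers,
             stringsAsFactors = FALSE)
}

# parse an event's core column ranges ("s1-e1,s2-e2") into a column vector
core_columns <- function(event) {
  if (is.null(event$core) || is.na(event$core))
    return(event$start_col:event$end_col)
  parts <- strsplit(event$core, ",")[[1L]]
  unlist(lapply(strsplit(parts, "-"), function(p)
    as.integer(p[1L]):as.integer(p[2L])), use.names = FALSE)
}

# taxa that carry the segment (ungapped over the span), ordered by
# phylogenetic closeness to the gapped set: the nearest relative best
# preserves the sequence context at the time of the event
segment_donors <- function(aln, event, gap_taxa, topo = NULL) {
  cands <- setdiff(aln$taxa, gap_taxa)
  if (!is.null(topo)) {
    prox <- vapply(cands, function(tx)
      min(vapply(gap_taxa, function(g) mrca_age(topo, tx, g), numeric(1L))),
      numeric(1L))
    cands <- cands[order(prox)]
  } else {
    cands <- c(intersect(aln$reference, cands), setdiff(cands, aln$reference))
  }
  cols <- core_columns(event)
  ok <- vapply(cands, function(tx) {
    b <- aln$mat[tx, cols]
    !any(b == "-") && !any(b == "N")
  }, logical(1L))
  cands[ok]
}

smallest_period <- function(seg) {
  n <- length(seg)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (all(seg == rep_len(seg[seq_len(p)], n))) return(p)
  }
  n
}

#' Classify a candidate gap event as indel, tandem repeat or microsatellite
#'
#' Decision cascade, applied in this order:
#' 1. *microsatellite* — the inserted/deleted segment consists of whole
#'    copies of a 1–3 bp motif and the flanking sequence of the longer
#'    allele extends the motif run to at least `ms_min_run` bp total for
#'    mononucleotide motifs, or at least `ms_min_copies` total copies for
#'    di-/trinucleotide motifs;
#' 2. *repeat* — the segment (length >= `min_repeat_len`) duplicates the
#'    immediately adjacent upstream or downstream sequence of equal length
#'    in the longer allele (tandem duplication); segments of at least
#'    `repeat_mismatch_min_len` bp may differ from the flank copy at up to
#'    `repeat_mismatch` positions, since the two copies diverge by
#'    substitution after the duplication arises;
#' 3. otherwise *indel*.
#'
#' The segment and flanks are read from the taxon nearest the gapped set
#' that still carries the segment; if that taxon's context classifies the
#' event as plain indel, the remaining donors are consulted in closeness
#' order (divergence after the event erodes exact duplication structure in
#' any single genome, so one intact witness suffices).
#'
#' @param event one row of [extract_gap_events()] output (list or 1-row df).
#' @param aln a [plastome_alignment()].
#' @param topo optional [dated_topology()] used to rank donor taxa by
#'   closeness to the gapped set.
#' @param ms_min_run minimum total mononucleotide run (bp), default 8.
#' @param ms_min_copies minimum total copies for 2–3 bp motifs, default 3.
#' @param min_repeat_len minimum segment length for the tandem-repeat call,
#'   default 3 (shorter duplications are indistinguishable from chance).
#' @param repeat_mismatch mismatches tolerated between segment and flank
#'   copy, default 1; applies only to segments of at least
#'   `repeat_mismatch_min_len` bp (default 5), shorter segments must match
#'   exactly.
#' @param repeat_mismatch_min_len see `repeat_mismatch`.
#' @return list `(category, motif, segment, flagged)`; `flagged` marks
#'   events whose segment could not be resolved (classified indel).
#' @export
classify_structural <- function(event, aln, topo = NULL, ms_min_run = 8L,
                                ms_min_copies = 3L, min_repeat_len = 3L,
                                repeat_mismatch = 1L,
                                repeat_mismatch_min_len = 5L) {
  gap_taxa <- strsplit(event$gap_taxa, ",")[[1L]]
  donors <- segment_donors(aln, event, gap_taxa, topo)
  if (!length(donors))
    return(list(category = "indel", motif = NA_character_,
                segment = NA_character_, flagged = TRUE))
  res <- NULL
  for (donor in donors) {
    res0 <- classify_with_donor(event, aln, donor, ms_min_run,
                                ms_min_copies, min_repeat_len,
                                repeat_mismatch, repeat_mismatch_min_len)
    if (is.null(res)) res <- res0
    if (res0$category != "indel") return(res0)
  }
  res
}

classify_with_donor <- function(event, aln, donor, ms_min_run,
                                ms_min_copies, min_repeat_len,
                                repeat_mismatch = 1L,
                                repeat_mismatch_min_len = 5L) {
  row <- aln$mat[donor, ]
  cols <- core_columns(event)
  seg <- row[cols]
  useq <- row[row != "-"]
  upos <- cumsum(row != "-")  # position in useq of each column (for non-gaps)
  si <- upos[cols[1L]]; ei <- upos[cols[length(cols)]]
  k <- length(seg)
  # rule 1: microsatellite
  p <- smallest_period(seg)
  if (p <= 3L) {
    motif <- seg[seq_len(p)]
    # extend the motif run through the donor's flanks; one interrupted
    # copy is tolerated in total (imperfect microsatellites arise as the
    # run erodes by substitution but remain slippage loci)
    budget <- new.env(); budget$left <- 1L
    count_copies <- function(start, dirn) {
      copies <- 0L; pos <- start
      repeat {
        lo <- if (dirn < 0L) pos - p + 1L else pos
        hi <- lo + p - 1L
        if (lo < 1L || hi > length(useq)) break
        if (identical(useq[lo:hi], motif)) {
          copies <- copies + 1L
          pos <- pos + dirn * p
        } else if (budget$left > 0L) {
          lo2 <- lo + dirn * p; hi2 <- lo2 + p - 1L
          if (lo2 >= 1L && hi2 <= length(useq) &&
              identical(useq[lo2:hi2], motif)) {
            budget$left <- budget$left - 1L
            copies <- copies + 1L
            pos <- pos + 2L * dirn * p
          } else break
        } else break
      }
      copies
    }
    copies <- k %/% p +
      count_copies(si - 1L, -1L) + count_copies(ei + 1L, +1L)
    run_bp <- copies * p
    ok <- if (p == 1L) run_bp >= ms_min_run else copies >= ms_min_copies
    if (ok)
      return(list(category = "microsatellite",
                  motif = paste(motif, collapse = ""),
                  segment = paste(seg, collapse = ""), flagged = FALSE))
  }
  # rule 2: tandem repeat
  if (k >= min_repeat_len) {
    allow <- if (k >= repeat_mismatch_min_len) repeat_mismatch else 0L
    up_ok <- si - k >= 1L &&
      sum(useq[(si - k):(si - 1L)] != seg) <= allow
    dn_ok <- ei + k <= length(useq) &&
      sum(useq[(ei + 1L):(ei + k)] != seg) <= allow
    if (up_ok || dn_ok)
      return(list(category = "repeat", motif = NA_character_,
                  segment = paste(seg, collapse = ""), flagged = FALSE))
  }
  list(category = "indel", motif = NA_character_,
       segment = paste(seg, collapse = ""), flagged = FALSE)
}

#' Polarize a structural event against its rank-appropriate outgroups
#'
#' Reads the rank outgroup taxa over the event span: if all of them carry
#' the segment (ungapped throughout), the derived state is absence and the
#' event a deletion; if all lack it (gapped throughout), an insertion;
#' any disagreement or partial gap yields uncertain.
#'
#' @param event one row of [extract_gap_events()] output.
#' @param topo a [dated_topology()].
#' @param aln a [plastome_alignment()].
#' @return `"insertion"`, `"deletion"` or `"uncertain"`.
#' @export
infer_structural_direction <- function(event, topo, aln) {
  if (!event$rank %in% names(topo$outgroups)) return("uncertain")
  og <- topo$outgroups[[event$rank]]
  span <- core_columns(event)
  state <- vapply(og, function(tx) {
    b <- aln$mat[tx, span]
    if (all(b != "-")) "has" else if (all(b == "-")) "lacks" else "mixed"
  }, character(1L))
  gap_taxa <- strsplit(event$gap_taxa, ",")[[1L]]
  if (all(state == "has")) {
    # ancestral presence: the gapped lineages lost the segment
    if (all(!og %in% gap_taxa)) "deletion" else "uncertain"
  } else if (all(state == "lacks")) "insertion" else "uncertain"
}

# region-map row index per alignment column (same inheritance rule as
# project_regions)
project_region_rows <- function(regions, cmap, aln_length) {
  idx <- findInterval(cmap$col_to_pos, regions$start)
  last <- NA_integer_
  for (i in seq_len(aln_length)) {
    if (!is.na(idx[i])) last <- idx[i] else idx[i] <- last
  }
  if (anyNA(idx)) idx[is.na(idx)] <- idx[which(!is.na(idx))[1L]]
  idx
}

#' Locate a structural event in the genome partition
#'
#' The location is the region label at the event's 5'-most column; events
#' spanning a region boundary keep the 5' label and are flagged. Spacer
#' events are named by their flanking genes.
#'
#' @param event one row of event table (needs `start_col`, `end_col`).
#' @param regions a [region_map()].
#' @param cmap reference coordinate map.
#' @param aln_length alignment length.
#' @return list `(location, locus, span_boundary)`.
#' @export
locate_event <- function(event, regions, cmap, aln_length) {
  rows <- project_region_rows(regions, cmap, aln_length)
  r5 <- rows[event$start_col]
  kind <- regions$kind[r5]
  locus <- if (kind == "spacer") spacer_name(regions, r5) else regions$gene[r5]
  list(location = kind, locus = locus,
       span_boundary = length(unique(rows[event$start_col:event$end_col])) > 1L)
}

#' Call and classify all structural events
#'
#' Runs [extract_gap_events()], classifies each candidate
#' ([classify_structural()]), polarizes it ([infer_structural_direction()]),
#' locates it in the genome partition ([locate_event()]), and appends
#' stem-loop inversions from [detect_inversions()]. Inversions are
#' non-directional: their `direction` is NA by construction.
#'
#' @param aln a [plastome_alignment()].
#' @param topo a [dated_topology()].
#' @param regions optional [region_map()].
#' @param min_stem,max_loop inversion detector parameters.
#' @param inversions optional precomputed [detect_inversions()] output
#'   (avoids detecting twice when the caller also needs the loop spans to
#'   mask the SNP census).
#' @param ... classification thresholds passed to [classify_structural()].
#' @return data.frame, one row per event: category, span, length, motif,
#'   carriers, branch, rank, direction, location, locus, loop/stem lengths.
#' @export
call_structural_events <- function(aln, topo, regions = NULL,
                                   min_stem = 7L, max_loop = 100L,
                                   inversions = NULL, ...) {
  ev <- extract_gap_events(aln, topo)
  n <- nrow(ev)
  out <- data.frame(
    category = character(n), start_col = ev$start_col, end_col = ev$end_col,
    length = ev$length, core = ev$core,
    motif = NA_character_, segment = NA_character_,
    carriers = ev$carriers, gap_taxa = ev$gap_taxa, branch = ev$branch,
    rank = ev$rank, parallel = ev$parallel, direction = NA_character_,
    location = NA_character_, locus = NA_character_, span_boundary = FALSE,
    loop_length = NA_integer_, stem_length = NA_integer_,
    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    e <- ev[i, ]
    cl <- classify_structural(e, aln, topo, ...)
    out$category[i] <- cl$category
    out$motif[i] <- cl$motif
    out$segment[i] <- cl$segment
    out$flagged[i] <- cl$flagged
    out$direction[i] <- infer_structural_direction(e, topo, aln)
  }
  inv <- if (is.null(inversions))
    detect_inversions(aln, topo, min_stem = min_stem, max_loop = max_loop)
  else inversions
  if (nrow(inv)) {
    invdf <- data.frame(
      category = "inversion", start_col = inv$start_col,
      end_col = inv$end_col, length = inv$loop_length, core = NA_character_,
      motif = NA_character_,
      segment = NA_character_, carriers = inv$carriers,
      gap_taxa = NA_character_, branch = inv$branch, rank = inv$rank,
      parallel = inv$parallel, direction = NA_character_,
      location = NA_character_, locus = NA_character_, span_boundary = FALSE,
      loop_length = inv$loop_length, stem_length = inv$stem_length,
      flagged = !inv$polarity_known, stringsAsFactors = FALSE)
    out <- rbind(out, invdf)
  }
  if (!is.null(regions) && nrow(out)) {
    cmap <- build_coordinate_map(aln, aln$reference)
    for (i in seq_len(nrow(out))) {
      loc <- locate_event(out[i, ], regions, cmap, aln$length)
      out$location[i] <- loc$location
      out$locus[i] <- loc$locus
      out$span_boundary[i] <- loc$span_boundary
    }
  }
  rownames(out) <- NULL
  out
}

size_class_indel <- function(len) {
  cut(len, breaks = c(0, 10, 50, 100, Inf),
      labels = c("1-10", "11-50", "51-100", ">100"))
}

size_class_repeat <- function(len) {
  ifelse(len > 10L, ">10", as.character(len))
}

#' Summarize structural events (counts, sizes, locations, directions)
#'
#' Produces per-category rank counts, the indel and repeat size-class
#' histograms, location counts, direction counts, and the exact test of
#' direction bias (insertions vs deletions against 1:1) per category.
#'
#' @param events event table from [call_structural_events()].
#' @return list of data.frames: `by_rank`, `indel_sizes`, `repeat_sizes`,
#'   `by_location`, `by_direction`, `direction_tests`.
#' @export
summarize_structural <- function(events) {
  cats <- c("indel", "repeat", "microsatellite", "inversion")
  tab <- function(f) {
    if (!nrow(events))
      return(data.frame(category = cats, value = NA_character_, count = 0L,
                        stringsAsFactors = FALSE))
    d <- as.data.frame(table(factor(events$category, levels = cats),
                             f), stringsAsFactors = FALSE)
    names(d) <- c("category", "value", "count")
    d
  }
  by_rank <- tab(events$rank)
  ind <- events[events$category == "indel", , drop = FALSE]
  rep_ <- events[events$category == "repeat", , drop = FALSE]
  indel_sizes <- as.data.frame(table(size_class_indel(ind$length)),
                               stringsAsFactors = FALSE)
  names(indel_sizes) <- c("size_class", "count")
  repeat_sizes <- as.data.frame(table(factor(size_class_repeat(rep_$length),
                                             levels = c(as.character(3:10), ">10"))),
                                stringsAsFactors = FALSE)
  names(repeat_sizes) <- c("size_bp", "count")
  by_location <- tab(events$location)
  by_direction <- tab(events$direction)
  dtests <- do.call(rbind, lapply(c("indel", "repeat", "microsatellite"),
                                  function(cc) {
    d <- events[events$category == cc, , drop = FALSE]
    ins <- sum(d$direction %in% "insertion")
    del <- sum(d$direction %in% "deletion")
    data.frame(category = cc, insertions = ins, deletions = del,
               uncertain = sum(d$direction %in% "uncertain"),
               ratio = if (min(ins, del) > 0L)
                 round(max(ins, del) / min(ins, del), 1L) else NA_real_,
               p_value = if (ins + del > 0L)
                 direction_bias_test(ins, del) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(by_rank = by_rank, indel_sizes = indel_sizes,
       repeat_sizes = repeat_sizes, by_location = by_location,
       by_direction = by_direction, direction_tests = dtests)
}
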