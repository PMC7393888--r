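# shared fixtures: the seven study taxa, tiny alignments built per test,
# and an independent parsimony oracle used against the Fitch machinery

TOPO <- calycanthaceae_topology()
TAXA <- TOPO$tips
ING <- TOPO$ingroup_tips

# alignment from per-taxon strings (named, equal length)
aln_from <- function(..., reference = NULL) {
  seqs <- c(...)
  plastome_alignment(seqs, reference = reference)
}

# one alignment column as a named base vector over all 7 taxa
col_states <- function(...) {
  st <- setNames(rep("A", length(TAXA)), TAXA)
  over <- c(...)
  st[names(over)] <- over
  st
}

# blind exhaustive parsimony oracle: enumerate every assignment of the
# internal nodes over the observed alleles, count changes, and collect the
# single-change edges and the derived-state multisets of minimal
# reconstructions (independent of the package's Fitch implementation)
parsimony_oracle <- function(states, topo) {
  obs <- sort(unique(states[!is.na(states) & states %in% c("A", "C", "G", "T")]))
  internal <- setdiff(unique(c(names(topo$children), "root")), topo$tips)
  grid <- do.call(expand.grid,
                  c(rep(list(obs), length(internal)),
                    list(stringsAsFactors = FALSE)))
  names(grid) <- internal
  nch <- integer(nrow(grid))
  change_edges <- vector("list", nrow(grid))
  derived_dup <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    asg <- as.character(grid[i, ]); names(asg) <- internal
    ch <- character(); der <- character()
    for (nd in names(topo$parent)) {
      pst <- asg[[topo$parent[[nd]]]]
      cst <- if (nd %in% topo$tips) states[[nd]] else asg[[nd]]
      if (nd %in% topo$tips && (is.na(cst) || !cst %in% c("A", "C", "G", "T")))
        next  # missing tip matches anything
      if (cst != pst) { ch <- c(ch, nd); der <- c(der, cst) }
    }
    nch[i] <- length(ch)
    change_edges[[i]] <- ch
    derived_dup[i] <- anyDuplicated(der) > 0L
  }
  minc <- min(nch)
  single_edges <- unique(unlist(change_edges[nch == minc]))
  list(min_changes = minc,
       edges = if (minc == 1L) sort(single_edges) else character(),
       parallel = any(derived_dup[nch == minc]))
}

# write a minimal GFF3 annotation to a temp file
write_test_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

rc_chars <- function(x) rev(unname(c(A = "T", C = "G", G = "C", T = "A")[x]))

# brute-force re-implementation of the window predicate: enumerate every
# candidate window and apply the same criteria through independent code
brute_force_windows <- function(rowA, rowB, min_stem = 7L, max_loop = 100L,
                                loop_identity = 0.8, stem_mismatch = 2L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- length(rowA)
  valid <- rowA %in% names(comp) & rowB %in% names(comp)
  stem_of <- function(row, s, e) {
    k <- 0L; bad <- 0L; q <- 0L
    while (q < 60L && s - q - 1L >= 1L && e + q + 1L <= L) {
      i1 <- s - q - 1L; i2 <- e + q + 1L
      if (!valid[i1] || !valid[i2]) break
      if (row[i1] == comp[[row[i2]]]) k <- q + 1L
      else { bad <- bad + 1L; if (bad > stem_mismatch) break }
      q <- q + 1L
    }
    k
  }
  found <- list()
  for (s in seq_len(L - 1L)) {
    if (!valid[s] || rowA[s] == rowB[s]) next
    for (e in (s + 1L):min(L, s + max_loop - 1L)) {
      if (!valid[e] || rowA[e] == rowB[e]) next
      idx <- s:e
      if (!all(valid[idx])) break
      rc_id <- mean(rowB[idx] == comp[rowA[(s + e) - idx]])
      if (rc_id < loop_identity) next
      if (mean(rowB[idx] == rowA[idx]) >= rc_id) next
      kA <- stem_of(rowA, s, e); if (kA < min_stem) next
      kB <- stem_of(rowB, s, e); if (kB < min_stem) next
      found[[length(found) + 1L]] <- c(s, e, e - s + 1L, min(kA, kB))
    }
  }
  if (!length(found)) return(matrix(numeric(0), ncol = 4))
  m <- unique(do.call(rbind, found))
  keep <- vapply(seq_len(nrow(m)), function(i)
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           (m[, 1] < m[i, 1] | m[, 2] > m[i, 2])), logical(1L))
  m <- m[keep, , drop = FALSE]
  m[order(m[, 1]), , drop = FALSE]
}

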