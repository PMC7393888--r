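# Lineage state during simulation: integer column ids plus bases. Column
# ids are global and never reused; the master column order interleaves all
# insertions, so the true alignment falls out of the bookkeeping with no
# realignment step.

new_truth_row <- function(branch, kind, direction, ids, anc = NA, der = NA,
                          segment = NA) {
  data.frame(branch = branch, kind = kind, direction = direction,
             ids = paste(ids, collapse = ","), anc = anc, der = der,
             segment = segment, stringsAsFactors = FALSE)
}

#' Evolve a root genome along the dated topology
#'
#' Events are drawn per branch as Poisson with expectation rate x current
#' sequence length x branch duration (My). Substitutions draw a directed
#' class from the 12-class weights and then a uniform site currently
#' carrying the source base, so realized class proportions follow the
#' weights. Indels delete (or insert) noncoding segments with the
#' configured size and direction distributions; repeats duplicate (or
#' de-duplicate) an adjacent noncoding segment; microsatellite loci mutate
#' by whole-motif slippage; inversions reverse-complement the loop of a
#' planted inverted-repeat substrate once per lineage. Structural events
#' are restricted to noncoding sequence and keep clear of the planted
#' substrate loci, which have their own processes. Overlap conflicts are
#' resolved by redraw (bounded retries).
#'
#' @param root output of [generate_root()].
#' @param topo a [dated_topology()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `aln` (a [plastome_alignment()], reference from config),
#'   `regions` (region map in reference coordinates), `truth` (event log
#'   with alignment spans and carriers), `master` (column id order).
#' @export
evolve <- function(root, topo, config, seed) {
  set.seed(seed + 1L)
  L0 <- length(root$seq)
  # region row of each original id; inserted ids inherit their anchor's row
  reg_of_id <- findInterval(seq_len(L0), root$regions$start)
  noncoding_row <- root$regions$kind != "exon"
  # per-unit rate multiplier (hotspot scenario)
  unit_mult <- rep(1, nrow(root$regions))
  if (config$hotspot_multiplier != 1) {
    # hotspots are noncoding: the co-localization scenario is elevated
    # substitution and structural activity in the same spacer/intron units
    nc_rows <- which(noncoding_row)
    nh <- max(1L, round(length(nc_rows) * config$hotspot_fraction))
    hot <- sample(nc_rows, nh)
    unit_mult[hot] <- config$hotspot_multiplier
  }
  # protected zones: planted microsatellite loci and inversion substrates
  protect <- rep(FALSE, L0)
  mark <- function(s, e, pad = 2L) {
    s <- max(1L, s - pad); e <- min(L0, e + pad)
    protect[s:e] <<- TRUE
  }
  if (nrow(root$ms_loci))
    for (i in seq_len(nrow(root$ms_loci)))
      mark(root$ms_loci$start[i], root$ms_loci$end[i])
  if (nrow(root$inv_substrates))
    for (i in seq_len(nrow(root$inv_substrates)))
      mark(root$inv_substrates$loop_start[i] -
             root$inv_substrates$stem_length[i],
           root$inv_substrates$loop_end[i] +
             root$inv_substrates$stem_length[i], pad = 4L)

  master <- seq_len(L0)
  next_id <- L0 + 1L
  id_region <- reg_of_id  # grows as ids are created
  truth <- list()
  ms_anchor_ids <- lapply(seq_len(nrow(root$ms_loci)), function(i)
    root$ms_loci$start[i]:root$ms_loci$end[i])
  inv_loop_ids <- lapply(seq_len(nrow(root$inv_substrates)), function(i)
    root$inv_substrates$loop_start[i]:root$inv_substrates$loop_end[i])

  new_ids <- function(k, region_row) {
    ids <- next_id:(next_id + k - 1L)
    next_id <<- next_id + k
    id_region[ids] <<- region_row
    ids
  }
  insert_master <- function(anchor_id, ids) {
    at <- if (anchor_id == 0L) 0L else match(anchor_id, master)
    master <<- append(master, ids, after = at)
  }
  log_event <- function(...) truth[[length(truth) + 1L]] <<- new_truth_row(...)

  draw_indel_size <- function() {
    cls <- sample(4L, 1L, prob = config$indel_size_probs)
    switch(cls, sample(1:10, 1L), sample(11:50, 1L), sample(51:100, 1L),
           sample(101:364, 1L))
  }
  draw_repeat_size <- function() {
    k <- sample(9L, 1L, prob = config$repeat_size_weights)
    if (k == 9L) sample(11:22, 1L) else k + 2L
  }

  evolve_branch <- function(state, branch) {
    ids <- state$ids; bases <- state$bases
    used_inv <- state$used_inv
    dur <- topo$age[[topo$parent[[branch]]]] - topo$age[[branch]]
    Lc <- length(ids)
    claimed <- integer()  # ids touched by a structural event on this branch
    protect_ok <- function(sel_ids)
      all(sel_ids > L0 | !protect[pmin(sel_ids, L0)])
    free_of_claims <- function(pos_span) {
      # include 2 neighbours each side so adjacent events stay separable
      lo <- max(1L, min(pos_span) - 2L); hi <- min(length(ids), max(pos_span) + 2L)
      !any(ids[lo:hi] %in% claimed)
    }
    claim <- function(pos_span) {
      lo <- max(1L, min(pos_span) - 2L); hi <- min(length(ids), max(pos_span) + 2L)
      claimed <<- c(claimed, ids[lo:hi])
    }
    noncoding_at <- function(pos) noncoding_row[id_region[ids[pos]]]
    # ---- structural events --------------------------------------------
    n_ind <- rpois(1L, config$indel_rate * Lc * dur)
    n_rep <- rpois(1L, config$repeat_rate * Lc * dur)
    n_ms <- rpois(1L, config$ms_rate * Lc * dur)
    n_inv <- rpois(1L, config$inv_rate * Lc * dur)
    hot_w <- function(pos) unit_mult[id_region[ids[pos]]]
    for (j in seq_len(n_ind)) {
      is_del <- runif(1L) < config$del_ins_odds / (config$del_ins_odds + 1)
      k <- draw_indel_size()
      for (try in 1:50) {
        p <- sample(length(ids) - k, 1L, prob = hot_w(seq_len(length(ids) - k)))
        span <- p:(p + k - 1L)
        if (is_del) {
          if (all(noncoding_at(span)) && protect_ok(ids[span]) &&
              free_of_claims(span)) {
            claim(span)
            log_event(branch, "indel", "deletion", ids[span])
            ids <- ids[-span]; bases <- bases[-span]
            break
          }
        } else {
          if (noncoding_at(p) && protect_ok(ids[p]) && free_of_claims(p)) {
            claim(p)
            seg <- rand_bases(k, config$gc)
            nid <- new_ids(k, id_region[ids[p]])
            insert_master(ids[p], nid)
            ids <- append(ids, nid, after = p)
            bases <- append(bases, seg, after = p)
            log_event(branch, "indel", "insertion", nid,
                      segment = paste(seg, collapse = ""))
            break
          }
        }
      }
    }
    for (j in seq_len(n_rep)) {
      gain <- runif(1L) < config$repeat_gain_prob
      k <- draw_repeat_size()
      done <- FALSE
      for (try in 1:50) {
        if (gain) {
          p <- sample(length(ids) - k, 1L, prob = hot_w(seq_len(length(ids) - k)))
          span <- p:(p + k - 1L)
          if (all(noncoding_at(span)) && protect_ok(ids[span]) &&
              free_of_claims(span)) {
            claim(span)
            seg <- bases[span]
            nid <- new_ids(k, id_region[ids[p + k - 1L]])
            insert_master(ids[p + k - 1L], nid)
            ids <- append(ids, nid, after = p + k - 1L)
            bases <- append(bases, seg, after = p + k - 1L)
            log_event(branch, "repeat", "insertion", nid,
                      segment = paste(seg, collapse = ""))
            done <- TRUE; break
          }
        } else {
          # loss: delete the second copy of an existing tandem pair
          kk <- sample(3:6, 1L)
          s <- seq_len(length(ids) - 2L * kk)
          cand <- s[vapply(s, function(p0)
            all(bases[p0:(p0 + kk - 1L)] ==
                  bases[(p0 + kk):(p0 + 2L * kk - 1L)]) &&
              all(noncoding_at(p0:(p0 + 2L * kk - 1L))) &&
              protect_ok(ids[p0:(p0 + 2L * kk - 1L)]) &&
              free_of_claims(p0:(p0 + 2L * kk - 1L)), logical(1L))]
          if (length(cand)) {
            p <- if (length(cand) == 1L) cand else sample(cand, 1L)
            claim(p:(p + 2L * kk - 1L))
            span <- (p + kk):(p + 2L * kk - 1L)
            log_event(branch, "repeat", "deletion", ids[span])
            ids <- ids[-span]; bases <- bases[-span]
            done <- TRUE; break
          }
          gain <- TRUE  # no tandem pair available: fall back to a gain
        }
      }
    }
    for (j in seq_len(n_ms)) {
      if (!length(ms_anchor_ids)) break
      li <- sample(length(ms_anchor_ids), 1L)
      motif <- strsplit(root$ms_loci$motif[li], "")[[1L]]
      pd <- length(motif)
      present <- which(ids %in% ms_anchor_ids[[li]])
      if (!length(present)) next
      a <- min(present); b <- max(present)
      # slippage needs an intact repeat structure: a locus eroded by
      # substitution stops slipping
      if (any(bases[a:b] != rep_len(motif, b - a + 1L))) next
      # maximal motif run containing the locus
      while (a - pd >= 1L &&
             all(bases[(a - pd):(a - 1L)] == bases[a:(a + pd - 1L)])) a <- a - pd
      while (b + pd <= length(ids) &&
             all(bases[(b + 1L):(b + pd)] == bases[(b - pd + 1L):b])) b <- b + pd
      # a chance extension of the run across a region boundary must not
      # pull coding bases into a slippage event
      while (a <= b && !noncoding_at(a)) a <- a + pd
      while (b >= a && !noncoding_at(b)) b <- b - pd
      if (b - a + 1L < pd) next
      run_copies <- (b - a + 1L) %/% pd
      min_copies <- if (pd == 1L) 8L else 3L
      if (!free_of_claims(a:b)) next
      expand <- runif(1L) < 0.5 || run_copies <= min_copies
      claim(a:b)
      # slippage acts on a random copy of the run, so independent events
      # in different lineages rarely hit identical columns
      cp <- sample(run_copies, 1L)
      at <- a + (cp - 1L) * pd
      if (expand) {
        nid <- new_ids(pd, id_region[ids[at]])
        insert_master(ids[at + pd - 1L], nid)
        ids <- append(ids, nid, after = at + pd - 1L)
        bases <- append(bases, motif, after = at + pd - 1L)
        log_event(branch, "microsatellite", "insertion", nid,
                  segment = paste(motif, collapse = ""))
      } else {
        span <- at:(at + pd - 1L)
        log_event(branch, "microsatellite", "deletion", ids[span])
        ids <- ids[-span]; bases <- bases[-span]
      }
    }
    for (j in seq_len(n_inv)) {
      avail <- setdiff(seq_along(inv_loop_ids), used_inv)
      if (!length(avail)) break
      li <- if (length(avail) == 1L) avail else sample(avail, 1L)
      pos <- which(ids %in% inv_loop_ids[[li]])
      if (length(pos) < 2L) next
      bases[pos] <- rev(unname(COMPLEMENT[bases[pos]]))
      used_inv <- c(used_inv, li)
      log_event(branch, "inversion", NA_character_, ids[pos])
    }
    # ---- substitutions -------------------------------------------------
    n_sub <- rpois(1L, config$sub_rate * length(ids) * dur)
    classes <- sample(DIRECTED_CLASSES, n_sub, replace = TRUE,
                      prob = config$class_weights)
    for (cl in classes) {
      src <- substr(cl, 1L, 1L); dst <- substr(cl, 4L, 4L)
      hits <- which(bases == src)
      if (!length(hits)) next
      w <- unit_mult[id_region[ids[hits]]]
      p <- if (length(hits) == 1L) hits else sample(hits, 1L, prob = w)
      bases[p] <- dst
      log_event(branch, "substitution", NA_character_, ids[p],
                anc = src, der = dst)
    }
    list(ids = ids, bases = bases, used_inv = used_inv)
  }

  tips_state <- list()
  walk <- function(node, state) {
    if (node %in% topo$tips) { tips_state[[node]] <<- state; return(invisible()) }
    for (child in topo$children[[node]])
      walk(child, evolve_branch(state, child))
  }
  walk("root", list(ids = seq_len(L0), bases = root$seq, used_inv = integer()))

  # assemble the true alignment from the column registry
  mat <- matrix("-", nrow = length(topo$tips), ncol = length(master),
                dimnames = list(topo$tips, NULL))
  for (tx in topo$tips) {
    st <- tips_state[[tx]]
    mat[tx, match(st$ids, master)] <- st$bases
  }
  aln <- plastome_alignment(mat, reference = config$reference)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(branch = character(), kind = character(),
               direction = character(), ids = character(), anc = character(),
               der = character(), segment = character())
  if (nrow(truth_df)) {
    pos_of <- function(idstr) {
      ids <- as.integer(strsplit(idstr, ",")[[1L]])
      range(match(ids, master))
    }
    spans <- t(vapply(truth_df$ids, pos_of, integer(2L)))
    truth_df$start_col <- spans[, 1L]
    truth_df$end_col <- spans[, 2L]
    truth_df$rank <- unname(topo$branch_rank[truth_df$branch])
    truth_df$carriers <- vapply(truth_df$branch, function(b)
      paste(tips_below(topo, b), collapse = ","), character(1L))
  }
  rownames(truth_df) <- NULL

  regions_ref <- reference_regions(tips_state[[config$reference]],
                                   id_region, root$regions)
  list(aln = aln, regions = regions_ref, truth = truth_df, master = master,
       root = root, topo = topo, config = config)
}

# region map in the reference tip's own (ungapped) coordinates, rebuilt
# from the per-id region assignment
reference_regions <- function(state, id_region, root_regions) {
  rows_of <- id_region[state$ids]
  r <- rle(rows_of)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  df <- data.frame(start = starts, end = ends,
                   kind = root_regions$kind[r$values],
                   gene = root_regions$gene[r$values],
                   strand = root_regions$strand[r$values],
                   coding = root_regions$coding[r$values],
                   stringsAsFactors = FALSE)
  # merge consecutive intervals that landed in the same kind+gene (an
  # interior deletion can split one root interval into adjacent runs)
  keep <- rep(TRUE, nrow(df))
  i <- 1L
  while (i < nrow(df)) {
    j <- i + 1L
    if (df$kind[i] == df$kind[j] &&
        identical(df$gene[i], df$gene[j])) {
      df$end[i] <- df$end[j]
      df <- df[-j, , drop = FALSE]
    } else i <- i + 1L
  }
  region_map(df, length(state$ids))
}

#' Simulate an aligned set of plastomes with ground truth
#'
#' Convenience wrapper: [generate_root()] then [evolve()].
#'
#' @param config a [sim_config()].
#' @param topo a [dated_topology()] (default [calycanthaceae_topology()]).
#' @param seed integer seed (drives both stages).
#' @return see [evolve()].
#' @export
simulate_plastomes <- function(config = sim_config(),
                               topo = calycanthaceae_topology(), seed = 1L) {
  root <- generate_root(config, seed)
  evolve(root, topo, config, seed)
}

#' Score pipeline recovery against the simulator truth log
#'
#' Structural calls are matched to truth events by same category and
#' reciprocal span overlap >= 50%; substitution calls by column identity.
#' Matching runs over all events regardless of branch, so a call whose
#' footprint comes from an outgroup-branch truth event is not a false
#' positive; the reported metrics then cover the ingroup census: recall is
#' over truth events on ingroup branches, precision over calls not
#' assigned to outgroup branches. Direction accuracy is measured over
#' matched direction-known calls, rank accuracy over matched calls with an
#' unambiguous rank.
#'
#' @param truth truth log from [evolve()].
#' @param snps SNP table from [annotate_snps()].
#' @param events event table from [call_structural_events()].
#' @return list: `by_category` data.frame (category, n_truth, n_called,
#'   matched, precision, recall), `direction_accuracy`, `rank_accuracy`,
#'   `snp_direction_accuracy`, `snp_rank_accuracy`.
#' @export
score_recovery <- function(truth, snps, events, topo = NULL) {
  if (is.null(topo)) topo <- calycanthaceae_topology()
  cats <- c("indel", "repeat", "microsatellite", "inversion")
  truth <- drop_unobservable_truth(truth, topo)
  truth_kind <- truth$kind
  truth_kind[truth_kind == "substitution"] <- "snp"
  res <- list()
  dir_ok <- dir_tot <- rank_ok <- rank_tot <- 0L
  for (cc in cats) {
    td <- truth[truth_kind == cc, , drop = FALSE]
    cd <- events[events$category == cc, , drop = FALSE]
    t_in <- td$rank != "outgroup"
    # the census covers rank-assigned calls; rank-ambiguous calls are
    # superposed footprints of events on different branches and are
    # reported but not counted against precision
    c_in <- !cd$rank %in% c("outgroup", "ambiguous")
    matched_t <- logical(nrow(td)); matched_c <- logical(nrow(cd))
    for (i in order(-t_in)) {
      if (!nrow(td)) break
      tl <- td$end_col[i] - td$start_col[i] + 1L
      best <- 0L; bj <- NA_integer_
      for (j in which(!matched_c)) {
        ov <- min(td$end_col[i], cd$end_col[j]) -
          max(td$start_col[i], cd$start_col[j]) + 1L
        cl <- cd$end_col[j] - cd$start_col[j] + 1L
        if (ov >= 0.5 * tl && ov >= 0.5 * cl && ov > best) { best <- ov; bj <- j }
      }
      if (!is.na(bj)) {
        matched_t[i] <- TRUE; matched_c[bj] <- TRUE
        if (t_in[i] && cc != "inversion" && !is.na(cd$direction[bj]) &&
            cd$direction[bj] != "uncertain") {
          dir_tot <- dir_tot + 1L
          if (identical(cd$direction[bj], td$direction[i]))
            dir_ok <- dir_ok + 1L
        }
        if (t_in[i] && !cd$rank[bj] %in% c("ambiguous", "outgroup")) {
          rank_tot <- rank_tot + 1L
          if (identical(cd$rank[bj], td$rank[i])) rank_ok <- rank_ok + 1L
        }
      }
    }
    res[[cc]] <- data.frame(
      category = cc, n_truth = sum(t_in), n_called = sum(c_in),
      matched = sum(matched_t & t_in),
      precision = if (sum(c_in)) sum(matched_c & c_in) / sum(c_in) else NA_real_,
      recall = if (sum(t_in)) sum(matched_t & t_in) / sum(t_in) else NA_real_,
      stringsAsFactors = FALSE)
  }
  # substitutions: ingroup-branch columns carrying exactly one truth event
  ts <- truth[truth_kind == "snp" & truth$rank != "outgroup", , drop = FALSE]
  single <- ts[!(ts$start_col %in% ts$start_col[duplicated(ts$start_col)]), ,
               drop = FALSE]
  m <- match(single$start_col, snps$column)
  hit <- !is.na(m)
  sdir_tot <- srank_tot <- sdir_ok <- srank_ok <- 0L
  for (i in which(hit)) {
    r <- snps[m[i], ]
    if (r$direction_known) {
      sdir_tot <- sdir_tot + 1L
      if (identical(r$ancestral, single$anc[i])) sdir_ok <- sdir_ok + 1L
    }
    if (r$rank != "ambiguous" && !r$parallel) {
      srank_tot <- srank_tot + 1L
      if (identical(r$rank, single$rank[i])) srank_ok <- srank_ok + 1L
    }
  }
  list(by_category = do.call(rbind, res),
       direction_accuracy = if (dir_tot) dir_ok / dir_tot else NA_real_,
       direction_n = dir_tot,
       rank_accuracy = if (rank_tot) rank_ok / rank_tot else NA_real_,
       snp_direction_accuracy = if (sdir_tot) sdir_ok / sdir_tot else NA_real_,
       snp_direction_n = sdir_tot,
       snp_rank_accuracy = if (srank_tot) srank_ok / srank_tot else NA_real_)
}

#' Write a simulated dataset to standard files
#'
#' Emits the alignment (FASTA), the reference annotation (GFF3), the dated
#' tree (Newick, ages as node labels) and the truth log (TSV) into a
#' directory, the same formats the analysis stages consume.
#'
#' @param sim output of [evolve()] / [simulate_plastomes()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths (named list).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(alignment = file.path(dir, "alignment.fasta"),
                annotation = file.path(dir, "ref.gff3"),
                tree = file.path(dir, "tree.nwk"),
                truth = file.path(dir, "truth.tsv"))
  write_alignment(sim$aln, paths$alignment)
  write_gff3(sim$regions, paths$annotation, seqid = sim$aln$reference)
  write_dated_tree(sim$topo, paths$tree)
  write_tsv_report(sim$truth, paths$truth,
                   "simulator truth log (one row per generated event)")
  invisible(paths)
}

# Independent identical events in the two lineages flanking the ingroup
# root (the subfamily tip and the subfamily crown) jointly produce a
# family-stem pattern: every ingroup taxon carries the derived state, so
# nothing is observable at subfamily/genus/species rank. Such truth groups
# are excluded from recovery scoring: for inversions when every ingroup
# tip has equal flip parity, for gap events when the combined carriers
# cover the whole ingroup.
drop_unobservable_truth <- function(truth, topo) {
  if (!nrow(truth)) return(truth)
  structural <- truth$kind != "substitution"
  key <- paste(truth$kind, truth$start_col, truth$end_col)
  drop <- rep(FALSE, nrow(truth))
  for (k in unique(key[structural])) {
    idx <- which(key == k & structural)
    if (length(idx) < 2L) next
    carr <- lapply(strsplit(truth$carriers[idx], ","), intersect,
                   x = topo$ingroup_tips)
    if (truth$kind[idx[1L]] == "inversion") {
      parity <- vapply(topo$ingroup_tips, function(tx)
        sum(vapply(carr, function(cs) tx %in% cs, logical(1L))) %% 2L,
        integer(1L))
      if (length(unique(parity)) == 1L) drop[idx] <- TRUE
    } else {
      if (setequal(unique(unlist(carr)), topo$ingroup_tips))
        drop[idx] <- TRUE
    }
  }
  truth[!drop, , drop = FALSE]
}
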