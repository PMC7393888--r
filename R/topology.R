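#' Construct the fixed dated topology of the study clade
#'
#' The analysis assumes one fully resolved rooted shape: an ingroup of five
#' taxa — two genera of two species each, plus a monotypic sister subfamily —
#' and two successive outgroups below the family crown:
#' `(out2,(out1,(subfam_tip,((g1_sp1,g1_sp2),(g2_sp1,g2_sp2)))))`.
#' Node ages (million years) define branch durations; every branch carries a
#' taxonomic rank label. The hierarchical outgroup scheme follows from the
#' shape: subfamily-rank changes are polarized against the two external
#' outgroups, genus-rank changes against the monotypic subfamily, and
#' species-rank changes against the two species of the sister genus.
#'
#' @param phy an `ape::phylo` tree whose internal node labels are node ages
#'   in My (tips are at age 0).
#' @return A `dated_topology` list: `tips`, `ingroup_tips`, `outgroup_tips`,
#'   `parent`, `children`, `age`, `branch_rank` (rank of the branch leading
#'   into each non-root node), `outgroups` (rank -> polarizing taxa),
#'   `genus_tips`, `crown` (ingroup MRCA node name), `ranks` (rank levels).
#' @export
dated_topology <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape phylo object")
  ntip <- length(phy$tip.label)
  if (ntip < 7L) stop("outgroups required: expected 5 ingroup taxa plus 2 outgroups")
  if (ntip > 7L) stop("expected exactly 7 taxa")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("tree must be rooted and fully resolved")
  if (is.null(phy$node.label) || any(!nzchar(phy$node.label)))
    stop("missing ages: internal node labels must carry node ages (My)")
  ages_int <- suppressWarnings(as.numeric(phy$node.label))
  if (anyNA(ages_int)) stop("missing ages: non-numeric internal node label")

  kids_of <- function(n) phy$edge[phy$edge[, 1L] == n, 2L]
  label <- function(n) if (n <= ntip) phy$tip.label[n] else NA_character_
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])

  pick_tip <- function(kids) {
    tip <- kids[kids <= ntip]
    if (length(tip) != 1L) NA_integer_ else tip
  }
  rk <- kids_of(root)
  out2 <- pick_tip(rk)
  join <- setdiff(rk, out2)
  if (is.na(out2) || join <= ntip)
    stop("topology mismatch: root must join the outermost outgroup tip to the rest")
  jk <- kids_of(join)
  out1 <- pick_tip(jk)
  crown <- setdiff(jk, out1)
  if (is.na(out1) || crown <= ntip)
    stop("outgroups required: second outgroup tip must branch below the family crown")
  ck <- kids_of(crown)
  subfam_tip <- pick_tip(ck)
  subcrown <- setdiff(ck, subfam_tip)
  if (is.na(subfam_tip) || subcrown <= ntip)
    stop("topology mismatch: family crown must join the monotypic subfamily tip to the 4-taxon clade")
  gk <- kids_of(subcrown)
  if (any(gk <= ntip))
    stop("topology mismatch: expected two two-species genera")
  g1 <- gk[1L]; g2 <- gk[2L]
  g1_tips <- kids_of(g1); g2_tips <- kids_of(g2)
  if (any(g1_tips > ntip) || any(g2_tips > ntip))
    stop("topology mismatch: genus crowns must each hold two species tips")

  genus_label <- function(tips) {
    labs <- phy$tip.label[tips]
    pre <- sub("_.*$", "", labs)
    if (length(unique(pre)) == 1L) pre[1L] else paste(labs, collapse = "+")
  }
  g1_lab <- genus_label(g1_tips); g2_lab <- genus_label(g2_tips)
  if (identical(g1_lab, g2_lab)) { g1_lab <- paste0(g1_lab, "_1"); g2_lab <- paste0(g2_lab, "_2") }

  node_name <- setNames(rep(NA_character_, ntip + phy$Nnode), seq_len(ntip + phy$Nnode))
  node_name[seq_len(ntip)] <- phy$tip.label
  node_name[as.character(root)] <- "root"
  node_name[as.character(join)] <- "outgroup_join"
  node_name[as.character(crown)] <- "family_crown"
  node_name[as.character(subcrown)] <- "subfamily_crown"
  node_name[as.character(g1)] <- paste0("crown_", g1_lab)
  node_name[as.character(g2)] <- paste0("crown_", g2_lab)

  age <- setNames(c(rep(0, ntip), ages_int), node_name)
  parent <- setNames(node_name[as.character(phy$edge[, 1L])],
                     node_name[as.character(phy$edge[, 2L])])
  for (nd in names(parent))
    if (age[nd] >= age[parent[nd]])
      stop(sprintf("validation error: node '%s' (age %g) not younger than its parent (age %g)",
                   nd, age[nd], age[parent[nd]]))
  children <- split(names(parent), unname(parent))

  sp1 <- paste0("species_", g1_lab); sp2 <- paste0("species_", g2_lab)
  branch_rank <- setNames(rep("outgroup", length(parent)), names(parent))
  branch_rank[phy$tip.label[g1_tips]] <- sp1
  branch_rank[phy$tip.label[g2_tips]] <- sp2
  branch_rank[paste0("crown_", g1_lab)] <- "genus"
  branch_rank[paste0("crown_", g2_lab)] <- "genus"
  branch_rank[phy$tip.label[subfam_tip]] <- "subfamily"
  branch_rank["subfamily_crown"] <- "subfamily"

  outgroups <- list(subfamily = phy$tip.label[c(out1, out2)],
                    genus = phy$tip.label[subfam_tip])
  outgroups[[sp1]] <- phy$tip.label[g2_tips]
  outgroups[[sp2]] <- phy$tip.label[g1_tips]

  structure(list(
    tips = phy$tip.label,
    ingroup_tips = phy$tip.label[c(g1_tips, g2_tips, subfam_tip)],
    outgroup_tips = phy$tip.label[c(out1, out2)],
    parent = parent, children = children, age = age,
    branch_rank = branch_rank, outgroups = outgroups,
    genus_tips = setNames(list(phy$tip.label[g1_tips], phy$tip.label[g2_tips]),
                          c(g1_lab, g2_lab)),
    crown = "family_crown",
    ranks = c("subfamily", "genus", sp1, sp2),
    phy = phy), class = "dated_topology")
}

#' @export
print.dated_topology <- function(x, ...) {
  cat(sprintf("dated_topology: %d ingroup + %d outgroup taxa; crown age %.1f My\n",
              length(x$ingroup_tips), length(x$outgroup_tips),
              x$age["family_crown"]))
  invisible(x)
}

#' Read a dated rooted topology from Newick
#'
#' Internal node labels must carry the node ages in million years; tips sit
#' at age 0 (the tree is ultrametric by construction). The topology must
#' match the fixed study shape (see [dated_topology()]).
#'
#' @param path Newick file.
#' @return A [dated_topology()].
#' @export
read_dated_tree <- function(path) {
  if (!file.exists(path)) stop(sprintf("tree file not found: %s", path))
  dated_topology(ape::read.tree(path))
}

#' Write a dated topology to Newick (ages as internal node labels)
#' @param topo a [dated_topology()].
#' @param path output file.
#' @export
write_dated_tree <- function(topo, path) {
  phy <- topo$phy
  writeLines(ape::write.tree(phy), path)
  invisible(path)
}

#' The Calycanthaceae study topology
#'
#' Five ingroup plastomes (two *Calycanthus*, two *Chimonanthus*,
#' *Idiospermum*) with two Magnoliaceae outgroups, dated at the crown nodes:
#' 108.8 My (subfamily split), 18.7 My (genus split), 7.6 and 6.2 My
#' (species splits). The two outgroup attachment ages default to 125 and
#' 140 My; they only set outgroup branch durations and never enter the
#' ingroup rate denominators.
#'
#' @param outgroup_ages ages (My) of the two outgroup attachment nodes.
#' @return A [dated_topology()].
#' @export
calycanthaceae_topology <- function(outgroup_ages = c(125, 140)) {
  nwk <- sprintf(paste0(
    "(Magnolia_kwangsiensis,(Liriodendron_tulipifera,",
    "(Idiospermum_australiense,((Calycanthus_chinensis,Calycanthus_floridus)7.6,",
    "(Chimonanthus_nitens,Chimonanthus_praecox)6.2)18.7)108.8)%g)%g;"),
    outgroup_ages[1L], outgroup_ages[2L])
  dated_topology(ape::read.tree(text = nwk))
}

#' Tips descending from a node (the node itself if terminal)
#' @param topo a [dated_topology()].
#' @param node node name.
#' @return character vector of tip names.
#' @export
tips_below <- function(topo, node) {
  if (node %in% topo$tips) return(node)
  unlist(lapply(topo$children[[node]], tips_below, topo = topo),
         use.names = FALSE)
}

#' Total additive branch time of the ingroup (My)
#'
#' Sum over ingroup branches (every branch below the family crown) of
#' parent age minus child age; terminals contribute their full subtending
#' branch. This is the time denominator for structural mutation rates.
#'
#' @param topo a [dated_topology()].
#' @return total branch time in million years.
#' @export
additive_time <- function(topo) {
  br <- names(topo$branch_rank)[topo$branch_rank != "outgroup"]
  sum(topo$age[topo$parent[br]] - topo$age[br])
}

#' Age of the most recent common ancestor of two taxa
#' @param topo a [dated_topology()].
#' @param a,b tip names.
#' @return MRCA age in My (0 if `a == b`).
#' @export
mrca_age <- function(topo, a, b) {
  if (identical(a, b)) return(0)
  anc <- function(n) {
    path <- n
    while (n %in% names(topo$parent)) { n <- topo$parent[[n]]; path <- c(path, n) }
    path
  }
  pa <- anc(a)
  for (n in anc(b)) if (n %in% pa) return(unname(topo$age[[n]]))
  stop("taxa share no ancestor")
}

## ---- Fitch small parsimony on the fixed topology -------------------------

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
MISSING_BITS <- 15L

encode_bits <- function(states) {
  b <- unname(BASE_BITS[states])
  b[is.na(b)] <- MISSING_BITS
  b
}

postorder_internal <- function(topo) {
  ord <- character()
  walk <- function(n) {
    if (n %in% topo$tips) return(invisible())
    for (k in topo$children[[n]]) walk(k)
    ord <<- c(ord, n)
  }
  walk("root")
  ord
}

#' Minimum number of state changes (Fitch down-pass), vectorized over sites
#'
#' @param tip_bits integer matrix (taxa x sites) of bit-encoded states
#'   (A=1, C=2, G=4, T=8; missing = 15). Row names must name the tips.
#' @param topo a [dated_topology()].
#' @return integer vector of minimum change counts per site.
#' @export
fitch_min_changes <- function(tip_bits, topo) {
  S <- ncol(tip_bits)
  counts <- integer(S)
  sets <- list()
  for (tx in topo$tips) sets[[tx]] <- tip_bits[tx, ]
  for (nd in postorder_internal(topo)) {
    kids <- topo$children[[nd]]
    a <- sets[[kids[1L]]]; b <- sets[[kids[2L]]]
    inter <- bitwAnd(a, b)
    empty <- inter == 0L
    counts <- counts + as.integer(empty)
    inter[empty] <- bitwOr(a, b)[empty]
    sets[[nd]] <- inter
  }
  counts
}

# per-edge candidate test: a single change on the branch into `node` explains
# the site iff the tips below are monochrome in one state and all remaining
# tips monochrome in a different state (missing tips match anything).
single_change_candidates <- function(tip_bits, topo) {
  S <- ncol(tip_bits)
  edges <- names(topo$parent)
  res <- list()
  for (nd in edges) {
    below <- tips_below(topo, nd)
    above <- setdiff(topo$tips, below)
    band <- Reduce(bitwAnd, lapply(below, function(t) tip_bits[t, ]),
                   rep(MISSING_BITS, S))
    aand <- Reduce(bitwAnd, lapply(above, function(t) tip_bits[t, ]),
                   rep(MISSING_BITS, S))
    ok <- band %in% BASE_BITS & aand %in% BASE_BITS & band != aand
    res[[nd]] <- list(ok = ok, derived = band)
  }
  res
}

# exhaustive minimal-reconstruction check used only for sites whose Fitch
# minimum is >= 2: does some minimal reconstruction contain two or more
# changes to the same derived state (a parallel gain)?
has_parallel_gain <- function(bits, topo) {
  alleles <- unname(BASE_BITS[vapply(BASE_BITS, function(b)
    any(bits != MISSING_BITS & bitwAnd(bits, b) > 0L), logical(1L))])
  if (length(alleles) < 2L) return(FALSE)
  internal <- postorder_internal(topo)
  grid <- expand.grid(rep(list(alleles), length(internal)))
  names(grid) <- internal
  tipsv <- topo$tips
  nchanges <- integer(nrow(grid))
  derived_dup <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    assign_state <- unlist(grid[i, , drop = TRUE])
    names(assign_state) <- internal
    ch <- 0L
    derived <- integer(0)
    for (nd in names(topo$parent)) {
      pstate <- assign_state[[topo$parent[[nd]]]]
      if (nd %in% tipsv) {
        tb <- bits[match(nd, tipsv)]
        if (bitwAnd(tb, pstate) == 0L) { ch <- ch + 1L; derived <- c(derived, tb) }
      } else {
        cstate <- assign_state[[nd]]
        if (cstate != pstate) { ch <- ch + 1L; derived <- c(derived, cstate) }
      }
    }
    nchanges[i] <- ch
    derived_dup[i] <- anyDuplicated(derived) > 0L
  }
  any(derived_dup[nchanges == min(nchanges)])
}

#' Map polymorphic sites to branches and ranks by parsimony
#'
#' For each site, if exactly one single-change placement on the fixed
#' topology explains the observed states, the site is assigned to that
#' branch and the branch's taxonomic rank; ties yield rank `"ambiguous"`.
#' Sites whose parsimony minimum is two or more changes are checked for a
#' parallel gain (two changes to the same derived state among minimal
#' reconstructions) and get rank `"ambiguous"` either way.
#'
#' @param tip_bits integer matrix (taxa x sites), see [fitch_min_changes()];
#'   use [encode_bits()] on base characters (gaps/N become missing).
#' @param topo a [dated_topology()].
#' @return data.frame per site: `branch`, `rank`, `parallel`, `min_changes`,
#'   `derived_fitch` (bit of the derived state under the unique placement).
#' @export
map_sites_to_branches <- function(tip_bits, topo) {
  S <- ncol(tip_bits)
  minc <- fitch_min_changes(tip_bits, topo)
  cand <- single_change_candidates(tip_bits, topo)
  okmat <- vapply(cand, function(x) x$ok, logical(S))
  if (S == 1L) okmat <- matrix(okmat, nrow = 1L, dimnames = list(NULL, names(cand)))
  ncand <- rowSums(okmat)
  branch <- rep(NA_character_, S)
  rank <- rep("ambiguous", S)
  parallel <- rep(FALSE, S)
  derived <- rep(NA_integer_, S)
  one <- which(minc == 1L & ncand == 1L)
  for (i in one) {
    nd <- names(cand)[which(okmat[i, ])]
    rank[i] <- topo$branch_rank[[nd]]
    if (rank[i] != "outgroup") {
      branch[i] <- nd
      derived[i] <- cand[[nd]]$derived[i]
    }
  }
  # tied single-change placements that all sit on branches of one rank are
  # assigned that rank with no branch (e.g. the two root-child edges are
  # one unrooted edge, so an outermost-outgroup autapomorphy always ties)
  tie <- which(minc == 1L & ncand >= 2L)
  for (i in tie) {
    nds <- names(cand)[which(okmat[i, ])]
    rks <- unique(unname(topo$branch_rank[nds]))
    if (length(rks) == 1L) rank[i] <- rks
  }
  multi <- which(minc >= 2L)
  for (i in multi)
    parallel[i] <- has_parallel_gain(tip_bits[, i], topo)
  data.frame(branch = branch, rank = rank, parallel = parallel,
             min_changes = minc, derived_fitch = derived,
             stringsAsFactors = FALSE)
}

#' Map a single site (named base vector) to a branch
#' @param states named character vector taxon -> base ("A","C","G","T";
#'   anything else is treated as missing).
#' @param topo a [dated_topology()].
#' @return one-row data.frame as in [map_sites_to_branches()].
#' @export
map_to_branch <- function(states, topo) {
  bits <- matrix(encode_bits(states[topo$tips]), ncol = 1L,
                 dimnames = list(topo$tips, NULL))
  map_sites_to_branches(bits, topo)
}
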