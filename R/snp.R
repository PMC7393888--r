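COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

DIRECTED_CLASSES <- c("A->C", "A->G", "A->T", "C->A", "C->G", "C->T",
                      "G->A", "G->C", "G->T", "T->A", "T->C", "T->G")

POOLED_OF <- c("A->G" = "A->G+T->C", "T->C" = "A->G+T->C",
               "G->A" = "G->A+C->T", "C->T" = "G->A+C->T",
               "A->C" = "A->C+T->G", "T->G" = "A->C+T->G",
               "C->A" = "C->A+G->T", "G->T" = "C->A+G->T",
               "A->T" = "A->T+T->A", "T->A" = "A->T+T->A",
               "G->C" = "G->C+C->G", "C->G" = "G->C+C->G")

POOLED_CLASSES <- unique(unname(POOLED_OF))

.plastmut_cache <- new.env(parent = emptyenv())

genetic_code_11 <- function() {
  if (is.null(.plastmut_cache$code11))
    .plastmut_cache$code11 <- Biostrings::getGeneticCode("11")
  .plastmut_cache$code11
}

#' Call polymorphic alignment columns among the ingroup taxa
#'
#' A column is polymorphic if at least two distinct bases occur among the
#' five ingroup taxa and no ingroup taxon carries a gap or N there (gapped
#' columns belong to structural events; N columns are excluded as
#' unresolved). Allelism counts distinct ingroup bases.
#'
#' @param aln a [plastome_alignment()].
#' @param topo a [dated_topology()] whose taxa are all present in `aln`.
#' @return data.frame: `column`, `allelism` (2/3/4), `alleles`
#'   (collapsed string, alphabetical).
#' @export
call_polymorphic_sites <- function(aln, topo) {
  if (!all(topo$tips %in% aln$taxa))
    stop("alignment lacks taxa of the topology: ",
         paste(setdiff(topo$tips, aln$taxa), collapse = ", "))
  ing <- aln$mat[topo$ingroup_tips, , drop = FALSE]
  clean <- colSums(ing == "-" | ing == "N") == 0L
  bits <- matrix(encode_bits(ing), nrow = nrow(ing))
  orbits <- Reduce(bitwOr, lapply(seq_len(nrow(bits)), function(i) bits[i, ]))
  nall <- vapply(0:15, function(x) sum(bitwAnd(x, BASE_BITS) > 0L),
                 integer(1L))[orbits + 1L]
  keep <- which(clean & nall >= 2L)
  alleles <- vapply(keep, function(j)
    paste(sort(unique(ing[, j])), collapse = ""), character(1L))
  data.frame(column = keep, allelism = nall[keep], alleles = alleles,
             stringsAsFactors = FALSE)
}

#' Polarize one biallelic site against its rank-appropriate outgroups
#'
#' The outgroup set is chosen by the site's rank (subfamily: the two
#' external outgroups; genus: the monotypic subfamily tip; species: the two
#' species of the sister genus). If every rank-outgroup taxon carries the
#' same base and that base is one of the two ingroup alleles, that base is
#' the ancestral state and the other allele the derived state; otherwise
#' the direction is uncertain.
#'
#' @param states named base vector over all topology taxa at the column.
#' @param rank the site's rank (from [map_to_branch()]).
#' @param topo a [dated_topology()].
#' @return list `(direction_known, ancestral, derived)`.
#' @export
infer_direction <- function(states, rank, topo) {
  ing <- states[topo$ingroup_tips]
  alleles <- sort(unique(ing[ing %in% names(BASE_BITS)]))
  if (length(alleles) != 2L || !rank %in% names(topo$outgroups))
    return(list(direction_known = FALSE, ancestral = NA_character_,
                derived = NA_character_))
  og <- states[topo$outgroups[[rank]]]
  if (all(og %in% names(BASE_BITS)) && length(unique(og)) == 1L &&
      og[1L] %in% alleles) {
    anc <- unname(og[1L])
    list(direction_known = TRUE, ancestral = anc,
         derived = setdiff(alleles, anc))
  } else {
    list(direction_known = FALSE, ancestral = NA_character_,
         derived = NA_character_)
  }
}

#' Classify a polarized substitution
#'
#' Purine<->purine and pyrimidine<->pyrimidine changes are transitions; all
#' others transversions. The directed class is the ordered ancestral->derived
#' pair; the pooled class merges complementary-strand pairs (e.g. A->G with
#' T->C), since an unstranded genome cannot distinguish them.
#'
#' @param ancestral,derived single bases, distinct.
#' @return list `(ts_tv, class, pool)`.
#' @export
classify_substitution <- function(ancestral, derived) {
  if (any(!c(ancestral, derived) %in% names(BASE_BITS)) ||
      ancestral == derived)
    stop("classify_substitution requires two distinct bases in A/C/G/T")
  purine <- c("A", "G")
  ts <- (ancestral %in% purine) == (derived %in% purine)
  cls <- paste0(ancestral, "->", derived)
  list(ts_tv = if (ts) "transition" else "transversion",
       class = cls, pool = unname(POOLED_OF[cls]))
}

# alignment columns of a gene's CDS, in translation order (minus-strand
# genes reversed); returns NULL for non-coding genes
gene_cds_columns <- function(regions, cmap, gene) {
  ex <- regions[regions$kind == "exon" & regions$gene %in% gene, , drop = FALSE]
  if (nrow(ex) == 0L || !ex$coding[1L]) return(NULL)
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
  cols <- cmap$pos_to_col[pos]
  if (identical(ex$strand[1L], "-")) cols <- rev(cols)
  cols
}

#' Synonymous or nonsynonymous effect of one polarized exon SNP
#'
#' The ancestral codon is reconstructed by placing the ancestral base into
#' the reference codon context at the site (strand-aware: for minus-strand
#' genes the codon is read on the annotated strand), the derived base is
#' substituted, and the two codons are translated under the plastid
#' (bacterial, table 11) genetic code.
#'
#' @param column alignment column of the SNP.
#' @param ancestral,derived the polarized alleles (alignment strand).
#' @param gene gene name (must be protein-coding).
#' @param regions a [region_map()].
#' @param aln a [plastome_alignment()].
#' @param cmap coordinate map of the reference taxon.
#' @return list `(effect, codon_anc, codon_der, reason)`; `effect` is
#'   `"synonymous"`, `"nonsynonymous"` or NA (with `reason`) when the codon
#'   is interrupted by a reference gap.
#' @export
classify_coding_effect <- function(column, ancestral, derived, gene,
                                   regions, aln, cmap) {
  cols <- gene_cds_columns(regions, cmap, gene)
  if (is.null(cols)) return(list(effect = NA_character_, codon_anc = NA,
                                 codon_der = NA, reason = "not_coding"))
  i <- match(column, cols)
  if (is.na(i)) return(list(effect = NA_character_, codon_anc = NA,
                            codon_der = NA, reason = "not_in_cds"))
  strand <- regions$strand[regions$kind == "exon" & regions$gene %in% gene][1L]
  codon_cols <- cols[(((i - 1L) %/% 3L) * 3L) + 1:3]
  refb <- aln$mat[aln$reference, codon_cols]
  if (any(refb == "-")) return(list(effect = NA_character_, codon_anc = NA,
                                    codon_der = NA, reason = "codon_gap"))
  offset <- (i - 1L) %% 3L + 1L
  if (identical(strand, "-")) {
    refb <- unname(COMPLEMENT[refb])
    anc <- unname(COMPLEMENT[ancestral]); der <- unname(COMPLEMENT[derived])
  } else {
    anc <- ancestral; der <- derived
  }
  canc <- refb; canc[offset] <- anc
  cder <- refb; cder[offset] <- der
  code <- genetic_code_11()
  aa_anc <- code[[paste(canc, collapse = "")]]
  aa_der <- code[[paste(cder, collapse = "")]]
  list(effect = if (identical(aa_anc, aa_der)) "synonymous" else "nonsynonymous",
       codon_anc = paste(canc, collapse = ""),
       codon_der = paste(cder, collapse = ""), reason = NA_character_)
}

#' Call, map, polarize and classify all SNPs in one pass
#'
#' Orchestrates [call_polymorphic_sites()], [map_sites_to_branches()],
#' [infer_direction()], [classify_substitution()], region projection and
#' [classify_coding_effect()] into the per-site SNP table. Triallelic and
#' parallel sites are recorded but not polarized. Codons hit by more than
#' one SNP are flagged.
#'
#' Columns inside detected stem-loop inversions must be masked
#' (`mask_columns`): a reverse-complemented loop makes every mismatching
#' column look like a substitution of the complementary class, but those
#' columns record one structural event, not point mutations.
#'
#' @param aln a [plastome_alignment()].
#' @param topo a [dated_topology()].
#' @param regions optional [region_map()] on the reference taxon; without it
#'   the region/coding columns stay NA.
#' @param mask_columns columns to exclude from the SNP census (typically
#'   the loop spans of [detect_inversions()]).
#' @return data.frame, one row per polymorphic site.
#' @export
annotate_snps <- function(aln, topo, regions = NULL, mask_columns = NULL) {
  sites <- call_polymorphic_sites(aln, topo)
  if (length(mask_columns))
    sites <- sites[!(sites$column %in% mask_columns), , drop = FALSE]
  n <- nrow(sites)
  empty <- data.frame(
    column = integer(), alleles = character(), allelism = integer(),
    branch = character(), rank = character(), parallel = logical(),
    direction_known = logical(), ancestral = character(),
    derived = character(), ts_tv = character(), class = character(),
    pool = character(), region = character(), gene = character(),
    effect = character(), multi_snp_codon = logical(),
    stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  tip_bits <- matrix(encode_bits(aln$mat[topo$tips, sites$column]),
                     nrow = length(topo$tips),
                     dimnames = list(topo$tips, NULL))
  bi <- sites$allelism == 2L
  mapres <- data.frame(branch = NA_character_, rank = "ambiguous",
                       parallel = FALSE, min_changes = NA_integer_,
                       derived_fitch = NA_integer_)[rep(1L, n), ]
  if (any(bi))
    mapres[bi, ] <- map_sites_to_branches(tip_bits[, bi, drop = FALSE], topo)
  out <- cbind(sites, mapres[, c("branch", "rank", "parallel")])
  out$direction_known <- FALSE
  out$ancestral <- out$derived <- NA_character_
  pol <- which(bi & !out$parallel & out$rank != "ambiguous")
  for (i in pol) {
    d <- infer_direction(aln$mat[topo$tips, out$column[i]], out$rank[i], topo)
    out$direction_known[i] <- d$direction_known
    out$ancestral[i] <- d$ancestral
    out$derived[i] <- d$derived
  }
  out$ts_tv <- out$class <- out$pool <- NA_character_
  dk <- which(out$direction_known)
  for (i in dk) {
    cl <- classify_substitution(out$ancestral[i], out$derived[i])
    out$ts_tv[i] <- cl$ts_tv; out$class[i] <- cl$class; out$pool[i] <- cl$pool
  }
  out$region <- out$gene <- out$effect <- NA_character_
  out$multi_snp_codon <- FALSE
  if (!is.null(regions)) {
    cmap <- build_coordinate_map(aln, aln$reference)
    proj <- project_regions(regions, cmap, aln$length)
    out$region <- proj$kind[out$column]
    out$gene <- proj$gene[out$column]
    ex <- which(out$region == "exon" & out$direction_known)
    codon_id <- rep(NA_character_, n)
    for (i in ex) {
      eff <- classify_coding_effect(out$column[i], out$ancestral[i],
                                    out$derived[i], out$gene[i],
                                    regions, aln, cmap)
      out$effect[i] <- eff$effect
      cols <- gene_cds_columns(regions, cmap, out$gene[i])
      j <- match(out$column[i], cols)
      if (!is.na(j)) codon_id[i] <- paste0(out$gene[i], ":", (j - 1L) %/% 3L)
    }
    dup <- codon_id[!is.na(codon_id)]
    dup <- unique(dup[duplicated(dup)])
    out$multi_snp_codon <- !is.na(codon_id) & codon_id %in% dup
  }
  rownames(out) <- NULL
  out
}

#' Substitution spectrum over directed and pooled classes
#'
#' @param snps SNP table from [annotate_snps()].
#' @param by_rank also stratify by rank.
#' @return data.frame: `stratum`, `class`, `pool`, `count`, `percent`
#'   (percent of direction-known SNPs in the stratum, 2 dp).
#' @export
substitution_spectrum <- function(snps, by_rank = TRUE) {
  dk <- snps[snps$direction_known, , drop = FALSE]
  strata <- list(all = dk)
  if (by_rank) for (r in unique(dk$rank)) strata[[r]] <- dk[dk$rank == r, ]
  res <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    cnt <- table(factor(d$class, levels = DIRECTED_CLASSES))
    data.frame(stratum = s, class = DIRECTED_CLASSES,
               pool = unname(POOLED_OF[DIRECTED_CLASSES]),
               count = as.integer(cnt),
               percent = round(100 * as.integer(cnt) / max(1L, nrow(d)), 2L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pool a directed 12-class spectrum into the 6 complementary-pair classes
#' @param spectrum output of [substitution_spectrum()] (one stratum).
#' @return data.frame `pool`, `count`, `percent`.
#' @export
pool_spectrum <- function(spectrum) {
  agg <- aggregate(count ~ pool, data = spectrum, sum)
  agg <- agg[match(POOLED_CLASSES, agg$pool), ]
  agg$percent <- round(100 * agg$count / max(1L, sum(agg$count)), 2L)
  rownames(agg) <- NULL
  agg
}

#' Rank-by-region summary of biallelic SNPs
#'
#' The shape of the study's taxonomic/genomic distribution table: per rank
#' and genome region, the SNP count, the percent of the region length, and
#' for coding regions the nonsynonymous and synonymous counts with their
#' raw count ratio dN/dS (not a per-site-normalized estimate).
#'
#' @param snps SNP table from [annotate_snps()] (with regions projected).
#' @param regions a [region_map()].
#' @return data.frame: `rank`, `region`, `length_bp`, `count`, `percent`,
#'   `nonsynonymous`, `synonymous`, `dn_ds`.
#' @export
summarize_rank_region <- function(snps, regions) {
  lens <- c(total = attr(regions, "ref_length"),
            exon = sum(regions$end[regions$kind == "exon"] -
                         regions$start[regions$kind == "exon"] + 1L),
            intron = sum(regions$end[regions$kind == "intron"] -
                           regions$start[regions$kind == "intron"] + 1L),
            spacer = sum(regions$end[regions$kind == "spacer"] -
                           regions$start[regions$kind == "spacer"] + 1L))
  use <- snps[snps$allelism == 2L & !snps$parallel &
                snps$rank != "ambiguous", , drop = FALSE]
  ranks <- c(sort(unique(use$rank)), "total")
  rows <- list()
  for (r in ranks) {
    d <- if (r == "total") use else use[use$rank == r, , drop = FALSE]
    for (reg in c("total", "exon", "intron", "spacer")) {
      dd <- if (reg == "total") d else d[!is.na(d$region) & d$region == reg, ,
                                         drop = FALSE]
      ns <- sum(dd$effect %in% "nonsynonymous")
      sy <- sum(dd$effect %in% "synonymous")
      rows[[length(rows) + 1L]] <- data.frame(
        rank = r, region = reg, length_bp = unname(lens[reg]),
        count = nrow(dd),
        percent = round(100 * nrow(dd) / lens[reg], 2L),
        nonsynonymous = if (reg %in% c("total", "exon")) ns else NA_integer_,
        synonymous = if (reg %in% c("total", "exon")) sy else NA_integer_,
        dn_ds = if (reg %in% c("total", "exon") && sy > 0L)
          round(ns / sy, 2L) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ts/Tv and dN/dS per functional gene group
#'
#' Genes are grouped by name prefix (default groups: atp, ndh, pet, psa,
#' psb, rpl, rpo, rps); genes matching no group are reported under
#' `"other"`. Ratios are raw event-count ratios; a zero denominator yields
#' NA, never infinity.
#'
#' @param snps SNP table from [annotate_snps()].
#' @param grouping optional named character vector gene -> group label.
#' @return data.frame per group: counts of Ts, Tv, dN, dS and the ratios.
#' @export
summarize_gene_groups <- function(snps, grouping = NULL) {
  d <- snps[!is.na(snps$gene) & snps$region %in% "exon" &
              snps$direction_known, , drop = FALSE]
  if (is.null(grouping)) {
    known <- grepl("^(atp|ndh|pet|psa|psb|rpl|rpo|rps)", d$gene)
    grp <- rep("other", nrow(d))
    grp[known] <- sub("^(atp|ndh|pet|psa|psb|rpl|rpo|rps).*$", "\\1",
                      d$gene[known])
  } else {
    grp <- ifelse(d$gene %in% names(grouping), grouping[d$gene], "other")
  }
  res <- lapply(split(seq_len(nrow(d)), grp), function(idx) {
    dd <- d[idx, ]
    ts <- sum(dd$ts_tv %in% "transition"); tv <- sum(dd$ts_tv %in% "transversion")
    dn <- sum(dd$effect %in% "nonsynonymous"); ds <- sum(dd$effect %in% "synonymous")
    data.frame(ts = ts, tv = tv,
               ts_tv = if (tv > 0L) round(ts / tv, 2L) else NA_real_,
               dn = dn, ds = ds,
               dn_ds = if (ds > 0L) round(dn / ds, 2L) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio G-test of equal class proportions
#'
#' G = 2 * sum(O * ln(O / E)) against expected proportions (uniform by
#' default), with df = classes - 1 and a chi-square p-value. Classes with
#' zero observations contribute nothing to G.
#'
#' @param counts vector of class counts, total > 0.
#' @param expected_prop optional expected proportions (default uniform).
#' @return list `(G, df, p_value, expected, small_expected)`;
#'   `small_expected` flags any expected count below 1, where the
#'   chi-square approximation is unreliable and an exact multinomial test
#'   would be preferred.
#' @export
test_substitution_bias <- function(counts, expected_prop = NULL) {
  counts <- as.numeric(counts)
  if (sum(counts) <= 0) stop("total count must be positive")
  k <- length(counts)
  if (is.null(expected_prop)) expected_prop <- rep(1 / k, k)
  expected <- sum(counts) * expected_prop / sum(expected_prop)
  nz <- counts > 0
  G <- 2 * sum(counts[nz] * log(counts[nz] / expected[nz]))
  small <- any(expected < 1)
  if (small) warning("expected count < 1; chi-square approximation unreliable")
  list(G = G, df = k - 1L, p_value = pchisq(G, df = k - 1L, lower.tail = FALSE),
       expected = expected, small_expected = small)
}

#' Codon usage and amino-acid composition of one taxon's coding genes
#'
#' Reads each protein-coding gene of the region map through the alignment
#' for the given taxon (strand-aware), degaps it, and tallies codons.
#' Codons containing N are counted separately and excluded from percents.
#' Genes whose degapped length is not a multiple of 3 are skipped with a
#' warning.
#'
#' @param aln a [plastome_alignment()].
#' @param regions a [region_map()] on the reference taxon of `aln`.
#' @param taxon taxon whose codon usage is tallied.
#' @return list with data.frames `codons` (`codon`, `aa`, `count`,
#'   `percent`) and `amino_acids` (`aa`, `count`, `percent`), plus
#'   `n_codons` and `n_with_N`.
#' @export
codon_usage <- function(aln, regions, taxon = NULL) {
  if (is.null(taxon)) taxon <- aln$reference
  cmap <- build_coordinate_map(aln, aln$reference)
  genes <- unique(regions$gene[regions$kind == "exon" & regions$coding])
  codons <- character()
  for (g in genes) {
    cols <- gene_cds_columns(regions, cmap, g)
    b <- aln$mat[taxon, cols]
    strand <- regions$strand[regions$kind == "exon" & regions$gene %in% g][1L]
    if (identical(strand, "-")) b <- unname(COMPLEMENT[b])
    b <- b[b != "-"]
    if (length(b) %% 3L != 0L) {
      warning(sprintf("gene '%s': degapped length %d not a multiple of 3; skipped",
                      g, length(b)))
      next
    }
    if (!length(b)) next
    m <- matrix(b, nrow = 3L)
    codons <- c(codons, paste0(m[1L, ], m[2L, ], m[3L, ]))
  }
  withN <- grepl("N", codons)
  clean <- codons[!withN]
  code <- genetic_code_11()
  all_codons <- names(code)
  cnt <- table(factor(clean, levels = all_codons))
  cod <- data.frame(codon = all_codons, aa = unname(code),
                    count = as.integer(cnt),
                    percent = round(100 * as.integer(cnt) / max(1L, length(clean)), 2L),
                    stringsAsFactors = FALSE)
  aa <- aggregate(cbind(count = count) ~ aa, data = cod, sum)
  aa$percent <- round(100 * aa$count / max(1L, length(clean)), 2L)
  list(codons = cod, amino_acids = aa,
       n_codons = length(clean), n_with_N = sum(withN))
}
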