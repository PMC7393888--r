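#' Uncorrected pairwise p-distance over a column subset
#'
#' Mismatches divided by compared columns, after excluding columns gapped
#' or N in either taxon. An optional Jukes-Cantor correction is available;
#' the default (and the distance used throughout the association analysis)
#' is the plain p-distance.
#'
#' @param aln a [plastome_alignment()].
#' @param taxonA,taxonB taxon names.
#' @param columns optional column subset (default: all columns).
#' @param correction `"none"` (default) or `"JC69"`.
#' @return list `(gd, compared, mismatches)`; `gd` is NA (with zero
#'   `compared`) when no column is comparable.
#' @export
p_distance <- function(aln, taxonA, taxonB, columns = NULL,
                       correction = c("none", "JC69")) {
  correction <- match.arg(correction)
  if (is.null(columns)) columns <- seq_len(aln$length)
  a <- aln$mat[taxonA, columns]; b <- aln$mat[taxonB, columns]
  ok <- a %in% names(BASE_BITS) & b %in% names(BASE_BITS)
  n <- sum(ok)
  if (n == 0L) return(list(gd = NA_real_, compared = 0L, mismatches = 0L))
  mm <- sum(a[ok] != b[ok])
  p <- mm / n
  gd <- if (correction == "JC69") -3 / 4 * log(1 - 4 * p / 3) else p
  list(gd = gd, compared = n, mismatches = mm)
}

# annotation units: one unit per coding gene's exon set, per intron
# interval, per spacer interval; returns per-column unit id and kind
annotation_units <- function(regions, cmap, aln_length) {
  rows <- project_region_rows(regions, cmap, aln_length)
  kind <- regions$kind[rows]
  unit <- ifelse(kind == "exon", paste0("gene:", regions$gene[rows]),
                 paste0(kind, ":", rows))
  data.frame(column = seq_len(aln_length), unit = unit, kind = kind,
             stringsAsFactors = FALSE)
}

default_pairs <- function(topo) {
  subfam <- topo$outgroups$genus  # the monotypic subfamily tip
  g1 <- topo$genus_tips[[1L]]; g2 <- topo$genus_tips[[2L]]
  rbind(
    do.call(rbind, lapply(c(g1, g2), function(t)
      data.frame(level = "subfamily", taxonA = subfam, taxonB = t))),
    do.call(rbind, lapply(g1, function(a) do.call(rbind, lapply(g2, function(b)
      data.frame(level = "genus", taxonA = a, taxonB = b))))),
    data.frame(level = "species", taxonA = g1[1L], taxonB = g1[2L]),
    data.frame(level = "species", taxonA = g2[1L], taxonB = g2[2L]))
}

#' Associate structural mutations with nucleotide substitutions
#'
#' For each comparison pair, the alignment is partitioned into annotation
#' units (each gene's exon set, each intron, each spacer). A unit is "with
#' structural mutation" for the pair if at least one structural event whose
#' carriers distinguish the two taxa starts inside it. gdS and gdN are
#' p-distances over the concatenated columns of the two unit classes; N
#' and S count the substitutions and structural events distinguishing the
#' pair. Rows are produced for the whole genome and for the
#' noncoding/coding partitions.
#'
#' @param snps SNP table from [annotate_snps()].
#' @param events event table from [call_structural_events()].
#' @param regions a [region_map()].
#' @param aln a [plastome_alignment()].
#' @param topo a [dated_topology()].
#' @param pairs optional data.frame (`level`, `taxonA`, `taxonB`); default:
#'   the hierarchical scheme (subfamily tip vs the four species, the four
#'   cross-genus pairs, the two within-genus pairs).
#' @param exclude_columns columns excluded from the genetic distances
#'   (typically [inversion_mask()] output: an inverted loop is one
#'   structural event, and its mismatch columns would otherwise masquerade
#'   as nucleotide divergence).
#' @return data.frame per pair x partition: `N`, `S`, `N_over_S`, `gdS`,
#'   `gdN`, `gdS_gdN`, `units_S`, `units_N`.
#' @export
associate <- function(snps, events, regions, aln, topo, pairs = NULL,
                      exclude_columns = NULL) {
  if (is.null(pairs)) pairs <- default_pairs(topo)
  cmap <- build_coordinate_map(aln, aln$reference)
  units <- annotation_units(regions, cmap, aln$length)
  if (length(exclude_columns))
    units <- units[!(units$column %in% exclude_columns), , drop = FALSE]
  ev_carriers <- strsplit(events$carriers, ",")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    A <- pairs$taxonA[i]; B <- pairs$taxonB[i]
    dist_ev <- vapply(ev_carriers, function(cs)
      xor(A %in% cs, B %in% cs), logical(1L))
    ev_units <- unique(units$unit[events$start_col[dist_ev]])
    a <- aln$mat[A, snps$column]; b <- aln$mat[B, snps$column]
    N_total <- sum(a != b & a %in% names(BASE_BITS) & b %in% names(BASE_BITS))
    S_total <- sum(dist_ev)
    for (part in c("whole", "noncoding", "coding")) {
      sel <- switch(part,
                    whole = rep(TRUE, nrow(units)),
                    noncoding = units$kind != "exon",
                    coding = units$kind == "exon")
      cols_S <- units$column[sel & units$unit %in% ev_units]
      cols_N <- units$column[sel & !(units$unit %in% ev_units)]
      gdS <- if (length(cols_S)) p_distance(aln, A, B, cols_S)$gd else NA_real_
      gdN <- if (length(cols_N)) p_distance(aln, A, B, cols_N)$gd else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        level = pairs$level[i], taxonA = A, taxonB = B, partition = part,
        N = N_total, S = S_total,
        N_over_S = if (S_total > 0L) N_total / S_total else NA_real_,
        gdS = gdS, gdN = gdN,
        gdS_gdN = if (!is.na(gdS) && !is.na(gdN) && gdN > 0) gdS / gdN
        else NA_real_,
        units_S = length(unique(units$unit[sel & units$unit %in% ev_units])),
        units_N = length(unique(units$unit[sel & !(units$unit %in% ev_units)])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site substitution rate from counts, sites and divergence time
#'
#' mu = m / (n * T) mutations per site per year, with a Poisson standard
#' error sqrt(m) / (n * T).
#'
#' @param m observed mutation count (>= 0).
#' @param n number of sites (bp, > 0).
#' @param T_years divergence time in years (> 0).
#' @return list `(m, n, T_years, mu, se)`.
#' @export
estimate_substitution_rate <- function(m, n, T_years) {
  if (n <= 0 || T_years <= 0) stop("n and T must be positive")
  if (m < 0) stop("m must be non-negative")
  list(m = m, n = n, T_years = T_years,
       mu = m / (n * T_years), se = sqrt(m) / (n * T_years))
}

#' Structural mutation rate over the additive branch time
#'
#' Same arithmetic as [estimate_substitution_rate()] but with the additive
#' time (sum of ingroup branch durations) as the time denominator, the
#' standard treatment for events counted over a whole tree rather than
#' since a single node.
#'
#' @param event_count number of structural events.
#' @param n number of sites (bp).
#' @param additive_time_years additive branch time in years.
#' @return list `(m, n, T_years, mu, se)`.
#' @export
estimate_structural_rate <- function(event_count, n, additive_time_years) {
  estimate_substitution_rate(event_count, n, additive_time_years)
}

#' Exact two-sided test of direction bias (two categories against 1:1)
#'
#' @param a,b the two category counts (a + b > 0).
#' @return two-sided exact binomial p-value.
#' @export
direction_bias_test <- function(a, b) {
  if (a < 0 || b < 0 || a + b == 0) stop("need non-negative counts, a + b > 0")
  stats::binom.test(a, a + b, p = 0.5)$p.value
}

#' Correlation between inversion loop and stem lengths
#'
#' @param inversions data.frame with `loop_length` and `stem_length`
#'   (>= 3 rows required).
#' @return list `(r, p_value, n)`; `r` is NA when either length has zero
#'   variance.
#' @export
stem_loop_correlation <- function(inversions) {
  n <- nrow(inversions)
  if (n < 3L) return(list(r = NA_real_, p_value = NA_real_, n = n))
  x <- inversions$loop_length; y <- inversions$stem_length
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
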