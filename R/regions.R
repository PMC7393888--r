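#' Construct a validated region map
#'
#' A region map is the three-way partition of the reference sequence into
#' coding exons, introns and intergenic spacers, with gene names, strands and
#' codon phases attached to exons. Intervals are 1-based inclusive on the
#' ungapped reference coordinate system, sorted, non-overlapping and jointly
#' covering `1..ref_length`.
#'
#' @param df data.frame with columns `start`, `end`, `kind` (one of
#'   `"exon"`, `"intron"`, `"spacer"`), `gene` (NA for spacers), `strand`
#'   (`"+"`/`"-"`, NA for spacers), `coding` (logical; protein-coding gene).
#' @param ref_length reference sequence length.
#' @return A `region_map` data.frame with an added `phase` column for exons
#'   (number of codon bases preceding the exon's first base, 0/1/2, reading
#'   in gene strand order) and attribute `ref_length`.
#' @export
region_map <- function(df, ref_length) {
  need <- c("start", "end", "kind", "gene", "strand", "coding")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("region data.frame lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- df[order(df$start), need, drop = FALSE]
  if (nrow(df) == 0L)
    df <- data.frame(start = 1L, end = as.integer(ref_length), kind = "spacer",
                     gene = NA_character_, strand = NA_character_, coding = FALSE)
  if (any(df$end > ref_length) || any(df$start < 1L))
    stop("region interval outside [1, reference length]")
  if (any(df$start > df$end)) stop("region interval with start > end")
  gaps <- c(df$start[1L] != 1L,
            df$start[-1L] != df$end[-nrow(df)] + 1L,
            df$end[nrow(df)] != ref_length)
  if (any(gaps))
    stop("region intervals must tile the reference without gaps or overlaps")
  if (!all(df$kind %in% c("exon", "intron", "spacer")))
    stop("region kind must be exon, intron or spacer")
  # codon phase per exon, accumulated along the gene in strand order
  df$phase <- NA_integer_
  for (g in unique(df$gene[df$kind == "exon" & !is.na(df$gene)])) {
    idx <- which(df$kind == "exon" & df$gene %in% g)
    strand <- df$strand[idx[1L]]
    ord <- if (identical(strand, "-")) rev(idx) else idx
    lens <- df$end[ord] - df$start[ord] + 1L
    df$phase[ord] <- as.integer(cumsum(c(0L, lens[-length(lens)])) %% 3L)
    if (df$coding[idx[1L]] && sum(lens) %% 3L != 0L)
      stop(sprintf("protein-coding gene '%s' has exon length sum %d, not a multiple of 3",
                   g, sum(lens)))
  }
  rownames(df) <- NULL
  structure(df, ref_length = as.integer(ref_length),
            class = c("region_map", "data.frame"))
}

#' Read a GFF3 annotation into a region map
#'
#' Protein-coding genes are taken from `CDS` features (grouped by their
#' `Parent`/`ID`/`gene` attribute); non-CDS `exon` features define
#' non-protein-coding genes. Introns are derived as the within-gene
#' complements of the exons; the remaining sequence becomes intergenic
#' spacers. Overlapping genes are out of scope and raise an error.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param reference_length length of the (ungapped) reference sequence.
#' @return A [region_map()].
#' @export
read_annotation <- function(path, reference_length) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  gff <- ape::read.gff(path, GFF3 = TRUE)
  feat <- gff[gff$type %in% c("CDS", "exon"), , drop = FALSE]
  if (nrow(feat) == 0L)
    return(region_map(data.frame(start = integer(), end = integer(),
                                 kind = character(), gene = character(),
                                 strand = character(), coding = logical()),
                      reference_length))
  attr_field <- function(attr, keys) {
    for (k in keys) {
      m <- regmatches(attr, regexpr(paste0("(^|;)\\s*", k, "=[^;]+"), attr))
      if (length(m) && nzchar(m)) return(sub(paste0(".*", k, "="), "", m))
    }
    NA_character_
  }
  feat$gene <- vapply(as.character(feat$attributes), attr_field,
                      character(1L), keys = c("Parent", "gene", "ID", "Name"))
  if (anyNA(feat$gene)) stop("CDS/exon feature without Parent/gene/ID attribute")
  if (any(feat$end > reference_length))
    stop("feature beyond reference length")
  rows <- list()
  genes <- split(feat, feat$gene)
  for (g in names(genes)) {
    f <- genes[[g]][order(genes[[g]]$start), , drop = FALSE]
    coding <- any(f$type == "CDS")
    strand <- as.character(f$strand[1L])
    if (nrow(f) > 1L && any(f$start[-1L] <= f$end[-nrow(f)]))
      stop(sprintf("overlapping exons within gene '%s'", g))
    for (i in seq_len(nrow(f))) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = f$start[i], end = f$end[i], kind = "exon", gene = g,
        strand = strand, coding = coding)
      if (i < nrow(f))
        rows[[length(rows) + 1L]] <- data.frame(
          start = f$end[i] + 1L, end = f$start[i + 1L] - 1L, kind = "intron",
          gene = g, strand = strand, coding = coding)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$start[-1L] <= df$end[-nrow(df)]))
    stop("overlapping features of distinct genes are out of scope")
  # fill spacers
  out <- list()
  prev_end <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > prev_end + 1L)
      out[[length(out) + 1L]] <- data.frame(
        start = prev_end + 1L, end = df$start[i] - 1L, kind = "spacer",
        gene = NA_character_, strand = NA_character_, coding = FALSE)
    out[[length(out) + 1L]] <- df[i, ]
    prev_end <- df$end[i]
  }
  if (prev_end < reference_length)
    out[[length(out) + 1L]] <- data.frame(
      start = prev_end + 1L, end = as.integer(reference_length),
      kind = "spacer", gene = NA_character_, strand = NA_character_,
      coding = FALSE)
  region_map(do.call(rbind, out), reference_length)
}

#' Write a region map to GFF3
#'
#' Emits one `gene` feature per gene plus `CDS` (protein-coding) or `exon`
#' rows; introns and spacers are implicit (a reader re-derives them).
#'
#' @param regions a [region_map()].
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @export
write_gff3 <- function(regions, path, seqid = "reference") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", seqid,
                     attr(regions, "ref_length")), con)
  ex <- regions[regions$kind == "exon", , drop = FALSE]
  for (g in unique(ex$gene)) {
    f <- ex[ex$gene == g, , drop = FALSE]
    writeLines(sprintf("%s\tplastmut\tgene\t%d\t%d\t.\t%s\t.\tID=%s", seqid,
                       min(f$start), max(f$end), f$strand[1L], g), con)
    type <- if (f$coding[1L]) "CDS" else "exon"
    for (i in seq_len(nrow(f))) {
      # GFF3 phase: bases to skip to reach the next codon start
      ph <- if (f$coding[1L]) as.character((3L - f$phase[i]) %% 3L) else "."
      writeLines(sprintf("%s\tplastmut\t%s\t%d\t%d\t.\t%s\t%s\tID=%s.%d;Parent=%s",
                         seqid, type, f$start[i], f$end[i], f$strand[i],
                         ph, g, i, g), con)
    }
  }
  invisible(path)
}

#' Project a region map onto alignment columns
#'
#' Every alignment column receives exactly one region label. Columns where
#' the reference row is gapped inherit the label of the enclosing reference
#' interval (the interval of the nearest preceding non-gap reference
#' position; leading gaps take the first interval's label).
#'
#' @param regions a [region_map()] on the reference taxon.
#' @param cmap coordinate map for the reference taxon
#'   (from [build_coordinate_map()]).
#' @param aln_length number of alignment columns.
#' @return data.frame with one row per column: `column`, `kind`, `gene`.
#' @export
project_regions <- function(regions, cmap, aln_length) {
  if (length(cmap$pos_to_col) != attr(regions, "ref_length"))
    stop("coordinate map ungapped length does not match region map reference length")
  interval_at <- findInterval(cmap$col_to_pos, regions$start)
  # carry the last seen interval over reference-gap columns, then back-fill
  idx <- interval_at
  last <- NA_integer_
  for (i in seq_len(aln_length)) {
    if (!is.na(idx[i])) last <- idx[i] else idx[i] <- last
  }
  if (anyNA(idx)) {
    first <- idx[which(!is.na(idx))[1L]]
    idx[is.na(idx)] <- first
  }
  data.frame(column = seq_len(aln_length),
             kind = regions$kind[idx],
             gene = regions$gene[idx],
             stringsAsFactors = FALSE)
}

#' Name the spacer at a reference interval by its flanking genes
#' @param regions a [region_map()].
#' @param row row index of a spacer interval in `regions`.
#' @return `"left-right"` style name; `"end"` stands in at sequence ends.
#' @export
spacer_name <- function(regions, row) {
  genes <- regions$gene
  left <- if (row > 1L) rev(genes[seq_len(row - 1L)]) else character()
  right <- if (row < nrow(regions)) genes[(row + 1L):nrow(regions)] else character()
  l <- c(left[!is.na(left)], "start")[1L]
  r <- c(right[!is.na(right)], "end")[1L]
  paste0(l, "-", r)
}
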