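#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames rpois runif rbinom cor.test pchisq binom.test sd aggregate
#' @importFrom utils write.table read.table head tail
NULL

ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a validated multiple alignment object
#'
#' The alignment is the substrate for every caller in the package: a set of
#' equal-length gapped sequences over \{A,C,G,T,N,-\}, with one row designated
#' as the reference (the row whose annotation the region map describes).
#'
#' @param seqs named character vector of aligned sequences (equal length),
#'   or a character matrix of single characters with taxa as rows.
#' @param reference name of the reference taxon; defaults to the first taxon.
#' @return An object of class `plastome_alignment` with elements `mat`
#'   (character matrix, taxa x columns), `taxa`, `length`, `reference`.
#' @export
plastome_alignment <- function(seqs, reference = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must carry unique taxon names")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[lens != lens[1L]][1L]
      stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                   bad, nchar(seqs[[bad]]), lens[1L]))
    }
    mat <- do.call(rbind, strsplit(toupper(chartr("Uu", "Tt", seqs)), ""))
    rownames(mat) <- names(seqs)
  }
  if (ncol(mat) < 1L) stop("alignment must have at least one column")
  if (anyDuplicated(rownames(mat))) stop("taxon names must be unique")
  bad <- which(!(mat %in% ALPHABET))
  if (length(bad)) {
    col <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf("illegal character '%s' at alignment column %d",
                 mat[bad[1L]], col))
  }
  if (is.null(reference)) reference <- rownames(mat)[1L]
  if (!reference %in% rownames(mat))
    stop(sprintf("reference taxon '%s' not in alignment", reference))
  structure(list(mat = mat, taxa = rownames(mat), length = ncol(mat),
                 reference = reference),
            class = "plastome_alignment")
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat(sprintf("plastome_alignment: %d taxa x %d columns (reference: %s)\n",
              length(x$taxa), x$length, x$reference))
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA
#'
#' Sequences are upper-cased and U is mapped to T on read. All records must
#' have equal (aligned) length; at least three records are required.
#'
#' @param path FASTA file.
#' @param reference reference taxon name (default: first record).
#' @return A [plastome_alignment()].
#' @export
read_alignment <- function(path, reference = NULL) {
  if (!file.exists(path)) stop(sprintf("alignment file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 3L) stop("alignment must contain at least 3 records")
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  plastome_alignment(seqs, reference = reference)
}

#' Write an alignment to FASTA
#'
#' @param aln a [plastome_alignment()].
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in aln$taxa) {
    s <- paste(aln$mat[tx, ], collapse = "")
    writeLines(paste0(">", tx), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build the column <-> ungapped-position coordinate map for one taxon
#'
#' Non-gap columns are numbered 1..ungapped length; gap columns map to NA.
#' The two directions are mutually inverse bijections restricted to non-gap
#' columns.
#'
#' @param aln a [plastome_alignment()].
#' @param taxon taxon name.
#' @return list with `taxon`, `col_to_pos` (length = alignment columns,
#'   NA at gaps) and `pos_to_col` (length = ungapped length).
#' @export
build_coordinate_map <- function(aln, taxon) {
  if (!taxon %in% aln$taxa) stop(sprintf("unknown taxon '%s'", taxon))
  row <- aln$mat[taxon, ]
  nongap <- row != "-"
  col_to_pos <- rep(NA_integer_, aln$length)
  col_to_pos[nongap] <- seq_len(sum(nongap))
  if (!any(nongap)) warning(sprintf("taxon '%s' is all-gap; empty map", taxon))
  list(taxon = taxon, col_to_pos = col_to_pos,
       pos_to_col = which(nongap))
}

#' Ungapped sequence of one taxon
#' @param aln a [plastome_alignment()].
#' @param taxon taxon name.
#' @return character vector of bases (no gaps).
#' @export
ungapped_sequence <- function(aln, taxon) {
  row <- aln$mat[taxon, ]
  row[row != "-"]
}
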