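#' Write a TSV report with '#'-prefixed metadata lines
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param meta character vector of metadata lines (written as `# ...`).
#' @export
write_tsv_report <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full mutation analysis and write all reports
#'
#' Executes the pipeline stages in order — SNP calling/classification,
#' structural event calling, structural/nucleotide association, rate
#' estimation — and writes the report bundle plus a run manifest (input
#' checksums and parameters; no timestamps, so reruns on identical inputs
#' are byte-identical). All analysis stages are deterministic; the only
#' randomness in the package lives in the simulator.
#'
#' @param alignment path to the FASTA alignment.
#' @param annotation path to the GFF3 annotation of the reference taxon.
#' @param tree path to the dated Newick tree.
#' @param out_dir output directory (created if needed).
#' @param reference reference taxon (default: first alignment record).
#' @param min_stem,max_loop inversion detector parameters.
#' @return invisibly, a list with the in-memory results
#'   (`snps`, `events`, `assoc`, `rates`, summaries).
#' @export
run_all <- function(alignment, annotation, tree, out_dir,
                    reference = NULL, min_stem = 7L, max_loop = 100L) {
  for (f in c(alignment, annotation, tree))
    if (!file.exists(f)) stop(sprintf("input file missing: %s", f))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(alignment, reference = reference)
  topo <- read_dated_tree(tree)
  cmap <- build_coordinate_map(aln, aln$reference)
  regions <- read_annotation(annotation, length(cmap$pos_to_col))

  inv <- detect_inversions(aln, topo, min_stem = min_stem,
                           max_loop = max_loop)
  mask <- inversion_mask(inv)
  snps <- annotate_snps(aln, topo, regions, mask_columns = mask)
  events <- call_structural_events(aln, topo, regions,
                                   min_stem = min_stem, max_loop = max_loop,
                                   inversions = inv)
  spec <- substitution_spectrum(snps)
  t2 <- summarize_rank_region(snps, regions)
  gg <- summarize_gene_groups(snps)
  cu <- codon_usage(aln, regions)
  ssum <- summarize_structural(events)
  assoc <- associate(snps, events, regions, aln, topo,
                     exclude_columns = mask)
  rates <- rate_table(snps, events, regions, topo)

  rep1 <- function(x, d) ifelse(is.na(x), NA, round(x, d))
  snps_out <- snps
  write_tsv_report(snps_out, file.path(out_dir, "snps.tsv"),
                   sprintf("polymorphic sites: %d", nrow(snps)))
  write_tsv_report(spec, file.path(out_dir, "spectrum.tsv"),
                   "substitution spectrum (directed classes, per stratum)")
  write_tsv_report(t2, file.path(out_dir, "table2.tsv"),
                   "biallelic SNP distribution by rank and genome region")
  write_tsv_report(gg, file.path(out_dir, "genegroups.tsv"),
                   "Ts/Tv and dN/dS per functional gene group")
  write_tsv_report(cu$codons, file.path(out_dir, "codon_usage.tsv"),
                   sprintf("codon usage, reference taxon (%d codons)",
                           cu$n_codons))
  write_tsv_report(events, file.path(out_dir, "structural_events.tsv"),
                   sprintf("structural events: %d", nrow(events)))
  t3 <- rbind(
    data.frame(section = "by_rank", key = ssum$by_rank$category,
               value = ssum$by_rank$value, count = ssum$by_rank$count),
    data.frame(section = "indel_sizes", key = "indel",
               value = ssum$indel_sizes$size_class,
               count = ssum$indel_sizes$count),
    data.frame(section = "repeat_sizes", key = "repeat",
               value = ssum$repeat_sizes$size_bp,
               count = ssum$repeat_sizes$count),
    data.frame(section = "by_location", key = ssum$by_location$category,
               value = ssum$by_location$value, count = ssum$by_location$count),
    data.frame(section = "by_direction", key = ssum$by_direction$category,
               value = ssum$by_direction$value,
               count = ssum$by_direction$count))
  write_tsv_report(t3, file.path(out_dir, "table3.tsv"),
                   "structural mutation counts by rank, size, location, direction")
  inv <- events[events$category == "inversion", , drop = FALSE]
  write_tsv_report(inv, file.path(out_dir, "inversions.tsv"),
                   "stem-loop inversions")
  assoc_out <- assoc
  assoc_out$N_over_S <- rep1(assoc$N_over_S, 2)
  assoc_out$gdS <- rep1(assoc$gdS, 4)
  assoc_out$gdN <- rep1(assoc$gdN, 4)
  assoc_out$gdS_gdN <- rep1(assoc$gdS_gdN, 2)
  write_tsv_report(assoc_out, file.path(out_dir, "table5.tsv"),
                   "association of nucleotide to structural mutations")
  rates_out <- rates
  rates_out$mu <- signif(rates$mu, 2)
  rates_out$se <- signif(rates$se, 2)
  write_tsv_report(rates_out, file.path(out_dir, "rates.tsv"),
                   "per-site mutation rates (per year)")
  manifest <- data.frame(
    key = c("plastmut_version", "alignment", "annotation", "tree",
            "alignment_md5", "annotation_md5", "tree_md5", "reference",
            "min_stem", "max_loop"),
    value = c(as.character(utils::packageVersion("plastmut")),
              alignment, annotation, tree,
              unname(tools::md5sum(alignment)),
              unname(tools::md5sum(annotation)), unname(tools::md5sum(tree)),
              aln$reference, min_stem, max_loop))
  write_tsv_report(manifest, file.path(out_dir, "manifest.tsv"),
                   "run manifest")
  invisible(list(snps = snps, events = events, spectrum = spec, table2 = t2,
                 gene_groups = gg, codon_usage = cu, structural = ssum,
                 assoc = assoc, rates = rates))
}

#' Per-rank substitution and per-category structural rate table
#'
#' Substitution rates use the rank's SNP count, the reference length and
#' the rank's divergence node age; structural rates use category totals
#' over the additive ingroup branch time (ages are My; the single
#' My-to-year conversion lives here).
#'
#' @param snps SNP table.
#' @param events structural event table.
#' @param regions a [region_map()].
#' @param topo a [dated_topology()].
#' @return data.frame: `quantity`, `m`, `n`, `T_My`, `mu`, `se`.
#' @export
rate_table <- function(snps, events, regions, topo) {
  n <- attr(regions, "ref_length")
  use <- snps[snps$allelism == 2L & !snps$parallel &
                snps$rank %in% topo$ranks, , drop = FALSE]
  node_age_of_rank <- c(
    subfamily = unname(topo$age["family_crown"]),
    genus = unname(topo$age["subfamily_crown"]),
    setNames(topo$age[paste0("crown_", names(topo$genus_tips))],
             paste0("species_", names(topo$genus_tips))))
  rows <- list()
  for (r in topo$ranks) {
    m <- sum(use$rank == r)
    T_My <- node_age_of_rank[[r]]
    est <- estimate_substitution_rate(m, n, T_My * 1e6)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("substitution_", r), m = m, n = n, T_My = T_My,
      mu = est$mu, se = est$se)
  }
  at <- additive_time(topo)
  for (cc in c("indel", "repeat")) {
    m <- sum(events$category == cc & events$rank %in% topo$ranks)
    est <- estimate_structural_rate(m, n, at * 1e6)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("structural_", cc), m = m, n = n, T_My = at,
      mu = est$mu, se = est$se)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
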