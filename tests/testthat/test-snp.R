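make_col_aln <- function(cols) {
  # cols: list of named base vectors (over TAXA); build an alignment
  mat <- do.call(cbind, lapply(cols, function(cc) cc[TAXA]))
  rownames(mat) <- TAXA
  plastome_alignment(mat, reference = "Calycanthus_floridus")
}

test_that("polymorphic site calling respects allelism and gap exclusion", {
  aln <- make_col_aln(list(
    col_states(),                                        # monomorphic
    col_states(Chimonanthus_nitens = "G", Chimonanthus_praecox = "G"),
    col_states(Calycanthus_chinensis = "C",
               Chimonanthus_nitens = "G", Chimonanthus_praecox = "G"),
    col_states(Idiospermum_australiense = "-",
               Chimonanthus_nitens = "G", Chimonanthus_praecox = "G"),
    col_states(Magnolia_kwangsiensis = "-",
               Chimonanthus_nitens = "G", Chimonanthus_praecox = "G")))
  sites <- call_polymorphic_sites(aln, TOPO)
  # col 1 monomorphic, col 4 has an ingroup gap; cols 2, 3, 5 are called
  expect_equal(sites$column, c(2L, 3L, 5L))
  expect_equal(sites$allelism, c(2L, 3L, 2L))
  expect_equal(sites$alleles[2], "ACG")
})

test_that("hierarchical outgroup polarization follows rank", {
  # species-rank SNP in Calycanthus, sister genus unanimous
  st <- col_states(Calycanthus_chinensis = "G")
  d <- infer_direction(st, "species_Calycanthus", TOPO)
  expect_true(d$direction_known)
  expect_equal(d$ancestral, "A")
  expect_equal(d$derived, "G")
  # rank outgroups disagreeing with each other -> uncertain
  st2 <- col_states(Calycanthus_chinensis = "G", Chimonanthus_nitens = "T")
  d2 <- infer_direction(st2, "species_Calycanthus", TOPO)
  expect_false(d2$direction_known)
  # outgroup base not among the ingroup alleles -> uncertain
  st3 <- col_states(Idiospermum_australiense = "G",
                    Liriodendron_tulipifera = "C",
                    Magnolia_kwangsiensis = "C")
  d3 <- infer_direction(st3, "subfamily", TOPO)
  expect_false(d3$direction_known)
})

test_that("substitution classification: 4 transitions, 8 transversions, pooling", {
  bases <- c("A", "C", "G", "T")
  ts <- tv <- 0L
  for (a in bases) for (b in setdiff(bases, a)) {
    cl <- classify_substitution(a, b)
    if (cl$ts_tv == "transition") ts <- ts + 1L else tv <- tv + 1L
    expect_match(cl$pool, paste0(a, "->", b), fixed = TRUE)
  }
  expect_equal(c(ts, tv), c(4L, 8L))
  expect_equal(classify_substitution("A", "G")$pool, "A->G+T->C")
  expect_equal(classify_substitution("C", "A")$ts_tv, "transversion")
  expect_equal(classify_substitution("C", "A")$pool, "C->A+G->T")
  expect_error(classify_substitution("A", "A"), "distinct")
})

test_that("coding effect matches the genetic code, strand-aware", {
  # plus-strand gene ATG ATT TAA at reference positions 1..9
  f <- write_test_gff("ref\tx\tCDS\t1\t9\t.\t+\t0\tID=g.1;Parent=g")
  rm <- read_annotation(f, 12L)
  s <- "ATGATTTAAAAA"
  aln <- aln_from(Calycanthus_floridus = s, o1 = s, o2 = s,
                  reference = "Calycanthus_floridus")
  cm <- build_coordinate_map(aln, "Calycanthus_floridus")
  # third position ATT -> ATC: Ile -> Ile
  e1 <- classify_coding_effect(6L, "T", "C", "g", rm, aln, cm)
  expect_equal(e1$effect, "synonymous")
  # first position ATT -> CTT: Ile -> Leu
  e2 <- classify_coding_effect(4L, "A", "C", "g", rm, aln, cm)
  expect_equal(e2$effect, "nonsynonymous")

  # minus-strand version of the same gene occupying positions 1..9
  fm <- write_test_gff("ref\tx\tCDS\t1\t9\t.\t-\t0\tID=g.1;Parent=g")
  rmm <- read_annotation(fm, 12L)
  sm <- "TTAAATCATAAA"  # reverse complement of ATGATTTAA + AAA
  alnm <- aln_from(Calycanthus_floridus = sm, o1 = sm, o2 = sm,
                   reference = "Calycanthus_floridus")
  cmm <- build_coordinate_map(alnm, "Calycanthus_floridus")
  # alignment column 4 is CDS codon-2 third position (A on minus strand = T)
  e3 <- classify_coding_effect(4L, "A", "G", "g", rmm, alnm, cmm)
  expect_equal(e3$effect, "synonymous")  # ATT -> ATC on the gene strand
})

test_that("coding effect equals whole-gene translation on simulated SNPs", {
  sim <- simulate_plastomes(sim_config(genome_length = 8000L), seed = 5)
  inv <- detect_inversions(sim$aln, TOPO)
  snps <- annotate_snps(sim$aln, TOPO, sim$regions,
                        mask_columns = inversion_mask(inv))
  ex <- snps[!is.na(snps$effect), ]
  set.seed(9)
  ex <- ex[sample(nrow(ex), min(60L, nrow(ex))), ]
  cm <- build_coordinate_map(sim$aln, sim$aln$reference)
  code <- Biostrings::getGeneticCode("11")
  for (i in seq_len(nrow(ex))) {
    cols <- plastmut:::gene_cds_columns(sim$regions, cm, ex$gene[i])
    ref <- sim$aln$mat[sim$aln$reference, ]
    strand <- sim$regions$strand[sim$regions$kind == "exon" &
                                   sim$regions$gene %in% ex$gene[i]][1]
    mk <- function(base) {
      g <- ref; g[ex$column[i]] <- base
      cds <- g[cols]
      if (identical(strand, "-")) cds <- unname(c(A = "T", C = "G", G = "C",
                                                  T = "A")[cds])
      paste(cds, collapse = "")
    }
    aa <- function(s) as.character(Biostrings::translate(
      Biostrings::DNAString(s), genetic.code = code, no.init.codon = TRUE))
    oracle <- if (aa(mk(ex$ancestral[i])) == aa(mk(ex$derived[i])))
      "synonymous" else "nonsynonymous"
    expect_equal(ex$effect[i], oracle, info = paste("column", ex$column[i]))
  }
})

test_that("rank-by-region summary reproduces count-ratio arithmetic", {
  f <- write_test_gff("ref\tx\tCDS\t1\t300\t.\t+\t0\tID=g.1;Parent=g")
  rm <- read_annotation(f, 1000L)
  # synthetic classified table: 53 nonsynonymous, 65 synonymous at genus rank
  snps <- data.frame(
    column = 1:118, alleles = "AG", allelism = 2L, branch = "crown_Calycanthus",
    rank = "genus", parallel = FALSE, direction_known = TRUE,
    ancestral = "A", derived = "G", ts_tv = "transition", class = "A->G",
    pool = "A->G+T->C", region = "exon", gene = "g",
    effect = rep(c("nonsynonymous", "synonymous"), c(53, 65)),
    multi_snp_codon = FALSE, stringsAsFactors = FALSE)
  t2 <- summarize_rank_region(snps, rm)
  g_exon <- t2[t2$rank == "genus" & t2$region == "exon", ]
  expect_equal(g_exon$dn_ds, 0.82)
  expect_equal(g_exon$count, 118L)
  expect_equal(g_exon$percent, round(100 * 118 / 300, 2))
  # empty input: all-zero table with undefined ratios
  t0 <- summarize_rank_region(snps[0, ], rm)
  expect_true(all(t0$count == 0L))
  expect_true(all(is.na(t0$dn_ds)))
})

test_that("gene-group ratios are raw count ratios, never infinite", {
  snps <- data.frame(
    column = 1:8, alleles = "AG", allelism = 2L, branch = "b",
    rank = "subfamily", parallel = FALSE, direction_known = TRUE,
    ancestral = "A", derived = "G",
    ts_tv = rep(c("transition", "transversion"), c(6, 2)),
    class = "A->G", pool = "A->G+T->C", region = "exon",
    gene = c(rep("psbA", 6), rep("psbB", 2)),
    effect = "synonymous", multi_snp_codon = FALSE, stringsAsFactors = FALSE)
  gg <- summarize_gene_groups(snps)
  expect_equal(gg$ts_tv[gg$group == "psb"], 3)
  expect_equal(gg$dn_ds[gg$group == "psb"], 0)  # dN = 0, dS = 8
  # genes with no known prefix fall into "other"; zero denominators give NA
  snps$gene <- "ycf1"
  snps$ts_tv <- "transition"
  gg2 <- summarize_gene_groups(snps)
  expect_equal(gg2$group, "other")
  expect_true(is.na(gg2$ts_tv))
})

test_that("G-test matches the likelihood-ratio formula", {
  expect_equal(test_substitution_bias(c(10, 10, 10, 10))$G, 0)
  expect_equal(test_substitution_bias(c(10, 10, 10, 10))$p_value, 1)
  g <- test_substitution_bias(c(100, 0, 0, 0))
  expect_equal(g$G, 2 * 100 * log(4), tolerance = 1e-12)
  expect_equal(g$df, 3L)
  # independent direct computation on random counts
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(6, 40) + 1
    E <- sum(x) / 6
    expect_equal(test_substitution_bias(x)$G, 2 * sum(x * log(x / E)),
                 tolerance = 1e-10)
  }
  expect_warning(test_substitution_bias(c(1, 0, 0, 0, 0, 0, 0, 0)),
                 "expected count")
})

test_that("codon usage tallies and aggregates to amino acids", {
  f <- write_test_gff("ref\tx\tCDS\t1\t9\t.\t+\t0\tID=g.1;Parent=g")
  rm <- read_annotation(f, 9L)
  s <- "ATGATTTAA"
  aln <- aln_from(Calycanthus_floridus = s, o1 = s, o2 = s,
                  reference = "Calycanthus_floridus")
  cu <- codon_usage(aln, rm)
  got <- cu$codons[cu$codons$count > 0, ]
  expect_setequal(got$codon, c("ATG", "ATT", "TAA"))
  expect_true(all(got$percent == 33.33))
  expect_equal(sum(cu$codons$percent), 99.99, tolerance = 0.02)
  # amino-acid percents equal codon percents aggregated through the code
  code <- Biostrings::getGeneticCode("11")
  for (a in unique(cu$amino_acids$aa)) {
    expect_equal(cu$amino_acids$count[cu$amino_acids$aa == a],
                 sum(cu$codons$count[code[cu$codons$codon] == a]))
  }
})

test_that("spectrum pooling preserves totals and percents", {
  sim <- simulate_plastomes(sim_config(genome_length = 8000L), seed = 7)
  snps <- annotate_snps(sim$aln, TOPO, sim$regions)
  spec <- substitution_spectrum(snps, by_rank = TRUE)
  all_str <- spec[spec$stratum == "all", ]
  expect_equal(sum(all_str$count), sum(snps$direction_known))
  pooled <- pool_spectrum(all_str)
  expect_equal(sum(pooled$count), sum(all_str$count))
  for (p in pooled$pool)
    expect_equal(pooled$count[pooled$pool == p],
                 sum(all_str$count[all_str$pool == p]))
  # per-stratum counts sum to the all-stratum
  ranks <- setdiff(unique(spec$stratum), "all")
  expect_equal(sum(spec$count[spec$stratum %in% ranks]), sum(all_str$count))
})
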