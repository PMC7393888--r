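test_that("FASTA reading validates, normalizes and round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ACGT-", ">t2", "acgu-", ">t3", "ACGTN"), f)
  aln <- read_alignment(f)
  expect_equal(aln$length, 5L)
  expect_equal(length(aln$taxa), 3L)
  expect_equal(paste(aln$mat["t2", ], collapse = ""), "ACGT-")

  f2 <- tempfile(fileext = ".fasta")
  write_alignment(aln, f2)
  aln2 <- read_alignment(f2)
  expect_identical(aln$mat, aln2$mat)
  expect_identical(aln$taxa, aln2$taxa)

  writeLines(c(">a", "ACGTA", ">b", "ACGTAC", ">c", "ACGTA"), f)
  expect_error(read_alignment(f), "ragged.*b")
  writeLines(c(">a", "ACGXA", ">b", "ACGTA", ">c", "ACGTA"), f)
  expect_error(read_alignment(f), "illegal character")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), f)
  expect_error(read_alignment(f), "at least 3")
})

test_that("coordinate maps are inverse bijections on non-gap columns", {
  aln <- aln_from(t1 = "A-CG", t2 = "AACG", t3 = "AAC-")
  cm <- build_coordinate_map(aln, "t1")
  expect_equal(cm$col_to_pos, c(1L, NA, 2L, 3L))
  expect_equal(cm$pos_to_col, c(1L, 3L, 4L))
  # gapless row: identity
  cm2 <- build_coordinate_map(aln, "t2")
  expect_equal(cm2$col_to_pos, 1:4)
  # round trip on random gapped rows
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE), collapse = "")
    a <- aln_from(x = s, y = gsub("-", "A", s), z = gsub("-", "C", s))
    cm <- build_coordinate_map(a, "x")
    nongap <- which(!is.na(cm$col_to_pos))
    expect_identical(cm$pos_to_col[cm$col_to_pos[nongap]], nongap)
  }
  expect_warning(build_coordinate_map(aln_from(g = "---", h = "AAA", i = "AAA"), "g"),
                 "all-gap")
  expect_error(build_coordinate_map(aln, "nope"), "unknown taxon")
})

test_that("GFF3 annotation builds the exon/intron/spacer partition", {
  f <- write_test_gff(c(
    "ref\tx\tgene\t2\t91\t.\t+\t.\tID=gA",
    "ref\tx\tCDS\t2\t31\t.\t+\t0\tID=gA.1;Parent=gA",
    "ref\tx\tCDS\t62\t91\t.\t+\t0\tID=gA.2;Parent=gA"))
  rm <- read_annotation(f, 120L)
  expect_equal(rm$kind, c("spacer", "exon", "intron", "exon", "spacer"))
  expect_equal(rm$start, c(1L, 2L, 32L, 62L, 92L))
  expect_equal(rm$end, c(1L, 31L, 61L, 91L, 120L))
  expect_equal(rm$phase[rm$kind == "exon"], c(0L, 0L))
  expect_true(all(rm$gene[rm$kind != "spacer"] == "gA"))

  # empty feature list: one spacer covering the reference
  f0 <- write_test_gff(character())
  rm0 <- read_annotation(f0, 50L)
  expect_equal(nrow(rm0), 1L)
  expect_equal(rm0$kind, "spacer")
  expect_equal(c(rm0$start, rm0$end), c(1L, 50L))

  # protein-coding exon total not a multiple of 3
  fbad <- write_test_gff("ref\tx\tCDS\t1\t31\t.\t+\t0\tID=gB.1;Parent=gB")
  expect_error(read_annotation(fbad, 60L), "multiple of 3")

  # overlapping genes are out of scope
  fov <- write_test_gff(c(
    "ref\tx\tCDS\t1\t30\t.\t+\t0\tID=g1.1;Parent=g1",
    "ref\tx\tCDS\t25\t54\t.\t+\t0\tID=g2.1;Parent=g2"))
  expect_error(read_annotation(fov, 60L), "overlap")

  # feature beyond reference length
  ffar <- write_test_gff("ref\tx\tCDS\t1\t30\t.\t+\t0\tID=g1.1;Parent=g1")
  expect_error(read_annotation(ffar, 20L), "beyond reference length")
})

test_that("region projection labels every column exactly once", {
  f <- write_test_gff(c(
    "ref\tx\tCDS\t3\t8\t.\t+\t0\tID=g.1;Parent=g"))
  rm <- read_annotation(f, 10L)
  # reference has a gap inside the exon -> gap column inherits exon label
  aln <- aln_from(ref = "AACGT-TCGAA", o1 = "AACGTATCGAA", o2 = "AACGTATCGAA")
  cm <- build_coordinate_map(aln, "ref")
  proj <- project_regions(rm, cm, aln$length)
  expect_equal(nrow(proj), aln$length)
  expect_false(anyNA(proj$kind))
  expect_equal(proj$kind[6], "exon")  # the reference-gap column
  # conservation: label counts sum to alignment length
  expect_equal(sum(table(proj$kind)), aln$length)
  # gapless reference: labels equal interval kinds positionwise
  aln2 <- aln_from(ref = "AACGTTCGAA", o1 = "AACGTTCGAA", o2 = "AACGTTCGAA")
  proj2 <- project_regions(rm, build_coordinate_map(aln2, "ref"), 10L)
  expect_equal(proj2$kind, rm$kind[findInterval(1:10, rm$start)])
})

test_that("GFF3 writing round-trips through read_annotation", {
  sim <- simulate_plastomes(sim_config(genome_length = 6000L), seed = 11)
  f <- tempfile(fileext = ".gff3")
  write_gff3(sim$regions, f, seqid = sim$aln$reference)
  back <- read_annotation(f, attr(sim$regions, "ref_length"))
  expect_equal(back$start, sim$regions$start)
  expect_equal(back$end, sim$regions$end)
  expect_equal(back$kind, sim$regions$kind)
  expect_equal(back$phase, sim$regions$phase)
})

test_that("dated topology encodes ranks, ages and the outgroup scheme", {
  topo <- TOPO
  expect_equal(sort(unname(topo$branch_rank[topo$branch_rank == "subfamily"])),
               c("subfamily", "subfamily"))
  expect_equal(unname(topo$age["family_crown"]), 108.8)
  expect_equal(unname(topo$age["subfamily_crown"]), 18.7)
  expect_setequal(topo$outgroups$subfamily,
                  c("Liriodendron_tulipifera", "Magnolia_kwangsiensis"))
  expect_equal(topo$outgroups$genus, "Idiospermum_australiense")
  expect_setequal(topo$outgroups$species_Calycanthus,
                  c("Chimonanthus_nitens", "Chimonanthus_praecox"))
  # additive ingroup branch time: 108.8 + 90.1 + 11.1 + 2*7.6 + 12.5 + 2*6.2
  expect_equal(additive_time(topo), 250.1)

  # newick round trip
  f <- tempfile(fileext = ".nwk")
  write_dated_tree(topo, f)
  topo2 <- read_dated_tree(f)
  expect_equal(topo2$age[names(topo$age)], topo$age)
  expect_equal(additive_time(topo2), 250.1)

  # child age >= parent age
  bad <- "(Magnolia_kwangsiensis,(Liriodendron_tulipifera,(Idiospermum_australiense,((Calycanthus_chinensis,Calycanthus_floridus)20,(Chimonanthus_nitens,Chimonanthus_praecox)6.2)18.7)108.8)125)140;"
  expect_error(dated_topology(ape::read.tree(text = bad)), "not younger")
  # ingroup-only tree: outgroups required
  five <- "((Calycanthus_chinensis,Calycanthus_floridus)7.6,(Chimonanthus_nitens,Chimonanthus_praecox)6.2)18.7;"
  expect_error(dated_topology(ape::read.tree(text = five)), "outgroup")
})
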