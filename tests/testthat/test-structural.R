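pad_aln <- function(rows, reference = "Calycanthus_floridus") {
  plastome_alignment(rows[TAXA], reference = reference)
}

# alignment where every taxon shares `base_seq` except edits per taxon;
# edits: named list taxon -> gapped string of equal length
build_variant_aln <- function(base_seq, edits = list()) {
  rows <- setNames(rep(base_seq, length(TAXA)), TAXA)
  for (tx in names(edits)) rows[tx] <- edits[[tx]]
  pad_aln(rows)
}

test_that("gap runs become events with parsimony ranks and carriers", {
  base <- "ACGTACGTACGTACGTACGT"
  gapped <- "ACGTA-----GTACGTACGT"
  aln <- build_variant_aln(base, list(Calycanthus_chinensis = gapped))
  ev <- extract_gap_events(aln, TOPO)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_col, ev$end_col, ev$length), c(6L, 10L, 5L))
  expect_equal(ev$rank, "species_Calycanthus")
  expect_equal(ev$carriers, "Calycanthus_chinensis")
  expect_equal(ev$derived_state, "absent")

  # shared identical gap run in two sisters -> one stem-branch event
  aln2 <- build_variant_aln(base, list(Chimonanthus_nitens = gapped,
                                       Chimonanthus_praecox = gapped))
  ev2 <- extract_gap_events(aln2, TOPO)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$branch, "crown_Chimonanthus")
  expect_equal(ev2$rank, "genus")
})

test_that("split pieces of one gap rejoin across a nested insertion", {
  # Idiospermum deleted 8 bp; inside that span the Calycanthoideae carry a
  # 2 bp insertion (so Ia, Lt, Mk are gapped there too)
  rows <- setNames(rep("ACGTACGGTACCGTACGT", length(TAXA)), TAXA)
  #                     123456789012345678
  del <- "ACGT----------ACGT"  # Ia lacks 10 alignment columns (8 bp + insert)
  ins_absent <- "ACGTACG--TACCGTACGT"
  for (tx in TAXA) rows[tx] <- "ACGTACGGTACCGTACGT"
  # build by columns instead: base 16 bp, Ia deletes cols 5..12 (8 bp);
  # cols 8..9 are an insertion carried only by the 4 Calycanthoideae
  ing4 <- setdiff(ING, "Idiospermum_australiense")
  mat <- matrix("N", nrow = length(TAXA), ncol = 18,
                dimnames = list(TAXA, NULL))
  for (tx in TAXA) {
    s <- strsplit("ACGTACGGTACCGTACGT", "")[[1]]
    if (!tx %in% ing4) s[8:9] <- "-"          # insertion absent outside clade
    if (tx == "Idiospermum_australiense") s[5:12] <- "-"  # deletion
    mat[tx, ] <- s
  }
  aln <- plastome_alignment(mat, reference = "Calycanthus_floridus")
  ev <- extract_gap_events(aln, TOPO)
  ia <- ev[grepl("Idiospermum", ev$gap_taxa) & !grepl(",", ev$gap_taxa), ]
  expect_equal(nrow(ia), 1L)
  expect_equal(c(ia$start_col, ia$end_col), c(5L, 12L))
  expect_equal(ia$length, 6L)            # 8 columns minus the 2 insert columns
  expect_equal(ia$core, "5-7,10-12")
})

test_that("classification cascade: microsatellite, repeat, indel", {
  base <- paste0("ACGTT", strrep("A", 10), "GCCGTACGGACTACGGTACT")
  # deletion of 2 A's from the poly-A run
  del_ms <- sub(strrep("A", 10), paste0(strrep("A", 8), "--"), base)
  aln <- build_variant_aln(base, list(Calycanthus_chinensis = del_ms))
  ev <- extract_gap_events(aln, TOPO)
  cl <- classify_structural(ev[1, ], aln, TOPO)
  expect_equal(cl$category, "microsatellite")
  expect_equal(cl$motif, "A")

  # deletion of one copy of a 5 bp tandem duplication
  base2 <- "ACCTGACCTGTTGACGGATCGATTACCGGTTACG"
  del_rep <- "ACCTG-----TTGACGGATCGATTACCGGTTACG"
  aln2 <- build_variant_aln(base2, list(Chimonanthus_nitens = del_rep))
  ev2 <- extract_gap_events(aln2, TOPO)
  cl2 <- classify_structural(ev2[1, ], aln2, TOPO)
  expect_equal(cl2$category, "repeat")

  # 7 bp segment with neither motif nor adjacent duplicate
  base3 <- "ACGGATTCAGTCCTATGCAACGGTTACG"
  del_ind <- "ACGGA-------TATGCAACGGTTACG"
  del_ind <- "ACGGA-------ATGCAACGGTTACG"
  del_ind <- sub("TTCAGTC", "-------", base3)
  aln3 <- build_variant_aln(base3, list(Calycanthus_floridus = del_ind))
  ev3 <- extract_gap_events(aln3, TOPO)
  cl3 <- classify_structural(ev3[1, ], aln3, TOPO)
  expect_equal(cl3$category, "indel")
})

test_that("structural direction reads the rank outgroups", {
  base <- "ACGTACGTACGTACGTACGT"
  gapped <- "ACGTA-----GTACGTACGT"
  # subfamily-rank deletion: both Magnoliaceae outgroups carry the segment
  aln <- build_variant_aln(base, list(Idiospermum_australiense = gapped))
  ev <- extract_gap_events(aln, TOPO)
  expect_equal(ev$rank, "subfamily")
  expect_equal(infer_structural_direction(ev[1, ], TOPO, aln), "deletion")

  # outgroups disagree -> uncertain
  aln2 <- build_variant_aln(base, list(Idiospermum_australiense = gapped,
                                       Magnolia_kwangsiensis = gapped))
  ev2 <- extract_gap_events(aln2, TOPO)
  ia2 <- ev2[grepl("Idiospermum", ev2$gap_taxa), ][1, ]
  expect_equal(infer_structural_direction(ia2, TOPO, aln2), "uncertain")

  # insertion: all rank outgroups lack the segment
  ing4 <- setdiff(ING, "Idiospermum_australiense")
  rows <- setNames(rep(gapped, length(TAXA)), TAXA)
  for (tx in ing4) rows[tx] <- base
  aln3 <- pad_aln(rows)
  ev3 <- extract_gap_events(aln3, TOPO)
  expect_equal(ev3$rank, "subfamily")
  expect_equal(infer_structural_direction(ev3[1, ], TOPO, aln3), "insertion")
})

test_that("events locate to regions with spacer flank naming", {
  f <- write_test_gff(c(
    "ref\tx\tCDS\t11\t40\t.\t+\t0\tID=gX.1;Parent=gX",
    "ref\tx\tCDS\t61\t90\t.\t+\t0\tID=gY.1;Parent=gY"))
  rm <- read_annotation(f, 100L)
  aln <- build_variant_aln(strrep("ACGTT", 20))
  cm <- build_coordinate_map(aln, aln$reference)
  ev <- list(start_col = 45L, end_col = 50L)
  loc <- locate_event(ev, rm, cm, aln$length)
  expect_equal(loc$location, "spacer")
  expect_equal(loc$locus, "gX-gY")
  expect_false(loc$span_boundary)
  # boundary-spanning event keeps the 5' label and is flagged
  ev2 <- list(start_col = 38L, end_col = 45L)
  loc2 <- locate_event(ev2, rm, cm, aln$length)
  expect_equal(loc2$location, "exon")
  expect_true(loc2$span_boundary)
})

test_that("structural summary tallies sizes, directions and bias tests", {
  ev <- data.frame(
    category = rep(c("indel", "repeat"), c(162, 116)),
    start_col = 1, end_col = 1,
    length = c(rep(5L, 150), rep(12L, 8), rep(55L, 2), rep(120L, 2),
               rep(5L, 116)),
    rank = "subfamily", location = "spacer",
    direction = c(rep("deletion", 145), rep("insertion", 17),
                  rep("insertion", 99), rep("deletion", 17)),
    stringsAsFactors = FALSE)
  s <- summarize_structural(ev)
  dt <- s$direction_tests
  expect_equal(dt$ratio[dt$category == "indel"], 8.5)
  expect_lt(dt$p_value[dt$category == "indel"], 0.001)
  expect_equal(dt$insertions[dt$category == "repeat"] /
                 sum(dt$insertions[dt$category == "repeat"],
                     dt$deletions[dt$category == "repeat"]) * 100,
               85.3, tolerance = 0.06)
  expect_equal(sum(s$indel_sizes$count), 162L)
  expect_equal(sum(s$repeat_sizes$count), 116L)
  # size-class bin edges: 10 vs 11, 50 vs 51, 100 vs 101
  expect_equal(as.character(plastmut:::size_class_indel(c(10, 11, 50, 51, 100, 101))),
               c("1-10", "11-50", "11-50", "51-100", "51-100", ">100"))
  # empty event list: all-zero summary
  s0 <- summarize_structural(ev[0, ])
  expect_true(all(s0$by_rank$count == 0L))
})
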